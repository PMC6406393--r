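#include <Rcpp.h>
using namespace Rcpp;

// Self-avoiding walk with fixed virtual-bond length and a persistence bias.
// Directions are drawn as normalize(kappa * previous + u) with u uniform on
// the unit sphere; kappa >= 0 stiffens the chain. Non-bonded residue pairs
// are kept at least min_sep apart (hard spheres). Uses R's RNG so set.seed()
// governs the output.

static bool chain_attempt(int L, double bond, double min_sep, double kappa,
                          NumericMatrix &xyz, int max_step_try) {
  const double ms2 = min_sep * min_sep;
  xyz(0, 0) = 0.0; xyz(0, 1) = 0.0; xyz(0, 2) = 0.0;
  double px = 0.0, py = 0.0, pz = 1.0;
  for (int i = 1; i < L; ++i) {
    bool placed = false;
    for (int tr = 0; tr < max_step_try; ++tr) {
      double ux = norm_rand(), uy = norm_rand(), uz = norm_rand();
      double un = sqrt(ux * ux + uy * uy + uz * uz);
      if (un < 1e-12) continue;
      ux /= un; uy /= un; uz /= un;
      double dx, dy, dz;
      if (i == 1) { dx = ux; dy = uy; dz = uz; }
      else {
        dx = kappa * px + ux; dy = kappa * py + uy; dz = kappa * pz + uz;
        double dn = sqrt(dx * dx + dy * dy + dz * dz);
        if (dn < 1e-12) continue;
        dx /= dn; dy /= dn; dz /= dn;
      }
      double cx = xyz(i - 1, 0) + bond * dx;
      double cy = xyz(i - 1, 1) + bond * dy;
      double cz = xyz(i - 1, 2) + bond * dz;
      bool clash = false;
      for (int j = 0; j <= i - 2; ++j) {
        double ex = cx - xyz(j, 0), ey = cy - xyz(j, 1), ez = cz - xyz(j, 2);
        if (ex * ex + ey * ey + ez * ez < ms2) { clash = true; break; }
      }
      if (!clash) {
        xyz(i, 0) = cx; xyz(i, 1) = cy; xyz(i, 2) = cz;
        px = dx; py = dy; pz = dz;
        placed = true;
        break;
      }
    }
    if (!placed) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".sawChain")]]
NumericMatrix saw_chain(int L, double bond, double min_sep, double kappa,
                        int max_step_try = 60, int max_restart = 1000) {
  NumericMatrix xyz(L, 3);
  for (int r = 0; r < max_restart; ++r)
    if (chain_attempt(L, bond, min_sep, kappa, xyz, max_step_try))
      return xyz;
  stop("self-avoiding walk failed after %d restarts", max_restart);
}
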