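---
title: "The PAGE4 phospho-circuit and its conformational ensembles: models and methods"
author: "page4dyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PAGE4 phospho-circuit and its conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(page4dyn)
```

# The circuit model

PAGE4 exists in three phospho-forms: wild-type (W), HIPK1-phosphorylated
(H) and CLK2 hyper-phosphorylated (C). HIPK1 double-phosphorylates W into
H at rate `k_H` (the HIPK1 kinase itself carries no known regulation in
this system, so it is absorbed into the rate constant); the CLK2 kinase
(K) converts H into C by mass action, `k_C * K * H`. H inhibits androgen
receptor activity (A) through c-Jun; since c-Jun has no independent
dynamics of its own here, that cascade is lumped into a single decreasing
Hill function. A in turn represses CLK2 expression. The closed loop
H ⊣ A ⊣ K, with K consuming H, is a three-stage negative feedback:

$$\begin{aligned}
\dot W &= g_W - k_H W - \delta_W W\\
\dot H &= k_H W - k_C K H - \delta_H H\\
\dot C &= k_C K H - \delta_C C\\
\dot K &= g_K\,\frac{1}{1+(A/A_0)^{n_A}} - \delta_K K\\
\dot A &= g_A\,\frac{1}{1+(H/H_0)^{n_H}}\,(1-u_{ADT}(t)) +
          \beta_{OE}\,u_{OE}(t) - \delta_A A
\end{aligned}$$

Concentrations are dimensionless; time is in hours. All production and
degradation is first-order apart from the bilinear kinase conversion.
Treatment enters in two places only: androgen deprivation multiplies AR
production by $(1-u_{ADT})$ (full ADT, $u_{ADT}=1$, silences it), and AR
overexpression adds a constant production $\beta_{OE} u_{OE}$.

Two modelling choices were genuinely open and are worth recording. First,
AR activity could have been treated as an instantaneous function of H; we
made it dynamical with its own relaxation rate $\delta_A$, because the
phase lag it contributes is part of what lets the loop oscillate, and a
finite AR response time is the physically conservative choice. Second,
with $u_{ADT}=1$ the model must only quench oscillations and settle on an
AI-like state (CLK2-PAGE4 above its untreated cycle average); we do not
impose a particular bifurcation structure on which fixed point becomes
stable.

## Why these parameters oscillate

A three-stage negative feedback with first-order stages obeys the secant
condition: the product of the logarithmic gains around the loop must
exceed $\sec^3(\pi/3) = 8$ at the fixed point, and the bound is easiest to
meet when the three effective relaxation rates are equal. With Hill
coefficients $n_H = n_A = 4$ (the steepness a lumped multi-step cascade
can plausibly supply; lower coefficients such as 1–2 cannot satisfy the
condition in this topology), each Hill stage contributes a gain of at
most 4, and the K-mediated degradation stage contributes
$k_C K/(k_C K + \delta_H) < 1$. The reference parameter shape therefore
places the fixed point on the steep flank of both Hill curves (the
thresholds $H_0 = 0.1155$ and $A_0 = 0.0577$ sit below the respective
fixed-point levels) and equalizes the effective degradation rates of H, A
and K, giving a loop gain comfortably above 8.

## Calibration

Two anchors define the default parameter set: the WT-PAGE4 half-life of
150 h ($\delta_W = \ln 2/150$, held exactly) and a target limit-cycle
period of one week (168 h). `calibrateDefaultParams()` multiplies every
rate except $\delta_W$ by a single global time-scale factor $s$ — this
preserves the dimensionless fixed-point structure (and hence the secant
condition) while stretching the clock — and searches $s$ over the grid
0.30–1.00 in steps of 0.05 in ascending order. The first grid point whose
untreated attractor oscillates within ±10 % of the target period seeds a
secant refinement to within ±1 %. Ties cannot arise: the first hit in
grid order wins. The refined set is cached in `inst/params/default.yaml`
and served by `defaultCircuitParams()`; with the period anchor disabled
(`target_period = Inf`) the unscaled reference shape is returned and a
stable fixed point is acceptable.

## Integration

`simulateCircuit()` uses `deSolve::lsoda` (adaptive, stiff-capable) with
relative tolerance 1e-8 and absolute tolerance 1e-10, sampling dense
output every 0.5 h by default. Protocols are honored exactly by
integrating segment by segment between treatment switch points rather
than letting the integrator step across discontinuities. Non-negativity
of all species follows from the dynamics (every loss term vanishes with
its species); no clipping is applied, and trajectories are validated
against a floor of −1e-9 to catch integrator pathologies. The test suite
cross-checks the adaptive integrator against an independently written
fixed-step RK4 oracle (dt = 0.01 h over 2000 h) to 1e-4 relative error.

# Treatment protocols

Protocols are ordered lists of contiguous half-open segments
$[t_{start}, t_{end})$ carrying $(u_{ADT}, u_{OE})$; the final segment
extends to infinity so any simulation span is covered, and lookups use
binary search. Half-open intervals make step placement unambiguous: at
the boundary the new segment applies. "Two weeks" is fixed at 336 h.
Intermittent ADT defaults to 168 h on / 168 h off — the published
protocol figures state durations only in weeks, so one week on, one week
off is our configurable default — and bipolar androgen treatment (BAT)
alternates 336 h of AR overexpression with 336 h of full ADT.

# Cohorts, heterogeneity and synchronization

A cohort is a population of non-interacting cells sharing one parameter
set; the only heterogeneity source is the initial oscillation phase,
drawn uniformly on the untreated limit cycle
(`sampleInitialConditions()`, deterministic given a seed). No cell
division, death or communication is modelled, so post-treatment
homogenization reflects phase dynamics alone — in reality
therapy-induced apoptosis would additionally select among cells.

Population spread is summarized by the coefficient of variation using
the population (divide-by-n) standard deviation, so small hand-checkable
examples are exact. Phase synchronization uses a Kuramoto-style order
parameter: each cell's phase is the angle of its $(H, C)$ displacement
from the limit-cycle centroid, and $R = |\langle e^{i\phi}\rangle|$.
The geometric phase avoids spectral estimation and is well defined
whenever cells are off-centroid; it is the package's metric of record
for the synchronization that intermittent ADT and BAT induce (the
original report shows four example cells without a quantitative
synchrony measure). Phenotypes are classified against the limit-cycle
midranges: AD requires H above and C below its midrange, AI the
opposite, and boundary cases are indeterminate.

# Oscillation analysis

`detectPeriod()` finds local maxima after a burn-in whose topographic
prominence is at least 5 % of the post-burn-in range; the period is the
mean successive peak spacing, and a trajectory counts as oscillating
with at least three peaks and a peak-to-peak amplitude of at least 1 %
of the mean. Fewer than three peaks yields a flagged non-oscillating
summary, not an error. `quenchTime()` reports the first time after
treatment onset at which the peak-to-peak range inside a sliding window
of one pre-treatment period falls below 5 % of the pre-treatment
amplitude, with an infinite sentinel when that never happens. The
"quenched" state in the source figures is visual; the 5 % amplitude
criterion and one-period window are fixed here for reproducibility.
Period estimation is deliberately peak-based (no FFT/Lomb–Scargle):
relaxation oscillations are strongly anharmonic and peak spacing is the
quantity of interest.

# Synthetic conformational ensembles

The generator is an emulator, not a force field: it produces Cα chains
whose ensemble statistics carry the qualitative signatures that the
structural metrics are designed to detect. Conformers are independent
draws (no kinetics, no temperature), so autocorrelation analyses do not
apply to its output.

Each conformer is a self-avoiding random walk of 102 residues with fixed
3.8 Å virtual bonds and hard-sphere residue radius 2.0 Å (non-bonded
centers at least 4.0 Å apart). Successive directions are drawn as
$\hat d_{i+1} \propto \kappa\,\hat d_i + \hat u$ with $\hat u$ uniform on
the sphere and $\kappa = \text{expansion} - 1$: at expansion 1 the chain
is maximally flexible, larger values stiffen and expand it. Loop
restraints place the centroid of a terminal motif within 9 Å of the
centroid of the central acidic region (residues 43–62) and are enforced
by rejection sampling of whole chains — slower than biased growth but
trivially correct, and affordable at this chain length; a conformer
errors out after 10⁴ failed attempts.

The three presets are calibration knobs of the emulator (the source
reports "non-zero probabilities of contacts", not occupancies, so the
numbers are free parameters chosen once): WT forms the N-loop in 60 % of
conformers; HIPK1 forms the N- or C-loop in 45 % each, mutually
exclusive, so the two looping motions are anti-correlated by
construction; CLK2 forms no loops and expands with factor 1.8. What the
presets do *not* emulate: real excluded-volume statistics beyond hard
spheres, sequence-specific interactions, secondary structure, solvent,
or the absolute sizes of the real ensembles — consequently passing tests
demonstrate that the metrics detect the intended signatures, not that
the generator reproduces PAGE4's actual ensembles, and the published
absolute radii of gyration are out of reach by design.

# Structural metrics

* **Radius of gyration** is the unweighted RMS distance to the centroid;
  free-energy profiles are $F = -k_B T\log P$ over equal-width histogram
  bins with $k_B T = 1$ (dimensionless) by default, shifted to zero
  minimum, with empty bins masked as `NA` rather than infinities.
* **Contact maps** use a 9.5 Å Cα–Cα cutoff with sequence separation
  $|i-j| \ge 3$ (a standard coarse-grained convention; the source's
  "close spatial proximity" is unquantified), both configurable.
* **Contact-based PCA** encodes each conformer as a binary contact
  vector over retained pairs (whether the original analysis used binary
  or weighted contacts is unstated; binary is chosen and stated), and
  eigen-decomposes the pair-space covariance (divide-by-(n−1)) via SVD
  of the centered contact matrix — equivalent to the explicit covariance
  eigen-decomposition, which the tests verify to 1e-8 on toy ensembles.
  Modes are orthonormal and deterministic up to sign; the sign is fixed
  by making each mode's largest-magnitude coefficient positive.
* **Turn propensity** replaces secondary-structure assignment, which
  needs backbone atoms unavailable in Cα-only ensembles, with a
  geometric criterion: residue $i$ is turn-like when $d(i, i+3) < 7$ Å
  and both internal virtual-bond angles are below 150° (excluding
  near-collinear stretches). The first and last three residues are
  reported missing.

# Problem sizes and determinism

Default analysis sizes are chosen to keep every quantity's sampling
error well below the margins the qualitative claims rest on: single-cell
trajectories of 6000 h (about 30 untreated cycles), cohorts of 200–1000
cells, and 200–300 conformers per preset. The headline script
`scripts/acceptance.R` uses 1000 cells for the homogenization claim and
300 conformers per preset. Every stochastic entry point takes an
explicit integer seed (default 42) and restores the caller's RNG state;
equal seeds give byte-identical ensembles and identical pipeline
summaries.

# Known limitations

* Rates other than $\delta_W$ are calibrated, not measured; only the
  two anchors and the qualitative behaviors are load-bearing.
* The cohort model omits proliferation and death, so treatment
  "homogenization" is purely dynamical.
* The ensemble emulator's preset numbers (0.6, 0.45/0.45, 1.8) are
  tuning choices; analyses of its output support only qualitative
  orderings and signature detection.
* The Kuramoto phase is undefined exactly at the cycle centroid; cells
  quenched precisely onto the centroid would need a different phase
  convention (in practice the ADT attractor lies well off-centroid).
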