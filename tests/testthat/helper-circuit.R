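# Independent fixed-step RK4 integrator over the circuit equations, written
# out directly from the model definition (does not call the package's rate
# code). Treatment signals are constants here; used as the oracle for the
# adaptive integrator.
rk4Circuit <- function(params, init, tEnd, dt = 0.01, outEvery = 50L,
                       uADT = 0, uOE = 0) {
  v <- paramsVector(params)
  g_W <- v[["g_W"]]; k_H <- v[["k_H"]]; k_C <- v[["k_C"]]
  dW <- v[["delta_W"]]; dH <- v[["delta_H"]]; dC <- v[["delta_C"]]
  dK <- v[["delta_K"]]; dA <- v[["delta_A"]]
  g_A <- v[["g_A"]]; g_K <- v[["g_K"]]
  H0 <- v[["H0"]]; nH <- v[["n_H"]]; A0 <- v[["A0"]]; nA <- v[["n_A"]]
  bOE <- v[["beta_OE"]]
  f <- function(y) {
    conv <- k_C * y[4L] * y[2L]
    c(g_W - (k_H + dW) * y[1L],
      k_H * y[1L] - conv - dH * y[2L],
      conv - dC * y[3L],
      g_K / (1 + (y[5L] / A0)^nA) - dK * y[4L],
      g_A / (1 + (y[2L] / H0)^nH) * (1 - uADT) + bOE * uOE - dA * y[5L])
  }
  nSteps <- round(tEnd / dt)
  y <- unname(init[c("W", "H", "C", "K", "A")])
  nOut <- nSteps %/% outEvery
  out <- matrix(NA_real_, nOut + 1L, 5L,
                dimnames = list(NULL, c("W", "H", "C", "K", "A")))
  times <- numeric(nOut + 1L)
  out[1L, ] <- y
  r <- 2L
  for (s in seq_len(nSteps)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (s %% outEvery == 0L) {
      out[r, ] <- y
      times[r] <- s * dt
      r <- r + 1L
    }
  }
  list(times = times, states = out)
}

# Trajectory carrying an arbitrary signal in the H column (other species
# held at a positive constant), for exercising the oscillation analysis.
signalTrajectory <- function(times, x) {
  states <- matrix(1, length(times), 5L,
                   dimnames = list(NULL, c("W", "H", "C", "K", "A")))
  states[, "H"] <- x
  new("Trajectory", times = times, states = states, paramsId = "synthetic",
      protocolId = "synthetic")
}

# CohortResult with prescribed (H, C) positions at a single time point,
# for exercising the phase/CV summaries in isolation.
pointCohort <- function(H, C, center = c(H = 1, C = 1)) {
  n <- length(H)
  states <- array(1, dim = c(n, 1L, 5L),
                  dimnames = list(NULL, NULL, c("W", "H", "C", "K", "A")))
  states[, 1L, "H"] <- H
  states[, 1L, "C"] <- C
  new("CohortResult", nCells = as.integer(n), seed = 0L, times = 0,
      states = states, protocolId = "manual", cycleCenter = center,
      cycleMid = c(h_mid = 1, c_mid = 1))
}

# Independent root-find of the no-treatment fixed point. At steady state W,
# A, K and C are explicit functions of H, leaving a single scalar equation
# for H solved by uniroot; does not touch the integrator.
circuitFixedPoint <- function(params, hMax = 10) {
  v <- paramsVector(params)
  Wstar <- v[["g_W"]] / (v[["k_H"]] + v[["delta_W"]])
  Astar <- function(H)
    v[["g_A"]] * hillInhibition(H, v[["H0"]], v[["n_H"]]) / v[["delta_A"]]
  Kstar <- function(H)
    v[["g_K"]] * hillInhibition(Astar(H), v[["A0"]], v[["n_A"]]) /
      v[["delta_K"]]
  resid <- function(H)
    v[["k_H"]] * Wstar - v[["k_C"]] * Kstar(H) * H - v[["delta_H"]] * H
  H <- stats::uniroot(resid, c(1e-12, hMax), tol = 1e-14)$root
  K <- Kstar(H)
  c(W = Wstar, H = H, C = v[["k_C"]] * K * H / v[["delta_C"]], K = K,
    A = Astar(H))
}
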