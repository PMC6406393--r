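test_that("Hill inhibition has the exact closed form and rejects bad input", {
  expect_identical(hillInhibition(0, 1, 4), 1)
  expect_equal(hillInhibition(1, 1, 4), 0.5)
  expect_equal(hillInhibition(3, 3, 7), 0.5)
  expect_equal(hillInhibition(2, 1, 4), 1 / 17)
  x <- seq(0, 5, 0.1)
  expect_true(all(diff(hillInhibition(x, 0.7, 4)) <= 0))
  expect_error(hillInhibition(1, 0, 4), "x0")
  expect_error(hillInhibition(1, 1, 0.5), "n")
  expect_error(hillInhibition(-1, 1, 4), "non-negative")
})

test_that("parameter validity permits zero rates but not negative ones", {
  expect_s4_class(circuitParams(g_K = 0, delta_K = 0), "CircuitParams")
  expect_error(circuitParams(g_W = -1), "non-negative")
  expect_error(circuitParams(H0 = 0), "H0")
  expect_error(circuitParams(n_H = 0.5), "n_H")
})

test_that("derivatives reduce to isolated decay and forced AR suppression", {
  pd <- circuitParams(g_W = 0, k_H = 0, k_C = 0, delta_H = 0, delta_C = 0,
                      g_A = 0, g_K = 0, beta_OE = 0, delta_W = log(2) / 150)
  d <- circuitDerivatives(circuitState(W = 1), 0, pd)
  expect_equal(unname(d["W"]), -log(2) / 150)
  expect_equal(unname(d[c("H", "C", "K")]), c(0, 0, 0))

  # full ADT with no overexpression: AR production term vanishes entirely
  p <- defaultCircuitParams()
  s <- circuitState(W = 1, H = 0.2, C = 0.3, K = 0.4, A = 0.7)
  d <- circuitDerivatives(s, 10, p, constantADT(0, 1))
  expect_equal(unname(d["A"]), -slot(p, "delta_A") * 0.7)

  expect_error(circuitDerivatives(c(W = -1, H = 0, C = 0, K = 0, A = 0),
                                  0, p), "non-negative")
})

test_that("total production balances total loss at the fixed point", {
  p <- defaultCircuitParams()
  fp <- circuitFixedPoint(p)
  d <- circuitDerivatives(fp, 0, p)
  expect_lt(max(abs(d)), 1e-8)
  # conversion fluxes cancel in the species sum: production == degradation
  v <- paramsVector(p)
  production <- v[["g_W"]] + v[["g_A"]] * hillInhibition(fp[["H"]],
                                                        v[["H0"]],
                                                        v[["n_H"]]) +
    v[["g_K"]] * hillInhibition(fp[["A"]], v[["A0"]], v[["n_A"]])
  loss <- v[["delta_W"]] * fp[["W"]] + v[["delta_H"]] * fp[["H"]] +
    v[["delta_C"]] * fp[["C"]] + v[["delta_K"]] * fp[["K"]] +
    v[["delta_A"]] * fp[["A"]]
  expect_lt(abs(production - loss), 1e-8)
})

test_that("isolated WT-PAGE4 decay hits its 150 h half-life", {
  pd <- circuitParams(g_W = 0, k_H = 0, k_C = 0, delta_H = 0, delta_C = 0,
                      g_A = 0, g_K = 0, beta_OE = 0, delta_W = log(2) / 150)
  tr <- simulateCircuit(pd, noTreatment(), circuitState(W = 1), c(0, 300))
  W <- speciesSeries(tr, "W")
  tt <- timePoints(tr)
  expect_lt(abs(W[tt == 150] - 0.5), 1e-6)
  # full closed form e^(-ln2 t / 150) along the way
  expect_lt(max(abs(W - 2^(-tt / 150))), 1e-6)
})

test_that("with zero production every species drains to zero", {
  p0 <- circuitParams(g_W = 0, g_A = 0, g_K = 0, beta_OE = 0)
  tr <- simulateCircuit(p0, noTreatment(),
                        circuitState(W = 1, H = 1, C = 1, K = 1, A = 1),
                        c(0, 6000))
  st <- speciesMatrix(tr)
  expect_true(all(st[nrow(st), ] < 1e-3))
  # the source species decays monotonically; downstream species may rise
  # transiently from conversion flux but the total mass never grows
  expect_true(all(diff(st[, "W"]) <= 1e-12))
  expect_true(all(diff(rowSums(st)) <= 1e-9))
})

test_that("default calibrated parameters sustain a week-scale oscillation", {
  p <- defaultCircuitParams()
  expect_equal(slot(p, "delta_W"), log(2) / 150)
  tr <- simulateCircuit(p, noTreatment(), tSpan = c(0, 6000))
  osc <- detectPeriod(tr, "H", burnIn = 1000)
  expect_true(osc@isOscillating)
  H <- speciesSeries(tr, "H")[timePoints(tr) > 1000]
  expect_gt(osc@amplitude, 0.1 * mean(H))
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle", {
  p <- defaultCircuitParams()
  init <- circuitState(W = 1, H = 0.05, C = 0.1, K = 0.05, A = 0.5)
  tr <- simulateCircuit(p, noTreatment(), init, c(0, 2000), outputDt = 0.5)
  oracle <- rk4Circuit(p, init, 2000, dt = 0.01, outEvery = 50L)
  idx <- match(oracle$times, timePoints(tr))
  expect_false(anyNA(idx))
  for (sp in c("W", "H", "C", "K", "A")) {
    a <- speciesMatrix(tr)[idx, sp]
    b <- oracle$states[, sp]
    expect_lt(max(abs(a - b)) / max(abs(b)), 1e-4)
  }
})

test_that("trajectories stay non-negative across random parameters and states", {
  base <- paramsVector(defaultCircuitParams())
  withr::with_seed(1301, {
    for (rep in 1:5) {
      v <- base
      jitter <- stats::runif(length(v), 0.5, 2)
      names(jitter) <- names(v)
      jitter[c("n_H", "n_A")] <- 1  # keep coefficients at their design value
      v <- v * jitter
      p <- do.call(circuitParams, as.list(v))
      init <- circuitState(W = stats::runif(1, 0, 2), H = stats::runif(1, 0, 2),
                           C = stats::runif(1, 0, 2), K = stats::runif(1, 0, 2),
                           A = stats::runif(1, 0, 2))
      tr <- simulateCircuit(p, noTreatment(), init, c(0, 1500))
      expect_gt(min(speciesMatrix(tr)), -1e-9)
    }
  })
})

test_that("freezing the CLK2 kinase (feedback ablation) kills the oscillation", {
  p <- defaultCircuitParams()
  tr <- simulateCircuit(p, noTreatment(), tSpan = c(0, 5000))
  Kbar <- mean(speciesMatrix(tr)[timePoints(tr) > 2000, "K"])
  v <- paramsVector(p)
  v[c("g_K", "delta_K")] <- 0  # dK/dt == 0: K pinned at its initial value
  pAblated <- do.call(circuitParams, as.list(v))
  trA <- simulateCircuit(pAblated, noTreatment(),
                         circuitState(W = 1, H = 0.05, C = 0.1, K = Kbar,
                                      A = 0.5), c(0, 6000))
  H <- speciesSeries(trA, "H")[timePoints(trA) > 5000]
  expect_lt(diff(range(H)), 0.01 * mean(H))
})

test_that("time-averaged AR activity decreases with ADT efficacy", {
  p <- defaultCircuitParams()
  meanA <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(u) {
    tr <- simulateCircuit(p, constantADT(0, u), tSpan = c(0, 6000))
    mean(speciesSeries(tr, "A")[timePoints(tr) > 3000])
  }, numeric(1))
  expect_true(all(diff(meanA) <= 1e-9))
})

test_that("calibration reproduces the target period and honors its anchors", {
  p <- calibrateDefaultParams()
  expect_equal(slot(p, "delta_W"), log(2) / 150)
  osc <- detectPeriod(simulateCircuit(p, noTreatment(), tSpan = c(0, 9000)),
                      "H", 3000)
  expect_true(osc@isOscillating)
  expect_gte(osc@period, 151.2)
  expect_lte(osc@period, 184.8)
  # disabled period anchor returns the reference shape (fixed point allowed)
  pInf <- calibrateDefaultParams(anchors = list(half_life_W = 150,
                                                target_period = Inf))
  expect_s4_class(pInf, "CircuitParams")
  expect_equal(slot(pInf, "delta_W"), log(2) / 150)
})
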