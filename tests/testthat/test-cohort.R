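test_that("sampled initial conditions are deterministic and lie on the cycle", {
  p <- defaultCircuitParams()
  cyc <- limitCycle(p)
  a <- sampleInitialConditions(p, 5L, seed = 11L, cycle = cyc)
  b <- sampleInitialConditions(p, 5L, seed = 11L, cycle = cyc)
  expect_identical(a, b)

  # a single sampled state sits on a densely recomputed cycle (max-norm)
  dense <- limitCycle(p, outputDt = 0.05)
  s <- sampleInitialConditions(p, 1L, seed = 3L, cycle = cyc)
  gap <- min(apply(dense$states, 1L, function(row) max(abs(row - s[1L, ]))))
  expect_lt(gap, 1e-3)
})

test_that("sampled phases are uniform on the period", {
  p <- defaultCircuitParams()
  cyc <- limitCycle(p)
  s <- sampleInitialConditions(p, 10000L, seed = 5L, cycle = cyc)
  phases <- attr(s, "phases")
  ks <- suppressWarnings(stats::ks.test(phases, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("fixed-point-only dynamics refuse to seed a cohort", {
  # shallow Hill curves cannot sustain the relaxation oscillation
  pFlat <- circuitParams(n_H = 1, n_A = 1)
  expect_error(limitCycle(pFlat, burnIn = 1500, tEnd = 3000),
               "no limit cycle")
})

test_that("a one-cell cohort reproduces the single-cell simulation", {
  p <- defaultCircuitParams()
  ch <- simulateCohort(p, constantADT(0), 1L, seed = 9L, tSpan = c(0, 200))
  init <- sampleInitialConditions(p, 1L, seed = 9L)
  tr <- simulateCircuit(p, constantADT(0), init[1L, ], c(0, 200))
  expect_equal(unname(ch@states[1L, , ]), unname(speciesMatrix(tr)),
               tolerance = 1e-10)
})

test_that("cohorts from disjoint seeds are statistically indistinguishable", {
  p <- defaultCircuitParams()
  cyc <- limitCycle(p)
  a <- sampleInitialConditions(p, 1000L, seed = 21L, cycle = cyc)
  b <- sampleInitialConditions(p, 1000L, seed = 22L, cycle = cyc)
  ks <- suppressWarnings(stats::ks.test(a[, "K"], b[, "K"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("population CV follows the population-sd convention", {
  ch <- pointCohort(H = c(1, 1, 1), C = c(2, 2, 2))
  # all cells identical: zero CV for any species
  expect_equal(populationCV(ch, "H", 0), 0)
  ch2 <- pointCohort(H = c(1, 3), C = c(1, 1))
  expect_equal(populationCV(ch2, "H", 0), 0.5)  # sd_pop([1,3]) / 2 = 1/2
  ch0 <- pointCohort(H = c(0, 0), C = c(1, 1))
  expect_error(populationCV(ch0, "H", 0), "zero mean")
})

test_that("the order parameter hits its closed-form reference cases", {
  # identical phases
  ch <- pointCohort(H = c(2, 2, 2), C = c(1, 1, 1), center = c(H = 1, C = 1))
  expect_equal(syncOrderParameter(ch, 0), 1)
  # two antipodal cells cancel
  ch <- pointCohort(H = c(2, 0), C = c(1, 1), center = c(H = 1, C = 1))
  expect_lt(syncOrderParameter(ch, 0), 1e-12)
  # uniform phases on the circle
  th <- 2 * pi * (seq_len(10000L) - 1) / 10000L
  ch <- pointCohort(H = 1 + cos(th), C = 1 + sin(th), center = c(H = 1, C = 1))
  expect_lt(syncOrderParameter(ch, 0), 0.05)
  # degenerate: everyone at the centroid
  ch <- pointCohort(H = c(1, 1), C = c(1, 1), center = c(H = 1, C = 1))
  expect_error(syncOrderParameter(ch, 0), "undefined phase")
})

test_that("phenotype classification follows the H/C quadrant rules", {
  expect_identical(classifyPhenotype(c(H = 2, C = 0), 1, 1), "AD")
  expect_identical(classifyPhenotype(c(H = 0, C = 2), 1, 1), "AI")
  expect_identical(classifyPhenotype(c(H = 1, C = 1), 1, 1), "indeterminate")
  expect_identical(classifyPhenotype(c(H = 2, C = 2), 1, 1), "indeterminate")
  m <- rbind(c(H = 2, C = 0.1), c(H = 0.1, C = 2))
  expect_identical(classifyPhenotype(m, 1, 1), c("AD", "AI"))
})

test_that("cell order does not affect cohort summaries", {
  p <- defaultCircuitParams()
  ch <- simulateCohort(p, constantADT(0), 20L, seed = 4L, tSpan = c(0, 100))
  perm <- withr::with_seed(1, sample(20L))
  chPerm <- ch
  chPerm@states <- ch@states[perm, , , drop = FALSE]
  for (t in c(0, 50, 100)) {
    expect_equal(populationCV(chPerm, "K", t), populationCV(ch, "K", t))
    expect_equal(syncOrderParameter(chPerm, t), syncOrderParameter(ch, t))
  }
})

test_that("untreated cohorts keep a stationary CLK2 spread", {
  p <- defaultCircuitParams()
  ch <- simulateCohort(p, noTreatment(), 200L, seed = 13L, tSpan = c(0, 400))
  cvs <- vapply(c(0, 100, 200, 300, 400),
                function(t) populationCV(ch, "K", t), numeric(1))
  expect_lt(max(cvs) - min(cvs), 0.05)
})

test_that("constant full ADT drives the order parameter towards one", {
  p <- defaultCircuitParams()
  ch <- simulateCohort(p, constantADT(0), 50L, seed = 17L, tSpan = c(0, 504))
  r <- vapply(c(0, 168, 336, 504), function(t) syncOrderParameter(ch, t),
              numeric(1))
  expect_gt(r[4L], 0.95)  # within three weeks
  expect_true(all(diff(r) > -0.05))
})
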