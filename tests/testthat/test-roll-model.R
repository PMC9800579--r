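test_that("parameter validation rejects non-physical values", {
  expect_error(rollModelParams(kc = -1e-19), "positive")
  expect_error(rollModelParams(c0 = 0), "positive")
  expect_s4_class(rollModelParams("methods"), "RollModelParams")
  expect_equal(rollModelParams("methods")@kc, 4.0e-20)
  expect_equal(rollModelParams()@kc, 1.0e-19)
})

test_that("energy profile starts at zero and converges under grid refinement", {
  p <- refParams()
  ep <- energyProfile(p, lMax = 1e-4, nPoints = 2001)
  expect_identical(ep@energyPerWidth[1], 0)
  # quadrature convergence: doubling the grid changes dE by < 0.01 %
  e1 <- energyProfile(p, 1e-4, 4001)@energyPerWidth
  e2 <- energyProfile(p, 1e-4, 8001)@energyPerWidth
  expect_lt(abs(e2[8001] - e1[4001]) / abs(e1[4001]), 1e-4)
})

test_that("energy profile matches an independent fine-grid quadrature oracle", {
  # oracle: plain trapezoid integration of the same physics written from
  # scratch with the thin-pitch length-radius mapping
  p <- refParams()
  lMax <- 1e-4
  L <- seq(0, lMax, length.out = 40001)
  r <- sqrt(p@r0^2 + p@b * L / pi)
  g <- (p@kc / 2) * ((1 / r - p@c0)^2 - p@c0^2) + p@wad
  oracle <- c(0, cumsum(diff(L) * (g[-1] + g[-length(g)]) / 2))
  ep <- energyProfile(p, lMax, 10001)
  at <- seq(1, 40001, by = 4)           # shared grid points
  expect_lt(max(abs(ep@energyPerWidth - oracle[at])) /
              max(abs(oracle)), 1e-3)
})

test_that("thin-pitch fast path agrees with the exact spiral mapping", {
  p <- refParams()
  eEx <- energyProfile(p, 1e-4, 2001, mapping = "exact")@energyPerWidth
  eAp <- energyProfile(p, 1e-4, 2001, mapping = "thin-pitch")@energyPerWidth
  expect_lt(max(abs(eEx - eAp)) / max(abs(eEx)), 0.01)
})

test_that("marginal conditions give zero rolled length", {
  # adhesion equal to the maximal curvature-energy gain: no rolling
  p <- rollModelParams(wad = 0.5 * 1e-19 * (3.33e7)^2)
  expect_identical(rolledLength(p), 0)
  p2 <- rollModelParams(wad = 1e-4)   # above the gain
  expect_identical(rolledLength(p2), 0)
})

test_that("rolled length is monotone in adhesion and curvature and scale-invariant", {
  p <- refParams()
  sw <- sweepAdhesion(p, factors = c(1, 2, 3, 5, 8))
  expect_true(all(diff(sw@rolledLengths) <= 0))
  swc <- sweepSpontaneousCurvature(p, fractions = c(0.3, 0.5, 0.7, 0.9, 1))
  expect_true(all(diff(swc@rolledLengths) >= 0))
  # scaling (kc, wad) together leaves L* unchanged (dimensional consistency)
  p2 <- rollModelParams(kc = p@kc * 7.3, wad = p@wad * 7.3)
  expect_equal(rolledLength(p2), rolledLength(p), tolerance = 1e-12)
  # vanishing adhesion lets the roll grow without bound
  expect_gt(rolledLength(rollModelParams(wad = 1e-9)), 0.01)
})

test_that("rolled length equals the brute-force minimizer of the energy profile", {
  p <- refParams()
  lStar <- rolledLength(p)
  # dense-grid minimization over [0, 1 mm]
  ep <- energyProfile(p, 1e-3, 1e6 + 1)
  i <- which.min(ep@energyPerWidth)
  expect_lt(abs(ep@lengths[i] - lStar), diff(ep@lengths[1:2]) * 1.5)

  # property over random parameter sets within x/÷10 of the reference
  set.seed(42)
  for (k in 1:100) {
    q <- rollModelParams(
      kc = p@kc * 10^runif(1, -1, 1), c0 = p@c0 * 10^runif(1, -1, 1),
      wad = p@wad * 10^runif(1, -1, 1), b = p@b * 10^runif(1, -1, 1))
    q@r0 <- 1 / q@c0
    ls <- rolledLength(q)
    lMax <- max(4 * ls, 1e-5)
    epq <- energyProfile(q, lMax, 20001)
    j <- which.min(epq@energyPerWidth)
    expect_lt(abs(epq@lengths[j] - ls), diff(epq@lengths[1:2]) * 1.5)
  }
})

test_that("adhesion sweep brackets and refines the critical factor", {
  p <- refParams()
  sw <- sweepAdhesion(p, factors = seq(1, 10, by = 0.5))
  cf <- criticalFactor(sw)
  expect_false(is.na(cf))
  # the refined factor indeed pins L* to the resolution limit
  pc <- p; pc@wad <- p@wad * cf
  expect_equal(rolledLength(pc), 1e-6, tolerance = 1e-3)
  # identity sweep
  sw1 <- sweepAdhesion(p, factors = 1)
  expect_equal(sw1@rolledLengths, rolledLength(p))
  expect_true(is.na(criticalFactor(sw1)))
  expect_error(sweepAdhesion(p, numeric(0)), "non-empty")
})

test_that("curvature sweep reports the largest fraction at the limit", {
  p <- refParams()
  swc <- sweepSpontaneousCurvature(p, fractions = seq(0.3, 1, by = 0.01))
  cf <- criticalFactor(swc)
  expect_false(is.na(cf))
  pc <- p; pc@c0 <- p@c0 * cf; pc@r0 <- 1 / pc@c0
  expect_equal(rolledLength(pc), 1e-6, tolerance = 1e-3)
  expect_error(sweepSpontaneousCurvature(p, c(0.5, 1.2)), "\\(0, 1\\]")
  # fixed-r0 convention is also accepted
  swf <- sweepSpontaneousCurvature(p, fractions = seq(0.3, 1, by = 0.05),
                                   r0Convention = "fixed")
  expect_s4_class(swf, "SweepResult")
})

test_that("model parameters round-trip through YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("preset: methods", "w_ad: 2.0e-5"), yml)
  p <- readModelParams(yml)
  expect_equal(p@kc, 4.0e-20)
  expect_equal(p@wad, 2.0e-5)
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(k_c = 5e-20, c0 = 2e7, w_ad = 1e-5, b = 2.1e-9),
                       js, auto_unbox = TRUE, digits = NA)
  q <- readModelParams(js)
  expect_equal(q@kc, 5e-20)
  expect_equal(q@r0, 1 / 2e7)
})
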