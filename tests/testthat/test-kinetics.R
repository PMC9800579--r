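test_that("a static stack yields zero incremental area", {
  st <- shrinkingDiscStack(rep(30, 6))
  tr <- incrementalRolledArea(st, cutoff = 0.5)
  expect_true(all(tr@incrementalArea == 0))
  expect_true(all(tr@cumulativeArea == 0))
})

test_that("a shrinking disc recovers the analytic annulus areas", {
  radii <- seq(40, 10, by = -5)
  px <- 0.5
  st <- shrinkingDiscStack(radii, dim = 128L, pixelSize = px)
  tr <- incrementalRolledArea(st, cutoff = 0.5, medianFilter = FALSE)
  analytic <- pi * (radii[-length(radii)]^2 - radii[-1]^2) * px^2
  # agreement within 2 pixel-rows of boundary discretization
  tol <- 2 * 2 * pi * radii[-length(radii)] * px^2
  expect_true(all(abs(tr@incrementalArea - analytic) < tol))
  expect_equal(tr@cumulativeArea, cumsum(tr@incrementalArea))
})

test_that("logistic fit is exact on noiseless traces across time constants", {
  for (tau in c(1, 5, 20, 100)) {
    tr <- logisticTrace(tau, t0 = 5 * tau, A = 400)
    fit <- fitLogistic(tr)
    expect_lt(abs(rollTau(fit) - tau) / tau, 1e-3)
    expect_lt(abs(fit@t0 - 5 * tau) / (5 * tau), 1e-3)
    expect_lt(abs(rollAmplitude(fit) - 400) / 400, 1e-3)
    expect_lte(rollOnset(fit), fit@t0)
  }
})

test_that("logistic fit recovers tau from noisy traces", {
  set.seed(7)
  taus <- replicate(20, {
    tr <- logisticTrace(8, t0 = 40, A = 400, tEnd = 90, dt = 0.25)
    noisy <- list(times = tr@times,
                  cumulative = tr@cumulativeArea +
                    rnorm(length(tr@times), 0, 20))   # sigma = 5 % of A
    rollTau(fitLogistic(noisy))
  })
  expect_lt(abs(mean(taus) - 8) / 8, 0.05)
})

test_that("degenerate traces raise a fit-failure condition with diagnostics", {
  flat <- new("RollingTrace", times = 1:10, incrementalArea = rep(0, 10),
              cumulativeArea = rep(0, 10))
  err <- tryCatch(fitLogistic(flat), patchRoll_fitFailure = identity)
  expect_s3_class(err, "patchRoll_fitFailure")
  expect_true(is.list(err$diagnostics))
})

test_that("onset time is stable when the noise level doubles", {
  on <- sapply(c(0.05, 0.1), function(ns) {
    g <- genRollingMovie(patchRadius = 12, tau = 8, onset = 16,
                         noiseSigma = ns, pixelSize = 0.32,
                         frameInterval = 1, dim = 96L, seed = 31)
    rollOnset(fitLogistic(incrementalRolledArea(g$stack)))
  })
  expect_lt(abs(on[2] - on[1]), 1)    # < 1 frame interval
})

test_that("relative area increase tracks linear growth and stays flat without it", {
  g <- genUnrollingMovie(initialArea = 120, growth = 0.008, duration = 80,
                         noiseSigma = 0.05, dim = 192L, seed = 3)
  ut <- relativeAreaIncrease(g$stack)
  expect_identical(ut@relativeArea[1], 1)
  slope <- coef(lm(ut@relativeArea ~ ut@times))[2]
  expect_lt(abs(slope - 0.008) / 0.008, 0.03)
  # fully crosslinked patch: no growth beyond binarization jitter
  g0 <- genUnrollingMovie(initialArea = 120, growth = 0, duration = 80,
                          noiseSigma = 0.05, dim = 192L, seed = 4)
  ut0 <- relativeAreaIncrease(g0$stack)
  expect_lt(max(abs(ut0@relativeArea - 1)), 0.02)
  # static noiseless stack is exactly flat
  st <- shrinkingDiscStack(rep(30, 5))
  expect_true(all(relativeAreaIncrease(st, cutoff = 0.5)@relativeArea == 1))
  # duration truncation
  expect_lte(max(relativeAreaIncrease(g$stack, duration = 40)@times), 40)
})

test_that("line profiles localize a protein rim on the dye edge", {
  dim <- 96L
  ctr <- (dim + 1) / 2
  xi <- matrix(seq_len(dim), dim, dim) - ctr
  r <- sqrt(xi^2 + t(xi)^2)
  dye <- 0.1 + 0.9 * (r <= 30)
  rim <- 0.05 + 0.95 * (abs(r - 30) <= 1.5)
  arr <- array(0, c(dim, dim, 2, 2))
  arr[, , 1, 1] <- dye; arr[, , 1, 2] <- dye
  arr[, , 2, 1] <- rim; arr[, , 2, 2] <- rim
  st <- frameStack(arr, pixelSize = 0.5, frameInterval = 1,
                   channels = c("dye", "protein"))
  lp <- extractLineProfile(st, 1, a = c(ctr, ctr), b = c(ctr, dim), width = 3)
  # the dye edge (largest gradient ~ peak of the protein channel)
  expect_false(any(is.na(lp@peaks["protein"])))
  expect_lt(abs(lp@peaks[["protein"]] - 30 * 0.5), 2 * 0.5)
  # uniform protein coverage: no isolated peak
  arrU <- arr
  arrU[, , 2, 1] <- 0.4 + 0.2 * (r <= 30)   # covers the whole patch
  stU <- frameStack(arrU, 0.5, 1, c("dye", "protein"))
  lpU <- extractLineProfile(stU, 1, a = c(ctr, ctr), b = c(ctr, dim))
  expect_true(is.na(lpU@peaks[["protein"]]))
  # uniform image maps to the all-zero profile
  flat <- frameStack(array(0.3, c(32, 32, 2)), 0.5, 1)
  lpF <- extractLineProfile(flat, 1, c(16, 2), c(16, 30))
  expect_true(all(lpF@intensities == 0))
  expect_error(extractLineProfile(flat, 1, c(16, 5), c(16, 5)), "degenerate")
})

test_that("Welch's t matches the textbook formula and handles edge cases", {
  expect_equal(unname(welchT(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))[1:2]),
               c(0, 1))
  expect_lt(welchT(1:5, 1:5 + 10)[["p.value"]], 1e-3)
  set.seed(11)
  for (k in 1:50) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    got <- welchT(a, b)
    ref <- welchOracle(a, b)
    expect_lt(abs(got[["p.value"]] - ref[["p.value"]]), 1e-10)
    expect_lt(abs(got[["statistic"]] - ref[["statistic"]]), 1e-10)
    expect_lt(abs(got[["df"]] - ref[["df"]]), 1e-8)
  }
  expect_error(welchT(1, 1:5), "at least 2")
})

test_that("frame-shape mismatches and bad ROIs are rejected", {
  expect_error(frameStack(list(matrix(0, 4, 4), matrix(0, 5, 5)), 1, 1),
               "same shape")
  expect_error(frameStack(array(0, c(8, 8, 1)), 1, 1), "2 frames")
})
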