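test_that("generators are bit-exact under a fixed seed and leave the RNG alone", {
  a <- genAfmImage(spacing = 9.08, domainFractionHigh = 30, sizePx = 128L,
                   seed = 77)
  set.seed(123); probe1 <- runif(1)
  b <- genAfmImage(spacing = 9.08, domainFractionHigh = 30, sizePx = 128L,
                   seed = 77)
  expect_identical(heights(a$map), heights(b$map))
  # global RNG stream is untouched by generator calls
  set.seed(123); genRollingMovie(dim = 64L, patchRadius = 8, seed = 1)
  expect_identical(runif(1), probe1)

  m1 <- genRollingMovie(patchRadius = 10, tau = 6, onset = 12, dim = 96L,
                        frameInterval = 1, seed = 5)
  m2 <- genRollingMovie(patchRadius = 10, tau = 6, onset = 12, dim = 96L,
                        frameInterval = 1, seed = 5)
  expect_identical(frames(m1$stack), frames(m2$stack))
  f1 <- genMembraneFrame(seed = 9); f2 <- genMembraneFrame(seed = 9)
  expect_identical(f1$frame@positions, f2$frame@positions)
})

test_that("truth records regenerate their datasets and carry all parameters", {
  g <- genRollingMovie(patchRadius = 10, tau = 6, onset = 12, dim = 96L,
                       frameInterval = 1, seed = 5)
  tp <- truthParams(g$truth)
  expect_equal(tp$tau, 6)
  expect_equal(tp$onset, 12)
  expect_gt(tp$amplitude_um2, 0)
  g2 <- do.call(genRollingMovie, list(
    patchRadius = tp$patchRadius_um, tau = tp$tau, onset = tp$onset,
    mode = tp$mode, noiseSigma = tp$noiseSigma, pixelSize = tp$pixelSize_um,
    frameInterval = tp$frameInterval_s, nFrames = tp$nFrames,
    dim = tp$dim_px, seed = g$truth@seed))
  expect_identical(frames(g$stack), frames(g2$stack))
})

test_that("rolling movies honour the logistic schedule", {
  g <- genRollingMovie(patchRadius = 12, tau = 10, onset = 20,
                       noiseSigma = 0, pixelSize = 0.32, frameInterval = 1,
                       dim = 96L, seed = 2)
  tr <- incrementalRolledArea(g$stack, cutoff = 0.5, medianFilter = FALSE)
  # at most the onset-defining 5 % of A is consumed before the onset, and
  # the earliest frames are exactly static
  A <- truthParams(g$truth)$amplitude_um2
  expect_lt(max(tr@cumulativeArea[tr@times <= 20]), 0.05 * A * 1.05)
  # the logistic's early tail: well under 1 % of A in the first frames
  expect_lt(sum(tr@incrementalArea[tr@times < 5]), 0.01 * A)
  # the pipeline closes the loop on tau within 3 %
  fit <- fitLogistic(tr)
  expect_lt(abs(rollTau(fit) - 10) / 10, 0.03)
  # and the final cumulative area matches the truth amplitude within 3 %
  A <- truthParams(g$truth)$amplitude_um2
  expect_lt(abs(max(tr@cumulativeArea) - A) / A, 0.03)
})

test_that("multidirectional movies start from distinct edge seeds", {
  g <- genRollingMovie(patchRadius = 12, tau = 8, onset = 16, mode = "multi",
                       nFronts = 3L, noiseSigma = 0, frameInterval = 1,
                       dim = 96L, seed = 12)
  ang <- truthParams(g$truth)$frontAngles
  expect_length(ang, 3L)
  expect_true(min(diff(sort(ang))) > 1e-3)
  # first active frame shows disjoint consumed arcs at the patch edge
  f <- frames(g$stack)
  i <- which(apply(f, 3, function(m) sum(m < 0.5)) >
               sum(f[, , 1] < 0.5) + 30)[1]
  loss <- f[, , 1] > 0.5 & f[, , i] < 0.5
  lab <- EBImage::bwlabel(EBImage::Image(loss * 1))
  expect_gte(max(EBImage::imageData(lab)), 2)
})

test_that("generator preconditions are enforced", {
  expect_error(genRollingMovie(tau = -1), "tau")
  expect_error(genRollingMovie(mode = "multi", nFronts = 1L), "nFronts")
  expect_error(genRollingMovie(tau = 10, onset = 20, nFrames = 10L,
                               frameInterval = 0.1), "span")
  expect_error(genUnrollingMovie(growth = -0.1), "growth")
  expect_error(genUnrollingMovie(duration = 0), "duration")
  expect_error(genAfmImage(spacing = 1, pixelSize = 0.5), "spacing")
  expect_error(genAfmImage(domainFractionHigh = 120), "domainFractionHigh")
  expect_error(genMembraneFrame(nPerLeaflet = 10L), "100")
  expect_error(genMembraneFrame(list(type = "sphere-cap", R = 20,
                                     rhoMax = 19.9)), "slope")
})

test_that("membrane frames sample the analytic surfaces they declare", {
  # flat: curvature at the noise floor
  g <- genMembraneFrame(list(type = "flat"), box = c(40, 40),
                        nPerLeaflet = 10000L, zNoise = 0, seed = 3)
  cf <- meanCurvatureField(fitMidplane(g$frame, cellSize = 2),
                           smoothSigma = 0)
  expect_lt(max(abs(meanCurvature(cf))), 1e-10)
  # sphere cap: |H| = 1/R within 2 % via the full pipeline
  gs <- genMembraneFrame(list(type = "sphere-cap", R = 100),
                         box = c(320, 320), nPerLeaflet = 40000L,
                         zNoise = 0, seed = 2)
  ms <- fitMidplane(gs$frame, cellSize = 4)
  H <- meanCurvature(meanCurvatureField(ms, smoothSigma = 0))
  nC <- nrow(H); ctr <- round(nC / 2); w <- 7L
  Hc <- H[(ctr - w):(ctr + w), (ctr - w):(ctr + w)]
  expect_lt(abs(abs(mean(Hc)) * 100 - 1), 0.02)
})
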