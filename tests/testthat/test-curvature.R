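test_that("the midplane of two flat leaflets is identically zero", {
  set.seed(3)
  n <- 800
  pos <- cbind(runif(2 * n, 0, 40), runif(2 * n, 0, 40),
               rep(c(2, -2), each = n))
  pf <- particleFrame(pos, rep(c("upper", "lower"), each = n), box = c(40, 40))
  ms <- fitMidplane(pf, cellSize = 4)
  expect_lt(max(abs(surfaceGrid(ms))), 1e-12)
  cf <- meanCurvatureField(ms, smoothSigma = 0)
  expect_true(all(meanCurvature(cf) == 0))
})

test_that("a sampled Gaussian dimple reproduces the analytic surface", {
  g <- genMembraneFrame(list(type = "gaussian-dimple", A = 1.2, sigma = 3),
                        box = c(40, 40), nPerLeaflet = 20000L,
                        thickness = 4, zNoise = 0, seed = 5)
  ms <- fitMidplane(g$frame, cellSize = 1)   # occupancy >= 4 on average
  x <- (seq_len(nrow(surfaceGrid(ms))) - 0.5) * ms@cellSize - 20
  zAna <- outer(x, x, dimpleFun(1.2, 3))
  expect_lt(sqrt(mean((surfaceGrid(ms) - zAna)^2)), 0.1)
})

test_that("under-sampled frames raise a resolution error", {
  # particles alternate leaflets so each leaflet misses most cells
  pos <- cbind(rep(seq(0.5, 39.5, by = 1), each = 2),
               rep(seq(0.5, 39.5, by = 1), times = 2),
               rep(c(2, -2), 40))
  pf <- particleFrame(pos, rep(c("upper", "lower"), 40), box = c(40, 40))
  expect_error(fitMidplane(pf, cellSize = 2), "cellSize")
})

test_that("curvature is translation-invariant and odd under reflection", {
  s <- surfaceFromFunction(dimpleFun(1.2, 3), 30, 64)
  H1 <- meanCurvature(meanCurvatureField(s, smoothSigma = 0))
  s2 <- s; s2@grid <- s@grid + 5.7
  expect_equal(meanCurvature(meanCurvatureField(s2, smoothSigma = 0)), H1)
  s3 <- s; s3@grid <- -s@grid
  H3 <- meanCurvature(meanCurvatureField(s3, smoothSigma = 0))
  expect_equal(H3, -H1, tolerance = 1e-12)
})

test_that("sphere caps give |H| = 1/R within 2 % away from the rim", {
  for (R in c(50, 100, 200)) {
    box <- 2.6 * 0.6 * R
    nC <- ceiling(box / (R / 50))
    s <- surfaceFromFunction(sphereCapFun(R), box, nC)
    H <- meanCurvature(meanCurvatureField(s, smoothSigma = 0))
    ctr <- round(nC / 2); w <- max(2L, round(0.3 * R / s@cellSize))
    Hc <- H[(ctr - w):(ctr + w), (ctr - w):(ctr + w)]
    expect_lt(abs(mean(abs(Hc)) * R - 1), 0.02)
  }
})

test_that("dimple curvature matches the closed-form Monge expression", {
  s <- surfaceFromFunction(dimpleFun(1.2, 3), 30, 64)  # cell 0.47 nm
  H <- meanCurvature(meanCurvatureField(s, smoothSigma = 0))
  x <- (seq_len(64) - 0.5) * s@cellSize - 15
  HA <- outer(x, x, dimpleMeanCurvature, A = 1.2, sigma = 3)
  ctr <- which.min(abs(x))
  expect_lt(abs(H[ctr, ctr] / HA[ctr, ctr] - 1), 0.01)
  # and over the central 2-sigma region
  sel <- abs(x) <= 6
  expect_lt(max(abs(H[sel, sel] - HA[sel, sel])) / max(abs(HA)), 0.02)
})

test_that("footprint statistics aggregate frames correctly", {
  flat <- new("CurvatureField", meanCurvature = matrix(0, 16, 16),
              cellSize = 1, signConvention = "z")
  fp <- footprintMeanCurvature(flat, c(4, 12, 4, 12))
  expect_identical(c(fp@meanH, fp@sdAcrossFrames), c(0, 0))
  # replica arithmetic on hand-set values
  mk <- function(v) new("CurvatureField", meanCurvature = matrix(v, 16, 16),
                        cellSize = 1, signConvention = "z")
  fp3 <- footprintMeanCurvature(lapply(c(0.007, 0.008, 0.010), mk),
                                c(2, 14, 2, 14))
  expect_equal(fp3@meanH, mean(c(0.007, 0.008, 0.010)), tolerance = 1e-14)
  expect_equal(fp3@sdAcrossFrames, sd(c(0.007, 0.008, 0.010)),
               tolerance = 1e-14)
  expect_identical(fp3@nFrames, 3L)
  expect_error(footprintMeanCurvature(flat, matrix(FALSE, 16, 16)), "empty")
})

test_that("footprint mean curvature matches the analytic region average", {
  g <- genMembraneFrame(list(type = "gaussian-dimple", A = 1.2, sigma = 3),
                        box = c(40, 40), nPerLeaflet = 20000L,
                        thickness = 4, zNoise = 0, seed = 5)
  cf <- meanCurvatureField(fitMidplane(g$frame, cellSize = 1),
                           smoothSigma = 0)
  x <- (seq_len(nrow(meanCurvature(cf))) - 0.5) * cf@cellSize - 20
  sel <- abs(x) <= 5
  fp <- footprintMeanCurvature(cf, outer(sel, sel, `&`))
  xs <- seq(-5, 5, length.out = 201)
  HBar <- mean(outer(xs, xs, dimpleMeanCurvature, A = 1.2, sigma = 3))
  expect_lt(abs(fp@meanH / HBar - 1), 0.02)
})

test_that("footprint curvature is robust to grid refinement and z-noise", {
  g <- genMembraneFrame(list(type = "gaussian-dimple", A = 1.2, sigma = 3),
                        box = c(40, 40), nPerLeaflet = 40000L,
                        thickness = 4, zNoise = 0, seed = 8)
  # cells tiling exactly [-4, 4]^2 at every cell size, so the geometric
  # footprint is identical across resolutions
  region <- function(cf) {
    cs <- cf@cellSize
    lo <- (seq_len(nrow(meanCurvature(cf))) - 1) * cs - 20
    sel <- lo >= -4 - 1e-9 & lo + cs <= 4 + 1e-9
    outer(sel, sel, `&`)
  }
  mH <- sapply(c(2, 1), function(cs) {
    cf <- meanCurvatureField(fitMidplane(g$frame, cellSize = cs),
                             smoothSigma = 0)
    footprintMeanCurvature(cf, region(cf))@meanH
  })
  expect_lt(abs(mH[2] / mH[1] - 1), 0.05)
  # 0.2 nm particle z-noise (protrusion scale) at occupancy >= 8
  gn <- genMembraneFrame(list(type = "gaussian-dimple", A = 1.2, sigma = 3),
                         box = c(40, 40), nPerLeaflet = 40000L,
                         thickness = 4, zNoise = 0.2, seed = 8)
  cfn <- meanCurvatureField(fitMidplane(gn$frame, cellSize = 2))
  cf0 <- meanCurvatureField(fitMidplane(g$frame, cellSize = 2))
  h1 <- footprintMeanCurvature(cfn, region(cfn))@meanH
  h0 <- footprintMeanCurvature(cf0, region(cf0))@meanH
  expect_lt(abs(h1 / h0 - 1), 0.15)
})

test_that("non-finite surfaces and tiny grids are rejected", {
  s <- surfaceFromFunction(function(x, y) 0 * x, 10, 4)
  expect_error(meanCurvatureField(s), "8 x 8")
  s2 <- surfaceFromFunction(function(x, y) 0 * x, 10, 16)
  s2@grid[3, 3] <- NaN
  expect_error(meanCurvatureField(s2), "finite")
})
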