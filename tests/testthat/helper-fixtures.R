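# Shared fixture builders. All synthetic inputs are generated in code, at
# fixed seeds, so the suite is self-contained.

# MidplaneSurface sampling an analytic height function f(x, y) at cell
# centres of an nCell x nCell periodic grid over [−box/2, box/2]^2
surfaceFromFunction <- function(f, box, nCell) {
  cs <- box / nCell
  x <- (seq_len(nCell) - 0.5) * cs - box / 2
  new("MidplaneSurface", grid = outer(x, x, f), cellSize = cs,
      occupancy = matrix(10, nCell, nCell),
      filled = matrix(FALSE, nCell, nCell))
}

sphereCapFun <- function(R, rhoMax = 0.6 * R) {
  zE <- sqrt(R^2 - rhoMax^2)
  function(x, y) ifelse(x^2 + y^2 < rhoMax^2,
                        sqrt(pmax(R^2 - x^2 - y^2, 0)) - zE, 0)
}

dimpleFun <- function(A, sigma) {
  function(x, y) -A * exp(-(x^2 + y^2) / (2 * sigma^2))
}

# closed-form Monge mean curvature of the Gaussian dimple (independent
# hand-derived oracle, no shared code with the package)
dimpleMeanCurvature <- function(x, y, A, sigma) {
  r2 <- x^2 + y^2
  E <- exp(-r2 / (2 * sigma^2))
  zx <- A * x / sigma^2 * E
  zy <- A * y / sigma^2 * E
  zxx <- A / sigma^2 * E * (1 - x^2 / sigma^2)
  zyy <- A / sigma^2 * E * (1 - y^2 / sigma^2)
  zxy <- -A * x * y / sigma^4 * E
  ((1 + zx^2) * zyy - 2 * zx * zy * zxy + (1 + zy^2) * zxx) /
    (2 * (1 + zx^2 + zy^2)^1.5)
}

# noiseless logistic cumulative trace
logisticTrace <- function(tau, t0, A, tEnd = t0 + 6 * tau, dt = tEnd / 400) {
  t <- seq(dt, tEnd, by = dt)
  y <- A / (1 + exp(-(t - t0) / tau))
  inc <- diff(c(0, y))
  new("RollingTrace", times = t, incrementalArea = inc, cumulativeArea = y)
}

# frame stack of a disc shrinking by prescribed radii (sharp edges, no noise)
shrinkingDiscStack <- function(radiiPx, dim = 96L, pixelSize = 0.5,
                               frameInterval = 1) {
  ctr <- (dim + 1) / 2
  xi <- matrix(seq_len(dim), dim, dim) - ctr
  r2 <- xi^2 + t(xi)^2
  fr <- lapply(radiiPx, function(r) {
    m <- matrix(0.1, dim, dim); m[r2 <= r^2] <- 1; m
  })
  frameStack(fr, pixelSize, frameInterval)
}

# independently coded Welch test (textbook formulas)
welchOracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a) / n1; v2 <- var(b) / n2
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  c(statistic = t, p.value = 2 * pt(-abs(t), df), df = df)
}

refParams <- function(preset = "results") rollModelParams(preset)
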