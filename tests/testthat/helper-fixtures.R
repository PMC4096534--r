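# Shared fixtures, built in code and memoized so expensive renders are done
# once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small clean plate: 6 x 8 array, default optics, low noise so measured
# masses track the recorded truth tightly
smallRender <- function() memo("smallRender", function() {
  spec <- simPlateSpec(nRows = 6, nCols = 8, noiseSd = 5e-4, seed = 42)
  truths <- simColonyTruths(spec, aCV = 0.05, cCV = 0.05)
  renderTimelapse(spec, truths, neighborModel())
})

smallMeasure <- function() memo("smallMeasure", function() {
  ren <- smallRender()
  measureTimelapse(ren$images, ren$layout)
})

# default-noise render used for segmentation / mass* invariant checks
noisyRender <- function() memo("noisyRender", function() {
  spec <- simPlateSpec(nRows = 4, nCols = 5, seed = 7)
  truths <- simColonyTruths(spec, aCV = 0.05, cCV = 0.05)
  renderTimelapse(spec, truths, neighborModel())
})

# flat-background image with one hand-placed colony window, used for
# manual segmentation traces
flatImage <- function(value = 100, H = 30, W = 30)
  PlateImage(matrix(value, H, W), "toy", 5)

oneCellLayout <- function(H = 30, W = 30)
  ArrayLayout(1, 1, cbind(x = (W + 1) / 2, y = (H + 1) / 2), min(H, W))

# independent brute-force mass oracle: plain double loop over member pixels
bruteForceMass <- function(px, member, agarMean) {
  total <- 0
  for (i in seq_len(nrow(member))) {
    I <- px[member[i, 1], member[i, 2]]
    absb <- -log10(I / agarMean)
    if (absb > 0) total <- total + absb
  }
  total
}

# independent Otsu oracle: try every cut between consecutive observed
# levels and score the between-class variance directly
bruteForceOtsu <- function(v) {
  u <- sort(unique(v))
  best <- -Inf
  bestThr <- NA_real_
  for (k in seq_len(length(u) - 1)) {
    thr <- (u[k] + u[k + 1]) / 2
    lo <- v[v < thr]; hi <- v[v >= thr]
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) {
      best <- sb
      bestThr <- thr
    }
  }
  bestThr
}

# numerically locate the maximum slope of the Gompertz curve by central
# finite differences (independent of the closed forms)
numericMGR <- function(a, b, c) {
  h <- 1e-4
  slope <- function(t) (gompertz(t + h, a, b, c) - gompertz(t - h, a, b, c)) / (2 * h)
  grid <- seq(0.01, 40, length.out = 400)
  t0 <- grid[which.max(vapply(grid, slope, numeric(1)))]
  opt <- optimize(slope, c(max(1e-6, t0 - 0.5), t0 + 0.5), maximum = TRUE,
                  tol = 1e-10)
  list(tMax = opt$maximum, mgr = opt$objective)
}

# geometric lag-time oracle: where the tangent at the maximum-slope point
# crosses zero
tangentLTG <- function(a, b, c) {
  mx <- numericMGR(a, b, c)
  mx$tMax - gompertz(mx$tMax, a, b, c) / mx$mgr
}
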