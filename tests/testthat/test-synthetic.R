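test_that("Gompertz series match direct model evaluation and its identities", {
  # point-by-point against an independent scalar evaluation
  times <- seq(0, 20, 0.5)
  s <- genGompertzSeries(2, 50, 0.7, times)
  expected <- vapply(times, function(t) 2 * exp(-50 * 0.7^t), numeric(1))
  expect_equal(s$value, expected, tolerance = 1e-14)

  # asymptote and inflection identity
  expect_equal(gompertz(500, a = 3, b = 4, c = 0.5), 3, tolerance = 1e-12)
  tInfl <- log(1 / 4) / log(0.5)          # b * c^t = 1
  expect_equal(gompertz(tInfl, 3, 4, 0.5), 3 / exp(1), tolerance = 1e-12)

  # noiseless series strictly increasing; bad rate base rejected
  expect_true(all(diff(s$value) > 0))
  expect_error(genGompertzSeries(2, 50, 1.2, times), "non-growth")
  expect_error(genGompertzSeries(2, 50, 0, times), "non-growth")
})

test_that("generators are deterministic and subsets match the full stack", {
  times <- seq(0, 20, 0.5)
  s1 <- genGompertzSeries(2, 50, 0.7, times, noiseSd = 0.05, seed = 9)
  s2 <- genGompertzSeries(2, 50, 0.7, times, noiseSd = 0.05, seed = 9)
  expect_identical(s1, s2)

  spec <- simPlateSpec(nRows = 3, nCols = 3, seed = 5)
  tr <- simColonyTruths(spec)
  r1 <- renderTimelapse(spec, tr, times = c(0, 10, 20))
  r2 <- renderTimelapse(spec, tr, times = c(0, 10, 20))
  expect_identical(lapply(r1$images, pixels), lapply(r2$images, pixels))
  # rendering a subset of scans reproduces the same frames bit-identically
  rSub <- renderTimelapse(spec, tr, times = 10)
  expect_identical(pixels(rSub$images[[1]]), pixels(r1$images[[2]]))
})

test_that("rendered images compose background, vignette and exact dome mass", {
  # empty plate, no vignette, no noise: pure agar level everywhere
  spec0 <- simPlateSpec(nRows = 2, nCols = 2, vignetteAmplitude = 0,
                        noiseSd = 0, seed = 1)
  empty <- simColonyTruths(spec0)[0, ]
  r0 <- renderTimelapse(spec0, empty, times = 0)
  expect_true(all(pixels(r0$images[[1]]) == spec0$agarIntensity))

  # vignette only: intensities bounded by the gradient amplitude, corners
  # darker than the center
  specV <- simPlateSpec(nRows = 2, nCols = 2, vignetteAmplitude = 0.1,
                        noiseSd = 0, seed = 1)
  rV <- renderTimelapse(specV, empty, times = 0)
  pxV <- pixels(rV$images[[1]])
  expect_lte(max(pxV), specV$agarIntensity)
  expect_gte(min(pxV), specV$agarIntensity * 0.9 - 1e-9)
  expect_lt(pxV[1, 1], pxV[round(nrow(pxV) / 2), round(ncol(pxV) / 2)])

  # conservation: summed pixel absorbance of an isolated colony equals the
  # recorded true mass (brute-force pixel sum oracle)
  spec1 <- simPlateSpec(nRows = 1, nCols = 1, vignetteAmplitude = 0,
                        noiseSd = 0, seed = 1)
  tr1 <- simColonyTruths(spec1)
  r1 <- renderTimelapse(spec1, tr1, times = c(5, 10, 20))
  for (k in 1:3) {
    px <- pixels(r1$images[[k]])
    absb <- -log10(px / spec1$agarIntensity)
    recorded <- r1$truth$trueMass[r1$truth$time == scanTime(r1$images[[k]])]
    expect_equal(sum(absb), recorded, tolerance = 1e-8)
  }

  # overlapping domes at a too-small pitch are rejected
  specTight <- simPlateSpec(nRows = 2, nCols = 2, pixelPitch = 12, seed = 1)
  expect_error(renderTimelapse(specTight, simColonyTruths(specTight),
                               times = 20),
               "pitch too small")
})

test_that("neighbor effect: identity at zero, monotone with crowding, and
           equal to an independent step-by-step simulation", {
  spec <- simPlateSpec(nRows = 3, nCols = 3, seed = 2)
  tr <- simColonyTruths(spec)     # identical parameters at all 9 positions

  mass0 <- applyNeighborEffect(tr, spec, neighborModel(0))
  times <- attr(mass0, "times")
  ideal <- t(sapply(seq_len(9), function(i)
    gompertz(times, tr$a[i], tr$b[i], tr$c[i])))
  expect_equal(unname(mass0), unname(ideal), tolerance = 1e-12, ignore_attr = TRUE)

  nm <- neighborModel(1e-3)
  mass <- applyNeighborEffect(tr, spec, nm)
  center <- which(tr$row == 2 & tr$col == 2)   # 8 neighbors
  edge <- which(tr$row == 1 & tr$col == 2)     # 5 neighbors
  corner <- which(tr$row == 1 & tr$col == 1)   # 3 neighbors
  expect_lt(mass[center, length(times)], mass[edge, length(times)])
  expect_lt(mass[edge, length(times)], mass[corner, length(times)])

  # independent per-step simulator oracle (plain loops, no shared code)
  cen <- centers(specLayout(spec))
  rad <- 1.6 * spec$pixelPitch
  n <- nrow(tr)
  oracle <- matrix(0, n, length(times))
  for (i in seq_len(n))
    oracle[i, 1] <- tr$a[i] * exp(-tr$b[i] * tr$c[i]^times[1])
  for (j in 2:length(times)) {
    for (i in seq_len(n)) {
      gPrev <- tr$a[i] * exp(-tr$b[i] * tr$c[i]^times[j - 1])
      gNow <- tr$a[i] * exp(-tr$b[i] * tr$c[i]^times[j])
      inc <- gNow - gPrev
      diam <- 2 * (2 * oracle[i, j - 1] / (pi * tr$kappa[i]))^(1 / 3)
      if (diam > nm$onsetDiameter) {
        S <- 0
        for (l in seq_len(n)) {
          if (l == i) next
          d <- sqrt(sum((cen[l, ] - cen[i, ])^2))
          if (d <= rad) S <- S + oracle[l, j - 1]
        }
        inc <- inc / (1 + nm$suppressionCoeff * S)
      }
      oracle[i, j] <- oracle[i, j - 1] + inc
    }
  }
  expect_equal(unname(mass), unname(oracle), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("simulated screens carry the stated effects, biases and noise", {
  # degenerate null: no effects, no biases, no noise -> identical replicates
  null <- simulateScreen(50, nReplicates = 3, noiseSpec = list(cv = 0),
                         seed = 1)
  wide <- split(null$table$MGR, null$table$replicate)
  expect_identical(wide[[1]], wide[[2]])
  expect_identical(wide[[1]], wide[[3]])
  expect_false(any(null$labels$slowMGR))

  # labeled slow strains sit at the stated multiplicative effect
  scr <- simulateScreen(400, nReplicates = 4,
                        effectSpec = list(slowMGR = list(fraction = 0.05,
                                                         factor = 0.8)),
                        noiseSpec = list(cv = 0.02), seed = 3)
  byStrain <- aggregate(MGR ~ strain, scr$table, mean)
  slow <- byStrain$strain %in% scr$labels$strain[scr$labels$slowMGR]
  ratio <- mean(byStrain$MGR[slow]) / mean(byStrain$MGR[!slow])
  expect_equal(ratio, 0.8, tolerance = 0.03)

  # plate bias shows up as the stated median ratio
  bias <- simulateScreen(384 * 2, nReplicates = 2,
                         biasSpec = list(plateFactors = c(1, 1.2)),
                         noiseSpec = list(cv = 0.02),
                         layoutDims = c(16, 24), seed = 4)
  med <- tapply(bias$table$MGR, bias$table$plate, median)
  expect_equal(unname(med[2] / med[1]), 1.2, tolerance = 0.02)

  expect_error(simulateScreen(100, effectSpec = list(
    slowMGR = list(fraction = 0.6, factor = 0.8),
    lowSPG = list(fraction = 0.6, factor = 0.8))), "sum")
})
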