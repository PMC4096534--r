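test_that("Otsu threshold separates classes and matches the exhaustive oracle", {
  # two-level image: threshold strictly between the levels
  v <- c(rep(10, 90), rep(100, 10))
  thr <- otsuThreshold(v)
  expect_gt(thr, 10)
  expect_lt(thr, 100)

  # brute-force between-class-variance scan on random discrete images
  for (s in 1:5) {
    vv <- withr::with_seed(s, sample(1:50, 200, replace = TRUE))
    expect_equal(otsuThreshold(vv), bruteForceOtsu(vv), tolerance = 1e-12)
  }

  # translation equivariance: a constant offset shifts the threshold exactly
  vv <- withr::with_seed(1, rnorm(500, 10, 2))
  expect_equal(otsuThreshold(vv + 7.25), otsuThreshold(vv) + 7.25,
               tolerance = 1e-12)

  expect_error(otsuThreshold(rep(3, 10)), "single intensity")
})

test_that("lighting correction flattens a known vignette and preserves masses", {
  # flat field passes through unchanged
  flat <- PlateImage(matrix(0.8, 60, 80), "f", 0)
  expect_equal(pixels(correctLighting(flat)), pixels(flat), tolerance = 1e-12)

  # vignette-only plate: residual trend amplitude < 1% of the agar mean
  spec <- simPlateSpec(nRows = 2, nCols = 2, vignetteAmplitude = 0.08,
                       noiseSd = 0, seed = 1)
  rV <- renderTimelapse(spec, simColonyTruths(spec)[0, ], times = 0)
  corr <- pixels(correctLighting(rV$images[[1]]))
  expect_lt((max(corr) - min(corr)) / mean(corr), 0.01)

  # vignetted plate with colonies: measured masses within 2% of truth
  ren <- smallRender()                     # vignette 0.06, low noise
  se <- smallMeasure()
  nT <- length(ren$images)
  final <- SummarizedExperiment::assay(se, "mass")[, nT]
  truthFinal <- ren$massMatrix[, nT]
  expect_lt(max(abs(final - truthFinal) / truthFinal), 0.02)
})

test_that("grid detection returns the full lattice within 2 px, also with
           missing colonies, and fails cleanly without an array", {
  ren <- smallRender()
  img <- ren$images[[length(ren$images)]]
  lay <- detectGrid(img, 6, 8)
  expect_identical(unname(gridDims(lay)), c(6L, 8L))
  expect_equal(nrow(centers(lay)), 48L)
  expect_lt(max(abs(centers(lay) - centers(ren$layout))), 2)

  # 10% of colonies absent: lattice completion still yields every center
  spec <- simPlateSpec(nRows = 6, nCols = 8, seed = 13)
  tr <- simColonyTruths(spec, aCV = 0.05, cCV = 0.05)
  drop <- withr::with_seed(13, sample(nrow(tr), 5))
  renM <- renderTimelapse(spec, tr[-drop, ], times = 20)
  layM <- detectGrid(renM$images[[1]], 6, 8)
  expect_equal(nrow(centers(layM)), 48L)
  expect_lt(max(abs(centers(layM) - centers(ren$layout))), 2)

  # pure noise image: no grid
  noise <- PlateImage(matrix(withr::with_seed(1, runif(200 * 300, 0.7, 0.9)),
                             200, 300), "x", 0)
  expect_error(detectGrid(noise, 6, 8), "grid not found")
})

test_that("colony-region membership follows the 10-sigma rule on a hand-built
           window", {
  # deterministic low-amplitude background texture so the 10-sigma cut is a
  # real intensity level, plus hand-placed colony pixels and one
  # near-background pixel that must stay out
  px <- 100 + 0.5 * sin(outer(1:30, (1:30) * 2.3))
  dark <- rbind(c(15, 15), c(15, 16), c(16, 15), c(14, 15), c(15, 14))
  for (i in seq_len(nrow(dark))) px[dark[i, 1], dark[i, 2]] <- 40
  px[16, 16] <- 99            # above agarMean - 10 sd: must be excluded
  imgT <- PlateImage(px, "toy", 5)
  reg <- extractColonyRegion(imgT, oneCellLayout(), 1, 1)
  expect_true(reg@valid)
  expect_equal(reg@agarMean, 100, tolerance = 0.01)
  # hand evaluation of the membership rule over every window pixel, using
  # the region's background statistics
  thr <- reg@agarMean - 10 * reg@agarSd
  want <- which(px < thr, arr.ind = TRUE)
  got <- reg@memberPixels[order(reg@memberPixels[, 1],
                                reg@memberPixels[, 2]), ]
  want <- want[order(want[, 1], want[, 2]), ]
  expect_equal(unname(got), unname(want), ignore_attr = TRUE)
  expect_equal(unname(got), unname(dark[order(dark[, 1], dark[, 2]), ]),
               ignore_attr = TRUE)

  # empty position over pure noise background: 10-sigma rejects everything
  noisePx <- matrix(100 + withr::with_seed(2, rnorm(900, 0, 1)), 30, 30)
  regN <- extractColonyRegion(PlateImage(noisePx, "n", 0),
                              oneCellLayout(), 1, 1)
  expect_equal(nrow(regN@memberPixels), 0L)
})

test_that("colony mass equals the decade identity and the brute-force oracle", {
  img <- flatImage(100)
  px <- pixels(img)
  # three pixels at I/I_agar = 0.1, 0.01, 1.0 -> absorbances 1, 2, 0
  px[10, 10] <- 10; px[10, 11] <- 1; px[10, 12] <- 100
  member <- cbind(y = c(10, 10, 10), x = c(10, 11, 12))
  reg <- new("ColonyRegion", position = c(1L, 1L), memberPixels = member,
             thresholdUsed = 50, agarMean = 100, agarSd = 1, valid = TRUE)
  imgT <- PlateImage(px, "toy", 5)
  expect_equal(colonyMass(imgT, reg), 3, tolerance = 1e-12)

  # uniform region at the agar level has zero mass
  regFlat <- new("ColonyRegion", position = c(1L, 1L),
                 memberPixels = cbind(y = 1:5, x = 1:5),
                 thresholdUsed = 50, agarMean = 100, agarSd = 1, valid = TRUE)
  expect_equal(colonyMass(img, regFlat), 0)

  # random toy regions vs the independent per-pixel sum
  for (s in 1:5) {
    pxR <- matrix(withr::with_seed(s, runif(400, 20, 120)), 20, 20)
    mem <- withr::with_seed(s + 100, cbind(y = sample(20, 20, TRUE),
                                           x = sample(20, 20, TRUE)))
    regR <- new("ColonyRegion", position = c(1L, 1L), memberPixels = mem,
                thresholdUsed = 0, agarMean = 90, agarSd = 1, valid = TRUE)
    got <- colonyMass(PlateImage(pxR, "r", 0), regR)
    want <- bruteForceMass(pxR, mem, 90)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("center-region mass uses a 17-px-wide disc and never exceeds mass", {
  # stripe fixture: absorbance 1 on a single row; the disc at an integer
  # center must admit exactly 17 of its pixels in that row
  px <- matrix(100, 41, 41)
  px[21, 4:38] <- 10                       # absorbance 1 each
  member <- cbind(y = rep(21L, 35), x = 4:38)
  reg <- new("ColonyRegion", position = c(1L, 1L), memberPixels = member,
             thresholdUsed = 50, agarMean = 100, agarSd = 1, valid = TRUE)
  img <- PlateImage(px, "stripe", 5)
  expect_equal(colonyMassCenter(img, reg, diameter = 17, center = c(21, 21)),
               17, tolerance = 1e-12)

  # containment: colony entirely inside the disc -> mass* = mass
  pxS <- matrix(100, 41, 41)
  pxS[19:23, 19:23] <- 10
  memS <- as.matrix(expand.grid(y = 19:23, x = 19:23))
  regS <- new("ColonyRegion", position = c(1L, 1L),
              memberPixels = cbind(y = memS[, "y"], x = memS[, "x"]),
              thresholdUsed = 50, agarMean = 100, agarSd = 1, valid = TRUE)
  imgS <- PlateImage(pxS, "s", 5)
  expect_equal(colonyMassCenter(imgS, regS, 17), colonyMass(imgS, regS))

  # straddling region vs a per-pixel distance oracle
  pxB <- matrix(100, 41, 41)
  pxB[6:36, 6:36] <- withr::with_seed(4, runif(31 * 31, 10, 60))
  memB <- as.matrix(expand.grid(y = 6:36, x = 6:36))
  regB <- new("ColonyRegion", position = c(1L, 1L),
              memberPixels = cbind(y = memB[, "y"], x = memB[, "x"]),
              thresholdUsed = 90, agarMean = 100, agarSd = 1, valid = TRUE)
  imgB <- PlateImage(pxB, "b", 5)
  ctr <- c(21.3, 20.6)                     # (x, y)
  got <- colonyMassCenter(imgB, regB, 17, center = ctr)
  want <- 0
  for (i in seq_len(nrow(memB))) {
    d <- sqrt((memB[i, "x"] - ctr[1])^2 + (memB[i, "y"] - ctr[2])^2)
    if (d <= 8.5)
      want <- want + max(0, -log10(pxB[memB[i, "y"], memB[i, "x"]] / 100))
  }
  expect_equal(got, want, tolerance = 1e-12)

  # invariant on a rendered run with default noise: mass* <= mass everywhere
  ren <- noisyRender()
  se <- measureTimelapse(ren$images, ren$layout)
  m <- SummarizedExperiment::assay(se, "mass")
  mc <- SummarizedExperiment::assay(se, "mass_center")
  expect_true(all(mc <= m + 1e-9, na.rm = TRUE))
})

test_that("time-lapse measurement has full cardinality, monotone noiseless
           mass, and tracks the recorded truth within 2%", {
  spec <- simPlateSpec(nRows = 3, nCols = 4, vignetteAmplitude = 0,
                       noiseSd = 0, seed = 21)
  tr <- simColonyTruths(spec, aCV = 0.05, cCV = 0.05)
  ren <- renderTimelapse(spec, tr)
  se <- measureTimelapse(ren$images, ren$layout)
  expect_identical(dim(se), c(12L, 41L))
  m <- SummarizedExperiment::assay(se, "mass")
  expect_true(all(apply(m, 1, function(x) all(diff(x) >= -1e-9))))

  # low-noise fixture: every scan's mass within 2% of the recorded truth
  ren2 <- smallRender()
  se2 <- smallMeasure()
  m2 <- SummarizedExperiment::assay(se2, "mass")
  relErr <- abs(m2 - ren2$massMatrix) / pmax(ren2$massMatrix, 1)
  expect_lt(max(relErr, na.rm = TRUE), 0.02)

  # observation table round-trips the assays in long form
  obs <- observationTable(se2)
  expect_identical(nrow(obs), 48L * 41L)
  expect_true(all(obs$mass_center <= obs$mass + 1e-9, na.rm = TRUE))
})
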