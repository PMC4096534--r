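mkGrid <- function(nr, nc, seed = 1, base = 1)
  matrix(base * withr::with_seed(seed, runif(nr * nc, 0.9, 1.1)), nr, nc)

# corner-to-corner amplitude of the best-fit plane through a grid of ratios
planeAmplitude <- function(g) {
  d <- data.frame(z = as.vector(g), u = as.vector((col(g) - 1) / (ncol(g) - 1)),
                  v = as.vector((row(g) - 1) / (nrow(g) - 1)))
  co <- coef(lm(z ~ u + v, d))
  (abs(co[["u"]]) + abs(co[["v"]])) / co[["(Intercept)"]]
}

test_that("plate normalization equalizes plate medians", {
  g <- mkGrid(6, 6)
  # identical plates: unchanged
  expect_equal(plateNormalize(list(g, g)), list(g, g), tolerance = 1e-14)
  # one plate scaled: medians agree afterwards
  out <- plateNormalize(list(g, g * 1.2))
  expect_equal(median(out[[1]]), median(out[[2]]), tolerance = 1e-12)
  # manual grand-median arithmetic on three toy 4x4 grids
  gs <- list(matrix(1:16, 4), matrix(seq(2, 32, 2), 4),
             matrix(seq(3, 48, 3), 4))
  meds <- vapply(gs, median, numeric(1))
  grand <- median(meds)
  out3 <- plateNormalize(gs)
  for (i in 1:3)
    expect_equal(out3[[i]], gs[[i]] * grand / meds[i], tolerance = 1e-14)
  # under-populated plates are skipped with a warning
  tiny <- matrix(c(1, 2, rep(NA, 14)), 4)
  expect_warning(plateNormalize(list(g, tiny)), "skipped")
})

test_that("row/column normalization removes injected line biases", {
  # bias-free grid (all line medians equal the plate median): identity
  flat <- matrix(2.5, 6, 6)
  expect_equal(rowcolNormalize(flat), flat, tolerance = 1e-12)

  # constant base with one row scaled: restored exactly by construction
  gr <- matrix(2, 6, 6)
  gr[3, ] <- gr[3, ] * 1.5
  out <- rowcolNormalize(gr)
  expect_equal(median(out[3, ]) / median(out), 1, tolerance = 1e-6)

  g <- mkGrid(6, 6, 2)

  # manual trace: constant base with row x1.5 and column x0.8 biases is
  # restored exactly (row pass first, then columns on recomputed medians)
  gb <- matrix(1, 6, 6)
  gb[3, ] <- gb[3, ] * 1.5
  gb[, 5] <- gb[, 5] * 0.8
  outB <- rowcolNormalize(gb)
  expect_equal(outB, matrix(1, 6, 6), tolerance = 1e-12)

  # textured variant: residual line biases < 1% when refitting medians
  gt <- g
  gt[3, ] <- gt[3, ] * 1.5
  gt[, 5] <- gt[, 5] * 0.8
  outT <- rowcolNormalize(gt)
  colRes <- apply(outT, 2, median) / median(outT)
  expect_lt(max(abs(colRes - 1)), 0.01)
})

test_that("spatial normalization removes smooth gradients but keeps isolated
           effects", {
  flat <- matrix(1, 12, 12)
  expect_equal(spatialNormalize(flat), flat, tolerance = 1e-14)

  # smooth 20% corner-to-corner gradient on a production-format grid: the
  # refit plane of the output drops below 2% (residuals are edge effects of
  # the clipped median window)
  g <- matrix(1, 32, 48)
  u <- (col(g) - 1) / (ncol(g) - 1); v <- (row(g) - 1) / (nrow(g) - 1)
  grad <- 1 + 0.2 * (u + v - 1) / 2
  expect_gt(planeAmplitude(grad), 0.15)             # before: ~20%
  out <- spatialNormalize(g * grad)
  expect_lt(planeAmplitude(out), 0.02)

  # a single half-speed colony survives the local median
  one <- matrix(1, 12, 12)
  one[6, 6] <- 0.5
  outOne <- spatialNormalize(one)
  expect_equal(outOne[6, 6], 0.5, tolerance = 0.05)
})

test_that("the pipeline removes plate/row/column/spatial biases in the stated
           order while preserving strain effects", {
  nr <- 16; nc <- 24
  mkTable <- function(valueFn) {
    do.call(rbind, lapply(1:2, function(p) {
      idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
      data.frame(plate = paste0("p", p), row = idx$row, col = idx$col,
                 MGR = valueFn(p, idx$row, idx$col))
    }))
  }
  # one strain on plate 1 carries a real 20% defect
  effRow <- 6; effCol <- 13

  value <- function(p, r, c, biased) {
    v <- rep(1, length(r))
    if (biased) {
      v <- v * ifelse(p == 2, 1.2, 1) * ifelse(r == 3, 1.5, 1) *
        ifelse(c == 5, 0.8, 1) *
        (1 + 0.2 * ((c - 1) / (nc - 1) + (r - 1) / (nr - 1) - 1) / 2)
    }
    v * ifelse(p == 1 & r == effRow & c == effCol, 0.8, 1)
  }

  tab0 <- mkTable(function(p, r, c) value(p, r, c, biased = FALSE))
  out0 <- normalizePipeline(tab0, "MGR")
  # zero-bias table with a flat background: pipeline leaves values in place
  unaffected <- !(tab0$plate == "p1" & tab0$row == effRow &
                    tab0$col == effCol)
  expect_equal(out0$MGR_norm[unaffected], tab0$MGR[unaffected],
               tolerance = 1e-9)

  tabB <- mkTable(function(p, r, c) value(p, r, c, biased = TRUE))
  outB <- normalizePipeline(tabB, "MGR")
  # residuals measured against each plate's recovered background level
  # (plate-plate normalization equalizes plates to the grand median, so the
  # absolute level is a compromise between the two plates)
  bg <- median(outB$MGR_norm[unaffected])
  expect_lt(max(abs(outB$MGR_norm[unaffected] / bg - 1)), 0.02)
  # the injected 20% strain effect survives within 5%
  eff <- outB$MGR_norm[!unaffected] / bg
  expect_equal(eff, 0.8, tolerance = 0.05)

  # order sensitivity: permuting the stated step order changes the result
  grids <- tableToGrids(tabB, "MGR", nr, nc)
  stated <- lapply(plateNormalize(grids), function(g)
    spatialNormalize(rowcolNormalize(g)))
  permuted <- plateNormalize(lapply(grids, function(g)
    rowcolNormalize(spatialNormalize(g))))
  expect_gt(max(abs(permuted[[1]] / stated[[1]] - 1)), 1e-3)
})

test_that("every step is scale-equivariant", {
  g <- mkGrid(8, 8, 5)
  k <- 3.7
  expect_equal(plateNormalize(list(g * k, g * 2 * k))[[1]],
               plateNormalize(list(g, g * 2))[[1]] * k, tolerance = 1e-12)
  expect_equal(rowcolNormalize(g * k), rowcolNormalize(g) * k,
               tolerance = 1e-12)
  expect_equal(spatialNormalize(g * k), spatialNormalize(g) * k,
               tolerance = 1e-12)
})
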