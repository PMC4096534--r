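# Normalization module: plate-plate, row/column and spatial median-ratio
# normalization, applied in that order. All corrections are multiplicative
# (growth values are positive and scale-like) and use medians throughout for
# robustness to defective-mutant outliers. The neighbor-effect and batch
# steps of the conventional recipe are intentionally absent.

#' Plate-plate normalization
#'
#' Rescales each plate grid multiplicatively so its median equals the grand
#' median of all plate medians. A single plate passes through unchanged;
#' plates with fewer than 10 valid cells are skipped with a warning.
#'
#' @param grids list of numeric matrices (one per plate, `NA` = invalid).
#' @return list of normalized matrices.
#' @export
plateNormalize <- function(grids) {
  stopifnot(length(grids) >= 1L)
  nValid <- vapply(grids, function(g) sum(is.finite(g)), integer(1L))
  usable <- nValid >= 10L
  if (any(!usable))
    warning(sum(!usable), " plate(s) with < 10 valid cells skipped")
  if (length(grids) == 1L || sum(usable) < 2L) return(grids)
  meds <- vapply(grids[usable], median, numeric(1L), na.rm = TRUE)
  grand <- median(meds)
  out <- grids
  out[usable] <- Map(function(g, m) g * (grand / m), grids[usable], meds)
  out
}

#' Row/column normalization
#'
#' Divides each value by its row median relative to the plate median, then
#' (with medians recomputed) by its column median relative to the plate
#' median. Rows or columns with no valid cells get factor 1.
#'
#' @param grid numeric matrix (`NA` = invalid).
#' @return normalized matrix.
#' @export
rowcolNormalize <- function(grid) {
  lineFactors <- function(g, margin) {
    pm <- median(g, na.rm = TRUE)
    lm <- apply(g, margin, median, na.rm = TRUE)
    f <- lm / pm
    f[!is.finite(f) | f == 0] <- 1
    f
  }
  f <- lineFactors(grid, 1L)
  grid <- grid / f
  f <- lineFactors(grid, 2L)
  t(t(grid) / f)
}

#' Spatial normalization
#'
#' Divides each value by the median of its `window x window` neighborhood
#' (clipped at the grid edges) relative to the plate median. Smooth spatial
#' gradients with period much larger than the window are removed; isolated
#' single-colony effects survive because the local median is robust to a
#' single outlier.
#'
#' @param grid numeric matrix (`NA` = invalid).
#' @param window odd window size >= 3 (default 7, about the colony-block
#'   scale).
#' @return normalized matrix.
#' @export
spatialNormalize <- function(grid, window = 7L) {
  stopifnot(window >= 3L, window %% 2L == 1L)
  h <- (window - 1L) %/% 2L
  nr <- nrow(grid); nc <- ncol(grid)
  pm <- median(grid, na.rm = TRUE)
  local <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1L, i - h):min(nr, i + h)
    for (j in seq_len(nc)) {
      cj <- max(1L, j - h):min(nc, j + h)
      local[i, j] <- median(grid[ri, cj], na.rm = TRUE)
    }
  }
  f <- local / pm
  f[!is.finite(f) | f == 0] <- 1
  grid / f
}

# table <-> per-plate grid helpers (row-major value grids keyed by plate)
tableToGrids <- function(df, metric, nRows, nCols) {
  plates <- unique(df$plate)
  setNames(lapply(plates, function(p) {
    g <- matrix(NA_real_, nRows, nCols)
    sub <- df[df$plate == p, ]
    g[cbind(sub$row, sub$col)] <- sub[[metric]]
    g
  }), plates)
}

gridsToColumn <- function(df, grids) {
  out <- rep(NA_real_, nrow(df))
  for (p in names(grids))
    out[df$plate == p] <-
      grids[[p]][cbind(df$row[df$plate == p], df$col[df$plate == p])]
  out
}

#' Full normalization pipeline on a phenotype table
#'
#' Applies, per requested metric independently and in this order:
#' plate-plate, row/column, then spatial normalization. Adds a
#' `<metric>_norm` column per metric.
#'
#' @param df phenotype table with columns `plate`, `row`, `col` and the
#'   metric columns.
#' @param metrics character vector of metric columns (e.g.
#'   `c("LTG", "MGR", "SPG", "CONV")`).
#' @param window spatial window size.
#' @return `df` with `<metric>_norm` columns appended.
#' @export
normalizePipeline <- function(df, metrics = c("LTG", "MGR", "SPG", "CONV"),
                              window = 7L) {
  stopifnot(all(c("plate", "row", "col") %in% names(df)))
  nRows <- max(df$row); nCols <- max(df$col)
  for (metric in metrics) {
    if (!metric %in% names(df)) stop("missing metric column: ", metric)
    grids <- tableToGrids(df, metric, nRows, nCols)
    grids <- plateNormalize(grids)
    grids <- lapply(grids, rowcolNormalize)
    grids <- lapply(grids, spatialNormalize, window = window)
    df[[paste0(metric, "_norm")]] <- gridsToColumn(df, grids)
  }
  df
}
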