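# Screening module: rank-product selection of growth-defective strains with
# permutation significance and pfp-based FDR, group classification, and the
# reproducibility metrics ICC and CV.

#' Rank-product statistic
#'
#' Within each replicate, strains are ranked (direction `"low"`: smallest
#' value gets rank 1; `"high"`: largest gets rank 1; ties receive average
#' ranks). The statistic is the geometric mean of rank ratios,
#' `(prod r_i / N_i)^(1/k)`. Strains missing in a replicate are ranked only
#' where present, with `k` adjusted per strain; all-missing strains get
#' `NA`.
#'
#' @param mat numeric matrix, strains x replicates, with strain rownames.
#' @param direction `"low"` (defect = small value) or `"high"`.
#' @return named numeric vector of statistics in `(0, 1]`.
#' @export
rankProduct <- function(mat, direction = c("low", "high")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(mat), ncol(mat) >= 2L, nrow(mat) >= 2L)
  lr <- matrix(NA_real_, nrow(mat), ncol(mat))
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    if (direction == "high") v <- -v
    present <- !is.na(v)
    Nj <- sum(present)
    if (Nj == 0L) next
    lr[present, j] <- log(rank(v[present], ties.method = "average") / Nj)
  }
  out <- exp(rowMeans(lr, na.rm = TRUE))
  out[rowSums(!is.na(lr)) == 0L] <- NA_real_
  names(out) <- rownames(mat)
  out
}

#' Permutation significance and pfp for rank products
#'
#' For each permutation, the observed ranks of every replicate are randomly
#' reassigned among the strains present in it and the rank products are
#' recomputed; this preserves the missingness pattern and tie structure.
#' `p` is the plus-one-corrected fraction of the pooled null statistics at
#' or below the observed one; `pfp` (percentage of false positives, the FDR
#' estimate) is the expected number of null statistics at or below the
#' observed one divided by the strain's rank position.
#'
#' @param mat strains x replicates matrix.
#' @param direction `"low"` or `"high"` (see [rankProduct()]).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed; identical seeds give identical p-values.
#' @return data.frame: `strain`, `rp`, `p`, `pfp`.
#' @export
rpSignificance <- function(mat, direction = c("low", "high"),
                           nPerm = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(nPerm >= 100L)
  obs <- rankProduct(mat, direction)
  N <- nrow(mat)
  k <- ncol(mat)
  # per-replicate observed rank-ratio pools (log scale)
  pools <- lapply(seq_len(k), function(j) {
    v <- mat[, j]
    if (direction == "high") v <- -v
    present <- !is.na(v)
    Nj <- sum(present)
    list(present = present,
         lr = if (Nj > 0L)
           log(rank(v[present], ties.method = "average") / Nj)
         else numeric(0L))
  })
  nullStats <- withSeed(seed, {
    out <- vector("list", nPerm)
    lrPerm <- matrix(NA_real_, N, k)
    for (b in seq_len(nPerm)) {
      for (j in seq_len(k)) {
        pj <- pools[[j]]
        if (length(pj$lr))
          lrPerm[pj$present, j] <- sample(pj$lr)
      }
      rpB <- exp(rowMeans(lrPerm, na.rm = TRUE))
      out[[b]] <- rpB[rowSums(!is.na(lrPerm)) > 0L]
    }
    unlist(out)
  })
  sorted <- sort(nullStats)
  M <- length(sorted)
  cnt <- findInterval(obs, sorted)        # null statistics <= observed
  p <- (cnt + 1) / (M + 1)
  eFP <- cnt / nPerm
  pos <- rank(obs, ties.method = "average", na.last = "keep")
  pfp <- eFP / pos
  data.frame(strain = rownames(mat) %||% as.character(seq_len(N)),
             rp = unname(obs), p = unname(p), pfp = unname(pfp))
}

#' Select growth-defective strains
#'
#' Strains passing both the p-value and pfp (FDR) thresholds. Monotone in
#' both thresholds: loosening either can only enlarge the selection.
#'
#' @param result data.frame from [rpSignificance()].
#' @param alpha p-value threshold (default 0.01).
#' @param fdr pfp threshold (default 0.01).
#' @return character vector of selected strain names.
#' @export
selectDefective <- function(result, alpha = 0.01, fdr = 0.01) {
  sel <- !is.na(result$p) & result$p < alpha & result$pfp < fdr
  result$strain[sel]
}

#' Classify defective strains into kinetic groups
#'
#' Intersects the slow-MGR, long-LTG and low-SPG selections into the
#' kinetic defect groups (long-lag slow growers, low-yield slow growers,
#' and the triple intersection).
#'
#' @param slowSet,longLtgSet,lowSpgSet character vectors of strain names.
#' @param universe optional full strain universe for the flag table.
#' @return list: `longLTG_slowMGR`, `lowSPG_slowMGR`, `all3` (character
#'   vectors) and `flags` (per-strain logical data.frame).
#' @export
classifyGroups <- function(slowSet, longLtgSet, lowSpgSet, universe = NULL) {
  if (is.null(universe))
    universe <- sort(unique(c(slowSet, longLtgSet, lowSpgSet)))
  flags <- data.frame(strain = universe,
                      slowMGR = universe %in% slowSet,
                      longLTG = universe %in% longLtgSet,
                      lowSPG = universe %in% lowSpgSet)
  list(longLTG_slowMGR = intersect(longLtgSet, slowSet),
       lowSPG_slowMGR = intersect(lowSpgSet, slowSet),
       all3 = Reduce(intersect, list(slowSet, longLtgSet, lowSpgSet)),
       flags = flags)
}

#' One-way ANOVA intra-class correlation coefficient
#'
#' `ICC(1) = (MSB - MSW) / (MSB + (k - 1) MSW)` from the one-way ANOVA of
#' repeated measurements grouped by strain, with the confidence interval
#' from the F distribution. Balanced designs are exact; unbalanced designs
#' use the mean group size `k0 = (N - sum(k_i^2)/N) / (n - 1)`.
#'
#' @param mat strains x repeats matrix (`NA` allowed).
#' @param conf confidence level (default 0.95).
#' @return list: `icc`, `lower`, `upper`, `F`, `df1`, `df2`, `k`.
#' @export
iccOneway <- function(mat, conf = 0.95) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L, ncol(mat) >= 2L)
  vals <- lapply(seq_len(nrow(mat)), function(i) mat[i, !is.na(mat[i, ])])
  ki <- lengths(vals)
  keep <- ki >= 1L
  vals <- vals[keep]; ki <- ki[keep]
  n <- length(vals)
  N <- sum(ki)
  if (n < 2L || N <= n) stop("need >= 2 strains and >= 2 repeats overall")
  all <- unlist(vals)
  if (var(all) == 0) stop("ICC undefined: zero total variance")
  grand <- mean(all)
  gm <- vapply(vals, mean, numeric(1L))
  ssb <- sum(ki * (gm - grand)^2)
  ssw <- sum(vapply(seq_len(n), function(i) sum((vals[[i]] - gm[i])^2),
                    numeric(1L)))
  df1 <- n - 1L
  df2 <- N - n
  msb <- ssb / df1
  msw <- ssw / df2
  k0 <- (N - sum(ki^2) / N) / (n - 1L)
  if (msw == 0) {
    return(list(icc = 1, lower = 1, upper = 1, F = Inf, df1 = df1,
                df2 = df2, k = k0))
  }
  Fv <- msb / msw
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  alpha <- 1 - conf
  FL <- Fv / qf(1 - alpha / 2, df1, df2)
  FU <- Fv * qf(1 - alpha / 2, df2, df1)
  list(icc = icc,
       lower = (FL - 1) / (FL + k0 - 1),
       upper = (FU - 1) / (FU + k0 - 1),
       F = Fv, df1 = df1, df2 = df2, k = k0)
}

#' Coefficient of variation (percent)
#'
#' `100 * sample SD / mean`; scale-invariant, zero for constant values.
#'
#' @param values numeric vector, `n >= 2`, non-zero mean.
#' @return CV in percent.
#' @export
cvPercent <- function(values) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 2L)
  m <- mean(values)
  if (m == 0) stop("CV undefined: zero mean")
  100 * sd(values) / m
}
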