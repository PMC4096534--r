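# Correction module: remove the growth-rate (MGR) dependence of lag (LTG)
# and yield (SPG) using theoretical lag / maintenance-energy relationships
# fitted by least trimmed squares, then subtract the fitted expectations.

#' Expected growth lag as a function of growth rate
#'
#' Theoretical population-lag relationship for dense inocula:
#' `lambda(mu) = log(1 + mu * tau) / mu`, where `tau` is the mean individual
#' growth lag. The small-`mu` limit is `tau` (computed by series expansion
#' for numerical stability).
#'
#' @param mu growth rate(s), strictly positive.
#' @param tau mean individual growth lag (hours), >= 0.
#' @return expected measured lag for each `mu`.
#' @examples
#' lagExpectation(1, 1)   # log(2)
#' @export
lagExpectation <- function(mu, tau) {
  stopifnot(tau >= 0)
  if (any(mu <= 0)) stop("mu must be > 0")
  x <- mu * tau
  out <- log1p(x) / mu
  tiny <- x < 1e-8
  if (any(tiny))
    out[tiny] <- tau * (1 - x[tiny] / 2 + x[tiny]^2 / 3)
  out
}

#' Expected growth yield as a function of growth rate
#'
#' Maintenance-energy relationship `Y(mu) = mu / ((1/Y_G) mu + m)`, with
#' maintenance coefficient `m >= 0` and theoretical growth yield `Y_G > 0`.
#' Monotone increasing in `mu` with limit `Y_G`.
#'
#' @param mu growth rate(s), strictly positive.
#' @param m maintenance coefficient, >= 0.
#' @param YG theoretical growth yield, > 0.
#' @return expected measured yield for each `mu`.
#' @examples
#' yieldExpectation(2, 0.5, 4)   # 2
#' @export
yieldExpectation <- function(mu, m, YG) {
  stopifnot(m >= 0, YG > 0)
  if (any(mu <= 0)) stop("mu must be > 0")
  mu / (mu / YG + m)
}

# least-squares fit of one model on a point subset; returns params or NULL
ltsInnerFit <- function(x, y, model) {
  if (model == "lag") {
    upper <- max(1e-6, 20 * max(abs(y)) + 1)
    opt <- optimize(function(tau) sum((y - lagExpectation(x, tau))^2),
                    interval = c(0, upper), tol = 1e-12)
    return(c(tau = opt$minimum))
  }
  # yield: linearization 1/y = 1/YG + m * (1/x) as a start, then refine on
  # the y-scale objective with log-parameterized (m, YG)
  ok <- y > 0
  if (sum(ok) < 2L) return(NULL)
  co <- tryCatch(coef(lm(I(1 / y[ok]) ~ I(1 / x[ok]))),
                 error = function(e) NULL)
  if (is.null(co) || any(!is.finite(co))) return(NULL)
  YG0 <- if (co[[1L]] > 0) 1 / co[[1L]] else max(y)
  m0 <- max(co[[2L]], 1e-8)
  obj <- function(p) sum((y - yieldExpectation(x, exp(p[1L]), exp(p[2L])))^2)
  fit <- tryCatch(optim(c(log(m0), log(YG0)), obj,
                        control = list(reltol = 1e-14, maxit = 2000L)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  c(m = exp(fit$par[1L]), YG = exp(fit$par[2L]))
}

ltsResiduals <- function(x, y, params, model) {
  pred <- if (model == "lag") lagExpectation(x, params[["tau"]])
          else yieldExpectation(x, params[["m"]], params[["YG"]])
  y - pred
}

#' Least trimmed squares fit of the lag or yield model
#'
#' Robust nonlinear regression minimizing the sum of the `h` smallest
#' squared residuals, `h = max(ceiling(trimFraction * n),
#' ceiling((n + p + 1) / 2))`. Implemented as concentration steps (fit on a
#' subset, re-select the `h` best residuals, repeat to convergence) from the
#' full-data start plus `nStarts` random elemental subsets; deterministic
#' given `seed`. The breakdown point is `1 - h/n`: a fit with the default
#' trim fraction 0.75 tolerates just under 25% arbitrary outliers; for
#' heavier contamination lower `trimFraction` (0.5 gives the maximal
#' breakdown).
#'
#' @param x growth rates (MGR), > 0.
#' @param y measured lag (LTG) or yield (SPG) values.
#' @param model `"lag"` (parameter `tau`) or `"yield"` (parameters `m`,
#'   `YG`).
#' @param trimFraction fraction of points retained, in `[0.5, 1]`.
#' @param nStarts number of random elemental starts.
#' @param seed integer seed for the random starts.
#' @return list of class `ltsFit`: `params`, `objective` (trimmed sum of
#'   squares), `h`, `subset` (indices of the h retained points), `model`.
#' @export
fitLTS <- function(x, y, model = c("lag", "yield"), trimFraction = 0.75,
                   nStarts = 50L, seed = 1L) {
  model <- match.arg(model)
  ok <- is.finite(x) & is.finite(y) & x > 0
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("need at least 10 finite points for the LTS fit")
  stopifnot(trimFraction >= 0.5, trimFraction <= 1)
  p <- if (model == "lag") 1L else 2L
  h <- as.integer(max(ceiling(trimFraction * n), ceiling((n + p + 1) / 2)))
  concentrate <- function(idx) {
    best <- NULL
    for (iter in seq_len(50L)) {
      params <- ltsInnerFit(x[idx], y[idx], model)
      if (is.null(params)) return(NULL)
      r2 <- ltsResiduals(x, y, params, model)^2
      newIdx <- sort(order(r2)[seq_len(h)])
      obj <- sum(r2[newIdx])
      best <- list(params = params, objective = obj, subset = newIdx)
      if (identical(newIdx, idx)) break
      idx <- newIdx
    }
    best
  }
  starts <- list(seq_len(n))
  withSeed(seed, {
    for (k in seq_len(nStarts))
      starts[[k + 1L]] <- sort(sample(n, min(n, p + 2L)))
  })
  best <- NULL
  for (st in starts) {
    cand <- if (length(st) < h) {
      params <- ltsInnerFit(x[st], y[st], model)
      if (is.null(params)) NULL
      else concentrate(sort(order(ltsResiduals(x, y, params, model)^2)[seq_len(h)]))
    } else concentrate(st)
    if (!is.null(cand) &&
        (is.null(best) || cand$objective < best$objective))
      best <- cand
  }
  if (is.null(best)) stop("LTS fit failed: no convergent subset found")
  structure(c(best, list(model = model, h = h, n = n,
                         trimFraction = trimFraction)),
            class = "ltsFit")
}

#' @export
print.ltsFit <- function(x, ...) {
  cat(sprintf("LTS %s fit: %s (h = %d of %d, objective %.4g)\n", x$model,
              paste(names(x$params), signif(unlist(x$params), 5),
                    sep = " = ", collapse = ", "),
              x$h, x$n, x$objective))
  invisible(x)
}

#' Subtract the MGR dependence from LTG and SPG
#'
#' Fits the lag model to (MGR, LTG) and the yield model to (MGR, SPG) by
#' least trimmed squares, then subtracts the fitted expectations:
#' `LTG_corr = LTG - lambda(MGR; tau_hat)` and
#' `SPG_corr = SPG - Y(MGR; m_hat, YG_hat)`. Invalid phenotypes pass
#' through as `NA`. The fitted curves are attached for reporting.
#'
#' @param df phenotype table; the columns named by `mgrCol`, `ltgCol`,
#'   `spgCol` are used (defaults target normalized values).
#' @param trimFraction,nStarts,seed passed to [fitLTS()].
#' @param mgrCol,ltgCol,spgCol column names.
#' @return `df` with `LTG_corr` and `SPG_corr` columns; attributes
#'   `lagFit`, `yieldFit` (the [fitLTS()] objects) and `curves` (a
#'   data.frame of the fitted expectations on an MGR grid).
#' @export
correctGrowthValues <- function(df, trimFraction = 0.75, nStarts = 50L,
                                seed = 1L, mgrCol = "MGR_norm",
                                ltgCol = "LTG_norm", spgCol = "SPG_norm") {
  stopifnot(all(c(mgrCol, ltgCol, spgCol) %in% names(df)))
  mu <- df[[mgrCol]]
  lagFit <- fitLTS(mu, df[[ltgCol]], "lag", trimFraction, nStarts,
                   subSeed(seed, 11L))
  yieldFit <- fitLTS(mu, df[[spgCol]], "yield", trimFraction, nStarts,
                     subSeed(seed, 12L))
  okMu <- is.finite(mu) & mu > 0
  ltgCorr <- spgCorr <- rep(NA_real_, nrow(df))
  ltgCorr[okMu] <- df[[ltgCol]][okMu] -
    lagExpectation(mu[okMu], lagFit$params[["tau"]])
  spgCorr[okMu] <- df[[spgCol]][okMu] -
    yieldExpectation(mu[okMu], yieldFit$params[["m"]],
                     yieldFit$params[["YG"]])
  df$LTG_corr <- ltgCorr
  df$SPG_corr <- spgCorr
  grid <- seq(min(mu[okMu]), max(mu[okMu]), length.out = 100L)
  attr(df, "lagFit") <- lagFit
  attr(df, "yieldFit") <- yieldFit
  attr(df, "curves") <- data.frame(
    mu = grid,
    lambda_hat = lagExpectation(grid, lagFit$params[["tau"]]),
    Y_hat = yieldExpectation(grid, yieldFit$params[["m"]],
                             yieldFit$params[["YG"]]))
  df
}
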