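# Kinetics module: series preprocessing, Gompertz regression, and the four
# growth values LTG / MGR / SPG / CONV.

#' Preprocess a raw growth series for Gompertz regression
#'
#' Applies, in order: (1) floor every raw value at 1 (the lower
#' quantification limit); (2) divide all values by the series minimum;
#' (3) keep, in time order, the first 25 points whose normalized value
#' strictly exceeds 1 and whose observation is flagged valid. Fewer than 5
#' qualifying points means the colony showed insufficient growth.
#'
#' The procedure is idempotent: preprocessing an already-preprocessed series
#' selects the same points.
#'
#' @param time observation hours.
#' @param value raw growth values (area, mass or mass*).
#' @param valid optional logical flags from the imaging stage; defaults to
#'   all finite observations.
#' @param maxPoints points retained for the regression (default 25).
#' @param minPoints minimum qualifying points (default 5).
#' @return list with `time`, `value` (normalized, qualifying points only),
#'   `ok`, `reason` (`NA` or `"insufficient growth"`), `nQualifying`, and
#'   the full floored-and-normalized series as `allTime` / `allValue`
#'   (re-running the preprocessing on these reproduces the same selection).
#' @export
preprocessSeries <- function(time, value, valid = NULL, maxPoints = 25L,
                             minPoints = 5L) {
  stopifnot(length(time) == length(value), length(time) >= 1L)
  if (is.null(valid)) valid <- rep(TRUE, length(value))
  valid <- valid & is.finite(value)
  ord <- order(time)
  time <- time[ord]; value <- value[ord]; valid <- valid[ord]
  floored <- pmax(value, 1)
  floored[!valid] <- NA_real_
  mn <- suppressWarnings(min(floored, na.rm = TRUE))
  if (!is.finite(mn))
    return(list(time = numeric(0L), value = numeric(0L), ok = FALSE,
                reason = "insufficient growth", nQualifying = 0L,
                allTime = time, allValue = rep(NA_real_, length(time))))
  normed <- floored / mn
  qual <- which(valid & !is.na(normed) & normed > 1)
  nq <- length(qual)
  keep <- qual[seq_len(min(maxPoints, nq))]
  list(time = time[keep], value = normed[keep], ok = nq >= minPoints,
       reason = if (nq >= minPoints) NA_character_ else "insufficient growth",
       nQualifying = nq, allTime = time, allValue = normed)
}

# starting values for the Gompertz fit: a0 slightly above the maximum,
# (b0, c0) from the linearization log(-log(y/a0)) = log b + t log c.
gompertzStart <- function(time, value) {
  a0 <- 1.05 * max(value)
  w <- value / a0
  ok <- w > 1e-12 & w < 1
  if (sum(ok) < 2L) return(NULL)
  z <- log(-log(w[ok]))
  fit <- stats::lm.fit(cbind(1, time[ok]), z)
  lc <- fit$coefficients[[2L]]
  lb <- fit$coefficients[[1L]]
  c0 <- exp(lc)
  if (!is.finite(c0) || c0 <= 0 || c0 >= 1) c0 <- 0.7
  b0 <- exp(lb)
  if (!is.finite(b0) || b0 <= 0) b0 <- 10
  c(a = a0, b = b0, c = min(max(c0, 1e-4), 1 - 1e-4))
}

#' Fit the Gompertz growth model
#'
#' Levenberg-Marquardt nonlinear least squares of `G(t) = a exp(-b c^t)`
#' with analytic gradients. Parameter bounds (`a > 0`, `b > 0`,
#' `0 < c < 1`) are enforced by log/logit transforms rather than constrained
#' optimization, so every converged fit satisfies them by construction.
#' Degenerate inputs (constant series, too few points) yield
#' `converged = FALSE` without raising.
#'
#' @param time,value preprocessed points ([preprocessSeries()]); at least 5,
#'   times ascending.
#' @return a [GompertzFit-class].
#' @examples
#' s <- genGompertzSeries(3.2, 40, 0.75, seq(0, 20, 0.5))
#' fitGompertz(s$time, s$value)
#' @export
fitGompertz <- function(time, value) {
  bad <- new("GompertzFit", a = NA_real_, b = NA_real_, c = NA_real_,
             rss = NA_real_, converged = FALSE,
             nPoints = min(length(time), 25L))
  if (length(time) < 5L || length(time) != length(value)) return(bad)
  if (is.unsorted(time, strictly = TRUE)) return(bad)
  if (!all(is.finite(value)) || sd(value) == 0) return(bad)
  start <- gompertzStart(time, value)
  if (is.null(start)) return(bad)
  par0 <- c(log(start[["a"]]), log(start[["b"]]),
            stats::qlogis(start[["c"]]))
  model <- function(p) {
    a <- exp(p[1L]); b <- exp(p[2L]); c <- stats::plogis(p[3L])
    a * exp(-b * c^time)
  }
  resid <- function(p) value - model(p)
  jac <- function(p) {
    a <- exp(p[1L]); b <- exp(p[2L]); c <- stats::plogis(p[3L])
    ct <- c^time
    g <- a * exp(-b * ct)
    cbind(-g,                       # d r / d log a
          g * b * ct,               # d r / d log b
          g * b * time * ct * (1 - c))  # d r / d logit c
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid, jac = jac,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200L, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:3 || any(!is.finite(fit$par)))
    return(bad)
  a <- exp(fit$par[1L]); b <- exp(fit$par[2L]); c <- stats::plogis(fit$par[3L])
  if (!is.finite(a) || !is.finite(b) || c <= 0 || c >= 1) return(bad)
  new("GompertzFit", a = a, b = b, c = c, rss = sum(resid(fit$par)^2),
      converged = TRUE, nPoints = min(length(time), 25L))
}

#' Growth characters from a Gompertz fit
#'
#' Closed forms derived from the fitted curve:
#' `LTG = (log(1/b) + 1) / log(c)` (where the tangent at the inflection
#' point crosses zero), `MGR = -a log(c) / e` (the maximum slope, attained
#' at the inflection), and `SPG = a` (the asymptote). A non-converged fit
#' yields all `NA`.
#'
#' @param fit a [GompertzFit-class].
#' @return named numeric vector `c(LTG=, MGR=, SPG=)`.
#' @export
growthCharacters <- function(fit) {
  if (!is(fit, "GompertzFit")) stop("fit must be a GompertzFit")
  if (!fit@converged)
    return(c(LTG = NA_real_, MGR = NA_real_, SPG = NA_real_))
  c(LTG = (log(1 / fit@b) + 1) / log(fit@c),
    MGR = -fit@a * log(fit@c) / exp(1),
    SPG = fit@a)
}

#' Conventional growth value (area at a fixed time)
#'
#' The prior standard for arrayed-colony screens: colony area at the scan
#' nearest the reference incubation time (default 20 h); equidistant scans
#' resolve to the earlier one. Undefined when the series ends more than one
#' scan interval before the reference time.
#'
#' @param time scan hours, ascending.
#' @param area colony areas (pixels) per scan.
#' @param refTime reference incubation time in hours.
#' @return area at the reference scan, or `NA` if undefined.
#' @export
conventionalValue <- function(time, area, refTime = 20) {
  stopifnot(length(time) == length(area), length(time) >= 1L)
  ord <- order(time)
  time <- time[ord]; area <- area[ord]
  interval <- if (length(time) > 1L) median(diff(time)) else Inf
  if (max(time) < refTime - interval) return(NA_real_)
  d <- abs(time - refTime)
  # tie -> earlier scan: among minimal distances pick the smallest time
  area[which(d <= min(d) + 1e-12)[1L]]
}

#' Analyze one colony series into a growth phenotype
#'
#' Composition of [preprocessSeries()], [fitGompertz()],
#' [growthCharacters()] and [conventionalValue()]. Failures at any stage are
#' captured in `valid` / `reason`, never raised.
#'
#' @param time scan hours.
#' @param value growth values of the chosen metric (mass* recommended).
#' @param area colony areas for the conventional value; defaults to `value`.
#' @param valid observation validity flags from imaging.
#' @param refTime reference time for CONV (hours).
#' @return one-row data.frame: `LTG`, `MGR`, `SPG`, `CONV`, `a`, `b`, `c`,
#'   `rss`, `nPoints`, `valid`, `reason`.
#' @export
analyzeColony <- function(time, value, area = NULL, valid = NULL,
                          refTime = 20) {
  if (is.null(area)) area <- value
  conv <- tryCatch(conventionalValue(time[!is.na(area)], area[!is.na(area)],
                                     refTime),
                   error = function(e) NA_real_)
  pre <- preprocessSeries(time, value, valid)
  out <- data.frame(LTG = NA_real_, MGR = NA_real_, SPG = NA_real_,
                    CONV = conv, a = NA_real_, b = NA_real_, c = NA_real_,
                    rss = NA_real_, nPoints = length(pre$time),
                    valid = FALSE, reason = NA_character_)
  if (!pre$ok) {
    out$reason <- pre$reason
    return(out)
  }
  fit <- fitGompertz(pre$time, pre$value)
  if (!fit@converged) {
    out$reason <- "regression failed"
    return(out)
  }
  ch <- growthCharacters(fit)
  out$LTG <- ch[["LTG"]]; out$MGR <- ch[["MGR"]]; out$SPG <- ch[["SPG"]]
  out$a <- fit@a; out$b <- fit@b; out$c <- fit@c; out$rss <- fit@rss
  out$valid <- ch[["MGR"]] > 0 && ch[["SPG"]] > 0
  if (!out$valid) out$reason <- "non-positive growth characters"
  out
}

#' Growth phenotypes for every position of a measured plate
#'
#' Runs [analyzeColony()] on the chosen assay of a [measureTimelapse()]
#' result.
#'
#' @param se SummarizedExperiment from [measureTimelapse()].
#' @param metric assay used for kinetics: `"mass_center"` (default),
#'   `"mass"` or `"area"`.
#' @param refTime reference time for CONV (hours).
#' @return data.frame with one row per position: `plate`, `row`, `col`,
#'   phenotype columns of [analyzeColony()].
#' @export
colonyPhenotypes <- function(se, metric = c("mass_center", "mass", "area"),
                             refTime = 20) {
  metric <- match.arg(metric)
  rd <- SummarizedExperiment::rowData(se)
  cd <- SummarizedExperiment::colData(se)
  vals <- SummarizedExperiment::assay(se, metric)
  areas <- SummarizedExperiment::assay(se, "area")
  valid <- SummarizedExperiment::assay(se, "valid")
  rows <- lapply(seq_len(nrow(se)), function(i)
    analyzeColony(cd$time, vals[i, ], areas[i, ], valid[i, ], refTime))
  out <- do.call(rbind, rows)
  cbind(data.frame(plate = cd$plate[1L], row = rd$row, col = rd$col), out)
}
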