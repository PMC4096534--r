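# Imaging module: lighting correction, Otsu binarization, grid detection,
# colony-region extraction, and the mass / center-mass (mass*) quantities.

#' Otsu intensity threshold
#'
#' Exact Otsu threshold: the cut maximizing the between-class variance of the
#' intensity distribution, computed over the observed intensity levels (no
#' histogram binning), so the threshold is translation-equivariant on
#' arbitrary linear intensity scales. The returned value is the midpoint
#' between the two levels straddling the optimal cut.
#'
#' @param image a [PlateImage-class] or numeric matrix/vector.
#' @return a single intensity threshold.
#' @examples
#' otsuThreshold(c(rep(10, 90), rep(100, 10)))
#' @export
otsuThreshold <- function(image) {
  v <- if (is(image, "PlateImage")) pixels(image) else image
  v <- as.numeric(v)
  u <- sort(unique(v))
  if (length(u) < 2L)
    stop("Otsu threshold undefined: image has a single intensity value")
  cnt <- tabulate(match(v, u))
  n <- length(v)
  cw <- cumsum(cnt)                       # class-0 sizes per cut after u[k]
  cs <- cumsum(cnt * u)
  tot <- cs[length(cs)]
  k <- seq_len(length(u) - 1L)
  w0 <- cw[k] / n
  w1 <- 1 - w0
  mu0 <- cs[k] / cw[k]
  mu1 <- (tot - cs[k]) / (n - cw[k])
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  kstar <- which.max(sigma_b)
  (u[kstar] + u[kstar + 1L]) / 2
}

# Otsu threshold from a deterministic pixel subsample: plenty for masking
# purposes and much cheaper than the exact threshold on megapixel scans.
sampledThreshold <- function(px, maxPixels = 50000L) {
  v <- as.numeric(px)
  if (length(v) > maxPixels)
    v <- v[round(seq(1L, length(v), length.out = maxPixels))]
  otsuThreshold(v)
}

#' Correct the lighting gradient of a plate image
#'
#' Estimates the large-scale multiplicative intensity trend from non-colony
#' (agar) pixels by fitting a quadratic polynomial surface, then divides it
#' out. The surface is normalized to mean 1 so the overall intensity scale is
#' preserved; a flat image passes through unchanged up to global scale.
#'
#' @param image a [PlateImage-class].
#' @param maxFitPixels background pixels are subsampled to at most this many
#'   for the surface fit.
#' @return corrected [PlateImage-class].
#' @export
correctLighting <- function(image, maxFitPixels = 20000L) {
  px <- pixels(image)
  rng <- range(px)
  if (rng[1L] == rng[2L]) return(image)
  thr <- sampledThreshold(px)
  bg <- px >= thr                         # agar is bright; colonies dark
  if (sum(bg) < 100L) bg[] <- TRUE        # nearly-dark image: fit everything
  H <- nrow(px); W <- ncol(px)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  idx <- which(bg)
  if (length(idx) > maxFitPixels)
    idx <- idx[seq(1L, length(idx), length.out = maxFitPixels)]
  uN <- xx[idx] / W; vN <- yy[idx] / H
  X <- cbind(1, uN, vN, uN^2, uN * vN, vN^2)
  beta <- qr.solve(crossprod(X), crossprod(X, px[idx]))
  uF <- as.numeric(xx) / W; vF <- as.numeric(yy) / H
  surf <- matrix(cbind(1, uF, vF, uF^2, uF * vF, vF^2) %*% beta, H, W)
  surf <- surf / mean(surf)
  if (any(surf <= 0)) return(image)       # degenerate fit: leave untouched
  PlateImage(pmax(px / surf, 0), plateId(image), scanTime(image))
}

#' Detect the colony array lattice
#'
#' Binarizes the (lighting-corrected) image with the Otsu threshold, labels
#' connected colony components, and fits an affine lattice per axis to the
#' component centroids. Exactly `nRows * nCols` centers are returned, ordered
#' by (row, col); positions with no detectable colony are inferred from the
#' lattice fit.
#'
#' @param image a [PlateImage-class].
#' @param nRows,nCols expected array dimensions.
#' @param minComponentPx components smaller than this are treated as noise.
#' @return an [ArrayLayout-class].
#' @export
detectGrid <- function(image, nRows, nCols, minComponentPx = 9L) {
  img <- correctLighting(image)
  px <- pixels(img)
  thr <- sampledThreshold(px)
  mask <- px < thr
  lab <- EBImage::bwlabel(mask)
  nLab <- max(lab)
  if (nLab < 1L) stop("grid not found: no colony components detected")
  sizes <- tabulate(lab[lab > 0L], nbins = nLab)
  keep <- which(sizes >= minComponentPx)
  if (length(keep) < nRows * nCols / 2)
    stop("grid not found: fewer than half the expected colonies detected")
  labs <- lab[lab > 0L]
  okpix <- labs %in% keep
  idxAll <- which(lab > 0L, arr.ind = TRUE)[okpix, , drop = FALSE]
  labsOk <- labs[okpix]
  cy <- tapply(idxAll[, 1L], labsOk, mean)
  cx <- tapply(idxAll[, 2L], labsOk, mean)
  fitAxis <- function(z, nLines) {
    z0 <- min(z); z1 <- max(z)
    if (nLines == 1L) return(c(mean(z), 0, 0))
    p0 <- (z1 - z0) / (nLines - 1L)
    if (p0 <= 0) stop("grid not found: colony centers are collinear")
    iz <- round((z - z0) / p0)
    co <- coef(lm(z ~ iz))
    resid <- z - (co[[1L]] + iz * co[[2L]])
    c(co[[1L]], co[[2L]], mean(abs(resid)))
  }
  ax <- fitAxis(cx, nCols)
  ay <- fitAxis(cy, nRows)
  # centroids must sit on a regular lattice; large axis-fit residuals mean
  # the detected components are not an array
  pitch0 <- mean(c(if (nCols > 1L) ax[2L], if (nRows > 1L) ay[2L]))
  if (!is.finite(pitch0) || pitch0 <= 0 ||
      max(ax[3L], ay[3L]) > pitch0 / 4)
    stop("grid not found: detected components do not form a regular lattice")
  grid <- expand.grid(col = seq_len(nCols), row = seq_len(nRows))
  cenX <- ax[1L] + (grid$col - 1L) * ax[2L]
  cenY <- ay[1L] + (grid$row - 1L) * ay[2L]
  pit <- mean(c(if (nCols > 1L) ax[2L], if (nRows > 1L) ay[2L]))
  ArrayLayout(nRows, nCols, cbind(x = cenX, y = cenY), pit)
}

# Internal single-window extraction; `px` is the pixel matrix. Returns a
# plain list for speed; extractColonyRegion() wraps it in the S4 class.
# The cell window is a pitch x pitch square clipped to the image; the
# background band is its outer 15% frame with colony-like pixels (below
# median - 4 * robust SD) excluded. agarSd carries a tiny relative floor so
# a strictly noiseless rendering does not binarize its own float jitter.
extractRegionRaw <- function(px, cx, cy, pit, sdMultiple = 10) {
  H <- nrow(px); W <- ncol(px)
  half <- pit / 2
  xs <- max(1L, ceiling(cx - half)):min(W, floor(cx + half))
  ys <- max(1L, ceiling(cy - half)):min(H, floor(cy + half))
  win <- px[ys, xs, drop = FALSE]
  bw <- max(2L, round(0.15 * min(length(xs), length(ys))))
  border <- matrix(FALSE, length(ys), length(xs))
  border[c(seq_len(bw), length(ys) - seq_len(bw) + 1L), ] <- TRUE
  border[, c(seq_len(bw), length(xs) - seq_len(bw) + 1L)] <- TRUE
  band <- win[border]
  med <- median(band)
  rsd <- mad(band)
  agar <- band[band >= med - 4 * max(rsd, 1e-9 * med)]
  if (length(agar) < 5L || mean(agar) <= 0) {
    return(list(valid = FALSE, member = matrix(integer(), 0L, 2L),
                agarMean = NA_real_, agarSd = NA_real_, threshold = NA_real_))
  }
  agarMean <- mean(agar)
  agarSd <- max(sd(agar), 1e-9 * agarMean)
  thr <- agarMean - sdMultiple * agarSd
  sel <- which(win < thr, arr.ind = TRUE)
  member <- cbind(y = ys[sel[, 1L]], x = xs[sel[, 2L]])
  list(valid = TRUE, member = member, agarMean = agarMean, agarSd = agarSd,
       threshold = thr, window = list(xs = xs, ys = ys))
}

#' Extract the colony region at one array position
#'
#' Segments the colony in the position's cell window (a pitch x pitch square
#' around the lattice center). Background statistics come from the window's
#' outer 15% border band, excluding colony-like pixels; member pixels are
#' those whose intensity falls below `agarMean - 10 * agarSd` (one-sided:
#' transmitted-light colonies are darker than agar).
#'
#' @param image a [PlateImage-class] (lighting-corrected for best results).
#' @param layout an [ArrayLayout-class].
#' @param row,col 1-based array position.
#' @param sdMultiple threshold offset in background SDs (default 10).
#' @return a [ColonyRegion-class].
#' @export
extractColonyRegion <- function(image, layout, row, col, sdMultiple = 10) {
  dims <- gridDims(layout)
  stopifnot(row >= 1, row <= dims[["nRows"]], col >= 1, col <= dims[["nCols"]])
  i <- (row - 1L) * dims[["nCols"]] + col
  cen <- centers(layout)[i, ]
  r <- extractRegionRaw(pixels(image), cen[1L], cen[2L], pitch(layout),
                        sdMultiple)
  new("ColonyRegion", position = c(as.integer(row), as.integer(col)),
      memberPixels = r$member, thresholdUsed = r$threshold %||% NA_real_,
      agarMean = r$agarMean, agarSd = r$agarSd, valid = r$valid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# absorbance of member pixels relative to the region's agar mean, with
# negative absorbance (pixel brighter than agar) clipped to 0 and zero
# intensities floored at the smallest positive double.
memberAbsorbance <- function(px, region) {
  member <- if (is(region, "ColonyRegion")) region@memberPixels else region$member
  agarMean <- if (is(region, "ColonyRegion")) region@agarMean else region$agarMean
  if (nrow(member) == 0L) return(numeric(0L))
  I <- px[cbind(member[, 1L], member[, 2L])]
  if (any(I <= 0)) {
    warning("member pixel with non-positive intensity floored at the ",
            "smallest representable unit")
    I <- pmax(I, .Machine$double.xmin)
  }
  pmax(0, -log10(I / agarMean))
}

#' Integrated colony mass
#'
#' `mass = sum over member pixels of max(0, -log10(I_i / I_agar))`, the
#' integrated pixel absorbance of the whole colony region. An empty region
#' has mass 0.
#'
#' @param image a [PlateImage-class].
#' @param region a [ColonyRegion-class].
#' @return a single non-negative number (absorbance x pixels).
#' @export
colonyMass <- function(image, region) {
  sum(memberAbsorbance(pixels(image), region))
}

#' Center-region colony mass (mass*)
#'
#' The same absorbance integral as [colonyMass()], restricted to member
#' pixels within a disc of the given diameter around the colony center. The
#' center is the absorbance-weighted centroid of the region (falling back to
#' the lattice center for an empty region); a pixel belongs to the disc when
#' its center lies within Euclidean distance `diameter / 2` (inclusive) of
#' the colony center. Always `<=` the whole-region mass.
#'
#' @param image a [PlateImage-class].
#' @param region a [ColonyRegion-class].
#' @param diameter disc diameter in pixels (default 17, about 1 mm at the
#'   reference scan resolution; tune per setup).
#' @param center optional `c(x, y)` override of the disc center.
#' @return a single non-negative number.
#' @export
colonyMassCenter <- function(image, region, diameter = 17, center = NULL) {
  stopifnot(diameter >= 1)
  px <- pixels(image)
  absb <- memberAbsorbance(px, region)
  member <- region@memberPixels
  if (length(absb) == 0L) return(0)
  if (is.null(center)) {
    if (sum(absb) > 0) {
      center <- c(sum(member[, 2L] * absb), sum(member[, 1L] * absb)) / sum(absb)
    } else {
      center <- c(mean(member[, 2L]), mean(member[, 1L]))
    }
  }
  d2 <- (member[, 2L] - center[1L])^2 + (member[, 1L] - center[2L])^2
  sum(absb[d2 <= (diameter / 2)^2])
}

#' Measure a time-lapse image stack over an array layout
#'
#' Quantifies every array position in every scan: colony area (pixels),
#' whole-region mass, center-region mass (mass*) and a validity flag.
#' Positions whose background band cannot be estimated are flagged invalid,
#' not dropped.
#'
#' @param images list of [PlateImage-class] with ascending scan times and
#'   identical dimensions.
#' @param layout an [ArrayLayout-class].
#' @param centerDiameter disc diameter for mass* (pixels).
#' @param correct apply [correctLighting()] to each scan first.
#' @return a [SummarizedExperiment::SummarizedExperiment] with one row per
#'   array position (rowData: `row`, `col`) and one column per scan
#'   (colData: `time`, `plate`); assays `area`, `mass`, `mass_center`,
#'   `valid`.
#' @export
measureTimelapse <- function(images, layout, centerDiameter = 17,
                             correct = TRUE) {
  stopifnot(length(images) >= 1L)
  times <- vapply(images, scanTime, numeric(1L))
  stopifnot(!is.unsorted(times))
  dims <- vapply(images, function(im) dim(pixels(im)), integer(2L))
  if (any(dims != dims[, 1L]))
    stop("all scans in a time-lapse must share dimensions")
  dimsL <- gridDims(layout)
  nPos <- dimsL[["nRows"]] * dimsL[["nCols"]]
  nT <- length(images)
  area <- mass <- massC <- matrix(NA_real_, nPos, nT)
  valid <- matrix(FALSE, nPos, nT)
  cen <- centers(layout)
  pit <- pitch(layout)
  for (j in seq_len(nT)) {
    img <- if (correct) correctLighting(images[[j]]) else images[[j]]
    px <- pixels(img)
    for (i in seq_len(nPos)) {
      r <- extractRegionRaw(px, cen[i, 1L], cen[i, 2L], pit)
      if (!r$valid) next
      valid[i, j] <- TRUE
      area[i, j] <- nrow(r$member)
      if (nrow(r$member) == 0L) {
        mass[i, j] <- massC[i, j] <- 0
        next
      }
      I <- px[cbind(r$member[, 1L], r$member[, 2L])]
      absb <- pmax(0, -log10(pmax(I, .Machine$double.xmin) / r$agarMean))
      mass[i, j] <- sum(absb)
      sA <- sum(absb)
      ctr <- if (sA > 0)
        c(sum(r$member[, 2L] * absb), sum(r$member[, 1L] * absb)) / sA
      else cen[i, ]
      d2 <- (r$member[, 2L] - ctr[1L])^2 + (r$member[, 1L] - ctr[2L])^2
      massC[i, j] <- sum(absb[d2 <= (centerDiameter / 2)^2])
    }
  }
  idx <- expand.grid(col = seq_len(dimsL[["nCols"]]),
                     row = seq_len(dimsL[["nRows"]]))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(area = area, mass = mass, mass_center = massC,
                  valid = valid),
    rowData = S4Vectors::DataFrame(row = idx$row, col = idx$col),
    colData = S4Vectors::DataFrame(
      time = times,
      plate = vapply(images, plateId, character(1L))))
}

#' Long-format observation table from a measured time-lapse
#'
#' @param se result of [measureTimelapse()].
#' @return data.frame with columns `plate`, `row`, `col`, `time_h`,
#'   `area_px`, `mass`, `mass_center`, `valid`.
#' @export
observationTable <- function(se) {
  rd <- SummarizedExperiment::rowData(se)
  cd <- SummarizedExperiment::colData(se)
  nPos <- nrow(se); nT <- ncol(se)
  data.frame(
    plate = rep(cd$plate, each = nPos),
    row = rep(rd$row, times = nT),
    col = rep(rd$col, times = nT),
    time_h = rep(cd$time, each = nPos),
    area_px = as.vector(SummarizedExperiment::assay(se, "area")),
    mass = as.vector(SummarizedExperiment::assay(se, "mass")),
    mass_center = as.vector(SummarizedExperiment::assay(se, "mass_center")),
    valid = as.vector(SummarizedExperiment::assay(se, "valid")))
}
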