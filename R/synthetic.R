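# Synthetic-data module: plate image stacks and screen tables with known
# ground truth, so every downstream stage is testable without external data.

#' Gompertz growth model
#'
#' `G(t) = a * exp(-b * c^t)` with saturation `a`, displacement `b` and rate
#' base `c` (0 < c < 1). This is the model all growth series in the package
#' are fitted to.
#'
#' @param t time (hours), vectorized.
#' @param a saturation level, > 0.
#' @param b displacement, > 0.
#' @param c rate base, strictly between 0 and 1.
#' @return growth value at each `t`.
#' @examples
#' gompertz(0:20, a = 3, b = 40, c = 0.7)
#' @export
gompertz <- function(t, a, b, c) {
  stopifnot(a > 0, b > 0, c > 0, c < 1)
  a * exp(-b * c^t)
}

#' Generate a Gompertz growth series
#'
#' Evaluates the Gompertz model on a time grid and adds zero-mean Gaussian
#' noise. The noiseless series is strictly increasing in time.
#'
#' @inheritParams gompertz
#' @param times non-empty ascending vector of hours.
#' @param noiseSd standard deviation of additive noise (>= 0).
#' @param seed optional integer seed (caller's RNG stream is preserved).
#' @return data.frame with columns `time` and `value`.
#' @examples
#' genGompertzSeries(2, 50, 0.7, times = seq(0, 20, 0.5))
#' @export
genGompertzSeries <- function(a, b, c, times, noiseSd = 0, seed = NULL) {
  stopifnot(length(times) >= 1L, !is.unsorted(times, strictly = TRUE),
            noiseSd >= 0)
  if (c >= 1 || c <= 0)
    stop("c must lie strictly in (0, 1): non-growth parameterization")
  value <- gompertz(times, a, b, c)
  if (noiseSd > 0)
    value <- value + withSeed(seed, rnorm(length(times), 0, noiseSd))
  data.frame(time = times, value = value)
}

#' Simulated plate specification
#'
#' Geometry, optics and schedule of a synthetic time-lapse plate. Defaults
#' describe a 1536-format array (32 rows x 48 columns) scanned every 30
#' minutes over 20 h. Intensities are arbitrary linear units in [0, 1]; the
#' scanner's true bit depth and units are not modeled.
#'
#' @param nRows,nCols array dimensions.
#' @param pixelPitch pixels between adjacent colony centers.
#' @param agarIntensity mean transmitted-light level of bare agar.
#' @param vignetteAmplitude fractional amplitude of the smooth multiplicative
#'   lighting gradient (quadratic bowl, darker corners).
#' @param noiseSd per-pixel additive Gaussian noise SD (intensity units).
#' @param scanIntervalH hours between scans.
#' @param durationH total incubation hours.
#' @param margin pixels between the outermost colony centers and the image
#'   edge; must be >= pixelPitch / 2 so all colonies fit.
#' @param seed integer seed for all randomness derived from this plate.
#' @return object of class `SimPlateSpec`.
#' @examples
#' simPlateSpec(nRows = 4, nCols = 6, pixelPitch = 30)
#' @export
simPlateSpec <- function(nRows = 32, nCols = 48, pixelPitch = 40,
                         agarIntensity = 0.85, vignetteAmplitude = 0.06,
                         noiseSd = 0.004, scanIntervalH = 0.5,
                         durationH = 20, margin = pixelPitch, seed = 1L) {
  stopifnot(nRows >= 1, nCols >= 1, pixelPitch > 0, agarIntensity > 0,
            noiseSd >= 0, scanIntervalH > 0, durationH > 0)
  if (margin < pixelPitch / 2)
    stop("margin must be >= pixelPitch/2 so colonies fit inside the image")
  spec <- list(nRows = as.integer(nRows), nCols = as.integer(nCols),
               pixelPitch = pixelPitch, agarIntensity = agarIntensity,
               vignetteAmplitude = vignetteAmplitude, noiseSd = noiseSd,
               scanIntervalH = scanIntervalH, durationH = durationH,
               margin = margin, seed = seed)
  class(spec) <- "SimPlateSpec"
  spec
}

#' @export
print.SimPlateSpec <- function(x, ...) {
  cat(sprintf(
    "SimPlateSpec: %d x %d array, pitch %g px, %g h every %g h, noise %g\n",
    x$nRows, x$nCols, x$pixelPitch, x$durationH, x$scanIntervalH, x$noiseSd))
  invisible(x)
}

# scan schedule of a spec
scanTimes <- function(spec) seq(0, spec$durationH, by = spec$scanIntervalH)

# true lattice of a spec: centers in image coordinates, row-major
specLayout <- function(spec) {
  idx <- expand.grid(col = seq_len(spec$nCols), row = seq_len(spec$nRows))
  cx <- spec$margin + (idx$col - 0.5) * spec$pixelPitch
  cy <- spec$margin + (idx$row - 0.5) * spec$pixelPitch
  ArrayLayout(spec$nRows, spec$nCols, cbind(x = cx, y = cy), spec$pixelPitch)
}

specImageDims <- function(spec) {
  c(H = ceiling(2 * spec$margin + spec$nRows * spec$pixelPitch),
    W = ceiling(2 * spec$margin + spec$nCols * spec$pixelPitch))
}

#' Per-colony ground-truth parameters for a simulated plate
#'
#' Draws one Gompertz parameter set per array position. Default kinetics
#' (lag ~ 1.7 h, inflection ~ 4 h, saturation well before 20 h) emulate
#' colonies pinned from a dense inoculum. Colony-to-colony variation is
#' lognormal on `a` (saturation mass) and `c` (rate base, through `log c`).
#'
#' @param spec a [simPlateSpec()].
#' @param aMean mean saturation mass (absorbance x pixels).
#' @param aCV lognormal coefficient of variation of `a` across colonies.
#' @param b displacement parameter (shared).
#' @param cMean mean rate base.
#' @param cCV coefficient of variation applied to `-log(c)` across colonies
#'   (so MGR varies proportionally).
#' @param peak per-pixel absorbance at the colony center at saturation; the
#'   cap height at smaller masses scales with the dome radius (colonies
#'   thicken as they widen, so mass grows as radius cubed).
#' @param seed integer seed; per-colony substreams are derived from it.
#' @return data.frame with one row per position: `row`, `col`, `a`, `b`,
#'   `c`, `peak`, and the derived dome-shape coefficient `kappa`.
#' @export
simColonyTruths <- function(spec, aMean = 600, aCV = 0.05, b = 5.6,
                            cMean = 0.65, cCV = 0, peak = 1.19,
                            seed = spec$seed) {
  idx <- expand.grid(col = seq_len(spec$nCols), row = seq_len(spec$nRows))
  n <- nrow(idx)
  withSeed(subSeed(seed, 1L), {
    a <- if (aCV > 0) rlnorm(n, log(aMean) - log(1 + aCV^2) / 2,
                             sqrt(log(1 + aCV^2))) else rep(aMean, n)
    lc <- -log(cMean)
    lcs <- if (cCV > 0) lc * rlnorm(n, -log(1 + cCV^2) / 2,
                                    sqrt(log(1 + cCV^2))) else rep(lc, n)
    data.frame(row = idx$row, col = idx$col, a = a, b = b,
               c = exp(-lcs), peak = peak, kappa = domeShape(a, peak))
  })
}

#' Neighbor-effect model
#'
#' Phenomenological growth suppression by nearby colonies. Once a colony's
#' diameter exceeds `onsetDiameter` (the empirical size below which no
#' crowding differences are seen), each subsequent growth increment is
#' divided by `1 + suppressionCoeff * sum(neighbor masses within
#' interactionRadius)`. A coefficient of zero reproduces independent growth
#' exactly.
#'
#' @param suppressionCoeff dimensionless suppression strength, >= 0.
#' @param interactionRadius pixels; neighbors within this center-to-center
#'   distance suppress each other. `NULL` means 1.6 x pitch (the 8-cell
#'   neighborhood) at render time.
#' @param onsetDiameter colony diameter (pixels) at which suppression starts.
#' @return object of class `NeighborModel`.
#' @export
neighborModel <- function(suppressionCoeff = 0, interactionRadius = NULL,
                          onsetDiameter = 17) {
  stopifnot(suppressionCoeff >= 0, onsetDiameter > 0)
  structure(list(suppressionCoeff = suppressionCoeff,
                 interactionRadius = interactionRadius,
                 onsetDiameter = onsetDiameter),
            class = "NeighborModel")
}

# Dome geometry. A colony is a quadratic absorbance cap
# A(r) = h * max(0, 1 - (r/r0)^2) whose height grows with its radius,
# h = kappa * r0 (colonies thicken as they widen), so integrated absorbance
# m = pi * kappa * r0^3 / 2 and the radius scales as m^(1/3). kappa is set
# per colony so that the cap height at saturation (mass = a) equals the
# requested peak absorbance: r0sat = sqrt(2a / (pi * peak)),
# kappa = peak / r0sat.
domeShape <- function(a, peak) peak / sqrt(2 * a / (pi * peak))

domeRadius <- function(m, kappa) (pmax(0, 2 * m / (pi * kappa)))^(1 / 3)

#' Apply the neighbor effect to ideal growth trajectories
#'
#' Runs the discrete per-scan suppression dynamic: at each scan the ideal
#' Gompertz increment of every colony past onset is divided by
#' `1 + s * sum(neighbor masses at the previous scan)`. Growth before a
#' colony reaches the onset diameter is unchanged.
#'
#' @param truths data.frame from [simColonyTruths()].
#' @param spec the plate spec (for the lattice geometry and scan schedule).
#' @param neighbor a [neighborModel()].
#' @return numeric matrix of true masses, one row per colony (in `truths`
#'   order), one column per scan; attribute `times` carries the scan hours.
#' @export
applyNeighborEffect <- function(truths, spec, neighbor = neighborModel()) {
  times <- scanTimes(spec)
  n <- nrow(truths)
  ideal <- t(vapply(seq_len(n), function(i)
    gompertz(times, truths$a[i], truths$b[i], truths$c[i]),
    numeric(length(times))))
  s <- neighbor$suppressionCoeff
  if (s == 0) {
    attr(ideal, "times") <- times
    return(ideal)
  }
  rad <- neighbor$interactionRadius
  if (is.null(rad)) rad <- 1.6 * spec$pixelPitch
  cen <- centers(specLayout(spec))
  # truths rows may be any subset/order of the lattice; locate their centers
  pos <- (truths$row - 1L) * spec$nCols + truths$col
  cen <- cen[pos, , drop = FALSE]
  d2 <- outer(cen[, 1], cen[, 1], "-")^2 + outer(cen[, 2], cen[, 2], "-")^2
  adj <- (d2 <= rad^2) & (d2 > 0)
  mass <- matrix(0, n, length(times))
  mass[, 1L] <- ideal[, 1L]
  onset <- neighbor$onsetDiameter
  for (j in 2L:length(times)) {
    inc <- ideal[, j] - ideal[, j - 1L]
    prev <- mass[, j - 1L]
    sup <- 1 + s * as.numeric(adj %*% prev)
    past <- 2 * domeRadius(prev, truths$kappa) > onset
    mass[, j] <- prev + ifelse(past, inc / sup, inc)
  }
  attr(mass, "times") <- times
  mass
}

# One colony dome as a local patch (indices + values). The sampled profile
# is rescaled so the *discrete* pixel sum equals the target mass exactly,
# which keeps rendered mass and recorded truth identical up to floating
# point. The caller adds the patch in place to avoid copying the full
# image accumulator per colony.
domePatch <- function(H, W, cx, cy, m, kappa) {
  if (m <= 0) return(NULL)
  r0 <- domeRadius(m, kappa)
  xs <- max(1L, floor(cx - r0)):min(W, ceiling(cx + r0))
  ys <- max(1L, floor(cy - r0)):min(H, ceiling(cy + r0))
  prof <- outer((ys - cy)^2, (xs - cx)^2, "+")
  prof <- (kappa * r0) * pmax(0, 1 - prof / r0^2)
  s <- sum(prof)
  if (s <= 0) return(NULL)
  list(xs = xs, ys = ys, values = prof * (m / s))
}

# multiplicative vignette surface: quadratic bowl, darker corners
vignetteSurface <- function(H, W, amplitude) {
  u <- ((seq_len(W) - (W + 1) / 2) / ((W - 1) / 2))
  v <- ((seq_len(H) - (H + 1) / 2) / ((H - 1) / 2))
  1 - amplitude * outer(v^2, u^2, "+") / 2
}

#' Render a synthetic time-lapse image stack
#'
#' Composes, for each scan, all colony absorbance domes on the lattice, then
#' applies the multiplicative lighting gradient and additive pixel noise:
#' `I = agar * 10^(-A) * vignette + noise` (clamped at 0). Each dome is a
#' radially decreasing quadratic cap whose integrated absorbance equals the
#' colony's true mass at that scan.
#'
#' @param spec a [simPlateSpec()].
#' @param truths data.frame from [simColonyTruths()] (may cover a subset of
#'   positions; omitted positions stay empty).
#' @param neighbor a [neighborModel()].
#' @param times scan hours to render; default the full schedule. Rendering a
#'   subset produces bit-identical images to the corresponding members of
#'   the full stack.
#' @param plateId plate identifier stamped on every image.
#' @return list with `images` (list of [PlateImage-class]), `truth`
#'   (long data.frame `row`, `col`, `time`, `trueMass`), `massMatrix`
#'   (colonies x scans), `layout` (the true [ArrayLayout-class]) and
#'   `params` (the input truths).
#' @export
renderTimelapse <- function(spec, truths, neighbor = neighborModel(),
                            times = NULL, plateId = "plate1") {
  stopifnot(all(truths$row >= 1), all(truths$row <= spec$nRows),
            all(truths$col >= 1), all(truths$col <= spec$nCols))
  massMat <- applyNeighborEffect(truths, spec, neighbor)
  allTimes <- attr(massMat, "times")
  if (is.null(times)) times <- allTimes
  scanIdx <- match(times, allTimes)
  if (anyNA(scanIdx)) stop("requested times are not on the scan schedule")
  finalR <- domeRadius(massMat[, ncol(massMat)], truths$kappa)
  if (any(2 * finalR > spec$pixelPitch))
    stop("pixel_pitch too small: colony domes would overlap at saturation")
  dims <- specImageDims(spec)
  H <- dims[["H"]]; W <- dims[["W"]]
  lay <- specLayout(spec)
  pos <- (truths$row - 1L) * spec$nCols + truths$col
  cen <- centers(lay)[pos, , drop = FALSE]
  V <- vignetteSurface(H, W, spec$vignetteAmplitude)
  images <- vector("list", length(scanIdx))
  for (k in seq_along(scanIdx)) {
    j <- scanIdx[k]
    A <- matrix(0, H, W)
    for (i in seq_len(nrow(truths))) {
      p <- domePatch(H, W, cen[i, 1], cen[i, 2], massMat[i, j],
                     truths$kappa[i])
      if (!is.null(p)) A[p$ys, p$xs] <- A[p$ys, p$xs] + p$values
    }
    I <- spec$agarIntensity * 10^(-A) * V
    if (spec$noiseSd > 0)
      I <- I + withSeed(subSeed(spec$seed, 1000L + j),
                        rnorm(H * W, 0, spec$noiseSd))
    images[[k]] <- PlateImage(pmax(I, 0), plateId, allTimes[j])
  }
  truth <- data.frame(
    row = rep(truths$row, times = length(scanIdx)),
    col = rep(truths$col, times = length(scanIdx)),
    time = rep(allTimes[scanIdx], each = nrow(truths)),
    trueMass = as.vector(massMat[, scanIdx]))
  list(images = images, truth = truth, massMatrix = massMat,
       layout = lay, params = truths)
}

#' Write a rendered time-lapse to 16-bit TIFF files
#'
#' One file per scan, named `<plate>_<HHMM>.tif`. Intensities are assumed to
#' lie in [0, 1].
#'
#' @param rendered result of [renderTimelapse()].
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
writeTimelapse <- function(rendered, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(rendered$images, function(img) {
    path <- file.path(dir, sprintf("%s_%s.tif", plateId(img),
                                   timeTag(scanTime(img))))
    tiff::writeTIFF(pmin(pixels(img), 1), path, bits.per.sample = 16L)
    path
  }, character(1L))
  invisible(paths)
}

#' Read a directory of plate scans back into PlateImage objects
#'
#' Expects the `<plate>_<HHMM>.tif` naming convention of [writeTimelapse()].
#'
#' @param dir directory of TIFF scans.
#' @param plate plate identifier to read.
#' @return list of [PlateImage-class], ordered by scan time.
#' @export
readTimelapse <- function(dir, plate) {
  files <- list.files(dir, pattern = paste0("^", plate, "_\\d{4}\\.tif$"),
                      full.names = TRUE)
  if (length(files) == 0L) stop("no scans found for plate '", plate, "'")
  tag <- sub("\\.tif$", "", sub(paste0("^", plate, "_"), "", basename(files)))
  hours <- as.numeric(substr(tag, 1, 2)) + as.numeric(substr(tag, 3, 4)) / 60
  ord <- order(hours)
  lapply(ord, function(i) {
    px <- tryCatch(tiff::readTIFF(files[i]),
                   error = function(e) stop("corrupted scan file '",
                                            files[i], "': ",
                                            conditionMessage(e)))
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    PlateImage(px, plate, hours[i])
  })
}

#' Simulate a strain x replicate screen table with known perturbations
#'
#' Emits LTG/MGR/SPG/CONV values per strain per replicate. Strain-level
#' baselines follow the theoretical lag and yield models (so LTG and SPG are
#' MGR-dependent, as in real screens); a labeled fraction of strains carries
#' multiplicative defects; positional biases (plate / row / column / smooth
#' spatial gradient) and replicate noise are applied multiplicatively on top.
#'
#' @param nStrains number of strains.
#' @param nReplicates independent replicate experiments (default 7, the
#'   standard same-array design).
#' @param effectSpec list of `slowMGR`, `longLTG`, `lowSPG`, each
#'   `list(fraction=, factor=)`. Fractions must sum to at most 1 (perturbed
#'   sets are disjoint).
#' @param noiseSpec list with `cv`: replicate-level multiplicative noise CV
#'   (default 0.05, typical replicate variation for the center-mass metric).
#' @param biasSpec list with optional `plateFactors` (one per plate),
#'   `rowFactor = list(row=, factor=)`, `colFactor = list(col=, factor=)`
#'   and `spatialAmplitude` (corner-to-corner fractional gradient).
#' @param layoutDims `c(nRows, nCols)` of the virtual plates strains are
#'   arrayed on (row-major, plates filled in order).
#' @param tau,m,YG parameters of the lag (`lambda = log(1+mu*tau)/mu`) and
#'   yield (`Y = mu/((1/YG)*mu + m)`) baselines.
#' @param mgrCV strain-to-strain lognormal CV of baseline MGR.
#' @param seed integer seed.
#' @return list with `table` (long data.frame: `strain`, `replicate`,
#'   `plate`, `row`, `col`, `LTG`, `MGR`, `SPG`, `CONV`) and `labels`
#'   (per-strain logical flags `slowMGR`, `longLTG`, `lowSPG`).
#' @export
simulateScreen <- function(nStrains, nReplicates = 7,
                           effectSpec = list(), noiseSpec = list(cv = 0.05),
                           biasSpec = list(), layoutDims = c(16, 24),
                           tau = 2, m = 0.05, YG = 4, mgrCV = 0.05,
                           seed = 1L) {
  frac <- vapply(effectSpec, function(e) e$fraction, numeric(1L))
  if (sum(frac) > 1) stop("effect fractions must sum to at most 1")
  nr <- layoutDims[1L]; nc <- layoutDims[2L]
  perPlate <- nr * nc
  nPlates <- ceiling(nStrains / perPlate)
  idx0 <- seq_len(nStrains) - 1L
  plate <- idx0 %/% perPlate + 1L
  within <- idx0 %% perPlate
  row <- within %/% nc + 1L
  col <- within %% nc + 1L
  withSeed(seed, {
    strains <- sprintf("s%04d", seq_len(nStrains))
    mu0 <- rlnorm(nStrains, log(1) - log(1 + mgrCV^2) / 2,
                  sqrt(log(1 + mgrCV^2)))
    labels <- data.frame(strain = strains, slowMGR = FALSE, longLTG = FALSE,
                         lowSPG = FALSE)
    pool <- sample(nStrains)
    used <- 0L
    pick <- function(fraction) {
      k <- round(fraction * nStrains)
      out <- pool[seq_len(k) + used]
      used <<- used + k
      out
    }
    fx <- list(slowMGR = 1, longLTG = 1, lowSPG = 1)
    for (nm in names(effectSpec)) {
      sel <- pick(effectSpec[[nm]]$fraction)
      labels[[nm]][sel] <- TRUE
      fx[[nm]] <- ifelse(seq_len(nStrains) %in% sel,
                         effectSpec[[nm]]$factor, 1)
    }
    MGR0 <- mu0 * fx$slowMGR
    LTG0 <- lagExpectation(MGR0, tau) * fx$longLTG
    SPG0 <- yieldExpectation(MGR0, m, YG) * fx$lowSPG
    CONV0 <- SPG0 * 120            # area proxy: footprint scales with yield
    pf <- rep(1, nPlates)
    if (!is.null(biasSpec$plateFactors))
      pf[seq_along(biasSpec$plateFactors)] <- biasSpec$plateFactors
    posBias <- rep(1, nStrains)
    if (!is.null(biasSpec$rowFactor))
      posBias <- posBias * ifelse(row == biasSpec$rowFactor$row,
                                  biasSpec$rowFactor$factor, 1)
    if (!is.null(biasSpec$colFactor))
      posBias <- posBias * ifelse(col == biasSpec$colFactor$col,
                                  biasSpec$colFactor$factor, 1)
    if (!is.null(biasSpec$spatialAmplitude) && biasSpec$spatialAmplitude != 0) {
      u <- (col - 1) / max(1, nc - 1)
      v <- (row - 1) / max(1, nr - 1)
      posBias <- posBias * (1 + biasSpec$spatialAmplitude * (u + v - 1) / 2)
    }
    bias <- posBias * pf[plate]
    cv <- if (is.null(noiseSpec$cv)) 0 else noiseSpec$cv
    tab <- do.call(rbind, lapply(seq_len(nReplicates), function(r) {
      noise <- function() if (cv > 0) 1 + rnorm(nStrains, 0, cv) else 1
      data.frame(strain = strains, replicate = r, plate = plate,
                 row = row, col = col,
                 LTG = LTG0 * bias * noise(), MGR = MGR0 * bias * noise(),
                 SPG = SPG0 * bias * noise(), CONV = CONV0 * bias * noise())
    }))
    list(table = tab, labels = labels)
  })
}
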