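#' @import methods
#' @importFrom stats median mad sd coef lm optimize optim rnorm runif rlnorm
#'   setNames quantile cor qf pf var complete.cases aggregate
NULL

#' PlateImage: one grayscale scan of one plate
#'
#' Transmitted-light intensities of a single plate at a single incubation
#' time. Pixels are stored as a numeric matrix indexed `[y, x]` with row 1 at
#' the top and column 1 at the left; colonies appear *darker* than the
#' surrounding agar.
#'
#' @slot pixels numeric matrix of non-negative intensities (arbitrary linear
#'   units; scanner bit depth is not assumed).
#' @slot plateId single character plate identifier.
#' @slot scanTime hours since inoculation (single non-negative number).
#'
#' @seealso [correctLighting()], [measureTimelapse()]
#' @export
setClass("PlateImage",
  slots = c(pixels = "matrix", plateId = "character", scanTime = "numeric"))

setValidity("PlateImage", function(object) {
  msg <- NULL
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  else if (any(!is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
  else if (any(object@pixels < 0)) msg <- c(msg, "pixels must be >= 0")
  if (length(object@plateId) != 1L) msg <- c(msg, "plateId must be length 1")
  if (length(object@scanTime) != 1L || is.na(object@scanTime) ||
      object@scanTime < 0)
    msg <- c(msg, "scanTime must be a single non-negative number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PlateImage
#'
#' @param pixels numeric matrix `[y, x]` of non-negative intensities.
#' @param plateId plate identifier.
#' @param scanTime hours since inoculation.
#' @return a [PlateImage-class] object.
#' @examples
#' img <- PlateImage(matrix(0.8, 20, 30), "plateA", scanTime = 2.5)
#' dim(pixels(img))
#' @export
PlateImage <- function(pixels, plateId = "plate", scanTime = 0) {
  new("PlateImage", pixels = pixels, plateId = as.character(plateId),
      scanTime = as.numeric(scanTime))
}

#' ArrayLayout: colony-center lattice of an arrayed plate
#'
#' Centers of the `nRows x nCols` colony array in image pixel coordinates,
#' ordered row-major (row 1 = top, column 1 = left, both 1-based). Centers
#' must form an approximately regular lattice: the maximum residual from the
#' best-fit affine lattice is required to be below `pitch / 4`.
#'
#' @slot nRows,nCols integer array dimensions.
#' @slot centers numeric matrix with one row per position and columns
#'   `x`, `y`, ordered by (row, col).
#' @slot pitch pixels between adjacent colony centers.
#' @export
setClass("ArrayLayout",
  slots = c(nRows = "integer", nCols = "integer", centers = "matrix",
            pitch = "numeric"))

setValidity("ArrayLayout", function(object) {
  msg <- NULL
  n <- object@nRows * object@nCols
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (nrow(object@centers) != n)
    msg <- c(msg, "centers must have nRows*nCols rows")
  if (ncol(object@centers) != 2L)
    msg <- c(msg, "centers must have columns x, y")
  if (length(object@pitch) != 1L || object@pitch <= 0)
    msg <- c(msg, "pitch must be a single positive number")
  if (is.null(msg) && n > 3L) {
    idx <- expand.grid(col = seq_len(object@nCols), row = seq_len(object@nRows))
    X <- cbind(1, idx$col, idx$row)
    res <- object@centers - X %*% qr.solve(X, object@centers)
    if (max(abs(res)) >= object@pitch / 4)
      msg <- c(msg, "centers deviate from an affine lattice by >= pitch/4")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an ArrayLayout
#'
#' @param nRows,nCols array dimensions (e.g. 32 x 48 for 1536 format).
#' @param centers numeric matrix (`x`, `y`) of colony centers, row-major.
#' @param pitch pixels between adjacent centers.
#' @return an [ArrayLayout-class] object.
#' @export
ArrayLayout <- function(nRows, nCols, centers, pitch) {
  new("ArrayLayout", nRows = as.integer(nRows), nCols = as.integer(nCols),
      centers = as.matrix(centers), pitch = as.numeric(pitch))
}

#' ColonyRegion: segmented pixel set for one array position
#'
#' Pixels assigned to the colony at one array position, together with the
#' local agar reference statistics used for segmentation and absorbance.
#' Member pixels are those in the cell window whose intensity falls below
#' `agarMean - 10 * agarSd` (one-sided: transmitted-light colonies are
#' darker than agar).
#'
#' @slot position integer vector `(row, col)`, 1-based.
#' @slot memberPixels integer matrix with columns `y`, `x` (absolute image
#'   coordinates); zero rows for an empty position.
#' @slot thresholdUsed intensity threshold applied.
#' @slot agarMean,agarSd background statistics from the cell window's border
#'   band (colony pixels excluded).
#' @slot valid FALSE when background statistics could not be computed (e.g.
#'   the colony overflows its cell window).
#' @export
setClass("ColonyRegion",
  slots = c(position = "integer", memberPixels = "matrix",
            thresholdUsed = "numeric", agarMean = "numeric",
            agarSd = "numeric", valid = "logical"))

setValidity("ColonyRegion", function(object) {
  msg <- NULL
  if (length(object@position) != 2L) msg <- c(msg, "position must be (row, col)")
  if (ncol(object@memberPixels) != 2L)
    msg <- c(msg, "memberPixels must have columns y, x")
  if (isTRUE(object@valid) && (!is.finite(object@agarMean) ||
                               object@agarMean <= 0))
    msg <- c(msg, "agarMean must be > 0 for a valid region")
  if (is.null(msg)) TRUE else msg
})

#' GompertzFit: fitted Gompertz growth model for one colony
#'
#' Parameters of `G(t) = a * exp(-b * c^t)` fitted to a preprocessed growth
#' series. A converged fit satisfies `a > 0`, `b > 0`, `0 < c < 1`
#' (guaranteed by the log/logit parameterization of the solver).
#'
#' @slot a saturation level (normalized growth units).
#' @slot b displacement (dimensionless, > 0).
#' @slot c rate base (0 < c < 1).
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot nPoints number of points fitted (at most 25).
#' @seealso [fitGompertz()], [growthCharacters()]
#' @export
setClass("GompertzFit",
  slots = c(a = "numeric", b = "numeric", c = "numeric", rss = "numeric",
            converged = "logical", nPoints = "integer"))

setValidity("GompertzFit", function(object) {
  msg <- NULL
  if (object@nPoints > 25L) msg <- c(msg, "nPoints must be <= 25")
  if (isTRUE(object@converged)) {
    if (!(object@a > 0)) msg <- c(msg, "converged fit requires a > 0")
    if (!(object@b > 0)) msg <- c(msg, "converged fit requires b > 0")
    if (!(object@c > 0 && object@c < 1))
      msg <- c(msg, "converged fit requires 0 < c < 1")
  }
  if (is.null(msg)) TRUE else msg
})

## ------------------------------------------------------------------------
## Generics and accessors
## ------------------------------------------------------------------------

#' @describeIn PlateImage-class pixel matrix accessor
#' @param object,x a `PlateImage`.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname PlateImage-class
#' @export
setMethod("pixels", "PlateImage", function(x) x@pixels)

#' @rdname PlateImage-class
#' @export
setGeneric("plateId", function(x) standardGeneric("plateId"))

#' @rdname PlateImage-class
#' @export
setMethod("plateId", "PlateImage", function(x) x@plateId)

#' @rdname PlateImage-class
#' @export
setGeneric("scanTime", function(x) standardGeneric("scanTime"))

#' @rdname PlateImage-class
#' @export
setMethod("scanTime", "PlateImage", function(x) x@scanTime)

#' @rdname ArrayLayout-class
#' @param x an `ArrayLayout`.
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))

#' @rdname ArrayLayout-class
#' @export
setMethod("centers", "ArrayLayout", function(x) x@centers)

#' @rdname ArrayLayout-class
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname ArrayLayout-class
#' @export
setMethod("gridDims", "ArrayLayout",
          function(x) c(nRows = x@nRows, nCols = x@nCols))

#' @rdname ArrayLayout-class
#' @export
setGeneric("pitch", function(x) standardGeneric("pitch"))

#' @rdname ArrayLayout-class
#' @export
setMethod("pitch", "ArrayLayout", function(x) x@pitch)

setMethod("show", "PlateImage", function(object) {
  cat(sprintf("PlateImage '%s' at %.2f h: %d x %d px, intensity [%.4g, %.4g]\n",
              object@plateId, object@scanTime,
              nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ArrayLayout", function(object) {
  cat(sprintf("ArrayLayout %d rows x %d cols (%d positions), pitch %.1f px\n",
              object@nRows, object@nCols, nrow(object@centers), object@pitch))
})

setMethod("show", "ColonyRegion", function(object) {
  cat(sprintf(
    "ColonyRegion (row %d, col %d): area %d px, agar %.4g +/- %.3g%s\n",
    object@position[1L], object@position[2L], nrow(object@memberPixels),
    object@agarMean, object@agarSd, if (object@valid) "" else " [invalid]"))
})

setMethod("show", "GompertzFit", function(object) {
  if (object@converged) {
    cat(sprintf(
      "GompertzFit: a = %.4g, b = %.4g, c = %.4g (rss %.3g, n = %d)\n",
      object@a, object@b, object@c, object@rss, object@nPoints))
  } else {
    cat("GompertzFit: not converged\n")
  }
})
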