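# Design-evaluation module: quantifies, on neighbor-effect simulations, how
# much the center-mass metric (mass*) improves over whole-colony mass --
# crowded-vs-uncrowded growth gap, within-plate CV of MGR, and the
# intra-class correlation of shuffled-array replicate measurements.

# MGR per array position from a measured time-lapse, for one metric
mgrFromSE <- function(se, metric, refTime = 20) {
  ph <- colonyPhenotypes(se, metric = metric, refTime = refTime)
  ph$MGR
}

crowdedMask <- function(nRows, nCols) {
  idx <- expand.grid(col = seq_len(nCols), row = seq_len(nRows))
  interior <- idx$row > 1L & idx$row < nRows & idx$col > 1L & idx$col < nCols
  corner <- (idx$row %in% c(1L, nRows)) & (idx$col %in% c(1L, nCols))
  border <- (idx$row %in% c(1L, nRows) | idx$col %in% c(1L, nCols)) & !corner
  list(crowded = interior, uncrowded = border)
}

#' Evaluate the mass vs mass* measurement designs on a neighbor-effect
#' simulation
#'
#' Simulates (i) one wild-type plate (all colonies drawn from the same
#' strain distribution) to compare the within-plate CV of MGR and the
#' crowded (8 neighbors) vs uncrowded (border, 5 neighbors) final growth
#' gap between the two quantification metrics, and (ii) a shuffled-array
#' design (the same strain set re-arrayed at random positions on each of
#' `nShufflePlates` plates) to compare the intra-class correlation of
#' repeated MGR measurements.
#'
#' @param nRows,nCols array dimensions of the simulated plates.
#' @param suppressionCoeff neighbor-effect strength (0 = no neighbor
#'   effect).
#' @param nShufflePlates replicate plates in the shuffled-array design.
#' @param strainCV strain-to-strain CV of the rate parameter in the
#'   shuffled-array design (wild-type plates use `wtCV`).
#' @param wtCV residual colony-to-colony biological variation on the
#'   wild-type plate.
#' @param pixelPitch,noiseSd,scanIntervalH,durationH plate spec overrides.
#' @param centerDiameter mass* disc diameter (pixels).
#' @param seed integer seed.
#' @return list with elements `gap` (relative crowded-uncrowded gap of the
#'   final value, per metric), `cv` (within-plate CV of MGR in percent,
#'   per metric), `icc` (shuffled-array ICC of MGR, per metric, with
#'   confidence bounds), and `settings`.
#' @export
evaluateDesigns <- function(nRows = 12, nCols = 16, suppressionCoeff = 1e-3,
                            nShufflePlates = 4, strainCV = 0.08,
                            wtCV = 0.03, pixelPitch = 40, noiseSd = 0.004,
                            scanIntervalH = 0.5, durationH = 20,
                            centerDiameter = 17, seed = 1L) {
  neigh <- neighborModel(suppressionCoeff)
  masks <- crowdedMask(nRows, nCols)
  metrics <- c("mass", "mass_center")

  plateSpec <- function(k) {
    simPlateSpec(nRows = nRows, nCols = nCols, pixelPitch = pixelPitch,
                 noiseSd = noiseSd, scanIntervalH = scanIntervalH,
                 durationH = durationH, seed = subSeed(seed, k))
  }

  ## wild-type plate: same strain everywhere, small biological scatter
  spec <- plateSpec(1L)
  truths <- simColonyTruths(spec, aCV = wtCV, cCV = wtCV)
  ren <- renderTimelapse(spec, truths, neigh)
  se <- measureTimelapse(ren$images, ren$layout, centerDiameter)
  nT <- ncol(se)
  gap <- cv <- setNames(numeric(2L), metrics)
  for (met in metrics) {
    finalVal <- SummarizedExperiment::assay(se, met)[, nT]
    mu_c <- mean(finalVal[masks$crowded], na.rm = TRUE)
    mu_u <- mean(finalVal[masks$uncrowded], na.rm = TRUE)
    gap[met] <- abs(mu_c - mu_u) / mu_u
    mgr <- mgrFromSE(se, met, refTime = durationH)
    cv[met] <- cvPercent(mgr[is.finite(mgr)])
  }

  ## shuffled-array design: one strain per position, re-arrayed per plate
  nStrains <- nRows * nCols
  baseSpec <- plateSpec(2L)
  # strain-to-strain variation acts on the rate base (MGR differences);
  # saturation mass keeps only the residual biological scatter so domes
  # stay within the lattice pitch
  strainTruths <- simColonyTruths(baseSpec, aCV = wtCV, cCV = strainCV,
                                  seed = subSeed(seed, 99L))
  icc <- list()
  mgrMat <- setNames(vector("list", 2L), metrics)
  for (met in metrics) mgrMat[[met]] <- matrix(NA_real_, nStrains,
                                               nShufflePlates)
  for (p in seq_len(nShufflePlates)) {
    specP <- plateSpec(10L + p)
    perm <- withSeed(subSeed(seed, 200L + p), sample(nStrains))
    idx <- expand.grid(col = seq_len(nCols), row = seq_len(nRows))
    truthsP <- strainTruths[perm, ]
    truthsP$row <- idx$row
    truthsP$col <- idx$col
    renP <- renderTimelapse(specP, truthsP, neigh,
                            plateId = sprintf("shuffle%d", p))
    seP <- measureTimelapse(renP$images, renP$layout, centerDiameter)
    for (met in metrics)
      mgrMat[[met]][perm, p] <- mgrFromSE(seP, met, refTime = durationH)
  }
  for (met in metrics) icc[[met]] <- iccOneway(mgrMat[[met]])

  list(gap = gap, cv = cv, icc = icc,
       settings = list(nRows = nRows, nCols = nCols,
                       suppressionCoeff = suppressionCoeff,
                       nShufflePlates = nShufflePlates,
                       strainCV = strainCV, wtCV = wtCV, seed = seed))
}
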