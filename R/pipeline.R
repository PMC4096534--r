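# Workbench module: run configuration, flat-file orchestration of the
# simulate -> measure -> fit -> normalize -> correct -> screen pipeline, and
# the run manifest. A flat TSV + manifest store replaces any database
# backend: every stage output is a diffable text file.

#' Default run configuration
#'
#' All defaults are the reference measurement conditions: 1536-format array
#' (32 rows x 48 columns), scans every 0.5 h over 20 h, 17-pixel center
#' disc, conventional value at 20 h, 7x7 spatial window, LTS trim fraction
#' 0.75, selection thresholds p < 0.01 and FDR < 0.01 with 1000
#' permutations, and 7 replicate plates. Override any entry (typically the
#' array size and replicate count, for desk-scale runs) via [runPipeline()]
#' or a YAML file read by [readRunConfig()].
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @return named list of configuration entries.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = seed,
    nRows = 32L, nCols = 48L,
    pixelPitch = 40, noiseSd = 0.004,
    scanIntervalH = 0.5, durationH = 20,
    centerDiameter = 17, refTime = 20,
    metric = "mass_center",
    metrics = c("LTG", "MGR", "SPG", "CONV"),
    window = 7L,
    trimFraction = 0.75,
    alpha = 0.01, fdr = 0.01, nPerm = 1000L,
    nReplicates = 7L,
    effects = list(slowMGR = list(fraction = 0.05, factor = 0.8)),
    aCV = 0.05, cCV = 0.03)
}

#' Read a run configuration from YAML
#'
#' Entries present in the file override [defaultRunConfig()].
#'
#' @param path YAML file.
#' @param seed fallback seed if the file does not set one.
#' @return configuration list.
#' @export
readRunConfig <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig(seed)
  cfg[names(user)] <- user
  cfg
}

stageFile <- function(dir, name) file.path(dir, name)

#' Run the full pipeline on a synthetic screen
#'
#' Orchestrates simulate -> measure -> fit -> normalize -> correct ->
#' screen into a run directory of TSV tables plus a JSON manifest. The
#' simulate stage arrays one strain per position (the same array on every
#' replicate plate) and injects the configured multiplicative strain
#' defects; downstream stages then recover them blind. Stage failures abort
#' with the failing stage named; outputs written up to that point are
#' preserved. Reruns with an identical configuration are bit-identical for
#' all stage tables.
#'
#' @param config list from [defaultRunConfig()] / [readRunConfig()], or
#'   overrides passed as a partial list.
#' @param outDir run directory (created).
#' @param keepImages write the simulated TIFF scans under
#'   `<outDir>/images` (default TRUE; the measure stage reads them back
#'   from disk).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = list(), outDir, keepImages = TRUE) {
  cfg <- defaultRunConfig()
  cfg[names(config)] <- config
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, stageFile(outDir, "config.yaml"))
  manifest <- list(stages = list(), seed = cfg$seed,
                   configHash = unname(tools::md5sum(
                     stageFile(outDir, "config.yaml"))))
  addStage <- function(name, files) {
    manifest$stages[[name]] <<- list(files = basename(files))
    manifest
  }
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- simulate ----------------------------------------------------------
  spec <- simPlateSpec(nRows = cfg$nRows, nCols = cfg$nCols,
                       pixelPitch = cfg$pixelPitch, noiseSd = cfg$noiseSd,
                       scanIntervalH = cfg$scanIntervalH,
                       durationH = cfg$durationH, seed = cfg$seed)
  nPos <- cfg$nRows * cfg$nCols
  simOut <- runStage("simulate", {
    truths <- simColonyTruths(spec, aCV = cfg$aCV, cCV = cfg$cCV,
                              seed = subSeed(cfg$seed, 3L))
    strains <- sprintf("s%04d", seq_len(nPos))
    labels <- data.frame(strain = strains, slowMGR = FALSE)
    if (!is.null(cfg$effects$slowMGR) && cfg$effects$slowMGR$fraction > 0) {
      k <- round(cfg$effects$slowMGR$fraction * nPos)
      sel <- withSeed(subSeed(cfg$seed, 4L), sample(nPos, k))
      # MGR scales with -log(c); factor f maps c -> c^f
      truths$c[sel] <- truths$c[sel]^cfg$effects$slowMGR$factor
      labels$slowMGR[sel] <- TRUE
    }
    layoutTab <- data.frame(plate = NA_character_, row = truths$row,
                            col = truths$col, strain = strains)
    plates <- sprintf("rep%d", seq_len(cfg$nReplicates))
    imgDir <- stageFile(outDir, "images")
    truthTabs <- list()
    for (r in seq_len(cfg$nReplicates)) {
      specR <- spec
      specR$seed <- subSeed(cfg$seed, 100L + r)
      ren <- renderTimelapse(specR, truths, neighborModel(),
                             plateId = plates[r])
      if (keepImages) writeTimelapse(ren, imgDir)
      truthTabs[[r]] <- cbind(plate = plates[r], ren$truth)
    }
    layoutTab <- do.call(rbind, lapply(plates, function(p) {
      lt <- layoutTab; lt$plate <- p; lt
    }))
    writeGrowthTable(layoutTab, stageFile(outDir, "layout.tsv"))
    writeGrowthTable(do.call(rbind, truthTabs),
                     stageFile(outDir, "truth.tsv"))
    writeGrowthTable(labels, stageFile(outDir, "labels.tsv"))
    list(plates = plates, layout = layoutTab, imgDir = imgDir,
         spec = spec)
  })
  manifest <- addStage("simulate",
                       c("layout.tsv", "truth.tsv", "labels.tsv"))

  ## -- measure -----------------------------------------------------------
  obs <- runStage("measure", {
    tabs <- lapply(simOut$plates, function(p) {
      images <- readTimelapse(simOut$imgDir, p)
      lay <- detectGrid(images[[length(images)]], cfg$nRows, cfg$nCols)
      se <- measureTimelapse(images, lay, cfg$centerDiameter)
      observationTable(se)
    })
    tab <- do.call(rbind, tabs)
    writeGrowthTable(tab, stageFile(outDir, "observations.tsv"))
    tab
  })
  manifest <- addStage("measure", "observations.tsv")

  ## -- fit ---------------------------------------------------------------
  phen <- runStage("fit", {
    tab <- fitPhenotypeTable(obs, metric = cfg$metric,
                             refTime = cfg$refTime)
    tab <- merge(tab, simOut$layout, by = c("plate", "row", "col"),
                 sort = FALSE)
    tab <- tab[order(tab$plate, tab$row, tab$col), ]
    writeGrowthTable(tab, stageFile(outDir, "phenotypes.tsv"))
    tab
  })
  manifest <- addStage("fit", "phenotypes.tsv")

  ## -- normalize ---------------------------------------------------------
  normTab <- runStage("normalize", {
    tab <- normalizePipeline(phen, metrics = cfg$metrics,
                             window = cfg$window)
    writeGrowthTable(tab, stageFile(outDir, "normalized.tsv"))
    tab
  })
  manifest <- addStage("normalize", "normalized.tsv")

  ## -- correct -----------------------------------------------------------
  corrTab <- runStage("correct", {
    tab <- correctGrowthValues(normTab, trimFraction = cfg$trimFraction,
                               seed = subSeed(cfg$seed, 7L))
    writeGrowthTable(tab, stageFile(outDir, "corrected.tsv"))
    writeGrowthTable(attr(tab, "curves"),
                     stageFile(outDir, "correction_curves.tsv"))
    tab
  })
  manifest <- addStage("correct", c("corrected.tsv",
                                    "correction_curves.tsv"))

  ## -- screen ------------------------------------------------------------
  runStage("screen", {
    mat <- strainMatrix(corrTab, "MGR_norm")
    res <- rpSignificance(mat, "low", nPerm = cfg$nPerm,
                          seed = subSeed(cfg$seed, 8L))
    res$selected <- res$strain %in%
      selectDefective(res, cfg$alpha, cfg$fdr)
    writeGrowthTable(res, stageFile(outDir, "screen.tsv"))
    res
  })
  manifest <- addStage("screen", "screen.tsv")

  jsonlite::write_json(manifest, stageFile(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Fit growth phenotypes for every plate of an observation table
#'
#' @param obs long observation table ([observationTable()] format, possibly
#'   several plates).
#' @param metric growth metric column to fit.
#' @param refTime reference time for CONV (hours).
#' @return phenotype table, one row per plate x position.
#' @export
fitPhenotypeTable <- function(obs, metric = "mass_center", refTime = 20) {
  stopifnot(metric %in% names(obs))
  keys <- unique(obs[, c("plate", "row", "col")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- obs[obs$plate == keys$plate[i] & obs$row == keys$row[i] &
               obs$col == keys$col[i], ]
    sub <- sub[order(sub$time_h), ]
    cbind(keys[i, , drop = FALSE],
          analyzeColony(sub$time_h, sub[[metric]], sub$area_px, sub$valid,
                        refTime))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Strain x replicate matrix from a phenotype table
#'
#' @param df table with `strain`, the replicate key and the value column.
#' @param valueCol column to spread.
#' @param by replicate key column (default `"plate"`; use `"replicate"`
#'   for [simulateScreen()] tables).
#' @return matrix with strain rownames, one column per replicate.
#' @export
strainMatrix <- function(df, valueCol, by = "plate") {
  stopifnot(all(c("strain", by, valueCol) %in% names(df)))
  reps <- unique(df[[by]])
  strains <- unique(df$strain)
  mat <- matrix(NA_real_, length(strains), length(reps),
                dimnames = list(strains, as.character(reps)))
  mat[cbind(match(df$strain, strains), match(df[[by]], reps))] <-
    df[[valueCol]]
  mat
}
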