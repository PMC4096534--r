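# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so library code never
#' disturbs the user's RNG stream. A `NULL` seed evaluates the code with the
#' current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic substream seed; stays below 2^31 so set.seed() accepts it.
subSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483587)
}

#' Write a tab-separated growth table
#'
#' All tables exchanged between pipeline stages are plain TSV with a header
#' row, no quoting and no row names, so they diff and round-trip cleanly.
#'
#' @param x data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGrowthTable <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated growth table
#'
#' @param path file written by [writeGrowthTable()].
#' @return data.frame.
#' @export
readGrowthTable <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# hours -> "HHMM" tag used in scan filenames
timeTag <- function(hours) {
  h <- floor(hours + 1e-9)
  m <- round((hours - h) * 60)
  sprintf("%02d%02d", h, m)
}
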