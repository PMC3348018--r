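#' @importFrom methods new validObject is setValidity slot
#' @importFrom stats median rbinom rnorm runif setNames var
#' @importFrom utils read.delim write.table packageVersion
NULL

## Evaluate `expr` under a fixed RNG state, restoring the caller's state.
## All simulators funnel through this so that a spec + seed is a pure
## function of its inputs.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Canonical chromosome ordering: chr1..chr22 < chrX < chrY < chrM,
## then anything else alphabetically. Labels are never rewritten.
chromRank <- function(chrom) {
  core <- sub("^chr", "", chrom, ignore.case = FALSE)
  num <- suppressWarnings(as.numeric(core))
  rank <- ifelse(!is.na(num), num,
          ifelse(core == "X", 100,
          ifelse(core == "Y", 101,
          ifelse(core %in% c("M", "MT"), 102, NA_real_))))
  order(is.na(rank), rank, chrom)
}

chromLevels <- function(chrom) {
  u <- unique(as.character(chrom))
  u[chromRank(u)]
}

#' Normalize chromosome labels
#'
#' Adds a \code{"chr"} prefix where it is absent and maps \code{"chrMT"} to
#' \code{"chrM"}. Comparison of chromosome labels elsewhere in the package is
#' verbatim and case-sensitive; call this helper explicitly on both sides
#' when two sources use different conventions.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of the same length.
#' @examples
#' normalizeChrom(c("1", "chr2", "MT"))
#' @export
normalizeChrom <- function(chrom) {
  chrom <- as.character(chrom)
  out <- ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  ifelse(out == "chrMT", "chrM", out)
}

## Numbers formatted for TSV output: `digits` significant digits,
## plain (non-scientific) notation where possible.
fmtNum <- function(x, digits = 6L) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(signif(v, digits), scientific = FALSE, trim = TRUE, digits = 15L)
  }, character(1L))
  out
}

## Atomic file write: materialize in a temp file in the destination
## directory, then rename over the target.
atomicWrite <- function(lines, file) {
  dir <- dirname(file)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, file))
    stop("could not move temporary file onto ", file)
  invisible(file)
}

## Recognized missing-value tokens in numeric TSV fields.
isMissingToken <- function(x) {
  x <- trimws(x)
  x == "" | tolower(x) %in% c("na", "nan")
}

parseNumericField <- function(x, file = "<stream>", lineno = NULL,
                              what = "numeric") {
  out <- rep(NA_real_, length(x))
  miss <- isMissingToken(x)
  val <- suppressWarnings(as.numeric(x[!miss]))
  bad <- is.na(val)
  if (any(bad)) {
    i <- which(!miss)[which(bad)[1L]]
    where <- if (is.null(lineno)) i else lineno[i]
    stop(sprintf("%s: line %d: cannot parse %s value '%s'",
                 file, where, what, x[!miss][which(bad)[1L]]))
  }
  out[!miss] <- val
  out
}
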