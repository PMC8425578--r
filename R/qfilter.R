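#' Whole-read Q-score composition test
#'
#' A read passes when the number of bases with Q below `q` does not exceed
#' the failing allowance `(100 - p)/100 * read_length`.  The allowance is
#' kept as an exact rational quantity (not floored) and a count exactly at
#' the allowance passes.  Equivalently, at least `p` percent of bases must
#' be at or above Q `q`.
#'
#' @param x a [fastq_df()] or character vector of quality strings.
#' @param q minimum passing Q score (0--40).
#' @param p required percent of bases at or above `q` (0--100).
#' @return logical vector of per-read pass decisions.
#' @export
passes_qthreshold <- function(x, q, p) {
  stopifnot(q >= 0L, q <= .Q_MAX, p >= 0, p <= 100)
  qual <- if (is.data.frame(x)) x$qual else x
  thr_char <- .Q_OFFSET + as.integer(q)
  vapply(qual, function(s) {
    L <- nchar(s)
    if (L == 0L) return(TRUE)
    nfail <- sum(utf8ToInt(s) < thr_char)
    nfail <= (100 - p) / 100 * L
  }, NA, USE.NAMES = FALSE)
}

# Scalar early-exit variant: quality characters are tested 3' to 5' and the
# read is rejected as soon as the failing allowance is exceeded.  Same
# decisions as passes_qthreshold (property-tested); exposed for the
# equivalence check.
passes_qthreshold_scan <- function(qual, q, p) {
  thr <- .Q_OFFSET + as.integer(q)
  L <- nchar(qual)
  if (L == 0L) return(TRUE)
  allowance <- (100 - p) / 100 * L
  v <- rev(utf8ToInt(qual))
  nfail <- 0L
  for (ch in v) {
    if (ch < thr) {
      nfail <- nfail + 1L
      if (nfail > allowance) return(FALSE)
    }
  }
  TRUE
}

#' Q-score threshold filtering of FASTQ files
#'
#' Applies [passes_qthreshold()] to single- or paired-end input with the
#' same pass/fail/pair routing as [filter_motif()]: both mates passing stay
#' paired, a lone passing mate goes to a `se.`-prefixed file and failing
#' reads are written to `fail.`-prefixed files.
#'
#' @param r1_path input R1 FASTQ path.
#' @param r2_path optional R2 FASTQ path.
#' @param q,p see [passes_qthreshold()].
#' @param outdir output directory.
#' @return list of class `filter_result` with output paths and counts.
#' @export
filter_quality <- function(r1_path, r2_path = NULL, q, p, outdir = ".") {
  if (is.null(r2_path)) {
    r1 <- read_fastq(r1_path)
    pass <- passes_qthreshold(r1, q, p)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    base1 <- basename(r1_path)
    paths <- c(r1 = file.path(outdir, base1),
               fail_r1 = file.path(outdir, paste0("fail.", base1)))
    write_fastq(fq_slice(r1, pass), paths["r1"])
    write_fastq(fq_slice(r1, !pass), paths["fail_r1"])
    out <- list(files = paths, n_in = nrow(r1), n_paired = 0L,
                n_se = sum(pass), n_fail = sum(!pass))
  } else {
    pr <- read_fastq_pairs(r1_path, r2_path)
    out <- route_pairs(pr$r1, pr$r2,
                       passes_qthreshold(pr$r1, q, p),
                       passes_qthreshold(pr$r2, q, p),
                       outdir, basename(r1_path), basename(r2_path))
  }
  class(out) <- "filter_result"
  out
}
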