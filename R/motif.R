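#' Test whether reads begin with an expected motif
#'
#' Exact, anchored matching at position 1 with zero mismatch tolerance:
#' library construction (restriction digestion or A-tailing) dictates the
#' first bases of a correctly sequenced read, so a mismatched motif is
#' itself the error signal.  Multiple motifs are OR-ed.
#'
#' @param seqs character vector of read sequences (or a [fastq_df()]).
#' @param motifs non-empty character vector of motifs.
#' @return logical vector: TRUE where the read starts with any motif.
#' @export
has_motif <- function(seqs, motifs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  stopifnot(length(motifs) >= 1L)
  Reduce(`|`, lapply(motifs, function(m) startsWith(seqs, m)))
}

# Shared paired pass/fail routing used by the motif and quality filters:
# (pass, pass) -> paired outputs; (pass, fail) -> passing mate to the
# se.-prefixed file, failing mate to the fail file; (fail, fail) -> both to
# fail files.  Reads are never modified.
route_pairs <- function(r1, r2, pass1, pass2, outdir, base1, base2) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    r1 = file.path(outdir, base1),
    r2 = file.path(outdir, base2),
    se_r1 = file.path(outdir, paste0("se.", base1)),
    se_r2 = file.path(outdir, paste0("se.", base2)),
    fail_r1 = file.path(outdir, paste0("fail.", base1)),
    fail_r2 = file.path(outdir, paste0("fail.", base2))
  )
  write_fastq(fq_slice(r1, pass1 & pass2), paths["r1"])
  write_fastq(fq_slice(r2, pass1 & pass2), paths["r2"])
  write_fastq(fq_slice(r1, pass1 & !pass2), paths["se_r1"])
  write_fastq(fq_slice(r2, !pass1 & pass2), paths["se_r2"])
  write_fastq(fq_slice(r1, !pass1), paths["fail_r1"])
  write_fastq(fq_slice(r2, !pass2), paths["fail_r2"])
  list(files = paths,
       n_in = 2L * nrow(r1),
       n_paired = 2L * sum(pass1 & pass2),
       n_se = sum(pass1 & !pass2) + sum(!pass1 & pass2),
       n_fail = sum(!pass1) + sum(!pass2))
}

#' Motif-filter paired or single-end FASTQ files
#'
#' Routes reads by presence of the expected 5' motif(s).  Failed reads are
#' written to `fail.`-prefixed files (not discarded) so that the passing
#' and failing populations can be compared downstream.
#'
#' @param r1_path input R1 FASTQ path.
#' @param r2_path optional R2 FASTQ path.
#' @param r1_motifs motifs expected at the start of R1 reads.
#' @param r2_motifs motifs expected at the start of R2 reads (paired input).
#' @param outdir output directory.
#' @return list of class `filter_result` with output paths and counts.
#' @export
filter_motif <- function(r1_path, r2_path = NULL, r1_motifs,
                         r2_motifs = NULL, outdir = ".") {
  if (is.null(r2_path)) {
    r1 <- read_fastq(r1_path)
    pass <- has_motif(r1$seq, r1_motifs)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    base1 <- basename(r1_path)
    paths <- c(r1 = file.path(outdir, base1),
               fail_r1 = file.path(outdir, paste0("fail.", base1)))
    write_fastq(fq_slice(r1, pass), paths["r1"])
    write_fastq(fq_slice(r1, !pass), paths["fail_r1"])
    out <- list(files = paths, n_in = nrow(r1), n_paired = 0L,
                n_se = sum(pass), n_fail = sum(!pass))
  } else {
    stopifnot(!is.null(r2_motifs))
    pr <- read_fastq_pairs(r1_path, r2_path)
    out <- route_pairs(pr$r1, pr$r2,
                       has_motif(pr$r1$seq, r1_motifs),
                       has_motif(pr$r2$seq, r2_motifs),
                       outdir, basename(r1_path), basename(r2_path))
  }
  class(out) <- "filter_result"
  out
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter: %d reads in -> %d paired pass, %d single-end pass, %d fail\n",
              x$n_in, x$n_paired, x$n_se, x$n_fail))
  invisible(x)
}
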