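#' Fixed-position trimming of read ends
#'
#' Removes `front` bases from the 5' end and `back` bases from the 3' end of
#' every read; sequence and quality are cropped identically.  Reads shorter
#' than `front + back` become empty (length 0); callers normally route
#' empties to a discard file.  With `back_is_cut = TRUE` the `back` value is
#' instead interpreted as an absolute cut position: the read is truncated to
#' its first `back` bases.
#'
#' @param x a [fastq_df()].
#' @param front,back non-negative integers.
#' @param back_is_cut interpret `back` as an absolute 3' cut position.
#' @return trimmed [fastq_df()], same number of rows.
#' @export
trim_fixed <- function(x, front = 0L, back = 0L, back_is_cut = FALSE) {
  stopifnot(front >= 0L, back >= 0L)
  len <- nchar(x$seq)
  start <- pmin(front + 1L, len + 1L)
  end <- if (back_is_cut) pmin(back, len) else pmax(len - back, 0L)
  end <- pmax(end, start - 1L)
  x$seq <- substr(x$seq, start, end)
  x$qual <- substr(x$qual, start, end)
  x
}

#' Quality sliding-window end trimming
#'
#' A window of `window` bases walks base-by-base from the 3' end towards the
#' 5' end; the read is cut at the 3' edge of the first (most 3') window in
#' which every base has Q >= `end_q`.  If no window qualifies the read
#' becomes empty.  A window larger than the read treats the whole read as
#' the single window.  The operation is idempotent.
#'
#' @param x a [fastq_df()].
#' @param window window size (>= 1).
#' @param end_q minimum Q score required throughout the window (0--40).
#' @return trimmed [fastq_df()].
#' @export
trim_quality_end <- function(x, window, end_q) {
  stopifnot(window >= 1L, end_q >= 0L, end_q <= .Q_MAX)
  keep <- vapply(x$qual, function(qs) {
    L <- nchar(qs)
    if (L == 0L) return(0L)
    q <- utf8ToInt(qs) - .Q_OFFSET
    w <- min(window, L)
    ok <- q >= end_q
    # window ending at j qualifies iff ok[j-w+1..j] all TRUE
    cs <- cumsum(ok)
    ends <- w:L
    full <- (cs[ends] - c(0L, cs)[ends - w + 1L]) == w
    if (!any(full)) 0L else max(ends[full])
  }, 0L, USE.NAMES = FALSE)
  x$seq <- substr(x$seq, 1L, keep)
  x$qual <- substr(x$qual, 1L, keep)
  x
}

#' File-level trimming stage with paired-end bookkeeping
#'
#' Applies [trim_fixed()] and/or [trim_quality_end()] to single- or
#' paired-end FASTQ files.  Reads trimmed to length 0 are routed to a
#' discard file; for paired input, the surviving mate of a discarded read is
#' rerouted to a single-end (`se.`-prefixed) output.
#'
#' @param r1_path input R1 FASTQ path.
#' @param r2_path optional R2 FASTQ path.
#' @param front,back,back_is_cut see [trim_fixed()].
#' @param window,end_q see [trim_quality_end()]; window `NULL` disables
#'   quality end-trimming.
#' @param outdir output directory.
#' @return list of class `trim_result` with output paths and read counts
#'   (`n_in`, `n_paired`, `n_se`, `n_discard`); counts conserve the input.
#' @export
trim_files <- function(r1_path, r2_path = NULL, front = 0L, back = 0L,
                       back_is_cut = FALSE, window = NULL, end_q = NULL,
                       outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  apply_trims <- function(x) {
    x <- trim_fixed(x, front, back, back_is_cut)
    if (!is.null(window)) x <- trim_quality_end(x, window, end_q)
    x
  }
  out <- list(outdir = outdir)
  base1 <- basename(r1_path)
  if (is.null(r2_path)) {
    r1 <- read_fastq(r1_path)
    n_in <- nrow(r1)
    t1 <- apply_trims(r1)
    ok1 <- nchar(t1$seq) > 0L
    p_keep <- file.path(outdir, base1)
    p_disc <- file.path(outdir, paste0("discard.", base1))
    write_fastq(fq_slice(t1, ok1), p_keep)
    write_fastq(fq_slice(r1, !ok1), p_disc)
    out$files <- c(r1 = p_keep, discard_r1 = p_disc)
    out$n_paired <- 0L
    out$n_se <- sum(ok1)
    out$n_discard <- sum(!ok1)
    out$n_in <- n_in
  } else {
    pr <- read_fastq_pairs(r1_path, r2_path)
    n_in <- 2L * nrow(pr$r1)
    t1 <- apply_trims(pr$r1); t2 <- apply_trims(pr$r2)
    ok1 <- nchar(t1$seq) > 0L; ok2 <- nchar(t2$seq) > 0L
    base2 <- basename(r2_path)
    paths <- c(
      r1 = file.path(outdir, base1),
      r2 = file.path(outdir, base2),
      se_r1 = file.path(outdir, paste0("se.", base1)),
      se_r2 = file.path(outdir, paste0("se.", base2)),
      discard_r1 = file.path(outdir, paste0("discard.", base1)),
      discard_r2 = file.path(outdir, paste0("discard.", base2))
    )
    write_fastq(fq_slice(t1, ok1 & ok2), paths["r1"])
    write_fastq(fq_slice(t2, ok1 & ok2), paths["r2"])
    write_fastq(fq_slice(t1, ok1 & !ok2), paths["se_r1"])
    write_fastq(fq_slice(t2, !ok1 & ok2), paths["se_r2"])
    write_fastq(fq_slice(pr$r1, !ok1), paths["discard_r1"])
    write_fastq(fq_slice(pr$r2, !ok2), paths["discard_r2"])
    out$files <- paths
    out$n_in <- n_in
    out$n_paired <- 2L * sum(ok1 & ok2)
    out$n_se <- sum(ok1 & !ok2) + sum(!ok1 & ok2)
    out$n_discard <- sum(!ok1) + sum(!ok2)
  }
  class(out) <- "trim_result"
  out
}

#' @export
print.trim_result <- function(x, ...) {
  cat(sprintf("trim: %d reads in -> %d paired, %d single-end, %d discarded\n",
              x$n_in, x$n_paired, x$n_se, x$n_discard))
  invisible(x)
}
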