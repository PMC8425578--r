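#' Positional nucleotide and Q-score summaries
#'
#' Builds the two per-position count matrices used for read QC: a 5 x n
#' nucleotide matrix (rows A, C, G, T, N) and a 41 x n Q-score matrix (rows
#' for scores 0--40), where n is the maximum read length observed.  Reads
#' are traversed k bases at a time: each unique k-length chunk of sequence
#' (or quality) is tallied once per chunk window and then decomposed into
#' per-position counts, so the result is identical for every k.
#'
#' Ambiguity codes other than N in the sequence are counted under N with a
#' warning.
#'
#' @param x a [fastq_df()] or a FASTQ file path.
#' @param k chunk width for the k-walk traversal (efficiency device; the
#'   matrices do not depend on it). Default 6.
#' @return list of class `qc_summary` with elements `nucleotide` (5 x n) and
#'   `qscore` (41 x n) integer matrices; columns named `pos1..posn`.
#' @export
qc_summarize <- function(x, k = 6L) {
  stopifnot(k >= 1L)
  if (is.character(x) && length(x) == 1L) x <- read_fastq(x)
  n <- if (nrow(x) == 0L) 0L else max(nchar(x$seq))
  nuc_rows <- c("A", "C", "G", "T", "N")
  q_rows <- as.character(0:.Q_MAX)
  nuc <- matrix(0L, nrow = 5L, ncol = n, dimnames = list(nuc_rows, NULL))
  qsc <- matrix(0L, nrow = 41L, ncol = n, dimnames = list(q_rows, NULL))
  if (n > 0L) {
    starts <- seq(1L, n, by = k)
    saw_other <- FALSE
    for (s in starts) {
      e <- min(s + k - 1L, n)
      chunk_counts <- function(strings) {
        ch <- substr(strings, s, e)
        tab <- table(ch[nchar(ch) > 0L])
        tab
      }
      # nucleotide chunks
      tab <- chunk_counts(x$seq)
      for (i in seq_along(tab)) {
        key <- names(tab)[i]
        cnt <- as.integer(tab[[i]])
        chars <- strsplit(key, "", fixed = TRUE)[[1]]
        other <- !(chars %in% nuc_rows)
        if (any(other)) {
          saw_other <- TRUE
          chars[other] <- "N"
        }
        pos <- s:(s + length(chars) - 1L)
        ridx <- match(chars, nuc_rows)
        for (j in seq_along(pos)) nuc[ridx[j], pos[j]] <- nuc[ridx[j], pos[j]] + cnt
      }
      # quality chunks
      tab <- chunk_counts(x$qual)
      for (i in seq_along(tab)) {
        key <- names(tab)[i]
        cnt <- as.integer(tab[[i]])
        q <- utf8ToInt(key) - .Q_OFFSET
        if (any(q < 0L | q > .Q_MAX)) {
          stop(sprintf("quality score outside [0, %d] in chunk '%s'", .Q_MAX, key))
        }
        pos <- s:(s + length(q) - 1L)
        for (j in seq_along(pos)) qsc[q[j] + 1L, pos[j]] <- qsc[q[j] + 1L, pos[j]] + cnt
      }
    }
    if (saw_other) {
      warning("ambiguity characters other than N were counted under N")
    }
  }
  if (n > 0L) {
    colnames(nuc) <- paste0("pos", seq_len(n))
    colnames(qsc) <- paste0("pos", seq_len(n))
  }
  structure(list(nucleotide = nuc, qscore = qsc), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  n <- ncol(x$nucleotide)
  cat(sprintf("QC summary over %d positions\n", n))
  if (n > 0) {
    cov <- colSums(x$nucleotide)
    cat(sprintf("  coverage: %d reads at position 1, %d at position %d\n",
                cov[1], cov[n], n))
    mq <- qc_mean_q(x)
    cat(sprintf("  mean Q: %.2f (per-position range %.2f-%.2f)\n",
                sum(mq * cov) / sum(cov), min(mq), max(mq)))
  }
  invisible(x)
}

#' Per-position mean and standard deviation of Q scores
#'
#' @param x a `qc_summary`.
#' @return for `qc_mean_q`, numeric vector of per-position means; for
#'   `qc_sd_q`, per-position standard deviations.
#' @export
qc_mean_q <- function(x) {
  m <- x$qscore
  if (ncol(m) == 0L) return(numeric(0))
  q <- 0:.Q_MAX
  colSums(m * q) / colSums(m)
}

#' @rdname qc_mean_q
#' @export
qc_sd_q <- function(x) {
  m <- x$qscore
  if (ncol(m) == 0L) return(numeric(0))
  q <- 0:.Q_MAX
  n <- colSums(m)
  mu <- colSums(m * q) / n
  sqrt(pmax(0, colSums(m * q^2) / n - mu^2))
}

#' Write or read a positional count matrix as CSV
#'
#' Plain CSV with category row labels (nucleotides or Q scores) and one
#' column per read position.
#'
#' @param m integer matrix (a component of a `qc_summary`).
#' @param path output/input CSV path.
#' @export
write_qc_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_qc_matrix
#' @export
read_qc_matrix <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Write both QC matrices for a FASTQ file
#'
#' Writes `<name>.nucleotides.csv` and `<name>.qscores.csv` into `outdir`.
#'
#' @param x a `qc_summary` or input accepted by [qc_summarize()].
#' @param name basename for the output files.
#' @param outdir output directory (created if missing).
#' @param k passed to [qc_summarize()] when `x` is not already a summary.
#' @return invisibly, the two paths written.
#' @export
write_qc_summary <- function(x, name, outdir = ".", k = 6L) {
  if (!inherits(x, "qc_summary")) x <- qc_summarize(x, k = k)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(outdir, paste0(name, ".nucleotides.csv"))
  p2 <- file.path(outdir, paste0(name, ".qscores.csv"))
  write_qc_matrix(x$nucleotide, p1)
  write_qc_matrix(x$qscore, p2)
  invisible(c(p1, p2))
}
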