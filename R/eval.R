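#' Collapse identical reads to unique sequences with frequencies
#'
#' Reads should be end-trimmed to identical length before collapsing so the
#' comparison is unbiased; unequal lengths raise an error unless
#' `allow_mixed_lengths = TRUE`.  Reads containing N are kept as distinct
#' literal sequences.
#'
#' @param x a [fastq_df()], FASTQ path, or character vector of sequences.
#' @param allow_mixed_lengths permit collapsing reads of unequal length.
#' @return named integer vector: unique sequence -> frequency, with
#'   frequencies summing to the total read count.
#' @export
collapse_reads <- function(x, allow_mixed_lengths = FALSE) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) x <- read_fastq(x)
  seqs <- if (is.data.frame(x)) x$seq else x
  if (length(seqs) && length(unique(nchar(seqs))) > 1L) {
    if (!allow_mixed_lengths) {
      stop("reads have unequal lengths; end-trim to identical length first ",
           "or set allow_mixed_lengths = TRUE")
    }
    warning("collapsing reads of unequal length biases the comparison")
  }
  tab <- table(seqs)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read-compression rate of a collapsed read multiset
#'
#' The compression rate is the percent by which the read multiset shrinks
#' when identical reads are collapsed: `(1 - unique/total) * 100`.  It
#' approximates mean read depth per locus in reduced-representation data
#' and falls as sequencing error manufactures novel singleton reads.  The
#' raw unique/total ratio is also reported for transparency.
#'
#' @param counts named frequency vector from [collapse_reads()] (or input
#'   accepted by it).
#' @return list of class `compression_report`: `total_reads`,
#'   `unique_reads`, `compression_rate` (percent), `unique_ratio`.
#' @export
compression_rate <- function(counts) {
  if (!is.numeric(counts)) counts <- collapse_reads(counts)
  total <- sum(counts)
  if (total == 0L) stop("empty input: compression rate undefined")
  uniq <- length(counts)
  structure(list(total_reads = total, unique_reads = uniq,
                 compression_rate = (1 - uniq / total) * 100,
                 unique_ratio = uniq / total),
            class = "compression_report")
}

#' @export
print.compression_report <- function(x, ...) {
  cat(sprintf("%d reads, %d unique: compression rate %.2f%% (unique ratio %.4f)\n",
              x$total_reads, x$unique_reads, x$compression_rate, x$unique_ratio))
  if (!is.null(x$delta)) {
    cat(sprintf("  delta vs size-matched raw subsample: %+.2f points (subsample mean %.2f, sd %.3f, %d replicates)\n",
                x$delta, x$subsample_mean, x$subsample_sd, x$replicates))
  }
  invisible(x)
}

#' Size-normalized change in compression after filtering
#'
#' Compression rate depends on sample size, so the rate of a filtered read
#' set is compared against random subsamples of the raw set drawn at the
#' filtered size (without replacement).  Delta = rate(filtered) - mean rate
#' over `replicates` seeded subsamples.
#'
#' @param filtered filtered reads (any input accepted by
#'   [collapse_reads()]).
#' @param raw raw reads the filter was applied to.
#' @param seed integer seed for the subsampling.
#' @param replicates number of subsample replicates (>= 1, default 10).
#' @param allow_mixed_lengths passed through to [collapse_reads()].
#' @return `compression_report` for the filtered reads with added fields
#'   `delta` (percentage points), `subsample_mean`, `subsample_sd`,
#'   `replicates`.
#' @export
delta_compression <- function(filtered, raw, seed = 1L, replicates = 10L,
                              allow_mixed_lengths = FALSE) {
  get_seqs <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) x <- read_fastq(x)
    if (is.data.frame(x)) x$seq else x
  }
  fs <- get_seqs(filtered); rs <- get_seqs(raw)
  if (length(fs) > length(rs)) {
    stop("filtered set (", length(fs), ") is larger than raw set (", length(rs), ")")
  }
  rep_f <- compression_rate(collapse_reads(fs, allow_mixed_lengths))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sub_rates <- vapply(seq_len(replicates), function(i) {
    s <- sample(rs, length(fs), replace = FALSE)
    compression_rate(collapse_reads(s, allow_mixed_lengths))$compression_rate
  }, 0)
  rep_f$delta <- rep_f$compression_rate - mean(sub_rates)
  rep_f$subsample_mean <- mean(sub_rates)
  rep_f$subsample_sd <- stats::sd(sub_rates)
  rep_f$replicates <- replicates
  rep_f
}

#' Empirical base-calling error profile of the barcode region
#'
#' R1 reads are demultiplexed in staged mismatch passes (m = 0, 1, ...,
#' `max_m`); at each level the newly assigned reads are compared base-by-
#' base to their assigned barcode.  For level m, the per-position error
#' probability is the number of mismatching bases at that position divided
#' by the number of reads assessed at that level of mismatch *and fewer*
#' (positions beyond a read's barcode length are not assessed for that
#' read).  Phred equivalents (-10 log10 p, Inf at p = 0) and the
#' distribution of instrument-reported Q scores at each barcode position
#' are computed alongside.
#'
#' Levels at which the barcode set is no longer identifiable (2m >= minimum
#' pairwise Levenshtein distance) require `override_distance = TRUE`, the
#' deliberate stretch used to expose residual error.
#'
#' @param r1 a [fastq_df()] or FASTQ path of forward reads (barcodes still
#'   attached).
#' @param scheme a [barcode_scheme()]; its forward barcodes are used.
#' @param max_m highest mismatch level to profile.
#' @param override_distance allow profiling past the identifiability bound.
#' @return object of class `barcode_error_profile`: per level, a list with
#'   `n_reads`, per-position `n_assessed`, `errors`, `error_rate`,
#'   `phred_equivalent` and a 41-row `qscore_counts` matrix of reported Q
#'   scores.
#' @export
barcode_error_profile <- function(r1, scheme, max_m = 0L,
                                  override_distance = FALSE) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  stopifnot(inherits(scheme, "barcode_scheme"))
  check_identifiability(scheme$min_dist_forward, max_m, override_distance,
                        "forward")
  barcodes <- scheme$forward
  maxlen <- max(nchar(barcodes))
  mm <- match_barcode(r1$seq, barcodes, max_m)
  if (!any(!is.na(mm$barcode))) stop("no reads could be assigned a barcode")
  levels_out <- vector("list", max_m + 1L)
  names(levels_out) <- paste0("m", 0:max_m)
  for (m in 0:max_m) {
    sel <- which(!is.na(mm$barcode) & mm$mismatch <= m)
    bc <- barcodes[mm$barcode[sel]]
    bl <- nchar(bc)
    n_assessed <- vapply(seq_len(maxlen), function(j) sum(bl >= j), 0L)
    errors <- integer(maxlen)
    qcounts <- matrix(0L, nrow = 41L, ncol = maxlen,
                      dimnames = list(as.character(0:.Q_MAX),
                                      paste0("pos", seq_len(maxlen))))
    if (length(sel)) {
      for (L in unique(bl)) {
        ii <- sel[bl == L]
        pref <- substr(r1$seq[ii], 1L, L)
        bytes <- matrix(charToRaw(paste(pref, collapse = "")), nrow = L)
        bmat <- matrix(charToRaw(paste(barcodes[mm$barcode[ii]], collapse = "")),
                       nrow = L)
        errors[1:L] <- errors[1:L] + rowSums(bytes != bmat)
        qpref <- substr(r1$qual[ii], 1L, L)
        qb <- matrix(as.integer(charToRaw(paste(qpref, collapse = ""))) - .Q_OFFSET,
                     nrow = L)
        for (j in 1:L) {
          tj <- tabulate(qb[j, ] + 1L, nbins = 41L)
          qcounts[, j] <- qcounts[, j] + tj
        }
      }
    }
    rate <- ifelse(n_assessed > 0, errors / n_assessed, NA_real_)
    levels_out[[m + 1L]] <- list(
      n_reads = length(sel), n_assessed = n_assessed, errors = errors,
      error_rate = rate,
      phred_equivalent = ifelse(is.na(rate), NA_real_, phred_equivalent(rate)),
      qscore_counts = qcounts)
  }
  structure(list(levels = levels_out, max_m = max_m,
                 n_input = nrow(r1), barcode_length = maxlen),
            class = "barcode_error_profile")
}

#' @export
print.barcode_error_profile <- function(x, ...) {
  cat(sprintf("empirical barcode error profile (%d reads in, %d positions)\n",
              x$n_input, x$barcode_length))
  for (nm in names(x$levels)) {
    lv <- x$levels[[nm]]
    overall <- sum(lv$errors) / max(1, sum(lv$n_assessed))
    cat(sprintf("  %s: %d reads assigned, mean error %.4g (Phred-equivalent %.1f)\n",
                nm, lv$n_reads, overall,
                phred_equivalent(min(max(overall, .Machine$double.xmin), 1))))
  }
  invisible(x)
}

#' Write a barcode error profile as a TSV report
#'
#' One row per (mismatch level, barcode position) with the assessed read
#' count, error count, error rate, Phred equivalent and mean reported Q.
#'
#' @param profile a `barcode_error_profile`.
#' @param path output TSV path.
#' @export
write_error_profile <- function(profile, path) {
  rows <- do.call(rbind, lapply(names(profile$levels), function(nm) {
    lv <- profile$levels[[nm]]
    q <- 0:.Q_MAX
    mean_q <- vapply(seq_along(lv$n_assessed), function(j) {
      tot <- sum(lv$qscore_counts[, j])
      if (tot == 0) NA_real_ else sum(lv$qscore_counts[, j] * q) / tot
    }, 0)
    data.frame(level = nm, position = seq_along(lv$n_assessed),
               n_assessed = lv$n_assessed, errors = lv$errors,
               error_rate = lv$error_rate,
               phred_equivalent = lv$phred_equivalent,
               mean_reported_q = mean_q)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
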