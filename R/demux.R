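#' Barcode scheme for single- or dual-indexed demultiplexing
#'
#' A dual scheme maps (forward barcode, reverse barcode) cells to sample
#' names via a tab-separated matrix file with forward barcodes as column
#' labels and reverse barcodes as row labels.  A single-index scheme is a
#' two-column TSV (barcode, sample).  The minimum pairwise Levenshtein
#' distance within each barcode set is recorded; demultiplexing at mismatch
#' m with 2m >= that distance is refused (no longer identifiable) unless
#' explicitly overridden.
#'
#' @param forward named character vector of forward barcodes, or character
#'   vector (names default to the barcodes themselves).
#' @param reverse reverse barcodes, or NULL for single-index schemes.
#' @param samples for dual schemes, a character matrix (rows = reverse
#'   barcodes, cols = forward barcodes) of sample names; for single-index
#'   schemes, a character vector parallel to `forward`.
#' @return object of class `barcode_scheme`.
#' @export
barcode_scheme <- function(forward, reverse = NULL, samples) {
  forward <- as.character(forward)
  if (anyDuplicated(forward)) stop("duplicate forward barcodes")
  if (!all(grepl("^[ACGT]+$", forward))) stop("barcodes must be A/C/G/T strings")
  sch <- list(forward = forward,
              min_dist_forward = min_pairwise_levenshtein(forward))
  if (is.null(reverse)) {
    stopifnot(length(samples) == length(forward))
    sch$reverse <- NULL
    sch$samples <- as.character(samples)
    sch$dual <- FALSE
  } else {
    reverse <- as.character(reverse)
    if (anyDuplicated(reverse)) stop("duplicate reverse barcodes")
    if (!all(grepl("^[ACGT]+$", reverse))) stop("barcodes must be A/C/G/T strings")
    samples <- as.matrix(samples)
    if (nrow(samples) != length(reverse) || ncol(samples) != length(forward)) {
      stop("sample matrix must be length(reverse) x length(forward)")
    }
    dimnames(samples) <- list(reverse, forward)
    sch$reverse <- reverse
    sch$min_dist_reverse <- min_pairwise_levenshtein(reverse)
    sch$samples <- samples
    sch$dual <- TRUE
  }
  class(sch) <- "barcode_scheme"
  sch
}

#' @export
print.barcode_scheme <- function(x, ...) {
  if (x$dual) {
    cat(sprintf("dual-index barcode scheme: %d forward x %d reverse (%d sample cells)\n",
                length(x$forward), length(x$reverse), sum(!is.na(x$samples))))
    cat(sprintf("  min pairwise Levenshtein distance: forward %s, reverse %s\n",
                format(x$min_dist_forward), format(x$min_dist_reverse)))
  } else {
    cat(sprintf("single-index barcode scheme: %d barcodes\n", length(x$forward)))
    cat(sprintf("  min pairwise Levenshtein distance: %s\n", format(x$min_dist_forward)))
  }
  invisible(x)
}

#' Read a barcode scheme from a TSV file
#'
#' Dual schemes: first column holds reverse barcodes, header row holds
#' forward barcodes, cells hold sample names (empty cells = unused
#' combinations).  Single-index schemes: two columns, barcode then sample,
#' no header.
#'
#' @param path TSV file path.
#' @param dual logical; `NA` (default) auto-detects from the header row.
#' @return a [barcode_scheme()].
#' @export
read_barcode_scheme <- function(path, dual = NA) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (is.na(dual)) dual <- length(first) > 2L
  if (!dual) {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
    barcode_scheme(forward = d[[1]], samples = d[[2]])
  } else {
    d <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA"))
    barcode_scheme(forward = colnames(d), reverse = rownames(d),
                   samples = as.matrix(d))
  }
}

#' Write a barcode scheme to TSV
#'
#' @param scheme a [barcode_scheme()].
#' @param path output path.
#' @export
write_barcode_scheme <- function(scheme, path) {
  if (scheme$dual) {
    m <- scheme$samples
    m[is.na(m)] <- ""
    utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    utils::write.table(data.frame(scheme$forward, scheme$samples), path,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Distance matrix reads x barcodes: Hamming distance between each barcode
# and the read prefix of that barcode's own length (Inf if read shorter).
barcode_distances <- function(seqs, barcodes) {
  D <- matrix(Inf, nrow = length(seqs), ncol = length(barcodes))
  for (j in seq_along(barcodes)) D[, j] <- prefix_hamming(seqs, barcodes[j])
  D
}

#' Match reads against a barcode set at a given mismatch tolerance
#'
#' Each barcode is compared against the read prefix of the barcode's own
#' length.  Staged semantics: a read is assigned to the barcode at minimum
#' Hamming distance provided that distance is <= `m` and the minimum is
#' achieved by exactly one barcode; ties (including a read matching both a
#' shorter and a longer barcode exactly, i.e. prefix nesting) are reported
#' as unmatched so no sample is misassigned.  Assignment does not depend on
#' barcode order.
#'
#' @param seqs character vector of read sequences.
#' @param barcodes character vector of barcodes (variable lengths allowed).
#' @param m maximum Hamming distance (>= 0).
#' @return data.frame with columns `barcode` (index into `barcodes` or NA),
#'   `mismatch` (distance used, NA if unmatched) and `ambiguous`.
#' @export
match_barcode <- function(seqs, barcodes, m = 0L) {
  stopifnot(m >= 0L)
  D <- barcode_distances(seqs, barcodes)
  best <- do.call(pmin, as.data.frame(D))
  nbest <- rowSums(D == best)
  hit <- is.finite(best) & best <= m & nbest == 1L
  amb <- is.finite(best) & best <= m & nbest > 1L
  idx <- rep(NA_integer_, length(seqs))
  idx[hit] <- max.col(-D[hit, , drop = FALSE], ties.method = "first")
  data.frame(barcode = idx,
             mismatch = ifelse(hit, best, NA_real_),
             ambiguous = amb)
}

check_identifiability <- function(min_dist, m, override, what) {
  if (is.finite(min_dist) && 2 * m >= min_dist && !override) {
    stop(sprintf(
      "mismatch %d is not identifiable for the %s barcode set (2*%d >= min pairwise Levenshtein distance %d); use override_distance = TRUE to force",
      m, what, m, min_dist))
  }
}

#' Demultiplex paired-end reads with staged mismatch passes
#'
#' Forward barcodes are matched against R1 prefixes and reverse barcodes
#' against R2 prefixes, each in staged passes m = 0, 1, ..., `max_m` where
#' each pass only examines reads left unknown by earlier passes.  A read
#' within distance m of more than one barcode is kept as unknown to avoid
#' misassignment.  A pair is assigned to the sample cell (forward, reverse)
#' when both mates matched and the cell is populated; matched barcodes are
#' trimmed from the 5' ends.  Unknown pairs keep their original, untrimmed
#' sequence.  Optional single-end inputs are assigned only when their single
#' barcode determines a unique sample in the scheme.
#'
#' @param r1,r2 [fastq_df()]s or FASTQ paths (paired input).
#' @param scheme a [barcode_scheme()].
#' @param max_m maximum Hamming distance for the final pass (default 0).
#' @param se_r1,se_r2 optional single-end inputs carried through the stage.
#' @param override_distance allow 2*max_m >= min Levenshtein distance of the
#'   barcode set (used for empirical error profiling, never for routine
#'   demultiplexing).
#' @return object of class `demux_result`: trimmed reads, per-read sample
#'   assignments, per-category counts (all sample cells enumerated, plus
#'   unknown), and conservation totals.
#' @export
demultiplex <- function(r1, r2 = NULL, scheme, max_m = 0L,
                        se_r1 = NULL, se_r2 = NULL,
                        override_distance = FALSE) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  check_identifiability(scheme$min_dist_forward, max_m, override_distance, "forward")
  if (scheme$dual) {
    check_identifiability(scheme$min_dist_reverse, max_m, override_distance, "reverse")
  }
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (!is.null(r2) && is.character(r2)) r2 <- read_fastq(r2)
  if (is.character(se_r1)) se_r1 <- read_fastq(se_r1)
  if (is.character(se_r2)) se_r2 <- read_fastq(se_r2)

  if (scheme$dual) {
    if (is.null(r2)) stop("dual-index scheme requires paired input")
    if (nrow(r1) != nrow(r2)) stop("unpaired inputs: ", nrow(r1), " vs ", nrow(r2))
    m1 <- match_barcode(r1$seq, scheme$forward, max_m)
    m2 <- match_barcode(r2$seq, scheme$reverse, max_m)
    sample <- rep(NA_character_, nrow(r1))
    both <- !is.na(m1$barcode) & !is.na(m2$barcode)
    sample[both] <- scheme$samples[cbind(m2$barcode[both], m1$barcode[both])]
    assigned <- !is.na(sample)
    # trim matched barcodes from assigned reads only
    t1 <- r1; t2 <- r2
    bl1 <- nchar(scheme$forward)[m1$barcode]
    bl2 <- nchar(scheme$reverse)[m2$barcode]
    t1$seq[assigned] <- substring(r1$seq[assigned], bl1[assigned] + 1L)
    t1$qual[assigned] <- substring(r1$qual[assigned], bl1[assigned] + 1L)
    t2$seq[assigned] <- substring(r2$seq[assigned], bl2[assigned] + 1L)
    t2$qual[assigned] <- substring(r2$qual[assigned], bl2[assigned] + 1L)
    assignments <- data.frame(
      id = r1$id, sample = sample,
      forward = ifelse(is.na(m1$barcode), NA, scheme$forward[m1$barcode]),
      reverse = ifelse(is.na(m2$barcode), NA, scheme$reverse[m2$barcode]),
      mismatch_forward = m1$mismatch, mismatch_reverse = m2$mismatch,
      ambiguous = m1$ambiguous | m2$ambiguous,
      stringsAsFactors = FALSE)
    cells <- sort(unique(as.vector(scheme$samples[!is.na(scheme$samples)])))
    # single-end inputs: assignable only if the barcode pins down one sample
    se_assign <- function(se, barcodes, margin) {
      if (is.null(se) || nrow(se) == 0L) {
        return(list(reads = fq_empty(), sample = character(0)))
      }
      mm <- match_barcode(se$seq, barcodes, max_m)
      smp <- rep(NA_character_, nrow(se))
      for (i in which(!is.na(mm$barcode))) {
        cands <- if (margin == 1L) scheme$samples[, mm$barcode[i]] else scheme$samples[mm$barcode[i], ]
        cands <- unique(cands[!is.na(cands)])
        if (length(cands) == 1L) smp[i] <- cands
      }
      tr <- se
      ok <- !is.na(smp)
      bl <- nchar(barcodes)[mm$barcode]
      tr$seq[ok] <- substring(se$seq[ok], bl[ok] + 1L)
      tr$qual[ok] <- substring(se$qual[ok], bl[ok] + 1L)
      list(reads = tr, sample = smp)
    }
    se1 <- se_assign(se_r1, scheme$forward, 1L)
    se2 <- se_assign(se_r2, scheme$reverse, 2L)
    res <- list(
      scheme = scheme, max_m = max_m, dual = TRUE,
      r1 = t1, r2 = t2, sample = sample, assignments = assignments,
      se_r1 = se1$reads, se_r1_sample = se1$sample,
      se_r2 = se2$reads, se_r2_sample = se2$sample,
      samples = cells)
    res$counts <- demux_counts(res)
    res$n_in <- 2L * nrow(r1) +
      (if (is.null(se_r1)) 0L else nrow(se_r1)) +
      (if (is.null(se_r2)) 0L else nrow(se_r2))
  } else {
    mm <- match_barcode(r1$seq, scheme$forward, max_m)
    sample <- rep(NA_character_, nrow(r1))
    hit <- !is.na(mm$barcode)
    sample[hit] <- scheme$samples[mm$barcode[hit]]
    t1 <- r1
    bl <- nchar(scheme$forward)[mm$barcode]
    t1$seq[hit] <- substring(r1$seq[hit], bl[hit] + 1L)
    t1$qual[hit] <- substring(r1$qual[hit], bl[hit] + 1L)
    assignments <- data.frame(
      id = r1$id, sample = sample,
      forward = ifelse(hit, scheme$forward[mm$barcode], NA),
      mismatch_forward = mm$mismatch, ambiguous = mm$ambiguous,
      stringsAsFactors = FALSE)
    res <- list(scheme = scheme, max_m = max_m, dual = FALSE,
                r1 = t1, r2 = NULL, sample = sample,
                assignments = assignments,
                se_r1 = fq_empty(), se_r1_sample = character(0),
                se_r2 = fq_empty(), se_r2_sample = character(0),
                samples = sort(unique(scheme$samples)))
    res$counts <- demux_counts(res)
    res$n_in <- nrow(r1)
  }
  class(res) <- "demux_result"
  res
}

# Category table: every sample cell appears as a paired category and as
# se.R1/se.R2 categories, plus the unknown categories, whether populated
# or not.
demux_counts <- function(res) {
  paired <- table(factor(res$sample, levels = res$samples))
  se1 <- table(factor(res$se_r1_sample, levels = res$samples))
  se2 <- table(factor(res$se_r2_sample, levels = res$samples))
  data.frame(
    sample = c(res$samples, res$samples, res$samples, "unknown", "unknown"),
    category = c(rep("paired", length(res$samples)),
                 rep("se.R1", length(res$samples)),
                 rep("se.R2", length(res$samples)),
                 "unknown.R1", "unknown.R2"),
    reads = c(as.integer(paired), as.integer(se1), as.integer(se2),
              sum(is.na(res$sample)) + sum(is.na(res$se_r1_sample)),
              if (is.null(res$r2)) 0L else sum(is.na(res$sample)) +
                sum(is.na(res$se_r2_sample))),
    stringsAsFactors = FALSE)
}

#' @export
print.demux_result <- function(x, ...) {
  n_pairs <- nrow(x$r1)
  n_assigned <- sum(!is.na(x$sample))
  cat(sprintf("demultiplexed %d %s at max mismatch %d\n", n_pairs,
              if (x$dual) "pairs" else "reads", x$max_m))
  cat(sprintf("  assigned: %d (%.2f%%), unknown: %d, samples used: %d of %d\n",
              n_assigned, 100 * n_assigned / max(1, n_pairs),
              n_pairs - n_assigned,
              length(unique(stats::na.omit(x$sample))), length(x$samples)))
  invisible(x)
}

#' Write demultiplexed reads to per-sample FASTQ files
#'
#' File naming: `<sample>.R1.fastq` / `<sample>.R2.fastq` for paired reads,
#' `se.<sample>.R1.fastq` / `se.<sample>.R2.fastq` for single ends and
#' `unknown.R1.fastq` / `unknown.R2.fastq` for unassigned reads.  By default
#' only populated categories are written.
#'
#' @param res a `demux_result`.
#' @param outdir output directory.
#' @param write_empty also create files for empty categories.
#' @return invisibly, a character vector of written paths.
#' @export
write_demux <- function(res, outdir, write_empty = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(reads, path) {
    if (nrow(reads) > 0L || write_empty) {
      write_fastq(reads, path)
      written <<- c(written, path)
    }
  }
  groups <- if (write_empty) res$samples else
    unique(stats::na.omit(c(res$sample, res$se_r1_sample, res$se_r2_sample)))
  for (s in groups) {
    i <- which(!is.na(res$sample) & res$sample == s)
    emit(fq_slice(res$r1, i), file.path(outdir, paste0(s, ".R1.fastq")))
    if (!is.null(res$r2)) {
      emit(fq_slice(res$r2, i), file.path(outdir, paste0(s, ".R2.fastq")))
    }
    j <- which(!is.na(res$se_r1_sample) & res$se_r1_sample == s)
    emit(fq_slice(res$se_r1, j), file.path(outdir, paste0("se.", s, ".R1.fastq")))
    k <- which(!is.na(res$se_r2_sample) & res$se_r2_sample == s)
    emit(fq_slice(res$se_r2, k), file.path(outdir, paste0("se.", s, ".R2.fastq")))
  }
  un <- which(is.na(res$sample))
  un1 <- fq_rbind(fq_slice(res$r1, un), fq_slice(res$se_r1, is.na(res$se_r1_sample)))
  write_fastq(un1, file.path(outdir, "unknown.R1.fastq"))
  written <- c(written, file.path(outdir, "unknown.R1.fastq"))
  if (!is.null(res$r2)) {
    un2 <- fq_rbind(fq_slice(res$r2, un), fq_slice(res$se_r2, is.na(res$se_r2_sample)))
    write_fastq(un2, file.path(outdir, "unknown.R2.fastq"))
    written <- c(written, file.path(outdir, "unknown.R2.fastq"))
  }
  invisible(written)
}
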