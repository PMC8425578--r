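# Fixture generators and independent brute-force oracles shared by the
# test files.  Everything is generated in code under fixed seeds.

rand_reads <- function(n, len = 100L, len_range = NULL, qmin = 0L, qmax = 40L,
                       prefix = "r") {
  lens <- if (is.null(len_range)) rep(len, n) else
    sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  quals <- vapply(lens, function(L) {
    intToUtf8(sample(qmin:qmax, L, replace = TRUE) + 33L)
  }, "")
  fastq_df(paste0(prefix, seq_len(n)), seqs, quals)
}

tmp_fastq <- function(reads, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  write_fastq(reads, path)
  path
}

# Oracle: naive per-position single-base tally for the QC matrices.
oracle_position_counts <- function(reads) {
  n <- if (nrow(reads) == 0) 0L else max(nchar(reads$seq))
  nuc <- matrix(0L, 5, n, dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  qsc <- matrix(0L, 41, n, dimnames = list(as.character(0:40), NULL))
  for (i in seq_len(nrow(reads))) {
    s <- strsplit(reads$seq[i], "")[[1]]
    s[!s %in% c("A", "C", "G", "T")] <- "N"
    q <- utf8ToInt(reads$qual[i]) - 33L
    for (j in seq_along(s)) {
      nuc[s[j], j] <- nuc[s[j], j] + 1L
      qsc[q[j] + 1L, j] <- qsc[q[j] + 1L, j] + 1L
    }
  }
  if (n > 0) colnames(nuc) <- colnames(qsc) <- paste0("pos", seq_len(n))
  list(nucleotide = nuc, qscore = qsc)
}

# Oracle: exhaustive window scan for quality end trimming; returns kept
# length for one quality string.
oracle_window_trim <- function(qual, window, end_q) {
  q <- utf8ToInt(qual) - 33L
  L <- length(q)
  if (L == 0) return(0L)
  w <- min(window, L)
  best <- 0L
  for (j in L:w) {
    if (all(q[(j - w + 1):j] >= end_q)) return(j)
  }
  0L
}

# Oracle: exhaustive all-barcode Hamming scan; returns index of the unique
# closest barcode within m, else NA (ties or no match -> NA).
oracle_barcode_match <- function(seq, barcodes, m) {
  d <- vapply(barcodes, function(b) {
    L <- nchar(b)
    if (nchar(seq) < L) return(Inf)
    sum(strsplit(substr(seq, 1, L), "")[[1]] != strsplit(b, "")[[1]])
  }, 0)
  dm <- min(d)
  if (!is.finite(dm) || dm > m) return(NA_integer_)
  hits <- which(d == dm)
  if (length(hits) == 1L) hits else NA_integer_
}

# Oracle: slide the full adapter template across the read and accept the
# smallest start whose overlapping portion is within max_mm mismatches and
# covers at least min_overlap template bases.
oracle_adapter_slide <- function(read, template, max_mm = 0L, min_overlap = 12L) {
  rl <- nchar(read); tl <- nchar(template)
  rch <- strsplit(read, "")[[1]]
  tch <- strsplit(template, "")[[1]]
  for (s in 1:(rl - min_overlap + 1L)) {
    span <- min(tl, rl - s + 1L)
    if (span < min_overlap) break
    mm <- sum(rch[s:(s + span - 1L)] != tch[1:span])
    if (mm <= max_mm) return(s)
  }
  NA_integer_
}

# Vectorized variant of oracle_adapter_slide for large read sets: same
# smallest-qualifying-start semantics, computed shift-by-shift.
oracle_adapter_slide_vec <- function(reads, template, max_mm = 0L,
                                     min_overlap = 12L) {
  n <- length(reads)
  rl <- nchar(reads)
  tl <- nchar(template)
  tb <- charToRaw(template)
  out <- rep(NA_integer_, n)
  open <- rep(TRUE, n)
  for (s in seq_len(max(rl) - min_overlap + 1L)) {
    act <- which(open & rl - s + 1L >= min_overlap)
    if (!length(act)) break
    span <- pmin(tl, rl[act] - s + 1L)
    for (sp in unique(span)) {
      ii <- act[span == sp]
      seg <- substr(reads[ii], s, s + sp - 1L)
      bytes <- matrix(charToRaw(paste(seg, collapse = "")), nrow = sp)
      mm <- colSums(bytes != tb[1:sp])
      hit <- ii[mm <= max_mm]
      out[hit] <- s
      open[hit] <- FALSE
    }
  }
  out
}

# Oracle: maximum per-family k-mer vote support available for a template
# placed at start s of a read (families = offset residues mod k, limited to
# `rounds` families), used to enumerate legitimate detection misses.
oracle_vote_support <- function(read, template, s, k = 8L, rounds = 3L) {
  rl <- nchar(read); tl <- nchar(template)
  best <- 0L
  for (rd in 0:(rounds - 1L)) {
    offs <- seq.int(rd, tl - k, by = k)
    votes <- 0L
    for (o in offs) {
      p <- s + o
      if (p < 1L || p + k - 1L > rl) next
      if (substr(read, p, p + k - 1L) == substr(template, o + 1L, o + k)) {
        votes <- votes + 1L
      }
    }
    best <- max(best, votes)
  }
  best
}

# Oracle: direct per-read fraction test for the Q threshold filter.
oracle_qthreshold <- function(qual, q, p) {
  v <- utf8ToInt(qual) - 33L
  if (length(v) == 0) return(TRUE)
  sum(v >= q) / length(v) >= p / 100
}

# Small deterministic dual-index scheme for demux tests.
test_scheme <- function(nf = 12L, nr = 12L, seed = 42L) {
  sim_scheme(nf, nr, seed = seed)
}
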