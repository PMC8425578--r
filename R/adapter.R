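#' Build a k-mer index over adapter sequences
#'
#' Each adapter (optionally a composite of adapter proper plus buffer,
#' barcode and restriction-motif context, which sharpens detection) is split
#' into all overlapping k-mers; each k-mer maps to the adapters containing
#' it and its 0-based offset from the adapter start.
#'
#' @param adapters character vector of adapter template sequences; names are
#'   used as adapter ids (defaulting to `adapter1..n`).
#' @param k k-mer size (>= 1); every adapter must be at least k long.
#' @return object of class `adapter_index`: list with `k`, `adapters` and
#'   `entries` (named list k-mer -> data.frame(adapter, offset)).
#' @export
adapter_index <- function(adapters, k = 8L) {
  stopifnot(k >= 1L)
  if (is.null(names(adapters))) {
    names(adapters) <- paste0("adapter", seq_along(adapters))
  }
  short <- nchar(adapters) < k
  if (any(short)) {
    stop("adapter shorter than k: ", paste(names(adapters)[short], collapse = ", "))
  }
  tuples <- do.call(rbind, lapply(seq_along(adapters), function(i) {
    L <- nchar(adapters[i])
    off <- 0:(L - k)
    data.frame(kmer = substring(adapters[i], off + 1L, off + k),
               adapter = names(adapters)[i], offset = off,
               stringsAsFactors = FALSE)
  }))
  entries <- split(tuples[c("adapter", "offset")], tuples$kmer)
  structure(list(k = as.integer(k), adapters = adapters, entries = entries),
            class = "adapter_index")
}

#' @export
print.adapter_index <- function(x, ...) {
  cat(sprintf("adapter index: %d adapters, k = %d, %d distinct k-mers (%d entries)\n",
              length(x$adapters), x$k, length(x$entries),
              sum(vapply(x$entries, nrow, 0L))))
  invisible(x)
}

# Offset schedule: round 1 visits adapter offsets {0, k, 2k, ...}, round 2
# {1, k+1, 2k+1, ...} and so on, for `rounds` rounds or until offsets are
# exhausted.  Returns the 0-based offsets in visiting order for an adapter
# of length L.
offset_schedule <- function(L, k, rounds) {
  maxoff <- L - k
  out <- integer(0)
  for (rd in 0:(min(rounds, k) - 1L)) {
    if (rd > maxoff) break
    out <- c(out, seq.int(rd, maxoff, by = k))
  }
  out
}

#' Scan reads for adapter contamination by k-mer offset voting
#'
#' Adapter k-mers are examined in a round schedule (offsets 0, k, 2k, ...;
#' then 1, k+1, ...; for up to `rounds` rounds).  Every occurrence of an
#' indexed k-mer at read position p (1-based) with adapter offset o votes
#' for adapter start p - o; the first start index to accumulate `votes`
#' supporting offsets *within one round's offset family* is reported.
#' Offsets within a family are spaced k apart, so the supporting k-mers do
#' not overlap: `votes = 2` demands 2k independently matching adapter bases,
#' which keeps chance matches in genomic sequence (e.g. a single lucky run
#' of k+1 bases under overlapping offsets) from triggering spurious trims.
#' Ties arising in the same schedule step resolve to the smaller (5'-most)
#' start, the conservative choice for contamination removal.  A hit whose
#' start leaves fewer than `min_overlap` adapter bases inside the read is
#' suppressed (such shallow read-through is left to the alignment
#' fallback).  A computed start before the read start reports start 1 (the
#' whole read is adapter).
#'
#' @param seqs character vector of read sequences (or [fastq_df()]).
#' @param index an [adapter_index()].
#' @param votes matching positions required to call a hit (default 2).
#' @param rounds number of offset rounds to search (default 3).
#' @param min_overlap minimum adapter bases that must lie within the read
#'   for a k-mer hit (default 12).
#' @return data.frame with one row per read: `start` (1-based adapter start
#'   in the read, NA if adapter-free), `adapter` id and `votes`.
#' @export
scan_adapters <- function(seqs, index, votes = 2L, rounds = 3L,
                          min_overlap = 12L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  stopifnot(votes >= 1L, rounds >= 1L)
  n <- length(seqs)
  out <- data.frame(start = rep(NA_integer_, n),
                    adapter = rep(NA_character_, n),
                    votes = rep(NA_integer_, n))
  if (n == 0L) return(out)
  k <- index$k
  len <- nchar(seqs)
  # schedule steps across all adapters: visit offset families in order
  steps <- do.call(rbind, lapply(names(index$adapters), function(a) {
    offs <- offset_schedule(nchar(index$adapters[[a]]), k, rounds)
    if (!length(offs)) return(NULL)
    data.frame(adapter = a, offset = offs, order = seq_along(offs),
               stringsAsFactors = FALSE)
  }))
  steps <- steps[order(steps$order, steps$adapter, steps$offset), ]
  hits <- vector("list", nrow(steps))
  for (s in seq_len(nrow(steps))) {
    a <- steps$adapter[s]; o <- steps$offset[s]
    kmer <- substr(index$adapters[[a]], o + 1L, o + k)
    mpos <- gregexpr(kmer, seqs, fixed = TRUE)
    cnt <- vapply(mpos, function(p) if (p[1] == -1L) 0L else length(p), 0L)
    if (sum(cnt) == 0L) next
    ridx <- rep(seq_len(n), cnt)
    p <- unlist(mpos[cnt > 0L], use.names = FALSE)
    hits[[s]] <- data.frame(read = ridx, adapter = a,
                            start = p - o, offset = o, step = s)
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) return(out)
  # clamp starts before the read start to 1 (adapter begins upstream)
  hits$start_eff <- pmax(hits$start, 1L)
  # overlap requirement on the effective start
  hits <- hits[len[hits$read] - hits$start_eff + 1L >= min_overlap, , drop = FALSE]
  if (nrow(hits) == 0L) return(out)
  # distinct offsets per (read, adapter, start, offset family); completion
  # step of the votes-th offset in a family decides which candidate fires
  # first
  hits$family <- hits$offset %% k
  hits <- hits[order(hits$read, hits$adapter, hits$start_eff, hits$family,
                     hits$step), , drop = FALSE]
  key <- paste(hits$read, hits$adapter, hits$start_eff, hits$family, sep = "\r")
  first_of_key <- !duplicated(paste(key, hits$offset, sep = "\r"))
  h <- hits[first_of_key, , drop = FALSE]
  kk <- key[first_of_key]
  rank_in_group <- stats::ave(seq_along(kk), kk, FUN = seq_along)
  nvotes <- stats::ave(seq_along(kk), kk, FUN = length)
  cand <- h[rank_in_group == votes, , drop = FALSE]
  cand$nvotes <- nvotes[rank_in_group == votes]
  if (nrow(cand) == 0L) return(out)
  # winner per read: earliest completion step, then smaller start
  ord <- order(cand$read, cand$step, cand$start_eff)
  cand <- cand[ord, , drop = FALSE]
  win <- cand[!duplicated(cand$read), , drop = FALSE]
  out$start[win$read] <- win$start_eff
  out$adapter[win$read] <- win$adapter
  out$votes[win$read] <- win$nvotes
  out
}

#' Local alignment fallback for shallow or mutated adapter read-through
#'
#' Smith-Waterman local alignment (match +1, mismatch -1, linear gap -2) of
#' one adapter against one read.  A hit requires the aligned block to span
#' at least `t` adapter bases or to reach the read's 3' end; the inferred
#' adapter start in the read extrapolates the block to the adapter's first
#' base.
#'
#' @param read read sequence (single string).
#' @param adapter adapter sequence (single string).
#' @param t minimum adapter bases in the aligned block (>= 1).
#' @param match,mismatch,gap scoring parameters.
#' @return list with `score`, `hit` (logical), `start` (inferred 1-based
#'   adapter start in the read, NA when no hit), and the aligned block
#'   coordinates `read_start`, `read_end`, `adapter_start`, `adapter_end`.
#' @export
align_adapter <- function(read, adapter, t = 12L,
                          match = 1, mismatch = -1, gap = -2) {
  stopifnot(t >= 1L)
  r <- utf8ToInt(read); a <- utf8ToInt(adapter)
  n <- length(r); m <- length(a)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- max(0,
                H[i, j] + if (r[i] == a[j]) match else mismatch,
                H[i, j + 1L] + gap,
                H[i + 1L, j] + gap)
      H[i + 1L, j + 1L] <- sc
      if (sc > best) { best <- sc; bi <- i; bj <- j }
    }
  }
  if (best <= 0) {
    return(list(score = 0, hit = FALSE, start = NA_integer_,
                read_start = NA_integer_, read_end = NA_integer_,
                adapter_start = NA_integer_, adapter_end = NA_integer_))
  }
  # traceback for block extent
  i <- bi; j <- bj
  while (H[i + 1L, j + 1L] > 0) {
    diag <- H[i, j] + if (r[i] == a[j]) match else mismatch
    up <- H[i, j + 1L] + gap
    left <- H[i + 1L, j] + gap
    cur <- H[i + 1L, j + 1L]
    if (cur == diag) { i <- i - 1L; j <- j - 1L }
    else if (cur == up) i <- i - 1L
    else j <- j - 1L
    if (i == 0L || j == 0L) break
  }
  rs <- i + 1L; as_ <- j + 1L
  span <- bj - as_ + 1L
  hit <- span >= t || bi == n
  start <- rs - (as_ - 1L)
  list(score = best, hit = hit,
       start = if (hit) max(start, 1L) else NA_integer_,
       read_start = rs, read_end = bi,
       adapter_start = as_, adapter_end = bj)
}

#' Detect and trim 3' adapter read-through in FASTQ files
#'
#' Reads with a k-mer voting hit (optionally rescued by the alignment
#' fallback when `t` is given) are truncated at the detected adapter start;
#' sequence and quality are trimmed in lockstep.  Reads shorter than
#' `min_len` after trimming go to a discard file; adapter-free reads pass
#' unchanged.
#'
#' @param r1_path input R1 FASTQ path.
#' @param r2_path optional R2 FASTQ path (trimmed against `r2_adapters`).
#' @param r1_adapters,r2_adapters adapter template vectors (composites of
#'   adapter, buffer, barcode and motif context are encouraged), or a path
#'   to a newline-separated adapter file for `r1_adapters`.
#' @param k,votes,rounds,min_overlap see [scan_adapters()].
#' @param t overlap for the [align_adapter()] fallback; NULL disables it.
#' @param min_len minimum surviving read length (default 50).
#' @param outdir output directory.
#' @return list of class `adapter_result` with paths, counts and the trim
#'   length distribution.
#' @export
trim_adapters <- function(r1_path, r2_path = NULL, r1_adapters,
                          r2_adapters = NULL, k = 8L, votes = 2L,
                          rounds = 3L, min_overlap = 12L, t = NULL,
                          min_len = 50L, outdir = ".") {
  if (length(r1_adapters) == 1L && file.exists(r1_adapters) &&
      !grepl("^[ACGTN]+$", r1_adapters)) {
    r1_adapters <- readLines(r1_adapters)
    r1_adapters <- r1_adapters[nzchar(r1_adapters)]
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  one <- function(reads, adapters) {
    idx <- adapter_index(adapters, k)
    hit <- scan_adapters(reads$seq, idx, votes, rounds, min_overlap)
    if (!is.null(t)) {
      miss <- which(is.na(hit$start))
      for (i in miss) {
        for (a in names(idx$adapters)) {
          al <- align_adapter(reads$seq[i], idx$adapters[[a]], t = t)
          if (al$hit) {
            hit$start[i] <- al$start; hit$adapter[i] <- a
            break
          }
        }
      }
    }
    cut <- ifelse(is.na(hit$start), nchar(reads$seq), hit$start - 1L)
    reads$seq <- substr(reads$seq, 1L, cut)
    reads$qual <- substr(reads$qual, 1L, cut)
    list(reads = reads, hit = hit)
  }
  emit <- function(reads, base) {
    keep <- nchar(reads$seq) >= min_len
    p1 <- file.path(outdir, base)
    p2 <- file.path(outdir, paste0("discard.", base))
    write_fastq(fq_slice(reads, keep), p1)
    write_fastq(fq_slice(reads, !keep), p2)
    c(keep = p1, discard = p2)
  }
  r1 <- read_fastq(r1_path)
  o1 <- one(r1, r1_adapters)
  files <- emit(o1$reads, basename(r1_path))
  out <- list(files = list(r1 = files),
              hits = list(r1 = o1$hit),
              n_in = nrow(r1),
              n_trimmed = sum(!is.na(o1$hit$start)),
              n_discard = sum(nchar(o1$reads$seq) < min_len),
              trimmed_lengths = table(nchar(o1$reads$seq)))
  if (!is.null(r2_path)) {
    stopifnot(!is.null(r2_adapters))
    r2 <- read_fastq(r2_path)
    o2 <- one(r2, r2_adapters)
    files2 <- emit(o2$reads, basename(r2_path))
    out$files$r2 <- files2
    out$hits$r2 <- o2$hit
    out$n_in <- out$n_in + nrow(r2)
    out$n_trimmed <- out$n_trimmed + sum(!is.na(o2$hit$start))
    out$n_discard <- out$n_discard + sum(nchar(o2$reads$seq) < min_len)
  }
  class(out) <- "adapter_result"
  out
}

#' @export
print.adapter_result <- function(x, ...) {
  cat(sprintf("adapter trimming: %d reads in, %d trimmed, %d discarded (< min length)\n",
              x$n_in, x$n_trimmed, x$n_discard))
  invisible(x)
}
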