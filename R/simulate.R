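#' Restriction enzyme cut specifications
#'
#' Built-in enzymes for the reduced-representation simulator.  `cut5` is
#' the 0-based offset within the recognition site at which the downstream
#' fragment begins after cutting and end fill-in; `cut3` is the offset one
#' past the last retained base of the upstream fragment.  With NsiI
#' (ATGCAT) the downstream fragment begins `TGCAT...` and the upstream ends
#' `...ATGCA`; with NlaIII (CATG) both flanks retain the full palindromic
#' `CATG`.  AluI and HaeIII (blunt cutters used for the partial-digest
#' whole-genome preset) cut in the site middle.
#'
#' @param name one of "NsiI", "NlaIII", "AluI", "HaeIII".
#' @return list with `name`, `site`, `cut5`, `cut3`.
#' @export
enzyme_spec <- function(name) {
  specs <- list(
    NsiI   = list(site = "ATGCAT", cut5 = 1L, cut3 = 5L),
    NlaIII = list(site = "CATG",   cut5 = 0L, cut3 = 4L),
    AluI   = list(site = "AGCT",   cut5 = 2L, cut3 = 2L),
    HaeIII = list(site = "GGCC",   cut5 = 2L, cut3 = 2L)
  )
  if (!name %in% names(specs)) {
    stop("unknown enzyme: ", name, " (available: ",
         paste(names(specs), collapse = ", "), ")")
  }
  c(list(name = name), specs[[name]])
}

#' Generate a synthetic genome sequence
#'
#' I.i.d. bases at a given GC content; deterministic for a fixed seed.
#' Stands in for a real assembly so the simulator needs no download.
#'
#' @param length genome length in bases (>= 10000 recommended for useful
#'   digests).
#' @param gc GC fraction in [0, 1] (default 0.5).
#' @param seed integer seed.
#' @param path optional FASTA output path (written via Biostrings).
#' @return the genome as a single character string (invisibly also written
#'   to `path` if given), named `synthetic_chr1`.
#' @export
sim_genome <- function(length, gc = 0.5, seed = 1L, path = NULL) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  g <- paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  names(g) <- "synthetic_chr1"
  if (!is.null(path)) {
    ss <- Biostrings::DNAStringSet(g)
    names(ss) <- "synthetic_chr1"
    Biostrings::writeXStringSet(ss, path)
  }
  g
}

#' In silico restriction digest
#'
#' Cuts the genome at every recognition site of the given enzymes and
#' returns the fragments between consecutive cuts, annotated with the
#' enzyme flanking each end.  Fragments flanked by one NsiI-type and one
#' NlaIII-type end (in either orientation) are the double-digest class
#' retained by reduced-representation library preparation; these are
#' oriented so the NsiI end comes first.
#'
#' @param genome character string (or FASTA path, first record used).
#' @param enzymes list of [enzyme_spec()]s (default NsiI + NlaIII).
#' @return data.frame of class `digest_result`: `start`, `end` (1-based,
#'   inclusive, in genome coordinates), `left_enz`, `right_enz`, `seq`,
#'   `retained` (double-digest class), `orient` ("+" as-is, "-" reverse
#'   complemented into NsiI-first orientation).
#' @export
sim_digest <- function(genome,
                       enzymes = list(enzyme_spec("NsiI"), enzyme_spec("NlaIII"))) {
  if (file.exists(genome[1]) && !grepl("^[ACGTN]+$", genome[1])) {
    ss <- Biostrings::readDNAStringSet(genome[1])
    genome <- as.character(ss[[1]])
  }
  gs <- Biostrings::DNAString(genome)
  cuts <- do.call(rbind, lapply(enzymes, function(e) {
    hits <- Biostrings::matchPattern(e$site, gs)
    if (length(hits) == 0L) return(NULL)
    s <- Biostrings::start(hits)
    data.frame(site_start = s, enz = e$name,
               down_start = s + e$cut5,        # 1-based start of downstream frag
               up_end = s + e$cut3 - 1L)       # 1-based end of upstream frag
  }))
  if (is.null(cuts) || nrow(cuts) == 0L) {
    out <- data.frame(start = integer(0), end = integer(0),
                      left_enz = character(0), right_enz = character(0),
                      seq = character(0), retained = logical(0),
                      orient = character(0))
    class(out) <- c("digest_result", "data.frame")
    return(out)
  }
  cuts <- cuts[order(cuts$site_start), ]
  n <- nrow(cuts)
  # interior fragments between consecutive cuts
  if (n < 2L) {
    frag <- data.frame(start = integer(0), end = integer(0),
                       left_enz = character(0), right_enz = character(0))
  } else {
    frag <- data.frame(start = cuts$down_start[-n], end = cuts$up_end[-1L],
                       left_enz = cuts$enz[-n], right_enz = cuts$enz[-1L],
                       stringsAsFactors = FALSE)
  }
  # terminal fragments (genome ends are not enzyme ends -> never retained)
  frag <- rbind(
    data.frame(start = 1L, end = cuts$up_end[1L], left_enz = "end",
               right_enz = cuts$enz[1L], stringsAsFactors = FALSE),
    frag,
    data.frame(start = cuts$down_start[n], end = nchar(genome),
               left_enz = cuts$enz[n], right_enz = "end",
               stringsAsFactors = FALSE))
  frag <- frag[frag$end >= frag$start, , drop = FALSE]
  frag$seq <- substring(genome, frag$start, frag$end)
  pair <- paste(frag$left_enz, frag$right_enz)
  frag$retained <- pair %in% c("NsiI NlaIII", "NlaIII NsiI")
  frag$orient <- ifelse(frag$left_enz == "NlaIII" & frag$right_enz == "NsiI",
                        "-", "+")
  flip <- frag$retained & frag$orient == "-"
  frag$seq[flip] <- revcomp(frag$seq[flip])
  rownames(frag) <- NULL
  class(frag) <- c("digest_result", "data.frame")
  frag
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("digest: %d fragments, %d retained double-digest fragments (lengths %s)\n",
              nrow(x), sum(x$retained),
              if (any(x$retained)) paste0(min(nchar(x$seq[x$retained])), "-",
                                          max(nchar(x$seq[x$retained]))) else "-"))
  invisible(x)
}

#' Generate a dual-indexed barcode set for the simulator
#'
#' Greedy rejection sampling of variable-length barcodes (7--10 bp) with a
#' minimum pairwise Levenshtein distance of 3 within each direction.  To
#' guarantee unambiguous exact-match demultiplexing, no accepted barcode
#' may be a prefix of another accepted barcode extended by the motif that
#' always follows the barcode in a correctly constructed read.
#'
#' @param n barcodes per direction (default 96).
#' @param lengths barcode lengths to cycle through (default 7:10).
#' @param min_dist minimum pairwise Levenshtein distance (default 3).
#' @param motif the motif following the barcode in reads (prefix-safety
#'   context; default "TGCAT").
#' @param seed integer seed.
#' @return character vector of `n` barcodes.
#' @export
sim_barcodes <- function(n = 96L, lengths = 7:10, min_dist = 3L,
                         motif = "TGCAT", seed = 1L) {
  set.seed(seed)
  accepted <- character(0)
  want_len <- rep_len(lengths, n)
  tries <- 0L
  while (length(accepted) < n) {
    tries <- tries + 1L
    if (tries > 100000L) stop("could not build barcode set; relax constraints")
    L <- want_len[length(accepted) + 1L]
    cand <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    if (length(accepted)) {
      if (min(utils::adist(cand, accepted)) < min_dist) next
      if (any(startsWith(paste0(accepted, motif), cand)) ||
          any(startsWith(paste0(cand, motif), accepted))) next
    }
    accepted <- c(accepted, cand)
  }
  accepted
}

#' Full-plex dual-index scheme for simulation
#'
#' All forward x reverse combinations are populated with generated sample
#' names `S<f>_<r>`.
#'
#' @param n_forward,n_reverse barcodes per direction.
#' @param seed integer seed (forward and reverse sets use seed and seed+1).
#' @return a [barcode_scheme()].
#' @export
sim_scheme <- function(n_forward = 96L, n_reverse = 96L, seed = 1L) {
  fwd <- sim_barcodes(n_forward, motif = "TGCAT", seed = seed)
  rev <- sim_barcodes(n_reverse, motif = "CATG", seed = seed + 1L)
  samples <- outer(seq_len(n_reverse), seq_len(n_forward),
                   function(r, f) sprintf("S%02d_%02d", f, r))
  barcode_scheme(forward = fwd, reverse = rev, samples = samples)
}

# Default per-position quality profile: a high plateau with mild decay
# toward both read ends, mimicking the characteristic 5'/3' dips of
# sequencing-by-synthesis data.  Returns integer Q per position.
default_q_profile <- function(read_len, plateau = 38L, floor_q = 30L) {
  pos <- seq_len(read_len)
  q <- plateau - 5 * exp(-(pos - 1) / 2) - 7 * exp(-(read_len - pos) / 12)
  pmax(floor_q, pmin(.Q_MAX, round(q)))
}

#' Default sequencing adapter pair for the simulator
#'
#' Fixed synthetic P1/P2 adapter sequences and 6 bp buffer sequences used
#' to assemble library constructs.  These are arbitrary but fixed strings
#' standing in for platform adapters.
#'
#' @return list with `p1`, `p2`, `buffer1`, `buffer2`.
#' @export
sim_adapters <- function() {
  list(p1 = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
       p2 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
       buffer1 = "CTGACT", buffer2 = "GTCAGA")
}

#' Simulate a dual-indexed reduced-representation paired-end library
#'
#' Retained double-digest fragments are size-selected by acceptance
#' sampling against a Normal(frag_mean, frag_sd) length law and sampled
#' with replacement (the depth model of reduced-representation libraries:
#' many identical fragments per locus).  For each sampled fragment and
#' sample cell, the sequencing template is
#' `buffer1 + forward_barcode + fragment + rc(reverse_barcode) + rc(buffer2)`;
#' R1 is the first `read_len` bases of the template continued into the
#' read-through adapter `rc(p2)`, and R2 is the first `read_len` bases of
#' the reverse-complement template continued into `rc(p1)`.  Adapter
#' read-through occurs exactly when the template is shorter than the read,
#' and the 1-based position at which the adapter proper starts
#' (`template length + 1`) is recorded in the truth table (NA otherwise;
#' the position is identical in both mates' coordinate frames).
#'
#' Quality strings follow a per-position plateau-with-end-decay profile.
#' Output is deterministic for a fixed configuration and seed.
#'
#' @param fragments a `digest_result` (only retained fragments are used) or
#'   a character vector of fragment sequences.
#' @param scheme a [barcode_scheme()] from [sim_scheme()].
#' @param n_pairs number of read pairs to emit.
#' @param read_len read length (default 150).
#' @param frag_mean,frag_sd size-selection law (defaults 400 and 100).
#' @param adapters list from [sim_adapters()].
#' @param q_profile function(read_len) -> integer vector of per-position Q.
#' @param cells optional character vector of sample cells to draw from
#'   (default: all populated cells, cycled so every cell is covered before
#'   any repeats).
#' @param seed integer seed.
#' @return list of class `sim_library`: `r1`, `r2` ([fastq_df()]s) and
#'   `truth` (data.frame: id, sample, forward/reverse barcode, fragment
#'   row, frag_len, construct_len, adapter_start or NA).
#' @export
sim_library <- function(fragments, scheme, n_pairs, read_len = 150L,
                        frag_mean = 400, frag_sd = 100,
                        adapters = sim_adapters(),
                        q_profile = default_q_profile,
                        cells = NULL, seed = 1L) {
  set.seed(seed)
  frs <- if (is.data.frame(fragments)) fragments$seq[fragments$retained]
         else as.character(fragments)
  if (!length(frs)) stop("no retained fragments to sample from")
  flen <- nchar(frs)
  # size selection: weight fragments by the normal length law; keep the
  # usable range only (insert must extend past the barcode region)
  usable <- flen >= 10L
  w <- dnorm(flen, frag_mean, frag_sd) * usable
  if (sum(w) == 0) w <- as.numeric(usable)
  if (sum(w) == 0) stop("no usable fragments")
  pick <- sample(length(frs), n_pairs, replace = TRUE, prob = w)
  if (is.null(cells)) {
    cells <- sort(as.vector(scheme$samples[!is.na(scheme$samples)]))
  }
  # cover every cell before recycling
  cell_pick <- rep_len(sample(cells), n_pairs)
  cell_pos <- match(cell_pick, as.vector(scheme$samples))
  ri <- (cell_pos - 1L) %% nrow(scheme$samples) + 1L
  fi <- (cell_pos - 1L) %/% nrow(scheme$samples) + 1L
  bcf <- scheme$forward[fi]
  bcr <- scheme$reverse[ri]
  frag_seq <- frs[pick]
  template <- paste0(adapters$buffer1, bcf, frag_seq,
                     revcomp(bcr), revcomp(adapters$buffer2))
  tlen <- nchar(template)
  r1_full <- paste0(template, revcomp(adapters$p2))
  r2_full <- paste0(revcomp(template), revcomp(adapters$p1))
  r1_seq <- substr(r1_full, 1L, read_len)
  r2_seq <- substr(r2_full, 1L, read_len)
  # pad very short constructs (shorter than read even with adapter) with A
  pad <- function(s) {
    short <- nchar(s) < read_len
    s[short] <- paste0(s[short], strrep("A", read_len - nchar(s[short])))
    s
  }
  r1_seq <- pad(r1_seq); r2_seq <- pad(r2_seq)
  qv <- q_profile(read_len)
  qual <- int_to_qual(qv)
  ids <- sprintf("sim_%07d", seq_len(n_pairs))
  truth <- data.frame(
    id = ids, sample = cell_pick, forward = bcf, reverse = bcr,
    fragment = pick, frag_len = nchar(frag_seq),
    construct_len = tlen,
    adapter_start = ifelse(tlen < read_len, tlen + 1L, NA_integer_),
    stringsAsFactors = FALSE)
  structure(list(
    r1 = fastq_df(paste0(ids, "/1"), r1_seq, rep(qual, n_pairs)),
    r2 = fastq_df(paste0(ids, "/2"), r2_seq, rep(qual, n_pairs)),
    truth = truth, read_len = read_len, scheme = scheme,
    adapters = adapters), class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("simulated library: %d read pairs of length %d, %d sample cells\n",
              nrow(x$r1), x$read_len, length(unique(x$truth$sample))))
  cat(sprintf("  adapter read-through in %d pairs (%.2f%%)\n",
              sum(!is.na(x$truth$adapter_start)),
              100 * mean(!is.na(x$truth$adapter_start))))
  invisible(x)
}

#' Per-sample adapter search templates for a simulated library
#'
#' Builds the read-through adapter template seen by each mate, optionally
#' extended with the sample's barcode/buffer and the terminal restriction
#' motif context (the tiers that sharpen adapter detection).  In R1 the
#' read-through junk is `rc(reverse_barcode) + rc(buffer2) + rc(p2)`; in R2
#' it is `rc(forward_barcode) + rc(buffer1) + rc(p1)`.
#'
#' @param scheme a [barcode_scheme()].
#' @param sample sample cell name.
#' @param adapters list from [sim_adapters()].
#' @param tier one of "adapter", "barcode" (adapter through barcode) or
#'   "motif" (adapter through restriction site).
#' @return list with `r1` and `r2` template strings.
#' @export
sim_adapter_templates <- function(scheme, sample, adapters = sim_adapters(),
                                  tier = c("barcode", "adapter", "motif")) {
  tier <- match.arg(tier)
  pos <- which(scheme$samples == sample)
  if (length(pos) != 1L) stop("sample not found uniquely in scheme: ", sample)
  ri <- (pos - 1L) %% nrow(scheme$samples) + 1L
  fi <- (pos - 1L) %/% nrow(scheme$samples) + 1L
  bcf <- scheme$forward[fi]; bcr <- scheme$reverse[ri]
  a1 <- revcomp(adapters$p2)
  a2 <- revcomp(adapters$p1)
  if (tier %in% c("barcode", "motif")) {
    a1 <- paste0(revcomp(bcr), revcomp(adapters$buffer2), a1)
    a2 <- paste0(revcomp(bcf), revcomp(adapters$buffer1), a2)
  }
  if (tier == "motif") {
    a1 <- paste0("CATG", a1)   # fragment ends with the NlaIII site in R1
    a2 <- paste0("ATGCA", a2)  # rc(fragment) ends with rc(TGCAT) in R2
  }
  list(r1 = a1, r2 = a2)
}

#' Mutate simulated reads with per-base substitutions
#'
#' Independent substitution at the given rate(s), uniform over the three
#' alternative bases; the rate may be a single number or a per-position
#' vector (recycled/truncated to each read length), so elevated error at
#' read ends or in the motif region can be engineered.  Quality scores are
#' optionally degraded at mutated positions.  The ground truth is
#' unchanged; the caller keeps the unmutated reads.
#'
#' @param x a [fastq_df()].
#' @param rate substitution probability, scalar or per-position vector.
#' @param degrade_q if non-NULL, mutated positions get this Q score.
#' @param seed integer seed.
#' @return mutated [fastq_df()].
#' @export
sim_mutate <- function(x, rate, degrade_q = NULL, seed = 1L) {
  stopifnot(all(rate >= 0), all(rate <= 1))
  set.seed(seed)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  for (i in seq_len(nrow(x))) {
    s <- strsplit(x$seq[i], "", fixed = TRUE)[[1]]
    L <- length(s)
    if (L == 0L) next
    r <- if (length(rate) == 1L) rep(rate, L) else rep_len(rate, L)
    mut <- which(runif(L) < r)
    if (length(mut)) {
      s[mut] <- vapply(s[mut], function(b) sample(alt[[b]], 1L), "")
      x$seq[i] <- paste(s, collapse = "")
      if (!is.null(degrade_q)) {
        q <- utf8ToInt(x$qual[i]) - .Q_OFFSET
        q[mut] <- degrade_q
        x$qual[i] <- int_to_qual(q)
      }
    }
  }
  x
}

#' Write a simulated library to disk
#'
#' R1/R2 FASTQ plus the truth table as TSV.
#'
#' @param lib a `sim_library`.
#' @param prefix output path prefix; writes `<prefix>.R1.fastq`,
#'   `<prefix>.R2.fastq`, `<prefix>.truth.tsv`.
#' @param gzip write gzip-compressed FASTQ.
#' @return invisibly, the three paths.
#' @export
write_sim_library <- function(lib, prefix, gzip = FALSE) {
  sfx <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, ".R1", sfx)
  p2 <- paste0(prefix, ".R2", sfx)
  pt <- paste0(prefix, ".truth.tsv")
  write_fastq(lib$r1, p1)
  write_fastq(lib$r2, p2)
  utils::write.table(lib$truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, pt))
}
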