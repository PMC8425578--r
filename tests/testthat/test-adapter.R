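test_that("the k-mer index enumerates every offset of every adapter", {
  idx <- adapter_index(c(a = "ACGTACGT"), k = 4L)
  entries <- do.call(rbind, idx$entries)
  expect_equal(nrow(entries), 5L)                 # len - k + 1
  expect_equal(sort(entries$offset), 0:4)
  # repeated k-mer within one adapter keeps both offsets under one key
  expect_equal(idx$entries[["ACGT"]]$offset, c(0L, 4L))
  # a k-mer shared by two adapters lists both
  idx2 <- adapter_index(c(x = "AAAACGTA", y = "CCAACGTA"), k = 4L)
  expect_equal(sort(idx2$entries[["ACGT"]]$adapter), c("x", "y"))
  # total entries = sum(len - k + 1)
  expect_equal(sum(vapply(idx2$entries, nrow, 0L)), 2L * 5L)
  expect_error(adapter_index(c(tiny = "ACG"), k = 4L), "tiny")
})

test_that("voting finds exact embedded adapters and ignores adapter-free reads", {
  set.seed(91)
  genomic <- rand_reads(1, len = 40)$seq
  adapter <- "ACACTCTTTCCCTACACGACGCTCTTCCGA"   # 30 bp
  read <- paste0(genomic, adapter)
  idx <- adapter_index(c(ad = adapter), k = 8L)
  hit <- scan_adapters(read, idx, votes = 2L, rounds = 3L, min_overlap = 12L)
  expect_equal(hit$start, 41L)
  expect_gte(hit$votes, 2L)
  # adapter-free random read: no hit
  clean <- rand_reads(20, len = 70)$seq
  expect_true(all(is.na(scan_adapters(clean, idx)$start)))
})

test_that("mutated embedded adapters match the sliding-window Hamming oracle", {
  set.seed(92)
  adapter <- "CATGGTCAGAAGATCGGAAGAGCACACGTCTGAACT"
  idx <- adapter_index(c(ad = adapter), k = 8L)
  n <- 800L
  reads <- character(n); truth <- integer(n); nmut <- integer(n)
  for (i in seq_len(n)) {
    gl <- sample(20:140, 1)
    g <- rand_reads(1, len = gl)$seq
    r <- substr(paste0(g, adapter, strrep("A", 150)), 1, 150)
    k <- sample(0:2, 1)
    if (k > 0) {  # mutate only the embedded adapter portion that is in-read
      avail <- min(150 - gl, nchar(adapter))
      ch <- strsplit(r, "")[[1]]
      pos <- gl + sample(avail, min(k, avail))
      ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
      r <- paste(ch, collapse = "")
    }
    reads[i] <- r; truth[i] <- gl + 1L; nmut[i] <- k
  }
  got <- scan_adapters(reads, idx, votes = 2L, rounds = 3L, min_overlap = 12L)
  want <- vapply(reads, oracle_adapter_slide, 0L, template = adapter,
                 max_mm = 2L, min_overlap = 12L, USE.NAMES = FALSE)
  # where the voter calls a hit it must agree with the oracle; misses are
  # only allowed where vote support is below the threshold, which the
  # oracle enumerates as mutation-split k-mer coverage
  called <- !is.na(got$start)
  expect_true(all(got$start[called] == want[called]))
  # every clean (unmutated) read with enough in-read adapter for two
  # non-overlapping 8-mers of one offset family must be found
  avail <- 150L - truth + 1L
  expect_true(all(called[nmut == 0L & avail >= 16L]))
})

test_that("raising the vote threshold never increases the number of hits", {
  set.seed(93)
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
  idx <- adapter_index(c(ad = adapter), k = 8L)
  reads <- vapply(1:200, function(i) {
    g <- rand_reads(1, len = sample(100:140, 1))$seq
    substr(paste0(g, adapter, strrep("A", 150)), 1, 150)
  }, "")
  hits <- vapply(1:4, function(m) {
    sum(!is.na(scan_adapters(reads, idx, votes = m)$start))
  }, 0L)
  expect_true(all(diff(hits) <= 0L))
})

test_that("ties resolve to the 5'-most start and upstream starts clamp to 1", {
  # read that is pure adapter from position 1: start must be 1
  adapter <- "ACGTTGCAAGGCCTTAACGGATCCAAGG"
  idx <- adapter_index(c(ad = adapter), k = 8L)
  read <- substr(paste0(substring(adapter, 5), strrep("T", 40)), 1, 40)
  hit <- scan_adapters(read, idx, votes = 2L, min_overlap = 12L)
  expect_equal(hit$start, 1L)
})

test_that("local alignment fallback matches Smith-Waterman scoring", {
  skip_if_not_installed("Biostrings")
  set.seed(94)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:20) {
    read <- rand_reads(1, len = sample(30:60, 1))$seq
    adapter <- rand_reads(1, len = sample(15:30, 1))$seq
    ours <- align_adapter(read, adapter, t = 5L)
    ref <- Biostrings::pairwiseAlignment(read, adapter, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(ours$score, Biostrings::score(ref))
  }
})

test_that("fallback hit semantics follow the t-base overlap rule", {
  adapter <- "ACGTTGCAAGGCCTTA"
  # exact adapter suffix of length t at the read 3' end
  read <- paste0(strrep("C", 30), substr(adapter, 1, 12))
  al <- align_adapter(read, adapter, t = 12L)
  expect_true(al$hit)
  expect_equal(al$start, 31L)
  # no shared block of length t
  al2 <- align_adapter(strrep("C", 40), adapter, t = 12L)
  expect_false(al2$hit)
})

test_that("file-level trimming cuts exactly at truth with zero false positives", {
  g <- sim_genome(250000, seed = 95)
  sch <- test_scheme(4, 4)
  lib <- sim_library(sim_digest(g), sch, n_pairs = 400, frag_mean = 110,
                     frag_sd = 50, seed = 13)
  tr <- lib$truth
  # standalone mode: full adapter list over all samples (barcode tier)
  tpls <- unique(vapply(unique(tr$sample), function(s)
    sim_adapter_templates(sch, s, tier = "barcode")$r1, ""))
  d <- tempfile(); dir.create(d)
  res <- trim_adapters(tmp_fastq(lib$r1), r1_adapters = tpls, min_len = 20L,
                       outdir = d)
  hit <- res$hits$r1
  # expected template start: after buffer + forward barcode + fragment
  junk_start <- 6L + nchar(tr$forward) + tr$frag_len + 1L
  # k-mer voting needs 2k template bases in the read for a family of two
  detectable <- (150L - junk_start + 1L) >= 16L & junk_start <= 150L
  called <- !is.na(hit$start)
  expect_true(all(hit$start[called] == junk_start[called]))  # no false trims
  expect_true(all(called[detectable]))                       # full sensitivity
  # fragments longer than the read: no read-through, nothing trimmed
  long_lib <- sim_library(sim_digest(g), sch, n_pairs = 100, frag_mean = 500,
                          frag_sd = 50, seed = 14)
  res2 <- trim_adapters(tmp_fastq(long_lib$r1), r1_adapters = tpls,
                        outdir = tempfile())
  long_frag <- is.na(long_lib$truth$adapter_start) &
    (150L - (6L + nchar(long_lib$truth$forward) + long_lib$truth$frag_len)) < 12L
  expect_true(all(is.na(res2$hits$r1$start[long_frag])))
  # conservation of reads across keep/discard outputs
  kept <- read_fastq(res$files$r1[["keep"]])
  disc <- read_fastq(res$files$r1[["discard"]])
  expect_equal(nrow(kept) + nrow(disc), nrow(lib$r1))
})

test_that("detection is non-decreasing in template specificity (tier comparison)", {
  g <- sim_genome(250000, seed = 96)
  sch <- test_scheme(4, 4)
  lib <- sim_library(sim_digest(g), sch, n_pairs = 300, frag_mean = 120,
                     frag_sd = 50, seed = 15)
  # mutate reads a little so the adapter-only tier starts missing hits
  mut <- sim_mutate(lib$r1, rate = 0.02, seed = 16)
  count_hits <- function(tier) {
    total <- 0L
    for (s in unique(lib$truth$sample)) {
      i <- which(lib$truth$sample == s)
      tpl <- sim_adapter_templates(sch, s, tier = tier)$r1
      idx <- adapter_index(c(t = tpl), k = 8L)
      total <- total + sum(!is.na(scan_adapters(mut$seq[i], idx)$start))
    }
    total
  }
  h_adapter <- count_hits("adapter")
  h_barcode <- count_hits("barcode")
  h_motif <- count_hits("motif")
  expect_lte(h_adapter, h_barcode)
  expect_lte(h_barcode, h_motif)
})
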