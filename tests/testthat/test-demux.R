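test_that("exact matching assigns unique barcodes and refuses ambiguity", {
  bcs <- c("ACGTACGT", "TTTTCCCC")
  m <- match_barcode("ACGTACGTTTGC", bcs, m = 0L)
  expect_equal(m$barcode, 1L)
  expect_equal(m$mismatch, 0)
  # distance 1 from two distinct barcodes at m = 1: kept unknown
  bcs2 <- c("AAAA", "AAAT")
  m2 <- match_barcode("AAAG", bcs2, m = 1L)
  expect_true(is.na(m2$barcode))
  expect_true(m2$ambiguous)
  # read shorter than every barcode
  m3 <- match_barcode("AC", bcs, m = 2L)
  expect_true(is.na(m3$barcode))
})

test_that("prefix-nested barcodes matching exactly are kept unknown", {
  bcs <- c("ACGTACG", "ACGTACGTAC")
  m <- match_barcode("ACGTACGTACGGGG", bcs, m = 0L)
  expect_true(is.na(m$barcode))
  expect_true(m$ambiguous)
})

test_that("assignment equals the exhaustive Hamming oracle and ignores barcode order", {
  set.seed(51)
  barcodes <- sim_barcodes(24, seed = 7)
  reads <- rand_reads(300, len = 40)$seq
  # seed some reads with mutated barcodes to exercise the m > 0 passes
  for (i in 1:150) {
    b <- sample(barcodes, 1)
    nmut <- sample(0:2, 1)
    ch <- strsplit(b, "")[[1]]
    if (nmut > 0) {
      pos <- sample(length(ch), nmut)
      ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
    }
    reads[i] <- paste0(paste(ch, collapse = ""), substr(reads[i], 1, 25))
  }
  for (m in 0:2) {
    got <- match_barcode(reads, barcodes, m)$barcode
    want <- vapply(reads, oracle_barcode_match, 0L, barcodes = barcodes, m = m,
                   USE.NAMES = FALSE)
    expect_equal(got, want, info = paste("m =", m))
    shuf <- sample(length(barcodes))
    got_shuf <- match_barcode(reads, barcodes[shuf], m)$barcode
    expect_equal(barcodes[shuf][got_shuf], barcodes[got], info = "order independence")
  }
})

test_that("assignment is monotone in the mismatch allowance", {
  set.seed(52)
  barcodes <- sim_barcodes(16, seed = 9)
  reads <- rand_reads(400, len = 30)$seq
  prev <- rep(FALSE, length(reads))
  for (m in 0:2) {
    res <- match_barcode(reads, barcodes, m)
    now <- !is.na(res$barcode)
    # reads assigned at m stay assigned at m+1 unless newly ambiguous
    lost <- prev & !now
    expect_true(all(res$ambiguous[lost]))
    prev <- now
  }
})

test_that("dual demultiplexing recovers simulated truth and conserves reads", {
  g <- sim_genome(150000, seed = 61)
  sch <- test_scheme(6, 6)
  lib <- sim_library(sim_digest(g), sch, n_pairs = 300, seed = 8)
  t1 <- trim_fixed(lib$r1, front = 6L)
  t2 <- trim_fixed(lib$r2, front = 6L)
  dm <- demultiplex(t1, t2, sch, max_m = 0L)
  expect_equal(dm$sample, lib$truth$sample)
  expect_equal(sum(is.na(dm$sample)), 0L)
  # matched barcodes are trimmed; unknown reads would stay untrimmed
  expect_equal(nchar(dm$r1$seq),
               nchar(t1$seq) - nchar(lib$truth$forward))
  # conservation: category counts add up to input reads
  cnt <- dm$counts
  expect_equal(2L * sum(cnt$reads[cnt$category == "paired"]) +
                 sum(cnt$reads[cnt$category %in% c("se.R1", "se.R2")]) +
                 sum(cnt$reads[cnt$category %in% c("unknown.R1", "unknown.R2")]),
               dm$n_in)
})

test_that("one injected barcode error is recovered at m=1 and unknown at m=0", {
  sch <- test_scheme(8, 8)
  n <- 60L
  set.seed(53)
  body1 <- rand_reads(n, len = 40)$seq
  body2 <- rand_reads(n, len = 40)$seq
  f <- sample(sch$forward, n, replace = TRUE)
  r <- sample(sch$reverse, n, replace = TRUE)
  mut1 <- function(b) {   # exactly one substitution in the barcode
    ch <- strsplit(b, "")[[1]]
    i <- sample(length(ch), 1)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  fm <- vapply(f, mut1, "")
  r1 <- fastq_df(paste0("e", 1:n), paste0(fm, body1), strrep("I", nchar(f) + 40L))
  r2 <- fastq_df(paste0("e", 1:n), paste0(r, body2), strrep("I", nchar(r) + 40L))
  dm0 <- demultiplex(r1, r2, sch, max_m = 0L)
  expect_true(all(is.na(dm0$sample)))
  dm1 <- demultiplex(r1, r2, sch, max_m = 1L)
  expect_equal(dm1$assignments$forward, unname(f))
  expect_equal(dm1$assignments$mismatch_forward, rep(1, n))
  expect_false(any(is.na(dm1$sample)))
})

test_that("demultiplexing past the identifiability bound is refused without override", {
  sch <- test_scheme(6, 6)
  expect_gte(sch$min_dist_forward, 3)
  r1 <- fastq_df("a", strrep("A", 30), strrep("I", 30))
  r2 <- fastq_df("a", strrep("C", 30), strrep("I", 30))
  expect_error(demultiplex(r1, r2, sch, max_m = 2L), "Levenshtein")
  expect_silent(demultiplex(r1, r2, sch, max_m = 2L, override_distance = TRUE))
})

test_that("barcode scheme TSV round-trips for dual and single-index layouts", {
  sch <- test_scheme(5, 4)
  p <- tempfile(fileext = ".tsv")
  write_barcode_scheme(sch, p)
  back <- read_barcode_scheme(p)
  expect_equal(back$forward, sch$forward)
  expect_equal(back$reverse, sch$reverse)
  expect_equal(back$samples, sch$samples)
  s1 <- barcode_scheme(forward = c("ACGTAAA", "TGCATGC"),
                       samples = c("s1", "s2"))
  write_barcode_scheme(s1, p)
  back1 <- read_barcode_scheme(p)
  expect_false(back1$dual)
  expect_equal(back1$samples, c("s1", "s2"))
})

test_that("per-sample files are written with the documented naming scheme", {
  g <- sim_genome(100000, seed = 62)
  sch <- test_scheme(3, 3)
  lib <- sim_library(sim_digest(g), sch, n_pairs = 30, seed = 9)
  dm <- demultiplex(trim_fixed(lib$r1, front = 6L),
                    trim_fixed(lib$r2, front = 6L), sch)
  d <- tempfile(); dir.create(d)
  write_demux(dm, d)
  used <- unique(lib$truth$sample)
  expect_true(all(file.exists(file.path(d, paste0(used, ".R1.fastq")))))
  expect_true(all(file.exists(file.path(d, paste0(used, ".R2.fastq")))))
  expect_true(file.exists(file.path(d, "unknown.R1.fastq")))
  # reads land in their own sample file
  s <- used[1]
  back <- read_fastq(file.path(d, paste0(s, ".R1.fastq")))
  expect_equal(sort(back$id), sort(lib$r1$id[lib$truth$sample == s]))
})
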