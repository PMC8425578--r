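test_that("collapsing recovers the exact multiset of unique reads", {
  x <- rep("ACGTACGT", 100)
  expect_equal(collapse_reads(x), c(ACGTACGT = 100L))
  set.seed(101)
  distinct <- unique(rand_reads(120, len = 20)$seq)[1:100]
  cc <- collapse_reads(distinct)
  expect_equal(length(cc), 100L)
  expect_true(all(cc == 1L))
  # shuffled concatenation of a known multiset: sort-and-count oracle
  freq <- c(5L, 3L, 9L, 1L, 7L)
  pool <- sample(rep(distinct[1:5], freq))
  cc2 <- collapse_reads(pool)
  oracle <- table(sort(pool))
  expect_equal(cc2[order(names(cc2))],
               stats::setNames(as.integer(oracle), names(oracle)))
  expect_equal(sum(cc2), length(pool))
})

test_that("unequal read lengths are refused unless overridden", {
  x <- c("ACGT", "ACGTA")
  expect_error(collapse_reads(x), "length")
  expect_warning(cc <- collapse_reads(x, allow_mixed_lengths = TRUE), "bias")
  expect_equal(length(cc), 2L)
})

test_that("compression rate follows its defining arithmetic", {
  expect_equal(compression_rate(stats::setNames(rep(1L, 50),
                                                paste0("u", 1:50)))$compression_rate, 0)
  counts <- stats::setNames(rep(10L, 100), paste0("u", 1:100))  # 1000 reads, 100 unique
  r <- compression_rate(counts)
  expect_equal(r$compression_rate, 90)
  expect_equal(r$total_reads, 1000L)
  expect_equal(r$unique_ratio, 0.1)
  expect_error(compression_rate(integer(0)), "empty")
})

test_that("injected error strictly lowers compression of a duplicated pool", {
  set.seed(102)
  uniq <- rand_reads(150, len = 80)$seq
  pool <- fastq_df(paste0("d", 1:3000), rep(uniq, each = 20),
                   strrep("I", 80))
  rates <- vapply(c(0, 0.005, 0.02), function(e) {
    mutated <- if (e == 0) pool else sim_mutate(pool, rate = e, seed = 103)
    compression_rate(collapse_reads(mutated$seq))$compression_rate
  }, 0)
  expect_true(all(diff(rates) < 0))
})

test_that("delta compression is positive for error-removing filters and negative for their complement", {
  set.seed(104)
  true_reads <- rand_reads(80, len = 60)$seq
  dup_pool <- rep(true_reads, each = 25)            # 2000 duplicated true reads
  err <- sim_mutate(fastq_df(paste0("e", 1:400), sample(true_reads, 400, replace = TRUE),
                             strrep("I", 60)), rate = 0.05, seed = 105)$seq
  raw <- c(dup_pool, err)
  d_pass <- delta_compression(dup_pool, raw, seed = 1, replicates = 10)
  expect_gt(d_pass$delta, 0)
  d_fail <- delta_compression(err, raw, seed = 1, replicates = 10)
  expect_lt(d_fail$delta, 0)
  # null case: a random subsample scores ~0 within subsampling noise
  set.seed(106)
  d_null <- delta_compression(sample(raw, 1500), raw, seed = 2, replicates = 20)
  expect_lt(abs(d_null$delta), 4 * d_null$subsample_sd +
              .Machine$double.eps^0.25)
  expect_error(delta_compression(raw, dup_pool), "larger")
})

test_that("compression of merged disjoint files uses the merged multiset", {
  set.seed(107)
  a <- rep(rand_reads(30, len = 40)$seq, each = 4)
  b <- rep(rand_reads(20, len = 40, prefix = "z")$seq, each = 6)
  ca <- collapse_reads(a); cb <- collapse_reads(b)
  cab <- collapse_reads(c(a, b))
  expect_equal(sum(cab), sum(ca) + sum(cb))
  expect_equal(length(cab), length(unique(c(names(ca), names(cb)))))
})

test_that("the Phred equivalence follows Q = -10 log10(p)", {
  expect_equal(phred_equivalent(0.001), 30)
  expect_equal(phred_equivalent(0.01), 20)
  expect_equal(phred_equivalent(1), 0)
  expect_equal(phred_equivalent(0), Inf)
})

test_that("error-free barcodes profile to zero error at every level", {
  sch <- test_scheme(8, 8)
  set.seed(108)
  n <- 300L
  bc <- sample(sch$forward, n, replace = TRUE)
  r1 <- fastq_df(paste0("r", 1:n), paste0(bc, "TGCAT", rand_reads(n, len = 30)$seq),
                 strrep("I", nchar(bc) + 35L))
  pr <- barcode_error_profile(r1, sch, max_m = 1L)
  expect_equal(sum(pr$levels$m0$errors), 0L)
  expect_equal(sum(pr$levels$m1$errors), 0L)
  expect_true(all(pr$levels$m1$phred_equivalent == Inf, na.rm = TRUE))
  # m0 level equals an exact-match-only profile by construction
  expect_equal(pr$levels$m0$n_reads, n)
})

test_that("mutated barcode regions are recovered at the simulated error rate", {
  sch <- test_scheme(12, 12)
  set.seed(109)
  n <- 6000L
  eps <- 0.01
  bc <- sample(sch$forward, n, replace = TRUE)
  reads <- fastq_df(paste0("r", 1:n), paste0(bc, "TGCAT", rand_reads(n, len = 25)$seq),
                    strrep("I", nchar(bc) + 30L))
  L <- max(nchar(sch$forward))
  mut <- sim_mutate(reads, rate = c(rep(eps, L), rep(0, 100)), seed = 110)
  pr <- barcode_error_profile(mut, sch, max_m = 3L, override_distance = TRUE)
  lv <- pr$levels$m3
  for (j in seq_len(pr$barcode_length)) {
    sd_j <- sqrt(eps * (1 - eps) / lv$n_assessed[j])
    expect_lt(abs(lv$error_rate[j] - eps), 3 * sd_j + 1e-12)
  }
  # the reported-Q tally counts every assessed base
  expect_equal(unname(colSums(lv$qscore_counts)), lv$n_assessed)
})
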