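test_that("synthetic genomes are deterministic and respect base composition", {
  g1 <- sim_genome(20000, seed = 7)
  g2 <- sim_genome(20000, seed = 7)
  expect_identical(g1, g2)
  expect_false(identical(g1, sim_genome(20000, seed = 8)))
  # gc = 1: no A/T, so the NsiI site (contains A and T) cannot occur
  gall <- sim_genome(50000, gc = 1, seed = 9)
  expect_equal(gregexpr("ATGCAT", gall, fixed = TRUE)[[1]][1], -1L)
  expect_equal(sum(sim_digest(gall)$retained), 0L)
  # site count approximates the i.i.d. expectation within 3 SD
  g <- sim_genome(500000, gc = 0.5, seed = 10)
  hits <- gregexpr("ATGCAT", g, fixed = TRUE)[[1]]
  n_obs <- if (hits[1] == -1) 0L else length(hits)
  p <- (1 / 4)^6
  expected <- (500000 - 5) * p
  expect_lt(abs(n_obs - expected), 3 * sqrt(expected))
})

test_that("digest cuts at hand-computed positions and classifies fragments", {
  genome <- paste0(strrep("A", 10), "ATGCAT", "AA", strrep("G", 6), "CATG",
                   strrep("A", 10))
  frags <- sim_digest(genome)
  # NsiI site at 11..16: downstream fragment starts at 12 ("TGCAT...");
  # NlaIII site at 25..28: upstream fragment ends at 28 ("...CATG")
  ret <- frags[frags$retained, ]
  expect_equal(nrow(ret), 1L)
  expect_equal(ret$start, 12L)
  expect_equal(ret$end, 28L)
  expect_equal(ret$seq, paste0("TGCAT", "AA", strrep("G", 6), "CATG"))
  expect_true(startsWith(ret$seq, "TGCAT"))
  expect_true(endsWith(ret$seq, "CATG"))
  # genome without sites yields no retained fragments
  expect_equal(sum(sim_digest(strrep("AC", 200))$retained), 0L)
})

test_that("digest boundaries equal a brute-force regex scan with cut offsets", {
  g <- sim_genome(120000, seed = 11)
  frags <- sim_digest(g)
  # oracle: overlap-aware regex scan for both sites (ATGCAT can overlap
  # itself), cuts applied per enzyme convention
  nsi <- gregexpr("(?=ATGCAT)", g, perl = TRUE)[[1]]
  nla <- gregexpr("(?=CATG)", g, perl = TRUE)[[1]]
  cuts <- rbind(
    data.frame(pos = as.integer(nsi), down = as.integer(nsi) + 1L,
               up = as.integer(nsi) + 4L, enz = "NsiI"),
    data.frame(pos = as.integer(nla), down = as.integer(nla),
               up = as.integer(nla) + 3L, enz = "NlaIII"))
  cuts <- cuts[order(cuts$pos), ]
  want <- data.frame(start = cuts$down[-nrow(cuts)], end = cuts$up[-1],
                     left = cuts$enz[-nrow(cuts)], right = cuts$enz[-1])
  interior <- frags[frags$left_enz != "end" & frags$right_enz != "end", ]
  expect_equal(interior$start, want$start)
  expect_equal(interior$end, want$end)
  expect_equal(interior$left_enz, want$left)
  expect_equal(interior$right_enz, want$right)
  # retained class: exactly the NsiI/NlaIII-flanked fragments
  expect_equal(interior$retained,
               (want$left == "NsiI" & want$right == "NlaIII") |
                 (want$left == "NlaIII" & want$right == "NsiI"))
  # reverse-oriented retained fragments were flipped into TGCAT...CATG form
  ret <- frags[frags$retained, ]
  expect_true(all(startsWith(ret$seq, "TGCAT")))
  expect_true(all(endsWith(ret$seq, "CATG")))
})

test_that("library construction follows the construct layout arithmetic", {
  g <- sim_genome(150000, seed = 12)
  sch <- test_scheme(4, 4)
  lib <- sim_library(sim_digest(g), sch, n_pairs = 200, frag_mean = 120,
                     frag_sd = 60, seed = 13)
  tr <- lib$truth
  ad <- sim_adapters()
  # R1 begins buffer + forward barcode + TGCAT; R2 begins buffer2 + reverse
  # barcode + CATG
  expect_true(all(startsWith(lib$r1$seq, paste0(ad$buffer1, tr$forward, "TGCAT"))))
  expect_true(all(startsWith(lib$r2$seq, paste0(ad$buffer2, tr$reverse, "CATG"))))
  # construct length bookkeeping and the read-through condition
  expect_equal(tr$construct_len,
               6L + nchar(tr$forward) + tr$frag_len + nchar(tr$reverse) + 6L)
  expect_equal(!is.na(tr$adapter_start), tr$construct_len < 150L)
  i <- which(!is.na(tr$adapter_start))[1]
  expect_equal(tr$adapter_start[i], tr$construct_len[i] + 1L)
  # the adapter proper appears at the truth index in both mates
  expect_equal(substr(lib$r1$seq[i], tr$adapter_start[i],
                      min(150L, tr$adapter_start[i] + 9L)),
               substr(revcomp(ad$p2), 1, min(10L, 150L - tr$adapter_start[i] + 1L)))
  expect_equal(substr(lib$r2$seq[i], tr$adapter_start[i],
                      min(150L, tr$adapter_start[i] + 9L)),
               substr(revcomp(ad$p1), 1, min(10L, 150L - tr$adapter_start[i] + 1L)))
  # every emitted read appears in the truth table and vice versa
  expect_equal(sub("/1$", "", lib$r1$id), tr$id)
  expect_equal(nrow(tr), nrow(lib$r1))
})

test_that("simulation output is byte-identical for a fixed configuration and seed", {
  g <- sim_genome(80000, seed = 14)
  sch <- test_scheme(3, 3)
  a <- sim_library(sim_digest(g), sch, n_pairs = 100, seed = 15)
  b <- sim_library(sim_digest(g), sch, n_pairs = 100, seed = 15)
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  expect_identical(a$truth, b$truth)
  pa <- tempfile(); pb <- tempfile()
  write_sim_library(a, pa); write_sim_library(b, pb)
  expect_identical(readLines(paste0(pa, ".R1.fastq")),
                   readLines(paste0(pb, ".R1.fastq")))
})

test_that("mutation respects the scheduled substitution rate", {
  set.seed(16)
  reads <- rand_reads(200, len = 100)
  expect_identical(sim_mutate(reads, rate = 0, seed = 1), reads)
  all_mut <- sim_mutate(reads, rate = 1, seed = 2)
  same <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }, reads$seq, all_mut$seq)
  expect_true(all(same == 0))
  rate <- 0.03
  mut <- sim_mutate(reads, rate = rate, seed = 3)
  nm <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$seq, mut$seq))
  total <- sum(nchar(reads$seq))
  expect_lt(abs(nm - total * rate), 3 * sqrt(total * rate * (1 - rate)))
  # per-position schedule: only scheduled positions mutate
  sched <- c(rep(0.5, 10), rep(0, 90))
  mut2 <- sim_mutate(reads, rate = sched, seed = 4)
  expect_equal(substring(mut2$seq, 11), substring(reads$seq, 11))
  expect_false(all(substring(mut2$seq, 1, 10) == substring(reads$seq, 1, 10)))
})

test_that("zero-mutation reads always carry intact motifs after buffer and barcode removal", {
  g <- sim_genome(100000, seed = 17)
  sch <- test_scheme(5, 5)
  lib <- sim_library(sim_digest(g), sch, n_pairs = 150, seed = 18)
  r1 <- trim_fixed(lib$r1, front = 6L)
  dm <- demultiplex(r1, trim_fixed(lib$r2, front = 6L), sch)
  expect_true(all(has_motif(dm$r1$seq, "TGCAT")))
  expect_true(all(has_motif(dm$r2$seq, "CATG")))
})
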