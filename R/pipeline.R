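#' Pipeline configuration
#'
#' Declarative configuration for the full preprocessing pipeline.  Enabled
#' stages always run in the canonical order: front trim (buffer removal),
#' demultiplexing, motif filtering, quality end-trimming, Q-threshold
#' filtering, adapter trimming.  The relative order of end-trimming and
#' threshold filtering can be swapped via `qtrim_before_qfilter`.  Every
#' stage's parameters are validated before any data is touched.
#'
#' @param r1,r2 input FASTQ paths (R2 optional for single-end runs).
#' @param scheme a [barcode_scheme()] or path to a barcode TSV.
#' @param front buffer bases to trim from the 5' end before demultiplexing
#'   (0 disables the stage).
#' @param max_m maximum demultiplexing mismatch.
#' @param r1_motifs,r2_motifs motif lists (NULL disables motif filtering).
#' @param window,end_q quality end-trim parameters (NULL window disables).
#' @param q,p threshold-filter parameters (NULL q disables).
#' @param adapters per-sample adapter templates: a named list
#'   `sample -> list(r1 =, r2 =)` (pipeline mode, sample-restricted
#'   search), a list `list(r1 =, r2 =)` of template vectors shared by all
#'   samples, or NULL to disable adapter trimming.
#' @param adapter_k,adapter_votes,adapter_rounds,adapter_min_overlap,adapter_min_len
#'   see [scan_adapters()] and [trim_adapters()].
#' @param qtrim_before_qfilter run quality end-trimming before the
#'   threshold filter (default TRUE).
#' @param outdir output root (NULL keeps everything in memory).
#' @param write_intermediate write per-stage FASTQ directories under
#'   `outdir` (default FALSE: only final outputs are written).
#' @param qc emit positional QC matrices after each stage.
#' @param seed config-level seed for any randomized bookkeeping.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(r1, r2 = NULL, scheme = NULL, front = 6L,
                            max_m = 0L, r1_motifs = NULL, r2_motifs = NULL,
                            window = NULL, end_q = NULL, q = NULL, p = NULL,
                            adapters = NULL, adapter_k = 8L,
                            adapter_votes = 2L, adapter_rounds = 3L,
                            adapter_min_overlap = 12L, adapter_min_len = 50L,
                            qtrim_before_qfilter = TRUE, outdir = NULL,
                            write_intermediate = FALSE, qc = FALSE,
                            seed = 1L) {
  if (is.character(scheme)) scheme <- read_barcode_scheme(scheme)
  stopifnot(front >= 0L, max_m >= 0L)
  if (!is.null(window)) {
    stopifnot(window >= 1L, !is.null(end_q), end_q >= 0L, end_q <= .Q_MAX)
  }
  if (!is.null(q)) stopifnot(q >= 0L, q <= .Q_MAX, !is.null(p), p >= 0, p <= 100)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of `key = value`; lists are comma-separated; `#` starts a comment.
#' Recognized keys mirror the arguments of [pipeline_config()] (motifs as
#' comma-separated strings, `scheme` as a TSV path).
#'
#' @param path configuration file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  args <- list()
  num_keys <- c("front", "max_m", "window", "end_q", "q", "p", "adapter_k",
                "adapter_votes", "adapter_rounds", "adapter_min_overlap",
                "adapter_min_len", "seed")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- if (k %in% num_keys) as.numeric(v)
      else if (k %in% c("r1_motifs", "r2_motifs")) strsplit(v, ",")[[1]]
      else if (k %in% c("qtrim_before_qfilter", "write_intermediate", "qc"))
        as.logical(v)
      else v
  }
  do.call(pipeline_config, args)
}

# Apply per-read trims/filters to a set of per-sample read tables.
# `pools` is a list with elements r1, r2, sample (per-pair), se_r1,
# se_r1_sample, se_r2, se_r2_sample.
stage_counts <- function(pools) {
  2L * nrow(pools$r1) + nrow(pools$se_r1) + nrow(pools$se_r2)
}

#' Run the full preprocessing pipeline
#'
#' Executes the enabled stages in canonical order while tracking paired and
#' single-end read populations separately: a read whose mate is removed at
#' any stage migrates to the single-end pool and is retained in all
#' subsequent stages.  A conservation ledger is kept per stage (reads in ==
#' reads out across outputs, single ends and discards).
#'
#' @param cfg a [pipeline_config()] (or a path to a config file).
#' @param walkthrough_answers optional named list or answers file for
#'   [walkthrough_prompt()]-style per-stage parameter confirmation.
#' @return object of class `pipeline_result`: final read pools, per-sample
#'   assignment, a stage-by-stage `manifest` data.frame (stage, reads in,
#'   paired out, single-end out, discarded) and any QC summaries.
#' @export
run_pipeline <- function(cfg, walkthrough_answers = NULL) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  answers <- load_answers(walkthrough_answers)
  r1 <- if (is.character(cfg$r1)) read_fastq(cfg$r1) else cfg$r1
  r2 <- if (!is.null(cfg$r2) && is.character(cfg$r2)) read_fastq(cfg$r2) else cfg$r2
  if (!is.null(r2) && nrow(r1) != nrow(r2)) {
    stop("unpaired inputs: ", nrow(r1), " vs ", nrow(r2))
  }
  pools <- list(r1 = r1, r2 = if (is.null(r2)) fq_empty() else r2,
                sample = rep(NA_character_, nrow(r1)),
                se_r1 = fq_empty(), se_r1_sample = character(0),
                se_r2 = fq_empty(), se_r2_sample = character(0))
  paired <- !is.null(r2)
  manifest <- list()
  qc_list <- list()
  note <- function(stage, n_in, pools, n_discard, extra = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, reads_in = n_in,
      paired_out = 2L * nrow(pools$r1),
      se_out = nrow(pools$se_r1) + nrow(pools$se_r2),
      discarded = n_discard, note = extra, stringsAsFactors = FALSE)
    if (isTRUE(cfg$qc)) {
      qc_list[[stage]] <<- qc_summarize(fq_rbind(pools$r1, pools$se_r1))
    }
  }
  note("input", stage_counts(pools), pools, 0L)

  # helper: apply a per-read transformation that can empty reads; empties
  # are discarded and mates rerouted to the single-end pool
  apply_trim_stage <- function(pools, fun, stage) {
    n_in <- stage_counts(pools)
    t1 <- fun(pools$r1); t2 <- if (paired) fun(pools$r2) else pools$r2
    ok1 <- nchar(t1$seq) > 0L
    ok2 <- if (paired) nchar(t2$seq) > 0L else logical(0)
    n_disc <- 0L
    if (paired) {
      keep <- ok1 & ok2
      new_se1 <- fq_slice(t1, ok1 & !ok2)
      new_se2 <- fq_slice(t2, !ok1 & ok2)
      pools$se_r1 <- fq_rbind(pools$se_r1, new_se1)
      pools$se_r1_sample <- c(pools$se_r1_sample, pools$sample[ok1 & !ok2])
      pools$se_r2 <- fq_rbind(pools$se_r2, new_se2)
      pools$se_r2_sample <- c(pools$se_r2_sample, pools$sample[!ok1 & ok2])
      n_disc <- n_disc + sum(!ok1) + sum(!ok2)
      pools$r1 <- fq_slice(t1, keep); pools$r2 <- fq_slice(t2, keep)
      pools$sample <- pools$sample[keep]
    } else {
      n_disc <- n_disc + sum(!ok1)
      pools$r1 <- fq_slice(t1, ok1)
      pools$sample <- pools$sample[ok1]
    }
    if (nrow(pools$se_r1)) {
      s1 <- fun(pools$se_r1); k <- nchar(s1$seq) > 0L
      n_disc <- n_disc + sum(!k)
      pools$se_r1 <- fq_slice(s1, k)
      pools$se_r1_sample <- pools$se_r1_sample[k]
    }
    if (nrow(pools$se_r2)) {
      s2 <- fun(pools$se_r2); k <- nchar(s2$seq) > 0L
      n_disc <- n_disc + sum(!k)
      pools$se_r2 <- fq_slice(s2, k)
      pools$se_r2_sample <- pools$se_r2_sample[k]
    }
    note(stage, n_in, pools, n_disc)
    pools
  }
  # helper: apply a pass/fail filter; failing reads are counted as
  # discarded (they are retained in the result's fail pool for inspection)
  fail_pool <- list()
  apply_filter_stage <- function(pools, fun1, fun2, stage) {
    n_in <- stage_counts(pools)
    p1 <- fun1(pools$r1)
    n_disc <- 0L
    fails <- list()
    if (paired) {
      p2 <- fun2(pools$r2)
      keep <- p1 & p2
      fails$r1 <- fq_slice(pools$r1, !p1)
      fails$r2 <- fq_slice(pools$r2, !p2)
      pools$se_r1 <- fq_rbind(pools$se_r1, fq_slice(pools$r1, p1 & !p2))
      pools$se_r1_sample <- c(pools$se_r1_sample, pools$sample[p1 & !p2])
      pools$se_r2 <- fq_rbind(pools$se_r2, fq_slice(pools$r2, !p1 & p2))
      pools$se_r2_sample <- c(pools$se_r2_sample, pools$sample[!p1 & p2])
      n_disc <- sum(!p1) + sum(!p2)
      pools$r1 <- fq_slice(pools$r1, keep); pools$r2 <- fq_slice(pools$r2, keep)
      pools$sample <- pools$sample[keep]
    } else {
      fails$r1 <- fq_slice(pools$r1, !p1)
      n_disc <- sum(!p1)
      pools$r1 <- fq_slice(pools$r1, p1)
      pools$sample <- pools$sample[p1]
    }
    if (nrow(pools$se_r1)) {
      k <- fun1(pools$se_r1)
      fails$se_r1 <- fq_slice(pools$se_r1, !k)
      n_disc <- n_disc + sum(!k)
      pools$se_r1 <- fq_slice(pools$se_r1, k)
      pools$se_r1_sample <- pools$se_r1_sample[k]
    }
    if (nrow(pools$se_r2)) {
      k <- fun2(pools$se_r2)
      fails$se_r2 <- fq_slice(pools$se_r2, !k)
      n_disc <- n_disc + sum(!k)
      pools$se_r2 <- fq_slice(pools$se_r2, k)
      pools$se_r2_sample <- pools$se_r2_sample[k]
    }
    fail_pool[[stage]] <<- fails
    note(stage, n_in, pools, n_disc)
    pools
  }

  # stage 1: fixed front trim (buffer removal)
  front <- ask(answers, "front", cfg$front)
  if (front > 0L) {
    pools <- apply_trim_stage(pools, function(x) trim_fixed(x, front = front),
                              "front_trim")
  }
  # stage 2: demultiplexing
  if (!is.null(cfg$scheme)) {
    n_in <- stage_counts(pools)
    max_m <- ask(answers, "max_m", cfg$max_m)
    dm <- demultiplex(pools$r1, if (paired) pools$r2 else NULL, cfg$scheme,
                      max_m = max_m, se_r1 = pools$se_r1,
                      se_r2 = pools$se_r2)
    keep <- !is.na(dm$sample)
    n_disc <- sum(!keep) * (if (paired) 2L else 1L)
    k1 <- !is.na(dm$se_r1_sample); k2 <- !is.na(dm$se_r2_sample)
    n_disc <- n_disc + sum(!k1) + sum(!k2)
    fail_pool[["demultiplex"]] <- list(
      r1 = fq_slice(dm$r1, !keep),
      r2 = if (paired) fq_slice(dm$r2, !keep) else fq_empty())
    pools$r1 <- fq_slice(dm$r1, keep)
    pools$r2 <- if (paired) fq_slice(dm$r2, keep) else pools$r2
    pools$sample <- dm$sample[keep]
    pools$se_r1 <- fq_slice(dm$se_r1, k1)
    pools$se_r1_sample <- dm$se_r1_sample[k1]
    pools$se_r2 <- fq_slice(dm$se_r2, k2)
    pools$se_r2_sample <- dm$se_r2_sample[k2]
    note("demultiplex", n_in, pools, n_disc,
         sprintf("max_m=%d; unknown reads counted as discarded", max_m))
  }
  # stage 3: motif filtering
  if (!is.null(cfg$r1_motifs)) {
    pools <- apply_filter_stage(
      pools,
      function(x) has_motif(x$seq, cfg$r1_motifs),
      function(x) if (is.null(cfg$r2_motifs)) rep(TRUE, nrow(x))
                  else has_motif(x$seq, cfg$r2_motifs),
      "motif_filter")
  }
  # stages 4/5: quality end-trim and threshold filter (order configurable)
  do_qtrim <- function(pools) {
    if (is.null(cfg$window)) return(pools)
    w <- ask(answers, "window", cfg$window)
    e <- ask(answers, "end_q", cfg$end_q)
    apply_trim_stage(pools, function(x) trim_quality_end(x, w, e), "quality_end_trim")
  }
  do_qfilter <- function(pools) {
    if (is.null(cfg$q)) return(pools)
    q <- ask(answers, "q", cfg$q)
    p <- ask(answers, "p", cfg$p)
    f <- function(x) passes_qthreshold(x, q, p)
    apply_filter_stage(pools, f, f, "quality_filter")
  }
  if (isTRUE(cfg$qtrim_before_qfilter)) {
    pools <- do_qtrim(pools); pools <- do_qfilter(pools)
  } else {
    pools <- do_qfilter(pools); pools <- do_qtrim(pools)
  }
  # stage 6: adapter trimming (sample-restricted search in pipeline mode)
  if (!is.null(cfg$adapters)) {
    n_in <- stage_counts(pools)
    res <- adapter_stage(pools, cfg, paired)
    pools <- res$pools
    note("adapter_trim", n_in, pools, res$n_disc,
         sprintf("%d reads adapter-trimmed", res$n_trimmed))
  }
  manifest <- do.call(rbind, manifest)
  out <- list(config = cfg, pools = pools, manifest = manifest,
              fail = fail_pool, qc = qc_list)
  class(out) <- "pipeline_result"
  if (!is.null(cfg$outdir)) write_pipeline(out, cfg$outdir)
  out
}

# Adapter stage: per-sample template restriction when cfg$adapters is a
# named sample -> templates list; otherwise one shared template set.
adapter_stage <- function(pools, cfg, paired) {
  per_sample <- is.list(cfg$adapters) && !is.null(names(cfg$adapters)) &&
    !identical(sort(names(cfg$adapters)), sort(c("r1", "r2"))) &&
    all(names(cfg$adapters) != "")
  trim_with <- function(reads, templates) {
    if (nrow(reads) == 0L || is.null(templates)) {
      return(list(reads = reads, n_trimmed = 0L))
    }
    idx <- adapter_index(templates, cfg$adapter_k)
    hit <- scan_adapters(reads$seq, idx, cfg$adapter_votes,
                         cfg$adapter_rounds, cfg$adapter_min_overlap)
    cut <- ifelse(is.na(hit$start), nchar(reads$seq), hit$start - 1L)
    reads$seq <- substr(reads$seq, 1L, cut)
    reads$qual <- substr(reads$qual, 1L, cut)
    list(reads = reads, n_trimmed = sum(!is.na(hit$start)))
  }
  n_trimmed <- 0L
  if (per_sample) {
    for (pool in c("paired", "se1", "se2")) {
      smp <- switch(pool, paired = pools$sample, se1 = pools$se_r1_sample,
                    se2 = pools$se_r2_sample)
      if (!length(smp)) next
      for (s in unique(smp)) {
        tpl <- cfg$adapters[[s]]
        if (is.null(tpl)) next
        i <- which(smp == s)
        if (pool == "paired") {
          o <- trim_with(fq_slice(pools$r1, i), tpl$r1)
          pools$r1[i, ] <- o$reads; n_trimmed <- n_trimmed + o$n_trimmed
          if (paired) {
            o <- trim_with(fq_slice(pools$r2, i), tpl$r2)
            pools$r2[i, ] <- o$reads; n_trimmed <- n_trimmed + o$n_trimmed
          }
        } else if (pool == "se1") {
          o <- trim_with(fq_slice(pools$se_r1, i), tpl$r1)
          pools$se_r1[i, ] <- o$reads; n_trimmed <- n_trimmed + o$n_trimmed
        } else {
          o <- trim_with(fq_slice(pools$se_r2, i), tpl$r2)
          pools$se_r2[i, ] <- o$reads; n_trimmed <- n_trimmed + o$n_trimmed
        }
      }
    }
  } else {
    o <- trim_with(pools$r1, cfg$adapters$r1)
    pools$r1 <- o$reads; n_trimmed <- n_trimmed + o$n_trimmed
    if (paired) {
      o <- trim_with(pools$r2, cfg$adapters$r2)
      pools$r2 <- o$reads; n_trimmed <- n_trimmed + o$n_trimmed
    }
    o <- trim_with(pools$se_r1, cfg$adapters$r1)
    pools$se_r1 <- o$reads; n_trimmed <- n_trimmed + o$n_trimmed
    o <- trim_with(pools$se_r2, cfg$adapters$r2)
    pools$se_r2 <- o$reads; n_trimmed <- n_trimmed + o$n_trimmed
  }
  # reads shorter than min_len after trimming are discarded
  n_disc <- 0L
  ml <- cfg$adapter_min_len
  if (paired) {
    ok1 <- nchar(pools$r1$seq) >= ml; ok2 <- nchar(pools$r2$seq) >= ml
    keep <- ok1 & ok2
    pools$se_r1 <- fq_rbind(pools$se_r1, fq_slice(pools$r1, ok1 & !ok2))
    pools$se_r1_sample <- c(pools$se_r1_sample, pools$sample[ok1 & !ok2])
    pools$se_r2 <- fq_rbind(pools$se_r2, fq_slice(pools$r2, !ok1 & ok2))
    pools$se_r2_sample <- c(pools$se_r2_sample, pools$sample[!ok1 & ok2])
    n_disc <- sum(!ok1) + sum(!ok2)
    pools$r1 <- fq_slice(pools$r1, keep); pools$r2 <- fq_slice(pools$r2, keep)
    pools$sample <- pools$sample[keep]
  } else {
    ok1 <- nchar(pools$r1$seq) >= ml
    n_disc <- sum(!ok1)
    pools$r1 <- fq_slice(pools$r1, ok1)
    pools$sample <- pools$sample[ok1]
  }
  if (nrow(pools$se_r1)) {
    k <- nchar(pools$se_r1$seq) >= ml
    n_disc <- n_disc + sum(!k)
    pools$se_r1 <- fq_slice(pools$se_r1, k)
    pools$se_r1_sample <- pools$se_r1_sample[k]
  }
  if (nrow(pools$se_r2)) {
    k <- nchar(pools$se_r2$seq) >= ml
    n_disc <- n_disc + sum(!k)
    pools$se_r2 <- fq_slice(pools$se_r2, k)
    pools$se_r2_sample <- pools$se_r2_sample[k]
  }
  list(pools = pools, n_trimmed = n_trimmed, n_disc = n_disc)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run\n")
  print(x$manifest[, c("stage", "reads_in", "paired_out", "se_out", "discarded")],
        row.names = FALSE)
  invisible(x)
}

#' Write final pipeline outputs per sample
#'
#' Layout: `<outdir>/final/<sample>.R1.fastq` (and `.R2`), single ends
#' under `<outdir>/se/`, QC matrices under `<outdir>/qc/`, and the
#' manifest as `<outdir>/manifest.tsv`.
#'
#' @param x a `pipeline_result`.
#' @param outdir output root.
#' @return invisibly, `outdir`.
#' @export
write_pipeline <- function(x, outdir) {
  dir.create(file.path(outdir, "final"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "se"), showWarnings = FALSE, recursive = TRUE)
  pools <- x$pools
  groups <- unique(stats::na.omit(c(pools$sample, pools$se_r1_sample,
                                    pools$se_r2_sample)))
  if (!length(groups) && nrow(pools$r1)) groups <- NA  # un-demultiplexed run
  for (s in groups) {
    tag <- if (is.na(s)) "all" else s
    i <- if (is.na(s)) seq_len(nrow(pools$r1)) else which(pools$sample == s)
    if (length(i)) {
      write_fastq(fq_slice(pools$r1, i),
                  file.path(outdir, "final", paste0(tag, ".R1.fastq")))
      if (nrow(pools$r2)) {
        write_fastq(fq_slice(pools$r2, i),
                    file.path(outdir, "final", paste0(tag, ".R2.fastq")))
      }
    }
    j <- if (is.na(s)) seq_len(nrow(pools$se_r1)) else which(pools$se_r1_sample == s)
    if (length(j)) {
      write_fastq(fq_slice(pools$se_r1, j),
                  file.path(outdir, "se", paste0("se.", tag, ".R1.fastq")))
    }
    k <- if (is.na(s)) seq_len(nrow(pools$se_r2)) else which(pools$se_r2_sample == s)
    if (length(k)) {
      write_fastq(fq_slice(pools$se_r2, k),
                  file.path(outdir, "se", paste0("se.", tag, ".R2.fastq")))
    }
  }
  utils::write.table(x$manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(x$qc)) {
    for (nm in names(x$qc)) {
      write_qc_summary(x$qc[[nm]], nm, file.path(outdir, "qc"))
    }
  }
  invisible(outdir)
}

# --- walkthrough support -----------------------------------------------

load_answers <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    lines <- readLines(x)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[grepl("=", lines)]
    kv <- strsplit(lines, "\\s*=\\s*")
    x <- stats::setNames(lapply(kv, function(e) paste(e[-1], collapse = "=")),
                         vapply(kv, `[`, "", 1L))
  }
  as.list(x)
}

# Walkthrough parameter lookup: scripted answers override config defaults;
# interactive sessions are prompted; a non-interactive run with an empty
# answer set keeps the configured default (scripted "accept all defaults"
# equals walkaway mode).
ask <- function(answers, key, default) {
  if (is.null(answers)) return(default)
  if (!is.null(answers[[key]])) {
    v <- suppressWarnings(as.numeric(answers[[key]]))
    if (is.na(v)) stop("invalid walkthrough value for ", key, ": ", answers[[key]])
    return(v)
  }
  if (interactive()) {
    repeat {
      inp <- readline(sprintf("%s [%s]: ", key, format(default)))
      if (inp == "") return(default)
      v <- suppressWarnings(as.numeric(inp))
      if (!is.na(v)) return(v)
      message("invalid value, try again")
    }
  }
  default
}

#' Confirm or update a stage parameter in walkthrough mode
#'
#' With a scripted answers list/file the stored value is used (invalid
#' values abort); interactively the user is prompted with the default;
#' otherwise the default is kept.
#'
#' @param answers named list or answers file path (see [run_pipeline()]).
#' @param key parameter name.
#' @param default configured default.
#' @return the confirmed numeric value.
#' @export
walkthrough_prompt <- function(answers, key, default) {
  ask(load_answers(answers), key, default)
}
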