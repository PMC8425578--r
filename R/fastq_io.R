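#' Construct an in-memory table of FASTQ records
#'
#' Records are held as a plain `data.frame` with columns `id`, `seq` and
#' `qual`.  The identifier is stored without its leading `@`.  Sequence and
#' quality strings must have equal length and quality characters must decode
#' to Phred scores 0--40 (ASCII 33--73 at the default offset).
#'
#' @param id character vector of read identifiers (no leading `@`).
#' @param seq character vector of DNA sequences over A,C,G,T,N.
#' @param qual character vector of Phred+33 quality strings.
#' @param validate check invariants (default TRUE).
#' @return a `data.frame` of class `fastq_df`.
#' @export
fastq_df <- function(id, seq, qual, validate = TRUE) {
  x <- data.frame(id = as.character(id), seq = as.character(seq),
                  qual = as.character(qual), stringsAsFactors = FALSE)
  if (validate) validate_fastq(x)
  class(x) <- c("fastq_df", "data.frame")
  x
}

#' @export
print.fastq_df <- function(x, ...) {
  cat(sprintf("FASTQ records: %d reads", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", lengths %d-%d", min(nchar(x$seq)), max(nchar(x$seq))))
  }
  cat("\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 3L))
  invisible(x)
}

validate_fastq <- function(x, offset = 33L) {
  bad_len <- which(nchar(x$seq) != nchar(x$qual))
  if (length(bad_len)) {
    stop(sprintf("record %d: sequence and quality lengths differ (%d vs %d)",
                 bad_len[1], nchar(x$seq[bad_len[1]]), nchar(x$qual[bad_len[1]])))
  }
  if (nrow(x) > 0) {
    qr <- range(utf8ToInt(paste(x$qual[nchar(x$qual) > 0], collapse = "")) -
                  as.integer(offset), na.rm = TRUE)
    if (length(qr) == 2L && is.finite(qr[1])) {
      if (qr[1] < 0L || qr[2] > .Q_MAX) {
        stop(sprintf("quality scores outside [0, %d] at offset %d (observed %d..%d)",
                     .Q_MAX, offset, qr[1], qr[2]))
      }
    }
  }
  invisible(TRUE)
}

is_gzip_path <- function(path) grepl("\\.gz$", path)

#' Read a 4-line FASTQ file
#'
#' Reads plain or gzip-compressed FASTQ in the strict 4-line dialect
#' (identifier, sequence, `+` separator, quality).  Wrapped/multi-line
#' records are rejected.  Malformed records raise an error naming the
#' 1-based record index.
#'
#' @param path file path; gzip input is detected by a `.gz` suffix.
#' @param offset quality ASCII offset (default 33; Phred+64 files can be read
#'   by passing 64, there is no auto-detection).
#' @return a [fastq_df()] of all records, in file order.
#' @export
read_fastq <- function(path, offset = 33L) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (is_gzip_path(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("%s: line count %d is not divisible by 4", path, length(lines)))
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(fastq_df(character(0), character(0), character(0)))
  idx <- seq_len(n)
  hdr <- lines[4L * idx - 3L]
  seqs <- lines[4L * idx - 2L]
  plus <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) stop(sprintf("record %d: header does not start with '@'", bad[1]))
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad)) stop(sprintf("record %d: separator line does not start with '+'", bad[1]))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop(sprintf("record %d: sequence and quality lengths differ (%d vs %d)",
                 bad[1], nchar(seqs[bad[1]]), nchar(qual[bad[1]])))
  }
  x <- fastq_df(sub("^@", "", hdr), seqs, qual, validate = FALSE)
  validate_fastq(x, offset = offset)
  x
}

#' Write records to a 4-line FASTQ file
#'
#' @param x a [fastq_df()] (or data.frame with id/seq/qual columns).
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return invisibly, the number of records written.
#' @export
write_fastq <- function(x, path) {
  n <- nrow(x)
  con <- if (is_gzip_path(path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (n > 0L) {
    lines <- character(4L * n)
    idx <- seq_len(n)
    lines[4L * idx - 3L] <- paste0("@", x$id)
    lines[4L * idx - 2L] <- x$seq
    lines[4L * idx - 1L] <- "+"
    lines[4L * idx] <- x$qual
    writeLines(lines, con)
  }
  invisible(n)
}

#' Read two FASTQ files as synchronized mate pairs
#'
#' The i-th record of each file is paired with the i-th record of the other.
#' Unequal record counts are an error reporting both counts.
#'
#' @param r1_path,r2_path paths to the R1 and R2 FASTQ files.
#' @return list with elements `r1` and `r2`, both [fastq_df()]s of equal size.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("unpaired inputs: %d records in %s but %d in %s",
                 nrow(r1), r1_path, nrow(r2), r2_path))
  }
  list(r1 = r1, r2 = r2)
}

# Subset helper that preserves the fastq_df class.
fq_slice <- function(x, i) {
  y <- x[i, , drop = FALSE]
  rownames(y) <- NULL
  class(y) <- c("fastq_df", "data.frame")
  y
}

fq_empty <- function() fastq_df(character(0), character(0), character(0))

# Concatenate fastq_df objects.
fq_rbind <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, nrow, 0L) > 0L]
  if (!length(parts)) return(fq_empty())
  y <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(y) <- NULL
  class(y) <- c("fastq_df", "data.frame")
  y
}
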