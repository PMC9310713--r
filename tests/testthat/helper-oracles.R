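# Independent oracles and small random-input generators used across tests.
# These deliberately avoid the package's own code paths (map_exact,
# find_target_site, ...) so that implementation and check stay separate.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(len) paste(sample(BASES, len, replace = TRUE), collapse = "")

rand_seqs <- function(n, len_range = c(19L, 24L)) {
  vapply(seq_len(n), function(i)
    rand_seq(sample(seq(len_range[1], len_range[2]), 1L)), character(1))
}

comp_chr <- function(x) chartr("ACGT", "TGCA", x)

revcomp_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(comp_chr(s), "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

# all-window substring scan: every start (0-based) where `read` occurs in
# `ref_seq` on the given strand (for "-", its reverse complement occurs)
naive_scan_strand <- function(read, ref_seq, strand) {
  pat <- if (strand == "+") read else revcomp_chr(read)
  L <- nchar(pat); n <- nchar(ref_seq)
  if (L > n || grepl("N", pat, fixed = TRUE)) return(integer(0))
  windows <- substring(ref_seq, 1:(n - L + 1), L:n)
  which(windows == pat) - 1L
}

# full naive mapping of a ReadSet against references: data.frame in the
# same column layout and order as map_exact()
naive_map <- function(reads, refs) {
  if (inherits(refs, "ReferenceSeq")) refs <- list(refs)
  # window tables built once per (reference, read length)
  win_cache <- new.env()
  windows_of <- function(ref, L) {
    key <- sprintf("%s|%d", ref$ref_id, L)
    if (!exists(key, win_cache)) {
      n <- nchar(ref$sequence)
      w <- if (L > n) character(0) else substring(ref$sequence, 1:(n - L + 1), L:n)
      assign(key, w, win_cache)
    }
    get(key, win_cache)
  }
  scan <- function(read, ref, strand) {
    pat <- if (strand == "+") read else revcomp_chr(read)
    if (grepl("N", pat, fixed = TRUE)) return(integer(0))
    which(windows_of(ref, nchar(pat)) == pat) - 1L
  }
  rows <- list()
  for (i in seq_len(nrow(reads$reads))) {
    s <- reads$reads$seq[i]
    for (r in refs) {
      fs <- scan(s, r, "+")
      rs <- scan(s, r, "-")
      k <- length(fs) + length(rs)
      if (k == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        read_seq = s, count = reads$reads$count[i], ref_id = r$ref_id,
        strand = c(rep("+", length(fs)), rep("-", length(rs))),
        start0 = c(fs, rs), end0 = c(fs, rs) + nchar(s), length = nchar(s),
        weight = 1 / k, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(read_seq = character(0), count = integer(0),
                      ref_id = character(0), strand = character(0),
                      start0 = integer(0), end0 = integer(0),
                      length = integer(0), weight = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_id, out$start0, out$strand, out$read_seq), ]
  rownames(out) <- NULL
  out
}

# brute-force Hamming scan over all windows of a transcript
naive_target_scan <- function(srna, transcript_seq, max_mm) {
  q <- strsplit(revcomp_chr(srna), "")[[1]]
  L <- length(q); n <- nchar(transcript_seq)
  if (L > n) return(data.frame(start0 = integer(0), mismatches = integer(0)))
  tv <- strsplit(transcript_seq, "")[[1]]
  res <- lapply(0:(n - L), function(s) {
    mm <- sum(tv[(s + 1):(s + L)] != q)
    if (mm <= max_mm) data.frame(start0 = s, mismatches = mm) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(start0 = integer(0), mismatches = integer(0)))
  out[order(out$mismatches, out$start0), , drop = FALSE]
}

# library drawn from a fixed pool of sequences, as an uncollapsed ReadSet
rand_library <- function(n_reads, pool) {
  read_set(sample(pool, n_reads, replace = TRUE))
}

fixture_path <- function(...) {
  p <- system.file("extdata", ..., package = "srnaphase")
  if (p == "") p <- file.path("../../inst/extdata", ...)
  p
}

# references + config used by recovery-style tests
make_scenario <- function(seed, n_reads = 50000L, ...) {
  set.seed(seed)
  refs <- sim_references()
  sim_config(refs, n_reads = n_reads, seed = seed, ...)
}
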