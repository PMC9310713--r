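#' Reverse complement of DNA character strings
#'
#' Vectorised reverse complement over plain character vectors. `N` maps to
#' `N`; input must be uppercase DNA.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a ReadSet
#'
#' A ReadSet is the library container used throughout the pipeline: one row
#' per read sequence with its multiplicity, plus the library total. Before
#' collapsing, sequences may repeat (each with count 1); after
#' [collapse_reads()] they are unique.
#'
#' @param seq character vector of uppercase DNA sequences (A/C/G/T/N).
#' @param count integer vector of positive per-sequence counts.
#' @param library_id library label carried into reports.
#' @return an object of class `ReadSet` with elements `reads` (data.frame
#'   with columns `seq`, `count`), `library_id`, and `total_reads`.
#' @export
read_set <- function(seq, count = rep(1L, length(seq)), library_id = "library") {
  seq <- as.character(seq)
  count <- as.integer(count)
  if (length(seq) != length(count))
    stop("read_set: 'seq' and 'count' lengths differ")
  if (length(count) && any(is.na(count) | count <= 0L))
    stop("read_set: counts must be strictly positive integers")
  bad <- grep("^[ACGTN]*$", seq, invert = TRUE)
  if (length(bad))
    stop(sprintf("read_set: sequence %d contains characters outside A/C/G/T/N", bad[1]))
  structure(
    list(
      reads = data.frame(seq = seq, count = count, stringsAsFactors = FALSE),
      library_id = library_id,
      total_reads = sum(count)
    ),
    class = "ReadSet"
  )
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet '%s': %d sequences, %d total reads\n",
              x$library_id, nrow(x$reads), x$total_reads))
  invisible(x)
}

normalize_seq <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Read a small RNA library from FASTA, FASTQ, or collapsed FASTA
#'
#' FASTA and FASTQ records each contribute count 1 (collapse afterwards with
#' [collapse_reads()]). Collapsed FASTA is the fastx_collapser-style dialect
#' where the read count is encoded in the header as `id-count` (or
#' `id_count` with `dialect = "underscore"`). Sequences are uppercased and
#' U is converted to T; quality values are ignored.
#'
#' @param path input file.
#' @param format one of `"fasta"`, `"fastq"`, `"collapsed_fasta"`.
#' @param dialect collapsed-header separator: `"dash"` (default) or
#'   `"underscore"`.
#' @param library_id library label; defaults to the file name without
#'   extension.
#' @return a [read_set()].
#' @export
read_srna <- function(path, format = c("fasta", "fastq", "collapsed_fasta"),
                      dialect = c("dash", "underscore"), library_id = NULL) {
  format <- match.arg(format)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("read_srna: no such file: %s", path))
  if (is.null(library_id))
    library_id <- sub("\\.[^.]*$", "", basename(path))
  if (file.size(path) == 0L)
    return(read_set(character(0), integer(0), library_id = library_id))

  if (format == "fastq") {
    n_lines <- length(readLines(path, warn = FALSE))
    if (n_lines %% 4L != 0L)
      stop(sprintf("read_srna: %s: truncated FASTQ record near line %d", path, n_lines))
    recs <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq"),
      error = function(e) stop(sprintf("read_srna: %s: malformed FASTQ: %s",
                                       path, conditionMessage(e)))
    )
    seqs <- normalize_seq(as.character(recs))
    return(validate_parsed(seqs, rep(1L, length(seqs)), library_id, path))
  }

  recs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop(sprintf("read_srna: %s: malformed FASTA: %s",
                                     path, conditionMessage(e)))
  )
  seqs <- normalize_seq(as.character(recs))
  if (format == "fasta")
    return(validate_parsed(seqs, rep(1L, length(seqs)), library_id, path))

  # collapsed_fasta: count is the token after the last separator in each id
  sep <- if (dialect == "dash") "-" else "_"
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1L)
  pat <- sprintf("^.*\\%s([0-9]+)$", sep)
  ok <- grepl(pat, ids)
  if (any(!ok)) {
    i <- which(!ok)[1]
    stop(sprintf(
      "read_srna: %s: record %d (header '%s'): count not a positive integer after '%s'",
      path, i, ids[i], sep))
  }
  count <- as.integer(sub(pat, "\\1", ids))
  if (any(count <= 0L)) {
    i <- which(count <= 0L)[1]
    stop(sprintf("read_srna: %s: record %d: count must be positive", path, i))
  }
  validate_parsed(seqs, count, library_id, path)
}

validate_parsed <- function(seqs, count, library_id, path) {
  bad <- grep("^[ACGTN]+$", seqs, invert = TRUE)
  if (length(bad))
    stop(sprintf("read_srna: %s: record %d: sequence contains non-DNA characters",
                 path, bad[1]))
  read_set(seqs, count, library_id = library_id)
}

#' Collapse identical reads
#'
#' Merges identical sequences, summing their counts. The library total is
#' conserved; output order is lexicographic by sequence (deterministic).
#'
#' @param rs a [read_set()].
#' @return a collapsed [read_set()] with unique sequences.
#' @export
collapse_reads <- function(rs) {
  stopifnot(inherits(rs, "ReadSet"))
  if (nrow(rs$reads) == 0L) return(rs)
  agg <- rowsum(rs$reads$count, group = rs$reads$seq)
  read_set(rownames(agg), as.integer(agg[, 1]), library_id = rs$library_id)
}

#' Write a collapsed FASTA file
#'
#' Headers follow the `>seq{rank}-{count}` dialect (rank in output order);
#' `dialect = "underscore"` writes `>seq{rank}_{count}`.
#'
#' @param rs a collapsed [read_set()].
#' @param path output file.
#' @param dialect header separator, as in [read_srna()].
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(rs, path, dialect = c("dash", "underscore")) {
  stopifnot(inherits(rs, "ReadSet"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "dash") "-" else "_"
  hdr <- sprintf(">seq%d%s%d", seq_len(nrow(rs$reads)), sep, rs$reads$count)
  writeLines(as.vector(rbind(hdr, rs$reads$seq)), path)
  invisible(path)
}

#' Write plain FASTA
#'
#' One record per read occurrence (counts expanded are NOT written; each row
#' of the ReadSet becomes one record with its own id). Used by the simulator
#' for uncollapsed libraries where every count is 1.
#'
#' @param rs a [read_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(rs, path) {
  stopifnot(inherits(rs, "ReadSet"))
  hdr <- sprintf(">r%d", seq_len(nrow(rs$reads)))
  writeLines(as.vector(rbind(hdr, rs$reads$seq)), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

#' Write the report bundle
#'
#' Emits one tab-separated table per statistic present in `bundle`, plus a
#' flat key-value run summary. Tables contain no timestamps, so re-running
#' on identical input is byte-identical.
#'
#' Recognised bundle elements (all optional): `profile` (per-position
#' count/RPM data.frame), `hits` (hit table), `processing` (a
#' FormClassification, see [classify_forms()]), `processing_summary`
#' (data.frame of metric/window/length_filter/value rows), `phasing` (a
#' PhasingTable, see [phasing_table()]), `strand_rpm` (data.frame), and
#' `summary` (named list written to the run summary).
#'
#' @param bundle named list of report components.
#' @param out_dir output directory (created if absent).
#' @param prefix file-name prefix, typically the library id.
#' @return character vector of files written (the manifest).
#' @export
write_report <- function(bundle, out_dir, prefix = "library") {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0L)
    stop(sprintf("write_report: output directory not writable: %s", out_dir))
  manifest <- character(0)
  p <- function(name) file.path(out_dir, paste0(prefix, ".", name, ".tsv"))

  if (!is.null(bundle$profile))
    manifest <- c(manifest, write_tsv(as.data.frame(bundle$profile), p("profile")))
  if (!is.null(bundle$hits))
    manifest <- c(manifest, write_tsv(bundle$hits, p("hits")))
  if (!is.null(bundle$processing))
    manifest <- c(manifest, write_tsv(bundle$processing$cells, p("processing")))
  if (!is.null(bundle$processing_summary))
    manifest <- c(manifest, write_tsv(bundle$processing_summary, p("processing_summary")))
  if (!is.null(bundle$phasing)) {
    pt <- bundle$phasing
    df <- data.frame(register = seq_along(pt$proportions),
                     weighted_count = pt$counts,
                     proportion = pt$proportions)
    manifest <- c(manifest, write_tsv(df, p("phasing")))
  }
  if (!is.null(bundle$strand_rpm))
    manifest <- c(manifest, write_tsv(bundle$strand_rpm, p("strand_rpm")))

  summary_path <- file.path(out_dir, paste0(prefix, ".run_summary.txt"))
  kv <- bundle$summary
  lines <- if (is.null(kv)) character(0) else
    sprintf("%s\t%s", names(kv), vapply(kv, format_kv, character(1)))
  writeLines(lines, summary_path)
  manifest <- c(manifest, summary_path)
  manifest
}

format_kv <- function(v) {
  if (is.numeric(v)) format(v, digits = 12, scientific = FALSE, trim = TRUE)
  else as.character(v)
}
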