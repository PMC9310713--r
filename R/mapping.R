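#' Exact both-strand mapping of unique reads
#'
#' Maps every unique read against the forward and reverse strands of each
#' reference, allowing no mismatches and no gaps. A (+) hit means the read
#' equals `reference[start0:end0)`; a (-) hit means its reverse complement
#' does (hits are always reported in forward reference coordinates).
#' Within one reference, a read hitting k positions (both strands pooled)
#' carries weight 1/k per hit, so its count is conserved per reference.
#' Reads containing N never match (references are N-free and matching is
#' literal). Reads with no match anywhere are omitted.
#'
#' @param reads a collapsed [read_set()].
#' @param refs a [reference_seq()] or list of them.
#' @return data.frame with columns `read_seq`, `count`, `ref_id`, `strand`
#'   (`"+"`/`"-"`), `start0`, `end0`, `length`, `weight`, ordered by
#'   (ref_id, start0, strand, read_seq).
#' @export
map_exact <- function(reads, refs) {
  stopifnot(inherits(reads, "ReadSet"))
  if (inherits(refs, "ReferenceSeq")) refs <- list(refs)
  if (length(refs) == 0L) stop("map_exact: no references")
  ref_ids <- vapply(refs, function(r) r$ref_id, character(1))
  seqs <- reads$reads$seq
  counts <- reads$reads$count
  lengths <- sort(unique(nchar(seqs)))
  rc <- revcomp(seqs)

  # per-reference index of every forward-strand window of each read length:
  # window sequence -> 0-based start positions. One O(|reference|) build per
  # (reference, length); each read then resolves in O(1) hash lookups.
  # Reads containing N miss every window (references are N-free), so they
  # never produce hits. (-) hits are found by looking up the read's reverse
  # complement among forward windows and reported in forward coordinates.
  rows <- vector("list", 0L)
  for (j in seq_along(refs)) {
    ref_seq <- refs[[j]]$sequence
    n <- nchar(ref_seq)
    index <- lapply(lengths, function(L) {
      if (L > n) return(list())
      split(0:(n - L), substring(ref_seq, 1:(n - L + 1), L:n))
    })
    names(index) <- as.character(lengths)
    for (i in seq_along(seqs)) {
      idx <- index[[as.character(nchar(seqs[i]))]]
      fs <- idx[[seqs[i]]]
      rs <- idx[[rc[i]]]
      k <- length(fs) + length(rs)
      if (k == 0L) next
      L <- nchar(seqs[i])
      starts <- c(fs, rs)
      rows[[length(rows) + 1L]] <- data.frame(
        read_seq = seqs[i], count = counts[i], ref_id = ref_ids[j],
        strand = c(rep("+", length(fs)), rep("-", length(rs))),
        start0 = starts, end0 = starts + L, length = L,
        weight = 1 / k, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(read_seq = character(0), count = integer(0),
                      ref_id = character(0), strand = character(0),
                      start0 = integer(0), end0 = integer(0),
                      length = integer(0), weight = numeric(0)))
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$ref_id, hits$start0, hits$strand, hits$read_seq), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Per-position count and RPM profile
#'
#' Aggregates weighted hit counts by (reference, strand, start position,
#' read length) and converts them to reads per million. The denominator is
#' either the library total (all clean reads, default) or the total count
#' of reads with at least one hit on any reference (`"mapped_total"`).
#'
#' @param hits a [map_exact()] result.
#' @param library the [read_set()] the hits were produced from.
#' @param denominator `"library_total"` or `"mapped_total"`.
#' @return data.frame of class `PositionProfile` with columns `ref_id`,
#'   `strand`, `start0`, `length`, `count`, `rpm`, and attributes
#'   `library_total`, `denominator_mode`, `denominator`.
#' @export
build_profile <- function(hits, library,
                          denominator = c("library_total", "mapped_total")) {
  stopifnot(inherits(library, "ReadSet"))
  denominator <- match.arg(denominator)
  denom <- if (denominator == "library_total") {
    library$total_reads
  } else {
    mapped <- unique(hits$read_seq)
    sum(library$reads$count[library$reads$seq %in% mapped])
  }
  if (denom == 0L) stop("build_profile: empty library (denominator zero)")
  if (nrow(hits) == 0L) {
    prof <- data.frame(ref_id = character(0), strand = character(0),
                       start0 = integer(0), length = integer(0),
                       count = numeric(0), rpm = numeric(0))
  } else {
    prof <- stats::aggregate(
      list(count = hits$count * hits$weight),
      by = list(ref_id = hits$ref_id, strand = hits$strand,
                start0 = hits$start0, length = hits$length),
      FUN = sum)
    prof <- prof[order(prof$ref_id, prof$strand, prof$start0, prof$length), ]
    rownames(prof) <- NULL
    prof$rpm <- 1e6 * prof$count / denom
  }
  structure(prof, class = c("PositionProfile", "data.frame"),
            library_total = library$total_reads,
            denominator_mode = denominator, denominator = denom)
}

#' Guide and star strand accumulation (RPM)
#'
#' RPM of reads whose sequence is exactly the guide (resp. star) strand;
#' reads matching neither contribute to neither. Uses the denominator
#' recorded in `profile`.
#'
#' @param hits a [map_exact()] result (source of read counts).
#' @param guide guide strand sequence.
#' @param star star strand sequence.
#' @param profile the [build_profile()] result carrying the RPM denominator.
#' @return named numeric vector `c(guide_rpm = , star_rpm = )`.
#' @export
strand_accumulation <- function(hits, guide, star, profile) {
  if (identical(guide, star)) stop("strand_accumulation: guide and star identical")
  denom <- attr(profile, "denominator")
  rpm_of <- function(s) {
    rows <- hits[hits$read_seq == s, , drop = FALSE]
    if (nrow(rows) == 0L) return(0)
    1e6 * rows$count[1] / denom
  }
  c(guide_rpm = rpm_of(guide), star_rpm = rpm_of(star))
}
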