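#' Construct a reference sequence
#'
#' @param ref_id sequence identifier.
#' @param sequence uppercase DNA string over A/C/G/T (U is converted to T).
#' @param role `"precursor"` or `"transcript"`.
#' @return object of class `ReferenceSeq`.
#' @export
reference_seq <- function(ref_id, sequence, role = c("precursor", "transcript")) {
  role <- match.arg(role)
  sequence <- normalize_seq(sequence)
  if (nchar(sequence) == 0L) stop("reference_seq: empty sequence")
  if (!grepl("^[ACGT]+$", sequence))
    stop("reference_seq: sequence must be over A/C/G/T")
  structure(list(ref_id = ref_id, sequence = sequence, role = role),
            class = "ReferenceSeq")
}

#' Read references from a FASTA file
#'
#' @param path FASTA file.
#' @param roles named character vector mapping ref ids to roles; ids not
#'   listed default to `"transcript"`.
#' @return named list of [reference_seq()] objects.
#' @export
read_references <- function(path, roles = character(0)) {
  recs <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(recs), function(i) {
    role <- if (ids[i] %in% names(roles)) roles[[ids[i]]] else "transcript"
    reference_seq(ids[i], as.character(recs[[i]]), role = role)
  })
  names(out) <- ids
  out
}

#' Annotate a precursor with its expected mature sRNA geometry
#'
#' All coordinates are 0-based, half-open, on the (+) strand. For a
#' `tas_transcript` precursor the guide must occupy a phased slot: its start
#' is `trigger_cleavage_pos + k * phase_cycle` for some k >= 1 (e.g. the
#' 3'D2 position at k = 2 when counting slots, i.e. offset 21 for D2 with a
#' 21-nt cycle).
#'
#' @param ref a [reference_seq()] with role `"precursor"`.
#' @param kind `"mir_foldback"` or `"tas_transcript"`.
#' @param guide_start 0-based start of the mature guide on the (+) strand.
#' @param guide_length guide length in nucleotides (19-24; 21 or 22 in
#'   typical art-sRNA designs).
#' @param star_start optional 0-based start of an annotated star strand.
#' @param trigger_cleavage_pos for `tas_transcript`: 0-based position of the
#'   first nucleotide downstream of the trigger-miRNA cleavage.
#' @param phase_cycle phasing increment (default 21).
#' @return object of class `PrecursorSpec`.
#' @export
precursor_spec <- function(ref, kind = c("mir_foldback", "tas_transcript"),
                           guide_start, guide_length, star_start = NULL,
                           trigger_cleavage_pos = NULL, phase_cycle = 21L) {
  kind <- match.arg(kind)
  stopifnot(inherits(ref, "ReferenceSeq"))
  if (ref$role != "precursor") stop("precursor_spec: ref role must be 'precursor'")
  guide_start <- as.integer(guide_start)
  guide_length <- as.integer(guide_length)
  if (guide_length < 19L || guide_length > 24L)
    stop("precursor_spec: guide_length must be in [19, 24]")
  plen <- nchar(ref$sequence)
  if (guide_start < 0L || guide_start + guide_length > plen)
    stop("precursor_spec: guide interval exceeds precursor bounds")
  if (kind == "tas_transcript") {
    if (is.null(trigger_cleavage_pos))
      stop("precursor_spec: tas_transcript requires trigger_cleavage_pos")
    trigger_cleavage_pos <- as.integer(trigger_cleavage_pos)
    d <- guide_start - trigger_cleavage_pos
    if (d <= 0L || d %% phase_cycle != 0L)
      stop("precursor_spec: guide must sit on a phased slot downstream of the trigger cleavage")
  }
  if (!is.null(star_start)) {
    star_start <- as.integer(star_start)
    if (star_start < 0L || star_start + guide_length > plen)
      stop("precursor_spec: star interval exceeds precursor bounds")
    if (max(guide_start, star_start) < min(guide_start, star_start) + guide_length)
      stop("precursor_spec: star interval overlaps the guide interval")
  }
  structure(list(ref = ref, kind = kind, guide_start = guide_start,
                 guide_length = guide_length, star_start = star_start,
                 trigger_cleavage_pos = trigger_cleavage_pos,
                 phase_cycle = as.integer(phase_cycle)),
            class = "PrecursorSpec")
}

#' Mature guide sequence of a precursor
#' @param spec a [precursor_spec()].
#' @return the guide DNA string.
#' @export
guide_sequence <- function(spec) {
  stopifnot(inherits(spec, "PrecursorSpec"))
  substr(spec$ref$sequence, spec$guide_start + 1L,
         spec$guide_start + spec$guide_length)
}

#' Star strand sequence of a precursor
#'
#' Uses the annotated star interval when the precursor annotation carries
#' one (real
#' foldbacks contain mismatches, so annotation overrides derivation);
#' otherwise derives the star of a perfectly complementary duplex with
#' [derive_star()].
#'
#' @param spec a [precursor_spec()].
#' @return the star DNA string.
#' @export
star_sequence <- function(spec) {
  stopifnot(inherits(spec, "PrecursorSpec"))
  if (!is.null(spec$star_start))
    return(substr(spec$ref$sequence, spec$star_start + 1L,
                  spec$star_start + spec$guide_length))
  derive_star(guide_sequence(spec))
}

#' Derive the star strand of a perfect sRNA duplex
#'
#' Assumes a perfectly complementary guide/star duplex with `overhang`-nt
#' 3' overhangs on both strands: guide position i (0-based) pairs star
#' position L - overhang - 1 - i, so the paired star region is the reverse
#' complement of the guide's first L - overhang bases. The star's 3'
#' overhang pairs nothing; it is padded with the complement of the guide's
#' first `overhang` bases in reverse order (the bases it would face in a
#' fully self-complementary precursor arm).
#'
#' @param guide guide DNA string (length >= overhang + 2).
#' @param overhang 3' overhang length (canonical 2 for DCL products).
#' @return the star DNA string, same length as `guide`.
#' @export
derive_star <- function(guide, overhang = 2L) {
  guide <- normalize_seq(guide)
  L <- nchar(guide)
  if (L < 4L || L < overhang + 2L) stop("derive_star: guide too short")
  paired <- revcomp(substr(guide, 1L, L - overhang))
  pad <- revcomp(substr(guide, 1L, overhang))
  paste0(paired, pad)
}

#' Find target sites of an sRNA on a transcript
#'
#' Scans every window of the transcript for matches to the reverse
#' complement of the sRNA, allowing up to `max_mismatches` substitutions
#' and no gaps (simple Hamming distance; no G:U awareness).
#'
#' @param srna sRNA sequence (19-24 nt), 5'->3'.
#' @param transcript a [reference_seq()].
#' @param max_mismatches maximum Hamming distance.
#' @return data.frame of class `TargetSite` rows: `transcript_id`,
#'   `start0`, `end0` (0-based half-open), `mismatches`; sorted by
#'   (mismatches, start0). Empty when the sRNA is longer than the
#'   transcript.
#' @export
find_target_site <- function(srna, transcript, max_mismatches = 0L) {
  stopifnot(inherits(transcript, "ReferenceSeq"))
  srna <- normalize_seq(srna)
  L <- nchar(srna)
  if (L < 19L || L > 24L) stop("find_target_site: sRNA length must be in [19, 24]")
  empty <- data.frame(transcript_id = character(0), start0 = integer(0),
                      end0 = integer(0), mismatches = integer(0))
  if (L > nchar(transcript$sequence)) return(empty)
  query <- Biostrings::DNAString(revcomp(srna))
  subj <- Biostrings::DNAString(transcript$sequence)
  m <- Biostrings::matchPattern(query, subj, max.mismatch = max_mismatches,
                                with.indels = FALSE)
  if (length(m) == 0L) return(empty)
  starts <- BiocGenerics::start(m) - 1L
  mm <- vapply(starts, function(s) {
    Biostrings::neditAt(query, subj, at = s + 1L)
  }, integer(1))
  out <- data.frame(transcript_id = transcript$ref_id, start0 = starts,
                    end0 = starts + L, mismatches = mm)
  out[order(out$mismatches, out$start0), , drop = FALSE]
}

#' Predict the sRNA-guided cleavage site of a target site
#'
#' AGO-catalysed cleavage falls between the target nucleotides paired to
#' sRNA positions 10 and 11 (counting from the sRNA 5' end). With the sRNA
#' paired antiparallel, position k pairs target index start + L - k, so the
#' first nucleotide of the 3' cleavage fragment is `p0 = start + L - 10`.
#'
#' @param site one row of a [find_target_site()] result (or any list with
#'   `transcript_id`, `start0`, `end0`).
#' @return object of class `CleavageSite` with fields `transcript_id`, `p0`.
#' @export
predict_cleavage <- function(site) {
  start <- as.integer(site$start0)
  L <- as.integer(site$end0) - start
  if (L < 11L) stop("predict_cleavage: sRNA shorter than 11 nt has no canonical cleavage geometry")
  structure(list(transcript_id = as.character(site$transcript_id)[1],
                 p0 = start + L - 10L),
            class = "CleavageSite")
}

#' Expected 5' ends of phased siRNAs downstream of a cleavage site
#'
#' Returns the ladder `p0, p0 + cycle, ...` of expected (+)-strand 5' ends
#' (D1, D2, ... positions). Positions whose full `cycle`-length window would
#' exceed the transcript are truncated when `transcript_length` is given.
#'
#' @param cleavage a [predict_cleavage()] result.
#' @param cycle phasing increment (default 21).
#' @param n_cycles number of positions requested.
#' @param transcript_length optional transcript length for truncation.
#' @return integer vector of 0-based start positions.
#' @export
phase_positions <- function(cleavage, cycle = 21L, n_cycles = 1L,
                            transcript_length = NULL) {
  stopifnot(inherits(cleavage, "CleavageSite"), cycle >= 1L, n_cycles >= 1L)
  pos <- cleavage$p0 + cycle * (seq_len(n_cycles) - 1L)
  if (!is.null(transcript_length))
    pos <- pos[pos + cycle <= transcript_length]
  as.integer(pos)
}
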