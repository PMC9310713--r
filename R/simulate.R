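random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

occurs_in <- function(seqs, haystacks) {
  # TRUE for each seq occurring in any haystack string (forward orientation)
  vapply(seqs, function(s) any(grepl(s, haystacks, fixed = TRUE)), logical(1),
         USE.NAMES = FALSE)
}

#' Build a random precursor/target reference pair for simulation
#'
#' Constructs, from the current RNG stream, a random precursor carrying the
#' guide at a fixed position and a random target transcript carrying the
#' guide's fully complementary target site. The guide starts with T
#' (art-sRNAs are designed with a 5' U) and is rejection-sampled so that it
#' occurs exactly once in the precursor and its complement exactly once in
#' the target. The two bases immediately upstream of the guide are set so
#' that the derived star strand of a perfect duplex maps exactly to the
#' precursor (-) strand — a linear mimic of a self-complementary foldback
#' arm. For a TAS-type precursor the guide occupies the second phased slot
#' (3'D2) downstream of the trigger cleavage position.
#'
#' @param guide_length mature sRNA length (21 or 22 in typical designs).
#' @param kind precursor kind, as in [precursor_spec()].
#' @param precursor_length,target_length reference lengths (nt).
#' @param guide_start guide start on the precursor (mir_foldback only;
#'   for tas_transcript it is `trigger_cleavage_pos + phase_cycle`).
#' @param site_start target-site start on the transcript.
#' @param trigger_cleavage_pos TAS trigger cleavage position (tas only).
#' @param phase_cycle phasing increment.
#' @return list with `precursor` ([precursor_spec()]), `target`
#'   ([reference_seq()]), `site` (TargetSite row), `cleavage`
#'   ([predict_cleavage()]), `guide`, `star`.
#' @export
sim_references <- function(guide_length = 21L,
                           kind = c("mir_foldback", "tas_transcript"),
                           precursor_length = 150L, target_length = 300L,
                           guide_start = 60L, site_start = 100L,
                           trigger_cleavage_pos = 30L, phase_cycle = 21L) {
  kind <- match.arg(kind)
  L <- as.integer(guide_length)
  if (kind == "tas_transcript")
    guide_start <- as.integer(trigger_cleavage_pos + phase_cycle)
  repeat {
    guide <- paste0("T", random_dna(1L, L - 1L))
    pre <- strsplit(random_dna(1L, precursor_length), "")[[1]]
    g <- strsplit(guide, "")[[1]]
    pre[(guide_start + 1L):(guide_start + L)] <- g
    # bases upstream of the guide chosen so the derived star maps (-) exactly
    pre[(guide_start - 1L):guide_start] <- g[1:2]
    pre <- paste(pre, collapse = "")
    tgt <- strsplit(random_dna(1L, target_length), "")[[1]]
    tgt[(site_start + 1L):(site_start + L)] <- strsplit(revcomp(guide), "")[[1]]
    tgt <- paste(tgt, collapse = "")
    n_pre <- length(BiocGenerics::start(Biostrings::matchPattern(
      Biostrings::DNAString(guide), Biostrings::DNAString(pre))))
    n_tgt <- length(BiocGenerics::start(Biostrings::matchPattern(
      Biostrings::DNAString(revcomp(guide)), Biostrings::DNAString(tgt))))
    also <- occurs_in(guide, c(tgt)) || occurs_in(revcomp(guide), c(pre))
    if (n_pre == 1L && n_tgt == 1L && !also) break
  }
  pref <- reference_seq("precursor", pre, role = "precursor")
  tref <- reference_seq("target", tgt, role = "transcript")
  spec <- precursor_spec(pref, kind = kind, guide_start = guide_start,
                         guide_length = L,
                         trigger_cleavage_pos =
                           if (kind == "tas_transcript") trigger_cleavage_pos else NULL,
                         phase_cycle = phase_cycle)
  site <- data.frame(transcript_id = "target", start0 = as.integer(site_start),
                     end0 = as.integer(site_start + L), mismatches = 0L)
  list(precursor = spec, target = tref, site = site,
       cleavage = predict_cleavage(site),
       guide = guide, star = derive_star(guide))
}

default_jitter_table <- function(spec) {
  L <- spec$guide_length
  P <- nchar(spec$ref$sequence)
  gs <- spec$guide_start
  tab <- expand.grid(offset = -4:4, length = 19:24)
  tab <- tab[!(tab$offset == 0L & tab$length == L), , drop = FALSE]
  tab <- tab[gs + tab$offset >= 0L & gs + tab$offset + tab$length <= P, ,
             drop = FALSE]
  tab$prob <- 1 / nrow(tab)
  rownames(tab) <- NULL
  tab
}

#' Simulation configuration for an art-sRNA library
#'
#' Defines the generative mixture of read classes the simulator draws from:
#' accurately processed guide reads, 5'-jittered/length-variant precursor
#' reads, star-strand reads, precursor degradation fragments, phased
#' secondary siRNAs from the target transcript, and background reads absent
#' from all references.
#'
#' @param references a [sim_references()] bundle (or an equivalent list).
#' @param n_reads library size.
#' @param seed RNG seed; identical configs with identical seeds give
#'   byte-identical libraries.
#' @param w_guide_accurate,w_guide_jitter,w_star,w_degradation,w_phased,w_background
#'   mixture weights; must be non-negative and sum to 1.
#' @param jitter_table data.frame (`offset`, `length`, `prob`) over 5'
#'   offsets in [-4, 4] and lengths in [19, 24], excluding (0,
#'   guide_length); defaults to uniform over all in-bounds cells. Cells
#'   whose window would exceed the precursor are a validation error.
#' @param phase_fidelity probability that a phased read starts exactly on a
#'   phased position; off-phase reads start uniformly on downstream
#'   positions NOT congruent to p0 modulo the cycle.
#' @param n_cycles number of phased positions available to in-phase reads.
#' @param minus_strand_phased emit half the phased reads as (-)-strand
#'   duplex partners (with the 2-nt offset)?
#' @param library_id library label.
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(references, n_reads = 50000L, seed = 1L,
                       w_guide_accurate = 0.65, w_guide_jitter = 0.15,
                       w_star = 0.05, w_degradation = 0.05,
                       w_phased = 0.05, w_background = 0.05,
                       jitter_table = NULL, phase_fidelity = 0.4,
                       n_cycles = 8L, minus_strand_phased = FALSE,
                       library_id = "sim") {
  w <- c(guide_accurate = w_guide_accurate, guide_jitter = w_guide_jitter,
         star = w_star, degradation = w_degradation, phased = w_phased,
         background = w_background)
  if (any(w < 0)) stop("sim_config: mixture weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("sim_config: mixture weights must sum to 1")
  if (n_reads <= 0L) stop("sim_config: n_reads must be positive")
  if (phase_fidelity < 0 || phase_fidelity > 1)
    stop("sim_config: phase_fidelity must be in [0, 1]")
  spec <- references$precursor
  if (is.null(jitter_table)) jitter_table <- default_jitter_table(spec)
  P <- nchar(spec$ref$sequence)
  bad <- spec$guide_start + jitter_table$offset < 0L |
    spec$guide_start + jitter_table$offset + jitter_table$length > P
  if (any(bad))
    stop(sprintf("sim_config: jitter cell (offset %d, length %d) exceeds precursor bounds",
                 jitter_table$offset[bad][1], jitter_table$length[bad][1]))
  if (any(jitter_table$offset == 0L & jitter_table$length == spec$guide_length))
    stop("sim_config: jitter table must exclude the accurate cell (0, guide_length)")
  if (abs(sum(jitter_table$prob) - 1) > 1e-9)
    stop("sim_config: jitter probabilities must sum to 1")
  tlen <- nchar(references$target$sequence)
  pp <- phase_positions(references$cleavage, cycle = spec$phase_cycle,
                        n_cycles = n_cycles, transcript_length = tlen)
  if (w[["phased"]] > 0 && length(pp) == 0L)
    stop("sim_config: no phased position fits the target transcript")
  structure(list(references = references, n_reads = as.integer(n_reads),
                 seed = as.integer(seed), weights = w,
                 jitter_table = jitter_table, phase_fidelity = phase_fidelity,
                 n_cycles = as.integer(n_cycles),
                 minus_strand_phased = minus_strand_phased,
                 library_id = library_id),
            class = "SimConfig")
}

#' Simulate an art-sRNA sequencing library with ground truth
#'
#' Draws `n_reads` class labels from the configured mixture and emits one
#' read per label: accurate guides equal the guide exactly; jittered reads
#' are precursor substrings at the drawn (offset, length); star reads equal
#' the star strand; degradation reads are uniform (+)-strand precursor
#' substrings of length 19-24; phased reads are 21-nt target substrings
#' starting on a phased position with probability `phase_fidelity`, else on
#' a uniform off-phase downstream position; background reads are random
#' 21-mers rejection-sampled to be absent from both strands of every
#' reference. Identical configs and seeds give identical output.
#'
#' @param config a [sim_config()].
#' @return list with `reads` (an uncollapsed [read_set()], one row per
#'   read) and `truth` (class `SimTruth`: per-read labels data.frame
#'   `read_id`, `class`, `ref`, `start0`, `strand`, `seq`; `class_counts`;
#'   the `config`).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  refs <- config$references
  spec <- refs$precursor
  pre <- spec$ref$sequence
  tgt <- refs$target$sequence
  gs <- spec$guide_start
  L <- spec$guide_length
  P <- nchar(pre)
  tlen <- nchar(tgt)
  p0 <- refs$cleavage$p0
  cycle <- spec$phase_cycle
  n <- config$n_reads

  classes <- sample(names(config$weights), n, replace = TRUE,
                    prob = config$weights)
  seq_out <- character(n)
  ref_out <- rep(NA_character_, n)
  start_out <- rep(NA_integer_, n)
  strand_out <- rep(NA_character_, n)

  i <- which(classes == "guide_accurate")
  seq_out[i] <- refs$guide
  ref_out[i] <- spec$ref$ref_id; start_out[i] <- gs; strand_out[i] <- "+"

  i <- which(classes == "guide_jitter")
  if (length(i)) {
    jt <- config$jitter_table
    cell <- sample.int(nrow(jt), length(i), replace = TRUE, prob = jt$prob)
    st <- gs + jt$offset[cell]
    seq_out[i] <- substr(rep(pre, length(i)), st + 1L, st + jt$length[cell])
    ref_out[i] <- spec$ref$ref_id; start_out[i] <- st; strand_out[i] <- "+"
  }

  i <- which(classes == "star")
  if (length(i)) {
    seq_out[i] <- refs$star
    ref_out[i] <- spec$ref$ref_id; start_out[i] <- gs - 2L; strand_out[i] <- "-"
  }

  i <- which(classes == "degradation")
  if (length(i)) {
    len <- sample(19:24, length(i), replace = TRUE)
    st <- as.integer(floor(stats::runif(length(i)) * (P - len + 1L)))
    seq_out[i] <- substr(rep(pre, length(i)), st + 1L, st + len)
    ref_out[i] <- spec$ref$ref_id; start_out[i] <- st; strand_out[i] <- "+"
  }

  i <- which(classes == "phased")
  if (length(i)) {
    pp <- phase_positions(refs$cleavage, cycle = cycle,
                          n_cycles = config$n_cycles, transcript_length = tlen)
    off_support <- setdiff(seq(p0, tlen - cycle), pp)
    off_support <- off_support[(off_support - p0) %% cycle != 0L]
    in_phase <- stats::runif(length(i)) < config$phase_fidelity
    st <- integer(length(i))
    st[in_phase] <- pp[sample.int(length(pp), sum(in_phase), replace = TRUE)]
    if (any(!in_phase)) {
      if (length(off_support) == 0L)
        stop("simulate_library: no off-phase downstream position available")
      st[!in_phase] <- off_support[sample.int(length(off_support),
                                              sum(!in_phase), replace = TRUE)]
    }
    classes[i] <- ifelse(in_phase, "phased_in", "phased_off")
    minus <- if (config$minus_strand_phased)
      stats::runif(length(i)) < 0.5 else rep(FALSE, length(i))
    plus_seq <- substr(rep(tgt, length(i)), st + 1L, st + cycle)
    if (any(minus)) {
      mst <- st[minus] - 2L
      plus_seq[minus] <- revcomp(substr(rep(tgt, sum(minus)),
                                        mst + 1L, mst + cycle))
      st[minus] <- mst
    }
    seq_out[i] <- plus_seq
    ref_out[i] <- refs$target$ref_id
    start_out[i] <- st
    strand_out[i] <- ifelse(minus, "-", "+")
  }

  i <- which(classes == "background")
  if (length(i)) {
    hay <- c(pre, tgt, revcomp(pre), revcomp(tgt))
    got <- character(0)
    while (length(got) < length(i)) {
      cand <- random_dna(length(i) - length(got), 21L)
      cand <- cand[!occurs_in(cand, hay)]
      got <- c(got, cand)
    }
    seq_out[i] <- got
  }

  truth <- data.frame(read_id = sprintf("r%d", seq_len(n)), class = classes,
                      ref = ref_out, start0 = start_out, strand = strand_out,
                      seq = seq_out, stringsAsFactors = FALSE)
  list(reads = read_set(seq_out, library_id = config$library_id),
       truth = structure(list(labels = truth,
                              class_counts = table(classes),
                              config = config),
                         class = "SimTruth"))
}

#' Closed-form expectations of the pipeline statistics under a SimConfig
#'
#' Computes, from the mixture weights and reference geometry alone, the
#' expected value of every statistic the pipeline estimates: the exact and
#' +/-4-windowed processing accuracy, each (offset, length) cell frequency,
#' guide and star RPM (library-total denominator), and the register
#' proportions of the phasing table. Degradation fragments can land on the
#' guide window by chance; that term is included. Expectations assume
#' reads map uniquely at their source position (guaranteed up to chance
#' sequence collisions in the random references).
#'
#' @param config a [sim_config()].
#' @return list with `exact_accuracy`, `windowed_accuracy`, `cell_freqs`
#'   (data.frame `offset`, `length`, `freq`), `guide_rpm`, `star_rpm`,
#'   `register1`, `register_props` (length-cycle vector), and
#'   `denominator_weight` (expected fraction of reads entering the
#'   processing denominator).
#' @export
truth_expectations <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  refs <- config$references
  spec <- refs$precursor
  w <- config$weights
  P <- nchar(spec$ref$sequence)
  L <- spec$guide_length
  gs <- spec$guide_start
  cycle <- spec$phase_cycle
  tlen <- nchar(refs$target$sequence)
  p0 <- refs$cleavage$p0

  # degradation: length uniform on 19..24, start uniform on 0..P-len
  deg_cell <- function(off, len) {
    st <- gs + off
    if (st < 0L || st + len > P) return(0)
    (1 / 6) * (1 / (P - len + 1L))
  }
  cells <- expand.grid(offset = -4:4, length = 19:24)
  jt <- config$jitter_table
  jt_prob <- function(off, len) {
    m <- jt$offset == off & jt$length == len
    if (any(m)) sum(jt$prob[m]) else 0
  }
  num <- mapply(function(off, len) {
    w[["guide_accurate"]] * (off == 0L && len == L) +
      w[["guide_jitter"]] * jt_prob(off, len) +
      w[["degradation"]] * deg_cell(off, len)
  }, cells$offset, cells$length)
  denom_w <- w[["guide_accurate"]] + w[["guide_jitter"]] + w[["degradation"]]
  cells$freq <- if (denom_w > 0) num / denom_w else NA_real_

  exact_num <- w[["guide_accurate"]] + w[["degradation"]] * deg_cell(0L, L)
  win_deg <- sum(vapply(-4:4, function(off)
    sum(vapply(19:24, function(len) deg_cell(off, len), numeric(1))),
    numeric(1)))
  win_num <- w[["guide_accurate"]] + w[["guide_jitter"]] +
    w[["degradation"]] * win_deg

  pp <- phase_positions(refs$cleavage, cycle = cycle,
                        n_cycles = config$n_cycles, transcript_length = tlen)
  off_support <- setdiff(seq(p0, tlen - cycle), pp)
  off_support <- off_support[(off_support - p0) %% cycle != 0L]
  reg_props <- numeric(cycle)
  if (length(off_support)) {
    res <- ((off_support - p0) %% cycle) + 1L
    off_dist <- tabulate(res, nbins = cycle) / length(off_support)
  } else off_dist <- numeric(cycle)
  reg_props <- (1 - config$phase_fidelity) * off_dist
  reg_props[1] <- reg_props[1] + config$phase_fidelity

  list(
    exact_accuracy = if (denom_w > 0) exact_num / denom_w else NA_real_,
    windowed_accuracy = if (denom_w > 0) win_num / denom_w else NA_real_,
    cell_freqs = cells,
    guide_rpm = 1e6 * exact_num,
    star_rpm = 1e6 * w[["star"]],
    register1 = reg_props[1],
    register_props = reg_props,
    denominator_weight = denom_w
  )
}

#' Write a simulated library and its ground truth to files
#'
#' Emits the reads (FASTA, or 4-line FASTQ with constant quality `I`), the
#' per-read truth labels (TSV), the closed-form expectations (TSV), and the
#' two references (FASTA).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param format `"fasta"` (clean-read convention) or `"fastq"`.
#' @return character vector of files written.
#' @export
simulate_to_files <- function(config, out_dir, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_library(config)
  reads_path <- file.path(out_dir, paste0(config$library_id, ".reads.",
                                          if (format == "fasta") "fa" else "fq"))
  if (format == "fasta") {
    write_fasta(sim$reads, reads_path)
  } else {
    s <- sim$reads$reads$seq
    writeLines(as.vector(rbind(sprintf("@r%d", seq_along(s)), s, "+",
                               strrep("I", nchar(s)))), reads_path)
  }
  truth_path <- write_tsv(sim$truth$labels,
                          file.path(out_dir, paste0(config$library_id, ".truth.tsv")))
  exp <- truth_expectations(config)
  exp_df <- data.frame(
    statistic = c("exact_accuracy", "windowed_accuracy", "guide_rpm",
                  "star_rpm", "register1"),
    expected = c(exp$exact_accuracy, exp$windowed_accuracy, exp$guide_rpm,
                 exp$star_rpm, exp$register1))
  exp_path <- write_tsv(exp_df, file.path(out_dir,
                                          paste0(config$library_id, ".expectations.tsv")))
  refs_path <- file.path(out_dir, "references.fa")
  writeLines(c(paste0(">", config$references$precursor$ref$ref_id),
               config$references$precursor$ref$sequence,
               paste0(">", config$references$target$ref_id),
               config$references$target$sequence), refs_path)
  c(reads_path, truth_path, exp_path, refs_path)
}
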