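#' Read and validate a run configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with:
#' \preformatted{
#' out_dir: reports
#' rpm_denominator: library_total    # or mapped_total
#' processing: {window: 4}
#' phasing: {cycle: 21, strand_mode: plus_only}
#' references: references.fa
#' precursor:
#'   ref_id: precursor
#'   kind: mir_foldback              # or tas_transcript
#'   guide_start: 60
#'   guide_length: 21
#'   star_start: null                # optional
#'   trigger_cleavage_pos: null      # tas_transcript only
#'   phase_cycle: 21
#' target:
#'   ref_id: target
#'   site_start: 100                 # exactly one of site_start / p0
#' libraries:
#'   - {id: lib1, path: lib1.fa, format: fasta}
#' }
#' Paths are resolved relative to the config file's directory.
#'
#' @param config YAML file path or named list.
#' @return validated config list of class `RunConfig`, with references and
#'   precursor spec loaded.
#' @export
read_run_config <- function(config) {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  need <- function(field) {
    if (is.null(config[[field]]))
      stop(sprintf("run config: missing required field '%s'", field))
    config[[field]]
  }
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base_dir, p)

  refs_path <- resolve(need("references"))
  if (!file.exists(refs_path))
    stop(sprintf("run config: references file not found: %s", refs_path))
  pre_cfg <- need("precursor")
  roles <- stats::setNames("precursor", pre_cfg$ref_id)
  refs <- read_references(refs_path, roles = roles)
  if (!pre_cfg$ref_id %in% names(refs))
    stop(sprintf("run config: precursor '%s' not in references", pre_cfg$ref_id))
  spec <- precursor_spec(refs[[pre_cfg$ref_id]], kind = pre_cfg$kind,
                         guide_start = pre_cfg$guide_start,
                         guide_length = pre_cfg$guide_length,
                         star_start = pre_cfg$star_start,
                         trigger_cleavage_pos = pre_cfg$trigger_cleavage_pos,
                         phase_cycle = pre_cfg$phase_cycle %||% 21L)

  cleavage <- NULL
  tgt_cfg <- config$target
  if (!is.null(tgt_cfg)) {
    if (!tgt_cfg$ref_id %in% names(refs))
      stop(sprintf("run config: target '%s' not in references", tgt_cfg$ref_id))
    has_site <- !is.null(tgt_cfg$site_start)
    has_p0 <- !is.null(tgt_cfg$p0)
    if (has_site == has_p0)
      stop("run config: target needs exactly one of 'site_start' or 'p0'")
    cleavage <- if (has_p0) {
      structure(list(transcript_id = tgt_cfg$ref_id,
                     p0 = as.integer(tgt_cfg$p0)), class = "CleavageSite")
    } else {
      L <- spec$guide_length
      predict_cleavage(data.frame(transcript_id = tgt_cfg$ref_id,
                                  start0 = as.integer(tgt_cfg$site_start),
                                  end0 = as.integer(tgt_cfg$site_start) + L))
    }
  }

  libs <- need("libraries")
  for (lb in libs) {
    if (is.null(lb$id) || is.null(lb$path))
      stop("run config: each library needs 'id' and 'path'")
    if (!file.exists(resolve(lb$path)))
      stop(sprintf("run config: library file not found: %s", resolve(lb$path)))
  }
  libs <- lapply(libs, function(lb) { lb$path <- resolve(lb$path); lb })

  structure(list(
    out_dir = resolve(config$out_dir %||% "reports"),
    rpm_denominator = config$rpm_denominator %||% "library_total",
    processing_window = config$processing$window %||% 4L,
    phasing_cycle = config$phasing$cycle %||% 21L,
    phasing_strand_mode = config$phasing$strand_mode %||% "plus_only",
    refs = refs, precursor = spec, cleavage = cleavage, libraries = libs
  ), class = "RunConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' For each configured library: parse and collapse the reads, map them
#' exactly to both strands of every reference, build the per-position
#' count/RPM profile, classify precursor forms and compute processing
#' accuracy (exact-mature and windowed), measure guide/star strand
#' accumulation, and build the phasing register table on the target.
#' Reports are written with [write_report()]; a run is deterministic, so
#' re-running an identical config reproduces identical report bytes.
#' Statistics with a zero denominator are reported as NA (undefined), not
#' 0, with an explanatory log line.
#'
#' @param config a [read_run_config()] result, a YAML path, or a list.
#' @param out_dir optional override of the configured output directory.
#' @return (invisibly) list with `summary` (data.frame: library,
#'   statistic, value), `results` (per-library objects), `manifest`
#'   (files written).
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (!inherits(config, "RunConfig")) config <- read_run_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  spec <- config$precursor
  guide <- guide_sequence(spec)
  star <- star_sequence(spec)
  summary_rows <- list()
  results <- list()
  manifest <- character(0)

  for (lb in config$libraries) {
    lib <- read_srna(lb$path, format = lb$format %||% "fasta",
                     library_id = lb$id)
    log_msg("[%s] parsed %d reads (%d records)", lb$id, lib$total_reads,
            nrow(lib$reads))
    lib <- collapse_reads(lib)
    log_msg("[%s] collapsed to %d unique sequences", lb$id, nrow(lib$reads))
    hits <- map_exact(lib, unname(config$refs))
    mapped <- sum(lib$reads$count[lib$reads$seq %in% unique(hits$read_seq)])
    log_msg("[%s] %d reads mapped (%d hit rows)", lb$id, mapped, nrow(hits))

    stat <- list()
    if (lib$total_reads == 0L) {
      log_msg("[%s] empty library: all statistics undefined", lb$id)
      stat <- list(total_reads = 0, mapped_reads = 0,
                   exact_accuracy = NA_real_, windowed_accuracy = NA_real_,
                   guide_rpm = NA_real_, star_rpm = NA_real_,
                   phasing_n_reads = NA_real_, register1 = NA_real_)
      bundle <- list(summary = stat)
      cls <- NULL; pt <- NULL; prof <- NULL
    } else {
      prof <- build_profile(hits, lib, denominator = config$rpm_denominator)
      cls <- classify_forms(hits, spec)
      acc_exact <- acc_win <- NA_real_
      if (cls$denominator > 0) {
        acc_exact <- processing_accuracy(cls, window = 0L,
                                         exact_length = spec$guide_length)
        acc_win <- processing_accuracy(cls, window = config$processing_window)
      } else {
        log_msg("[%s] no (+)-strand precursor reads in range: accuracy undefined", lb$id)
      }
      rpm <- strand_accumulation(hits, guide, star, prof)
      pt <- NULL
      reg1 <- NA_real_
      pn <- NA_real_
      if (!is.null(config$cleavage)) {
        pt <- phasing_table(hits, config$cleavage,
                            cycle = config$phasing_cycle,
                            strand_mode = config$phasing_strand_mode)
        pn <- pt$n_reads
        if (pt$n_reads > 0) reg1 <- phased_fraction(pt, 1L)
        else log_msg("[%s] no qualifying phased-population reads: register proportions undefined", lb$id)
      }
      stat <- list(total_reads = lib$total_reads, mapped_reads = mapped,
                   exact_accuracy = acc_exact, windowed_accuracy = acc_win,
                   guide_rpm = rpm[["guide_rpm"]], star_rpm = rpm[["star_rpm"]],
                   phasing_n_reads = pn, register1 = reg1)
      proc_summary <- data.frame(
        metric = c("exact_accuracy", "windowed_accuracy"),
        window = c(0L, config$processing_window),
        length_filter = c(spec$guide_length, NA_integer_),
        value = c(acc_exact, acc_win))
      bundle <- list(profile = prof, hits = hits, processing = cls,
                     processing_summary = proc_summary, phasing = pt,
                     strand_rpm = data.frame(strand = c("guide", "star"),
                                             sequence = c(guide, star),
                                             rpm = c(rpm[["guide_rpm"]],
                                                     rpm[["star_rpm"]])),
                     summary = stat)
    }
    manifest <- c(manifest, write_report(bundle, config$out_dir, prefix = lb$id))
    results[[lb$id]] <- list(library = lib, hits = hits, profile = prof,
                             classification = cls, phasing = pt, stats = stat)
    summary_rows[[lb$id]] <- data.frame(
      library = lb$id, statistic = names(stat),
      value = vapply(stat, function(v) as.numeric(v)[1], numeric(1)),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  manifest <- c(manifest,
                write_tsv(summary, file.path(config$out_dir, "summary.tsv")))
  invisible(list(summary = summary, results = results, manifest = manifest))
}

#' Simulate, analyze, and compare against closed-form truth
#'
#' Recovery mode: simulates a library from `config`, runs the full analysis
#' on it, and tabulates each estimated statistic against its
#' [truth_expectations()] value together with a 3-binomial-SD bound on the
#' sampling error.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory for reports and the comparison table;
#'   when NULL nothing is written.
#' @return data.frame with columns `statistic`, `estimate`, `expected`,
#'   `bound`, `within` (logical).
#' @export
run_recovery <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  sim <- simulate_library(config)
  exp <- truth_expectations(config)
  refs <- config$references
  lib <- collapse_reads(sim$reads)
  hits <- map_exact(lib, list(refs$precursor$ref, refs$target))
  prof <- build_profile(hits, lib)
  cls <- classify_forms(hits, refs$precursor)
  acc_exact <- processing_accuracy(cls, window = 0L,
                                   exact_length = refs$precursor$guide_length)
  acc_win <- processing_accuracy(cls, window = 4L)
  rpm <- strand_accumulation(hits, refs$guide, refs$star, prof)
  pt <- phasing_table(hits, refs$cleavage, cycle = refs$precursor$phase_cycle)
  reg1 <- if (pt$n_reads > 0) phased_fraction(pt, 1L) else NA_real_

  n <- config$n_reads
  sd3 <- function(p, m) 3 * sqrt(pmax(p * (1 - p), 1e-12) / max(m, 1))
  n_denom <- n * exp$denominator_weight
  n_phase <- n * config$weights[["phased"]]
  cmp <- data.frame(
    statistic = c("exact_accuracy", "windowed_accuracy", "guide_rpm",
                  "star_rpm", "register1"),
    estimate = c(acc_exact, acc_win, rpm[["guide_rpm"]], rpm[["star_rpm"]], reg1),
    expected = c(exp$exact_accuracy, exp$windowed_accuracy, exp$guide_rpm,
                 exp$star_rpm, exp$register1),
    bound = c(sd3(exp$exact_accuracy, n_denom),
              sd3(exp$windowed_accuracy, n_denom),
              1e6 * sd3(exp$guide_rpm / 1e6, n),
              1e6 * sd3(exp$star_rpm / 1e6, n),
              sd3(exp$register1, n_phase)))
  cmp$within <- !is.na(cmp$estimate) &
    abs(cmp$estimate - cmp$expected) <= cmp$bound
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_tsv(cmp, file.path(out_dir, paste0(config$library_id, ".recovery.tsv")))
  }
  cmp
}
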