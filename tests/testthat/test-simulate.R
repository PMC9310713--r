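test_that("identical configs and seeds give byte-identical libraries", {
  cfg1 <- make_scenario(601, n_reads = 1000L)
  cfg2 <- make_scenario(601, n_reads = 1000L)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(simulate_library(cfg1)$reads, f1)
  write_fasta(simulate_library(cfg2)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the library
  cfg3 <- sim_config(cfg1$references, n_reads = 1000L, seed = 999L)
  f3 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(simulate_library(cfg3)$reads, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("every emitted read is consistent with its truth label", {
  cfg <- make_scenario(602, n_reads = 4000L, minus_strand_phased = TRUE,
                       w_phased = 0.3, w_guide_accurate = 0.3,
                       w_guide_jitter = 0.1, w_star = 0.1,
                       w_degradation = 0.1, w_background = 0.1)
  sim <- simulate_library(cfg)
  refs <- cfg$references
  tr <- sim$truth$labels
  expect_equal(nrow(tr), cfg$n_reads)
  expect_equal(sum(sim$truth$class_counts), cfg$n_reads)
  expect_identical(tr$seq, sim$reads$reads$seq)

  pre <- refs$precursor$ref$sequence
  tgt <- refs$target$sequence
  seq_at <- function(ref_seq, st, len, strand) {
    w <- substr(ref_seq, st + 1, st + len)
    if (strand == "-") revcomp(w) else w
  }
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    ok <- switch(row$class,
      guide_accurate = identical(row$seq, refs$guide),
      star = identical(row$seq, refs$star),
      guide_jitter = ,
      degradation = identical(row$seq, seq_at(pre, row$start0,
                                              nchar(row$seq), row$strand)),
      phased_in = ,
      phased_off = identical(row$seq, seq_at(tgt, row$start0, 21L, row$strand)),
      background = !grepl(row$seq, pre, fixed = TRUE) &&
        !grepl(row$seq, tgt, fixed = TRUE) &&
        !grepl(revcomp(row$seq), pre, fixed = TRUE) &&
        !grepl(revcomp(row$seq), tgt, fixed = TRUE))
    if (!isTRUE(ok)) fail(sprintf("read %d (%s) inconsistent", i, row$class))
  }
  succeed()
  # in-phase labels sit exactly on the register ladder
  pin <- tr[tr$class == "phased_in" & tr$strand == "+", ]
  expect_true(all((pin$start0 - refs$cleavage$p0) %% 21L == 0L))
  poff <- tr[tr$class == "phased_off" & tr$strand == "+", ]
  expect_true(all((poff$start0 - refs$cleavage$p0) %% 21L != 0L))
})

test_that("config validation rejects impossible settings at build time", {
  set.seed(603)
  refs <- sim_references()
  expect_error(sim_config(refs, w_guide_accurate = 0.9), "sum to 1")
  expect_error(sim_config(refs, n_reads = 0), "positive")
  expect_error(sim_config(refs, phase_fidelity = 1.5), "\\[0, 1\\]")
  jt_bad <- data.frame(offset = -4:4, length = 24L, prob = 1 / 9)
  jt_bad$offset[1] <- -100L
  expect_error(sim_config(refs, jitter_table = jt_bad), "bounds")
  jt_acc <- data.frame(offset = 0L, length = 21L, prob = 1)
  expect_error(sim_config(refs, jitter_table = jt_acc), "accurate cell")
})

test_that("degenerate mixtures flow through the whole pipeline exactly", {
  # all accurate guide: accuracy 1, star absent, no phased population
  cfg <- make_scenario(604, n_reads = 500L,
                       w_guide_accurate = 1, w_guide_jitter = 0, w_star = 0,
                       w_degradation = 0, w_phased = 0, w_background = 0)
  sim <- simulate_library(cfg)
  expect_true(all(sim$reads$reads$seq == cfg$references$guide))
  lib <- collapse_reads(sim$reads)
  hits <- map_exact(lib, list(cfg$references$precursor$ref,
                              cfg$references$target))
  cls <- classify_forms(hits, cfg$references$precursor)
  expect_equal(processing_accuracy(cls, 0L, 21L), 1)
  prof <- build_profile(hits, lib)
  acc <- strand_accumulation(hits, cfg$references$guide,
                             cfg$references$star, prof)
  expect_equal(acc[["star_rpm"]], 0)
  pt <- phasing_table(hits, cfg$references$cleavage)
  expect_equal(pt$n_reads, 0)
})

test_that("closed-form expectations match Monte-Carlo means over seeds", {
  set.seed(605)
  refs <- sim_references()
  n_seeds <- 20L
  n <- 3000L
  ests <- t(vapply(seq_len(n_seeds), function(s) {
    cfg <- sim_config(refs, n_reads = n, seed = 605000L + s,
                      w_guide_accurate = 0.5, w_guide_jitter = 0.2,
                      w_star = 0.05, w_degradation = 0.1, w_phased = 0.1,
                      w_background = 0.05, phase_fidelity = 0.4)
    sim <- simulate_library(cfg)
    lib <- collapse_reads(sim$reads)
    hits <- map_exact(lib, list(refs$precursor$ref, refs$target))
    cls <- classify_forms(hits, refs$precursor)
    prof <- build_profile(hits, lib)
    rpm <- strand_accumulation(hits, refs$guide, refs$star, prof)
    pt <- phasing_table(hits, refs$cleavage)
    c(exact = processing_accuracy(cls, 0L, 21L),
      windowed = processing_accuracy(cls, 4L),
      guide_rpm = rpm[["guide_rpm"]], star_rpm = rpm[["star_rpm"]],
      register1 = phased_fraction(pt, 1L))
  }, numeric(5)))
  cfg0 <- sim_config(refs, n_reads = n, seed = 1L,
                     w_guide_accurate = 0.5, w_guide_jitter = 0.2,
                     w_star = 0.05, w_degradation = 0.1, w_phased = 0.1,
                     w_background = 0.05, phase_fidelity = 0.4)
  exp <- truth_expectations(cfg0)
  want <- c(exp$exact_accuracy, exp$windowed_accuracy, exp$guide_rpm,
            exp$star_rpm, exp$register1)
  for (j in 1:5) {
    se <- stats::sd(ests[, j]) / sqrt(n_seeds)
    expect_lt(abs(mean(ests[, j]) - want[j]), 3 * se + 1e-9,
              label = sprintf("|MC mean - expectation| for %s",
                              colnames(ests)[j]))
  }
})

test_that("truth expectations honour degenerate configs exactly", {
  set.seed(606)
  refs <- sim_references()
  all_acc <- sim_config(refs, n_reads = 100L, w_guide_accurate = 1,
                        w_guide_jitter = 0, w_star = 0, w_degradation = 0,
                        w_phased = 0, w_background = 0)
  exp <- truth_expectations(all_acc)
  expect_equal(exp$exact_accuracy, 1)
  expect_equal(exp$star_rpm, 0)
  expect_equal(exp$guide_rpm, 1e6)

  fid0 <- sim_config(refs, n_reads = 100L, w_guide_accurate = 0,
                     w_guide_jitter = 0, w_star = 0, w_degradation = 0,
                     w_phased = 1, w_background = 0, phase_fidelity = 0)
  expect_equal(truth_expectations(fid0)$register1, 0)
  expect_equal(sum(truth_expectations(fid0)$register_props), 1)
})
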