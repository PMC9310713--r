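test_that("map_exact reports constructed hits on both strands", {
  set.seed(301)
  rseq <- rand_seq(200)
  ref <- reference_seq("r", rseq, role = "transcript")
  fwd <- substr(rseq, 6, 26)           # ref[5:26)
  rev <- revcomp_chr(substr(rseq, 6, 26))
  lib <- collapse_reads(read_set(c(fwd, rev, "NNNNNNNNNNNNNNNNNNNNN")))
  hits <- map_exact(lib, ref)
  h_f <- hits[hits$strand == "+", ]
  h_r <- hits[hits$strand == "-", ]
  expect_equal(h_f$start0, 5L)
  expect_equal(h_f$end0, 26L)
  expect_equal(h_r$start0, 5L)
  expect_equal(h_r$read_seq, rev)
  expect_true(all(hits$weight == 1))
  # reads containing N never match
  expect_false(any(grepl("N", hits$read_seq)))
  # hit invariants
  expect_equal(substr(rseq, h_f$start0 + 1, h_f$end0), h_f$read_seq)
  expect_equal(substr(rseq, h_r$start0 + 1, h_r$end0), revcomp(h_r$read_seq))
})

test_that("multi-hit reads share weight 1/k (overlapping homopolymer)", {
  ref <- reference_seq("r", strrep("A", 10), role = "transcript")
  lib <- read_set("AAAA")
  hits <- map_exact(lib, ref)
  expect_equal(nrow(hits), 7L)                 # starts 0..6, (+) only
  expect_equal(sort(hits$start0), 0:6)
  expect_true(all(hits$strand == "+"))         # revcomp(AAAA)=TTTT absent
  expect_equal(hits$weight, rep(1 / 7, 7))
  expect_equal(sum(hits$weight * hits$count), 1)
})

test_that("map_exact agrees with the naive all-window scan", {
  set.seed(302)
  for (i in 1:20) {
    refs <- list(reference_seq("a", rand_seq(sample(100:800, 1)), "transcript"),
                 reference_seq("b", rand_seq(sample(100:800, 1)), "transcript"))
    # mix of planted and random reads so some hit, some do not
    planted <- vapply(1:5, function(j) {
      r <- refs[[sample(2, 1)]]$sequence
      L <- sample(19:24, 1)
      s <- sample(nchar(r) - L, 1)
      w <- substr(r, s + 1, s + L)
      if (runif(1) < 0.5) revcomp_chr(w) else w
    }, character(1))
    lib <- collapse_reads(read_set(c(planted, rand_seqs(10))))
    expect_equal(map_exact(lib, refs), naive_map(lib, refs))
  }
})

test_that("mapping is strand-symmetric under reverse complement", {
  set.seed(303)
  ref <- reference_seq("r", rand_seq(400), role = "transcript")
  reads <- c(substr(ref$sequence, 51, 71), rand_seqs(5))
  for (s in reads) {
    h1 <- map_exact(read_set(s), ref)
    h2 <- map_exact(read_set(revcomp(s)), ref)
    expect_equal(nrow(h1), nrow(h2))
    if (nrow(h1)) {
      expect_equal(h1$start0, h2$start0)
      expect_equal(h1$strand, chartr("+-", "-+", h2$strand))
    }
  }
})

test_that("weighted hit counts conserve mapped read counts per reference", {
  set.seed(304)
  for (i in 1:10) {
    ref <- reference_seq("r", rand_seq(300), role = "transcript")
    pool <- c(vapply(1:8, function(j) {
      L <- sample(19:24, 1); s <- sample(300 - L, 1)
      substr(ref$sequence, s + 1, s + L)
    }, character(1)), rand_seqs(5))
    lib <- collapse_reads(rand_library(200, pool))
    hits <- map_exact(lib, ref)
    mapped_count <- sum(lib$reads$count[lib$reads$seq %in% unique(hits$read_seq)])
    expect_equal(sum(hits$count * hits$weight), mapped_count)
  }
})

test_that("build_profile computes RPM by definition and by oracle tally", {
  # single read, count 70, library of 10^6 -> RPM 70 at its position
  ref <- reference_seq("r", rand_seq(100), role = "transcript")
  r1 <- substr(ref$sequence, 11, 31)
  filler <- strrep("G", 30)  # unmappable 30-mer filler read
  lib <- read_set(c(r1, filler), c(70L, 999930L))
  hits <- map_exact(lib, ref)
  prof <- build_profile(hits, lib, denominator = "library_total")
  expect_equal(prof$rpm, 70)
  expect_equal(prof$start0, 10L)
  # mapped_total denominator: only the 70 mapped reads
  prof_m <- build_profile(hits, lib, denominator = "mapped_total")
  expect_equal(prof_m$rpm, 1e6)

  expect_equal(nrow(build_profile(hits[0, ], lib)), 0L)
  empty <- read_set(character(0))
  expect_error(build_profile(hits, empty), "empty library")

  # random library: per-(strand, position, length) counts equal a brute tally
  set.seed(305)
  pool <- vapply(1:10, function(j) {
    L <- sample(19:24, 1); s <- sample(100 - L, 1)
    w <- substr(ref$sequence, s + 1, s + L)
    if (runif(1) < 0.3) revcomp_chr(w) else w
  }, character(1))
  lib2 <- collapse_reads(rand_library(300, pool))
  hits2 <- map_exact(lib2, ref)
  prof2 <- build_profile(hits2, lib2)
  tally <- new.env()
  for (i in seq_len(nrow(lib2$reads))) {
    s <- lib2$reads$seq[i]; cnt <- lib2$reads$count[i]
    fs <- naive_scan_strand(s, ref$sequence, "+")
    rs <- naive_scan_strand(s, ref$sequence, "-")
    k <- length(fs) + length(rs)
    for (p in fs) {
      key <- sprintf("+|%d|%d", p, nchar(s))
      assign(key, (if (exists(key, tally)) get(key, tally) else 0) + cnt / k, tally)
    }
    for (p in rs) {
      key <- sprintf("-|%d|%d", p, nchar(s))
      assign(key, (if (exists(key, tally)) get(key, tally) else 0) + cnt / k, tally)
    }
  }
  got_keys <- sprintf("%s|%d|%d", prof2$strand, prof2$start0, prof2$length)
  expect_setequal(got_keys, ls(tally))
  expect_equal(prof2$count,
               vapply(got_keys, get, numeric(1), envir = tally),
               ignore_attr = TRUE)
})

test_that("strand accumulation reports guide/star RPM, zero when absent", {
  set.seed(306)
  refs <- sim_references()
  lib <- read_set(c(refs$guide, substr(refs$precursor$ref$sequence, 2, 22)),
                  c(5338L, 994662L))
  hits <- map_exact(lib, refs$precursor$ref)
  prof <- build_profile(hits, lib)
  acc <- strand_accumulation(hits, refs$guide, refs$star, prof)
  expect_equal(acc[["guide_rpm"]], 5338)
  expect_equal(acc[["star_rpm"]], 0)
  expect_error(strand_accumulation(hits, refs$guide, refs$guide, prof),
               "identical")
})

test_that("simulated guide:star ratio is recovered within 3 binomial SD", {
  cfg <- make_scenario(307, n_reads = 20000L,
                       w_guide_accurate = 0.5, w_guide_jitter = 0,
                       w_star = 0.05, w_degradation = 0.15,
                       w_phased = 0.15, w_background = 0.15)
  sim <- simulate_library(cfg)
  refs <- cfg$references
  lib <- collapse_reads(sim$reads)
  hits <- map_exact(lib, list(refs$precursor$ref, refs$target))
  prof <- build_profile(hits, lib)
  acc <- strand_accumulation(hits, refs$guide, refs$star, prof)
  n <- cfg$n_reads
  expect_lt(abs(acc[["guide_rpm"]] / 1e6 - 0.5), 3 * sqrt(0.5 * 0.5 / n))
  expect_lt(abs(acc[["star_rpm"]] / 1e6 - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # configured 10:1 ratio visible in the estimates
  expect_lt(abs(acc[["guide_rpm"]] / acc[["star_rpm"]] - 10), 1.5)
})
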