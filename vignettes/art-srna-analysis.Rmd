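---
title: "Quantifying art-sRNA processing accuracy and phasing with srnaphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying art-sRNA processing accuracy and phasing with srnaphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaphase)
```

## The analysis problem

Artificial small RNAs (art-sRNAs) are designed 21--22-nt silencing triggers
expressed in plants from two kinds of engineered precursor: artificial
microRNAs (amiRNAs), embedded in a miRNA foldback and released by DCL1, and
synthetic trans-acting siRNAs (syn-tasiRNAs), embedded in a TAS transcript
and released by DCL4 in 21-nt increments downstream of a trigger-miRNA
cleavage site. Assessing such a construct from a small RNA sequencing
library asks three questions:

1. **Was the precursor processed accurately?** What fraction of the
   precursor-derived reads is exactly the intended mature sRNA, and what
   fraction starts within a few nucleotides of the intended 5' end?
2. **Is the duplex present?** How abundant are the guide and star strands,
   in reads per million (RPM)?
3. **Did targeting trigger transitivity?** Are there 21-nt secondary
   siRNAs from the target transcript laid out in 21-nt register with the
   sRNA-guided cleavage site?

`srnaphase` implements this analysis as composable functions plus a
one-call pipeline (`run_analysis()`), and pairs it with a generative
simulator whose ground truth exercises every statistic.

## Pipeline model

**Collapsing.** Identical reads are merged into unique sequences with
counts (`collapse_reads()`); totals are conserved, so library-size
normalisation is unaffected.

**Exact mapping.** Unique reads are matched against the forward and
reverse strands of each reference with no mismatches and no gaps
(`map_exact()`). Short designed references (a precursor of a few hundred
nt, one target transcript) make exact matching both feasible and the
right specificity: a 19--24-nt read either is a substring of the
reference or it is not. The mapper builds, per reference and read length,
a hash index from every window of the reference to its start positions;
each read (and its reverse complement, for the (-) strand) is then a
constant-time lookup. A read hitting $k$ positions within one reference
receives weight $1/k$ per hit, so weighted counts conserve read counts
per reference. Reads containing `N` are retained through parsing but can
never produce a hit, because references are N-free and matching is
literal.

**Coordinates** are 0-based, half-open, on the (+) strand everywhere,
including `start0`/`end0` report columns. (-)-strand hits are reported on
the forward coordinates of the matched interval, which keeps profiles and
phasing in a single coordinate system.

**RPM.** $\mathrm{RPM} = 10^6 \cdot c / D$ with $c$ the weighted count.
The denominator $D$ is a switch: `library_total` (all clean reads;
default) or `mapped_total` (reads with at least one hit). `library_total`
is the default because it does not change when the reference set changes;
both denominators are recorded in the run summary so either convention
can be audited.

## The statistics

**Processing accuracy** (`classify_forms()` + `processing_accuracy()`).
(+)-strand precursor reads of 19--24 nt are tabulated by (5'-end offset
from the expected mature 5' end, read length). The expected 5' anchor is
the guide start for a foldback, and the guide's phased DCL4 slot for a
TAS precursor. Two framings are computed and reported side by side:

* *exact-mature fraction*: offset $= 0$ and read length $=$ guide length
  (under exact mapping this read **is** the mature guide) — the
  pie-chart-style number;
* *windowed accuracy*: $|\text{offset}| \le 4$, any length in range —
  the conventional $\pm 4$-nt statistic.

The denominator is all (+)-strand precursor reads in the length range;
(-)-strand reads are excluded from both numerator and denominator. A zero
denominator makes the statistic undefined: the pipeline reports `NA` with
a log line, never 0, because "no precursor reads" is a different finding
from "none accurate".

**Strand accumulation** (`strand_accumulation()`): RPM of reads exactly
equal to the guide and to the star strand. When the precursor annotation
carries a `star_start`, that sequence is the star; otherwise
`derive_star()` constructs the star of a perfectly complementary duplex
with 2-nt 3' overhangs (guide position $i$ pairs star position
$L-3-i$; the star's unpaired 3' overhang is padded with the complement of
the guide's first two bases, in reverse order). Annotation overrides
derivation because real foldbacks contain mismatches.

**Cleavage geometry** (`predict_cleavage()`). AGO-catalysed cleavage falls
between the target nucleotides paired to sRNA positions 10 and 11, so for
a site starting at $s$ with sRNA length $L$, the first nucleotide of the
3' fragment is $p_0 = s + L - 10$. This is exact arithmetic, checked for
all $L \in [19, 24]$ and under translation of the site.

**Phasing** (`phasing_table()` + `phased_fraction()`). Each 21-nt read on
the target with $\mathrm{start} \ge p_0$ is assigned register
$((\mathrm{start}-p_0) \bmod 21) + 1$; register 1 is in phase with the
cleavage site. Proportions are weighted counts per register over all
qualifying reads. Reads upstream of $p_0$ — including reads straddling
it — are excluded, matching the "downstream of the cleavage site"
convention. Only (+)-strand reads count by default; `strand_mode =
"both"` adds (-)-strand reads with the canonical 2-nt duplex offset
($\mathrm{start}+2$) and exists mainly to validate the simulator's
minus-strand emission. No pseudo-counts or minimum-read thresholds are
imposed; the table carries its qualifying-read count so callers can apply
their own.

## The simulator

`simulate_library()` draws each read from a labelled mixture:

| class | emission |
|---|---|
| `guide_accurate` | the exact mature guide |
| `guide_jitter` | precursor substring at a (5' offset, length) drawn from a jitter table over offsets $[-4,4]$ and lengths $[19,24]$, excluding the accurate cell |
| `star` | the star strand |
| `degradation` | uniform (+)-strand precursor fragment, length uniform on $[19,24]$ |
| `phased_in` / `phased_off` | 21-nt target substring starting on a phased position (probability = `phase_fidelity`) or on a uniform off-phase downstream position |
| `background` | random 21-mer rejection-sampled to be absent from both strands of every reference |

Defaults mirror a well-processed art-sRNA library: 65% accurate guide,
15% jittered, 5% star, 5% degradation, 5% phased, 5% background, phase
fidelity 0.4, 50,000 reads. These sit in the middle of the regimes
observed for art-sRNA constructs (roughly 20--80% accurately processed
reads, and register-1 proportions near 40% when transitivity is
triggered); validation additionally sweeps the accurate fraction over
0.20/0.65/0.82.

Because off-phase positions are drawn from downstream starts *not*
congruent to $p_0$ modulo 21, the expected register-1 proportion is
exactly the phase fidelity, and `truth_expectations()` can return every
statistic's expectation in closed form (including the small term from
degradation fragments that land on the guide window by chance). Those
expectations are the oracle for parameter-recovery tests, which require
estimates within 3 binomial standard deviations of truth.

`sim_references()` builds the synthetic references: a random precursor
with the guide embedded (starting with T, as designed art-sRNAs carry a
5' U) and a random target carrying the guide's perfect-complement site.
The two bases immediately upstream of the guide are chosen so that the
derived star maps exactly on the precursor (-) strand — a *linear mimic*
of a self-complementary foldback arm, not a real hairpin. Guides are
rejection-sampled to occur exactly once in their reference so that
multi-mapping never blurs the ground truth.

**What the simulator does not emulate:** sequencing error, adapter or
quality artefacts, ligation bias (including any preference for 21-nt
reads during library preparation), real foldback secondary structure with
its mismatches and loops, and genomic background beyond the two
references. Passing recovery tests therefore demonstrates that the
*statistics* are computed correctly on reads of known origin — not that
real libraries are free of such artefacts.

## Numerical and design choices

* **Multi-hit weighting** $1/k$ per reference conserves counts; with the
  short, unique-by-construction references it is rarely exercised, but
  homopolymeric edge cases are tested explicitly.
* **Determinism.** Collapsed output is ordered lexicographically, hit
  tables by (reference, position, strand, sequence), and reports contain
  no timestamps, so identical inputs give byte-identical reports.
* **Degenerate inputs.** Empty files parse to empty libraries (not
  errors); empty libraries make RPM denominators an error and downstream
  statistics `NA`; a phasing table with no qualifying reads is all-zero
  with `n_reads = 0`, and asking for its register proportion is an error
  rather than a silent 0.
* **`phase_positions()` truncation** removes ladder positions whose full
  21-nt window would overrun the transcript, since no 21-nt read can
  start there.
* **Validation problem sizes.** Property tests use 200 random
  (library, reference) pairs with references up to 2 kb for mapper/oracle
  equivalence, 100 random libraries for count conservation, and
  50,000-read simulations (5 seeds per regime) for recovery — sizes at
  which binomial 3-SD bounds are tight (about $\pm 0.6$ percentage
  points) while the whole suite stays fast.

## Limitations

* Exact mapping is by design: mismatch-tolerant or spliced alignment, and
  genome-scale indexing, are out of scope (references are a few kb at
  most). Target-site *search* (`find_target_site()`) does allow
  mismatches, but with plain Hamming distance — no gaps, no G:U wobble
  scoring, no thermodynamics.
* The star-strand derivation assumes a perfect duplex; for real
  precursors provide `star_start` in the annotation.
* Phasing analysis anchors on a single cleavage site per target and one
  register cycle; genome-wide PHAS-locus discovery and p-value-based
  phasing scores are out of scope.
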