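#' Phasing register table of target-derived siRNAs
#'
#' Assigns each 21-nt read on the target transcript, starting at or
#' downstream of the cleavage position p0, to one of `cycle` registers:
#' `register = ((start0 - p0) mod cycle) + 1`, so register 1 holds reads
#' whose 5' end sits immediately after the sRNA-guided cleavage site (and
#' every full cycle downstream of it). Reads upstream of p0, or straddling
#' it, are excluded. By default only (+)-strand reads are counted; with
#' `strand_mode = "both"`, (-)-strand reads enter with the canonical 2-nt
#' duplex offset correction `((start0 + 2 - p0) mod cycle) + 1`.
#'
#' @param hits a [map_exact()] result restricted by `ref_id` to the target
#'   transcript (rows on other references are ignored when
#'   `transcript_id` is supplied in `cleavage`).
#' @param cleavage a [predict_cleavage()] result (anchor p0).
#' @param cycle phasing increment; 21 for DCL4 products.
#' @param strand_mode `"plus_only"` (default) or `"both"`.
#' @param read_length read length defining the phased population (21).
#' @return object of class `PhasingTable`: list with `proportions` (length
#'   `cycle`, registers 1..cycle), `counts` (weighted), `n_reads` (total
#'   qualifying weighted count), `p0`, `cycle`. All-zero with `n_reads` 0
#'   when no read qualifies.
#' @export
phasing_table <- function(hits, cleavage, cycle = 21L,
                          strand_mode = c("plus_only", "both"),
                          read_length = 21L) {
  stopifnot(inherits(cleavage, "CleavageSite"), cycle >= 1L)
  strand_mode <- match.arg(strand_mode)
  p0 <- cleavage$p0
  sel <- hits$ref_id == cleavage$transcript_id &
    hits$length == read_length & hits$start0 >= p0
  if (strand_mode == "plus_only") sel <- sel & hits$strand == "+"
  h <- hits[sel, , drop = FALSE]
  counts <- numeric(cycle)
  if (nrow(h)) {
    shift <- ifelse(h$strand == "-", 2L, 0L)
    reg <- ((h$start0 + shift - p0) %% cycle) + 1L
    w <- rowsum(h$count * h$weight, group = reg)
    counts[as.integer(rownames(w))] <- w[, 1]
  }
  n <- sum(counts)
  structure(list(proportions = if (n > 0) counts / n else numeric(cycle),
                 counts = counts, n_reads = n, p0 = p0,
                 cycle = as.integer(cycle)),
            class = "PhasingTable")
}

#' @export
print.PhasingTable <- function(x, ...) {
  cat(sprintf("PhasingTable: p0 = %d, cycle %d, %.2f qualifying reads; register 1: %.3f\n",
              x$p0, x$cycle, x$n_reads,
              if (x$n_reads > 0) x$proportions[1] else NA_real_))
  invisible(x)
}

#' Proportion of reads in a phasing register
#'
#' @param table a [phasing_table()].
#' @param register register index (1..cycle); register 1 is in phase with
#'   the cleavage site.
#' @return the proportion at that register.
#' @export
phased_fraction <- function(table, register = 1L) {
  stopifnot(inherits(table, "PhasingTable"))
  if (register < 1L || register > table$cycle)
    stop("phased_fraction: register out of range")
  if (table$n_reads <= 0)
    stop("phased_fraction: no qualifying reads; proportion undefined")
  table$proportions[register]
}
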