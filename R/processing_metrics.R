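#' Classify precursor reads by 5' offset and length
#'
#' Tabulates weighted counts of (+)-strand precursor reads in the given
#' length range by (5' offset from the expected mature 5' end, read
#' length). The anchor is the guide start for a miRNA foldback, or the
#' guide's phased slot (e.g. the DCL4 processing position 3'D2) for a TAS
#' precursor — in both cases `spec$guide_start`. The denominator is the
#' weighted count of all (+)-strand precursor reads in the length range;
#' (-)-strand reads never enter any cell or the denominator.
#'
#' @param hits a [map_exact()] result.
#' @param spec the [precursor_spec()] for the precursor reference.
#' @param length_range inclusive read-length range, default 19-24 nt.
#' @param min_offset_span offsets reported at least over
#'   `[-min_offset_span, +min_offset_span]` (zero-filled), default 4.
#' @return object of class `FormClassification`: list with `cells`
#'   (data.frame `offset`, `length`, `weighted_count`, `fraction`),
#'   `denominator`, `anchor`, `guide_length`. With no qualifying reads the
#'   denominator is 0 and fractions are NA (flagged downstream).
#' @export
classify_forms <- function(hits, spec, length_range = c(19L, 24L),
                           min_offset_span = 4L) {
  stopifnot(inherits(spec, "PrecursorSpec"))
  anchor <- spec$guide_start
  sel <- hits$ref_id == spec$ref$ref_id & hits$strand == "+" &
    hits$length >= length_range[1] & hits$length <= length_range[2]
  h <- hits[sel, , drop = FALSE]
  denom <- sum(h$count * h$weight)

  base <- expand.grid(offset = seq(-min_offset_span, min_offset_span),
                      length = seq(length_range[1], length_range[2]))
  base$weighted_count <- 0
  if (nrow(h)) {
    tab <- stats::aggregate(
      list(weighted_count = h$count * h$weight),
      by = list(offset = h$start0 - anchor, length = h$length), FUN = sum)
    key_b <- paste(base$offset, base$length)
    key_t <- paste(tab$offset, tab$length)
    hitk <- match(key_t, key_b)
    base$weighted_count[hitk[!is.na(hitk)]] <- tab$weighted_count[!is.na(hitk)]
    extra <- tab[is.na(hitk), , drop = FALSE]
    if (nrow(extra)) base <- rbind(base, extra)
  }
  base <- base[order(base$offset, base$length), , drop = FALSE]
  rownames(base) <- NULL
  base$fraction <- if (denom > 0) base$weighted_count / denom else NA_real_
  structure(list(cells = base, denominator = denom, anchor = anchor,
                 guide_length = spec$guide_length),
            class = "FormClassification")
}

#' @export
print.FormClassification <- function(x, ...) {
  cat(sprintf("FormClassification: anchor %d, denominator %.2f reads\n",
              x$anchor, x$denominator))
  invisible(x)
}

#' Precursor processing accuracy
#'
#' Fraction of (+)-strand precursor reads (in the classification's length
#' range) whose 5' end lies within `window` nucleotides of the expected
#' mature 5' end, optionally restricted to one read length. The two
#' conventional framings are `window = 4, exact_length = NULL` (the
#' windowed accuracy statistic) and `window = 0, exact_length =
#' guide_length` (the accurately-processed-mature fraction shown in pie
#' charts — under exact mapping this is exactly the mature guide read).
#'
#' @param cls a [classify_forms()] result.
#' @param window maximum absolute 5' offset (`Inf` allowed).
#' @param exact_length required read length, or `NULL` for any.
#' @return fraction in [0, 1].
#' @export
processing_accuracy <- function(cls, window = 4L, exact_length = NULL) {
  stopifnot(inherits(cls, "FormClassification"))
  if (cls$denominator <= 0)
    stop("processing_accuracy: no qualifying reads (denominator zero); accuracy undefined")
  cells <- cls$cells
  sel <- abs(cells$offset) <= window
  if (!is.null(exact_length)) sel <- sel & cells$length == exact_length
  sum(cells$weighted_count[sel]) / cls$denominator
}
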