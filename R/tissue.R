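# Expressed/unexpressed calls and tissue specificity. On the barcode z-score
# scale a probe counts as expressed in a sample when its value is strictly
# greater than 2.54.

#' Per-tissue expressed fractions
#'
#' For each probe and tissue, the fraction of that tissue's samples in which
#' the probe is called expressed (value strictly greater than
#' `expression_threshold`).
#'
#' @param x Expression matrix (probes x samples).
#' @param samples Sample table aligned to `x` columns.
#' @param expression_threshold Expressed-call threshold on the z-score scale.
#'   Default 2.54.
#' @param class Restrict to samples of this class before tabulating
#'   (`"normal"` by default, matching tissue-specificity definitions); use
#'   `NULL` for all samples.
#' @return An object of class `expression_calls`: list with `fraction`
#'   (probes x tissues matrix), `n` (named sample counts per tissue) and
#'   `threshold`.
#' @export
expression_calls <- function(x, samples, expression_threshold = 2.54,
                             class = "normal") {
  stopifnot(nrow(samples) == ncol(x))
  keep <- if (is.null(class)) rep(TRUE, nrow(samples)) else samples$class == class
  if (!any(keep)) stop("no samples of class ", class, call. = FALSE)
  tissue <- samples$tissue[keep]
  if (any(is.na(tissue) | tissue == "")) stop("missing tissue labels", call. = FALSE)
  xx <- x[, keep, drop = FALSE]
  tissues <- sort(unique(tissue))
  frac <- vapply(tissues, function(t) rowMeans(xx[, tissue == t, drop = FALSE] > expression_threshold),
                 numeric(nrow(xx)))
  frac <- matrix(frac, nrow = nrow(xx), dimnames = list(rownames(xx), tissues))
  structure(list(fraction = frac,
                 n = stats::setNames(as.integer(table(tissue)[tissues]), tissues),
                 threshold = expression_threshold),
            class = "expression_calls")
}

#' Tissue-specific probes
#'
#' A probe is tissue-specific when it is expressed in strictly more than
#' `frac_threshold` of the samples of at least one and at most `max_tissues`
#' tissues. Only tissues with strictly more than `min_samples` samples in the
#' call table are counted.
#'
#' @param calls An `expression_calls` object.
#' @param frac_threshold Strict expressed-fraction threshold. Default 0.95.
#' @param max_tissues Maximum number of tissues a specific probe may be
#'   expressed in. Default 3.
#' @param min_samples Tissues with at most this many samples are ignored
#'   (strict "more than"). Default 10.
#' @return Character vector of tissue-specific probe ids, in call-table row
#'   order.
#' @export
tissue_specific_genes <- function(calls, frac_threshold = 0.95, max_tissues = 3,
                                  min_samples = 10) {
  stopifnot(inherits(calls, "expression_calls"))
  keep <- calls$n > min_samples
  if (!any(keep)) stop(sprintf("no tissue has more than %d samples", min_samples), call. = FALSE)
  frac <- calls$fraction[, keep, drop = FALSE]
  n_expressed <- rowSums(frac > frac_threshold)
  rownames(frac)[n_expressed >= 1L & n_expressed <= max_tissues]
}

#' Consistently expressed probes per tissue
#'
#' A probe is consistently expressed for a tissue when it is expressed in at
#' least `frac_threshold` of that tissue's samples (non-strict, "at least").
#'
#' @param calls An `expression_calls` object.
#' @param frac_threshold Non-strict expressed-fraction threshold. Default 0.95.
#' @return Named list mapping tissue to the character vector of its
#'   consistently expressed probe ids.
#' @export
consistently_expressed <- function(calls, frac_threshold = 0.95) {
  stopifnot(inherits(calls, "expression_calls"))
  out <- lapply(colnames(calls$fraction), function(t) {
    rownames(calls$fraction)[calls$fraction[, t] >= frac_threshold]
  })
  stats::setNames(out, colnames(calls$fraction))
}
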