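# Hyper-variability statistics and robust normal ranges.
#
# For one cancer/normal comparison the selection statistic per probe g is
#   r_g = log2(s_gc / s_gn)
# where s_gc, s_gn are across-sample SDs of expression among cancer and normal
# samples. r_g > 1 means the SD in cancer is more than twice that in normals.
# Across many tissues/cancer types the universal statistic is
#   u_g = log2(mean_c s_gc / mean_t s_gt)
# with per-type SDs averaged unweighted over cancer types c and normal tissues
# t. Normal ranges are median +/- k * MAD (raw MAD, no consistency constant).

#' Cancer/normal variance ratio statistic
#'
#' Computes, per probe, the across-sample SD of expression in normal and in
#' cancer samples (sample SD, n - 1 denominator) and the log2 ratio
#' `r = log2(s_cancer / s_normal)`. Probes with zero SD in either class are
#' flagged degenerate and carry `ratio = NA`; they are excluded from selection.
#'
#' @param x Expression matrix (probes x samples).
#' @param samples Sample table aligned to `x` columns; only rows with class
#'   `normal` or `cancer` are used.
#' @return A data.frame with columns `probe_id`, `s_normal`, `s_cancer`,
#'   `ratio`, `degenerate`.
#' @export
variance_ratio <- function(x, samples) {
  stopifnot(nrow(samples) == ncol(x))
  norm_cols <- which(samples$class == "normal")
  canc_cols <- which(samples$class == "cancer")
  if (length(norm_cols) < 2L || length(canc_cols) < 2L)
    stop(sprintf("need at least 2 samples per class (normal: %d, cancer: %d)",
                 length(norm_cols), length(canc_cols)), call. = FALSE)
  s_n <- row_sd(x[, norm_cols, drop = FALSE])
  s_c <- row_sd(x[, canc_cols, drop = FALSE])
  degenerate <- s_n == 0 | s_c == 0
  r <- ifelse(degenerate, NA_real_, log2(s_c / s_n))
  data.frame(probe_id = rownames(x), s_normal = s_n, s_cancer = s_c,
             ratio = r, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select hyper-variable probes
#'
#' Selects probes by the variance ratio statistic, either all probes with
#' statistic strictly above a threshold or the `n_top` largest. Degenerate
#' probes are excluded. Results are ordered by statistic descending with ties
#' broken by probe id ascending, so selection is deterministic.
#'
#' @param ratios Data.frame from [variance_ratio()] or
#'   [universal_statistics()] (`$ratios`): needs columns `probe_id`, `ratio`,
#'   `degenerate`.
#' @param mode `"threshold"` or `"top"`.
#' @param threshold Strict lower bound on the statistic in threshold mode.
#'   Default 1 (at least a twofold SD increase in cancer).
#' @param n_top Number of probes kept in top mode. Default 100.
#' @return Character vector of selected probe ids, best first.
#' @export
select_hypervariable <- function(ratios, mode = c("threshold", "top"),
                                 threshold = 1, n_top = 100) {
  mode <- match.arg(mode)
  elig <- ratios[!ratios$degenerate & !is.na(ratios$ratio), , drop = FALSE]
  elig <- elig[order(-elig$ratio, elig$probe_id), , drop = FALSE]
  if (mode == "threshold") {
    return(elig$probe_id[elig$ratio > threshold])
  }
  if (n_top > nrow(elig))
    stop(sprintf("n_top = %d exceeds the %d eligible probes", n_top, nrow(elig)),
         call. = FALSE)
  elig$probe_id[seq_len(n_top)]
}

#' Robust normal ranges of expression
#'
#' For each requested probe, the range is
#' `median +/- k * MAD` computed over the normal samples, with the raw MAD
#' (median absolute deviation from the median, no consistency constant by
#' default). A probe with zero MAD keeps its (collapsed) range but is flagged
#' degenerate: any deviation from the median then counts as outside.
#'
#' @param x Expression matrix (probes x samples).
#' @param samples Sample table aligned to `x` columns.
#' @param probes Character vector of probe ids; all must be rows of `x`.
#' @param k MAD multiplier. Default 5.
#' @param mad_constant Multiplier applied to the raw MAD (set to 1.4826 for
#'   normal-consistency sensitivity analyses). Default 1.
#' @return Data.frame with columns `probe_id`, `center`, `spread`, `lower`,
#'   `upper`, `degenerate`.
#' @export
normal_ranges <- function(x, samples, probes, k = 5, mad_constant = 1) {
  stopifnot(nrow(samples) == ncol(x))
  missing_probes <- setdiff(probes, rownames(x))
  if (length(missing_probes))
    stop("probe(s) absent from matrix: ", paste(missing_probes, collapse = ", "),
         call. = FALSE)
  norm_cols <- which(samples$class == "normal")
  if (length(norm_cols) < 1L) stop("no normal samples", call. = FALSE)
  m <- x[probes, norm_cols, drop = FALSE]
  center <- row_median(m)
  spread <- row_mad(m, constant = mad_constant)
  data.frame(probe_id = probes, center = center, spread = spread,
             lower = center - k * spread, upper = center + k * spread,
             degenerate = spread == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-tissue dispersion summaries and the universal variance ratio
#'
#' Computes, per probe, the SD of expression separately within each normal
#' tissue (`s_gt`, over normal samples grouped by tissue) and within each
#' cancer type (`s_gc`, over cancer samples grouped by tissue label), keeping
#' only tissues and cancer types with strictly more than `min_samples`
#' samples. The universal statistic is
#' `u = log2(mean_c s_gc / mean_t s_gt)` with unweighted means over types.
#' Per-tissue medians and MADs (`m_gt`, `mad_gt`) and their across-tissue
#' medians (`m_g`, `mad_g`) feed [universal_ranges()].
#'
#' @param x Expression matrix (probes x samples).
#' @param samples Sample table aligned to `x` columns with `class` and
#'   `tissue`.
#' @param min_samples Tissues/cancer types with at most this many samples are
#'   excluded (strict "more than"). Default 10.
#' @return A list of class `tissue_summary` with elements `tissues`,
#'   `cancer_types`, `s_gt`, `s_gc`, `m_gt`, `mad_gt`, `m_g`, `mad_g`
#'   (matrices/vectors indexed by probe) and `ratios`, a data.frame shaped as
#'   [variance_ratio()] output with the universal statistic in `ratio`.
#' @export
universal_statistics <- function(x, samples, min_samples = 10) {
  stopifnot(nrow(samples) == ncol(x))
  norm <- samples$class == "normal"
  canc <- samples$class == "cancer"
  t_counts <- table(samples$tissue[norm])
  c_counts <- table(samples$tissue[canc])
  tissues <- names(t_counts)[t_counts > min_samples]
  cancer_types <- names(c_counts)[c_counts > min_samples]
  if (!length(tissues) || !length(cancer_types))
    stop(sprintf("no %s with more than %d samples",
                 if (!length(tissues)) "normal tissue" else "cancer type", min_samples),
         call. = FALSE)
  group_cols <- function(keep, labels, groups) {
    lapply(groups, function(g) which(keep & labels == g))
  }
  t_cols <- group_cols(norm, samples$tissue, tissues)
  c_cols <- group_cols(canc, samples$tissue, cancer_types)
  per_group <- function(cols, fun) {
    matrix(vapply(cols, function(j) fun(x[, j, drop = FALSE]), numeric(nrow(x))),
           nrow = nrow(x))
  }
  s_gt <- per_group(t_cols, row_sd)
  s_gc <- per_group(c_cols, row_sd)
  m_gt <- per_group(t_cols, row_median)
  mad_gt <- per_group(t_cols, row_mad)
  dimnames(s_gt) <- dimnames(m_gt) <- dimnames(mad_gt) <- list(rownames(x), tissues)
  dimnames(s_gc) <- list(rownames(x), cancer_types)
  mean_t <- rowMeans(s_gt)
  mean_c <- rowMeans(s_gc)
  degenerate <- mean_t == 0 | mean_c == 0
  u <- ifelse(degenerate, NA_real_, log2(mean_c / mean_t))
  summary <- structure(list(
    tissues = tissues, cancer_types = cancer_types,
    s_gt = s_gt, s_gc = s_gc, m_gt = m_gt, mad_gt = mad_gt,
    m_g = row_median(m_gt), mad_g = row_median(mad_gt),
    min_samples = min_samples), class = "tissue_summary")
  ratios <- data.frame(probe_id = rownames(x), s_normal = mean_t, s_cancer = mean_c,
                       ratio = u, degenerate = degenerate,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, ratios = ratios)
}

#' Universal normal ranges
#'
#' The universal range for probe g is `m_g +/- k * mad_g`, where `m_g` is the
#' median over qualifying tissues of the per-tissue medians and `mad_g` the
#' median of the per-tissue MADs (see [universal_statistics()]).
#'
#' @param summary A `tissue_summary` from [universal_statistics()].
#' @param probes Probe ids to return ranges for.
#' @param k MAD multiplier. Default 5.
#' @return Data.frame shaped as [normal_ranges()] output.
#' @export
universal_ranges <- function(summary, probes, k = 5) {
  stopifnot(inherits(summary, "tissue_summary"))
  missing_probes <- setdiff(probes, names(summary$m_g))
  if (length(missing_probes))
    stop("probe(s) absent from tissue summary: ", paste(missing_probes, collapse = ", "),
         call. = FALSE)
  center <- summary$m_g[probes]
  spread <- summary$mad_g[probes]
  data.frame(probe_id = probes, center = unname(center), spread = unname(spread),
             lower = unname(center - k * spread), upper = unname(center + k * spread),
             degenerate = unname(spread == 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
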