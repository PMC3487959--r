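# The anti-profile model: an ordered set of probes that are hyper-variable in
# cancer, each with a robust range of normal expression. A sample's
# anti-profile score is the number of signature probes whose expression falls
# outside its range; high scores indicate cancer.

#' Fit an anti-profile
#'
#' Builds an anti-profile from a standardized expression matrix and sample
#' metadata. The build proceeds in three stages, each confined to the data
#' passed in (so cross-validation can rerun the whole build on training
#' folds): (1) candidate restriction — to probes whose transcription start
#' site lies in supplied genomic blocks, to tissue-specific probes computed
#' from the normal samples, or none; (2) hyper-variability selection — by the
#' cancer/normal SD ratio statistic `r = log2(s_cancer/s_normal)` or the
#' across-type universal statistic `u`, either all probes with statistic
#' strictly above a threshold or the top `n_top`; (3) robust normal ranges —
#' `median +/- k * MAD` over normal samples (per-comparison) or the universal
#' range `m_g +/- k * mad_g` of across-tissue medians.
#'
#' @param x Expression matrix (probes x samples), barcode z-score scale.
#' @param samples Sample table aligned to the columns of `x` with columns
#'   `sample_id`, `class` (`normal`/`cancer`/`other`) and `tissue`. `other`
#'   samples are ignored.
#' @param statistic `"sd_ratio"` for a single cancer/normal comparison or
#'   `"universal"` for the across-tissue statistic (which also switches the
#'   ranges to universal ranges).
#' @param selection `"threshold"` (statistic strictly greater than
#'   `threshold`) or `"top"` (largest `n_top`).
#' @param threshold Selection threshold. Default 1.
#' @param n_top Signature size in top mode. Default 100.
#' @param k MAD multiplier defining range width. Default 5.
#' @param restriction `"none"`, `"blocks"` (requires `annotation` and
#'   `blocks`) or `"tissue_specific"` (computed from the normal samples of
#'   `x`).
#' @param annotation Probe annotation for `restriction = "blocks"`.
#' @param blocks Genomic block data.frame for `restriction = "blocks"`.
#' @param candidates Optional explicit probe subset applied before any other
#'   restriction.
#' @param expression_threshold Expressed-call z-score threshold for
#'   tissue-specific restriction. Default 2.54.
#' @param specific_frac Strict expressed-fraction threshold for tissue
#'   specificity. Default 0.95.
#' @param max_tissues Maximum home tissues for a tissue-specific probe.
#'   Default 3.
#' @param min_tissue_samples Tissues/cancer types with at most this many
#'   samples are excluded from universal statistics and tissue-specific
#'   calls. Default 10.
#' @param mad_constant Multiplier on the raw MAD (1 = raw). Default 1.
#' @return An object of class `antiprofile`: list with `probes` (data.frame
#'   `probe_id`, `center`, `spread`, `lower`, `upper`, `degenerate`,
#'   `statistic`, ordered by decreasing statistic), `k`, `statistic`,
#'   `selection` metadata, `n_normal`, `n_cancer` and the matched `call`.
#' @examples
#' sim <- simulate_two_class(n_probes = 300, n_normal = 20, n_cancer = 20,
#'                           n_planted = 30, seed = 1)
#' ap <- antiprofile(sim$expr, sim$samples)
#' ap
#' head(predict(ap, sim$expr))
#' @export
antiprofile <- function(x, samples,
                        statistic = c("sd_ratio", "universal"),
                        selection = c("threshold", "top"),
                        threshold = 1, n_top = 100, k = 5,
                        restriction = c("none", "blocks", "tissue_specific"),
                        annotation = NULL, blocks = NULL, candidates = NULL,
                        expression_threshold = 2.54, specific_frac = 0.95,
                        max_tissues = 3, min_tissue_samples = 10,
                        mad_constant = 1) {
  statistic <- match.arg(statistic)
  selection <- match.arg(selection)
  restriction <- match.arg(restriction)
  validate_expression_matrix(x)
  stopifnot(nrow(samples) == ncol(x))

  keep <- samples$class %in% c("normal", "cancer")
  x <- x[, keep, drop = FALSE]
  samples <- samples[keep, , drop = FALSE]

  pool <- candidates %||% rownames(x)
  missing_probes <- setdiff(pool, rownames(x))
  if (length(missing_probes))
    stop("candidate probe(s) absent from matrix: ",
         paste(missing_probes, collapse = ", "), call. = FALSE)
  if (restriction == "blocks") {
    if (is.null(annotation) || is.null(blocks))
      stop("restriction = 'blocks' needs 'annotation' and 'blocks'", call. = FALSE)
    pool <- restrict_to_blocks(pool, annotation, blocks)
  } else if (restriction == "tissue_specific") {
    calls <- expression_calls(x, samples, expression_threshold = expression_threshold,
                              class = "normal")
    specific <- tissue_specific_genes(calls, frac_threshold = specific_frac,
                                      max_tissues = max_tissues,
                                      min_samples = min_tissue_samples)
    pool <- intersect(pool, specific)
  }
  if (!length(pool))
    stop("candidate restriction left no probes; relax the restriction", call. = FALSE)

  xr <- x[pool, , drop = FALSE]
  summary <- NULL
  if (statistic == "sd_ratio") {
    ratios <- variance_ratio(xr, samples)
  } else {
    us <- universal_statistics(xr, samples, min_samples = min_tissue_samples)
    ratios <- us$ratios
    summary <- us$summary
  }
  selected <- select_hypervariable(ratios, mode = selection,
                                   threshold = threshold, n_top = n_top)
  if (!length(selected))
    stop("no probes passed selection; lower 'threshold' or use selection = 'top'",
         call. = FALSE)

  ranges <- if (statistic == "sd_ratio") {
    normal_ranges(x, samples, selected, k = k, mad_constant = mad_constant)
  } else {
    universal_ranges(summary, selected, k = k)
  }
  ranges$statistic <- ratios$ratio[match(selected, ratios$probe_id)]

  structure(list(
    probes = ranges,
    k = k,
    statistic = statistic,
    selection = list(mode = selection, threshold = threshold, n_top = n_top,
                     restriction = restriction,
                     pool_size = length(pool)),
    mad_constant = mad_constant,
    n_normal = sum(samples$class == "normal"),
    n_cancer = sum(samples$class == "cancer"),
    call = match.call()), class = "antiprofile")
}

#' Anti-profile scores
#'
#' Counts, per sample, the signature probes whose expression falls strictly
#' outside their normal range (`value < lower` or `value > upper`; boundary
#' values count as inside). Works on any matrix sharing probe ids with the
#' signature, so a signature trained on one dataset can score another without
#' retraining.
#'
#' @param profile An `antiprofile` object.
#' @param x Expression matrix containing every signature probe.
#' @return Data.frame with columns `sample_id`, `score` (integer) and
#'   `n_profile`.
#' @export
score_samples <- function(profile, x) {
  stopifnot(inherits(profile, "antiprofile"))
  pr <- profile$probes
  missing_probes <- setdiff(pr$probe_id, rownames(x))
  if (length(missing_probes))
    stop("signature probe(s) missing from matrix: ",
         paste(missing_probes, collapse = ", "), call. = FALSE)
  v <- x[pr$probe_id, , drop = FALSE]
  outside <- v < pr$lower | v > pr$upper
  data.frame(sample_id = colnames(x),
             score = as.integer(colSums(outside)),
             n_profile = nrow(pr),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify samples from anti-profile scores
#'
#' Scores strictly greater than `cutoff` are called cancer; scores at or below
#' the cutoff are called normal.
#'
#' @param scores Data.frame from [score_samples()] (or any with `sample_id`
#'   and `score`).
#' @param cutoff Score cutoff.
#' @return Data.frame with columns `sample_id`, `score`, `class`.
#' @export
classify <- function(scores, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  data.frame(sample_id = scores$sample_id, score = scores$score,
             class = ifelse(scores$score > cutoff, "cancer", "normal"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @method print antiprofile
#' @export
print.antiprofile <- function(x, ...) {
  cat(sprintf("Anti-profile: %d probes (statistic: %s, selection: %s, restriction: %s)\n",
              nrow(x$probes), x$statistic, x$selection$mode, x$selection$restriction))
  cat(sprintf("Normal range: median +/- %g * MAD (trained on %d normal / %d cancer samples)\n",
              x$k, x$n_normal, x$n_cancer))
  if (any(x$probes$degenerate))
    cat(sprintf("%d probe(s) have zero MAD (degenerate collapsed range)\n",
                sum(x$probes$degenerate)))
  invisible(x)
}

#' @method summary antiprofile
#' @export
summary.antiprofile <- function(object, ...) {
  pr <- object$probes
  out <- list(n_probes = nrow(pr), k = object$k, statistic = object$statistic,
              selection = object$selection,
              statistic_range = range(pr$statistic),
              width_quartiles = stats::quantile(pr$upper - pr$lower, c(.25, .5, .75)),
              n_degenerate = sum(pr$degenerate))
  class(out) <- "summary.antiprofile"
  out
}

#' @method print summary.antiprofile
#' @export
print.summary.antiprofile <- function(x, ...) {
  cat(sprintf("Anti-profile with %d probes (statistic %s in [%.3f, %.3f])\n",
              x$n_probes, x$statistic, x$statistic_range[1], x$statistic_range[2]))
  cat(sprintf("Range width quartiles: %.3f / %.3f / %.3f (k = %g)\n",
              x$width_quartiles[1], x$width_quartiles[2], x$width_quartiles[3], x$k))
  cat(sprintf("Selection: %s (restriction: %s, candidate pool %d); %d degenerate probe(s)\n",
              x$selection$mode, x$selection$restriction, x$selection$pool_size,
              x$n_degenerate))
  invisible(x)
}

#' @method coef antiprofile
#' @export
coef.antiprofile <- function(object, ...) {
  pr <- object$probes
  m <- as.matrix(pr[, c("center", "spread", "lower", "upper")])
  rownames(m) <- pr$probe_id
  m
}

#' Predict method for anti-profiles
#'
#' @param object An `antiprofile`.
#' @param newdata Expression matrix to score.
#' @param type `"score"` for the integer anti-profile score, `"class"` for a
#'   cancer/normal call (requires `cutoff`).
#' @param cutoff Score cutoff for `type = "class"`.
#' @param ... Unused.
#' @return Named integer vector of scores, or named character vector of class
#'   calls.
#' @method predict antiprofile
#' @export
predict.antiprofile <- function(object, newdata, type = c("score", "class"),
                                cutoff = NULL, ...) {
  type <- match.arg(type)
  sc <- score_samples(object, newdata)
  if (type == "score")
    return(stats::setNames(sc$score, sc$sample_id))
  if (is.null(cutoff)) stop("type = 'class' needs a 'cutoff'", call. = FALSE)
  cl <- classify(sc, cutoff)
  stats::setNames(cl$class, cl$sample_id)
}

#' Residuals method: signed exceedance beyond the normal range
#'
#' Returns a probes-by-samples matrix that is 0 where expression lies inside
#' the normal range, `value - upper` above it and `value - lower` (negative)
#' below it. Column sums of `residuals != 0` reproduce the anti-profile
#' scores.
#'
#' @param object An `antiprofile`.
#' @param newdata Expression matrix containing every signature probe.
#' @param ... Unused.
#' @return Numeric matrix, signature probes x samples.
#' @method residuals antiprofile
#' @export
residuals.antiprofile <- function(object, newdata, ...) {
  pr <- object$probes
  missing_probes <- setdiff(pr$probe_id, rownames(newdata))
  if (length(missing_probes))
    stop("signature probe(s) missing from matrix: ",
         paste(missing_probes, collapse = ", "), call. = FALSE)
  v <- newdata[pr$probe_id, , drop = FALSE]
  res <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
  above <- v > pr$upper
  below <- v < pr$lower
  res[above] <- (v - pr$upper)[above]
  res[below] <- (v - pr$lower)[below]
  res
}

#' Simulate normal-like samples from a fitted anti-profile
#'
#' Draws samples from independent Gaussians per signature probe, centered at
#' the range center with SD `1.4826 * spread` (the normal-consistent scaling
#' of the raw MAD). Useful as a parametric bootstrap of the "normal
#' phenotype" the signature encodes.
#'
#' @param object An `antiprofile`.
#' @param nsim Number of samples. Default 1.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Expression matrix, signature probes x `nsim` samples.
#' @method simulate antiprofile
#' @export
simulate.antiprofile <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) withr::local_seed(seed)
  pr <- object$probes
  m <- matrix(stats::rnorm(nrow(pr) * nsim, mean = pr$center, sd = 1.4826 * pr$spread),
              nrow = nrow(pr),
              dimnames = list(pr$probe_id, sprintf("sim%03d", seq_len(nsim))))
  m
}

#' Plot anti-profile scores
#'
#' Strip chart of anti-profile scores, grouped by class when labels are
#' supplied.
#'
#' @param x An `antiprofile`.
#' @param newdata Expression matrix to score.
#' @param labels Optional class labels aligned to `newdata` columns.
#' @param cutoff Optional score cutoff drawn as a horizontal line.
#' @param ... Passed to [graphics::stripchart()].
#' @return The score data.frame, invisibly.
#' @method plot antiprofile
#' @export
plot.antiprofile <- function(x, newdata, labels = NULL, cutoff = NULL, ...) {
  sc <- score_samples(x, newdata)
  if (is.null(labels)) {
    graphics::stripchart(sc$score, method = "jitter", vertical = TRUE,
                         pch = 19, ylab = "anti-profile score", ...)
  } else {
    graphics::stripchart(sc$score ~ factor(labels), method = "jitter",
                         vertical = TRUE, pch = 19,
                         ylab = "anti-profile score", xlab = "class", ...)
  }
  if (!is.null(cutoff)) graphics::abline(h = cutoff, lty = 2)
  invisible(sc)
}

#' Write an anti-profile signature file
#'
#' The signature serializes as a TSV of `(probe_id, median, mad)` rows
#' preceded by `# key=value` header lines carrying the MAD multiplier `k` and
#' provenance metadata. Values are written at full precision so
#' write-then-read is the identity.
#'
#' @param profile An `antiprofile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_antiprofile <- function(profile, path) {
  stopifnot(inherits(profile, "antiprofile"))
  pr <- profile$probes
  hdr <- c(sprintf("# k=%s", num_chr(profile$k)),
           sprintf("# statistic=%s", profile$statistic),
           sprintf("# selection=%s", profile$selection$mode),
           sprintf("# restriction=%s", profile$selection$restriction),
           sprintf("# n_degenerate=%d", sum(pr$degenerate)))
  body <- data.frame(probe_id = pr$probe_id,
                     median = num_chr(pr$center),
                     mad = num_chr(pr$spread),
                     statistic = num_chr(pr$statistic),
                     stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an anti-profile signature file
#'
#' @param path Path written by [write_antiprofile()] (or any TSV of
#'   `probe_id`, `median`, `mad` with `# key=value` headers).
#' @return An `antiprofile` object; `lower`/`upper` are reconstructed from
#'   the stored medians, MADs and `k`.
#' @export
read_antiprofile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
  }
  k <- as.numeric(meta$k %||% 5)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  need <- c("probe_id", "median", "mad")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("signature file missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe id(s) in signature: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$median)) || any(!is.finite(df$mad)))
    stop("malformed signature row: non-numeric median or mad", call. = FALSE)
  if (any(df$mad < 0)) stop("negative mad in signature file", call. = FALSE)
  ranges <- data.frame(probe_id = df$probe_id, center = df$median, spread = df$mad,
                       lower = df$median - k * df$mad, upper = df$median + k * df$mad,
                       degenerate = df$mad == 0,
                       statistic = if ("statistic" %in% names(df)) df$statistic else NA_real_,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(probes = ranges, k = k,
                 statistic = meta$statistic %||% NA_character_,
                 selection = list(mode = meta$selection %||% NA_character_,
                                  threshold = NA_real_, n_top = NA_integer_,
                                  restriction = meta$restriction %||% NA_character_,
                                  pool_size = NA_integer_),
                 mad_constant = 1,
                 n_normal = NA_integer_, n_cancer = NA_integer_,
                 call = match.call()), class = "antiprofile")
}
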