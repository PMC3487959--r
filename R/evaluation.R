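# Classifier evaluation and statistical testing: ROC/AUC by the Mann-Whitney
# identity with midrank tie handling, stratified k-fold and
# leave-one-tissue-out cross-validation (the whole anti-profile build reruns
# on every training set), the random-signature significance test, variance
# F-tests, BH FDR control, and 2x2 set-enrichment testing.

#' ROC curve and AUC for anti-profile scores
#'
#' The AUC is the probability that a random cancer sample scores higher than
#' a random normal sample, with half credit for ties — the Mann-Whitney
#' statistic computed from midranks. The full ROC step curve (sensitivity and
#' specificity as a function of the "score > threshold" rule) is returned.
#'
#' @param scores Numeric vector of scores, or a data.frame from
#'   [score_samples()].
#' @param labels Class labels (`normal`/`cancer`) aligned to the scores; for a
#'   data.frame input a named vector or a vector aligned to its rows.
#' @return Object of class `roc_result`: list with `auc`, `thresholds`,
#'   `sensitivity`, `specificity`, `n_cancer`, `n_normal`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.data.frame(scores)) {
    if (!is.null(names(labels))) labels <- labels[scores$sample_id]
    scores <- scores$score
  }
  stopifnot(length(scores) == length(labels))
  is_cancer <- labels == "cancer"
  n1 <- sum(is_cancer); n0 <- sum(!is_cancer)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be represented to compute a ROC curve", call. = FALSE)
  r <- rank(scores)  # midranks
  auc <- (sum(r[is_cancer]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(scores[is_cancer] > t), numeric(1L))
  spec <- vapply(thr, function(t) mean(scores[!is_cancer] <= t), numeric(1L))
  structure(list(auc = auc, thresholds = thr, sensitivity = sens,
                 specificity = spec, n_cancer = n1, n_normal = n0),
            class = "roc_result")
}

#' @method print roc_result
#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d cancer vs %d normal, %d thresholds)\n",
              x$auc, x$n_cancer, x$n_normal, length(x$thresholds)))
  invisible(x)
}

#' Write a ROC curve as TSV
#' @param roc A `roc_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  utils::write.table(
    data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
               specificity = roc$specificity),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# assign stratified folds: within each class, shuffle then deal round-robin
stratified_folds <- function(classes, n_folds) {
  fold <- integer(length(classes))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    if (length(idx) < n_folds)
      stop(sprintf("class '%s' has %d samples, fewer than %d folds",
                   cl, length(idx), n_folds), call. = FALSE)
    idx <- sample(idx)
    fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the anti-profile
#'
#' Samples are split into `n_folds` folds preserving the normal/cancer
#' proportion (remainders dealt round-robin within class). For each fold the
#' complete anti-profile build — candidate restriction, hyper-variability
#' selection and range estimation — is rerun on the training samples only;
#' the held-out fold is then scored and a per-fold ROC computed.
#'
#' @param x Expression matrix (probes x samples).
#' @param samples Sample table aligned to `x` columns.
#' @param build_args Named list of arguments passed to [antiprofile()] for
#'   each training fold.
#' @param n_folds Number of folds. Default 10.
#' @param seed Optional integer seed controlling the fold assignment.
#' @return Object of class `cv_report`: list with `type`, `fold` (per-sample
#'   assignment), `scores` (data.frame with cross-validated scores), `rocs`
#'   (per-fold `roc_result`), `auc` (per-fold AUCs), `profiles` (per-fold
#'   selected probe ids) and `train_ids` (per-fold training sample ids).
#' @export
stratified_kfold_cv <- function(x, samples, build_args = list(), n_folds = 10,
                                seed = NULL) {
  stopifnot(nrow(samples) == ncol(x))
  if (!is.null(seed)) withr::local_seed(seed)
  keep <- samples$class %in% c("normal", "cancer")
  x <- x[, keep, drop = FALSE]
  samples <- samples[keep, , drop = FALSE]
  fold <- stratified_folds(samples$class, n_folds)
  run_cv(x, samples, split = fold, split_labels = as.character(seq_len(n_folds)),
         build_args = build_args, type = "kfold")
}

#' Leave-one-tissue-out cross-validation
#'
#' For each tissue, all of its samples (normal and cancer) are held out, the
#' complete anti-profile build is rerun on the remaining tissues, and the
#' held-out tissue's samples are scored. This measures generalization to
#' tissues absent from training.
#'
#' @param x Expression matrix (probes x samples).
#' @param samples Sample table aligned to `x` columns.
#' @param build_args Named list of arguments passed to [antiprofile()].
#' @param tissues Tissues to hold out; defaults to every tissue with both a
#'   normal and a cancer sample. Each held-out tissue must contain both
#'   classes.
#' @return A `cv_report` (see [stratified_kfold_cv()]) with `type`
#'   `"leave_one_tissue_out"` and folds named by tissue.
#' @export
leave_one_tissue_out_cv <- function(x, samples, build_args = list(),
                                    tissues = NULL) {
  stopifnot(nrow(samples) == ncol(x))
  keep <- samples$class %in% c("normal", "cancer")
  x <- x[, keep, drop = FALSE]
  samples <- samples[keep, , drop = FALSE]
  if (is.null(tissues)) {
    tab <- table(samples$tissue, samples$class)
    tissues <- rownames(tab)[tab[, "normal"] > 0 & tab[, "cancer"] > 0]
  }
  if (length(tissues) < 2L)
    stop("need at least 2 eligible tissues for leave-one-tissue-out CV", call. = FALSE)
  for (t in tissues) {
    cls <- samples$class[samples$tissue == t]
    if (!all(c("normal", "cancer") %in% cls))
      stop(sprintf("held-out tissue '%s' lacks %s samples", t,
                   setdiff(c("normal", "cancer"), cls)[1L]), call. = FALSE)
  }
  split <- match(samples$tissue, tissues)  # NA = never held out, always trains
  run_cv(x, samples, split = split, split_labels = tissues,
         build_args = build_args, type = "leave_one_tissue_out")
}

# shared CV engine: split[i] gives the fold in which sample i is TESTED
# (NA = train-only sample)
run_cv <- function(x, samples, split, split_labels, build_args, type) {
  n_folds <- length(split_labels)
  scores <- vector("list", n_folds)
  rocs <- vector("list", n_folds)
  profiles <- vector("list", n_folds)
  train_ids <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- which(!is.na(split) & split == f)
    train <- setdiff(seq_len(nrow(samples)), test)
    ap <- do.call(antiprofile,
                  c(list(x = x[, train, drop = FALSE],
                         samples = samples[train, , drop = FALSE]),
                    build_args))
    sc <- score_samples(ap, x[, test, drop = FALSE])
    sc$fold <- split_labels[f]
    sc$class <- samples$class[test]
    scores[[f]] <- sc
    rocs[[f]] <- roc_auc(sc$score, sc$class)
    profiles[[f]] <- ap$probes$probe_id
    train_ids[[f]] <- samples$sample_id[train]
  }
  names(rocs) <- names(profiles) <- names(train_ids) <- split_labels
  structure(list(type = type,
                 fold = stats::setNames(split_labels[split], samples$sample_id),
                 scores = do.call(rbind, scores),
                 rocs = rocs,
                 auc = vapply(rocs, `[[`, numeric(1L), "auc"),
                 profiles = profiles,
                 train_ids = train_ids), class = "cv_report")
}

#' @method print cv_report
#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d folds\n",
              if (x$type == "kfold") "Stratified k-fold" else "Leave-one-tissue-out",
              length(x$auc)))
  cat(sprintf("Per-fold AUC: %s\n", paste(sprintf("%.3f", x$auc), collapse = " ")))
  cat(sprintf("Mean AUC: %.4f\n", mean(x$auc)))
  invisible(x)
}

#' Serialize a CV report
#'
#' Writes cross-validated scores as TSV and a JSON summary (per-fold AUC,
#' mean AUC, fold sizes).
#'
#' @param report A `cv_report`.
#' @param score_path TSV output path for per-sample scores.
#' @param summary_path JSON output path.
#' @return Invisibly, the two paths.
#' @export
write_cv_report <- function(report, score_path, summary_path) {
  stopifnot(inherits(report, "cv_report"))
  utils::write.table(report$scores, score_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(type = report$type,
         auc = as.list(report$auc),
         mean_auc = mean(report$auc),
         fold_sizes = as.list(table(report$scores$fold)),
         profile_sizes = as.list(vapply(report$profiles, length, integer(1L)))),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(score_path, summary_path))
}

#' Random-signature significance test
#'
#' Draws `B` random probe subsets of the observed signature's size from a
#' candidate pool, scores the test samples with each (normal ranges are
#' estimated once, from the training normals, and do not change across
#' draws), and reports the empirical p-value
#' `p = (1 + #\{AUC_b >= observed\}) / (1 + B)`.
#'
#' @param x_train Training expression matrix (source of the normal ranges).
#' @param samples_train Training sample table.
#' @param x_test Test expression matrix.
#' @param samples_test Test sample table (class labels used for the ROC).
#' @param signature_size Number of probes per random signature.
#' @param observed_auc AUC of the signature under test.
#' @param B Number of random signatures. Default 1000.
#' @param pool Candidate probe ids to draw from; defaults to all probes of
#'   `x_train`.
#' @param k MAD multiplier for the ranges. Default 5.
#' @param mad_constant Multiplier on the raw MAD. Default 1.
#' @param seed Optional integer seed.
#' @return Object of class `randomization_result`: list with `observed_auc`,
#'   `null_auc` (length `B`), `p_value`, `signature_size`, `B`.
#' @export
randomization_test <- function(x_train, samples_train, x_test, samples_test,
                               signature_size, observed_auc, B = 1000,
                               pool = NULL, k = 5, mad_constant = 1,
                               seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  pool <- pool %||% rownames(x_train)
  if (length(pool) < signature_size)
    stop(sprintf("candidate pool (%d) smaller than signature size (%d)",
                 length(pool), signature_size), call. = FALSE)
  ranges <- normal_ranges(x_train, samples_train, pool, k = k,
                          mad_constant = mad_constant)
  v <- x_test[pool, , drop = FALSE]
  outside <- v < ranges$lower | v > ranges$upper
  labels <- samples_test$class
  null_auc <- vapply(seq_len(B), function(b) {
    idx <- sample.int(length(pool), signature_size)
    roc_auc(colSums(outside[idx, , drop = FALSE]), labels)$auc
  }, numeric(1L))
  p <- (1 + sum(null_auc >= observed_auc)) / (1 + B)
  structure(list(observed_auc = observed_auc, null_auc = null_auc,
                 p_value = p, signature_size = signature_size, B = B),
            class = "randomization_result")
}

#' @method print randomization_result
#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("Random-signature test: observed AUC %.4f vs %d random signatures of size %d\n",
              x$observed_auc, x$B, x$signature_size))
  cat(sprintf("Null AUC median %.3f; empirical p = %.4g\n",
              stats::median(x$null_auc), x$p_value))
  invisible(x)
}

#' Signature-size sweep
#'
#' Builds signatures of increasing size by adding probes in order of
#' decreasing hyper-variability (cancer/normal SD ratio on the training
#' data), scores the test set with each, and reports the AUC per size.
#' Ranges come from the training normals and do not change with size.
#'
#' @param x_train Training expression matrix.
#' @param samples_train Training sample table.
#' @param x_test Test expression matrix.
#' @param samples_test Test sample table.
#' @param sizes Integer vector of signature sizes (all >= 1).
#' @param pool Optional candidate probe ids (e.g. block-restricted); defaults
#'   to all probes.
#' @param k MAD multiplier. Default 5.
#' @param mad_constant Multiplier on the raw MAD. Default 1.
#' @return Data.frame with columns `size`, `auc`.
#' @export
signature_size_sweep <- function(x_train, samples_train, x_test, samples_test,
                                 sizes, pool = NULL, k = 5, mad_constant = 1) {
  if (any(sizes < 1L)) stop("signature sizes must be >= 1", call. = FALSE)
  pool <- pool %||% rownames(x_train)
  ratios <- variance_ratio(x_train[pool, , drop = FALSE], samples_train)
  ordered <- select_hypervariable(ratios, mode = "top",
                                  n_top = sum(!ratios$degenerate))
  if (any(sizes > length(ordered)))
    stop(sprintf("size exceeds the %d eligible probes", length(ordered)), call. = FALSE)
  ranges <- normal_ranges(x_train, samples_train, ordered, k = k,
                          mad_constant = mad_constant)
  v <- x_test[ordered, , drop = FALSE]
  outside <- v < ranges$lower | v > ranges$upper
  labels <- samples_test$class
  auc <- vapply(sizes, function(s) {
    roc_auc(colSums(outside[seq_len(s), , drop = FALSE]), labels)$auc
  }, numeric(1L))
  data.frame(size = as.integer(sizes), auc = auc)
}

#' Variance F-test
#'
#' Tests equality of variances between two groups with
#' `F = s1^2 / s2^2` on `(n1 - 1, n2 - 1)` degrees of freedom. The default
#' alternative is one-sided (`greater`: group 1 more variable), matching a
#' directional hyper-variability screen; `two.sided` is available.
#'
#' @param group1,group2 Numeric vectors with at least 2 values each.
#' @param alternative `"greater"` or `"two.sided"` (alias `"two_sided"`).
#' @return List with `statistic` (F), `p_value`, `df` (length-2).
#' @export
variance_f_test <- function(group1, group2, alternative = c("greater", "two.sided", "two_sided")) {
  alternative <- match.arg(alternative)
  if (alternative == "two_sided") alternative <- "two.sided"
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  vt <- stats::var.test(group1, group2, alternative = alternative)
  list(statistic = unname(vt$statistic), p_value = vt$p.value,
       df = unname(vt$parameter))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR-adjusted values (q-values in the BH sense); thresholding the
#' output at level alpha controls the FDR at alpha.
#'
#' @param p_values Numeric vector of p-values.
#' @return Numeric vector of BH-adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Set-enrichment test (2x2 / hypergeometric)
#'
#' Builds the 2x2 membership table of two probe sets over a common universe
#' and tests for enrichment (one-sided). The reported odds ratio is the
#' sample (cross-product) odds ratio `(n11 * n22) / (n12 * n21)`; the p-value
#' is the one-sided hypergeometric tail (Fisher's exact test, alternative =
#' greater).
#'
#' @param set_a,set_b Probe id vectors, both subsets of `universe`.
#' @param universe Probe id vector.
#' @return List with `odds_ratio`, `p_value`, `table` (2x2 matrix).
#' @export
enrichment_fisher <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (length(setdiff(set_a, universe)))
    stop("set_a contains probes outside the universe", call. = FALSE)
  if (length(setdiff(set_b, universe)))
    stop("set_b contains probes outside the universe", call. = FALSE)
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(odds_ratio = or, p_value = p, table = tab)
}
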