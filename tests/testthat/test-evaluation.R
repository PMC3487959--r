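test_that("AUC matches exhaustive pair enumeration and handles ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4, 5, 6), rep(c("normal", "cancer"), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(2, 8), rep(c("normal", "cancer"), 4))$auc, 0.5)
  # 6 wins + 2 half-credit ties out of 9 pairs
  tie_case <- roc_auc(c(1, 2, 3, 2, 3, 4), rep(c("normal", "cancer"), each = 3))
  expect_equal(tie_case$auc, 7 / 9)
  expect_equal(tie_case$auc,
               naive_auc(c(1, 2, 3, 2, 3, 4), rep(c("normal", "cancer"), each = 3)))
  expect_error(roc_auc(1:4, rep("normal", 4)), "both classes")

  # random instances: midrank formula == enumeration oracle, exactly
  set.seed(91)
  for (i in 1:20) {
    n1 <- sample(2:30, 1); n0 <- sample(2:30, 1)
    scores <- sample(0:10, n1 + n0, replace = TRUE)
    labels <- c(rep("cancer", n1), rep("normal", n0))
    expect_identical(roc_auc(scores, labels)$auc, naive_auc(scores, labels))
  }

  # agreement with an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(92)
  scores <- sample(0:20, 40, replace = TRUE)
  labels <- sample(c("normal", "cancer"), 40, replace = TRUE, prob = c(.5, .5))
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(suppressMessages(pROC::auc(labels, scores, levels = c("normal", "cancer"),
                                                     direction = "<"))))
})

test_that("the ROC step curve is a valid curve and serializes", {
  roc <- roc_auc(c(0, 1, 1, 3, 5, 9), rep(c("normal", "cancer"), each = 3))
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
  expect_equal(roc$sensitivity[1], 1)  # threshold -Inf calls everything cancer
  expect_equal(roc$specificity[length(roc$thresholds)], 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_roc(roc, path)
  got <- read.delim(path)
  expect_equal(got$sensitivity, roc$sensitivity)
})

test_that("stratified folds preserve class proportions and reproduce by seed", {
  sim <- simulate_two_class(n_probes = 400, n_normal = 40, n_cancer = 60,
                            n_planted = 40, seed = 41)
  cv <- stratified_kfold_cv(sim$expr, sim$samples, n_folds = 10, seed = 5)
  per_fold <- table(cv$scores$fold, cv$scores$class)
  expect_true(all(per_fold[, "normal"] == 4))
  expect_true(all(per_fold[, "cancer"] == 6))
  # folds partition the samples
  expect_setequal(cv$scores$sample_id, sim$samples$sample_id)
  expect_identical(anyDuplicated(cv$scores$sample_id), 0L)
  # no sample is scored by a model trained on it
  for (f in names(cv$train_ids)) {
    tested <- cv$scores$sample_id[cv$scores$fold == f]
    expect_length(intersect(tested, cv$train_ids[[f]]), 0)
  }
  cv2 <- stratified_kfold_cv(sim$expr, sim$samples, n_folds = 10, seed = 5)
  expect_identical(cv$scores, cv2$scores)
  expect_identical(cv$auc, cv2$auc)
  expect_error(stratified_kfold_cv(sim$expr, sim$samples, n_folds = 50),
               "fewer than 50")
  expect_output(print(cv), "Mean AUC")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cv_report(cv, tsv, js)
  expect_equal(jsonlite::read_json(js)$mean_auc, mean(cv$auc))
})

test_that("leave-one-tissue-out training sets exclude the held-out tissue", {
  sim <- simulate_multitissue(n_probes = 500, n_tissues = 3, n_specific = 75,
                              n_hyper = 30, seed = 42)
  loto <- leave_one_tissue_out_cv(sim$expr, sim$samples,
                                  build_args = list(statistic = "universal",
                                                    selection = "top", n_top = 20,
                                                    restriction = "tissue_specific"))
  expect_identical(sort(names(loto$auc)), sort(unique(sim$samples$tissue)))
  for (t in names(loto$train_ids)) {
    held_out <- sim$samples$sample_id[sim$samples$tissue == t]
    expect_length(intersect(loto$train_ids[[t]], held_out), 0)
    expect_setequal(loto$train_ids[[t]],
                    sim$samples$sample_id[sim$samples$tissue != t])
    expect_setequal(loto$scores$sample_id[loto$scores$fold == t], held_out)
  }
  # a tissue lacking one class is refused by name
  broken <- sim$samples
  broken$class[broken$tissue == "tissue01" & broken$class == "cancer"] <- "other"
  expect_error(leave_one_tissue_out_cv(sim$expr, broken,
                                       tissues = unique(sim$samples$tissue)),
               "tissue01")
})

test_that("randomization test follows the +1-corrected empirical p formula", {
  sim <- simulate_two_class(n_probes = 150, n_normal = 20, n_cancer = 20,
                            n_planted = 20, seed = 43)
  test_sim <- simulate_two_class(n_probes = 150, n_normal = 15, n_cancer = 15,
                                 n_planted = 20, seed = 44)
  res <- randomization_test(sim$expr, sim$samples, test_sim$expr, test_sim$samples,
                            signature_size = 10, observed_auc = 0.9, B = 50, seed = 45)
  expect_length(res$null_auc, 50)
  expect_equal(res$p_value, (1 + sum(res$null_auc >= 0.9)) / 51)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  # the worst possible observed AUC gives p = 1
  worst <- randomization_test(sim$expr, sim$samples, test_sim$expr, test_sim$samples,
                              signature_size = 10, observed_auc = 0, B = 20, seed = 46)
  expect_equal(worst$p_value, 1)
  expect_error(randomization_test(sim$expr, sim$samples, test_sim$expr, test_sim$samples,
                                  signature_size = 1000, observed_auc = 0.5, B = 5),
               "smaller than")
  expect_output(print(res), "empirical p")
})

test_that("signature size sweep orders genes by decreasing hyper-variability", {
  sim <- simulate_two_class(n_probes = 300, n_normal = 30, n_cancer = 30,
                            n_planted = 50, sd_inflation = 4, seed = 47)
  test_sim <- simulate_two_class(n_probes = 300, n_normal = 25, n_cancer = 25,
                                 n_planted = 50, sd_inflation = 4, seed = 48)
  # same planted set in train and test
  test_sim$expr <- test_sim$expr[rownames(sim$expr), ]
  sw <- signature_size_sweep(sim$expr, sim$samples, test_sim$expr, test_sim$samples,
                             sizes = c(5, 25, 50))
  expect_identical(sw$size, c(5L, 25L, 50L))
  expect_true(all(sw$auc >= 0 & sw$auc <= 1))
  expect_error(signature_size_sweep(sim$expr, sim$samples, test_sim$expr,
                                    test_sim$samples, sizes = 0), ">= 1")
  expect_error(signature_size_sweep(sim$expr, sim$samples, test_sim$expr,
                                    test_sim$samples, sizes = 10000), "exceeds")
})

test_that("variance F-test matches its sampling distribution and a permutation oracle", {
  x <- c(1.2, 0.8, 1.5, 0.3, 0.9, 1.1)
  same <- variance_f_test(x, x)
  expect_equal(same$statistic, 1)
  expect_equal(same$p_value, 0.5)  # P(F >= 1) with equal df
  expect_equal(variance_f_test(x, x, alternative = "two.sided")$p_value, 1)

  # variance ratio 4 gives F = 4
  set.seed(51)
  g2 <- rnorm(20)
  expect_equal(variance_f_test(2 * g2, g2)$statistic, 4)
  expect_error(variance_f_test(1, g2), "at least 2")

  # permutation oracle: on any single dataset the permutation p conditions on
  # the data, so the two agree in expectation over null datasets rather than
  # instance by instance; check the mean difference against its own MC error
  set.seed(52)
  diffs <- replicate(40, {
    a <- rnorm(20); b <- rnorm(20)
    p_f <- variance_f_test(a, b)$p_value
    pool <- c(a, b)
    perm <- replicate(2000, {
      idx <- sample(40, 20)
      var(pool[idx]) / var(pool[-idx])
    })
    p_f - mean(perm >= var(a) / var(b))
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1e-3)
})

test_that("BH adjustment matches the hand computation and is monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  # lowering any p never raises any adjusted value
  set.seed(53)
  for (i in 1:10) {
    p <- runif(20)
    q <- bh_fdr(p)
    j <- sample(20, 1)
    p2 <- p; p2[j] <- p[j] / 2
    expect_true(all(bh_fdr(p2) <= q + 1e-12))
  }
})

test_that("enrichment test reports the sample odds ratio with a hypergeometric p", {
  universe <- sprintf("u%03d", 1:100)
  set_a <- universe[1:20]                      # 10 overlap, 10 a-only
  set_b <- universe[c(1:10, 21:30)]            # 10 b-only
  res <- enrichment_fisher(set_a, set_b, universe)
  expect_equal(unname(res$table[1, ]), c(10, 10))
  expect_equal(unname(res$table[2, ]), c(10, 70))
  expect_equal(res$odds_ratio, 7)
  # one-sided hypergeometric tail, checked directly
  expect_equal(res$p_value,
               sum(dhyper(10:20, 20, 80, 20)))
  expect_error(enrichment_fisher(c(set_a, "alien"), set_b, universe), "outside")

  # independent random sets give OR near 1 on average
  set.seed(54)
  ors <- replicate(30, {
    a <- sample(universe, 30); b <- sample(universe, 30)
    log(enrichment_fisher(a, b, universe)$odds_ratio)
  })
  expect_lt(abs(mean(ors[is.finite(ors)])), 0.5)
})
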