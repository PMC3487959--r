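# Synthetic expression data with planted ground truth, on the barcode z-score
# scale. Normal samples are tight unimodal Gaussians per probe; cancer
# samples inflate the SD at planted hyper-variable probes (two-class design)
# or wander stochastically between the expressed and unexpressed states
# (multi-tissue design). Generated probe annotation and genomic blocks are
# internally consistent with the half-open containment used by
# restrict_to_blocks().

# shared scaffolding: probe ids, annotation on one synthetic chromosome
sim_annotation <- function(n_probes, chrom = "chrS1", spacing = 1000L) {
  probe_ids <- sprintf("p%05d", seq_len(n_probes))
  data.frame(probe_id = probe_ids,
             gene_id = sprintf("g%05d", seq_len(n_probes)),
             chrom = chrom,
             strand = rep(c("+", "-"), length.out = n_probes),
             tss = as.integer(spacing) * seq_len(n_probes),
             stringsAsFactors = FALSE)
}

#' Simulate a two-class (cancer vs normal) expression dataset
#'
#' Every probe's normal expression is drawn from a tight baseline Gaussian.
#' Cancer samples are drawn from the same Gaussian except at the planted
#' hyper-variable probes, where the SD is multiplied by `sd_inflation`; the
#' expected SD-ratio statistic there is `log2(sd_inflation)`. A configurable
#' fraction of planted probes is placed inside generated genomic blocks
#' (together with an equal number of decoy blocks over non-planted probes),
#' so block restriction is exercisable against ground truth.
#'
#' @param n_probes Number of probes. Default 10000.
#' @param n_normal,n_cancer Samples per class. Default 200 each.
#' @param n_planted Number of planted hyper-variable probes. Default 200.
#' @param sd_inflation SD multiplier (>= 1) at planted probes in cancer.
#'   Default 4.
#' @param baseline_mean,baseline_sd Baseline (unexpressed-state) Gaussian on
#'   the z-score scale. Defaults 0 and 1.
#' @param block_fraction Fraction of planted probes placed inside blocks.
#'   Default 1.
#' @param block_halfwidth Half-width in bases of each generated block around
#'   a probe's tss. Default 250.
#' @param tissue Tissue label given to every sample. Default `"colon"`.
#' @param seed Optional integer seed; same seed and arguments give
#'   bit-identical output.
#' @return List with `expr` (matrix), `samples`, `annotation`, `blocks` and
#'   `truth` (list: `planted`, `in_block`, `config`).
#' @export
simulate_two_class <- function(n_probes = 10000, n_normal = 200, n_cancer = 200,
                               n_planted = 200, sd_inflation = 4,
                               baseline_mean = 0, baseline_sd = 1,
                               block_fraction = 1, block_halfwidth = 250,
                               tissue = "colon", seed = NULL) {
  stopifnot(n_probes >= 1, n_normal >= 1, n_cancer >= 1,
            n_planted >= 0, n_planted <= n_probes,
            sd_inflation >= 1, baseline_sd > 0,
            block_fraction >= 0, block_fraction <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  annotation <- sim_annotation(n_probes)
  probe_ids <- annotation$probe_id
  planted <- sort(sample(probe_ids, n_planted))

  normal <- matrix(stats::rnorm(n_probes * n_normal, baseline_mean, baseline_sd),
                   nrow = n_probes)
  cancer <- matrix(stats::rnorm(n_probes * n_cancer, baseline_mean, baseline_sd),
                   nrow = n_probes)
  planted_idx <- match(planted, probe_ids)
  cancer[planted_idx, ] <- baseline_mean +
    (cancer[planted_idx, , drop = FALSE] - baseline_mean) * sd_inflation

  expr <- cbind(normal, cancer)
  rownames(expr) <- probe_ids
  colnames(expr) <- c(sprintf("norm%03d", seq_len(n_normal)),
                      sprintf("canc%03d", seq_len(n_cancer)))
  samples <- data.frame(
    sample_id = colnames(expr),
    class = rep(c("normal", "cancer"), c(n_normal, n_cancer)),
    tissue = tissue, stringsAsFactors = FALSE)

  n_in_block <- round(block_fraction * n_planted)
  in_block <- sort(sample(planted, n_in_block))
  decoys <- sample(setdiff(probe_ids, planted), min(n_in_block, n_probes - n_planted))
  block_probes <- c(in_block, decoys)
  tss <- annotation$tss[match(block_probes, probe_ids)]
  blocks <- data.frame(chrom = rep("chrS1", length(block_probes)),
                       start = as.integer(pmax(tss - block_halfwidth, 0)),
                       end = as.integer(tss + block_halfwidth),
                       stringsAsFactors = FALSE)
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL

  list(expr = expr, samples = samples, annotation = annotation, blocks = blocks,
       truth = list(planted = planted, in_block = in_block,
                    config = list(n_probes = n_probes, n_normal = n_normal,
                                  n_cancer = n_cancer, n_planted = n_planted,
                                  sd_inflation = sd_inflation,
                                  baseline_mean = baseline_mean,
                                  baseline_sd = baseline_sd,
                                  block_fraction = block_fraction,
                                  seed = seed)))
}

#' Simulate a multi-tissue expression dataset
#'
#' Emulates the expression structure behind universal anti-profiles. Each
#' probe is either ubiquitous (unexpressed state everywhere) or
#' tissue-specific: drawn from the expressed state in its 1-3 home tissues
#' and the unexpressed state elsewhere. A planted subset of the
#' tissue-specific probes is universally hyper-variable in cancer: cancer
#' samples at those probes are drawn from a mixture of the two states
#' (probability `mix_prob` of the expressed state, regardless of tissue), so
#' their outside-normal-range percentages sit away from 0% and 100%. All
#' other probes keep their tissue-appropriate state in cancer.
#'
#' The expressed state defaults to mean 6 SD 1 so that a robustly expressed
#' probe is called expressed (z > 2.54) in essentially every sample, as
#' barcode z-scores of expressed genes are; the unexpressed state defaults to
#' mean 0 SD 1.
#'
#' @param n_probes Number of probes. Default 2000.
#' @param n_tissues Number of tissues. Default 5.
#' @param n_normal_per_tissue,n_cancer_per_tissue Samples per tissue per
#'   class. Default 30 each.
#' @param n_specific Number of tissue-specific probes. Default 300.
#' @param n_hyper Number of planted universally hyper-variable probes (a
#'   subset of the tissue-specific probes). Default 100.
#' @param expressed_mean,unexpressed_mean State means. Defaults 6 and 0.
#' @param state_sd Within-state SD. Default 1.
#' @param mix_prob Probability that a cancer sample expresses a planted probe.
#'   Default 0.5.
#' @param seed Optional integer seed.
#' @return List with `expr`, `samples`, `annotation`, `blocks` (empty
#'   data.frame; blocks are a two-class concept) and `truth` (list:
#'   `hypervariable`, `specific` — named list tissue -> probes, `home` —
#'   named list probe -> home tissues, `config`).
#' @export
simulate_multitissue <- function(n_probes = 2000, n_tissues = 5,
                                 n_normal_per_tissue = 30,
                                 n_cancer_per_tissue = 30,
                                 n_specific = 300, n_hyper = 100,
                                 expressed_mean = 6, unexpressed_mean = 0,
                                 state_sd = 1, mix_prob = 0.5, seed = NULL) {
  stopifnot(n_tissues >= 2, n_specific <= n_probes, n_hyper <= n_specific,
            state_sd > 0, mix_prob >= 0, mix_prob <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  annotation <- sim_annotation(n_probes)
  probe_ids <- annotation$probe_id
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))

  specific <- sort(sample(probe_ids, n_specific))
  hyper <- sort(sample(specific, n_hyper))
  # 1-3 home tissues per specific probe, mostly one
  home <- lapply(specific, function(p) {
    n_home <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
    sort(sample(tissues, n_home))
  })
  names(home) <- specific

  n_per <- n_normal_per_tissue + n_cancer_per_tissue
  sample_tissue <- rep(tissues, each = n_per)
  sample_class <- rep(rep(c("normal", "cancer"),
                          c(n_normal_per_tissue, n_cancer_per_tissue)), n_tissues)
  sample_ids <- sprintf("%s_%s%03d", sample_tissue, substr(sample_class, 1, 4),
                        unlist(lapply(seq_len(n_tissues), function(i)
                          c(seq_len(n_normal_per_tissue), seq_len(n_cancer_per_tissue)))))
  n_samples <- length(sample_ids)

  # state mean per (probe, sample): unexpressed everywhere, expressed where a
  # specific probe meets a sample of one of its home tissues
  mean_mat <- matrix(unexpressed_mean, n_probes, n_samples)
  spec_idx <- match(specific, probe_ids)
  for (s in seq_along(specific)) {
    in_home <- sample_tissue %in% home[[s]]
    mean_mat[spec_idx[s], in_home] <- expressed_mean
  }
  # planted hyper-variable probes: cancer samples flip states stochastically
  hyper_idx <- match(hyper, probe_ids)
  canc <- which(sample_class == "cancer")
  flip <- matrix(stats::runif(length(hyper_idx) * length(canc)) < mix_prob,
                 nrow = length(hyper_idx))
  mean_mat[hyper_idx, canc] <- ifelse(flip, expressed_mean, unexpressed_mean)

  expr <- mean_mat + matrix(stats::rnorm(n_probes * n_samples, 0, state_sd),
                            n_probes, n_samples)
  rownames(expr) <- probe_ids
  colnames(expr) <- sample_ids
  samples <- data.frame(sample_id = sample_ids, class = sample_class,
                        tissue = sample_tissue, stringsAsFactors = FALSE)
  specific_by_tissue <- lapply(tissues, function(t)
    specific[vapply(home, function(h) t %in% h, logical(1L))])
  names(specific_by_tissue) <- tissues

  list(expr = expr, samples = samples, annotation = annotation,
       blocks = data.frame(chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE),
       truth = list(hypervariable = hyper, specific = specific_by_tissue,
                    home = home,
                    config = list(n_probes = n_probes, n_tissues = n_tissues,
                                  n_normal_per_tissue = n_normal_per_tissue,
                                  n_cancer_per_tissue = n_cancer_per_tissue,
                                  n_specific = n_specific, n_hyper = n_hyper,
                                  expressed_mean = expressed_mean,
                                  unexpressed_mean = unexpressed_mean,
                                  state_sd = state_sd, mix_prob = mix_prob,
                                  seed = seed)))
}

#' Write a simulated dataset to a directory
#'
#' Writes the matrix, sample table, probe annotation, blocks (BED3, when any)
#' and a JSON ground-truth file in the package's interchange formats.
#'
#' @param sim A list from [simulate_two_class()] or [simulate_multitissue()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$expr, file.path(dir, "expression.tsv"))
  write_sample_table(sim$samples, file.path(dir, "samples.tsv"))
  write_probe_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  if (nrow(sim$blocks)) write_blocks(sim$blocks, file.path(dir, "blocks.bed"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
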