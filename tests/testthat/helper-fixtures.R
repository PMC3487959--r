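# Fixture builders and independent oracles used across the suite.

make_matrix <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("p%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

make_samples <- function(ids, class, tissue = "t1", ...) {
  data.frame(sample_id = ids, class = class, tissue = tissue, ...,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build an antiprofile object directly from explicit ranges (bypassing fitting)
make_profile <- function(probe_id, lower, upper, k = 5) {
  center <- (lower + upper) / 2
  spread <- (upper - lower) / (2 * k)
  structure(list(
    probes = data.frame(probe_id = probe_id, center = center, spread = spread,
                        lower = lower, upper = upper, degenerate = spread == 0,
                        statistic = NA_real_, stringsAsFactors = FALSE),
    k = k, statistic = "sd_ratio",
    selection = list(mode = "threshold", threshold = 1, n_top = NA_integer_,
                     restriction = "none", pool_size = length(probe_id)),
    mad_constant = 1, n_normal = NA_integer_, n_cancer = NA_integer_,
    call = quote(make_profile())), class = "antiprofile")
}

# oracle: naive per-probe-per-sample double loop for anti-profile scores
naive_scores <- function(profile, x) {
  pr <- profile$probes
  out <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    cnt <- 0L
    for (i in seq_len(nrow(pr))) {
      v <- x[pr$probe_id[i], j]
      if (v < pr$lower[i] || v > pr$upper[i]) cnt <- cnt + 1L
    }
    out[j] <- cnt
  }
  out
}

# oracle: exhaustive pair enumeration of the AUC, half credit for ties
naive_auc <- function(scores, labels) {
  cs <- scores[labels == "cancer"]
  ns <- scores[labels == "normal"]
  tot <- 0
  for (cv in cs) for (nv in ns) tot <- tot + (cv > nv) + 0.5 * (cv == nv)
  tot / (length(cs) * length(ns))
}
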