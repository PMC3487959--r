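# internal helpers shared across the package

# raw median absolute deviation: median(|x - median(x)|), no 1.4826 consistency
# constant unless the caller asks for one
mad_raw <- function(x, constant = 1) {
  constant * stats::median(abs(x - stats::median(x)))
}

# row-wise sample SD (n - 1 denominator) for a numeric matrix
row_sd <- function(m) {
  n <- ncol(m)
  if (n < 2L) stop("need at least 2 columns to compute a sample SD", call. = FALSE)
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (n - 1)
  s <- sqrt(pmax(v, 0))
  # mean-based sums can leave ~1e-17 residue on constant rows; report exact zeros
  s[row_range(m) == 0] <- 0
  s
}

# row-wise max - min without apply() overhead
row_range <- function(m) {
  mx <- mn <- m[, 1L]
  if (ncol(m) > 1L) {
    for (j in 2L:ncol(m)) {
      mx <- pmax(mx, m[, j])
      mn <- pmin(mn, m[, j])
    }
  }
  mx - mn
}

# row-wise median
row_median <- function(m) apply(m, 1L, stats::median)

# row-wise raw MAD
row_mad <- function(m, constant = 1) {
  ctr <- row_median(m)
  constant * row_median(abs(m - ctr))
}

# full-precision numeric formatting so text round trips are exact
num_chr <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1L))
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
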