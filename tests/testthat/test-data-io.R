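test_that("expression matrix and metadata load as a validated, aligned pair", {
  m <- make_matrix(matrix(rnorm(12), 3, 4))
  samples <- make_samples(colnames(m), rep(c("normal", "cancer"), 2))
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, mp)
  write_sample_table(samples, sp)

  ds <- load_dataset(mp, sp)
  expect_identical(dim(ds$expr), c(3L, 4L))
  expect_identical(ds$expr, m)
  expect_identical(ds$samples$sample_id, colnames(m))

  # orphan sample in metadata is named in the error
  write_sample_table(rbind(samples, make_samples("ghost", "normal")), sp)
  expect_error(load_dataset(mp, sp), "ghost")

  # non-finite cell is localised to (probe, sample)
  lines <- strsplit(readLines(mp), "\t")
  lines[[3]][4] <- "NA"
  writeLines(vapply(lines, paste, "", collapse = "\t"), mp)
  write_sample_table(samples, sp)
  expect_error(load_dataset(mp, sp), "p02.*s03")
})

test_that("writers and readers are exact inverses", {
  m <- make_matrix(matrix(rnorm(20) * exp(rnorm(20, 0, 3)), 4, 5))
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, mp)
  expect_identical(read_expression_matrix(mp), m)

  samples <- make_samples(sprintf("s%02d", 1:5), c("normal", "cancer", "other", "normal", "cancer"),
                          tissue = "colon", quality = c(1, 1.1, 1.15, 0.9, 1.05))
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_sample_table(samples, sp)
  expect_identical(read_sample_table(sp), samples)

  annot <- data.frame(probe_id = c("pA", "pB"), gene_id = c("gA", "gB"),
                      chrom = "chr1", strand = c("+", "-"), tss = c(100L, 2000L),
                      stringsAsFactors = FALSE)
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_probe_annotation(annot, ap)
  expect_identical(read_probe_annotation(ap), annot)

  blocks <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 500L),
                       end = c(100L, 900L), stringsAsFactors = FALSE)
  bp <- withr::local_tempfile(fileext = ".bed")
  write_blocks(blocks, bp)
  got <- read_blocks(bp)
  expect_identical(got$start, blocks$start)
  expect_identical(got$end, blocks$end)
  expect_identical(got$chrom, blocks$chrom)
})

test_that("malformed inputs are rejected with informative errors", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "pA\t1\t2", "pA\t3\t4"), mp)
  expect_error(read_expression_matrix(mp), "duplicate probe")
  writeLines(c("probe_id\ts1\ts2", "pA\t1\tx"), mp)
  expect_error(read_expression_matrix(mp), "non-finite")
  expect_error(read_expression_matrix("no/such/file.tsv"), "not found")
  expect_error(read_blocks("no/such.bed"), "not found")
})

test_that("quality filter drops bad studies, then bad arrays, and is idempotent", {
  # all arrays under both thresholds: retained
  s1 <- make_samples(c("a", "b", "c"), "normal", quality = c(1.0, 1.1, 1.15))
  expect_identical(apply_quality_filter(s1)$sample_id, c("a", "b", "c"))

  # study median 1.3 > 1.25: whole study removed
  s2 <- make_samples(c("a", "b", "c"), "normal", quality = c(1.3, 1.3, 1.4))
  f2 <- apply_quality_filter(s2)
  expect_identical(nrow(f2), 0L)
  expect_setequal(attr(f2, "removed")$reason, "study_median_quality")

  # study median 1.0 passes; only the 1.25 array exceeds the 1.2 array cutoff
  s3 <- make_samples(c("a", "b", "c"), "normal", quality = c(1.0, 1.0, 1.25))
  f3 <- apply_quality_filter(s3)
  expect_identical(f3$sample_id, c("a", "b"))
  expect_identical(attr(f3, "removed")$sample_id, "c")
  expect_identical(attr(f3, "removed")$reason, "array_quality")

  # idempotence and subset property
  f3_again <- apply_quality_filter(f3)
  expect_identical(f3_again$sample_id, f3$sample_id)
  expect_true(all(f3$sample_id %in% s3$sample_id))

  # per-study grouping via explicit map
  s4 <- make_samples(c("a", "b", "c", "d"), "normal", quality = c(1.3, 1.35, 1.0, 1.1))
  f4 <- apply_quality_filter(s4, study_ids = c(a = "bad", b = "bad", c = "good", d = "good"))
  expect_identical(f4$sample_id, c("c", "d"))
  expect_error(apply_quality_filter(s4, study_ids = c(a = "x")), "no study id")

  # missing quality column: skipped with a warning, not an error
  s5 <- make_samples(c("a", "b"), "normal")
  expect_warning(f5 <- apply_quality_filter(s5), "skipped")
  expect_identical(f5$sample_id, s5$sample_id)
  expect_error(apply_quality_filter(make_samples("a", "normal", quality = NA_real_)),
               "missing quality")
})

test_that("duplicate arrays are removed keeping the first sample id", {
  base <- rnorm(10)
  # exact duplicate: one survivor
  m1 <- make_matrix(cbind(base, base), samples = c("s2", "s1"))
  out1 <- remove_duplicate_arrays(m1)
  expect_identical(colnames(out1), "s1")
  expect_identical(attr(out1, "removed")$removed, "s2")

  # d(A,B) small, d(A,C) and d(B,C) large: only B dropped
  m2 <- make_matrix(cbind(base, base + 0.5 / sqrt(10), base + 5),
                    samples = c("A", "B", "C"))
  out2 <- remove_duplicate_arrays(m2)
  expect_identical(colnames(out2), c("A", "C"))

  # all pairs distant: unchanged, and output pairwise distances >= threshold
  m3 <- make_matrix(matrix(rnorm(40, sd = 10), 10, 4))
  out3 <- remove_duplicate_arrays(m3)
  expect_identical(out3[, ], m3[, ])
  expect_true(all(dist(t(out3)) >= 1))

  # single sample passes through
  m4 <- make_matrix(matrix(base, ncol = 1))
  expect_identical(ncol(remove_duplicate_arrays(m4)), 1L)
})

test_that("duplicate removal leaves no close pair at any threshold", {
  set.seed(71)
  for (rep in 1:5) {
    m <- make_matrix(matrix(rnorm(20 * 12, sd = 0.4), 20, 12))
    thr <- runif(1, 0.5, 3)
    out <- remove_duplicate_arrays(m, distance_threshold = thr)
    if (ncol(out) > 1) expect_true(all(dist(t(out)) >= thr))
  }
})
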