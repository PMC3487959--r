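# Readers/writers for the plain-text interchange formats plus dataset-level
# validation. All tables are tab-separated; expression matrices are probes x
# samples with the probe id in the first column and sample ids in the header.

#' Read a standardized expression matrix
#'
#' Reads a tab-separated probes-by-samples matrix of standardized (barcode
#' z-score scale) expression values. The first column holds probe ids, the
#' header row holds sample ids. All cells must be finite numbers; probe and
#' sample ids must be unique.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames.
#' @seealso [write_expression_matrix()], [load_dataset()]
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2L) stop("expression matrix needs a probe id column and at least one sample", call. = FALSE)
  probe_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  vals <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), dimnames = list(probe_ids, sample_ids))
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix
#'
#' Values are written at full double precision so that a write/read cycle is
#' the exact identity.
#'
#' @param x Numeric matrix, probes x samples, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  out <- data.frame(probe_id = rownames(x),
                    matrix(num_chr(x), nrow = nrow(x)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("probe_id", colnames(x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression data must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry probe ids (rownames) and sample ids (colnames)", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate probe ids: ", paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ", paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(x))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf("non-finite expression value at probe '%s', sample '%s'",
                 rownames(x)[i], colnames(x)[j]), call. = FALSE)
  }
  invisible(x)
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `class` (one of `normal`, `cancer`,
#' `other`), `tissue`, and optionally `quality` (nonnegative per-array quality
#' score), `stage_grade` and `study`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  validate_sample_table(df)
  df
}

#' Write a sample metadata table
#' @param samples A sample table data.frame (see [read_sample_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  validate_sample_table(samples)
  out <- samples
  if ("quality" %in% names(out)) out$quality <- num_chr(out$quality)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_sample_table <- function(samples) {
  need <- c("sample_id", "class", "tissue")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(samples$class), c("normal", "cancer", "other"))
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "), call. = FALSE)
  if ("quality" %in% names(samples)) {
    q <- samples$quality
    if (any(!is.na(q) & q < 0)) stop("quality scores must be nonnegative", call. = FALSE)
  }
  invisible(samples)
}

#' Load and validate an expression matrix with its metadata
#'
#' Reads both files, checks that the sample sets agree exactly, and reorders
#' the metadata rows to match the matrix columns.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param metadata_path Path to the sample table TSV.
#' @return A list with elements `expr` (matrix) and `samples` (data.frame),
#'   samples ordered identically in both.
#' @export
load_dataset <- function(matrix_path, metadata_path) {
  expr <- read_expression_matrix(matrix_path)
  samples <- read_sample_table(metadata_path)
  only_meta <- setdiff(samples$sample_id, colnames(expr))
  if (length(only_meta))
    stop("sample(s) in metadata but not in matrix: ", paste(only_meta, collapse = ", "), call. = FALSE)
  only_mat <- setdiff(colnames(expr), samples$sample_id)
  if (length(only_mat))
    stop("sample(s) in matrix but not in metadata: ", paste(only_mat, collapse = ", "), call. = FALSE)
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  list(expr = expr, samples = samples)
}

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `gene_id`, `chrom`, `strand` (`+` or `-`) and
#' `tss` (0-based transcription start site coordinate).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per probe.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  validate_probe_annotation(df)
  df
}

#' Write a probe annotation table
#' @param annotation Probe annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path) {
  validate_probe_annotation(annotation)
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_probe_annotation <- function(annotation) {
  need <- c("probe_id", "gene_id", "chrom", "strand", "tss")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("probe annotation missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(annotation$probe_id)) stop("duplicate probe ids in annotation", call. = FALSE)
  if (!all(annotation$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  if (any(annotation$tss < 0)) stop("tss coordinates must be nonnegative", call. = FALSE)
  invisible(annotation)
}

#' Read genomic blocks from a BED3 file
#'
#' Intervals are returned in the BED convention: 0-based, half-open
#' `[start, end)`.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @export
read_blocks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  blocks <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr),
                       stringsAsFactors = FALSE)
  validate_blocks(blocks)
  blocks
}

#' Write genomic blocks to a BED3 file
#' @param blocks Data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  validate_blocks(blocks)
  gr <- GenomicRanges::GRanges(blocks$chrom,
                               IRanges::IRanges(start = blocks$start + 1L, end = blocks$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

validate_blocks <- function(blocks) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(blocks))
  if (length(miss)) stop("block table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(blocks$start < 0)) stop("block coordinates must be nonnegative", call. = FALSE)
  if (any(blocks$start >= blocks$end)) stop("blocks must satisfy start < end", call. = FALSE)
  invisible(blocks)
}

#' Sample-level quality filtering
#'
#' Drops whole studies whose median per-array quality exceeds
#' `study_threshold`, then drops remaining individual arrays whose quality
#' exceeds `array_threshold`. If the sample table carries no `quality` column
#' the filter is skipped with a warning (synthetic data need not carry quality
#' scores).
#'
#' @param samples Sample table with an optional `quality` column.
#' @param array_threshold Per-array quality cutoff (arrays strictly above are
#'   removed). Default 1.2.
#' @param study_threshold Study-median quality cutoff (studies with median
#'   strictly above are removed entirely). Default 1.25.
#' @param study_ids Optional named character vector mapping sample id to study
#'   id; alternatively a `study` column in `samples`. When absent, all samples
#'   are treated as one study.
#' @return The surviving sample table, with a `removed` attribute holding a
#'   data.frame log of removals (`sample_id`, `reason`).
#' @export
apply_quality_filter <- function(samples, array_threshold = 1.2,
                                 study_threshold = 1.25, study_ids = NULL) {
  if (!"quality" %in% names(samples)) {
    warning("no 'quality' column: quality filter skipped")
    attr(samples, "removed") <- data.frame(sample_id = character(), reason = character(),
                                           stringsAsFactors = FALSE)
    return(samples)
  }
  q <- samples$quality
  if (any(is.na(q))) stop("missing quality values for sample(s): ",
                          paste(samples$sample_id[is.na(q)], collapse = ", "), call. = FALSE)
  if (is.null(study_ids)) {
    study <- if ("study" %in% names(samples)) samples$study else rep("study1", nrow(samples))
  } else {
    study <- study_ids[samples$sample_id]
    if (any(is.na(study))) stop("no study id for sample(s): ",
                                paste(samples$sample_id[is.na(study)], collapse = ", "), call. = FALSE)
  }
  med <- tapply(q, study, stats::median)
  bad_study <- names(med)[med > study_threshold]
  drop_study <- study %in% bad_study
  drop_array <- !drop_study & q > array_threshold
  dropped <- drop_study | drop_array
  removed <- data.frame(
    sample_id = samples$sample_id[dropped],
    reason = ifelse(drop_study, "study_median_quality", "array_quality")[dropped],
    stringsAsFactors = FALSE)
  out <- samples[!(drop_study | drop_array), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Remove duplicate arrays
#'
#' Arrays deposited multiple times are detected as pairs of samples whose
#' Euclidean distance over the full probe vector is below
#' `distance_threshold`; within each offending pair only the first sample by
#' lexicographic sample id order is retained.
#'
#' @param x Expression matrix (probes x samples).
#' @param distance_threshold Distance below which two arrays count as
#'   duplicates. Default 1.
#' @return The matrix with duplicate columns dropped; a `removed` attribute
#'   logs each removal (`removed`, `duplicate_of`, `distance`).
#' @export
remove_duplicate_arrays <- function(x, distance_threshold = 1) {
  validate_expression_matrix(x)
  if (ncol(x) == 1L) {
    attr(x, "removed") <- data.frame(removed = character(), duplicate_of = character(),
                                     distance = numeric(), stringsAsFactors = FALSE)
    return(x)
  }
  ids <- colnames(x)
  d <- as.matrix(stats::dist(t(x)))
  log <- data.frame(removed = character(), duplicate_of = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  drop <- logical(length(ids))
  ord <- order(ids)
  for (jj in seq_along(ord)) {
    j <- ord[jj]
    if (jj == 1L) next
    earlier <- ord[seq_len(jj - 1L)]
    close <- earlier[d[earlier, j] < distance_threshold]
    if (length(close)) {
      drop[j] <- TRUE
      i <- close[which.min(d[close, j])]
      log <- rbind(log, data.frame(removed = ids[j], duplicate_of = ids[i],
                                   distance = d[i, j], stringsAsFactors = FALSE))
    }
  }
  out <- x[, !drop, drop = FALSE]
  attr(out, "removed") <- log
  out
}
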