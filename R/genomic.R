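# Genomic candidate restriction. All coordinates are 0-based; block intervals
# are half-open [start, end) in the BED convention.

#' Restrict probes to genomic blocks
#'
#' Keeps probes whose transcription start site lies inside a block on the same
#' chromosome, using half-open containment `start <= tss < end`. Input order
#' is preserved.
#'
#' @param probes Character vector of probe ids.
#' @param annotation Probe annotation data.frame (see
#'   [read_probe_annotation()]); every probe must be annotated.
#' @param blocks Block data.frame with `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @return The subset of `probes` whose tss falls inside a block.
#' @export
restrict_to_blocks <- function(probes, annotation, blocks) {
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx))
    stop("unannotated probe(s): ", paste(probes[is.na(idx)], collapse = ", "), call. = FALSE)
  validate_blocks(blocks)
  chrom <- annotation$chrom[idx]
  tss <- annotation$tss[idx]
  inside <- logical(length(probes))
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    on_ch <- which(chrom == ch)
    if (!length(on_ch)) next
    for (i in on_ch) {
      inside[i] <- any(b$start <= tss[i] & tss[i] < b$end)
    }
  }
  probes[inside]
}

#' Map probes to their nearest promoter CpG
#'
#' For each annotated probe, finds the CpG position inside the promoter window
#' nearest to the transcription start site. The window spans `upstream` bases
#' on the 5' side of the tss and `downstream` bases on the 3' side, reflected
#' by strand: on `+` it is `[tss - upstream, tss + downstream]`, on `-` it is
#' `[tss - downstream, tss + upstream]` (both inclusive; positions are
#' points). Ties in distance are broken toward the lower coordinate.
#'
#' @param annotation Probe annotation data.frame.
#' @param cpg_positions Data.frame with columns `chrom`, `pos` (0-based CpG
#'   coordinates on the same assembly).
#' @param upstream Window extent on the 5' side of the tss. Default 1000.
#' @param downstream Window extent on the 3' side. Default 250.
#' @return Data.frame with columns `probe_id`, `cpg_pos` (NA when no CpG lies
#'   in the window), `distance`.
#' @export
map_promoter_cpgs <- function(annotation, cpg_positions, upstream = 1000,
                              downstream = 250) {
  validate_probe_annotation(annotation)
  stopifnot(all(c("chrom", "pos") %in% names(cpg_positions)))
  n <- nrow(annotation)
  cpg <- rep(NA_real_, n)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tss <- annotation$tss[i]
    if (annotation$strand[i] == "+") {
      lo <- tss - upstream; hi <- tss + downstream
    } else {
      lo <- tss - downstream; hi <- tss + upstream
    }
    pos <- cpg_positions$pos[cpg_positions$chrom == annotation$chrom[i] &
                               cpg_positions$pos >= lo & cpg_positions$pos <= hi]
    if (!length(pos)) next
    dd <- abs(pos - tss)
    best <- pos[dd == min(dd)]
    cpg[i] <- min(best)
    dist[i] <- min(dd)
  }
  data.frame(probe_id = annotation$probe_id, cpg_pos = cpg, distance = dist,
             row.names = NULL, stringsAsFactors = FALSE)
}
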