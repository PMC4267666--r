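## ChIP signal intensities, promoter/enhancer association, enhancer
## clustering across the panel, differential chromatin marks and
## mark-mark correlation. Peak calling is an upstream input (BED).

#' The chromatin marks handled by the pipeline
#'
#' `H3K914ac` denotes H3K9/14ac (the slash is avoided in identifiers
#' and file names).
#' @export
CHROMATIN_MARKS <- c("H3K4me1", "H3K4me3", "H3K9me3", "H3K914ac",
                     "H3K27ac", "H3K27me3", "H3K36me3", "PolII")

#' Marks treated as promoter-active, promoter-repressive and enhancer
#' marks, and the elongation mark scored on gene bodies.
#' @rdname CHROMATIN_MARKS
#' @export
MARK_CLASSES <- list(
  active = c("H3K4me3", "H3K914ac", "PolII"),
  repressive = c("H3K27me3", "H3K9me3"),
  enhancer = c("H3K4me1", "H3K27ac"),
  elongation = "H3K36me3")

#' Construct a ChIP track
#'
#' Densities are windowed tag counts (bedGraph `score` = tags in
#' window). Intensity over a region is the WCE-normalized fold
#' enrichment `(chip_tags/chip_total) / (wce_tags/wce_total)`; region
#' PPM is `chip_tags / chip_total * 1e6`.
#'
#' @param cell_line,mark Labels.
#' @param chip,wce `GRanges` with `score` (tag counts per window) or
#'   bedGraph paths.
#' @param chip_total,wce_total Total mapped tags; default to the track
#'   sums.
#' @return A `ChipTrack` object.
#' @export
chip_track <- function(cell_line, mark, chip, wce,
                       chip_total = NULL, wce_total = NULL) {
  if (is.character(chip)) chip <- rtracklayer::import(chip, format = "bedGraph")
  if (is.character(wce)) wce <- rtracklayer::import(wce, format = "bedGraph")
  chip <- sort(chip); wce <- sort(wce)
  if (is.null(chip_total)) chip_total <- sum(chip$score)
  if (is.null(wce_total)) wce_total <- sum(wce$score)
  structure(list(cell_line = cell_line, mark = mark, chip = chip,
                 wce = wce, chip_total = chip_total,
                 wce_total = wce_total),
            class = "ChipTrack")
}

## Sum of windowed tag counts over regions, windows weighted by the
## fraction overlapping the region.
.region_tags <- function(track_gr, regions) {
  hits <- GenomicRanges::findOverlaps(regions, track_gr,
                                      ignore.strand = TRUE)
  out <- numeric(length(regions))
  if (!length(hits)) return(out)
  ov <- GenomicRanges::pintersect(regions[queryHits(hits)],
                                  track_gr[subjectHits(hits)],
                                  ignore.strand = TRUE)
  frac <- width(ov) / width(track_gr[subjectHits(hits)])
  contrib <- track_gr$score[subjectHits(hits)] * frac
  agg <- rowsum(contrib, queryHits(hits))
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Region intensity (fold of WCE) for a ChIP track
#' @param track A [chip_track()].
#' @param regions `GRanges`.
#' @return Numeric vector, one intensity per region (`NA` when the WCE
#'   has no tags in the region).
#' @export
region_intensity <- function(track, regions) {
  chip <- .region_tags(track$chip, regions) / track$chip_total
  wce <- .region_tags(track$wce, regions) / track$wce_total
  ifelse(wce > 0, chip / wce, NA_real_)
}

#' Region ChIP tag total in PPM
#' @inheritParams region_intensity
#' @return Numeric vector of PPM values.
#' @export
region_ppm <- function(track, regions) {
  .region_tags(track$chip, regions) / track$chip_total * 1e6
}

#' Promoter mark intensities and peak presence per gene
#'
#' For every gene: the WCE-normalized intensity over the +/- 1.5 kb
#' promoter window for each promoter mark (the elongation mark
#' H3K36me3 is scored on the gene body), the region PPM used by the
#' differential filter, and a peak-presence flag set when any peak of
#' the mark overlaps the window.
#'
#' @param tracks List of [chip_track()] objects (one per line x mark).
#' @param peaks Named list: `peaks[[line]][[mark]]` is a `GRanges` of
#'   peak intervals for that line and mark (may be missing).
#' @param ann A [GenomeAnnotation()].
#' @param flank Promoter flank (default 1500).
#' @return List per mark, each with matrices `intensity`, `ppm`,
#'   `peak` (genes x cell lines).
#' @export
promoter_mark_table <- function(tracks, peaks, ann, flank = 1500L) {
  genes <- names(ann$genes)
  proms <- promoter_of(ann, genes, mode = "window", flank = flank)
  bodies <- gene_body_of(ann, genes)
  lines <- sort(unique(vapply(tracks, `[[`, character(1), "cell_line")))
  marks <- sort(unique(vapply(tracks, `[[`, character(1), "mark")))
  out <- list()
  for (mk in marks) {
    regions <- if (mk %in% MARK_CLASSES$elongation) bodies else proms
    intensity <- matrix(NA_real_, length(genes), length(lines),
                        dimnames = list(genes, lines))
    ppm <- intensity
    peak <- matrix(FALSE, length(genes), length(lines),
                   dimnames = list(genes, lines))
    for (tr in tracks) {
      if (tr$mark != mk) next
      intensity[, tr$cell_line] <- region_intensity(tr, regions)
      ppm[, tr$cell_line] <- region_ppm(tr, regions)
    }
    for (ln in lines) {
      pk <- peaks[[ln]][[mk]]
      if (!is.null(pk) && length(pk))
        peak[, ln] <- IRanges::overlapsAny(proms, pk, ignore.strand = TRUE)
    }
    out[[mk]] <- list(intensity = intensity, ppm = ppm, peak = peak)
  }
  out
}

#' Cluster enhancer peaks across the panel
#'
#' All peaks of one enhancer mark from all cell lines are merged by
#' single linkage of overlapping intervals (the representative interval
#' is the union span), and each cluster is assigned to every gene whose
#' territory (100 kb upstream of the TSS plus the gene body) overlaps
#' the representative interval.
#'
#' @param peaks_by_line Named list (cell line -> `GRanges` of peaks of
#'   one mark).
#' @param ann A [GenomeAnnotation()].
#' @param mark Mark label recorded on the clusters.
#' @param upstream Territory upstream extent (default 1e5).
#' @return data.frame with `cluster_id`, `chrom`, `start`, `end`,
#'   `n_peaks`, `cell_lines` (comma-separated), `gene_ids`
#'   (comma-separated; empty when unassigned), plus a `ranges`
#'   attribute carrying the representative `GRanges`.
#' @export
cluster_enhancers <- function(peaks_by_line, ann, mark = "enhancer",
                              upstream = 1e5) {
  all_peaks <- GenomicRanges::GRanges()
  for (ln in names(peaks_by_line)) {
    pk <- peaks_by_line[[ln]]
    if (!length(pk)) next
    mcols(pk) <- NULL
    GenomicRanges::strand(pk) <- "*"
    mcols(pk)$cell_line <- ln
    all_peaks <- c(all_peaks, pk)
  }
  if (!length(all_peaks)) {
    out <- data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_peaks = integer(), cell_lines = character(),
                      gene_ids = character(), stringsAsFactors = FALSE)
    attr(out, "ranges") <- GenomicRanges::GRanges()
    return(out)
  }
  rep_iv <- GenomicRanges::reduce(all_peaks, min.gapwidth = 0L)
  rep_iv <- sort(rep_iv)
  hits <- GenomicRanges::findOverlaps(rep_iv, all_peaks)
  n_peaks <- tabulate(queryHits(hits), length(rep_iv))
  lines_per <- tapply(mcols(all_peaks)$cell_line[subjectHits(hits)],
                      queryHits(hits),
                      function(x) paste(sort(unique(x)), collapse = ","))
  terr <- gene_territory(ann, names(ann$genes), upstream = upstream)
  ghits <- GenomicRanges::findOverlaps(rep_iv, terr, ignore.strand = TRUE)
  gene_ids <- rep("", length(rep_iv))
  if (length(ghits)) {
    gp <- tapply(mcols(terr)$gene_id[subjectHits(ghits)],
                 queryHits(ghits),
                 function(x) paste(sort(unique(x)), collapse = ","))
    gene_ids[as.integer(names(gp))] <- as.character(gp)
  }
  out <- data.frame(
    cluster_id = sprintf("%s_cl%04d", mark, seq_along(rep_iv)),
    chrom = as.character(GenomeInfoDb::seqnames(rep_iv)),
    start = start(rep_iv), end = end(rep_iv), n_peaks = n_peaks,
    cell_lines = as.character(lines_per[as.character(seq_along(rep_iv))]),
    gene_ids = gene_ids, stringsAsFactors = FALSE)
  out$cell_lines[is.na(out$cell_lines)] <- ""
  attr(out, "ranges") <- rep_iv
  out
}

#' Per-cluster intensity matrix for an enhancer mark
#'
#' @param clusters A [cluster_enhancers()] result.
#' @param tracks List of [chip_track()] objects of the matching mark.
#' @return List with matrices `intensity` and `ppm` (clusters x lines).
#' @export
enhancer_intensity <- function(clusters, tracks) {
  rng <- attr(clusters, "ranges")
  lines <- sort(vapply(tracks, `[[`, character(1), "cell_line"))
  intensity <- matrix(NA_real_, nrow(clusters), length(lines),
                      dimnames = list(clusters$cluster_id, lines))
  ppm <- intensity
  for (tr in tracks) {
    intensity[, tr$cell_line] <- region_intensity(tr, rng)
    ppm[, tr$cell_line] <- region_ppm(tr, rng)
  }
  list(intensity = intensity, ppm = ppm)
}

#' Differential chromatin marks
#'
#' Features (genes or enhancer clusters) with at most 1 PPM of ChIP
#' tags in every cell line are excluded; the rest are tested with the
#' shared fold-change contract on their intensities.
#'
#' @param intensity Matrix features x lines of intensities.
#' @param ppm Matrix features x lines of region PPM.
#' @param mark Mark label; calls get layer `"chromatin:<mark>"`.
#' @param ppm_min PPM filter (strict `>` in at least one line,
#'   default 1).
#' @param ... Passed to [call_differential()].
#' @return data.frame of differential calls.
#' @export
call_differential_marks <- function(intensity, ppm, mark, ppm_min = 1,
                                    ...) {
  keep <- apply(ppm, 1L, function(x) any(x > ppm_min, na.rm = TRUE)) &
    rowSums(is.na(intensity)) == 0L
  call_differential(intensity[keep, , drop = FALSE],
                    layer = paste0("chromatin:", mark), ...)
}

#' Mark-mark Spearman correlation matrix
#'
#' Spearman rank correlations between every pair of chromatin marks,
#' computed per cell line over per-gene intensities (promoter window
#' plus gene body) and averaged across lines. Constant vectors give
#' `NA` entries; the diagonal is 1.
#'
#' @param intensities Named list: `intensities[[mark]]` is a matrix
#'   genes x cell lines of intensities on a common gene set.
#' @return Symmetric marks x marks matrix of averaged Spearman
#'   coefficients.
#' @export
mark_correlations <- function(intensities) {
  marks <- names(intensities)
  lines <- colnames(intensities[[1L]])
  stopifnot(length(marks) >= 2L, nrow(intensities[[1L]]) >= 3L)
  acc <- matrix(0, length(marks), length(marks),
                dimnames = list(marks, marks))
  cnt <- acc
  for (ln in lines) {
    m <- vapply(marks, function(mk) intensities[[mk]][, ln],
                numeric(nrow(intensities[[1L]])))
    cc <- suppressWarnings(stats::cor(m, method = "spearman",
                               use = "pairwise.complete.obs"))
    ok <- !is.na(cc)
    acc[ok] <- acc[ok] + cc[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  diag(out) <- 1
  out
}
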