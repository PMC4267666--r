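## Copy-number gain/loss/amplification calling from normalized ratio
## tracks, and the reference-tag/supporting-tag rearrangement caller.

#' Read a windowed copy-ratio track from bedGraph
#'
#' @param path bedGraph path (score = diploid-normalized copy number).
#' @return `GRanges` with a `score` column, sorted.
#' @export
read_copy_ratio <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  sort(gr)
}

#' Call copy-number aberrations from a windowed ratio track
#'
#' Maximal runs of consecutive windows with normalized copy number at or
#' above `gain_cn` are merged into gain calls, runs at or above `amp_cn`
#' into amplification calls, and runs at or below `loss_cn` into loss
#' calls; loss calls longer than `del_min_len` bp are additionally
#' emitted as deletion calls. Gene-level aberrations are intended to be
#' read off the higher-resolution (1.5 kb) track.
#'
#' @param track `GRanges` with a `score` column (see [read_copy_ratio()]).
#' @param ann Optional [GenomeAnnotation()] used to list overlapped genes.
#' @param gain_cn,loss_cn,amp_cn Thresholds (defaults 4, 1, 8).
#' @param del_min_len Minimum deletion length in bp (strict `>`,
#'   default 1000).
#' @param expected_windows Window sizes (bp) the caller expects; other
#'   sizes trigger a warning but are processed.
#' @return data.frame with columns `chrom`, `start`, `end`, `class`
#'   (`gain`/`loss`/`amplification`/`deletion`), `mean_cn`, `gene_ids`
#'   (comma-separated).
#' @export
call_cna <- function(track, ann = NULL, gain_cn = 4, loss_cn = 1,
                     amp_cn = 8, del_min_len = 1000,
                     expected_windows = c(50000L, 1500L)) {
  stopifnot(!is.null(track$score))
  w <- unique(width(track))
  if (!all(w %in% expected_windows))
    warning("unexpected window size(s): ",
            paste(setdiff(w, expected_windows), collapse = ", "))
  runs <- function(pred) {
    sel <- track[pred(track$score)]
    if (!length(sel)) return(NULL)
    merged <- GenomicRanges::reduce(sel, min.gapwidth = 1L)
    hits <- GenomicRanges::findOverlaps(merged, sel)
    mean_cn <- tapply(sel$score[subjectHits(hits)], queryHits(hits), mean)
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(merged)),
               start = start(merged), end = end(merged),
               mean_cn = as.numeric(mean_cn), stringsAsFactors = FALSE)
  }
  out <- list()
  g <- runs(function(s) s >= gain_cn)
  if (!is.null(g)) { g$class <- "gain"; out <- c(out, list(g)) }
  a <- runs(function(s) s >= amp_cn)
  if (!is.null(a)) { a$class <- "amplification"; out <- c(out, list(a)) }
  l <- runs(function(s) s <= loss_cn)
  if (!is.null(l)) {
    l$class <- "loss"; out <- c(out, list(l))
    d <- l[(l$end - l$start + 1L) > del_min_len, , drop = FALSE]
    if (nrow(d)) { d$class <- "deletion"; out <- c(out, list(d)) }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), class = character(),
                      mean_cn = numeric(), gene_ids = character(),
                      stringsAsFactors = FALSE))
  calls <- do.call(rbind, out)
  calls$gene_ids <- ""
  if (!is.null(ann) && length(ann$genes)) {
    body <- ann$features$body
    cgr <- GenomicRanges::GRanges(calls$chrom,
                                  IRanges::IRanges(calls$start, calls$end))
    hits <- GenomicRanges::findOverlaps(cgr, body, ignore.strand = TRUE)
    if (length(hits)) {
      by_call <- tapply(mcols(body)$gene_id[subjectHits(hits)],
                        queryHits(hits),
                        function(x) paste(sort(unique(x)), collapse = ","))
      calls$gene_ids[as.integer(names(by_call))] <- as.character(by_call)
    }
  }
  rownames(calls) <- NULL
  calls[order(calls$chrom, calls$start, calls$class),
        c("chrom", "start", "end", "class", "mean_cn", "gene_ids")]
}

#' Read mate pairs from TSV
#'
#' Columns: `pair_id`, `cell_line`, `chrom1`, `pos1`, `strand1`,
#' `chrom2`, `pos2`, `strand2` (one row per mapped pair, leftmost
#' mapping position of each mate).
#'
#' @param path TSV path.
#' @return data.frame of mate pairs.
#' @export
read_mate_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "cell_line", "chrom1", "pos1", "strand1",
            "chrom2", "pos2", "strand2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(path, ": missing columns ", paste(missing_cols, collapse = ", "))
  df
}

#' Select discordant mate pairs
#'
#' Keeps pairs whose mates map to different chromosomes, or to the same
#' chromosome more than `min_dist` bp apart (strict `>`).
#'
#' @param pairs Mate-pair data.frame (see [read_mate_pairs()]).
#' @param min_dist Intra-chromosomal distance cutoff in bp (default 1e6).
#' @return The discordant rows.
#' @export
detect_discordant <- function(pairs, min_dist = 1e6) {
  if (!nrow(pairs)) return(pairs)
  keep <- pairs$chrom1 != pairs$chrom2 |
    abs(pairs$pos1 - pairs$pos2) > min_dist
  pairs[keep, , drop = FALSE]
}

## Canonical ordering of a pair's two loci: lower chromosome name first,
## then lower position. Orientation signature follows the same ordering.
.canonical_pairs <- function(pairs) {
  swap <- pairs$chrom1 > pairs$chrom2 |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
  out <- pairs
  out$chrom1 <- ifelse(swap, pairs$chrom2, pairs$chrom1)
  out$pos1 <- ifelse(swap, pairs$pos2, pairs$pos1)
  out$strand1 <- ifelse(swap, pairs$strand2, pairs$strand1)
  out$chrom2 <- ifelse(swap, pairs$chrom1, pairs$chrom2)
  out$pos2 <- ifelse(swap, pairs$pos1, pairs$pos2)
  out$strand2 <- ifelse(swap, pairs$strand1, pairs$strand2)
  out
}

## Single-linkage clustering of canonical discordant pairs: two pairs are
## linked when their mate positions agree within `window` bp on both
## sides (orientation is recorded but does not split clusters; a valid
## junction must end up containing both orientations).
.cluster_pairs <- function(cp, window) {
  n <- nrow(cp)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  grp <- paste(cp$chrom1, cp$chrom2)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-1L]) for (b in seq_len(a - 1L)) {
      i <- idx[a]; j <- idx[b]
      if (abs(cp$pos1[i] - cp$pos1[j]) <= window &&
          abs(cp$pos2[i] - cp$pos2[j]) <= window) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Call rearrangement junctions from mate pairs
#'
#' Discordant pairs (different chromosomes, or more than `min_dist` bp
#' apart) are clustered into junction points: pairs whose mate positions
#' agree within `cluster_window` bp on both sides form one cluster
#' (single linkage). The clustered pairs are the junction's *reference
#' tags* and must support the junction from both relative orientations.
#' *Supporting tags* are all pairs (from `all_pairs`) with at least one
#' mate inside the cluster footprint (mate positions +/-
#' `cluster_window`) on each side, linking the same two loci. Junctions
#' are reported when reference tags >= `min_ref`, supporting tags >=
#' `min_supp`, both breakpoints fall in gene bodies, and the (unordered)
#' gene pair occurs in exactly one cell line of the panel (when
#' `unique_in_panel`).
#'
#' @param discordant Discordant mate pairs across the whole panel (a
#'   `cell_line` column selects the line); if `NULL`, computed from
#'   `all_pairs` via [detect_discordant()].
#' @param all_pairs All mapped mate pairs across the panel.
#' @param ann A [GenomeAnnotation()].
#' @param min_ref Minimum reference tags (default 2).
#' @param min_supp Minimum supporting tags (default 4).
#' @param min_dist Discordance distance (default 1e6).
#' @param cluster_window Clustering window in bp (default 500).
#' @param unique_in_panel Suppress gene pairs seen in more than one cell
#'   line (default `TRUE`).
#' @return data.frame with one row per reported junction: `cell_line`,
#'   `chrom_a`, `pos_a`, `chrom_b`, `pos_b`, `orientations`,
#'   `reference_tags`, `supporting_tags`, `gene_a`, `gene_b`.
#' @export
call_junctions <- function(discordant = NULL, all_pairs, ann,
                           min_ref = 2, min_supp = 4, min_dist = 1e6,
                           cluster_window = 500,
                           unique_in_panel = TRUE) {
  if (is.null(discordant)) discordant <- detect_discordant(all_pairs, min_dist)
  empty <- data.frame(cell_line = character(), chrom_a = character(),
                      pos_a = integer(), chrom_b = character(),
                      pos_b = integer(), orientations = character(),
                      reference_tags = integer(),
                      supporting_tags = integer(), gene_a = character(),
                      gene_b = character(), stringsAsFactors = FALSE)
  if (!nrow(discordant)) return(empty)
  body <- ann$features$body
  gene_at <- function(chrom, pos) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    hits <- GenomicRanges::findOverlaps(q, body, ignore.strand = TRUE)
    if (!length(hits)) return(NA_character_)
    sort(mcols(body)$gene_id[subjectHits(hits)])[1L]
  }
  ap <- .canonical_pairs(all_pairs)
  calls <- lapply(sort(unique(discordant$cell_line)), function(line) {
    cp <- .canonical_pairs(discordant[discordant$cell_line == line, ,
                                      drop = FALSE])
    ## deterministic clustering regardless of input order
    cp <- cp[order(cp$chrom1, cp$chrom2, cp$pos1, cp$pos2, cp$pair_id), ]
    cl <- .cluster_pairs(cp, cluster_window)
    apl <- ap[ap$cell_line == line, , drop = FALSE]
    do.call(rbind, lapply(unique(cl), function(k) {
      m <- cp[cl == k, , drop = FALSE]
      orient <- sort(unique(paste0(m$strand1, m$strand2)))
      pos_a <- as.integer(round(stats::median(m$pos1)))
      pos_b <- as.integer(round(stats::median(m$pos2)))
      fa <- c(min(m$pos1) - cluster_window, max(m$pos1) + cluster_window)
      fb <- c(min(m$pos2) - cluster_window, max(m$pos2) + cluster_window)
      supp <- sum(apl$chrom1 == m$chrom1[1L] & apl$chrom2 == m$chrom2[1L] &
                    apl$pos1 >= fa[1L] & apl$pos1 <= fa[2L] &
                    apl$pos2 >= fb[1L] & apl$pos2 <= fb[2L])
      data.frame(cell_line = line, chrom_a = m$chrom1[1L], pos_a = pos_a,
                 chrom_b = m$chrom2[1L], pos_b = pos_b,
                 orientations = paste(orient, collapse = ","),
                 reference_tags = nrow(m), supporting_tags = supp,
                 gene_a = gene_at(m$chrom1[1L], pos_a),
                 gene_b = gene_at(m$chrom2[1L], pos_b),
                 stringsAsFactors = FALSE)
    }))
  })
  calls <- do.call(rbind, calls)
  keep <- calls$reference_tags >= min_ref &
    calls$supporting_tags >= min_supp &
    lengths(regmatches(calls$orientations,
                       gregexpr(",", calls$orientations))) >= 1L &
    !is.na(calls$gene_a) & !is.na(calls$gene_b)
  calls <- calls[keep, , drop = FALSE]
  if (nrow(calls) && unique_in_panel) {
    pair_key <- vapply(seq_len(nrow(calls)), function(i)
      paste(sort(c(calls$gene_a[i], calls$gene_b[i])), collapse = "|"),
      character(1))
    n_lines <- tapply(calls$cell_line, pair_key,
                      function(x) length(unique(x)))
    calls <- calls[n_lines[pair_key] == 1L, , drop = FALSE]
  }
  rownames(calls) <- NULL
  calls[order(calls$cell_line, calls$chrom_a, calls$pos_a), , drop = FALSE]
}

#' Write junction calls as BEDPE
#' @param calls Junction data.frame from [call_junctions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junctions_bedpe <- function(calls, path) {
  bedpe <- data.frame(
    chrom1 = calls$chrom_a, start1 = calls$pos_a - 1L, end1 = calls$pos_a,
    chrom2 = calls$chrom_b, start2 = calls$pos_b - 1L, end2 = calls$pos_b,
    name = paste(calls$gene_a, calls$gene_b, calls$cell_line, sep = "|"),
    score = calls$supporting_tags)
  write.table(bedpe, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
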