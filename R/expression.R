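## Gene-expression quantification (PPM/RPKM), expressed/differential
## calling, and fusion-candidate filtering.

#' Quantify gene expression as PPM and RPKM
#'
#' PPM (parts per million mapped reads) is `count / total_mapped * 1e6`;
#' RPKM divides PPM by the effective gene length in kb (union of exon
#' intervals).
#'
#' @param counts Integer matrix of mapped-read counts, genes x cell
#'   lines, with dimnames.
#' @param length_kb Named numeric vector of effective gene lengths (kb),
#'   covering all rownames of `counts`.
#' @param total_mapped Named numeric vector of per-line total mapped
#'   reads; defaults to the column sums of `counts`.
#' @return An `ExpressionMatrix`: list with elements `counts`, `ppm`,
#'   `rpkm`, `length_kb`, `total_mapped`.
#' @export
quantify <- function(counts, length_kb, total_mapped = colSums(counts)) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  length_kb <- length_kb[rownames(counts)]
  if (anyNA(length_kb)) stop("missing gene length for some genes")
  if (any(length_kb <= 0)) stop("gene lengths must be positive")
  total_mapped <- rep_len(total_mapped, ncol(counts))
  if (any(total_mapped <= 0)) stop("zero total mapped reads")
  ppm <- sweep(counts, 2L, total_mapped, "/") * 1e6
  rpkm <- ppm / length_kb
  structure(list(counts = counts, ppm = ppm, rpkm = rpkm,
                 length_kb = length_kb, total_mapped = total_mapped),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "cell lines\n")
  invisible(x)
}

#' Per-line expressed gene sets
#'
#' A gene is expressed in a line iff its RPKM strictly exceeds the
#' threshold (default 1 RPKM).
#'
#' @param mat An [quantify()] `ExpressionMatrix`.
#' @param threshold RPKM threshold (strict, default 1).
#' @return Named list (one element per cell line) of expressed gene ids.
#' @export
call_expressed <- function(mat, threshold = 1) {
  apply(mat$rpkm > threshold, 2L, function(keep)
    rownames(mat$rpkm)[keep], simplify = FALSE)
}

#' Filter fusion-transcript candidates
#'
#' Candidates are kept iff they have at least `min_reads` spanning reads
#' and at least `min_pairs` spanning mate pairs (both inclusive).
#'
#' @param cands data.frame with columns `cell_line`, `gene_a`, `gene_b`,
#'   `spanning_read_count`, `spanning_mate_pair_count`.
#' @param min_reads Minimum spanning reads (default 10).
#' @param min_pairs Minimum spanning mate pairs (default 2).
#' @return The retained rows of `cands`.
#' @export
filter_fusions <- function(cands, min_reads = 10, min_pairs = 2) {
  need <- c("spanning_read_count", "spanning_mate_pair_count")
  stopifnot(all(need %in% names(cands)))
  if (any(cands$spanning_read_count < 0 | cands$spanning_mate_pair_count < 0))
    stop("negative spanning counts")
  cands[cands$spanning_read_count >= min_reads &
          cands$spanning_mate_pair_count >= min_pairs, , drop = FALSE]
}
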