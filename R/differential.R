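## Shared fold-change differential-calling contract, reused by the
## expression, methylation and chromatin layers.

#' Call differential features against the panel average
#'
#' For every feature/cell-line combination the fold change against the
#' panel average is computed and a call is emitted when it reaches
#' `high` (direction `"higher"`) or falls to `low` (direction `"lower"`).
#' The panel mean includes the focal cell line by default; note that with
#' an inclusive mean the fold of a single dominant line is damped towards
#' the number of lines, so implanted effects are usually screened with
#' `include_focal = FALSE`. Features whose panel mean is zero (after any
#' pseudocount) are skipped.
#'
#' @param values Numeric matrix, features x cell lines, with dimnames.
#' @param layer Label recorded on each call (e.g. `"expression"`,
#'   `"methylation"`, `"chromatin:H3K4me3"`).
#' @param high Fold at or above which `"higher"` is called (default 4).
#' @param low Fold at or below which `"lower"` is called (default 1/16).
#' @param include_focal Include the focal line in the panel mean
#'   (default `TRUE`).
#' @param pseudocount Added to every value before computing folds
#'   (default 0).
#' @return data.frame with columns `feature_id`, `cell_line`, `layer`,
#'   `direction`, `fold`.
#' @export
call_differential <- function(values, layer = "expression", high = 4,
                              low = 1 / 16, include_focal = TRUE,
                              pseudocount = 0) {
  stopifnot(is.matrix(values), ncol(values) >= 2L)
  empty <- data.frame(feature_id = character(), cell_line = character(),
                      layer = character(), direction = character(),
                      fold = numeric(), stringsAsFactors = FALSE)
  if (!nrow(values)) return(empty)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("line", seq_len(ncol(values)))
  v <- values + pseudocount
  n <- ncol(v)
  if (include_focal) {
    m <- rowMeans(v)
    fold <- v / m
    fold[m == 0, ] <- NA_real_
  } else {
    ## mean of the other lines, per focal column
    tot <- rowSums(v)
    other <- (tot - v) / (n - 1L)
    fold <- v / other
    fold[other == 0] <- ifelse(v[other == 0] > 0, Inf, NA_real_)
  }
  hi <- which(!is.na(fold) & fold >= high, arr.ind = TRUE)
  lo <- which(!is.na(fold) & fold <= low, arr.ind = TRUE)
  if (nrow(hi) + nrow(lo) == 0L) return(empty)
  out <- data.frame(
    feature_id = c(rownames(v)[hi[, 1L]], rownames(v)[lo[, 1L]]),
    cell_line = c(colnames(v)[hi[, 2L]], colnames(v)[lo[, 2L]]),
    layer = layer,
    direction = rep(c("higher", "lower"), c(nrow(hi), nrow(lo))),
    fold = c(fold[hi], fold[lo]),
    stringsAsFactors = FALSE)
  out[order(out$feature_id, out$cell_line, out$direction), , drop = FALSE]
}
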