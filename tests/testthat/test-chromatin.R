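make_track <- function(line = "L1", mark = "H3K4me3", chrom = "chr1",
                       n = 50L, w = 200L, chip = rep(4, n),
                       wce = rep(4, n)) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges((seq_len(n) - 1L) * w + 1L,
                                                seq_len(n) * w))
  cg <- gr; cg$score <- chip
  wg <- gr; wg$score <- wce
  chip_track(line, mark, cg, wg)
}

test_that("region intensity is the WCE-normalized fold enrichment", {
  tr <- make_track(chip = c(rep(10, 49), 20), wce = rep(10, 50))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9801L, 10000L))
  ## chip 20 of 510 total vs wce 10 of 500: fold = (20/510)/(10/500)
  expect_equal(region_intensity(tr, region), (20 / 510) / (10 / 500))
  expect_equal(region_ppm(tr, region), 20 / 510 * 1e6)
  ## window partially overlapping contributes proportionally
  half <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9901L, 10000L))
  expect_equal(region_ppm(tr, half), 10 / 510 * 1e6)
})

test_that("promoter mark table scores promoters (gene body for the
           elongation mark) and flags peak overlap half-open", {
  ann <- toy_annotation()
  tr <- make_track("L1", "H3K4me3", chip = c(rep(40, 10), rep(2, 40)))
  tr36 <- make_track("L1", "H3K36me3")
  ## gA promoter window is [1, 2500]; a peak ending at 2500 overlaps,
  ## one starting at 2501 does not
  peaks <- list(L1 = list(
    H3K4me3 = GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(c(2401L, 2501L),
                                                      c(2500L, 2600L)))))
  pmt <- promoter_mark_table(list(tr, tr36), peaks, ann)
  expect_true(pmt$H3K4me3$peak["gA", "L1"])
  expect_false(pmt$H3K4me3$peak["gC", "L1"])
  peaks2 <- list(L1 = list(
    H3K4me3 = GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(2501L, 2600L))))
  pmt2 <- promoter_mark_table(list(tr), peaks2, ann)
  expect_false(pmt2$H3K4me3$peak["gA", "L1"])
  ## intensity over gA promoter reflects the enriched windows
  expect_gt(pmt$H3K4me3$intensity["gA", "L1"], 2)
  ## H3K36me3 is scored on the gene body, not the promoter
  expect_equal(pmt$H3K36me3$intensity["gA", "L1"], 1,
               tolerance = 1e-6)
})

test_that("enhancer clustering is single-linkage, exhaustive,
           idempotent and order-invariant", {
  ann <- toy_annotation()
  peaks <- list(
    L1 = GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(3000L, 3500L),
                                                 c(3200L, 3700L))),
    L2 = GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(3200L, 6000L),
                                                 c(3400L, 6100L))))
  cl <- cluster_enhancers(peaks, ann, mark = "H3K27ac")
  ## 1 bp overlap merges across lines; disjoint peaks stay separate
  expect_equal(nrow(cl), 3L)
  expect_equal(cl$n_peaks, c(2L, 1L, 1L))
  expect_equal(cl$cell_lines[1], "L1,L2")
  ## every input peak belongs to exactly one cluster
  all_pk <- c(peaks$L1, peaks$L2)
  hits <- GenomicRanges::countOverlaps(all_pk, attr(cl, "ranges"))
  expect_true(all(hits == 1L))
  ## idempotence: re-clustering representatives changes nothing
  cl2 <- cluster_enhancers(list(x = attr(cl, "ranges")), ann,
                           mark = "H3K27ac")
  expect_equal(as.data.frame(attr(cl2, "ranges")),
               as.data.frame(attr(cl, "ranges")))
  ## order invariance
  cl3 <- cluster_enhancers(rev(peaks), ann, mark = "H3K27ac")
  expect_equal(cl3[c("chrom", "start", "end", "n_peaks")],
               cl[c("chrom", "start", "end", "n_peaks")])
  ## abutting (non-overlapping) peaks are not merged
  ab <- list(L1 = GenomicRanges::GRanges("chr1",
                                         IRanges::IRanges(c(1L, 101L),
                                                          c(100L, 200L))))
  expect_equal(nrow(cluster_enhancers(ab, ann)), 2L)
})

test_that("enhancer clusters are assigned within 100 kb upstream plus
           gene body", {
  ## sparse annotation where distances are controllable
  ann <- GenomeAnnotation(
    c(chrBig = 500000L),
    list(gene_model("gFar", "chrBig", "+",
                    list(list(tx_id = "t",
                              exons = IRanges::IRanges(200000L,
                                                       204000L))))))
  near <- GenomicRanges::GRanges("chrBig",
                                 IRanges::IRanges(150000L, 150500L))
  far <- GenomicRanges::GRanges("chrBig",
                                IRanges::IRanges(99000L, 99900L))
  cl <- cluster_enhancers(list(L1 = c(near, far)), ann)
  expect_equal(cl$gene_ids[cl$start == 150000L], "gFar")
  ## 100,001 bp upstream of the TSS: outside the territory
  expect_equal(cl$gene_ids[cl$start == 99000L], "")
})

test_that("differential marks require > 1 PPM in at least one line", {
  intensity <- matrix(c(1, 1, 1, 40), nrow = 1,
                      dimnames = list("gA", paste0("L", 1:4)))
  ppm_low <- matrix(0.9, 1, 4, dimnames = dimnames(intensity))
  ppm_ok <- matrix(c(0.5, 0.5, 0.5, 5), 1, 4,
                   dimnames = dimnames(intensity))
  expect_equal(nrow(call_differential_marks(intensity, ppm_low,
                                            "H3K4me3",
                                            include_focal = FALSE)), 0L)
  calls <- call_differential_marks(intensity, ppm_ok, "H3K4me3",
                                   include_focal = FALSE)
  expect_equal(calls$layer, "chromatin:H3K4me3")
  expect_equal(calls$direction, "higher")
})

test_that("mark correlations are symmetric, bounded, tie-aware and match
           a rank oracle", {
  set.seed(31)
  n <- 40L
  base <- rlnorm(n)
  ints <- list(
    A = matrix(base, ncol = 1, dimnames = list(NULL, "L1")),
    B = matrix(base * 2, ncol = 1, dimnames = list(NULL, "L1")),
    C = matrix(rev(base), ncol = 1, dimnames = list(NULL, "L1")),
    D = matrix(rlnorm(n), ncol = 1, dimnames = list(NULL, "L1")))
  cc <- mark_correlations(ints)
  expect_equal(cc, t(cc))
  expect_true(all(diag(cc) == 1))
  expect_true(all(cc >= -1 & cc <= 1, na.rm = TRUE))
  ## identical ranks give 1; monotone transforms leave entries unchanged
  expect_equal(cc["A", "B"], 1)
  ints2 <- ints; ints2$D <- ints$D^3
  expect_equal(mark_correlations(ints2)["A", "D"], cc["A", "D"])
  ## oracle: Pearson correlation of average ranks
  rk <- function(x) rank(x, ties.method = "average")
  expect_equal(cc["A", "D"],
               stats::cor(rk(ints$A[, 1]), rk(ints$D[, 1])))
  ## per-line correlations are averaged across lines
  ints3 <- list(
    A = cbind(L1 = base, L2 = base),
    B = cbind(L1 = base, L2 = rev(base)))
  cc3 <- mark_correlations(ints3)
  r2 <- stats::cor(rk(base), rk(rev(base)))
  expect_equal(cc3["A", "B"], (1 + r2) / 2)
  ## constant vectors give missing entries
  ints4 <- list(A = cbind(L1 = base), B = cbind(L1 = rep(1, n)))
  expect_true(is.na(mark_correlations(ints4)["A", "B"]))
})
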