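cn_track <- function(scores, chrom = "chr1", w = 1500L) {
  n <- length(scores)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges((seq_len(n) - 1L) * w + 1L,
                                                seq_len(n) * w))
  gr$score <- scores
  gr
}

test_that("copy-number calls merge threshold runs", {
  ## windows [2,2,4.5,5,2]: one gain call spanning windows 3-4
  calls <- call_cna(cn_track(c(2, 2, 4.5, 5, 2)))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$class, "gain")
  expect_equal(c(calls$start, calls$end), c(3001L, 6000L))
  expect_equal(calls$mean_cn, 4.75)
  ## diploid baseline: no calls
  expect_equal(nrow(call_cna(cn_track(rep(2, 10)))), 0L)
  ## amplification also reported as gain; deletion requires > 1 kb
  calls2 <- call_cna(cn_track(c(2, 9, 9, 2, 0.1, 2)))
  expect_setequal(calls2$class,
                  c("gain", "amplification", "loss", "deletion"))
  ## the 1.5 kb loss window exceeds 1 kb, hence deletion
  expect_equal(calls2$start[calls2$class == "deletion"], 6001L)
  ## a sub-kb loss is not a deletion
  calls3 <- call_cna(cn_track(c(2, 0.5, 2), w = 800L),
                     expected_windows = 800L)
  expect_equal(calls3$class, "loss")
})

test_that("copy-number calling is threshold-monotone and warns on odd
           windows", {
  set.seed(4)
  tr <- cn_track(runif(40, 0, 10))
  g1 <- call_cna(tr, gain_cn = 4)
  g2 <- call_cna(tr, gain_cn = 6)
  gain_w <- function(calls) sum(calls$end[calls$class == "gain"] -
                                  calls$start[calls$class == "gain"])
  expect_lte(gain_w(g2), gain_w(g1))
  expect_warning(call_cna(cn_track(c(2, 2), w = 777L)), "window")
})

test_that("CNA calls list overlapped genes from the annotation", {
  ann <- toy_annotation()
  scores <- rep(2, 6); scores[1:2] <- 0   # windows 1-2 cover gA
  calls <- call_cna(cn_track(scores), ann)
  del <- calls[calls$class == "deletion", ]
  expect_match(del$gene_ids, "gA")
})

test_that("discordance rule: different chromosome or > 1 Mb", {
  pairs <- data.frame(
    pair_id = paste0("p", 1:4), cell_line = "L1",
    chrom1 = c("chr1", "chr1", "chr1", "chr2"),
    pos1 = c(1L, 1L, 1L, 5L), strand1 = "+",
    chrom2 = c("chr1", "chr1", "chr2", "chr2"),
    pos2 = c(1000002L, 1000000L, 50L, 400L), strand2 = "-",
    stringsAsFactors = FALSE)
  kept <- detect_discordant(pairs)
  expect_equal(kept$pair_id, c("p1", "p3"))
  expect_equal(nrow(detect_discordant(pairs[0, ])), 0L)
})

junction_pairs <- function(line, n_fwd, n_rev, brk_a = 1500L,
                           brk_b = 2300L, chrom_a = "chr1",
                           chrom_b = "chr2", id0 = 0L) {
  offs <- function(k) if (k) round(seq(25, 295, length.out = k)) else integer()
  n <- n_fwd + n_rev
  data.frame(pair_id = sprintf("j%03d", id0 + seq_len(n)),
             cell_line = line,
             chrom1 = chrom_a,
             pos1 = c(brk_a - offs(n_fwd), brk_a + offs(n_rev)),
             strand1 = rep(c("+", "-"), c(n_fwd, n_rev)),
             chrom2 = chrom_b,
             pos2 = c(brk_b + offs(n_fwd), brk_b - offs(n_rev)),
             strand2 = rep(c("-", "+"), c(n_fwd, n_rev)),
             stringsAsFactors = FALSE)
}

test_that("junction calling enforces reference/supporting thresholds and
           bidirectional support", {
  ann <- toy_annotation()
  ## breakpoints inside gA (chr1) and gC (chr2)
  ok <- junction_pairs("L1", 1L, 1L)
  extra_supp <- junction_pairs("L1", 2L, 0L, id0 = 100L)
  all_pairs <- rbind(ok, extra_supp)
  calls <- call_junctions(all_pairs = all_pairs, ann = ann)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$reference_tags, 4L)
  expect_gte(calls$supporting_tags, 4L)
  expect_setequal(unlist(strsplit(calls$orientations, ",")),
                  c("+-", "-+"))
  expect_equal(c(calls$gene_a, calls$gene_b), c("gA", "gC"))
  ## one orientation only: suppressed even with many pairs
  uni <- junction_pairs("L1", 10L, 0L)
  expect_equal(nrow(call_junctions(all_pairs = uni, ann = ann)), 0L)
  ## 2 reference tags but fewer than 4 supporting tags: suppressed
  two <- junction_pairs("L1", 1L, 1L)
  expect_equal(nrow(call_junctions(all_pairs = two, ann = ann)), 0L)
})

test_that("gene pairs seen in two cell lines are suppressed in both", {
  ann <- toy_annotation()
  both <- rbind(junction_pairs("L1", 3L, 3L),
                junction_pairs("L2", 3L, 3L, id0 = 50L))
  expect_equal(nrow(call_junctions(all_pairs = both, ann = ann)), 0L)
  expect_equal(nrow(call_junctions(all_pairs = both, ann = ann,
                                   unique_in_panel = FALSE)), 2L)
})

test_that("junction calls are invariant under input order and locate
           the implanted breakpoint", {
  ann <- toy_annotation()
  pairs <- junction_pairs("L1", 8L, 8L)
  calls <- call_junctions(all_pairs = pairs, ann = ann)
  set.seed(2)
  shuffled <- pairs[sample(nrow(pairs)), ]
  calls2 <- call_junctions(all_pairs = shuffled, ann = ann)
  rownames(calls2) <- NULL
  expect_equal(calls, calls2)
  expect_lt(abs(calls$pos_a - 1500L), 500L)
  expect_lt(abs(calls$pos_b - 2300L), 500L)
})
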