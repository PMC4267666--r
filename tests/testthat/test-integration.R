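test_that("published marginals reproduce every derived accounting
           figure exactly", {
  fig <- derive_burden_figures(published_burden_marginals())
  expect_equal(fig$somatic_total, 3040654)
  expect_equal(fig$somatic_avg_per_line, 149209)
  expect_equal(fig$coding_burden_avg, 536)
  expect_equal(fig$regulatory_avg, 13573)
  expect_equal(fig$splice_site_total, 385)
  expect_equal(fig$upstream_total, 13845)
  expect_equal(fig$utr_total, 24915)
  expect_equal(fig$non_synonymous_snv_total, 11849)
  expect_equal(round(fig$genic_fraction_pct), 33)
  expect_true(fig$partition_ok)
  expect_equal(fig$genic_fraction_pct + fig$intergenic_fraction_pct, 100)
})

reg_fixture <- function() {
  ann <- toy_annotation()
  vars <- data.frame(
    cell_line = rep(c("L1", "L2"), each = 6),
    chrom = "chr1",
    pos = c(600L, 1900L, 4200L, 6010L, 9990L, 5200L,
            650L, 1900L, 4200L, 6010L, 8000L, 5205L),
    ref = "A", alt = "G",
    var_type = rep(c("SNV", "SNV", "SNV", "SNV", "indel", "SNV"), 2),
    status = "somatic_candidate", stringsAsFactors = FALSE)
  peaks <- list(
    L1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(4100L, 4300L)),
    L2 = GenomicRanges::GRanges("chr1", IRanges::IRanges(4250L, 4400L)))
  clusters <- list(H3K4me1 = cluster_enhancers(peaks, ann,
                                               mark = "H3K4me1"))
  diff <- data.frame(
    feature_id = c("gA", "gB", clusters$H3K4me1$cluster_id[1]),
    cell_line = "L1",
    layer = c("chromatin:H3K4me3", "methylation", "chromatin:H3K4me1"),
    direction = "higher", fold = 8, stringsAsFactors = FALSE)
  list(ann = ann, vars = vars, clusters = clusters, diff = diff)
}

test_that("regulatory overlap matches a brute-force interval recount", {
  fx <- reg_fixture()
  tab <- regulatory_overlap(fx$vars, fx$ann, fx$clusters, fx$diff)
  ## brute force: promoter windows and cluster intervals recomputed by
  ## hand from the gene definitions
  tss <- c(gA = 1001L, gB = 4800L, gC = 2001L, gD = 5001L, gE = 9500L)
  chroms <- c(gA = "chr1", gB = "chr1", gC = "chr2", gD = "chr2",
              gE = "chr2")
  in_prom <- function(chrom, pos) any(chroms == chrom &
                                        pos >= tss - 1500L &
                                        pos <= tss + 1499L)
  cl <- fx$clusters$H3K4me1
  in_enh <- function(chrom, pos) any(cl$gene_ids != "" &
                                       cl$chrom == chrom &
                                       pos >= cl$start & pos <= cl$end)
  for (line in c("L1", "L2")) for (vt in c("SNV", "indel")) {
    v <- fx$vars[fx$vars$cell_line == line & fx$vars$var_type == vt, ]
    get <- function(region) tab$count[tab$cell_line == line &
                                        tab$var_type == vt &
                                        tab$region == region]
    want_prom <- sum(mapply(in_prom, v$chrom, v$pos))
    want_enh <- sum(mapply(in_enh, v$chrom, v$pos))
    expect_equal(get("promoter"), want_prom, info = paste(line, vt))
    expect_equal(get("enhancer_H3K4me1"), want_enh,
                 info = paste(line, vt))
    union_want <- sum(mapply(function(c, p)
      in_prom(c, p) || in_enh(c, p), v$chrom, v$pos))
    expect_equal(get("regulatory_union"), union_want)
    ## nesting: differential rows never exceed their parent rows
    expect_lte(get("promoter_diff_H3K4me3"), get("promoter"))
    expect_lte(get("enhancer_diff_H3K4me1"), get("enhancer_H3K4me1"))
  }
  ## differential rows are line-specific: L1 carries the diff calls
  gA_prom_hits <- sum(fx$vars$cell_line == "L1" &
                        fx$vars$var_type == "SNV" &
                        fx$vars$pos >= tss["gA"] - 1500L &
                        fx$vars$pos <= tss["gA"] + 1499L)
  expect_equal(tab$count[tab$cell_line == "L1" & tab$var_type == "SNV" &
                           tab$region == "promoter_diff_H3K4me3"],
               gA_prom_hits)
  expect_equal(tab$count[tab$cell_line == "L2" & tab$var_type == "SNV" &
                           tab$region == "promoter_diff_H3K4me3"], 0L)
})

test_that("gene status follows the report thresholds", {
  counts <- matrix(c(3, 900, 40, 40), nrow = 2,
                   dimnames = list(c("gA", "gB"), c("L1", "L2")))
  expr <- quantify(counts, c(gA = 1, gB = 1), total_mapped = c(1e6, 1e6))
  ## gA in L1: 3 counts -> 3 PPM -> RPKM 3? scale so that it is <= 1
  expr$rpkm["gA", "L1"] <- 0.5
  layers <- list(
    expression = expr,
    diff_expression = data.frame(feature_id = "gB", cell_line = "L2",
                                 layer = "expression",
                                 direction = "higher", fold = 5),
    cna = list(L1 = data.frame(chrom = "chr1", start = 1L, end = 5000L,
                               class = c("amplification", "gain"),
                               mean_cn = 8.2, gene_ids = "gA,gB")),
    variants = data.frame(cell_line = "L1", gene_id = "gA",
                          category = "splice_site"))
  st <- gene_status(c("gA", "gB"), c("L1", "L2"), layers)
  a <- st[st$gene_id == "gA", ]
  expect_equal(a$expression, "no_exp")
  expect_equal(a$cna, "amp")
  expect_true(a$coding_mutation)
  b <- st[st$gene_id == "gB", ]
  expect_equal(b$expression, "up")
  expect_equal(b$cna, "n.s.")   # no CNA table for L2
  expect_equal(b$methylation, "n.s.")
})

test_that("hallmark scores use expressed denominators and simple
           ratios", {
  ann <- toy_annotation()
  counts <- matrix(c(100, 100, 0, 100, 100, 0), nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"), c("L1", "L2")))
  expr <- quantify(counts, c(gA = 1, gB = 1, gC = 1, gD = 1, gE = 1)[1:3],
                   total_mapped = c(1e4, 1e4))
  layers <- list(
    expression = expr,
    variants = data.frame(cell_line = "L1", gene_id = "gA",
                          category = "cds"))
  hs <- hallmark_scores(ann, layers)
  g <- hs[hs$hallmark == "growth" & hs$cell_line == "L1", ]
  ## growth = {gA, gB}, both expressed; gA mutated in L1 -> 50%
  expect_equal(g$n_genes, 2L)
  expect_equal(g$pct_mutation, 50)
  ## gC is never expressed: immortality denominator is 0
  im <- hs[hs$hallmark == "immortality", ]
  expect_true(all(im$n_genes == 0L))
  expect_true(all(is.na(im$pct_mutation)))
  ## percentages do not depend on gene or line ordering
  expect_equal(hs$pct_mutation[hs$hallmark == "growth" &
                                 hs$cell_line == "L1"], 50)
})

test_that("normal comparison applies the transcribed / not-transcribed
           rules", {
  cancer <- matrix(c(8, 2, 6, 4, 0.06, 2), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gHi", "gInd", "gLo"),
                                   c("L1", "L2")))
  normal <- c(gHi = 2, gInd = 0.5, gLo = 2)
  nc <- normal_comparison(cancer, normal)
  ## normal 2, cancer 8: 4-fold, aberrant
  expect_true(nc$flags["gHi", "L1"])
  expect_equal(nc$direction["gHi", "L1"], "higher")
  ## normal 2, cancer 2: not aberrant
  expect_false(nc$flags["gHi", "L2"])
  ## normal 0.5 (not transcribed): needs cancer > 5
  expect_true(nc$flags["gInd", "L1"])
  expect_equal(nc$direction["gInd", "L1"], "induced")
  expect_false(nc$flags["gInd", "L2"])
  ## lower direction: 0.06/2 < 1/16
  expect_true(nc$flags["gLo", "L1"])
  expect_equal(nc$direction["gLo", "L1"], "lower")
  expect_equal(unname(nc$any_line), c(TRUE, TRUE, TRUE))
  ## identical profiles carry no flags
  same <- matrix(c(2, 2), nrow = 1, dimnames = list("gHi", c("L1", "L2")))
  expect_false(any(normal_comparison(same, c(gHi = 2))$flags))
})
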