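test_that("annotation loads from GFF3/BED/TSV/FASTA with derived fields", {
  ann0 <- toy_annotation()
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "genes.gff3")
  panelomics:::.write_gff3(ann0$genes, gff)
  bed <- file.path(dir, "islands.bed")
  panelomics:::.write_bed3(ann0$islands, bed)
  hm <- file.path(dir, "hallmarks.tsv")
  write.table(data.frame(hallmark = c("growth", "growth", "immortality"),
                         gene_id = c("gA", "gB", "gC")),
              hm, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(ann0$genome, fa)
  ann <- load_annotation(gff, bed, hm, fa)
  expect_length(ann$genes, 5L)
  ## splice sites of gA enumerated by hand: first/last 2 bases of the
  ## introns (1201-1400) and (1601-1800)
  expect_equal(as.data.frame(ann$genes$gA$splice_sites),
               data.frame(start = c(1201L, 1399L, 1601L, 1799L),
                          end = c(1202L, 1400L, 1602L, 1800L),
                          width = 2L))
  ## single-exon gene: no introns, no splice sites
  expect_length(ann$genes$gC$splice_sites, 0L)
  ## most upstream TSS respects strand and multiple transcripts
  expect_equal(ann$genes$gD$most_upstream_tss, 5001L)
  expect_equal(ann$genes$gB$most_upstream_tss, 4800L)
  expect_equal(ann$chrom_lengths, c(chr1 = 10000L, chr2 = 10000L))
  expect_setequal(ann$hallmark_map$growth, c("gA", "gB"))
})

test_that("annotation validation rejects broken inputs", {
  genes <- toy_genes()
  expect_error(GenomeAnnotation(c(chr1 = 10000L), genes[1:2],
                                hallmark_map = list(x = "nope")),
               "unknown genes")
  expect_error(GenomeAnnotation(c(chr1 = 1500L), genes[1]),
               "outside chromosome bounds")
  dup <- c(genes[1], genes[1])
  expect_error(GenomeAnnotation(c(chr1 = 10000L), dup), "duplicate")
  expect_error(gene_model("bad", "chr1", "+",
                          list(list(tx_id = "t",
                                    exons = IRanges::IRanges(
                                      c(1L, 50L), c(100L, 150L))))),
               "overlapping exons")
})

test_that("classify_position applies the documented precedence", {
  ann <- toy_annotation()
  ## first two bases inside the intron are splice sites, the third is not
  expect_equal(classify_position(ann, "chr1", 1202)$category, "splice_site")
  expect_equal(classify_position(ann, "chr1", 1203)$category, "intronic")
  expect_equal(classify_position(ann, "chr1", 1550)$category, "cds")
  expect_equal(classify_position(ann, "chr1", 1100)$category, "utr")
  expect_equal(classify_position(ann, "chr1", 900)$category, "upstream")
  expect_equal(classify_position(ann, "chr1", 9000)$category, "intergenic")
  expect_true(is.na(classify_position(ann, "chr1", 9000)$gene_id))
  expect_equal(classify_position(ann, "chr1", 1550)$gene_id, "gA")
  expect_error(classify_position(ann, "chrX", 100), "unknown chromosome")
  expect_error(classify_position(ann, "chr1", 10001), "outside")
})

test_that("classify_position agrees with a brute-force per-base scan", {
  ann <- toy_annotation()
  pos <- seq(400L, 5400L)
  got <- classify_position(ann, "chr1", pos)
  want <- lapply(pos, function(p) brute_classify(ann, "chr1", p))
  expect_equal(got$category, vapply(want, `[[`, "", "category"))
  expect_equal(got$gene_id,
               vapply(want, `[[`, NA_character_, "gene_id"))
})

test_that("classify_position is a partition (category counts sum)", {
  ann <- toy_annotation()
  set.seed(3)
  chrom <- sample(c("chr1", "chr2"), 500, replace = TRUE)
  pos <- sample(10000L, 500, replace = TRUE)
  cls <- classify_position(ann, chrom, pos)
  expect_equal(nrow(cls), 500L)
  expect_equal(sum(table(cls$category)), 500L)
  expect_true(all(!is.na(cls$gene_id[cls$category != "intergenic"])))
})

test_that("promoter_of implements both conventions, clipped and
           strand-covariant", {
  ann <- toy_annotation()
  ## window mode: 3000 bp centred on the TSS (gD TSS at 5001)
  w <- promoter_of(ann, "gD", mode = "window")
  expect_equal(c(start(w), end(w)), c(5001L - 1500L, 5001L + 1499L))
  expect_equal(width(w), 3000L)
  ## upstream mode, + strand: the 1500 bp strictly 5' of the TSS
  u <- promoter_of(ann, "gD", mode = "upstream")
  expect_equal(c(start(u), end(u)), c(5001L - 1500L, 5000L))
  ## upstream mode, - strand: mirrored (gB TSS at 4800)
  u2 <- promoter_of(ann, "gB", mode = "upstream")
  expect_equal(c(start(u2), end(u2)), c(4801L, 4800L + 1500L))
  ## clipping at the chromosome start
  annc <- GenomeAnnotation(
    c(chr1 = 10000L),
    list(gene_model("gX", "chr1", "+",
                    list(list(tx_id = "t",
                              exons = IRanges::IRanges(500L, 900L))))))
  wc <- promoter_of(annc, "gX", mode = "window")
  expect_equal(c(start(wc), end(wc)), c(1L, 1999L))
  ## strand covariance: mirroring the gene mirrors the interval
  L <- 10000L
  mirrored <- gene_model("gBm", "chr1", "+",
                         list(list(tx_id = "t", exons = IRanges::IRanges(
                           L - 4800L + 1L, L - 4001L + 1L))))
  annm <- GenomeAnnotation(c(chr1 = L), list(mirrored))
  um <- promoter_of(annm, "gBm", mode = "upstream")
  expect_equal(start(um), L - end(u2) + 1L)
  expect_equal(end(um), L - start(u2) + 1L)
})

test_that("coding_effect matches translation of the full mutated CDS", {
  ann <- toy_annotation()
  set.seed(21)
  for (gid in c("gA")) {
    g <- ann$genes[[gid]]
    cds_pos <- unlist(lapply(seq_along(g$cds), function(i)
      seq(start(g$cds)[i], end(g$cds)[i])))
    for (rep in 1:25) {
      pos <- sample(cds_pos, 1L)
      ref <- substr(as.character(ann$genome[[g$chrom]]), pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      got <- coding_effect(ann, g$chrom, pos, ref, alt)
      ## oracle: translate the whole CDS before and after the change
      seq <- unlist(strsplit(as.character(ann$genome[[g$chrom]]), ""))
      mut <- seq; mut[pos] <- alt
      get_aa <- function(chars) {
        cds <- paste(chars[cds_pos], collapse = "")
        d <- Biostrings::DNAString(cds)
        if (g$strand == "-") d <- Biostrings::reverseComplement(d)
        as.character(suppressWarnings(Biostrings::translate(d)))
      }
      want <- if (get_aa(seq) == get_aa(mut)) "synonymous"
        else "non_synonymous"
      expect_equal(got, want, info = paste(gid, pos, ref, ">", alt))
    }
  }
  ## outside any CDS
  expect_equal(coding_effect(ann, "chr1", 1100, "A", "G"), "n/a")
})
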