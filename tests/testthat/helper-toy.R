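# Small hand-built annotation shared by the unit tests. Gene geometry is
# chosen so every positional category exists and splice sites / CDS
# frames can be enumerated by hand.

toy_genes <- function() {
  list(
    ## + strand, 3 exons, CDS of 201 bp split over exons 2 and 3
    gene_model("gA", "chr1", "+",
               list(list(tx_id = "gA.t1",
                         exons = IRanges::IRanges(
                           c(1001L, 1401L, 1801L),
                           c(1200L, 1600L, 2000L)))),
               cds = IRanges::IRanges(c(1501L, 1801L),
                                      c(1600L, 1901L))),
    ## - strand, 2 exons
    gene_model("gB", "chr1", "-",
               list(list(tx_id = "gB.t1",
                         exons = IRanges::IRanges(c(4001L, 4501L),
                                                  c(4200L, 4800L))))),
    ## single exon: no splice sites
    gene_model("gC", "chr2", "+",
               list(list(tx_id = "gC.t1",
                         exons = IRanges::IRanges(2001L, 2600L)))),
    ## two transcripts with different TSSs
    gene_model("gD", "chr2", "+",
               list(list(tx_id = "gD.t1",
                         exons = IRanges::IRanges(c(5001L, 5501L),
                                                  c(5200L, 5700L))),
                    list(tx_id = "gD.t2",
                         exons = IRanges::IRanges(c(5101L, 5501L),
                                                  c(5200L, 5700L))))),
    ## - strand single exon near the chromosome end
    gene_model("gE", "chr2", "-",
               list(list(tx_id = "gE.t1",
                         exons = IRanges::IRanges(9001L, 9500L)))))
}

toy_annotation <- function(seed = 11, with_genome = TRUE) {
  set.seed(seed)
  lens <- c(chr1 = 10000L, chr2 = 10000L)
  genome <- if (with_genome)
    Biostrings::DNAStringSet(setNames(vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1)), names(lens)))
  else NULL
  islands <- GenomicRanges::GRanges(
    factor(c("chr1", "chr2"), names(lens)),
    IRanges::IRanges(c(900L, 1900L), c(1100L, 2200L)))
  GenomeAnnotation(lens, toy_genes(), islands,
                   hallmark_map = list(growth = c("gA", "gB"),
                                       immortality = "gC"),
                   genome = genome)
}

# Brute-force positional classifier built straight from the gene
# definitions (independent of the package's feature index).
brute_classify <- function(ann, chrom, pos) {
  cats <- character(0); gene <- character(0)
  for (g in ann$genes) {
    if (g$chrom != chrom) next
    in_any <- function(ir) length(ir) &&
      any(pos >= IRanges::start(ir) & pos <= IRanges::end(ir))
    exons <- lapply(g$transcripts, `[[`, "exons")
    introns <- unlist(lapply(exons, function(ex) {
      if (length(ex) < 2L) return(list())
      lapply(seq_len(length(ex) - 1L), function(i)
        c(IRanges::end(ex)[i] + 1L, IRanges::start(ex)[i + 1L] - 1L))
    }), recursive = FALSE)
    ss <- any(vapply(introns, function(iv)
      pos %in% c(iv[1], iv[1] + 1L, iv[2] - 1L, iv[2]), logical(1)))
    tss <- if (g$strand == "+")
      min(vapply(exons, function(e) min(IRanges::start(e)), numeric(1)))
    else max(vapply(exons, function(e) max(IRanges::end(e)), numeric(1)))
    up <- if (g$strand == "+") pos >= tss - 500L && pos <= tss - 1L
          else pos >= tss + 1L && pos <= tss + 500L
    exonic <- any(vapply(exons, in_any, logical(1)))
    cds <- in_any(g$cds)
    body <- pos >= g$gene_body[1] && pos <= g$gene_body[2]
    cat <- if (ss) "splice_site" else if (cds) "cds"
      else if (exonic) "utr" else if (up) "upstream"
      else if (body) "intronic" else NA_character_
    if (!is.na(cat)) { cats <- c(cats, cat); gene <- c(gene, g$gene_id) }
  }
  if (!length(cats)) return(list(category = "intergenic",
                                 gene_id = NA_character_))
  prec <- c("splice_site", "cds", "utr", "upstream", "intronic")
  for (p in prec) {
    hit <- which(cats == p)
    if (length(hit))
      return(list(category = p, gene_id = sort(gene[hit])[1L]))
  }
}
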