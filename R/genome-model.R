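## Annotation data model and coordinate conventions shared by every stage.
## Internally everything is a GRanges (1-based, closed); 0-based half-open
## coordinates appear only on BED/bedGraph boundaries, where rtracklayer
## performs the conversion.

#' Construct a genome annotation
#'
#' Bundles chromosome lengths, gene models, CpG islands, an optional
#' hallmark-to-gene map and an optional genome sequence into a validated
#' annotation object used by all pipeline stages.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param genes List of gene models as produced by [gene_model()].
#' @param islands `GRanges` of CpG islands (may be empty).
#' @param hallmark_map Named list mapping hallmark names to character
#'   vectors of gene identifiers. All identifiers must exist in `genes`.
#' @param genome Optional `DNAStringSet` with one entry per chromosome.
#' @return An object of class `GenomeAnnotation`.
#' @export
GenomeAnnotation <- function(chrom_lengths, genes = list(),
                             islands = GenomicRanges::GRanges(),
                             hallmark_map = list(), genome = NULL) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genes) <- ids
  for (g in genes) {
    len <- chrom_lengths[g$chrom]
    if (is.na(len)) stop("gene ", g$gene_id, ": unknown chromosome ", g$chrom)
    if (g$gene_body[1] < 1L || g$gene_body[2] > len)
      stop("gene ", g$gene_id, " lies outside chromosome bounds")
  }
  if (length(islands)) {
    isl_len <- chrom_lengths[as.character(GenomeInfoDb::seqnames(islands))]
    if (anyNA(isl_len) || any(start(islands) < 1L) ||
        any(end(islands) > isl_len))
      stop("CpG island outside chromosome bounds")
  }
  bad <- setdiff(unique(unlist(hallmark_map, use.names = FALSE)), ids)
  if (length(bad))
    stop("hallmark map references unknown genes: ",
         paste(bad, collapse = ", "))
  ann <- structure(
    list(chrom_lengths = chrom_lengths, genes = genes, islands = islands,
         hallmark_map = hallmark_map, genome = genome),
    class = "GenomeAnnotation")
  ann$features <- .feature_ranges(ann)
  ann
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier (unique within an annotation).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts List; each element a list with `tx_id` and `exons`
#'   (an `IRanges` of exon intervals, 1-based closed).
#' @param cds Optional `IRanges` of coding intervals (taken from the
#'   most-upstream-TSS transcript when built from GFF3).
#' @return A list of class `GeneModel` with derived fields
#'   `most_upstream_tss`, per-transcript `tss`, `introns`, `splice_sites`,
#'   `exon_union`, `utr` and `gene_body`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts, cds = NULL) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1L)
  transcripts <- lapply(transcripts, function(tx) {
    ex <- sort(tx$exons)
    if (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      stop("gene ", gene_id, ": overlapping exons within a transcript")
    tx$exons <- ex
    tx$tss <- if (strand == "+") min(start(ex)) else max(end(ex))
    ## introns: gaps between consecutive exons
    tx$introns <- if (length(ex) > 1L) {
      s <- head(end(ex), -1L) + 1L
      e <- tail(start(ex), -1L) - 1L
      IRanges::IRanges(s[e >= s], e[e >= s])
    } else IRanges::IRanges()
    tx
  })
  tss_all <- vapply(transcripts, `[[`, numeric(1), "tss")
  mut <- if (strand == "+") min(tss_all) else max(tss_all)
  introns <- do.call(c, lapply(transcripts, `[[`, "introns"))
  ## splice sites: first and last two bases of each intron
  ss <- IRanges::IRanges()
  if (length(introns)) {
    introns <- unique(introns)
    ss <- IRanges::reduce(c(
      IRanges::IRanges(start(introns), pmin(start(introns) + 1L, end(introns))),
      IRanges::IRanges(pmax(end(introns) - 1L, start(introns)), end(introns))))
  }
  exon_union <- IRanges::reduce(do.call(c, lapply(transcripts, `[[`, "exons")))
  cds <- if (is.null(cds)) IRanges::IRanges() else IRanges::reduce(sort(cds))
  utr <- IRanges::setdiff(exon_union, cds)
  body_rng <- range(exon_union)
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         transcripts = transcripts, most_upstream_tss = as.integer(mut),
         cds = cds, exon_union = exon_union, utr = utr,
         introns = IRanges::reduce(introns), splice_sites = ss,
         gene_body = c(start(body_rng), end(body_rng))),
    class = "GeneModel")
}

## One GRanges per positional category, each carrying a gene_id column.
.gene_gr <- function(g, ir, seqlev = NULL) {
  if (!length(ir)) return(GenomicRanges::GRanges())
  sn <- if (is.null(seqlev)) g$chrom else factor(g$chrom, levels = seqlev)
  gr <- GenomicRanges::GRanges(sn, ir, strand = g$strand)
  mcols(gr)$gene_id <- g$gene_id
  gr
}

.feature_ranges <- function(ann, upstream_bp = 500L) {
  sl <- names(ann$chrom_lengths)
  take <- function(field) {
    grl <- lapply(ann$genes, function(g) .gene_gr(g, g[[field]], sl))
    if (!length(grl)) return(GenomicRanges::GRanges())
    do.call(c, unname(grl))
  }
  up <- lapply(ann$genes, function(g) {
    ir <- .upstream_ir(g$most_upstream_tss, g$strand, upstream_bp,
                       ann$chrom_lengths[[g$chrom]])
    .gene_gr(g, ir, sl)
  })
  body <- lapply(ann$genes, function(g)
    .gene_gr(g, IRanges::IRanges(g$gene_body[1], g$gene_body[2]), sl))
  list(splice_site = take("splice_sites"), cds = take("cds"),
       utr = take("utr"),
       upstream = do.call(c, unname(up)),
       body = do.call(c, unname(body)))
}

.upstream_ir <- function(tss, strand, width, chrom_len) {
  if (strand == "+") {
    s <- max(1L, tss - as.integer(width)); e <- tss - 1L
  } else {
    s <- tss + 1L; e <- min(chrom_len, tss + as.integer(width))
  }
  if (e < s) return(IRanges::IRanges())
  IRanges::IRanges(s, e)
}

#' Load an annotation from standard files
#'
#' Reads gene models (GFF3 or 12-column BED), CpG islands (BED), a
#' hallmark-to-gene table (TSV: hallmark, gene_id) and a genome FASTA,
#' and returns a validated [GenomeAnnotation()].
#'
#' @param gene_file Path to a GFF3 (`gene`/`mRNA`/`exon`/`CDS` features)
#'   or BED12 file of gene models.
#' @param island_file Optional path to a BED file of CpG islands.
#' @param hallmark_file Optional path to a two-column TSV (hallmark,
#'   gene_id).
#' @param genome_file Optional path to the genome FASTA; chromosome
#'   lengths are taken from it (falling back to feature extents, with a
#'   warning, when absent).
#' @return A `GenomeAnnotation`.
#' @export
load_annotation <- function(gene_file, island_file = NULL,
                            hallmark_file = NULL, genome_file = NULL) {
  genome <- NULL
  if (!is.null(genome_file)) {
    genome <- Biostrings::readDNAStringSet(genome_file)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  genes <- if (grepl("\\.bed$", gene_file, ignore.case = TRUE))
    .genes_from_bed12(gene_file) else .genes_from_gff3(gene_file)
  islands <- GenomicRanges::GRanges()
  if (!is.null(island_file)) {
    islands <- rtracklayer::import(island_file, format = "BED")
    GenomicRanges::strand(islands) <- "*"
  }
  hallmark_map <- list()
  if (!is.null(hallmark_file)) {
    hm <- read.delim(hallmark_file, header = TRUE,
                     stringsAsFactors = FALSE)
    if (ncol(hm) < 2L)
      stop(hallmark_file, ": expected two columns (hallmark, gene_id)")
    hallmark_map <- split(hm[[2L]], hm[[1L]])
  }
  if (!is.null(genome)) {
    chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  } else {
    ends <- vapply(genes, function(g) g$gene_body[2], numeric(1))
    chroms <- vapply(genes, `[[`, character(1), "chrom")
    chrom_lengths <- tapply(ends, chroms, max)
    warning("no genome given; chromosome lengths set to feature extents")
  }
  GenomeAnnotation(chrom_lengths, genes, islands, hallmark_map, genome)
}

.genes_from_gff3 <- function(path) {
  gff <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gff$type)
  get_parent <- function(x) vapply(x$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  tx_feats <- gff[type %in% c("mRNA", "transcript")]
  ex_feats <- gff[type == "exon"]
  cds_feats <- gff[type == "CDS"]
  ex_parent <- get_parent(ex_feats)
  cds_parent <- get_parent(cds_feats)
  tx_parent <- get_parent(tx_feats)
  lapply(which(type == "gene"), function(i) {
    grec <- gff[i]
    gid <- grec$ID
    if (is.na(gid)) stop(path, ": gene record without ID")
    tx_ids <- tx_feats$ID[tx_parent == gid]
    txs <- lapply(tx_ids, function(tid) {
      ex <- ex_feats[ex_parent == tid]
      if (!length(ex)) stop(path, ": transcript ", tid, " has no exons")
      list(tx_id = tid, exons = ranges(ex))
    })
    strand <- as.character(GenomicRanges::strand(grec))
    tss_all <- vapply(txs, function(tx)
      if (strand == "+") min(start(tx$exons)) else max(end(tx$exons)),
      numeric(1))
    rep_tx <- tx_ids[if (strand == "+") which.min(tss_all)
                     else which.max(tss_all)]
    cds <- ranges(cds_feats[cds_parent == rep_tx])
    gene_model(gid, as.character(GenomeInfoDb::seqnames(grec)), strand,
               txs, cds = if (length(cds)) cds else NULL)
  })
}

.genes_from_bed12 <- function(path) {
  bed <- rtracklayer::import(path, format = "BED")
  lapply(seq_along(bed), function(i) {
    rec <- bed[i]
    blocks <- IRanges::shift(rec$blocks[[1L]], start(rec) - 1L)
    thick <- rec$thick
    cds <- IRanges::intersect(blocks,
                              IRanges::IRanges(start(thick), end(thick)))
    gene_model(rec$name, as.character(GenomeInfoDb::seqnames(rec)),
               as.character(GenomicRanges::strand(rec)),
               list(list(tx_id = paste0(rec$name, ".t1"), exons = blocks)),
               cds = if (length(cds) && width(thick) > 1L) cds else NULL)
  })
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", length(x$chrom_lengths), "chromosomes,",
      length(x$genes), "genes,", length(x$islands), "CpG islands,",
      length(x$hallmark_map), "hallmarks",
      if (!is.null(x$genome)) "(genome attached)" else "", "\n")
  invisible(x)
}

#' Classify genomic positions against the annotation
#'
#' Assigns every position exactly one category with the fixed precedence
#' `splice_site > cds > utr > upstream > intronic > intergenic`, so that
#' per-category counts over any variant set sum to the set's size.
#' `upstream` is the 500 bp strand-aware window upstream of the most
#' upstream TSS. When several genes claim a position at equal precedence
#' the lexicographically smallest gene identifier wins.
#'
#' @param ann A [GenomeAnnotation()].
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions (recycled with `chrom`).
#' @return A data.frame with columns `chrom`, `pos`, `category`, `gene_id`
#'   (`NA` for intergenic).
#' @export
classify_position <- function(ann, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n); pos <- rep_len(as.integer(pos), n)
  unknown <- !(chrom %in% names(ann$chrom_lengths))
  if (any(unknown))
    stop("unknown chromosome: ", paste(unique(chrom[unknown]), collapse = ", "))
  if (any(pos < 1L | pos > ann$chrom_lengths[chrom]))
    stop("position outside chromosome bounds")
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  category <- rep(NA_character_, n); gene_id <- rep(NA_character_, n)
  order_feats <- c("splice_site", "cds", "utr", "upstream", "body")
  labels <- c(splice_site = "splice_site", cds = "cds", utr = "utr",
              upstream = "upstream", body = "intronic")
  for (f in order_feats) {
    todo <- which(is.na(category))
    if (!length(todo)) break
    sub <- ann$features[[f]]
    if (!length(sub)) next
    hits <- GenomicRanges::findOverlaps(q[todo], sub, ignore.strand = TRUE)
    if (!length(hits)) next
    hid <- mcols(sub)$gene_id[subjectHits(hits)]
    ord <- order(queryHits(hits), hid)
    keep <- !duplicated(queryHits(hits)[ord])
    qi <- todo[queryHits(hits)[ord][keep]]
    category[qi] <- labels[[f]]
    gene_id[qi] <- hid[ord][keep]
  }
  category[is.na(category)] <- "intergenic"
  data.frame(chrom = chrom, pos = pos, category = category,
             gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Promoter interval of a gene
#'
#' Two field conventions are supported, both anchored at the most
#' upstream TSS: the chromatin convention (`"window"`, +/- `flank` bp
#' around the TSS) and the methylation convention (`"upstream"`, `flank`
#' bp strictly 5' of the TSS, strand-aware). Intervals are clipped to
#' chromosome bounds.
#'
#' @param ann A [GenomeAnnotation()].
#' @param gene_id Gene identifier(s).
#' @param mode `"window"` or `"upstream"`.
#' @param flank Flank size in bp (default 1500).
#' @return A `GRanges` with one range per gene (`gene_id` metadata column).
#' @export
promoter_of <- function(ann, gene_id, mode = c("window", "upstream"),
                        flank = 1500L) {
  mode <- match.arg(mode)
  flank <- as.integer(flank)
  grl <- lapply(gene_id, function(gid) {
    g <- ann$genes[[gid]]
    if (is.null(g)) stop("unknown gene: ", gid)
    len <- ann$chrom_lengths[[g$chrom]]
    tss <- g$most_upstream_tss
    ir <- if (mode == "window") {
      IRanges::IRanges(max(1L, tss - flank), min(len, tss + flank - 1L))
    } else {
      .upstream_ir(tss, g$strand, flank, len)
    }
    .gene_gr(g, ir, names(ann$chrom_lengths))
  })
  do.call(c, grl)
}

#' Enhancer territory of a gene (100 kb upstream of the TSS plus the
#' gene body), used to assign enhancer clusters to genes.
#'
#' @inheritParams promoter_of
#' @param upstream Upstream extent in bp (default 100000).
#' @return `GRanges`, one range per gene.
#' @export
gene_territory <- function(ann, gene_id, upstream = 1e5) {
  grl <- lapply(gene_id, function(gid) {
    g <- ann$genes[[gid]]
    if (is.null(g)) stop("unknown gene: ", gid)
    len <- ann$chrom_lengths[[g$chrom]]
    if (g$strand == "+") {
      s <- max(1L, g$most_upstream_tss - as.integer(upstream))
      e <- g$gene_body[2]
    } else {
      s <- g$gene_body[1]
      e <- min(len, g$most_upstream_tss + as.integer(upstream))
    }
    .gene_gr(g, IRanges::IRanges(s, e), names(ann$chrom_lengths))
  })
  do.call(c, grl)
}

#' Gene-body intervals as GRanges
#' @inheritParams promoter_of
#' @return `GRanges`, one range per gene.
#' @export
gene_body_of <- function(ann, gene_id) {
  grl <- lapply(gene_id, function(gid) {
    g <- ann$genes[[gid]]
    .gene_gr(g, IRanges::IRanges(g$gene_body[1], g$gene_body[2]),
             names(ann$chrom_lengths))
  })
  do.call(c, grl)
}

#' Effective gene length (kb): union of exon intervals across transcripts
#' @inheritParams promoter_of
#' @return Numeric vector of lengths in kb.
#' @export
gene_length_kb <- function(ann, gene_id = names(ann$genes)) {
  vapply(gene_id, function(gid)
    sum(width(ann$genes[[gid]]$exon_union)) / 1000, numeric(1))
}

#' Coding effect of a single-nucleotide substitution
#'
#' Determines whether a substitution inside the coding sequence is
#' synonymous under the standard genetic code, translating the codon it
#' falls in on the CDS of the most-upstream-TSS transcript. Requires the
#' genome sequence to be attached to the annotation.
#'
#' @param ann A [GenomeAnnotation()] with `genome` attached.
#' @param chrom,pos Position of the substitution (1-based).
#' @param ref,alt Reference and alternate bases (sense strand of the
#'   genome).
#' @return `"synonymous"`, `"non_synonymous"`, or `"n/a"` when the
#'   position is not in any CDS.
#' @export
coding_effect <- function(ann, chrom, pos, ref, alt) {
  if (is.null(ann$genome)) stop("annotation has no genome sequence")
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  vapply(seq_len(n), function(i) {
    .coding_effect1(ann, chrom[i], pos[i], ref[i], alt[i])
  }, character(1))
}

.coding_effect1 <- function(ann, chrom, pos, ref, alt) {
  if (nchar(ref) != 1L || nchar(alt) != 1L) return("n/a")
  hit <- NULL
  for (g in ann$genes) {
    if (g$chrom == chrom && length(g$cds) &&
        any(pos >= start(g$cds) & pos <= end(g$cds))) { hit <- g; break }
  }
  if (is.null(hit)) return("n/a")
  cds <- hit$cds  # sorted, genomic order
  seq <- unlist(lapply(seq_along(cds), function(j)
    strsplit(as.character(Biostrings::subseq(
      ann$genome[[chrom]], start(cds)[j], end(cds)[j])), "")[[1L]]))
  offs <- unlist(lapply(seq_along(cds), function(j)
    seq.int(start(cds)[j], end(cds)[j])))
  idx <- match(pos, offs)
  if (seq[idx] != ref)
    warning("reference mismatch at ", chrom, ":", pos,
            " (genome ", seq[idx], ", given ", ref, ")")
  mut <- seq; mut[idx] <- alt
  if (hit$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    seq <- rev(comp[seq]); mut <- rev(comp[mut])
    idx <- length(seq) - idx + 1L
  }
  codon_i <- (idx - 1L) %/% 3L
  cstart <- codon_i * 3L + 1L
  if (cstart + 2L > length(seq)) return("n/a")  # trailing partial codon
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[paste(seq[cstart:(cstart + 2L)], collapse = "")]]
  aa_alt <- code[[paste(mut[cstart:(cstart + 2L)], collapse = "")]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "non_synonymous"
}
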