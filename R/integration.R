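## Cross-layer integration: regulatory-mutation overlap, per-gene
## multi-omics status, hallmark scoring and the published-marginal
## accounting.

.var_gr <- function(vars) {
  GenomicRanges::GRanges(vars$chrom, IRanges::IRanges(vars$pos, vars$pos))
}

.genes_with_call <- function(calls, line, layer_prefix, feature_to_gene = NULL) {
  sub <- calls[calls$cell_line == line &
                 startsWith(calls$layer, layer_prefix), , drop = FALSE]
  ids <- sub$feature_id
  if (!is.null(feature_to_gene))
    ids <- unlist(feature_to_gene[ids], use.names = FALSE)
  unique(ids[!is.na(ids)])
}

#' Mutations in regulatory regions
#'
#' Counts, per cell line and separately for SNVs and indels, the
#' somatic variants overlapping promoters (+/- 1.5 kb windows),
#' promoters of genes with a differential H3K4me3 call, gene-assigned
#' enhancer clusters of each enhancer mark, clusters whose mark is
#' differential in that line, differentially methylated promoters
#' (methylation convention, 1.5 kb upstream), and the regulatory union
#' (promoters plus assigned enhancers; a variant in several component
#' rows is counted once in the union).
#'
#' @param vars Annotated somatic variant data.frame (with `status`).
#' @param ann A [GenomeAnnotation()].
#' @param enhancer_clusters Named list (mark -> [cluster_enhancers()]
#'   result) for the enhancer marks.
#' @param diff_calls data.frame of differential calls across layers
#'   (layer `"chromatin:<mark>"` and `"methylation"` rows are used).
#' @return A `RegulatoryMutationTable` data.frame: one row per cell
#'   line x var_type x region row, column `count`.
#' @export
regulatory_overlap <- function(vars, ann, enhancer_clusters = list(),
                               diff_calls = NULL) {
  som <- somatic_variants(vars)
  proms <- promoter_of(ann, names(ann$genes), mode = "window")
  proms_meth <- promoter_of(ann, names(ann$genes), mode = "upstream")
  if (is.null(diff_calls))
    diff_calls <- data.frame(feature_id = character(),
                             cell_line = character(), layer = character(),
                             direction = character(), fold = numeric())
  cluster_gene_map <- lapply(enhancer_clusters, function(cl)
    setNames(strsplit(cl$gene_ids, ","), cl$cluster_id))
  assigned_rng <- lapply(enhancer_clusters, function(cl) {
    rng <- attr(cl, "ranges")
    rng[cl$gene_ids != ""]
  })
  assigned_ids <- lapply(enhancer_clusters, function(cl)
    cl$cluster_id[cl$gene_ids != ""])
  lines <- sort(unique(som$cell_line))
  rows <- list()
  for (line in lines) {
    sub <- som[som$cell_line == line, , drop = FALSE]
    for (vt in c("SNV", "indel")) {
      v <- sub[sub$var_type == vt, , drop = FALSE]
      gr <- .var_gr(v)
      in_prom <- IRanges::overlapsAny(gr, proms, ignore.strand = TRUE)
      ## promoters of genes with a differential H3K4me3 call in this line
      dg <- .genes_with_call(diff_calls, line, "chromatin:H3K4me3")
      dprom <- proms[mcols(proms)$gene_id %in% dg]
      in_dprom <- IRanges::overlapsAny(gr, dprom, ignore.strand = TRUE)
      mg <- .genes_with_call(diff_calls, line, "methylation")
      mprom <- proms_meth[mcols(proms_meth)$gene_id %in% mg]
      in_mprom <- IRanges::overlapsAny(gr, mprom, ignore.strand = TRUE)
      union_hit <- in_prom
      counts <- list(promoter = sum(in_prom),
                     promoter_diff_H3K4me3 = sum(in_dprom),
                     promoter_diff_methylation = sum(in_mprom))
      for (mk in names(enhancer_clusters)) {
        rng <- assigned_rng[[mk]]
        in_enh <- IRanges::overlapsAny(gr, rng, ignore.strand = TRUE)
        counts[[paste0("enhancer_", mk)]] <- sum(in_enh)
        union_hit <- union_hit | in_enh
        ## clusters assigned to this mark that are differential in line
        dcl <- .genes_with_call(diff_calls, line,
                                paste0("chromatin:", mk))
        drng <- rng[assigned_ids[[mk]] %in% dcl]
        counts[[paste0("enhancer_diff_", mk)]] <-
          sum(IRanges::overlapsAny(gr, drng, ignore.strand = TRUE))
      }
      counts$regulatory_union <- sum(union_hit)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = line, var_type = vt, region = names(counts),
        count = as.integer(unlist(counts)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("RegulatoryMutationTable", class(out))
  out
}

#' Per-gene multi-omics status
#'
#' Reproduces the per-gene status conventions of the panel report:
#' expression `no_exp` at <= 1 RPKM, `up`/`down` at >= 4-fold /
#' <= 1/16-fold of the panel average, else `normal`; methylation
#' `up`/`down` from differential methylation calls; CNA `amp`
#' (normalized copy number >= 8) or `del` (loss longer than 1 kb);
#' a coding-mutation flag for CDS/splice-site variants; and the list
#' of differential chromatin marks. Layers without data give `"n.s."`.
#'
#' @param gene_id,cell_line Vectors (recycled) selecting rows.
#' @param layers List with any of: `expression` (an `ExpressionMatrix`),
#'   `diff_expression`, `diff_methylation`, `diff_chromatin`
#'   (differential-call data.frames), `cna` (named list cell line ->
#'   [call_cna()] data.frame), `variants` (annotated variant
#'   data.frame).
#' @return data.frame with one row per gene/line and status columns.
#' @export
gene_status <- function(gene_id, cell_line, layers) {
  n <- max(length(gene_id), length(cell_line))
  gene_id <- rep_len(gene_id, n); cell_line <- rep_len(cell_line, n)
  expr_status <- rep("n.s.", n); meth_status <- rep("n.s.", n)
  cna_status <- rep("n.s.", n); chrom_status <- rep("n.s.", n)
  coding_mut <- rep(NA, n)
  for (i in seq_len(n)) {
    g <- gene_id[i]; l <- cell_line[i]
    ex <- layers$expression
    if (!is.null(ex) && g %in% rownames(ex$rpkm) &&
        l %in% colnames(ex$rpkm)) {
      rpkm <- ex$rpkm[g, l]
      de <- layers$diff_expression
      dir <- if (!is.null(de))
        de$direction[de$feature_id == g & de$cell_line == l] else character()
      expr_status[i] <- if (rpkm <= 1) "no_exp"
        else if ("higher" %in% dir) "up"
        else if ("lower" %in% dir) "down" else "normal"
    }
    dm <- layers$diff_methylation
    if (!is.null(dm)) {
      dir <- dm$direction[dm$feature_id == g & dm$cell_line == l]
      meth_status[i] <- if ("higher" %in% dir) "up"
        else if ("lower" %in% dir) "down" else "n.s."
    }
    cna <- layers$cna[[l]]
    if (!is.null(cna)) {
      hit <- cna[vapply(strsplit(cna$gene_ids, ","), function(x)
        g %in% x, logical(1)), , drop = FALSE]
      cna_status[i] <- if (any(hit$class == "amplification")) "amp"
        else if (any(hit$class == "deletion")) "del" else "none"
    }
    va <- layers$variants
    if (!is.null(va)) {
      coding_mut[i] <- any(va$cell_line == l & !is.na(va$gene_id) &
                             va$gene_id == g &
                             va$category %in% c("cds", "splice_site"))
    }
    dc <- layers$diff_chromatin
    if (!is.null(dc)) {
      sub <- dc[dc$feature_id == g & dc$cell_line == l &
                  startsWith(dc$layer, "chromatin:"), , drop = FALSE]
      chrom_status[i] <- if (nrow(sub))
        paste(paste0(sub("chromatin:", "", sub$layer),
                     ifelse(sub$direction == "higher", "+", "-")),
              collapse = ",") else "n.s."
    }
  }
  out <- data.frame(gene_id = gene_id, cell_line = cell_line,
                    expression = expr_status, methylation = meth_status,
                    cna = cna_status, coding_mutation = coding_mut,
                    chromatin = chrom_status, stringsAsFactors = FALSE)
  out[order(out$gene_id, out$cell_line), , drop = FALSE]
}

#' Hallmark aberration scores
#'
#' For each hallmark, the denominator is the number of assigned genes
#' expressed above 1 RPKM in at least one cell line; per line, the
#' percentage of those genes carrying (a) CDS/splice-site mutations,
#' (b) differential expression, (c) differential methylation,
#' (d) differential H3K4me3/H3K27me3/H3K9me3 marks is reported.
#'
#' @param ann A [GenomeAnnotation()] with a hallmark map.
#' @param layers As in [gene_status()] (`expression`, `variants`,
#'   `diff_expression`, `diff_methylation`, `diff_chromatin`).
#' @param marks Chromatin marks counted in class (d)
#'   (default H3K4me3, H3K27me3, H3K9me3).
#' @param expressed_rpkm Expression filter (strict `>`, default 1).
#' @return A `HallmarkReport` data.frame: hallmark, cell_line,
#'   n_genes (denominator), and count/percentage per aberration class.
#' @export
hallmark_scores <- function(ann, layers,
                            marks = c("H3K4me3", "H3K27me3", "H3K9me3"),
                            expressed_rpkm = 1) {
  ex <- layers$expression
  stopifnot(!is.null(ex))
  expressed_any <- rownames(ex$rpkm)[
    apply(ex$rpkm > expressed_rpkm, 1L, any)]
  lines <- colnames(ex$rpkm)
  va <- layers$variants
  rows <- list()
  for (hm in names(ann$hallmark_map)) {
    genes <- intersect(ann$hallmark_map[[hm]], expressed_any)
    denom <- length(genes)
    for (line in lines) {
      mut_genes <- if (!is.null(va))
        unique(va$gene_id[va$cell_line == line & !is.na(va$gene_id) &
                            va$category %in% c("cds", "splice_site")])
        else character()
      de <- .genes_with_call(layers$diff_expression %||% .empty_calls(),
                             line, "expression")
      dm <- .genes_with_call(layers$diff_methylation %||% .empty_calls(),
                             line, "methylation")
      dc_all <- layers$diff_chromatin %||% .empty_calls()
      dc <- unique(unlist(lapply(marks, function(mk)
        .genes_with_call(dc_all, line, paste0("chromatin:", mk)))))
      counts <- c(mutation = length(intersect(genes, mut_genes)),
                  expression = length(intersect(genes, de)),
                  methylation = length(intersect(genes, dm)),
                  chromatin = length(intersect(genes, dc)))
      pct <- if (denom > 0) 100 * counts / denom else rep(NA_real_, 4L)
      rows[[length(rows) + 1L]] <- data.frame(
        hallmark = hm, cell_line = line, n_genes = denom,
        t(counts), t(setNames(pct, paste0("pct_", names(counts)))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("HallmarkReport", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_calls <- function() {
  data.frame(feature_id = character(), cell_line = character(),
             layer = character(), direction = character(),
             fold = numeric(), stringsAsFactors = FALSE)
}

#' Aberration flags versus a normal reference line
#'
#' A gene is aberrant in a cancer line when the normal line transcribes
#' it (value > `transcribed_min`) and the cancer/normal fold reaches
#' `high` or falls to `low`, or when the normal line does not
#' (value <= `transcribed_min`) and the cancer value exceeds
#' `not_transcribed_min`. The same rule serves expression (RPKM,
#' thresholds 1 and 5) and chromatin marks (PPM, thresholds 1 and 5).
#'
#' @param cancer Matrix genes x cancer lines (RPKM or PPM).
#' @param normal Named numeric vector for the normal line (same genes).
#' @param high,low Fold thresholds (defaults 4 and 1/16).
#' @param transcribed_min,not_transcribed_min Level thresholds
#'   (defaults 1 and 5).
#' @return List with `flags` (logical genes x lines matrix),
#'   `direction` (character matrix: higher/lower/induced/`NA`) and
#'   `any_line` (logical vector).
#' @export
normal_comparison <- function(cancer, normal, high = 4, low = 1 / 16,
                              transcribed_min = 1,
                              not_transcribed_min = 5) {
  normal <- normal[rownames(cancer)]
  if (anyNA(normal)) stop("normal values missing for some genes")
  flags <- matrix(FALSE, nrow(cancer), ncol(cancer),
                  dimnames = dimnames(cancer))
  dir <- matrix(NA_character_, nrow(cancer), ncol(cancer),
                dimnames = dimnames(cancer))
  transcribed <- normal > transcribed_min
  fold <- sweep(cancer, 1L, normal, "/")
  hi <- transcribed & fold >= high
  lo <- transcribed & fold <= low
  ind <- !transcribed & cancer > not_transcribed_min
  flags[hi | lo | ind] <- TRUE
  dir[hi] <- "higher"; dir[lo] <- "lower"; dir[ind] <- "induced"
  list(flags = flags, direction = dir,
       any_line = apply(flags, 1L, any))
}

#' Derived figures from published burden marginals
#'
#' Recomputes every derived accounting figure from a per-category
#' marginal table of somatic SNV/indel counts (such as the published
#' counts shipped in
#' `system.file("extdata", "published_burden_marginals.tsv",
#' package = "panelomics")`, reported for a 26-line lung adenocarcinoma
#' panel): combined somatic totals and per-line means, the coding
#' burden (non-synonymous SNVs plus CDS indels), the regulatory burden,
#' per-category combined counts and the genic fraction.
#'
#' @param marginals data.frame with columns `section` (`A` totals with
#'   per-line averages, `B` per-line averages only), `category`,
#'   `snv_total`, `snv_avg`, `indel_total`, `indel_avg`.
#' @return List of derived figures.
#' @export
derive_burden_figures <- function(marginals) {
  m <- marginals
  row <- function(cat) m[m$category == cat, , drop = FALSE]
  tot <- function(cat) {
    r <- row(cat); r$snv_total + r$indel_total
  }
  avg <- function(cat) {
    r <- row(cat); r$snv_avg + r$indel_avg
  }
  somatic_total <- tot("somatic")
  genic_total <- tot("genic")
  list(
    somatic_total = somatic_total,
    somatic_avg_per_line = avg("somatic"),
    genic_total = genic_total,
    genic_fraction_pct = 100 * genic_total / somatic_total,
    intergenic_fraction_pct = 100 * tot("intergenic") / somatic_total,
    upstream_total = tot("upstream"),
    utr_total = tot("utr"),
    cds_total = tot("cds"),
    splice_site_total = tot("splice_site"),
    non_synonymous_snv_total = row("non_synonymous")$snv_total,
    coding_burden_avg = row("non_synonymous")$snv_avg + row("cds")$indel_avg,
    regulatory_avg = avg("regulatory"),
    partition_ok =
      isTRUE(all.equal(tot("genic") + tot("intergenic"), somatic_total)))
}

#' Read the published burden marginals shipped with the package
#' @return data.frame in the format of [derive_burden_figures()].
#' @export
published_burden_marginals <- function() {
  read.delim(system.file("extdata", "published_burden_marginals.tsv",
                         package = "panelomics", mustWork = TRUE),
             stringsAsFactors = FALSE)
}
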