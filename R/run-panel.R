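## End-to-end orchestrator: chains every stage over an on-disk panel
## (as produced by generate_panel() or assembled in the same layout)
## and writes the integrated report tables.

.read_counts_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Run the full multi-omics pipeline over a panel directory
#'
#' Loads the annotation, then runs variant screening/germline
#' removal/burden accounting, copy-number and junction calling,
#' expression quantification with differential calls, bisulfite mapping
#' with methylation rates and differential promoter methylation, ChIP
#' promoter/enhancer association with differential marks and mark
#' correlations, and the integration layer (regulatory overlap, gene
#' status, hallmark scores, normal comparison). Stage outputs are
#' written as TSV/BED/bedGraph under `out_dir` together with a JSON run
#' manifest.
#'
#' @param dir Panel directory (layout of [generate_panel()]).
#' @param out_dir Output directory (default `file.path(dir, "results")`).
#' @param include_focal Differential-contract convention for implanted
#'   effect screening (default `FALSE`, the focal-exclusive mean; the
#'   panel-inclusive convention is the contract default for
#'   free-standing calls).
#' @param run_methylation Run the bisulfite stage (the slowest stage;
#'   default `TRUE`).
#' @param thresholds Named list overriding stage thresholds
#'   (`min_var_reads`, `max_pop_af`, `gain_cn`, `loss_cn`, `amp_cn`,
#'   `min_ref`, `min_supp`, `expressed_rpkm`, `diff_high`, `diff_low`,
#'   `min_depth`, `ppm_min`).
#' @return A `PanelReport` list with every stage result.
#' @export
run_panel <- function(dir, out_dir = file.path(dir, "results"),
                      include_focal = FALSE, run_methylation = TRUE,
                      thresholds = list()) {
  th <- modifyList(list(min_var_reads = 4, max_pop_af = 0.001,
                        gain_cn = 4, loss_cn = 1, amp_cn = 8,
                        min_ref = 2, min_supp = 4,
                        expressed_rpkm = 1, diff_high = 4,
                        diff_low = 1 / 16, min_depth = 5, ppm_min = 1),
                   thresholds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- load_annotation(file.path(dir, "genes.gff3"),
                         island_file = file.path(dir, "cpg_islands.bed"),
                         hallmark_file = file.path(dir, "hallmarks.tsv"),
                         genome_file = file.path(dir, "genome.fa"))
  line_dirs <- list.dirs(file.path(dir, "lines"), recursive = FALSE)
  lines_all <- sort(basename(line_dirs))
  has_variants <- vapply(lines_all, function(l)
    file.exists(file.path(dir, "lines", l, "variants.tsv")), logical(1))
  cancer_lines <- lines_all[has_variants]
  normal_line <- setdiff(lines_all, cancer_lines)
  normal_line <- if (length(normal_line)) normal_line[1L] else NULL

  ## -- variants
  cands <- do.call(rbind, lapply(cancer_lines, function(l)
    read_variants(file.path(dir, "lines", l, "variants.tsv"))))
  screened <- screen_candidates(cands, min_var_reads = th$min_var_reads)
  statused <- remove_germline(screened, max_pop_af = th$max_pop_af)
  burden <- annotate_and_tabulate(statused, ann)
  write_burden_table(burden, file.path(out_dir, "burden_table.tsv"))

  ## -- copy number (gene-level calls from the 1.5 kb track)
  cna <- lapply(setNames(cancer_lines, cancer_lines), function(l) {
    tr <- read_copy_ratio(file.path(dir, "lines", l, "cn_1500.bedgraph"))
    call_cna(tr, ann, gain_cn = th$gain_cn, loss_cn = th$loss_cn,
             amp_cn = th$amp_cn)
  })
  cna_all <- do.call(rbind, lapply(cancer_lines, function(l) {
    x <- cna[[l]]
    if (nrow(x)) cbind(cell_line = l, x) else NULL
  }))
  if (!is.null(cna_all))
    write.table(cna_all, file.path(out_dir, "cna.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  ## -- rearrangements
  pairs <- do.call(rbind, lapply(cancer_lines, function(l)
    read_mate_pairs(file.path(dir, "lines", l, "matepairs.tsv"))))
  junctions <- call_junctions(all_pairs = pairs, ann = ann,
                              min_ref = th$min_ref,
                              min_supp = th$min_supp)
  write_junctions_bedpe(junctions, file.path(out_dir, "junctions.bedpe"))

  ## -- expression
  counts <- .read_counts_table(file.path(dir, "counts.tsv"))
  expr <- quantify(counts, gene_length_kb(ann))
  expressed <- call_expressed(expr, threshold = th$expressed_rpkm)
  cancer_rpkm <- expr$rpkm[, cancer_lines, drop = FALSE]
  diff_expr <- call_differential(cancer_rpkm, layer = "expression",
                                 high = th$diff_high, low = th$diff_low,
                                 include_focal = include_focal)
  fus_path <- file.path(dir, "fusions.tsv")
  fusions <- if (file.exists(fus_path))
    filter_fusions(read.delim(fus_path, stringsAsFactors = FALSE))
    else NULL

  ## -- methylation
  meth_tables <- NULL; diff_meth <- .empty_calls(); conv <- NULL
  if (run_methylation) {
    som <- somatic_variants(statused)
    meth_tables <- lapply(setNames(cancer_lines, cancer_lines),
                          function(l) {
      r1 <- as.character(Biostrings::readDNAStringSet(
        file.path(dir, "lines", l, "bs_R1.fastq"), format = "fastq"))
      r2 <- as.character(Biostrings::readDNAStringSet(
        file.path(dir, "lines", l, "bs_R2.fastq"), format = "fastq"))
      summ <- map_and_count(r1, r2, ann$genome)
      list(summary = summ, qc = conversion_qc(summ),
           table = site_rates(summ, ann,
                              variants = som[som$cell_line == l, ],
                              min_depth = th$min_depth))
    })
    conv <- data.frame(
      cell_line = cancer_lines,
      conversion_rate_pct = vapply(meth_tables, function(x)
        x$qc$conversion_rate_pct, numeric(1)),
      pass = vapply(meth_tables, function(x) x$qc$pass, logical(1)))
    pm <- promoter_rate_matrix(lapply(meth_tables, `[[`, "table"))
    diff_meth <- call_differential_methylation(
      pm, high = th$diff_high, low = th$diff_low,
      include_focal = include_focal)
    write_methylation_bedgraph(meth_tables[[1L]]$table,
                               file.path(out_dir,
                                         "methylation_rates.bedgraph"))
  }

  ## -- chromatin
  tracks <- list(); peaks <- list()
  for (l in lines_all) {
    peaks[[l]] <- list()
    wce_path <- file.path(dir, "lines", l, "chip", "WCE.bedgraph")
    for (mk in CHROMATIN_MARKS) {
      bp <- file.path(dir, "lines", l, "chip", paste0(mk, ".bedgraph"))
      if (!file.exists(bp)) next
      tracks[[paste(l, mk)]] <- chip_track(l, mk, bp, wce_path)
      pkp <- file.path(dir, "lines", l, "peaks", paste0(mk, ".bed"))
      if (file.exists(pkp) && file.size(pkp) > 0)
        peaks[[l]][[mk]] <- rtracklayer::import(pkp, format = "BED")
      else peaks[[l]][[mk]] <- GenomicRanges::GRanges()
    }
  }
  cancer_tracks <- Filter(function(t) t$cell_line %in% cancer_lines,
                          tracks)
  pmt <- promoter_mark_table(cancer_tracks, peaks, ann)
  enh_marks <- MARK_CLASSES$enhancer
  clusters <- lapply(setNames(enh_marks, enh_marks), function(mk)
    cluster_enhancers(lapply(setNames(cancer_lines, cancer_lines),
                             function(l) peaks[[l]][[mk]]),
                      ann, mark = mk))
  diff_chrom <- list()
  for (mk in setdiff(CHROMATIN_MARKS, enh_marks)) {
    diff_chrom[[mk]] <- call_differential_marks(
      pmt[[mk]]$intensity[, cancer_lines, drop = FALSE],
      pmt[[mk]]$ppm[, cancer_lines, drop = FALSE], mk,
      ppm_min = th$ppm_min, high = th$diff_high, low = th$diff_low,
      include_focal = include_focal)
  }
  enh_int <- list()
  for (mk in enh_marks) {
    trs <- Filter(function(t) t$mark == mk, cancer_tracks)
    enh_int[[mk]] <- enhancer_intensity(clusters[[mk]], trs)
    diff_chrom[[mk]] <- call_differential_marks(
      enh_int[[mk]]$intensity, enh_int[[mk]]$ppm, mk,
      ppm_min = th$ppm_min, high = th$diff_high, low = th$diff_low,
      include_focal = include_focal)
  }
  diff_chrom_all <- do.call(rbind, unname(diff_chrom))
  ## mark correlations over promoter-window + gene-body intensities
  bodies <- gene_body_of(ann, names(ann$genes))
  proms <- promoter_of(ann, names(ann$genes), mode = "window")
  prox <- GenomicRanges::punion(proms, bodies, fill.gap = TRUE)
  cor_int <- lapply(setNames(CHROMATIN_MARKS, CHROMATIN_MARKS),
                    function(mk) {
    m <- matrix(NA_real_, length(prox), length(cancer_lines),
                dimnames = list(names(ann$genes), cancer_lines))
    for (tr in cancer_tracks)
      if (tr$mark == mk) m[, tr$cell_line] <- region_intensity(tr, prox)
    m
  })
  mark_cor <- mark_correlations(cor_int)

  ## -- integration
  diff_all <- rbind(diff_expr, diff_meth, diff_chrom_all)
  reg <- regulatory_overlap(statused, ann, clusters, diff_all)
  write.table(reg, file.path(out_dir, "regulatory_overlap.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  layers <- list(expression = expr, diff_expression = diff_expr,
                 diff_methylation = diff_meth,
                 diff_chromatin = diff_chrom_all, cna = cna,
                 variants = somatic_variants(burden$variants))
  status <- gene_status(rep(names(ann$genes), each = length(cancer_lines)),
                        rep(cancer_lines, length(ann$genes)), layers)
  write.table(status, file.path(out_dir, "gene_status.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hallmarks <- if (length(ann$hallmark_map))
    hallmark_scores(ann, layers) else NULL
  if (!is.null(hallmarks))
    write.table(hallmarks, file.path(out_dir, "hallmark_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  normal_cmp <- NULL
  if (!is.null(normal_line) && normal_line %in% colnames(expr$rpkm))
    normal_cmp <- normal_comparison(cancer_rpkm,
                                    expr$rpkm[, normal_line])
  manifest <- list(package_version =
                     as.character(utils::packageVersion("panelomics")),
                   panel_dir = dir, thresholds = th,
                   include_focal = include_focal,
                   cell_lines = cancer_lines, normal_line = normal_line,
                   timestamp = "unset")
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  structure(list(annotation = ann, burden = burden, cna = cna,
                 junctions = junctions, expression = expr,
                 expressed = expressed, diff_expression = diff_expr,
                 fusions = fusions, methylation = meth_tables,
                 conversion_qc = conv, diff_methylation = diff_meth,
                 promoter_marks = pmt, enhancer_clusters = clusters,
                 enhancer_intensity = enh_int,
                 diff_chromatin = diff_chrom_all,
                 mark_correlations = mark_cor,
                 regulatory_overlap = reg, gene_status = status,
                 hallmarks = hallmarks, normal_comparison = normal_cmp,
                 out_dir = out_dir),
            class = "PanelReport")
}

#' @export
print.PanelReport <- function(x, ...) {
  cat("PanelReport:", x$burden$summary$n_cell_lines, "cell lines;",
      x$burden$summary$somatic_total, "somatic variants;",
      nrow(x$junctions), "junctions;",
      nrow(x$diff_expression), "differential-expression calls\n")
  invisible(x)
}
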