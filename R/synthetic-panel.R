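## Seeded synthetic-panel generator. Emits a toy genome, annotation and
## per-cell-line omics inputs (variant TSVs, copy-ratio bedGraphs, mate
## pairs, count tables, paired bisulfite FASTQ, ChIP/WCE bedGraphs and
## peak BEDs) together with a JSON ground-truth record sufficient to
## score the recovery of every implanted feature.

#' Specification of a synthetic panel
#'
#' Defaults describe the study conditions every test runs under: a
#' 4-line panel plus one normal reference on a 2 x 200 kb genome with
#' 30 three-exon genes, sequencing evidence at 33x mean depth,
#' target-captured bisulfite reads at ~60x over islands and promoters
#' with a 0.8% conversion-failure rate (a 99.2% conversion rate), and fold-of-WCE ChIP tracks for
#' the eight chromatin marks.
#'
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @param cell_lines Cancer cell-line names.
#' @param normal_line Normal reference line name.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param genes_per_chrom Genes per chromosome.
#' @param depth_mean Mean sequencing depth for variant evidence
#'   (Poisson).
#' @param vaf Variant allele fraction for implanted variants.
#' @param cn_windows Copy-ratio window sizes (bp).
#' @param insert_mean,insert_sd Mate-pair insert geometry.
#' @param read_len,frag_len,bs_depth,conv_fail Bisulfite read length,
#'   fragment length, target depth over baits, conversion-failure rate.
#' @param beta_island,beta_other Beta parameters (shape1, shape2) of
#'   per-CpG methylation probabilities inside/outside islands.
#' @param chip_window,chip_bg,chip_peak ChIP window size and Poisson
#'   rates for background and peak windows.
#' @return A `PanelSpec` list.
#' @export
panel_spec <- function(seed = 1L,
                       cell_lines = paste0("LINE", 1:4),
                       normal_line = "NORMAL",
                       chrom_lengths = c(chr1 = 200000L, chr2 = 200000L),
                       genes_per_chrom = 15L,
                       depth_mean = 33, vaf = 0.5,
                       cn_windows = c(1500L, 50000L),
                       insert_mean = 300, insert_sd = 30,
                       read_len = 100L, frag_len = 200L,
                       bs_depth = 60, conv_fail = 0.008,
                       beta_island = c(0.6, 5), beta_other = c(5, 1.5),
                       chip_window = 200L, chip_bg = 4, chip_peak = 80) {
  structure(as.list(environment()), class = "PanelSpec")
}

## ---- deterministic gene layout -------------------------------------

.panel_layout <- function(spec) {
  chroms <- names(spec$chrom_lengths)
  n <- spec$genes_per_chrom
  genes <- list()
  for (ci in seq_along(chroms)) {
    for (j in seq_len(n)) {
      idx <- (ci - 1L) * n + j
      gstart <- 4000L + (j - 1L) * 13000L
      strand <- if (idx %% 2L == 1L) "+" else "-"
      ex <- IRanges::IRanges(gstart + c(0L, 1500L, 3600L),
                             gstart + c(799L, 2299L, 4399L))
      cds <- IRanges::IRanges(gstart + c(1600L, 3600L),
                              gstart + c(2299L, 3901L))
      genes[[idx]] <- gene_model(sprintf("g%02d", idx), chroms[ci],
                                 strand, list(list(
                                   tx_id = sprintf("g%02d.t1", idx),
                                   exons = ex)), cds = cds)
    }
  }
  ## islands on every third promoter plus two intergenic ones
  isl <- list()
  for (g in genes) {
    idx <- as.integer(sub("g", "", g$gene_id))
    if (idx %% 3L == 1L) {
      tss <- g$most_upstream_tss
      isl[[length(isl) + 1L]] <- GenomicRanges::GRanges(
        factor(g$chrom, chroms), IRanges::IRanges(tss - 300L, tss + 299L))
    }
  }
  isl[[length(isl) + 1L]] <- GenomicRanges::GRanges(
    factor(chroms[1], chroms), IRanges::IRanges(1200L, 1799L))
  isl[[length(isl) + 1L]] <- GenomicRanges::GRanges(
    factor(chroms[2], chroms), IRanges::IRanges(197500L, 198099L))
  islands <- sort(do.call(c, isl))
  hallmarks <- c("sustaining_proliferative_signaling",
                 "evading_growth_suppressors",
                 "resisting_cell_death",
                 "enabling_replicative_immortality",
                 "inducing_angiogenesis",
                 "activating_invasion_metastasis",
                 "genome_instability_mutation",
                 "tumor_promoting_inflammation",
                 "deregulating_cellular_energetics",
                 "avoiding_immune_destruction")
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  hallmark_map <- split(ids, rep(hallmarks, each = 3L))
  list(genes = genes, islands = islands, hallmark_map = hallmark_map,
       gene_ids = ids)
}

.random_genome <- function(spec, islands) {
  bases <- c("A", "C", "G", "T")
  out <- lapply(names(spec$chrom_lengths), function(cn) {
    L <- spec$chrom_lengths[[cn]]
    v <- sample(bases, L, replace = TRUE, prob = c(.3, .2, .2, .3))
    isl <- islands[GenomeInfoDb::seqnames(islands) == cn]
    for (i in seq_along(isl)) {
      idx <- start(isl)[i]:end(isl)[i]
      v[idx] <- sample(bases, length(idx), replace = TRUE,
                       prob = c(.15, .35, .35, .15))
    }
    paste(v, collapse = "")
  })
  Biostrings::DNAStringSet(setNames(unlist(out),
                                    names(spec$chrom_lengths)))
}

## ---- writers --------------------------------------------------------

.write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  for (g in genes) {
    feat <- function(type, s, e, attrs)
      sprintf("%s\tpanelomics\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s, e, g$strand, attrs)
    writeLines(feat("gene", g$gene_body[1], g$gene_body[2],
                    paste0("ID=", g$gene_id)), con)
    for (tx in g$transcripts) {
      writeLines(feat("mRNA", min(start(tx$exons)), max(end(tx$exons)),
                      paste0("ID=", tx$tx_id, ";Parent=", g$gene_id)), con)
      for (k in seq_along(tx$exons))
        writeLines(feat("exon", start(tx$exons)[k], end(tx$exons)[k],
                        paste0("Parent=", tx$tx_id)), con)
    }
    for (k in seq_along(g$cds))
      writeLines(feat("CDS", start(g$cds)[k], end(g$cds)[k],
                      paste0("Parent=", g$transcripts[[1]]$tx_id)), con)
  }
  close(con)
}

.write_bed3 <- function(gr, path) {
  df <- data.frame(as.character(GenomeInfoDb::seqnames(gr)),
                   start(gr) - 1L, end(gr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

.write_bedgraph <- function(chrom, start0, end, score, path) {
  df <- data.frame(chrom, start0, end, sprintf("%.6g", score))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

.write_fastq <- function(ids, seqs, path) {
  con <- file(path, "w")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), con)
  close(con)
}

## ---- variant generation --------------------------------------------

.draw_evidence <- function(n, spec, min_var = 4L) {
  depth <- pmax(10L, rpois(n, spec$depth_mean))
  var <- pmax(min_var, rbinom(n, depth, spec$vaf))
  depth <- pmax(depth, var)
  fwd <- pmax(1L, pmin(var - 1L, rbinom(n, var, 0.5)))
  data.frame(variant_read_count = var, total_depth = depth,
             forward_variant_count = fwd,
             reverse_variant_count = var - fwd)
}

.alt_base <- function(ref) {
  vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
    USE.NAMES = FALSE)
}

.gen_variants <- function(spec, ann, gchars) {
  lines <- spec$cell_lines
  gene_ids <- names(ann$genes)
  ref_at <- function(chrom, pos) gchars[[chrom]][pos]
  pick_gene <- function(k) ann$genes[[sample(gene_ids, 1L)]]
  ## shared germline set: positions with database membership
  germ <- list()
  for (i in 1:9) {
    g <- pick_gene()
    pos <- g$gene_body[1] + sample(0:4399, 1L)
    rec <- list(chrom = g$chrom, pos = pos,
                in_dbsnp = FALSE, esp_af = NA_real_, kg_af = NA_real_,
                in_inhouse = FALSE, in_cosmic = FALSE)
    if (i <= 3L) rec$in_dbsnp <- TRUE
    else if (i <= 5L) rec$kg_af <- runif(1L, 0.002, 0.01)
    else if (i == 6L) rec$esp_af <- runif(1L, 0.002, 0.01)
    else if (i <= 8L) rec$in_inhouse <- TRUE
    else rec$kg_af <- 0.001   # boundary: exactly at the cutoff, somatic
    if (i %in% c(1L, 4L)) rec$in_cosmic <- TRUE   # rescued
    germ[[i]] <- rec
  }
  all_rows <- list(); truth <- list()
  for (line in lines) {
    rows <- list()
    used <- integer(0)
    add <- function(chrom, pos, var_type, truth_class, category,
                    flags = list(), evidence = NULL, alt = NULL,
                    ref = NULL) {
      ev <- if (is.null(evidence)) .draw_evidence(1L, spec) else evidence
      if (is.null(ref))
        ref <- if (var_type == "SNV") ref_at(chrom, pos)
               else paste0(ref_at(chrom, pos), ref_at(chrom, pos + 1L))
      if (is.null(alt))
        alt <- if (var_type == "SNV") .alt_base(ref) else substr(ref, 1, 1)
      fl <- list(in_dbsnp = FALSE, esp_af = NA_real_, kg_af = NA_real_,
                 in_inhouse = FALSE, in_cosmic = FALSE)
      fl[names(flags)] <- flags
      rows[[length(rows) + 1L]] <<- data.frame(
        cell_line = line, chrom = chrom, pos = pos, ref = ref, alt = alt,
        var_type = var_type, ev, fl, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        cell_line = line, chrom = chrom, pos = pos, var_type = var_type,
        truth_class = truth_class, category = category,
        stringsAsFactors = FALSE)
    }
    ## somatic implants per category, evidence above threshold
    for (r in 1:2) {  # upstream
      g <- pick_gene()
      off <- sample(1:500, 1L)
      pos <- if (g$strand == "+") g$most_upstream_tss - off
             else g$most_upstream_tss + off
      add(g$chrom, pos, "SNV", "somatic", "upstream")
    }
    for (r in 1:2) {  # UTR (first exon is untranslated)
      g <- pick_gene()
      add(g$chrom, g$gene_body[1] + sample(0:799, 1L), "SNV",
          "somatic", "utr")
    }
    syn_found <- 0L; nonsyn_found <- 0L; tries <- 0L
    while ((syn_found < 2L || nonsyn_found < 2L) && tries < 400L) {
      tries <- tries + 1L
      g <- pick_gene()
      pos <- start(g$cds)[1] + sample(0:(sum(width(g$cds)) %/% 2L), 1L)
      if (!any(pos >= start(g$cds) & pos <= end(g$cds))) next
      ref <- ref_at(g$chrom, pos)
      alt <- .alt_base(ref)
      eff <- coding_effect(ann, g$chrom, pos, ref, alt)
      if (eff == "synonymous" && syn_found < 2L) {
        syn_found <- syn_found + 1L
        add(g$chrom, pos, "SNV", "somatic_synonymous", "cds", alt = alt,
            ref = ref)
      } else if (eff == "non_synonymous" && nonsyn_found < 2L) {
        nonsyn_found <- nonsyn_found + 1L
        add(g$chrom, pos, "SNV", "somatic_non_synonymous", "cds",
            alt = alt, ref = ref)
      }
    }
    g <- pick_gene()  # splice site: first base of the first intron
    ss_pos <- g$gene_body[1] + 800L
    add(g$chrom, ss_pos, "SNV", "somatic", "splice_site")
    for (r in 1:2) {  # intronic (away from the 2-base splice edges)
      g <- pick_gene()
      add(g$chrom, g$gene_body[1] + sample(810:1490, 1L), "SNV",
          "somatic", "intronic")
    }
    ig <- 0L
    while (ig < 4L) {  # intergenic
      chrom <- sample(names(spec$chrom_lengths), 1L)
      pos <- sample(spec$chrom_lengths[[chrom]] - 200L, 1L) + 100L
      if (classify_position(ann, chrom, pos)$category != "intergenic")
        next
      ig <- ig + 1L
      add(chrom, pos, "SNV", "somatic", "intergenic")
    }
    ## one somatic SNV inside a fixed enhancer site (exercises the
    ## enhancer rows of the regulatory-overlap table)
    add(names(spec$chrom_lengths)[1L],
        9050L + match(line, lines) * 37L, "SNV", "somatic_enhancer",
        "intergenic")
    ## indels: one passing, one forward-strand-only (screened out)
    g <- pick_gene()
    add(g$chrom, g$gene_body[1] + 1700L, "indel", "somatic", "cds")
    g <- pick_gene()
    ev <- .draw_evidence(1L, spec)
    ev$forward_variant_count <- ev$variant_read_count
    ev$reverse_variant_count <- 0L
    add(g$chrom, g$gene_body[1] + 100L, "indel",
        "somatic_single_strand", "utr", evidence = ev)
    ## below-threshold somatic SNVs (fewer than 4 variant reads)
    for (r in 1:2) {
      g <- pick_gene()
      var <- sample(1:3, 1L)
      fwd <- sample(0:var, 1L)
      ev <- data.frame(variant_read_count = var, total_depth = 20L,
                       forward_variant_count = fwd,
                       reverse_variant_count = var - fwd)
      add(g$chrom, g$gene_body[1] + 2000L + r, "SNV",
          "somatic_below_threshold", "cds", evidence = ev)
    }
    ## shared germline set
    for (i in seq_along(germ)) {
      rec <- germ[[i]]
      cls <- if (rec$in_cosmic) "germline_cosmic_rescued"
        else if (isTRUE(rec$kg_af == 0.001)) "germline_boundary_somatic"
        else "germline"
      add(rec$chrom, rec$pos, "SNV", cls, NA_character_,
          flags = rec[c("in_dbsnp", "esp_af", "kg_af", "in_inhouse",
                        "in_cosmic")])
    }
    all_rows[[line]] <- do.call(rbind, rows)
  }
  list(variants = all_rows, truth = do.call(rbind, truth))
}

## ---- copy number ----------------------------------------------------

.cna_implants <- function(spec, ann) {
  lines <- spec$cell_lines
  picks <- data.frame(
    cell_line = lines[c(1, 1, 2, 2, 3, 4)],
    gene_id = c("g05", "g08", "g12", "g15", "g20", "g25"),
    cn = c(0, 8.5, 4.5, 1.0, 8.5, 0.2),
    stringsAsFactors = FALSE)
  picks$class <- ifelse(picks$cn >= 8, "amplification",
                 ifelse(picks$cn >= 4, "gain",
                 ifelse(picks$cn <= 1, "loss", "?")))
  picks$chrom <- vapply(picks$gene_id, function(g)
    ann$genes[[g]]$chrom, character(1))
  w <- 1500L
  picks$start <- vapply(picks$gene_id, function(g)
    (((ann$genes[[g]]$gene_body[1] - 1000L) %/% w) * w) + 1L, numeric(1))
  picks$end <- vapply(picks$gene_id, function(g)
    ((ann$genes[[g]]$gene_body[2] + 1000L) %/% w + 1L) * w, numeric(1))
  picks
}

.gen_cn_tracks <- function(spec, implants, line) {
  w <- 1500L
  out <- list()
  for (cn in names(spec$chrom_lengths)) {
    L <- spec$chrom_lengths[[cn]]
    nw <- L %/% w
    start0 <- (seq_len(nw) - 1L) * w
    score <- 2 + rnorm(nw, 0, 0.05)
    imp <- implants[implants$cell_line == line & implants$chrom == cn, ,
                    drop = FALSE]
    for (i in seq_len(nrow(imp))) {
      sel <- start0 >= imp$start[i] - 1L & start0 + w <= imp$end[i]
      val <- imp$cn[i]
      noise <- rnorm(sum(sel), 0, 0.02)
      score[sel] <- if (val <= 1) val - abs(noise) else val + abs(noise)
    }
    score <- pmax(score, 0)
    out[[cn]] <- data.frame(chrom = cn, start0 = start0,
                            end = start0 + w, score = score)
  }
  do.call(rbind, out)
}

.aggregate_cn <- function(track1500, width = 50000L) {
  out <- list()
  for (cn in unique(track1500$chrom)) {
    t <- track1500[track1500$chrom == cn, ]
    grp <- t$start0 %/% width
    sc <- tapply(t$score, grp, mean)
    s0 <- as.integer(names(sc)) * width
    out[[cn]] <- data.frame(chrom = cn, start0 = s0,
                            end = pmin(s0 + width, max(t$end)),
                            score = as.numeric(sc))
  }
  do.call(rbind, out)
}

## ---- mate pairs -----------------------------------------------------

.gen_mate_pairs <- function(spec, ann) {
  lines <- spec$cell_lines
  chroms <- names(spec$chrom_lengths)
  rows <- list(); truth <- list()
  junctions <- list(
    list(line = "LINE1", gene_a = "g13", gene_b = "g20", n = 30L,
         expect = "called"),
    list(line = "LINE2", gene_a = "g03", gene_b = "g25", n = 1L,
         expect = "below_threshold"),
    list(line = "LINE3", gene_a = "g07", gene_b = "g28", n = 10L,
         expect = "shared_suppressed"),
    list(line = "LINE4", gene_a = "g07", gene_b = "g28", n = 10L,
         expect = "shared_suppressed"))
  pid <- 0L
  for (line in lines) {
    ## concordant background
    n_bg <- 400L
    for (cn in chroms) {
      pos1 <- sample(spec$chrom_lengths[[cn]] - 1000L, n_bg %/% 2L)
      ins <- round(rnorm(n_bg %/% 2L, spec$insert_mean, spec$insert_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("p%06d", pid + seq_along(pos1)),
        cell_line = line, chrom1 = cn, pos1 = pos1, strand1 = "+",
        chrom2 = cn, pos2 = pos1 + ins, strand2 = "-",
        stringsAsFactors = FALSE)
      pid <- pid + length(pos1)
    }
    for (j in junctions) {
      if (j$line != line) next
      ga <- ann$genes[[j$gene_a]]; gb <- ann$genes[[j$gene_b]]
      brk_a <- ga$gene_body[1] + 2000L
      brk_b <- gb$gene_body[1] + 2000L
      n1 <- ceiling(j$n / 2); n2 <- j$n - n1
      ## evenly spread flank offsets keep every pair within the
      ## clustering window of its neighbours
      offs <- function(k) if (k) round(seq(25, 295, length.out = k)) else integer()
      pa <- c(brk_a - offs(n1), brk_a + offs(n2))
      pb <- c(brk_b + offs(n1), brk_b - offs(n2))
      s1 <- c(rep("+", n1), rep("-", n2))
      s2 <- c(rep("-", n1), rep("+", n2))
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("p%06d", pid + seq_len(j$n)),
        cell_line = line, chrom1 = ga$chrom, pos1 = pa, strand1 = s1,
        chrom2 = gb$chrom, pos2 = pb, strand2 = s2,
        stringsAsFactors = FALSE)
      pid <- pid + j$n
      truth[[length(truth) + 1L]] <- data.frame(
        cell_line = line, gene_a = j$gene_a, gene_b = j$gene_b,
        brk_a = brk_a, brk_b = brk_b, n_pairs = j$n, expect = j$expect,
        stringsAsFactors = FALSE)
    }
  }
  list(pairs = do.call(rbind, rows), truth = do.call(rbind, truth))
}

## ---- expression -----------------------------------------------------

.gen_expression <- function(spec, ann) {
  gene_ids <- names(ann$genes)
  cols <- c(spec$cell_lines, spec$normal_line)
  base <- round(rlnorm(length(gene_ids), meanlog = 5, sdlog = 1))
  names(base) <- gene_ids
  silent <- c("g06", "g17", "g23", "g29")
  base[silent] <- 0
  mean_mat <- matrix(rep(base, length(cols)), ncol = length(cols),
                     dimnames = list(gene_ids, cols))
  implants <- data.frame(
    cell_line = c("LINE1", "LINE2", "LINE3", "LINE4"),
    gene_id = c("g02", "g09", "g21", "g11"),
    factor = c(8, 1 / 64, 8, 1 / 64), stringsAsFactors = FALSE)
  ## down-regulation only separates from Poisson noise on a well
  ## expressed baseline
  down <- implants$gene_id[implants$factor < 1]
  base[down] <- pmax(base[down], 256)
  mean_mat[down, ] <- rep(base[down], length(cols))
  for (i in seq_len(nrow(implants)))
    mean_mat[implants$gene_id[i], implants$cell_line[i]] <-
      max(1, base[implants$gene_id[i]]) * implants$factor[i]
  ## cancer-vs-normal contrasts
  mean_mat["g24", spec$cell_lines] <- 300; mean_mat["g24", spec$normal_line] <- 0
  mean_mat["g26", spec$cell_lines] <- 15; mean_mat["g26", spec$normal_line] <- 400
  counts <- matrix(rpois(length(mean_mat), mean_mat),
                   nrow = nrow(mean_mat), dimnames = dimnames(mean_mat))
  list(counts = counts, implants = implants, silent = silent,
       induced_vs_normal = "g24", silenced_vs_normal = "g26")
}

.gen_fusions <- function(spec) {
  data.frame(
    cell_line = c("LINE1", "LINE2", "LINE3"),
    gene_a = c("g13", "g03", "g19"),
    gene_b = c("g20", "g25", "g30"),
    spanning_read_count = c(25L, 9L, 12L),
    spanning_mate_pair_count = c(6L, 5L, 1L),
    expect_kept = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

## ---- bisulfite ------------------------------------------------------

.bait_regions <- function(ann) {
  proms <- promoter_of(ann, names(ann$genes), mode = "upstream")
  GenomicRanges::reduce(sort(c(GenomicRanges::granges(proms),
                               GenomicRanges::granges(ann$islands))))
}

.gen_bisulfite <- function(spec, ann, gchars) {
  baits <- .bait_regions(ann)
  chroms <- names(spec$chrom_lengths)
  ## per-CpG methylation state is defined genome-wide; the baits only
  ## shape where coverage lands
  cpg <- lapply(chroms, function(cn) {
    g <- gchars[[cn]]
    which(g == "C" & c(g[-1L], "N") == "G")
  })
  names(cpg) <- chroms
  in_island <- lapply(chroms, function(cn) {
    isl <- ann$islands[GenomeInfoDb::seqnames(ann$islands) == cn]
    pos <- cpg[[cn]]
    keep <- rep(FALSE, length(pos))
    for (i in seq_along(isl))
      keep <- keep | (pos >= start(isl)[i] & pos <= end(isl)[i])
    keep
  })
  names(in_island) <- chroms
  ## shared per-site base probabilities, beta-distributed
  base_prob <- lapply(chroms, function(cn) {
    p <- numeric(length(cpg[[cn]]))
    isl <- in_island[[cn]]
    p[isl] <- rbeta(sum(isl), spec$beta_island[1], spec$beta_island[2])
    p[!isl] <- rbeta(sum(!isl), spec$beta_other[1], spec$beta_other[2])
    p
  })
  names(base_prob) <- chroms
  ## differential-methylation implants on promoters (upstream 1.5 kb)
  implants <- data.frame(
    cell_line = c("LINE1", "LINE2"), gene_id = c("g04", "g10"),
    kind = c("hyper", "hypo"), stringsAsFactors = FALSE)
  prob_line <- list()
  for (line in c(spec$cell_lines)) {
    pl <- base_prob
    for (i in seq_len(nrow(implants))) {
      g <- ann$genes[[implants$gene_id[i]]]
      prom <- promoter_of(ann, implants$gene_id[i], mode = "upstream")
      cn <- g$chrom
      sel <- cpg[[cn]] >= start(prom) & cpg[[cn]] <= end(prom)
      if (implants$kind[i] == "hyper") {
        pl[[cn]][sel] <- if (line == implants$cell_line[i]) 0.95 else 0.03
      } else {
        pl[[cn]][sel] <- if (line == implants$cell_line[i]) 0.02 else 0.65
      }
    }
    prob_line[[line]] <- pl
  }
  ## read generation per line
  reads <- list()
  for (line in spec$cell_lines) {
    r1 <- character(0); r2 <- character(0); ids <- character(0)
    fr_chrom <- character(0); fr_start <- integer(0)
    for (cn in chroms) {
      g <- gchars[[cn]]
      L <- spec$chrom_lengths[[cn]]
      b <- baits[GenomeInfoDb::seqnames(baits) == cn]
      probvec <- rep(NA_real_, L)
      probvec[cpg[[cn]]] <- prob_line[[line]][[cn]]
      for (i in seq_along(b)) {
        wdt <- width(b)[i]
        nfrag <- ceiling(wdt * spec$bs_depth / (2L * spec$read_len))
        lo <- max(1L, start(b)[i] - 150L)
        hi <- min(L - spec$frag_len, end(b)[i] + 150L - spec$frag_len)
        fs <- sample(lo:hi, nfrag, replace = TRUE)
        posmat <- outer(fs, 0:(spec$frag_len - 1L), "+")
        charmat <- matrix(g[posmat], nrow = nfrag)
        cmask <- charmat == "C"
        pmat <- matrix(probvec[posmat], nrow = nfrag)
        p_retain <- ifelse(!is.na(pmat),
                           pmat + (1 - pmat) * spec$conv_fail,
                           spec$conv_fail)
        conv <- cmask & (matrix(runif(length(p_retain)),
                                nrow = nfrag) >= p_retain)
        charmat[conv] <- "T"
        frag <- apply(charmat, 1L, paste, collapse = "")
        r1 <- c(r1, substring(frag, 1L, spec$read_len))
        r2 <- c(r2, .revcomp_chr(substring(frag,
                                           spec$frag_len - spec$read_len + 1L,
                                           spec$frag_len)))
        ids <- c(ids, sprintf("%s_%s_%d_%d", line, cn, i, seq_len(nfrag)))
        fr_chrom <- c(fr_chrom, rep(cn, nfrag)); fr_start <- c(fr_start, fs)
      }
    }
    reads[[line]] <- list(ids = ids, read1 = r1, read2 = r2,
                          fragments = data.frame(chrom = fr_chrom,
                                                 start = fr_start))
  }
  truth_sites <- do.call(rbind, lapply(chroms, function(cn) {
    df <- data.frame(chrom = cn, pos = cpg[[cn]],
                     in_island = in_island[[cn]])
    for (line in spec$cell_lines)
      df[[line]] <- prob_line[[line]][[cn]]
    df
  }))
  list(reads = reads, truth_sites = truth_sites, implants = implants,
       conv_fail = spec$conv_fail)
}

## ---- ChIP -----------------------------------------------------------

.gen_chip <- function(spec, ann, expr) {
  w <- spec$chip_window
  chroms <- names(spec$chrom_lengths)
  lines <- c(spec$cell_lines, spec$normal_line)
  gene_ids <- names(ann$genes)
  expressed <- rownames(expr$counts)[expr$counts[, spec$normal_line] > 0 |
                                       rowSums(expr$counts) > 50]
  silent <- expr$silent
  ## enhancer sites: fixed intergenic intervals
  enh_sites <- GenomicRanges::GRanges(
    rep(chroms, each = 4L),
    IRanges::IRanges(rep(c(9000L, 48000L, 100500L, 152500L), 2L),
                     width = 600L))
  ## differential chromatin implants
  implants <- data.frame(
    cell_line = c("LINE1", "LINE2", "LINE3", "LINE4"),
    mark = c("H3K4me3", "H3K4me3", "H3K27ac", "H3K27ac"),
    target = c("g05", "g07", "enh2", "enh5"),
    kind = c("higher", "lower", "higher", "lower"),
    stringsAsFactors = FALSE)
  peak_at <- function(line, mark, gid) {
    ## promoter peak rules
    imp <- implants[implants$mark == mark & implants$target == gid, ,
                    drop = FALSE]
    if (nrow(imp)) {
      if (imp$kind == "higher") return(line == imp$cell_line)
      if (imp$kind == "lower") return(line != imp$cell_line)
    }
    if (mark %in% c(MARK_CLASSES$active, MARK_CLASSES$elongation))
      return(gid %in% expressed && line %in% lines)
    if (mark %in% MARK_CLASSES$repressive) return(gid %in% silent)
    FALSE
  }
  tracks <- list(); peaks <- list()
  for (line in lines) {
    wins <- list()
    for (cn in chroms) {
      nw <- spec$chrom_lengths[[cn]] %/% w
      wins[[cn]] <- data.frame(chrom = cn, start0 = (seq_len(nw) - 1L) * w,
                               end = seq_len(nw) * w)
    }
    wdf <- do.call(rbind, wins)
    wce <- rpois(nrow(wdf), spec$chip_bg)
    peaks[[line]] <- list()
    for (mark in CHROMATIN_MARKS) {
      lambda <- rep(spec$chip_bg, nrow(wdf))
      pk_iv <- list()
      set_region <- function(chrom, s, e, lam) {
        sel <- wdf$chrom == chrom & wdf$start0 >= s - 1L & wdf$end <= e
        lambda[sel] <<- lam
      }
      if (mark %in% c(MARK_CLASSES$active, MARK_CLASSES$repressive)) {
        for (gid in gene_ids) {
          if (!peak_at(line, mark, gid)) next
          g <- ann$genes[[gid]]
          tss <- g$most_upstream_tss
          s <- ((tss - 400L) %/% w) * w + 1L; e <- ((tss + 400L) %/% w + 1L) * w
          lam <- spec$chip_peak
          imp <- implants[implants$mark == mark & implants$target == gid &
                            implants$cell_line == line, , drop = FALSE]
          if (nrow(imp) && imp$kind == "higher") lam <- spec$chip_peak
          set_region(g$chrom, s, e, lam)
          pk_iv[[length(pk_iv) + 1L]] <- data.frame(chrom = g$chrom,
                                                    start0 = s - 1L, end = e)
        }
        ## "lower" implants: near-zero signal over the target promoter
        imp <- implants[implants$mark == mark & implants$cell_line == line &
                          implants$kind == "lower" &
                          implants$target %in% gene_ids, , drop = FALSE]
        if (nrow(imp)) {
          g <- ann$genes[[imp$target]]
          tss <- g$most_upstream_tss
          set_region(g$chrom, tss - 1600L, tss + 1600L, 0.2)
        }
      } else if (mark %in% MARK_CLASSES$elongation) {
        for (gid in expressed) {
          g <- ann$genes[[gid]]
          s <- ((g$gene_body[1]) %/% w) * w + 1L
          e <- (g$gene_body[2] %/% w + 1L) * w
          set_region(g$chrom, s, e, spec$chip_peak / 2)
          pk_iv[[length(pk_iv) + 1L]] <- data.frame(chrom = g$chrom,
                                                    start0 = s - 1L, end = e)
        }
      } else {
        ## enhancer marks at the fixed sites
        for (k in seq_along(enh_sites)) {
          key <- paste0("enh", k)
          imp <- implants[implants$mark == mark & implants$target == key, ,
                          drop = FALSE]
          present <- TRUE; lam <- spec$chip_peak
          if (nrow(imp)) {
            if (imp$kind == "higher") present <- line == imp$cell_line
            if (imp$kind == "lower" && line == imp$cell_line) {
              present <- FALSE
              set_region(as.character(GenomeInfoDb::seqnames(enh_sites))[k],
                         start(enh_sites)[k], end(enh_sites)[k], 0.2)
            }
          }
          if (line == spec$normal_line && key == "enh2") present <- FALSE
          if (present) {
            cn <- as.character(GenomeInfoDb::seqnames(enh_sites))[k]
            set_region(cn, start(enh_sites)[k], end(enh_sites)[k], lam)
            pk_iv[[length(pk_iv) + 1L]] <- data.frame(
              chrom = cn, start0 = start(enh_sites)[k] - 1L,
              end = end(enh_sites)[k])
          }
        }
      }
      score <- rpois(nrow(wdf), lambda)
      tracks[[paste(line, mark, sep = ".")]] <- cbind(wdf, score = score)
      pk <- if (length(pk_iv)) unique(do.call(rbind, pk_iv)) else
        data.frame(chrom = character(), start0 = integer(),
                   end = integer())
      peaks[[line]][[mark]] <- pk
    }
    tracks[[paste(line, "WCE", sep = ".")]] <- cbind(wdf, score = wce)
  }
  list(tracks = tracks, peaks = peaks, implants = implants,
       enh_sites = enh_sites)
}

## ---- main entry -----------------------------------------------------

#' Generate a synthetic panel on disk
#'
#' Writes the toy genome (FASTA), annotation (GFF3, island BED,
#' hallmark TSV), per-line variant TSVs, copy-ratio bedGraphs at 1.5 kb
#' and 50 kb windows, mate-pair TSVs with implanted junction-spanning
#' pairs, a gene count table, paired bisulfite FASTQ files, per-mark
#' ChIP and WCE bedGraphs with peak BEDs, fusion candidates, and a
#' ground-truth JSON. Regeneration under the same spec (same seed) is
#' byte-identical.
#'
#' @param spec A [panel_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, the file `paths` and the
#'   in-memory `ground_truth`.
#' @export
generate_panel <- function(spec = panel_spec(), dir) {
  stopifnot(inherits(spec, "PanelSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  layout <- .panel_layout(spec)
  genome <- .random_genome(spec, layout$islands)
  gchars <- lapply(names(genome), function(cn)
    strsplit(as.character(genome[[cn]]), "")[[1L]])
  names(gchars) <- names(genome)
  ann <- GenomeAnnotation(spec$chrom_lengths, layout$genes,
                          layout$islands, layout$hallmark_map, genome)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(genome, p("genome.fa"), width = 80L)
  .write_gff3(layout$genes, p("genes.gff3"))
  .write_bed3(layout$islands, p("cpg_islands.bed"))
  hm <- data.frame(
    hallmark = rep(names(layout$hallmark_map),
                   lengths(layout$hallmark_map)),
    gene_id = unlist(layout$hallmark_map, use.names = FALSE))
  write.table(hm, p("hallmarks.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  vars <- .gen_variants(spec, ann, gchars)
  cna_imp <- .cna_implants(spec, ann)
  mp <- .gen_mate_pairs(spec, ann)
  expr <- .gen_expression(spec, ann)
  fus <- .gen_fusions(spec)
  bs <- .gen_bisulfite(spec, ann, gchars)
  chip <- .gen_chip(spec, ann, expr)
  for (line in spec$cell_lines) {
    d <- p("lines", line)
    dir.create(file.path(d, "chip"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(d, "peaks"), showWarnings = FALSE)
    write.table(vars$variants[[line]], file.path(d, "variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    t1500 <- .gen_cn_tracks(spec, cna_imp, line)
    .write_bedgraph(t1500$chrom, t1500$start0, t1500$end, t1500$score,
                    file.path(d, "cn_1500.bedgraph"))
    t50k <- .aggregate_cn(t1500)
    .write_bedgraph(t50k$chrom, t50k$start0, t50k$end, t50k$score,
                    file.path(d, "cn_50000.bedgraph"))
    pairs <- mp$pairs[mp$pairs$cell_line == line, ]
    write.table(pairs, file.path(d, "matepairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rd <- bs$reads[[line]]
    .write_fastq(paste0(rd$ids, "/1"), rd$read1,
                 file.path(d, "bs_R1.fastq"))
    .write_fastq(paste0(rd$ids, "/2"), rd$read2,
                 file.path(d, "bs_R2.fastq"))
  }
  for (line in c(spec$cell_lines, spec$normal_line)) {
    d <- p("lines", line)
    dir.create(file.path(d, "chip"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(d, "peaks"), showWarnings = FALSE)
    for (mark in CHROMATIN_MARKS) {
      t <- chip$tracks[[paste(line, mark, sep = ".")]]
      .write_bedgraph(t$chrom, t$start0, t$end, t$score,
                      file.path(d, "chip", paste0(mark, ".bedgraph")))
      pk <- chip$peaks[[line]][[mark]]
      write.table(pk, file.path(d, "peaks", paste0(mark, ".bed")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
    t <- chip$tracks[[paste(line, "WCE", sep = ".")]]
    .write_bedgraph(t$chrom, t$start0, t$end, t$score,
                    file.path(d, "chip", "WCE.bedgraph"))
  }
  counts_df <- data.frame(gene_id = rownames(expr$counts), expr$counts,
                          check.names = FALSE)
  write.table(counts_df, p("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fus, p("fusions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ground_truth <- list(
    seed = spec$seed,
    cell_lines = spec$cell_lines, normal_line = spec$normal_line,
    variants = vars$truth,
    cna = cna_imp,
    junctions = mp$truth,
    expression = list(implants = expr$implants, silent = expr$silent,
                      induced_vs_normal = expr$induced_vs_normal,
                      silenced_vs_normal = expr$silenced_vs_normal),
    fusions = fus,
    methylation = list(sites = bs$truth_sites, implants = bs$implants,
                       conv_fail = bs$conv_fail,
                       fragments = lapply(bs$reads, `[[`, "fragments")),
    chip = list(implants = chip$implants,
                enh_sites = data.frame(
                  key = paste0("enh", seq_along(chip$enh_sites)),
                  chrom = as.character(GenomeInfoDb::seqnames(chip$enh_sites)),
                  start = start(chip$enh_sites),
                  end = end(chip$enh_sites))))
  jsonlite::write_json(ground_truth, p("ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(spec[setdiff(names(spec), "")], p("panel_spec.yaml"))
  invisible(list(dir = dir, ground_truth = ground_truth,
                 annotation = ann))
}

#' Read the ground truth of a generated panel
#' @param dir Panel directory.
#' @return The ground-truth list (data.frames restored).
#' @export
read_ground_truth <- function(dir) {
  jsonlite::read_json(file.path(dir, "ground_truth.json"),
                      simplifyVector = TRUE)
}
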