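## Somatic screening cascade and per-category burden accounting.
##
## Candidates arrive as a TSV dialect (one row per alt allele) carrying
## the evidence counts and database-membership flags; the upstream
## mapping/genotyping that produces them is outside this package.

.variant_cols <- c("cell_line", "chrom", "pos", "ref", "alt", "var_type",
                   "variant_read_count", "total_depth",
                   "forward_variant_count", "reverse_variant_count",
                   "in_dbsnp", "esp_af", "kg_af", "in_inhouse", "in_cosmic")

#' Read variant candidates from TSV
#'
#' Expected columns: cell_line, chrom, pos, ref, alt, var_type
#' (`SNV`/`indel`), variant_read_count, total_depth,
#' forward_variant_count, reverse_variant_count, in_dbsnp, esp_af, kg_af,
#' in_inhouse, in_cosmic. Population allele frequencies may be `NA` when
#' the variant is absent from the corresponding database. An optional
#' `polyphen2` numeric column is passed through.
#'
#' @param path Path to the TSV file.
#' @return data.frame of variant candidates.
#' @export
read_variants <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.variant_cols, names(df))
  if (length(missing_cols))
    stop(path, ": missing columns ", paste(missing_cols, collapse = ", "))
  for (f in c("in_dbsnp", "in_inhouse", "in_cosmic"))
    df[[f]] <- as.logical(df[[f]])
  df
}

.validate_variants <- function(cands) {
  cnt <- c("variant_read_count", "total_depth", "forward_variant_count",
           "reverse_variant_count")
  for (f in cnt) if (any(cands[[f]] < 0, na.rm = TRUE))
    stop("negative ", f)
  if (any(cands$forward_variant_count + cands$reverse_variant_count !=
            cands$variant_read_count))
    stop("forward + reverse variant counts must equal variant_read_count")
  if (any(cands$variant_read_count > cands$total_depth))
    stop("variant_read_count exceeds total_depth")
  for (f in c("esp_af", "kg_af"))
    if (any(cands[[f]] < 0 | cands[[f]] > 1, na.rm = TRUE))
      stop(f, " outside [0, 1]")
  invisible(cands)
}

#' Screen variant candidates on read evidence
#'
#' SNVs are kept iff supported by at least `min_var_reads` variant reads;
#' indels additionally require variant evidence on both the forward and
#' the reverse strand.
#'
#' @param cands Variant candidate data.frame (see [read_variants()]).
#' @param min_var_reads Minimum variant-supporting reads (default 4).
#' @return The retained candidate rows.
#' @export
screen_candidates <- function(cands, min_var_reads = 4) {
  if (!nrow(cands)) return(cands)
  .validate_variants(cands)
  keep <- cands$variant_read_count >= min_var_reads
  is_indel <- cands$var_type == "indel"
  keep[is_indel] <- keep[is_indel] &
    cands$forward_variant_count[is_indel] >= 1L &
    cands$reverse_variant_count[is_indel] >= 1L
  cands[keep, , drop = FALSE]
}

#' Remove germline variants with COSMIC rescue
#'
#' A candidate is classed `germline_removed` when it is in dbSNP, has a
#' population allele frequency strictly above `max_pop_af` in ESP or the
#' 1000 Genomes set, or is in the in-house panel -- unless it is
#' registered in COSMIC, in which case it is `cosmic_rescued`. Everything
#' else is a `somatic_candidate`.
#'
#' @param cands Screened candidate data.frame.
#' @param max_pop_af Population allele-frequency cutoff (strict `>`,
#'   default 0.001).
#' @return `cands` with an added `status` column.
#' @export
remove_germline <- function(cands, max_pop_af = 0.001) {
  germ <- (cands$in_dbsnp %in% TRUE) |
    (!is.na(cands$esp_af) & cands$esp_af > max_pop_af) |
    (!is.na(cands$kg_af) & cands$kg_af > max_pop_af) |
    (cands$in_inhouse %in% TRUE)
  status <- ifelse(germ & cands$in_cosmic %in% TRUE, "cosmic_rescued",
                   ifelse(germ, "germline_removed", "somatic_candidate"))
  cands$status <- status
  cands
}

#' Somatic subset of annotated candidates
#' @param vars data.frame with a `status` column.
#' @return Rows with status `somatic_candidate` or `cosmic_rescued`.
#' @export
somatic_variants <- function(vars) {
  vars[vars$status %in% c("somatic_candidate", "cosmic_rescued"), ,
       drop = FALSE]
}

.burden_categories <- c("upstream", "utr", "cds", "splice_site",
                        "intronic", "intergenic")

#' Annotate somatic variants and tabulate the mutation burden
#'
#' Classifies every retained (somatic or rescued) variant with
#' [classify_position()], computes the coding effect of CDS SNVs when the
#' genome is attached, and assembles the per-category burden table:
#' per-line counts, panel averages, the genic fraction (all
#' non-intergenic categories) and the coding burden (non-synonymous SNVs
#' plus CDS indels).
#'
#' @param vars data.frame with `status` set (see [remove_germline()]).
#' @param ann A [GenomeAnnotation()].
#' @return A `BurdenTable`: list with `variants` (annotated rows),
#'   `counts` (long data.frame: cell_line, var_type, category, count),
#'   `per_line` (wide per-line totals) and `summary` (derived figures).
#' @export
annotate_and_tabulate <- function(vars, ann) {
  som <- somatic_variants(vars)
  cls <- classify_position(ann, som$chrom, som$pos)
  som$category <- cls$category
  som$gene_id <- cls$gene_id
  som$coding_effect <- "n/a"
  idx <- which(som$category == "cds" & som$var_type == "SNV")
  if (length(idx) && !is.null(ann$genome))
    som$coding_effect[idx] <- coding_effect(
      ann, som$chrom[idx], som$pos[idx], som$ref[idx], som$alt[idx])
  lines <- sort(unique(vars$cell_line))
  grid <- expand.grid(cell_line = lines, var_type = c("SNV", "indel"),
                      category = .burden_categories,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(som$cell_line, som$var_type, som$category)
  tab <- table(key)
  grid$count <- as.integer(tab[paste(grid$cell_line, grid$var_type,
                                     grid$category)])
  grid$count[is.na(grid$count)] <- 0L
  per_line <- do.call(rbind, lapply(lines, function(l) {
    sub <- grid[grid$cell_line == l, ]
    tot <- sum(sub$count)
    genic <- sum(sub$count[sub$category != "intergenic"])
    data.frame(cell_line = l, somatic_total = tot, genic = genic,
               stringsAsFactors = FALSE)
  }))
  n_line <- length(lines)
  cat_tot <- tapply(grid$count, list(grid$category, grid$var_type), sum)
  nonsyn <- sum(som$coding_effect == "non_synonymous")
  syn <- sum(som$coding_effect == "synonymous")
  cds_indel <- sum(som$category == "cds" & som$var_type == "indel")
  total <- sum(grid$count)
  genic_total <- sum(per_line$genic)
  summary <- list(
    n_cell_lines = n_line,
    somatic_total = total,
    somatic_avg_per_line = total / n_line,
    genic_total = genic_total,
    genic_fraction_pct = if (total > 0) 100 * genic_total / total else NA,
    splice_site_total = sum(cat_tot["splice_site", ]),
    upstream_total = sum(cat_tot["upstream", ]),
    utr_total = sum(cat_tot["utr", ]),
    non_synonymous_total = nonsyn,
    synonymous_total = syn,
    cds_indel_total = cds_indel,
    coding_burden_avg = (nonsyn + cds_indel) / n_line)
  structure(list(variants = som, counts = grid, per_line = per_line,
                 summary = summary),
            class = "BurdenTable")
}

#' @export
print.BurdenTable <- function(x, ...) {
  s <- x$summary
  cat("BurdenTable:", s$somatic_total, "somatic variants across",
      s$n_cell_lines, "cell lines\n")
  cat("  genic fraction:", round(s$genic_fraction_pct, 1), "%;",
      "coding burden/line:", round(s$coding_burden_avg, 1), "\n")
  invisible(x)
}

#' Write a burden table as TSV
#' @param bt A `BurdenTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(bt, path) {
  write.table(bt$counts, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Base-substitution spectrum of somatic SNVs
#'
#' Simple count report of the six pyrimidine-context substitution
#' classes per cell line.
#'
#' @param vars Annotated variant data.frame (SNVs considered only).
#' @return data.frame cell_line x substitution class counts (long).
#' @export
substitution_spectrum <- function(vars) {
  snv <- vars[vars$var_type == "SNV", , drop = FALSE]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- snv$ref; alt <- snv$alt
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]; alt[flip] <- comp[alt[flip]]
  cls <- paste0(ref, ">", alt)
  as.data.frame(table(cell_line = snv$cell_line, substitution = cls),
                stringsAsFactors = FALSE)
}
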