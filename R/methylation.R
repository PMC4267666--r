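## Bisulfite read conversion, toy-genome exact-match mapping, per-CpG
## methylation rates, conversion-rate QC, island/shore/promoter
## summaries and differential methylation.
##
## Mapping is by exact match of the fully converted read against the
## fully converted reference (both strands): synthetic reads are
## error-free and the toy genome is small, so mismatch-tolerant
## alignment is deliberately out of scope.

#' In-silico bisulfite conversion of a read pair
#'
#' Read 1 is fully converted C to T, read 2 G to A (read 2 observes the
#' complementary strand of the bisulfite-converted fragment). Original
#' sequences are kept by the caller for post-mapping context counting.
#'
#' @param read1,read2 Character vectors of read sequences (A/C/G/T/N).
#' @return List with elements `read1` and `read2`, converted.
#' @export
convert_reads <- function(read1, read2) {
  if (any(grepl("[^ACGTN]", c(toupper(read1), toupper(read2)))))
    stop("reads contain non-ACGTN characters")
  list(read1 = chartr("C", "T", toupper(read1)),
       read2 = chartr("G", "A", toupper(read2)))
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Exact-match index over the C->T-converted genome, both strands.
## Entries: converted k-mer -> (chrom, plus-strand start of the covered
## segment, strand). A k-mer occurring more than once is ambiguous.
.bisulfite_index <- function(genome, k) {
  keys <- character(0); chrom <- character(0)
  pos <- integer(0); strand <- character(0)
  for (cn in names(genome)) {
    s <- as.character(genome[[cn]])
    L <- nchar(s)
    if (L < k) next
    n <- L - k + 1L
    conv <- chartr("C", "T", s)
    keys <- c(keys, substring(conv, seq_len(n), seq_len(n) + k - 1L))
    chrom <- c(chrom, rep(cn, n)); pos <- c(pos, seq_len(n))
    strand <- c(strand, rep("+", n))
    rc <- .revcomp_chr(s)
    conv_rc <- chartr("C", "T", rc)
    keys <- c(keys, substring(conv_rc, seq_len(n), seq_len(n) + k - 1L))
    chrom <- c(chrom, rep(cn, n))
    pos <- c(pos, L - seq_len(n) - k + 2L)  # plus-strand start
    strand <- c(strand, rep("-", n))
  }
  amb <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  list(keys = keys, chrom = chrom, pos = pos, strand = strand, amb = amb,
       k = k)
}

## Place one batch of reads; returns chrom/pos/strand (NA: unmapped,
## "amb": ambiguous).
.bs_place <- function(index, conv_reads) {
  i <- match(conv_reads, index$keys)
  mapped <- !is.na(i)
  amb <- mapped & index$amb[i]
  list(chrom = ifelse(mapped & !amb, index$chrom[i], NA_character_),
       pos = ifelse(mapped & !amb, index$pos[i], NA_integer_),
       strand = ifelse(mapped & !amb, index$strand[i], NA_character_),
       n_unmapped = sum(!mapped), n_ambiguous = sum(amb))
}

#' Map bisulfite reads to a toy genome and tally methylation evidence
#'
#' Reads are converted in silico ([convert_reads()]), placed by exact
#' match of the converted sequence on the converted reference (both
#' strands; ambiguous placements are discarded and counted), and the
#' pre-modified sequences are then compared base-by-base with the
#' reference: at every reference cytosine covered, a retained C is a
#' methylated observation and a T a converted one, tallied by CpG
#' versus non-CpG genomic context and by the read dinucleotide context
#' (CG/CA/CT/CC retained, TG/TA/TT/TC converted). Observations from
#' reads placed on the minus strand are assigned to the CpG site's
#' plus-strand C position.
#'
#' @param read1,read2 Character vectors of original (pre-conversion)
#'   read sequences; all reads must share one length.
#' @param genome `DNAStringSet` toy genome.
#' @return A `BisulfiteAlignmentSummary`: list with `sites` (data.frame
#'   chrom, pos, meth, conv for every CpG site observed), `context`
#'   (named dinucleotide tallies), `noncpg_retained`, `noncpg_converted`
#'   and mapping statistics.
#' @export
map_and_count <- function(read1, read2, genome) {
  k <- unique(nchar(c(read1, read2)))
  if (length(k) != 1L) stop("all reads must have the same length")
  conv <- convert_reads(read1, read2)
  index <- .bisulfite_index(genome, k)
  ## read2 observes the reverse complement of the converted fragment:
  ## its sense-oriented sequence is revcomp(read2), whose full C->T
  ## conversion equals the converted reference.
  r2_sense <- .revcomp_chr(read2)
  p1 <- .bs_place(index, conv$read1)
  p2 <- .bs_place(index, chartr("C", "T", r2_sense))
  oriented <- c(read1, r2_sense)
  place <- list(chrom = c(p1$chrom, p2$chrom), pos = c(p1$pos, p2$pos),
                strand = c(p1$strand, p2$strand))
  gchars <- lapply(genome, function(s) strsplit(as.character(s), "")[[1L]])
  ctx_names <- paste0(rep(c("C", "T"), each = 4L), c("G", "A", "T", "C"))
  context <- setNames(integer(8L), ctx_names)
  noncpg_ret <- 0L; noncpg_conv <- 0L
  site_env <- list()
  ok <- !is.na(place$chrom)
  for (cn in names(genome)) {
    g <- gchars[[cn]]
    L <- length(g)
    sel <- which(ok & place$chrom == cn)
    if (!length(sel)) next
    for (str in c("+", "-")) {
      rs <- sel[place$strand[sel] == str]
      if (!length(rs)) next
      seqmat <- matrix(unlist(strsplit(oriented[rs], "")), ncol = k,
                       byrow = TRUE)
      ## oriented sequence is sense for "+" placements; for "-"
      ## placements the read observes the antisense strand, so the
      ## sense-oriented view shows G (methylated) / A (converted) at
      ## reference G positions.
      posmat <- outer(place$pos[rs], 0:(k - 1L), "+")
      refmat <- matrix(g[posmat], ncol = k)
      if (str == "+") {
        cmask <- refmat == "C"
        obs <- seqmat[cmask]
        p <- posmat[cmask]
        retained <- obs == "C"; converted <- obs == "T"
        is_cpg <- p < L & g[pmin(p + 1L, L)] == "G"
        cpg_c_pos <- p
        ## read dinucleotide context (within-read next base)
        colmat <- col(refmat)[cmask]
        has_next <- colmat < k
        nxt <- seqmat[cbind(row(refmat)[cmask][has_next],
                            colmat[has_next] + 1L)]
        ctx <- paste0(obs[has_next], nxt)
        valid_ctx <- (retained | converted)[has_next] & ctx %in% ctx_names
        tab <- table(ctx[valid_ctx])
        context[names(tab)] <- context[names(tab)] + as.integer(tab)
      } else {
        gmask <- refmat == "G"
        obs <- seqmat[gmask]
        p <- posmat[gmask]
        retained <- obs == "G"; converted <- obs == "A"
        is_cpg <- p > 1L & g[pmax(p - 1L, 1L)] == "C"
        cpg_c_pos <- p - 1L
      }
      use <- retained | converted
      cpg_u <- is_cpg & use
      if (any(cpg_u)) {
        key <- cpg_c_pos[cpg_u]
        meth <- rowsum(as.integer(retained[cpg_u]), key)
        conv_n <- rowsum(as.integer(converted[cpg_u]), key)
        df <- data.frame(chrom = cn,
                         pos = as.integer(rownames(meth)),
                         meth = as.integer(meth),
                         conv = as.integer(conv_n))
        site_env[[length(site_env) + 1L]] <- df
      }
      noncpg_ret <- noncpg_ret + sum(!is_cpg & retained)
      noncpg_conv <- noncpg_conv + sum(!is_cpg & converted)
    }
  }
  sites <- if (length(site_env)) {
    all <- do.call(rbind, site_env)
    agg <- rowsum(cbind(meth = all$meth, conv = all$conv),
                  paste(all$chrom, all$pos))
    parts <- strsplit(rownames(agg), " ")
    out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      meth = as.integer(agg[, "meth"]),
                      conv = as.integer(agg[, "conv"]))
    out[order(out$chrom, out$pos), ]
  } else {
    data.frame(chrom = character(), pos = integer(), meth = integer(),
               conv = integer())
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, context = context,
                 noncpg_retained = as.integer(noncpg_ret),
                 noncpg_converted = as.integer(noncpg_conv),
                 n_reads = length(oriented),
                 n_unmapped = p1$n_unmapped + p2$n_unmapped,
                 n_ambiguous = p1$n_ambiguous + p2$n_ambiguous),
            class = "BisulfiteAlignmentSummary")
}

#' @export
print.BisulfiteAlignmentSummary <- function(x, ...) {
  cat("BisulfiteAlignmentSummary:", x$n_reads, "reads (",
      x$n_unmapped, "unmapped,", x$n_ambiguous, "ambiguous ),",
      nrow(x$sites), "CpG sites observed\n")
  invisible(x)
}

#' Bisulfite conversion-rate QC
#'
#' The conversion rate is the percentage of non-CpG cytosine
#' observations read as T; complete conversion gives 100. The dataset
#' passes at `pass_pct` or above.
#'
#' @param summary A [map_and_count()] summary.
#' @param pass_pct Pass threshold in percent (default 99).
#' @return List with `conversion_rate_pct` and `pass`.
#' @export
conversion_qc <- function(summary, pass_pct = 99) {
  tot <- summary$noncpg_retained + summary$noncpg_converted
  rate <- if (tot > 0) 100 * summary$noncpg_converted / tot else NA_real_
  list(conversion_rate_pct = rate, pass = isTRUE(rate >= pass_pct))
}

## Shore regions: within `dist` of an island but not inside any island.
.shore_regions <- function(islands, dist = 2000L) {
  if (!length(islands)) return(GenomicRanges::GRanges())
  ext <- GenomicRanges::reduce(islands + dist)
  GenomicRanges::setdiff(ext, GenomicRanges::reduce(islands))
}

#' Per-CpG methylation rates and region summaries
#'
#' Computes the methylation rate (methylated / depth) for every CpG site
#' with depth at least `min_depth` that does not coincide with a
#' detected variant, flags island/shore membership (shore: within 2 kb
#' of an island and not in it), and summarises per island, per shore,
#' per promoter (1.5 kb upstream of the most upstream TSS) and per
#' `window_size` tiling window as the unweighted mean of per-site rates
#' (depth-weighted means via `weighted = TRUE`).
#'
#' @param summary A [map_and_count()] summary for one cell line.
#' @param ann A [GenomeAnnotation()] (islands and genes used).
#' @param variants Optional data.frame with `chrom`, `pos` of detected
#'   SNVs/indels; overlapping CpG sites are excluded.
#' @param min_depth Minimum depth (inclusive, default 5).
#' @param shore_dist Shore distance in bp (default 2000).
#' @param window_size Genome tiling window (default 50000).
#' @param weighted Use depth-weighted region means (default `FALSE`).
#' @return A `MethylationTable`: list with `sites`, `islands`, `shores`,
#'   `promoters`, `windows` data.frames.
#' @export
site_rates <- function(summary, ann, variants = NULL, min_depth = 5,
                       shore_dist = 2000L, window_size = 50000L,
                       weighted = FALSE) {
  s <- summary$sites
  s$depth <- s$meth + s$conv
  s <- s[s$depth >= min_depth, , drop = FALSE]
  if (!is.null(variants) && nrow(variants))
    s <- s[!(paste(s$chrom, s$pos) %in%
               paste(variants$chrom, variants$pos)), , drop = FALSE]
  s$rate <- ifelse(s$depth > 0, s$meth / s$depth, NA_real_)
  gr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, s$pos))
  isl <- ann$islands
  shores <- .shore_regions(isl, shore_dist)
  s$in_island <- IRanges::overlapsAny(gr, isl, ignore.strand = TRUE)
  s$in_shore <- IRanges::overlapsAny(gr, shores, ignore.strand = TRUE)
  region_summary <- function(regions, ids) {
    if (!length(regions))
      return(data.frame(id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        n_sites = integer(), mean_rate = numeric()))
    hits <- GenomicRanges::findOverlaps(regions, gr, ignore.strand = TRUE)
    mr <- rep(NA_real_, length(regions)); ns <- integer(length(regions))
    if (length(hits)) {
      qh <- queryHits(hits); sh <- subjectHits(hits)
      ns_t <- tapply(sh, qh, length)
      ns[as.integer(names(ns_t))] <- as.integer(ns_t)
      f <- if (weighted) {
        function(i) sum(s$meth[i]) / sum(s$depth[i])
      } else {
        function(i) mean(s$rate[i])
      }
      mr_t <- tapply(sh, qh, f)
      mr[as.integer(names(mr_t))] <- as.numeric(mr_t)
    }
    data.frame(id = ids,
               chrom = as.character(GenomeInfoDb::seqnames(regions)),
               start = start(regions), end = end(regions),
               n_sites = ns, mean_rate = mr, stringsAsFactors = FALSE)
  }
  isl_ids <- if (length(isl)) paste0("island_", seq_along(isl)) else character()
  shore_ids <- if (length(shores)) paste0("shore_", seq_along(shores)) else character()
  proms <- promoter_of(ann, names(ann$genes), mode = "upstream")
  tilew <- min(window_size, min(ann$chrom_lengths))
  wins <- GenomicRanges::tileGenome(ann$chrom_lengths,
                                    tilewidth = tilew,
                                    cut.last.tile.in.chrom = TRUE)
  win_ids <- paste0(GenomeInfoDb::seqnames(wins), ":", start(wins) - 1L)
  out <- list(sites = s,
              islands = region_summary(isl, isl_ids),
              shores = region_summary(shores, shore_ids),
              promoters = region_summary(proms, mcols(proms)$gene_id),
              windows = region_summary(wins, win_ids))
  class(out) <- "MethylationTable"
  out
}

#' @export
print.MethylationTable <- function(x, ...) {
  cat("MethylationTable:", nrow(x$sites), "CpG sites (",
      sum(x$sites$in_island), "in islands ),", nrow(x$islands),
      "islands,", nrow(x$promoters), "promoters\n")
  invisible(x)
}

#' Classify CpG islands by mean methylation
#'
#' Islands are `fully_methylated` at mean rate >= `fully`,
#' `non_methylated` at <= `non`, `intermediate` otherwise (matching the
#' 10-90% moderate band); islands with no covered sites are
#' `unclassified`.
#'
#' @param table A [site_rates()] `MethylationTable`.
#' @param fully,non Class boundaries (defaults 0.9 and 0.1).
#' @return The island data.frame with an added `class` column.
#' @export
classify_islands <- function(table, fully = 0.9, non = 0.1) {
  isl <- table$islands
  isl$class <- ifelse(is.na(isl$mean_rate), "unclassified",
               ifelse(isl$mean_rate >= fully, "fully_methylated",
               ifelse(isl$mean_rate <= non, "non_methylated",
                      "intermediate")))
  isl
}

#' Promoter methylation matrix across cell lines
#'
#' @param tables Named list (cell line -> [site_rates()] table).
#' @return Matrix genes x cell lines of promoter mean methylation rates.
#' @export
promoter_rate_matrix <- function(tables) {
  genes <- tables[[1L]]$promoters$id
  vals <- vapply(tables, function(t)
    t$promoters$mean_rate[match(genes, t$promoters$id)],
    numeric(length(genes)))
  rownames(vals) <- genes
  vals
}

#' Differential promoter methylation
#'
#' Delegates to the shared fold-change contract
#' ([call_differential()]) with layer `"methylation"`. Genes whose
#' promoter rate is `NA` in any line (no covered CpG) are skipped.
#'
#' @param promoter_rates Matrix genes x cell lines (see
#'   [promoter_rate_matrix()]).
#' @param ... Passed to [call_differential()].
#' @return data.frame of differential calls.
#' @export
call_differential_methylation <- function(promoter_rates, ...) {
  keep <- rowSums(is.na(promoter_rates)) == 0L
  call_differential(promoter_rates[keep, , drop = FALSE],
                    layer = "methylation", ...)
}

#' Write per-site methylation rates as bedGraph
#' @param table A `MethylationTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_bedgraph <- function(table, path) {
  s <- table$sites
  df <- data.frame(chrom = s$chrom, start = s$pos - 1L, end = s$pos,
                   rate = sprintf("%.6g", s$rate))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
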