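# Fragment simulator used as the independent oracle for the mapper:
# draws fragments from the sense strand, converts unmethylated Cs
# (CpG methylation state drawn per site), and emits the read pair as
# sequenced (read1 = fragment start; read2 = reverse complement of the
# fragment end).
sim_bs_reads <- function(gchars, chrom_start, chrom_end, n, p_meth,
                         conv_fail = 0, frag = 200L, rl = 100L,
                         seed = 1) {
  set.seed(seed)
  L <- length(gchars)
  is_cpg <- gchars == "C" & c(gchars[-1L], "N") == "G"
  r1 <- character(n); r2 <- character(n)
  for (i in seq_len(n)) {
    fs <- sample(chrom_start:(chrom_end - frag), 1L)
    idx <- fs:(fs + frag - 1L)
    chars <- gchars[idx]
    for (k in which(chars == "C")) {
      p_ret <- if (is_cpg[idx[k]])
        p_meth + (1 - p_meth) * conv_fail else conv_fail
      if (runif(1) >= p_ret) chars[k] <- "T"
    }
    s <- paste(chars, collapse = "")
    r1[i] <- substring(s, 1L, rl)
    r2[i] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substring(s, frag - rl + 1L, frag))))
  }
  list(read1 = r1, read2 = r2)
}

test_that("in-silico conversion substitutes read1 C->T and read2 G->A", {
  conv <- convert_reads("ACGT", "ACGT")
  expect_equal(conv$read1, "ATGT")
  expect_equal(conv$read2, "ACAT")
  expect_equal(convert_reads("AGGT", "ACTT")$read1, "AGGT")
  expect_error(convert_reads("ACXT", "ACGT"), "non-ACGTN")
})

test_that("fully methylated reads map back and give site rates of 1", {
  ann <- toy_annotation()
  gchars <- strsplit(as.character(ann$genome[["chr1"]]), "")[[1L]]
  rd <- sim_bs_reads(gchars, 800L, 2000L, 80L, p_meth = 1, seed = 3)
  summ <- map_and_count(rd$read1, rd$read2, ann$genome)
  expect_equal(summ$n_unmapped, 0L)
  expect_equal(summ$n_ambiguous, 0L)
  expect_true(nrow(summ$sites) > 5L)
  expect_true(all(summ$sites$conv == 0L))
  tab <- site_rates(summ, ann, min_depth = 1)
  expect_true(all(tab$sites$rate == 1))
  ## sites recovered are genuine CpGs of the reference
  is_cpg <- gchars == "C" & c(gchars[-1L], "N") == "G"
  ## restrict to chr1 observations
  s1 <- summ$sites[summ$sites$chrom == "chr1", ]
  expect_true(all(is_cpg[s1$pos]))
})

test_that("simulated methylation probabilities are recovered within
           binomial error and conversion QC converges", {
  ann <- toy_annotation()
  gchars <- strsplit(as.character(ann$genome[["chr1"]]), "")[[1L]]
  p <- 0.8; fail <- 0.008
  rd <- sim_bs_reads(gchars, 500L, 1500L, 400L, p_meth = p,
                     conv_fail = fail, seed = 5)
  summ <- map_and_count(rd$read1, rd$read2, ann$genome)
  tab <- site_rates(summ, ann, min_depth = 30)
  expect_gt(nrow(tab$sites), 3L)
  p_eff <- p + (1 - p) * fail
  dev <- abs(tab$sites$rate - p_eff)
  se3 <- 3 * sqrt(p_eff * (1 - p_eff) / tab$sites$depth)
  expect_gt(mean(dev <= se3), 0.95)
  qc <- conversion_qc(summ)
  expect_equal(qc$conversion_rate_pct, 100 * (1 - fail), tolerance = 0.01)
  expect_true(qc$pass)
  ## a sloppier conversion fails the 99% gate
  rd2 <- sim_bs_reads(gchars, 500L, 1500L, 150L, p_meth = p,
                      conv_fail = 0.03, seed = 6)
  qc2 <- conversion_qc(map_and_count(rd2$read1, rd2$read2, ann$genome))
  expect_false(qc2$pass)
})

test_that("ambiguously mapping reads are discarded and counted", {
  set.seed(17)
  seg <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
  uniq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrR = paste0(seg, uniq, seg)))
  read <- substr(seg, 10L, 109L)
  summ <- map_and_count(read, chartr("ACGT", "TGCA",
                                     paste(rev(strsplit(read, "")[[1L]]),
                                           collapse = "")),
                        genome)
  expect_gte(summ$n_ambiguous, 1L)
})

test_that("site rates honour the depth threshold and variant exclusion", {
  ann <- toy_annotation()
  summ <- structure(list(
    sites = data.frame(chrom = "chr1", pos = c(950L, 1000L, 1050L),
                       meth = c(4L, 4L, 3L), conv = c(1L, 0L, 0L)),
    context = setNames(integer(8), c("CG", "CA", "CT", "CC",
                                     "TG", "TA", "TT", "TC")),
    noncpg_retained = 1L, noncpg_converted = 99L, n_reads = 10L,
    n_unmapped = 0L, n_ambiguous = 0L),
    class = "BisulfiteAlignmentSummary")
  tab <- site_rates(summ, ann,
                    variants = data.frame(chrom = "chr1", pos = 1000L))
  ## depth 4 dropped, variant-overlapping site dropped
  expect_equal(tab$sites$pos, 950L)
  expect_equal(tab$sites$rate, 0.8)
  ## island flag: site 950 lies in the chr1 island (900-1100)
  expect_true(tab$sites$in_island)
  ## depth-weighted and unweighted region means agree on uniform depth
  expect_equal(tab$islands$mean_rate[tab$islands$chrom == "chr1"], 0.8)
})

test_that("shores are within 2 kb of an island and not in it", {
  ann <- toy_annotation()
  shores <- panelomics:::.shore_regions(ann$islands)
  expect_false(any(IRanges::overlapsAny(shores, ann$islands)))
  gaps <- GenomicRanges::distanceToNearest(shores, ann$islands)
  expect_true(all(S4Vectors::mcols(gaps)$distance <= 1L))
  expect_true(all(width(shores) <= 4000L))
})

test_that("island classification uses the 0.1/0.9 boundaries", {
  tab <- list(islands = data.frame(
    id = paste0("i", 1:5), chrom = "chr1", start = 1:5, end = 2:6,
    n_sites = c(3L, 3L, 3L, 3L, 0L),
    mean_rate = c(0.95, 0.9, 0.5, 0.05, NA)))
  cls <- classify_islands(tab)
  expect_equal(cls$class,
               c("fully_methylated", "fully_methylated", "intermediate",
                 "non_methylated", "unclassified"))
})
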