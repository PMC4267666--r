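---
title: "Methods: multi-omics panel analysis with panelomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics panel analysis with panelomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`panelomics` reimplements, as a tested pipeline, the analysis design of
a multi-omics cancer cell-line panel: whole-genome variant screening,
copy-number and rearrangement calling, RNA-seq quantification,
target-captured bisulfite methylation, ChIP-seq chromatin-mark
association, and their integration into per-gene and per-hallmark
summaries. This vignette documents the model conventions, the tunable
parameters and why they hold their defaults, the synthetic study panel
the tests run on, and the numerical edge-case policies.

## Coordinate and annotation model

All intervals are held internally as `GRanges` (1-based, closed), the
native convention of the R/Bioconductor interval stack; BED and
bedGraph files are converted on ingestion by `rtracklayer`. A
`GenomeAnnotation` bundles chromosome lengths, gene models, CpG
islands, an optional hallmark-to-gene map and an optional genome
sequence, and validates referential integrity (intervals within
chromosome bounds, unique gene identifiers, hallmark genes known).

Each `GeneModel` derives, at construction time, its most upstream TSS
(the 5′-most TSS across transcripts, respecting strand), introns,
splice sites (the first and last two bases of every intron), the exon
union, CDS and UTR intervals, and the gene body span. When gene models
are read from GFF3 with several transcripts, the gene-level CDS is
taken from the transcript with the most upstream TSS; that transcript
also decides coding effects when isoforms disagree.

`classify_position()` assigns every genomic position exactly one
category with the fixed precedence

> splice_site ≻ CDS ≻ UTR ≻ upstream ≻ intronic ≻ intergenic,

where *upstream* is the 500 bp strand-aware window 5′ of the most
upstream TSS. Single assignment makes per-category counts additive: a
variant set's category counts always sum to the set's size, which the
burden tables rely on. When several genes claim a position at equal
precedence, the lexicographically smallest gene identifier wins — an
arbitrary but deterministic tie-break.

Two promoter conventions coexist, both anchored at the most upstream
TSS and clipped to chromosome bounds: the chromatin convention
(`mode = "window"`, ± 1.5 kb) and the methylation convention
(`mode = "upstream"`, 1.5 kb strictly 5′ of the TSS). On the minus
strand the upstream window is the exact mirror image (1-based
`[tss + 1, tss + 1500]`), keeping `promoter_of()` strand-covariant.

Synonymous/non-synonymous determination translates the codon
containing the substitution on the gene-level CDS with the standard
genetic code; positions in a trailing partial codon or outside any CDS
return `"n/a"`.

## Layer conventions and thresholds

| Parameter | Default | Role |
|---|---|---|
| `min_var_reads` | 4 reads | SNV/indel evidence screen |
| indel strand rule | ≥ 1 read per strand | indel-specific artifact screen |
| `max_pop_af` | 0.001 (strict >) | ESP / 1000 Genomes germline cut |
| `gain_cn` / `amp_cn` | 4 / 8 | copy-ratio thresholds (diploid = 2) |
| `loss_cn` / `del_min_len` | 1 / 1000 bp (strict >) | loss and deletion calls |
| `min_dist` | 1 Mb (strict >) | mate-pair discordance |
| `min_ref` / `min_supp` | 2 / 4 tags | junction support |
| `cluster_window` | 500 bp | junction clustering window |
| `expressed_rpkm` | 1 (strict >) | expressed-gene filter |
| `diff_high` / `diff_low` | 4 / 1/16 | shared differential contract |
| fusion filter | ≥ 10 reads, ≥ 2 pairs | fusion-candidate screen |
| `min_depth` | 5× (inclusive) | per-CpG rate threshold |
| conversion pass | ≥ 99% | bisulfite QC gate |
| shore distance | 2 kb | CpG shore definition |
| `flank` | 1.5 kb | promoter windows |
| enhancer territory | 100 kb upstream + gene body | cluster-to-gene assignment |
| `ppm_min` | 1 PPM in ≥ 1 line (strict >) | chromatin testing filter |
| normal comparison | > 1 (transcribed), > 5 (induced) | RPKM and PPM alike |

All strictness choices (`>` versus `≥`) follow the stated definitions
of the respective screens; the boundary behaviour is pinned by unit
tests (e.g. an allele frequency of exactly 0.001 stays somatic; RPKM
exactly 1 is not expressed; 999,999 bp apart is concordant).

The germline screen treats dbSNP and in-house membership as
unconditional (no frequency qualifier is attached to those sources),
while ESP and 1000 Genomes use the allele-frequency cut; COSMIC
membership rescues any otherwise-germline call. Users who prefer a
frequency-aware dbSNP filter can encode it by populating the
frequency columns instead of the membership flag.

### The shared differential contract

Every layer reuses one rule: a feature is differential in a cell line
when its value is ≥ 4-fold or ≤ 1/16-fold of the panel average. The
panel average includes the focal line by default, matching the
"average over all lines" phrasing the thresholds come from. That
choice has a structural consequence on small panels: with *n* lines
the fold of a single dominant line is bounded by *n*, so on a 4-line
panel a lone up-regulated gene can never reach 4-fold unless every
other line is at zero. The contract therefore also offers a
focal-exclusive mean (`include_focal = FALSE`), which `run_panel()`
uses when screening implanted single-line effects; both conventions
are tested against direct fold arithmetic. Features with a zero panel
mean are skipped rather than pseudocounted (a `pseudocount` argument
exists for reuse on sparse layers).

### Junction calling

The rearrangement caller works from mate pairs only. Discordant pairs
(different chromosomes, or > 1 Mb apart) are clustered by single
linkage: two pairs join when their mate positions agree within 500 bp
on both sides. The clustered pairs are the junction's reference tags;
a junction is credible only when both relative orientations flank the
breakpoint. Supporting tags are all pairs with mates inside the
cluster footprint (± 500 bp) linking the same two loci. The 500 bp
window is not dictated by the screen definitions; it corresponds to
one to two insert sizes of the simulated library (300 ± 30 bp) and is
exposed as `cluster_window`. Breakpoints are reported as the median of
clustered mate positions per side; gene pairs are compared as
unordered sets for the one-line-uniqueness filter, and junctions whose
breakpoints fall outside any gene body are dropped (the caller's
output universe is gene-associated rearrangements).

### Bisulfite mapping

Reads are converted in silico (read 1 C→T; read 2 G→A — read 2
observes the complementary strand of the converted fragment) and
placed by exact match of the fully converted read against the fully
converted reference, both strands, via a k-mer index; ambiguous
placements are discarded and counted. Exact matching is a deliberate
design for error-free reads on a small reference — mismatch-tolerant
alignment is out of scope, and the mapper must not be read as a
general aligner. After placement the pre-modified sequence is compared
base-by-base with the reference: at every reference cytosine a
retained C is a methylated observation and a T a converted one,
tallied by CpG versus non-CpG genomic context; minus-strand
observations are folded onto the plus-strand C of the CpG. Non-CpG
cytosines feed the conversion-rate QC, which converges to
100 × (1 − failure rate) as read count grows.

Region summaries (islands, shores, promoters, 50 kb windows) use the
unweighted mean of per-site rates; a depth-weighted variant is
available (`weighted = TRUE`) and the two agree on uniform depth. The
"almost fully / almost non-methylated" island classes use 0.9 and 0.1
boundaries — chosen to complement the 10–90% moderate band used for
shores, not fixed by the screen definitions — and are configurable.

### Chromatin

ChIP tracks are windowed tag counts with a matched whole-cell-extract
(WCE) control; the intensity of a region is the totals-normalized fold
enrichment `(chip/chip_total)/(wce/wce_total)`, and region PPM is
`chip/chip_total × 10⁶`. Windows partially overlapping a region
contribute proportionally to their overlap fraction. Enhancer peaks
from all lines are merged by single linkage of *overlapping* intervals
(bookended peaks stay separate), making clustering idempotent and
order-invariant; every input peak belongs to exactly one cluster of
its mark. Mark–mark Spearman correlations are computed per line over
per-gene intensities on promoter-window ∪ gene-body regions, with
average ranks for ties, then averaged across lines; constant vectors
yield missing entries rather than arbitrary values.

### Integration

The regulatory-mutation table counts each variant once per row class
and once in the regulatory union (promoters ∪ gene-assigned
enhancers), so differential-subset rows are bounded by their parent
rows by construction. The differentially-methylated-promoter row uses
the methylation promoter convention (1.5 kb upstream), the
differential-H3K4me3 row the chromatin convention (± 1.5 kb); the
union row uses the chromatin convention for promoters. Hallmark
denominators are the hallmark genes expressed above 1 RPKM in at
least one line; empty hallmarks report zero denominators and missing
percentages. Report tables are emitted sorted by gene then cell line.

## The synthetic study panel

`panel_spec()` fixes the study conditions the test suite runs under:
4 cancer lines plus one normal line on a 2 × 200 kb genome with 30
three-exon genes (alternating strand), CpG islands on every third
promoter plus two intergenic islands, variant evidence at Poisson(33)
depth with a 0.5 allele fraction, copy-ratio tracks at 1.5 kb and
50 kb windows, mate pairs with 300 ± 30 bp inserts, bisulfite
fragments targeted at islands and promoters at ~60× with a 0.8%
conversion-failure rate (i.e. a 99.2% conversion rate, the panel-wide
value the design emulates), beta-distributed per-CpG methylation
(Beta(0.6, 5) in islands, Beta(5, 1.5) outside), and Poisson ChIP
tracks (background rate 4, peak rate 80 per 200 bp window) for the
eight marks. Implants cover every decision boundary: somatic variants
in each positional category, sub-threshold and single-strand
negatives, database-flagged germline with COSMIC-rescued and
exact-boundary cases, CNAs at copy numbers 0/1/4.5/8.5, one
above-threshold translocation plus a sub-threshold and a panel-shared
junction, ± fold-change expression implants (down-implants on a
baseline floored at 256 counts so Poisson zeros cannot blur the
1/16-fold boundary), hyper- and hypo-methylated promoters, and
line-specific chromatin gains and losses at promoters and enhancers.
A fixed seed makes regeneration byte-identical, and the ground-truth
JSON records every implant together with per-site methylation
probabilities and fragment positions.

What the panel does *not* emulate — and what passing tests therefore
do not establish about real data: sequencing error and base-quality
structure, mappability and GC biases, subclonality and impure allele
fractions, overdispersed expression counts, hemimethylation,
fragment-length variation in bisulfite libraries, and realistic
genome/annotation complexity (overlapping genes, many isoforms,
repeats). The pipeline's decision logic is exercised exhaustively; its
robustness to upstream noise sources that real aligners and callers
absorb is not.

Test problem sizes (a 400 kb genome, ~15,000 bisulfite fragments per
line, 2,000 ChIP windows per track) are the package's chosen balance
between exercising every code path at meaningful depth and keeping the
default suite fast enough to run routinely.

## Numerical and degenerate-input policies

* Empty inputs flow through every caller and return empty, correctly
  typed results (no `NULL`s).
* Division guards: zero-depth sites yield no rate; zero WCE regions
  yield missing intensities; zero panel means skip the feature.
* The focal-exclusive fold of a positive value against an all-zero
  rest-of-panel is `Inf`, which counts as a higher call.
* Copy-ratio windows of unexpected size warn and proceed.
* `call_cna` reports amplification runs alongside their containing
  gain runs (and deletions alongside losses), so class sets are
  nested rather than exclusive; consumers pick the strongest class.
* All orderings (report rows, junction clustering inputs) are made
  deterministic before processing so results are independent of input
  file order.

## Known limitations

* The bisulfite mapper requires one uniform read length per dataset
  and exact matches; reads with sequencing errors go unmapped rather
  than mismatch-tolerantly placed.
* Junction orientation signatures classify support direction only; no
  inversion/insertion typing or split-read refinement is attempted.
* PolyPhen-2-style impact scores are carried as an optional
  pass-through column; the package does not compute them.
* The hallmark map and annotation universe are whatever the loaded
  annotation provides; no reconciliation between alternative gene
  universes is attempted.
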