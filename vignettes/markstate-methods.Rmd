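---
title: "Gene-level chromatin state analysis with markstate: methods and design"
author: "markstate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level chromatin state analysis with markstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markstate)
```

## The problem

Tri-methylation of histone H3 at lysine 4 (H3K4me3) and lysine 36
(H3K36me3) marks transcriptionally active chromatin in plants, while
H3K27me3 is the Polycomb-deposited repressive mark. In *Brassica rapa* —
a mesohexaploid whose genome carries three subgenomes (LF, MF1, MF2) from
a whole-genome triplication — the interplay of these marks bears on
expression level, tissue specificity, stress responsiveness and the
subfunctionalization of paralogous gene copies. `markstate` implements
the downstream, gene-level side of such a study: it consumes peak
intervals (MACS2 narrowPeak or BED) and gene models (GFF3/BED), calls
"marked genes", and carries the mark-state table through co-occurrence,
expression, tissue-specificity, DEG, paralog-triplet, metagene, qPCR and
term-enrichment analyses. Upstream read processing (trimming, mapping,
peak calling) is out of scope; the package starts from intervals.

## The marked-gene rule

A gene is *marked* when a **single peak** intersects the gene span
extended by `flank_bp = 200` bp on both sides by **strictly more than**
`min_overlap_bp = 200` bp. Three choices deserve note:

* *Single peak, not a sum.* Whether several sub-threshold peaks may be
  summed is genuinely open; the per-peak reading is the default and the
  summed variant is available as `overlap_mode = "summed"`. On typical
  peak sets the two differ for a small minority of genes.
* *Strict inequality* at the threshold ("more than 200 bp").
* *Strand-independent flanks*: the rule is symmetric around the span, so
  strand plays no role in classification (it matters only for metagene
  orientation).

The genic region is the gene's full span; no downstream rule needs
exon/intron substructure. With two lines profiled, the *consensus*
marked set is the intersection of the per-line sets
(`consensus_marked()`), treating the lines as biological replicates.

Coordinates are held 1-based closed in `GRanges`, the Bioconductor
convention; BED and narrowPeak input (0-based half-open) is shifted on
read and back on write. Interval lengths and overlaps — all that the
rule consumes — are identical under either convention. Flank extension
clamps at base 1 of a chromosome.

## Co-occurrence, bivalency, antagonism

`mark_state_partition()` counts genes in all eight subsets of
{K4, K36, K27}; the counts always partition the universe. For a mark
pair, the *expected* co-marked count under independence is
$n_A n_B / N$ over the consensus universe and the reported ratio is
observed/expected (`expected_cooccurrence()`); the hypergeometric SD of
the overlap under fixed marginals is returned alongside so a ratio can
be judged against its sampling noise. The universe $N$ is a required
argument — whether it is all annotated genes or only expressed genes is
a study choice the package does not hide.

Printed percentages are reproduced from printed counts with half-up
rounding to one decimal (`percent_with_mark()`); base R's banker's
rounding cannot reproduce derivations such as 131/253 = 51.8%.

For co-marked genes, `peak_overlap_length_classes()` clips both marks'
peaks to the flank-extended span and takes the largest single peak-pair
intersection, reporting the fraction of co-marked genes exceeding each
threshold (defaults 150 and 500 bp, strict). Using the same ±200 bp
span as classification keeps the two rules consistent.

## Expression, tissue specificity, associations

Expression summaries use `log2(FPKM)` with genes below an FPKM floor of
0.01 excluded (`log2_expression()`). The floor is read as *excluding*
near-zero genes; the alternative reading (restricting to them) would
leave a near-empty, signal-free set.

The tissue-specificity index is
$$\tau = \frac{\sum_{i=1}^{n} (1 - x_i / x_{\max})}{n - 1},$$
0 for uniform (housekeeping) expression and 1 for strict one-tissue
expression. By default $x_i = \max(\log_2(\mathrm{FPKM}_i + 1), 0)$ —
the log scale keeps a single dominant tissue from saturating the index
— with `transform = "none"` exposed because the raw-scale variant is
exactly invariant to positive rescaling (the log-scale variant is only
approximately so). An all-zero vector is defined as $\tau = 0$.

Group contrasts of a per-gene value across mark states use a one-way
ANOVA with Tukey's HSD at $\alpha = 0.05$ (`group_summary()`); the
tested surface is the direction and significance of pairwise mean
differences, not a compact letter display. DEG composition is a 2×2
chi-squared (1 df) without continuity correction by default — cell
counts in genome-scale use are in the hundreds to tens of thousands —
with the correction available as an option. SNP-density contrasts use
Welch's t-test on per-gene SNPs/length, as group sizes and variances
are unequal by construction.

## Metagene profiles and window tracks

`metagene_profile()` aggregates peak occupancy in a
flank/scaled-body/flank frame (defaults 1 kb flanks in 50 bp bins, 40
body bins; the 2 kb view is the same operation with `flank_bp = 2000`).
Occupancy is *binary peak presence at bin midpoints*, not read
coverage: the package deliberately consumes peaks rather than
alignments, and profile shape (TSS-proximal enrichment, 5′→3′ decay)
is preserved under this proxy, though absolute levels are not
comparable with coverage-based plots. Minus-strand genes traverse the
same midpoints in reverse order, which makes strand flipping an exact
mirror of the profile — a property the tests exploit. Genes shorter
than one base per body bin are skipped with a warning.

`windowed_track()` tiles chromosomes with fixed windows and scores the
covered fraction per window; `track_correlation()` is plain Pearson on
a shared grid and refuses constant tracks, for which r is undefined.

## Paralog triplets

`triplet_mark_categories()` counts three-copy sets by marked copies: 3,
exactly 2, exactly 1, 0. The "exactly" reading is forced by arithmetic:
the published category counts partition their total (392 + 317 + 364 +
602 = 1,675), which nested "at least" categories could not.
`paired_value_contrast()` contrasts values of marked vs unmarked copies
in discordant triplets, per ordered subgenome pair and pooled, with
unpaired two-sample t-tests per the convention of the figure this
mirrors; concordant triplets carry no information and are excluded.

## qPCR arithmetic

`chip_enrichment()` implements input-corrected ddCt:
$\mathrm{fold} = E^{-[(Ct_{IP,t} - Ct_{in,t}) - (Ct_{IP,r} - Ct_{in,r})]}$
with efficiency $E = 2$ by default (no efficiency correction is
applied upstream of this package; $E$ is exposed for users who
calibrate primers). Adding a constant to all Cts of a replicate cancels
exactly. Technical duplicates are averaged on the Ct scale first; fold
values are computed per biological replicate and summarised as mean ±
SE, matching the three-biological-replicate design the arithmetic
serves. Sequential-ChIP (reChIP) enrichment is the same arithmetic on
second-round Cts against a gene carrying neither mark.

## Term enrichment

`hypergeom_enrichment()` is a generic overrepresentation engine:
upper-tail hypergeometric $P(X \ge k)$ per term, Benjamini–Hochberg
adjustment, significance at q ≤ 0.01 by default. BH (not BY) is used
as the standard FDR choice for GO-style screens. Terms with no study
gene are suppressed; they carry no evidence and only inflate the test
count. No GO-DAG propagation is performed — annotation maps are taken
as given.

## The synthetic-data generator

The generator exists so every stage is testable without the deposited
ChIP-seq data; its defaults are the study conditions, fixed once:

* **Mark structure.** Consensus marginals 0.423 / 0.299 / 0.264 for
  K4 / K36 / K27 — the reported fractions of annotated genes — and
  pairwise observed/expected ratios 2.0 (K4–K36), 0.84 (K4–K27) and
  0.21 (K36–K27), the latter two derived from the published observed
  and expected co-marked counts. The 8-cell joint distribution is
  fitted by iterative proportional fitting from these six constraints
  (three-way interaction defaults to the IPF maximum-entropy solution);
  infeasible combinations are rejected before sampling.
* **Two lines.** Each line marks every consensus-marked gene plus
  consensus-unmarked genes at `line_extra_rate = 0.07`, giving per-line
  K4 fractions near 46–47% against a 42.3% consensus — the observed
  two-line vs consensus gap.
* **Genome geometry.** Gene lengths log-normal with 2 kb median
  (sdlog 0.6, floor 300 bp); intergenic gaps at least 1 kb
  (exponential tail, 3 kb mean). Peaks are gamma-length (mean 1 kb,
  floor 420 bp), anchored at the TSS with up to 150 bp upstream
  overhang and truncated 150 bp beyond the far gene end. The floor and
  truncation guarantee a single-peak overlap above 400 bp with the
  marked gene's extended span, while the minimum gap keeps peaks out of
  neighbours' spans — so classification recovers planted states
  essentially exactly, and tests of the classifier on simulated data
  test the classifier, not the placement.
* **Expression.** Gene-level log2 expression is
  `1.5 + 1.5·K4 + 2.5·K36 − 1.8·K27` with SD 1.2, spread over six
  tissues by a profile whose noiseless tissue-specificity equals a
  state-dependent target (K36-marked 0.15, else K4 0.25, else K27 0.60,
  else 0.35; per-gene jitter 0.05) with Gaussian log-scale noise of
  SD 0.1. This realises the qualitative orderings the analysis should
  detect: K4&K36 > K4-only > unmarked > K27-only in expression, and
  K36-marked below average in tau.
* **DEGs.** Membership odds are the 5% baseline odds multiplied by 0.3
  per K36 mark and 2.5 per K27 mark — the depletion/enrichment
  directions the stress analysis should recover decisively at the
  default problem size.
* **qPCR.** True enrichments 0.5–16× enter as −log2(E) cycles on the
  target's IP Ct; per-gene primer offsets are shared between IP and
  input (and so cancel in the corrected ddCt); every Ct carries
  Gaussian noise of SD 0.2 cycles, three biological replicates.

One master seed drives fixed per-stage streams (offsets 0–6), so a
configuration determines every output byte-for-byte.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: read-level noise and peak-calling
variability (peaks appear exactly where states dictate); irregular peak
shapes, split peaks and peaks spanning several genes; correlated mark
states of neighbouring genes and chromosome-scale domains; repeat
regions; realistic expression covariance between tissues; GO term
structure. Tests on synthetic data validate the *arithmetic and
statistical machinery* under known truth, not the biology of any real
genome.

## Problem sizes and numerical choices

Default verification runs use 5,000 genes, two lines and three marks —
large enough for the binomial/chi-squared recoveries to be decisive,
small enough to run interactively. Permutation checks of the
independence expectation use 2,000 genes × 10,000 shuffles. Other
conventions: half-up rounding only at the printed-percentage surface
(all internal arithmetic is full precision); strict inequalities at
overlap thresholds; degenerate inputs (constant groups, empty peak
sets, all-zero expression) return defined values or explicit errors
rather than NaN; tau targets are clamped to [0.02, 0.95] in simulation
so no planted gene is exactly degenerate.

## Limitations

Binary occupancy metagenes understate within-peak signal structure;
the consensus rule is a hard intersection and does not model per-line
false negatives; the expected co-occurrence model assumes exchangeable
genes (no length or GC stratification); and the paralog contrasts pool
copies across triplets, so they test marginal association, not
triplet-level causality.
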