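---
title: "Methods: discovering nuclear-enriched disease-associated lncRNAs from fractionation RNA-seq"
author: "fracseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering nuclear-enriched disease-associated lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracseq)
```

# The analysis

Long noncoding RNAs (lncRNAs) that act in the nucleus — on chromatin, on
splicing, on nuclear bodies — are systematically missed by screens that only
look at whole-cell abundance. `fracseq` implements the downstream analysis
of a fractionation-then-sequencing design: cells are separated into
cytoplasmic and nuclear fractions before RNA-seq, and the per-gene ratio

$$r_{g\ell} = \log_2\!\frac{\mathrm{FPKM}^{\mathrm{cyto}}_{g\ell}}{\mathrm{FPKM}^{\mathrm{nuc}}_{g\ell}}$$

measured in each cell line $\ell$ quantifies fraction bias: negative values
mean nuclear retention, positive values cytoplasmic export. Around this core
statistic the package assembles the full discovery pipeline: a consensus
transcript catalog compared by intron chain, a lncRNA filter cascade with a
dual coding-potential consensus, consensus differential expression between
tumor and adjacent tissue, housekeeping-calibrated enrichment
classification, candidate characterization (promoter H3K4me3 marks,
preimplantation-embryo expression, Kaplan–Meier/log-rank survival), and
co-expression partner analysis.

# Transcript comparison by intron chain

Internally all coordinates are 0-based half-open; GTF I/O converts from the
1-based inclusive convention. Two transcripts are "the same" when they share
chromosome, strand, and the exact ordered set of intron intervals.
Terminal exon ends are ignored because de novo assemblers place them
inconsistently; which equivalence the original merge tools used is not
documented, so intron-chain identity is this package's stated choice. A
consequence: mono-exonic transcripts (empty chain) never match under this
relation. They are tolerated by the data model but removed by the lncRNA
filter anyway, which considers multi-exonic transcripts only.

Novel transcripts are related to a reference annotation through a
transfrag-style class code, decided in the fixed precedence order
`=`, `c`, `j`, `i`, `x`, `o`, `u`:
identical chain; contained sub-chain; shared splice junction; inside a
reference intron; antisense exonic overlap only; sense exonic overlap;
intergenic. The precedence order is a design choice — the categories
themselves do not determine tie-breaking — and makes the assignment a
total, deterministic function. The test suite checks the implementation
against an independent brute-force checker that works on enumerated base
sets instead of interval arithmetic.

*One boundary case worth noting*: the promoter and class-code geometry in
this package treats "overlap" as at least one shared base everywhere, with
window endpoints inclusive. All engineered geometries in the tests are
validated against the brute-force oracle rather than against hand-written
expectations.

# lncRNA identification

The filter cascade retains transcripts with ≥ 2 exons, spliced length
> 200 nt (the standard lncRNA length definition applied to summed exon
length, not genomic span), known strand, maximum TPM across samples > 1,
and no exonic overlap with the repeat mask. Two interpretations were open:

* **TPM rule.** Whether the original threshold was per-sample, mean or
  maximum is not stated; maximum is the default here (it matches how
  per-transcript expression maxima are usually displayed) and the operation
  takes the matrix so a caller can pre-aggregate differently.
* **Repeat rule.** "Non-repeat-masked regions" is not quantified; the
  default tolerance is zero exonic overlap, exposed as
  `max_repeat_fraction`.

Transcripts matching an annotated lincRNA/antisense gene (`=`) are
annotated lncRNAs; `=` against protein-coding is protein-coding; all other
codes are unannotated and are kept only if *every* required coding-potential
predictor labels them noncoding. Predictors are pluggable label tables; the
built-in ORF predictor (longest ATG-initiated open reading frame ≥ 100 aa
in the three sense frames of the spliced sequence) is a deliberately simple
stand-in so synthetic runs need no external tools — it is not a
reimplementation of any published classifier.

# Consensus differential expression

Per-method result tables are thresholded with the strict rules
|log2FC| > 1 with BH-adjusted p < 0.01 (FDR-style methods) or PPDE > 0.99
(posterior-probability methods), and the consensus is the intersection over
transcripts *with direction agreement* — a transcript cannot be both up-
and down-regulated, so sign conflicts are excluded and logged (the source
analysis does not address this case; requiring agreement is the
package's choice).

The built-in method exists so the pipeline runs standalone: library-size
scaling to a common depth, log2 fold change of means with pseudocount 0.5,
and a two-sided Mann–Whitney U p-value. For tiny groups
($\binom{n_1+n_2}{n_1} \le 100$) the exact null distribution is enumerated
over all assignments of the midranks, so within-group ties do not force the
normal approximation — for fully separated 4 vs 4 groups this gives the
exact p = 2/70 ≈ 0.0286. Larger samples use `wilcox.test` (exact when
feasible, tie-corrected normal approximation otherwise). This is a
rank-based stand-in, not a negative-binomial model; model-based results
enter as tables.

Whether a dysregulated lncRNA panel separates tumor from non-tumor samples
is checked by average-linkage clustering on the 1 − Pearson distance over
standardized log2(TPM+1) rows, cut at two clusters, followed by a
chi-square test of independence (1 df, no continuity correction) on the
2×2 cluster-by-status table. Distance and linkage are unspecified in the
source analysis; 1 − Pearson/average is the default and configurable.

# Fraction enrichment

FPKM matrices over the 2 × L fraction libraries are normalized by
median-of-ratios size factors (the DESeq estimator, computed over genes
positive in all libraries; the test suite cross-checks against
`DESeq2::estimateSizeFactorsForMatrix`). Size factors are estimated
jointly over all fraction libraries; per-line normalization is possible by
calling `normalize_fpkm` per pair, but joint mode is the default because
"in-sample normalization" is ambiguous in the source description.

A line's ratio is defined only when both fractions reach 0.1 FPKM. The
reference range is the 5th/95th percentile of the housekeeping genes' mean
ratios, by linear interpolation between order statistics (nearest-rank
available as an option; no convention was named). A gene is nuclear-
(cytoplasmic-) enriched when its ratio falls strictly below (above) the
limit in ≥ 4 of 8 lines; boundary values are non-fraction-specific because
the defining words are "below" and "exceeding". With the required line
count above half the lines the two enriched calls are mutually exclusive
by arithmetic. Genes evaluable in zero lines are `insufficient_data`; a
gene evaluable in fewer than `required_lines` lines can never satisfy
either rule, so it is effectively non-classifiable — a documented
consequence rather than a separate status.

Classical markers validate the calibration: GAPDH and RPS14 must come out
cytoplasmic, MALAT1 nuclear. The original study's numeric limits
(−1.278/3.056) and marker means require its restricted-access data and are
deliberately not reproduction targets.

# Characterization

* **Promoter marks.** A transcript is marked in an epigenome when an
  H3K4me3 peak shares ≥ 1 base with the ±1000 bp window (endpoints
  inclusive, clipped at zero) around the 5′ end — smallest coordinate on
  `+`, largest on `−`. Counts are reported per epigenome category (ESC,
  ESC-derived, iPSC, cancer).
* **Embryo expression.** Per stage, a gene is *expressed* when ≥ 2 embryos
  contain ≥ 1 cell with TPM > 1, and *lineage-specific* when some embryo
  has ≥ 2 expressing cells making up < 67% of its cells. The two clauses
  are evaluated independently (the lineage call does not additionally
  require the expressed call) and both flags are reported so either
  conjunction can be formed downstream. Embryo counting is within-stage,
  matching per-stage reporting. Stages with < 2 embryos are non-evaluable.
* **Survival.** High/low groups split at the median expression, ties to
  the low group (the most common convention; no split is defined in the
  source). Kaplan–Meier curves and the two-group log-rank test come from
  the `survival` package; the tests verify the statistic against a
  hand-tabulated O/E/V computation. Raw p-values are reported (that is how
  "p < 0.05" was screened), with a BH-adjusted column alongside for
  transparency.
* **Report.** One row per candidate, ordered by gene id, with the
  "not expressed" flag raised when FPKM < 0.5 in ≥ 5 of the cell lines.

# Co-expression

Genes positive in < 20% of tumor datasets are removed (≥ comparison, so
exactly 20% stays). Candidates are correlated with every other gene on
log2(TPM+1) (the transform is a package choice and configurable). Partners
require PCC ≥ 0.6 (inclusive) and p < 0.05 from the t-transform of r —
signed by default, because the printed rule has no absolute value; an
|PCC| mode exists. Candidates are then clustered by their partner-PCC rows
(Euclidean, average linkage, k = 3 by default). The original study names a
co-expression network package, but the reported selection rule is plain
pairwise correlation thresholding, which is exactly what is implemented;
soft-threshold networks and module eigengenes are intentionally out of
scope.

# The synthetic world

`simulate_study()` generates every input with recorded ground truth. What
it emulates — and what a green test does and does not establish:

* **Fraction structure.** Housekeeping mean ratios are Normal(1, 1) (a
  cytoplasm-shifted band whose 5th/95th percentiles sit near 1 ± 1.645);
  background mRNAs are Normal(0, 0.3), background lncRNAs Normal(−1.2,
  0.7) — nuclear-shifted as a population; planted nuclear and cytoplasmic
  genes sit at mean ratio −3.5 and +5.0 (beyond the band, comparable to
  real marker genes); per-line noise sd is 0.5. Background means are
  rejection-sampled to keep one noise-sd of margin from the band limits,
  so planted classes are separable but noisy (expected recovery ≈ 99%,
  not trivially 100%); the truth label of a background gene is the side of
  the true band its mean falls on. Real data have heavier tails,
  line-specific effects and measurement error correlated between
  fractions; none of that is modelled.
* **Counts.** Negative-binomial with dispersion 0.05 (typical for
  well-expressed bulk RNA-seq genes) and |log2FC| = 2 on the 50 planted
  transcripts; planted differential expression must be recoverable
  *exactly* through the strict consensus rules at 10 tumor pairs, which is
  only self-consistent in the low-dispersion regime — with dispersion 0.1
  the exact-rank test would miss a planted gene in a few percent of seeds.
* **Assembly support** per sample is Bernoulli with probability
  $1-e^{-\mathrm{count}/50}$, and planted tumor-specific transcripts are
  excluded from adjacent-sample assemblies, so their adjacent support is 0
  by construction.
* **Survival** times are exponential with the hazard multiplied by 3 for
  each planted prognostic gene whose expression exceeds its median, with
  20% uniform censoring.
* **Embryos**: 7 stages × 3 embryos × 8 cells; planted lineage-specific
  genes express in exactly 3 of 8 cells from the 4-cell stage on (a
  minority under the 67% rule), broadly expressed candidates in all cells
  from the zygote on.
* **Co-expression**: block latent factors with loading 0.9 on candidates
  and their planted partners.
* **Genome/catalog**: one gene per 4 kb tile; annotated genes get a
  reference transcript plus an assembled copy with jittered terminal ends
  (class `=`); unannotated lncRNA genes cycle through engineered
  geometries so every class code occurs. Protein-coding transcripts carry
  a planted ≥ 270-codon ORF; lncRNA transcripts have stop codons walked
  through all three frames.

All randomness is seeded; one configuration gives byte-identical output
trees. R's RNG is global state, so each generator derives a sub-seed from
the configuration seed rather than passing a generator object.

# Numerical and design choices

* Percentiles: linear interpolation (`quantile` type 7); nearest-rank
  optional.
* Strictness: DE thresholds and enrichment limits strict; PCC bound
  inclusive; prevalence bound inclusive — each matching the wording of its
  rule.
* Pseudocount 0.5 and total-count library scaling in the built-in DE test.
* Correlation r clamped to [−1, 1]; |r| = 1 maps to p = 0; zero-variance
  vectors correlate as NA/non-significant with a warning.
* Clustering ties: `hclust` is deterministic for a fixed input order;
  cluster ids are renumbered by first appearance.
* Degenerate inputs: all-censored cohorts, zero-variance expression,
  all-zero features, empty marker maps and empty candidate sets each have
  a defined, tested behavior (error or flagged pass-through as
  appropriate).

# Limitations

Upstream steps — alignment, assembly, quantification, repeat masking,
coding-potential model fitting, negative-binomial DE models, GO
enrichment — are out of scope; their outputs are inputs here. The built-in
DE test and ORF predictor are stand-ins with the statistical shape, not
the power, of the tools they replace. The synthetic world is a stated,
fixed description used to make every stage testable; recovering it
perfectly says the code implements the stated rules, not that the rules
would perform identically on real fractionation data.
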