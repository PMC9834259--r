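---
title: "Methods and design of the medipdmr DMR pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the medipdmr DMR pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

## The statistical model

MeDIP-seq read depth over a genomic interval is a proxy for that
interval's DNA methylation level, so two-group differential methylation
reduces to two-group differential counting over fixed 1000 bp windows.
`medipdmr` models the deduplicated count for window $w$ in sample $s$ as
negative binomial,

$$Y_{ws} \sim \mathrm{NB}(\mu_{ws},\ \phi), \qquad
  \mathrm{Var}(Y_{ws}) = \mu_{ws} + \phi\,\mu_{ws}^2,$$

with one dispersion $\phi$ shared by all windows. $\phi = 0$ recovers
the Poisson. A common dispersion is a deliberate choice: MeDIP designs
of 5–15 samples per group carry too little per-window replication for
stable tagwise estimation, and the conditional exact test used
downstream is defined for a single known $\phi$.

**Normalization.** Sample-to-sample differences in sequencing effort are
removed by TMM. Factors come from the doubly trimmed (30% of M-value
tails, 5% of A-value tails), precision-weighted mean of per-window log2
count-fraction ratios against a reference sample (the one whose
75th-percentile count fraction is closest to the across-sample mean).
Factors are rescaled to geometric mean 1, so they redistribute effective
library size without changing its total. These trim fractions and the
reference rule are the established TMM settings; the package states them
explicitly because "TMM" alone underdetermines the procedure.

**Dispersion estimation.** $\phi$ maximizes the sum over windows and
groups of the conditional likelihood of the within-group counts given
the group totals. The conditional likelihood is free of each window's
mean, so no abundance parameters are estimated, and it is evaluated
through the gamma function, so the non-integer pseudo-counts produced by
library-size equalization pose no difficulty. The search is bounded on
$\phi \in [0, 5]$ (BCV up to 2.2, far beyond anything a MeDIP design
produces); if optimization fails, a method-of-moments estimate is used
with a warning.

**The exact test.** Counts are scaled to the geometric mean of the
effective library sizes (making samples exchangeable, which the
conditional argument requires), summed within groups and rounded.
Conditional on the total $s = y_1 + y_2$, each group sum is negative
binomial with mean proportional to its group size and size parameter
$n_g/\phi$; the two-sided p value sums the conditional probabilities of
all outcomes no more likely than the observed one (minimum-likelihood
rule, the exact-test convention, rather than doubling one tail). At
$\phi = 0$ the conditional law is exactly $\mathrm{Binomial}(s,
n_1/(n_1+n_2))$, which the test suite uses as an independent oracle.
Ties in outcome probability (for example the mirror outcome under equal
group sizes) are kept together with a $10^{-8}$ relative slack so
floating-point rounding cannot split a mathematically tied pair.

**Fold change.** $\log_2$ of the ratio of group-mean pseudo-counts with
a prior count of 0.5 added to each mean, so zero groups give large but
finite values. Positive values mean more methylation signal in the
first contrast group (cases).

**Multiplicity.** Benjamini–Hochberg across all windows that survive
the depth filter, as one family per group comparison.

## DMR calling

Windows with $p < 10^{-5}$ seed DMRs. A DMR's edges extend iteratively:
any tested window with $p < 0.1$ whose edge-to-edge distance from the
current span is at most 1000 bp is absorbed, to a fixed point; touching
DMRs merge. Three boundary decisions deserve note:

* **Distance is edge-to-edge**, so an immediately adjacent window
  (gap 0) always qualifies — the most inclusive consistent reading of
  "within 1000 bp".
* **Depth-filtered windows are invisible to extension**: they carry no
  p value, so they neither trigger nor block it, but they are spanned
  when flanked by absorbed windows.
* **The fixed point equals transitive chaining** of sub-threshold
  windows at gaps ≤ 1000 bp, which is how it is implemented; a fuzz
  test audits the postcondition (no absorbable window within 1000 bp
  outside any called span) on a thousand random p tracks.

Each DMR reports the count of seed-threshold windows in its final span,
its minimum p value and that window's FDR and signed log2 fold change
(tables in this field report one fold change per DMR without stating
the rule; the minimum-p window is this package's documented choice),
its length, and its CpG density computed from the reference: CG
dinucleotides whose C lies inside the span (one straddling the end
boundary therefore counts), per 100 bp.

## Counting conventions

* Coordinates are 0-based half-open everywhere internally; BED is
  written natively and GFF3 converted on read. One convention
  eliminates off-by-one churn.
* PCR duplicates are records identical in (chromosome, 5′ alignment
  start, strand) within a sample — the standard single-end criterion;
  the 5′ start of a reverse-strand read is its rightmost aligned base,
  so soft-clipped duplicates with different POS still collapse.
* A read belongs to the single window containing its midpoint. Midpoint
  assignment conserves total counts, makes the simulator's SAM
  round-trip exact, and avoids double-counting at window boundaries.
* The final partial window of each chromosome is kept, and its true
  length is used for RPKM.
* Library sizes are fixed as the per-sample deduplicated mapped totals
  *before* depth filtering: normalization should reflect sequencing
  effort, not the analysis filter.

## Comparative analyses

Overlap between DMRs is "≥ 1 bp shared", the simplest defensible
predicate, used for Venn membership, extended overlap and truth
matching alike. Extended overlap re-calls the comparison set at a
relaxed seed threshold (default $p < 0.05$, same extension rule) and
reports the fraction of the strict set overlapping it; a set compared
against its own relaxed calls always yields 100%, which the tests
assert. Gene association takes the gene body, not the TSS alone, and an
inclusive gap of up to 10 kb, covering proximal and distal promoter
neighborhoods.

The PCA operates on RPKM over DMR windows with samples as observations,
centered but not scaled (RPKM is already on a common scale across
windows); components come from the covariance decomposition and each
component's sign is fixed by making its largest-magnitude loading
positive, so results are deterministic. Group separation is checked in
the tests by a perceptron on the first two components.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which the pipeline validates itself.

* **Genome.** Bases are iid with $P(C) = P(G) =
  \sqrt{d/100}$ where $d$ is the target CpG density per 100 bp
  (default 2), so the expected CG-dinucleotide density equals $d$. The
  default emulates the CpG-poor regions (1–3 CpG/100 bp) where MeDIP
  DMRs concentrate; the resulting ~28% GC content is low for a real
  genome but irrelevant to a pipeline that only reads CG positions.
* **Coverage.** Window baseline $\mu_w \propto (\text{CpG count}_w +
  1)$, scaled so the genome-wide mean equals `mean_depth_per_window`
  (default 30 reads — enough that the 10-read depth filter passes most
  windows while leaving a filtered tail to exercise it). The $+1$ floor
  reflects nonzero MeDIP background in CpG-free windows.
* **Samples.** Library-size factors are drawn log-uniformly from
  [0.7, 1.4] unless given — the few-fold spread typical of real
  libraries; NB noise uses the configured $\phi$ (default 0.1,
  BCV ≈ 0.32, a realistic biological-replicate value).
* **Spikes.** Differential regions are window-aligned, 1 or 2 kb,
  non-overlapping, separated by ≥ 3 windows so truth-to-call matching
  is unambiguous, with signed effects $2^{\pm\text{lfc}}$ applied to
  case samples and an even hyper/hypo split by default.
* **SAM emission.** Each counted read becomes a ~50 bp single-end
  record whose midpoint is drawn uniformly *without replacement* within
  its window, so no two distinct reads share an alignment start; exact
  positional duplicates are then added per read with the configured
  probability. Deduplicated recounting therefore recovers the count
  matrix exactly — the round trip is an identity, not an approximation.

What the generator does **not** emulate: fragment-length distributions,
antibody efficiency and CpG-density-dependent capture saturation, GC
bias, mappability, paired ends, and FASTQ-level errors. Passing tests
therefore demonstrate the correctness of counting, normalization,
testing and calling logic under the stated model — not robustness to
alignment artifacts or capture biases of real MeDIP libraries.

## Validation scale and determinism

The self-validation runs at desk scale, chosen to give stable Monte
Carlo estimates in seconds: 20,000 windows for null calibration (the
fraction of $p < 0.05$ windows must sit within 0.05 ± 0.015), 5,000
windows at 10 vs 10 samples for dispersion recovery (within a factor of
two at $\phi$ from 0.01 to 0.5), and 100 spiked regions at 8 vs 8 for
DMR recovery (≥ 90% sensitivity and precision, direction split
0.5 ± 0.1). The exact test is verified against brute-force enumeration
of the conditional distribution for every outcome with $s \le 40$ at
three dispersions, to $10^{-12}$.

All generator output is deterministic given `rng_seed`; per-chromosome
sub-streams are derived from it so a chromosome's sequence does not
depend on how many precede it, and the caller's RNG state is always
restored. Doubles are serialized to TSV with 17 significant digits, so
every intermediate file round-trips to the exact binary value and
re-writes are byte-identical — reproducibility one can checksum, which
the run manifest does.

## Known limitations

* One common dispersion can over- or under-state uncertainty for
  windows whose biological variability departs from the genome-wide
  norm; tagwise shrinkage is out of scope.
* The conditional exact test requires exchangeable library sizes;
  equalization by pseudo-counts (with rounding of group sums) is an
  approximation that degrades when effective library sizes differ by
  large factors.
* Covariates, paired designs and more than two groups per test are not
  supported; the "combined" analysis is pooling of case groups against
  controls.
* Gene association is distance-based; it does not assert regulatory
  function.
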