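---
title: "Evaluating single-cell whole-genome amplification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating single-cell whole-genome amplification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scwgaeval)
library(dplyr)
```

Single-cell sequencing starts from picograms of DNA, so every library is
preceded by whole-genome amplification (WGA) — multiple displacement
amplification (MDA), multiple annealing and looping-based amplification
cycles (MALBAC), or degenerate-oligonucleotide-primed PCR (DOP-PCR). Each
chemistry leaves a characteristic fingerprint on the data: allele drop-out
(ADO) at heterozygous sites, spurious false-positive (FP) alleles,
non-uniform coverage, and chimeric junctions formed when unrelated amplicons
join. `scwgaeval` implements the downstream evaluation framework used to
compare these methods — genotype concordance against a golden control,
coverage-uniformity diagnostics, a binned copy-number pipeline with
in-silico CNV spike-in, and breakpoint-level chimera classification —
together with a synthetic-data generator so the whole framework runs and is
tested without any external sequencing data.

## Golden-control genotype concordance

The comparison baseline is a *golden control*: a consensus genotype set from
bulk sequencing (one run, or the concordant intersection of two replicate
runs) restricted to the positions of a SNP array
(`build_golden_control()`). Sites are partitioned by
`classify_genotype()` into

* `HOMref` — both alleles equal the reference base,
* `HOMmut` — both alleles equal each other and differ from the reference,
* `HETref` — exactly one allele equals the reference.

A heterozygote carrying two non-reference alleles has no slot in this
three-way scheme; such calls are rare artifacts and are excluded from the
tabulation with a recorded count rather than silently mislabelled.

`concordance_matrix()` walks the golden-control sites and cross-tabulates
the single-cell call against the control at *share levels* 2, 1, 0 — the
number of alleles the two genotypes hold in common (multiset intersection,
`allele_share()`). Two summary families follow:

* **CGDE** (consensus genotype detection efficiency, `cgde()`): the fraction
  of control sites of each category genotyped in the cell.
* **Concordant ratio** (`consistency()`): among detected sites of a
  single-cell category, the fraction matching the control at both alleles.

`snv_metrics()` compares calls at the SNV level. With `detected_het` the
cell's heterozygous SNV calls and `ado_count` the bulk-heterozygous sites
where the cell retained only one allele,

$$\mathrm{ADO\ ratio} = \frac{\mathrm{ado}}{\mathrm{detected_{het}} + \mathrm{ado}},
\qquad
\mathrm{FP\ ratio} = \frac{\mathrm{fp_{total}}}{G},$$

where $G$ is the number of assessable genomic positions
(`genome_sites`, default $3\times10^9$, the approximate size of the human
genome). These two denominators are the forms that reproduce the published
per-cell ratios exactly from their printed counts, and they are exposed as
explicit arguments rather than hidden conventions. Detection efficiency is
reported in two variants: *gross* (`detected_total / control_total`, the
form behind the headline mean efficiency) and *net*
(FP calls subtracted first, the form printed per zygosity class in summary
tables). Both are returned; reports state which is used.

## The synthetic-data generator

`simulate_golden_control()` draws control sites with category proportions
defaulting to the composition of a lymphoblastoid control restricted to a
2.5M SNP array (HOMref : HOMmut : HETref $\approx$ 0.718 : 0.122 : 0.159).
`simulate_single_cell_calls()` then applies, per covered site, the three
artifact processes of a `method_profile()`:

1. **Coverage** — each site is callable with probability `site_coverage`.
2. **ADO** — each covered heterozygous site loses one allele with
   probability `ado_rate`. By default either allele is retained with
   probability 1/2; `ado_mode = "ref_biased"` retains the reference allele
   (i.e. the alternative allele fails to amplify), since the asymmetric
   reading of drop-out is also defensible. The symmetric default makes the
   homozygous direction of ADO errors unbiased.
3. **FP** — each covered site not already hit by ADO gains a spurious
   substitution with probability `fp_rate`; the new base is drawn uniformly
   from the bases *not present* in the true genotype.

Two design choices here are deliberate. ADO and FP are mutually exclusive
per site, and FP never re-creates an allele the site already carries;
together these guarantee that every simulated event is observable and
classifiable, so the estimator counts in `estimate_artifact_rates()` equal
the generator's truth labels *exactly*, not just in expectation. That exact
correspondence is what the parameter-recovery test suite leans on. The cost
is a slight idealisation: a real FP substitution can coincide with ADO or
duplicate an existing allele, at rates of order `ado_rate * fp_rate` —
negligible at the rates studied.

Per-bin read counts (`simulate_binned_counts()`) are
$\mathrm{Poisson}(\mu \, a_b \, N_b/2)$ with $a_b$ a per-bin amplification
factor, log-normal with unit *median* and log-s.d. `bin_dispersion`, and
$N_b$ the local truth copy number (length-weighted across bins that straddle
a region boundary). No generative form for amplification bias is mandated by
the data being emulated — only that normalized-depth distributions are
skewed and heavy-tailed with a method-dependent spread — so the log-normal
is a modelling choice; any heavy-tailed positive mixing distribution would
serve. Unit median (rather than unit mean) anchors the bulk of bins at
ratio 1, which is what mode-anchored copy-number calling assumes.

Bundled presets (`wga_profiles()`) fix the study conditions once: measured
quantities (ADO ratios, FP ratios, site coverage, the MDA chimera type mix)
use the reported per-method values; quantities reported only as orderings
are set to plausible values respecting that ordering — bin dispersion 0.8
(MDA-2) > 0.35 (MALBAC) > 0.15 (DOP) > 0.02 (bulk), duplication 0.70 for
DOP-PCR versus 0.05–0.15 elsewhere, chimera rates highest for MDA. These
are package defaults, documented here, and not tuned thereafter.

Breakpoints (`simulate_breakpoints()`) keep the true structural variants
(each end jittered uniformly within ±50 bp, half the matching threshold, so
truth remains matchable by construction) and inject chimeras with types
drawn from the profile's mix. Same-chromosome chimeras get exponential
end-to-end spans with mean `chimera_itx_length_scale` (default 10 kb, the
amplicon scale) — the short-range signature of neighbouring amplicons
joining — while CTX chimeras connect uniform positions on two chromosomes.

## The copy-number pipeline

`make_bins()` partitions the genome into `n_bins` (default 10,000) bins —
equal-width, or holding equal mappable-position weight when a mappability
track is supplied (the convention of count-based single-cell CNV
pipelines). `normalize_ratio()` divides counts by their mean (optionally
after dividing out a loess GC trend) so the genome-wide mean ratio is 1.

`segment_ratios()` implements circular binary segmentation: within each
chromosome the arc maximising a two-sample $t$-like statistic is tested
against a permutation null ($\alpha = 0.01$, 1000 permutations, minimum
segment width 2 bins); significant change-points are applied and the
procedure recurses. Three numerical choices matter:

* The scan runs on $\log_2$ ratios (floored at $10^{-6}$ before the log).
  Multiplicative amplification noise is approximately log-normal, so on the
  log scale it is symmetric and light-tailed; on the raw scale a couple of
  adjacent high outliers can dominate the permutation null as a spurious
  two-bin arc and mask genuine broad shifts. Reported segment means stay on
  the ratio scale.
* The permutation test stops early once the exceedance count makes
  rejection impossible at level $\alpha$ — on null data most tests finish
  after a few dozen permutations, which is what keeps 10,000-bin runs fast.
* Constant segments (zero variance) are never split.

`mode_normalize()` estimates the kernel-density mode of the per-bin segment
ratios on autosomes and assigns it copy number 2; every segment's copy
number is `2 * ratio / mode`, invariant under global rescaling. In a
tetraploid-like genome whose density is bimodal the heavier mode wins —
the standard, and standardly ambiguous, resolution; callers needing the
other anchoring can rescale explicitly.

`call_cnvs()` thresholds segment copy numbers at ≥ 2.5 (gain) and ≤ 1.5
(loss) — midpoints between integer copy states, a package choice, exposed
as arguments — merges adjacent same-direction segments and keeps calls
spanning at least 1 Mb. Spike-in follows $K_s = K_r \times R$ with
$R = N/2$, length-weighted where a region boundary crosses a bin, with
deterministic rounding by default (`rounding = "poisson"` resamples for
stochastic realism). `evaluate_cnvs()` scores by total length:
$\mathrm{sensitivity} = L_T/L_C$ and $\mathrm{specificity} = L_T/L$, where
$L$, $L_C$, $L_T$ are the CNV lengths (≥ 1 Mb) of the cell, the control and
their intersection. "Specificity" is precision-like but the field's name
for this quantity is retained. Overlap is direction-agnostic by default
(the defining formulas reference lengths only); `require_direction = TRUE`
intersects gains with gains and losses with losses.

## Chimera classification

`match_breakpoints()` labels a single-cell breakpoint *true* when a control
breakpoint of the same type and chromosome pairing lies within 100 bp; the
threshold is applied to **both** ends by default (stricter than a
single-end reading, which is available via `both_ends = FALSE`, since the
defining rule does not say which). Matching is greedy one-to-one — candidate
pairs ordered by total end distance, ties broken by genomic order — so one
control event cannot validate many single-cell events. Ends are
canonicalized (lexicographic chromosome order, then position) before
distances are computed. Everything unmatched is a chimera;
`chimera_type_fractions()` summarises the type mix and
`itx_length_compare()` runs the Mann–Whitney comparison of shared versus
chimeric ITX spans.

## Uniformity diagnostics

Depth tracks are 100 kb windows by default. `normalized_depth()` divides by
the width-weighted genome mean (all supplied windows by default, with an
`autosomes` filter), drops chromosome-end windows narrower than half the
modal width, and is exactly scale-invariant. `poisson_reference()` draws the
no-bias comparison distribution ($\lambda = 30$, 1000 draws, normalized by
$\lambda$). GC strata use strict inequalities — above 0.50 `HighGC`, below
0.35 `LowGC`, ties to `MiddleGC`. The duplication ratio uses mapped reads as
its denominator (the common convention; the quantity is not otherwise
pinned down).

## Statistical machinery

`mann_whitney()` delegates to `stats::wilcox.test()`: the exact null
distribution when both groups have at most 20 untied observations
(configurable crossover), otherwise a tie-corrected normal approximation
with continuity correction. Degenerate input — all pooled values identical —
returns $p = 1$ with a warning rather than `NaN`. The test suite checks the
exact branch against an independent brute-force enumeration of every group
assignment for all sample sizes up to 8. `bonferroni()` is
$\min(1, m\,p)$; `pearson()` is the product-moment correlation with
explicit degenerate-input errors.

## What the tests do and do not show

The test suite and the acceptance script rerun the framework end to end on
synthetic data at fixed problem sizes, chosen as the package's standard
verification conditions: $10^5$ control sites for artifact-rate recovery
(ADO $\times$ FP grid), 10,000 bins and 8 spiked regions of 5–20 Mb for
CNV recovery (10 seeds per condition; noise-free recovery is checked
per-seed, amplification-noise recovery as the mean over seeds, the form in
which such accuracies are conventionally reported), 1000-bin null tracks
(100 seeds) for the segmentation false-split rate, and $10^4$ injected
chimeras for type-fraction recovery.

The generator emulates the *statistical* structure the estimators assume —
independent per-site artifact events, independent per-bin multiplicative
bias, exponential short-range chimeras. Real WGA data violate some of these
in ways the suite deliberately does not model: amplification bias is
spatially autocorrelated along the genome and partially shared between
cells amplified by the same chemistry; coverage, GC content and mappability
are coupled; ADO probability varies with local depth; breakpoint discovery
has its own error profile upstream of classification. Passing tests
therefore certify the correctness of the estimators and pipeline under the
stated model, and the faithful reproduction of the published summary
statistics from their counts — not that any particular laboratory protocol
will achieve these numbers.

## Known limitations

* The concordance tabulation is control-anchored: single-cell calls outside
  the golden control enter only through `snv_metrics()` FP counting.
* Mode anchoring assumes the modal state is diploid; whole-genome
  duplications defeat it by construction (flagged above).
* The CBS permutation test calibrates the first split on each recursion
  level; deep recursions inherit the usual multiple-testing optimism of
  recursive segmentation, which the null-track false-split test bounds
  empirically.
* VCF support targets simple biallelic GT records; complex multi-allelic
  records should be normalised upstream.
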