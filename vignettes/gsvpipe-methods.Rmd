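---
title: "Statistical methods for GSV immunoisolation proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for GSV immunoisolation proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsvpipe)
```

## The experimental design the pipeline assumes

GLUT4 storage vesicles (GSVs) are immunoisolated with an anti-GLUT4
antibody from two membrane preparations of primary adipocytes — low
density microsomes (LDM) and the post-high-speed supernatant (pHS) — under
three conditions each: an IgG control immunoisolation (background
binding), a basal immunoprecipitate, and an immunoprecipitate from
insulin-stimulated cells. Each (preparation, condition) cell has a small
number of replicates; the design this package targets has two. Label-free
quantification (LFQ) intensities per protein group are the abundance
measure. A zero intensity in the input table means "not quantified", never
a measured zero — this missingness is heavily intensity-dependent (values
near the detection limit drop out first), which shapes both the imputation
model and the synthetic data.

The two preparations are treated as independent experiments throughout:
normalization is per sample, imputation parameters and variance priors are
estimated per preparation, and evidence is only combined at the final
Z-score integration step.

## The processing chain and its parameters

**Normalization.** Intensities are log2-transformed and each sample is
median-centered and rescaled so that its median absolute deviation (MAD)
equals the across-sample median of the raw per-sample MADs; the common
location is the median of the per-sample medians. Using the median MAD as
the target scale (rather than 1) and restoring the location keeps values
on the log2-intensity scale, so quantities like the abundance cutoff
remain interpretable as log2 LFQ intensities. With this choice the
transformation is exactly idempotent. A sample with zero MAD or fewer than
two observed values cannot be normalized and is reported as an error
naming the sample.

**Replicate completeness.** A protein enters a preparation's identified
set only if it is quantified in *every* basal immunoprecipitate replicate
of that preparation. The merged analysis set is the intersection of the
two preparations' sets; proteins identified in only one preparation are
carried in a side table (`$partial`) and reported but never classified —
some genuine cargo is expected to land there, the price of requiring
cross-preparation concordance.

**Variance trim** (`variance_trim_fraction`, default 0.05). The
`round(fraction * N)` most variable proteins are removed, rounding half
away from zero. Variability is measured as the pooled standard deviation
of observed values across replicates *within* each (preparation,
condition) group. This was a genuinely open design choice: an SD taken
across all samples of a protein conflates biological signal with
measurement noise — a strongly insulin-responsive protein spans ~1.3 log2
units across conditions even with perfectly tight replicates, and under
any scenario with realistic effect sizes the cross-sample ranking would
place essentially all true cargo in the top-variability tail and the trim
would delete the very proteins the pipeline exists to find. The
replicate-level pooled SD measures irreproducibility only, which is the
quantity a quality trim should target. Proteins with no group offering two
observed values have undefined variability and are never trimmed.

**Imputation** (`n_imputations`, default 20; conditions `IgG` and
`insulin`). Missing values are modeled as left-censored: for each
(preparation, condition) to be imputed, draws come from a Gaussian with
mean μ equal to the *minimum* observed log2 value in that condition's
columns and standard deviation σ equal to the SD of the observed values at
or below the condition's 25th percentile. Each missing cell is replaced by
the average of 20 independent draws. Three interpretation choices are
worth recording:

* "σ of the first quartile" is read as the SD of the observed values lying
  in the lowest quartile of the condition's pooled observed-value
  distribution (not a per-protein quantity, which would be undefined for
  the mostly-missing proteins that need imputation most). When fewer than
  two values fall in that quartile σ is set to 0.
* "Imputed 20 times and averaged" is read as averaging the 20 draws per
  cell, since the averaging modifies the missing values themselves, not
  downstream statistics. The averaged value has SD σ/√20 — a deliberately
  low-variance placeholder near the detection limit.
* Only IgG and insulin columns are imputed; basal columns are complete by
  construction of the completeness filter. The imputed-condition set is
  configurable.

Each cell's draws come from a private RNG substream keyed on (seed,
protein id, sample id), so imputed values are reproducible and invariant
to the row or column order of the table.

Minimum-anchored imputation is intentionally anti-conservative for
differential testing: a censored cell is replaced by a value near the
condition's detection floor, which exaggerates contrasts against complete
conditions. That is the behavior being reproduced — it encodes the belief
that absence from the IgG control reflects genuinely low abundance — but
it means false-positive calibration can only be assessed on complete data
(see the null preset below), and the abundance-median gate is what keeps
the resulting low-intensity artifacts out of the final calls.

**Moderated testing.** Both contrasts — enrichment (basal vs IgG) and
responsiveness (insulin vs basal) — are tested per preparation with a
moderated two-sample t-statistic: the pooled per-protein variance s² (df =
n_a + n_b − 2) is shrunk toward a prior, s²_post = (d₀s₀² + df·s²)/(d₀ +
df), and the statistic log-fold-change / sqrt(s²_post(1/n_a + 1/n_b)) is
referred to a t distribution with df + d₀ degrees of freedom. The prior
(d₀, s₀²) is fitted by method of moments on log s² under the scaled-F
marginal, separately per preparation and contrast; when the spread of log
s² does not exceed what sampling alone explains, d₀ = ∞ and all posterior
variances collapse to s₀². The test suite verifies the fit and the
statistics against limma's `squeezeVar`/`eBayes` as an independent
implementation; the package's own code never calls it.

**Z conversion.** t-statistics are mapped to standard-normal Z-scores by
matching tail probabilities, computed on the log scale tail-wise so the
map stays accurate far into the tails; |z| is capped at 8.2, past which
double-precision normal tails are degenerate. Capping events warn.

**Directional integration.** The two preparations' Z-scores are combined
by projecting (z_LDM, z_pHS) onto a quadrant's diagonal unit direction and
taking the one-sided upper normal tail of the projection — a Stouffer
combination along a direction. Enrichment uses the positive quadrant
(+1,+1)/√2, responsiveness the negative quadrant (−1,−1)/√2. The cited
direction-analysis methodology admits other constructions (e.g. rotation
followed by a maximum); the diagonal projection is the canonical
directional statistic, is exactly N(0,1) under the null with independent
preparations, makes discordant proteins (up in one preparation, down in
the other) project to ~0 and p ≈ 0.5, and is validated here against a
permutation oracle. No multiple-testing correction is applied by default —
classification thresholds the integrated p at α directly; a
Benjamini–Hochberg switch (`apply_bh`) exists and can only shrink the call
set.

**Classification** (`alpha`, default 0.05). The median abundance cutoff is
the median over the merged, trimmed, imputed population of each protein's
mean basal log2 intensity across both preparations (computed after
imputation, following the processing order; basal columns are complete so
imputation rarely matters here). The abundance gate is strict (`>`).
Tiers: `not_enriched`, `enriched_low_intensity` (significant enrichment,
at-or-below-median abundance), `enriched` (adds the abundance gate), and
`high_confidence_gsv` (adds insulin responsiveness). Without insulin
samples tiers cap at `enriched`.

## What the synthetic data emulate — and what they do not

`simulate_gsv_dataset()` generates the structure the analysis assumes:
per-protein base abundance N(22, 2²) on the log2 scale (a realistic LFQ
dynamic range of ~5 orders of magnitude); a `frac_true_gsv` fraction
(default 5%) of true cargo with per-protein realized enrichment effects
N(3, 0.3²) applied to immunoprecipitate conditions and realized insulin
depletions N(1.5, 0.3²) (truncated at 0) applied under insulin; background
binders and flagged contaminants flat across conditions; replicate noise
N(0, 0.5²); and logistic left-censoring P(missing | x) = 1/(1 +
exp(slope·(x − limit))) with limit 18 (two SDs below the median protein)
and slope 1, which yields the observed pattern that missingness
concentrates in the IgG and insulin samples of true cargo. IgG intensities
of true cargo sit `enrich_effect` *below* the immunoprecipitate level
rather than at zero, so the imputation path is genuinely exercised. The
per-protein effect spread (`effect_sd`, 0.3 log2) exists so that effect
recovery is a testable regression rather than a constant.

The defaults are the benchmarking scenario used by the acceptance checks
and `scripts/acceptance.R`; 1,000 proteins keeps every stage's behavior
measurable while the full pipeline runs in well under a second. Presets:
`"null"` sets both effects to zero *and disables censoring* — with
censoring active, minimum-anchored imputation is anti-conservative by
design, so a meaningful false-positive calibration of the
testing/integration chain requires complete data; `"strong"` has larger
effects and less noise.

Deliberately not emulated: peptide-level quantification and the LFQ
roll-up, correlated replicate noise (batch structure), intensity-dependent
variance trends, shared-peptide ambiguity between protein groups, and
immunoglobulin-chain interference. Passing tests on this generator show
the statistical chain does what it claims under its own assumptions; they
do not certify performance on real spectra.

## Numerical and validation choices

* **Rounding** of the trim count is half-away-from-zero (so 5% of 304 is
  15), implemented explicitly since base R rounds half-to-even.
* **Quartile membership** for σ uses values `<=` the type-7 25th
  percentile; at least 4 observed values per condition are required.
* **Prior fitting** requires ≥ 10 positive finite variances; the trigamma
  inversion is Newton iteration with asymptotic fallbacks at both ends.
* **Tie-breaking** in the variance trim is by row order (stable sort),
  which matters only for exactly tied SDs.
* **Permutation oracle.** `permutation_oracle_p()` validates the
  integrated p-value by relabeling the two condition groups within each
  preparation. It refuses to run when the group sizes admit fewer than
  1,000 distinct relabelings — at n = 2 per group there are only 36, so
  oracle-based validation uses richer synthetic designs (8 replicates per
  condition). Validation runs use the ordinary pooled t (d₀ = 0): the
  fully studentized statistic is conditionally pivotal, so its permutation
  distribution matches the t reference protein by protein. With moderation
  the shrunk denominator is only partially studentized and the *conditional*
  permutation distribution of a single protein deviates from the reference
  by an amount that depends on how far its realized variance sits from the
  prior — a property of moderation itself, not of the integration being
  validated. The moderated path's calibration is checked marginally
  instead (null tail frequencies and the uniformity of p_int).
* **Degenerate inputs.** All-flagged tables, all-missing columns,
  zero-MAD columns, empty post-filter sets and non-finite cutoffs raise
  errors naming the offending stage, sample or protein; σ = 0 imputation
  is exact; zero-variance proteins with zero fold change give t = 0.

## Known limitations

* With n = 2 per group the responsiveness contrast has limited power:
  moderately insulin-responsive cargo (realized depletion ≲ 1 log2) can
  fail gate 3, and true cargo below the median abundance fails gate 2 by
  construction. The tier vocabulary keeps such proteins visible
  (`enriched`, `enriched_low_intensity`) rather than discarding them.
* Averaging 20 imputed draws shrinks imputed-cell variance by √20, which
  understates uncertainty in the test statistic for heavily imputed
  proteins; the pipeline reproduces this behavior rather than propagating
  multiple-imputation variance.
* The variance prior is fitted per preparation/contrast on a few hundred
  proteins; with very small merged sets the method-of-moments fit is
  noisy, and below 10 proteins it refuses to run.
* Cross-preparation integration assumes the two preparations are
  independent; shared starting material would make the combined evidence
  anti-conservative.
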