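---
title: "Methods: multi-compartment small RNA analysis with mirc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-compartment small RNA analysis with mirc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirc)
```

## The problem

Hepatocellular carcinoma studies increasingly profile small RNAs in several
compartments of the same patient — tumor tissue, adjacent normal tissue,
whole serum, and serum exosomes — to ask whether tumor-driven miRNA changes
are visible in circulation and could serve as biomarkers. Analysing such
data raises a chain of linked statistical questions: how to normalize
sequencing counts whose library composition differs radically between
compartments; how to test differential expression on a handful of paired
patients; how to quantify whether two independent contrasts (tumor vs
normal tissue, exosome vs whole serum) move the same miRNAs in the same
direction; how to narrow thousands of predicted miRNA targets to pairs with
observed repression; and whether a candidate miRNA stratifies survival.

`mirc` implements this chain as composable, individually tested functions,
together with a synthetic-cohort generator that reproduces the data
structure the analysis assumes, so every stage can be validated without
patient data.

## Normalization

Counts are scaled to counts per million (CPM), where a sample's library
size is the sum over **non-calibrator** features. Spike-in calibrators are
added during library preparation in fixed amounts; including them in the
library size would let technical spike-in signal absorb biological signal.
On the log scale,

$$\text{log2 CPM} = \log_2\!\frac{c + c_0}{L \cdot s + 2 c_0} \times 10^6,$$

with prior count $c_0 = 0.5$ (the convention of precision-weighted count
modelling; exposed as `prior_count`) and optional per-sample size factors
$s$.

`calibrator_size_factors()` derives $s$ as the geometric mean of a sample's
calibrator counts, rescaled to overall geometric mean 1. The geometric mean
is robust to multiplicative noise; a zero calibrator count makes it
degenerate, so zeros are an error rather than silently pseudocounted — a
sample whose calibrators dropped out cannot be calibrated.

Expression filtering keeps features with CPM ≥ `min_cpm` (default 1) in at
least `min_fraction` (default 0.5) of the samples of the comparison at
hand; both thresholds are inclusive ("at least"). The filter is idempotent
and monotone in `min_cpm`, and calibrators are always retained since they
carry normalization, not biology.

`quantile_normalize()` maps every column onto the mean order-statistic
reference; tied values receive the mean of the reference values they span,
so column means agree exactly. `pca_expr()` is a feature-centered,
unscaled SVD of the samples, intended for logged filtered CPM.

## The differential expression engine

The engine is a precision-weighted linear-model pipeline with
empirical-Bayes variance moderation, re-implemented in full:

1. **Precision weights** (`voom_weights()`): per-feature linear models on
   log2 CPM give residual standard deviations; a LOWESS curve (span 0.5,
   fitted over features with positive residual df) of
   $\sqrt{\hat\sigma}$ against average log2 count abundance captures the
   count mean–variance relation; each observation's predicted standard
   deviation, evaluated at its fitted log2 count and clipped to the
   trend's range at the extremes, becomes an inverse-variance weight
   $w = \widehat{\text{sd}}^{-4}$.
2. **Weighted least squares + moderation** (`fit_and_moderate()`): each
   feature is fitted by WLS against the design. The residual variances
   $s^2_g$ (df $d$) are modelled as $s^2 \sim s_0^2 F(d, d_0)$; $(d_0,
   s_0^2)$ are estimated by moment matching on $\log s^2$ with the prior
   df obtained by Newton inversion of the trigamma function. The moderated
   t-statistic uses the posterior variance
   $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ with $d + d_0$ degrees of
   freedom; tests are two-sided everywhere.
3. **Multiplicity** (`bh_adjust()`): Benjamini–Hochberg step-up,
   $\tilde p_{(i)} = \min_{j \ge i} \min(1, m\, p_{(j)}/j)$.

Setting `d0 = 0` recovers the classical per-feature t-test exactly and
`d0 = Inf` the pooled-variance t-test (with $s_0^2$ the df-weighted mean of
the $s^2_g$); the test suite asserts both limits to 1e-10 and agreement of
the full pipeline with the established reference implementation to ~1e-10
on a fixture.

`run_contrast()` composes filtering, optional calibrator size factors,
weights, the fit and BH. Comparisons are named (`tumor_vs_normal`,
`exo_vs_serum`, `cancer_vs_control_serum`, and the clinical contrasts
`HBV`, `cirrhosis`, `surgery` within a stated compartment). Sample age — a
storage-time degradation proxy that can dominate expression variation — is
entered as a single continuous covariate via `adjust_for = "sample_age"`
(the coding is a package choice; nothing finer is identifiable from
storage-time alone). Matched tissue designs default to paired fits
(per-patient intercepts); pairing is optional because serum/exosome subsets
may be incomplete. Significance is `adj_p < 0.05` throughout. A design in
which the group indicator is collinear with covariates or pairing is
rejected with a "confounded" error rather than silently dropped columns.

## Concordance between contrasts

`compare_contrasts()` reports the exact set chain used in cross-compartment
analyses: features significant in either contrast; of those, the ones
expressed in all four sample types (expression sets are supplied per sample
type from `filter_expressed()`, matching the per-comparison filtering); of
those, the ones with identical nonzero logFC signs; plus the
significant-in-both set and its same-sign subset, with a Pearson
correlation over the both-significant logFC pairs (reported as absent below
3 pairs). A logFC of exactly 0 carries no sign and is excluded from
same-sign sets — sign concordance is undefined at 0.
`validate_directions()` measures directional reproducibility in an
independent cohort; features the validation cohort did not detect are
excluded from the denominator rather than counted as failures, and a zero
denominator yields an absent fraction, not 0.

Both functions are verified against brute-force double-loop references on
hundreds of random instances.

## The target-integration cascade

Predicted miRNA–gene pairs are narrowed by four filters, in this order:

1. **miRNA expression**: keep miRNAs whose 75th percentile of per-sample
   log2 CPM (linear interpolation between order statistics, the most
   common percentile convention; configurable) is strictly above 10.
2. **Predicted repression**: weighted context score strictly below −0.4
   (more negative = stronger predicted repression).
3. **Directional consistency**: for each gene, the fraction of its
   targeting miRNAs sharing the majority DE direction must be strictly
   above 0.75; retained pairs are restricted to the majority-direction
   miRNAs. The published description of this rule ("more than 75% … are
   either all up or all down") is internally contradictory; the
   majority-fraction reading implemented here is the permissive coherent
   one, and the threshold is exposed as `min_fraction`.
4. **Anticorrelation**: Pearson correlation (Spearman available) of miRNA
   and gene expression over shared samples must be negative. No p-value
   threshold is applied — the selection is by sign, which on null data
   passes about half of the candidate pairs; the test suite documents
   this deliberately weak behaviour. Tumor samples are the default
   correlation domain (the choice is open; pass any expression subset).

All three threshold filters are strict inequalities, asserted at their
boundary values in the tests (score −0.4 is dropped, P75 = 10 is dropped,
a 3-up/1-down gene is dropped). The expression and context-score filters
commute; attrition counts after every stage are recorded and are
monotonically non-increasing.

`enrich_gene_sets()` tests the surviving genes for over-representation in
user-supplied gene sets (GMT) with a one-sided hypergeometric test against
a detected-gene universe, BH across sets, default reporting cutoff
`adj_p < 0.01`. Up/down gene classes for enrichment inputs are
conventionally defined as `adj_p < 0.05` and `|logFC| > 0.5`.

## Survival analysis

Patients are dichotomized at the median expression of a feature; ties go
to Low (deterministic, and conservative for the High group).
`kaplan_meier()` is the product-limit estimator; censoring removes
patients from the risk set without a step. `logrank_test()` is the
standard two-group observed-minus-expected statistic. `cox_fit()`
maximizes the Breslow partial likelihood (the simplest well-defined tie
handling) by Newton–Raphson from $\beta = 0$ with tolerance 1e-8, at most
50 iterations and step-halving whenever a step decreases the likelihood;
monotone likelihoods (complete separation of event times) are flagged as
non-converged with an absent p-value. The reported p is the two-sided Wald
test; the score test at $\beta = 0$, which equals the log-rank statistic
for tie-free two-group data, is also returned. `survival_screen()` runs
the dichotomize-and-fit loop over features and applies Bonferroni
(`min(1, m p)`) across the features tested — the conventional choice when
a single survival marker is sought.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis assumes:

- **Design**: a discovery cohort (default 17 patients) and a validation
  cohort (default 80) with four matched compartments each, plus control
  sera (default 19) — the cohort layout of the motivating study design.
- **Counts**: negative binomial with mean `library size × relative
  abundance` and a single shared dispersion φ (default 0.2, a typical
  bulk-seq value; variance $\mu + \phi\mu^2$, Poisson in the φ→0 limit).
  Library sizes are log-uniform over 2–20 million reads.
- **Composition**: per-feature baseline abundances are drawn per RNA class
  (log-normal, sdlog 1.5 — expression mass concentrated in a few dominant
  features, as in real small RNA data) and rescaled inside each
  compartment so expected class read mass equals the configured
  composition. Defaults encode tRNA-depleted exosomes, snoRNA-rich
  tissue, and scRNA-rich serum/exosomes.
- **Calibrators**: 10 spike-ins with compartment- and age-independent
  means (they are added at library preparation, after any degradation).
- **Sample age**: each non-calibrator feature gets a log2-per-year slope
  ~N(0, `age_effect_sd`) applied to its true abundance before sampling —
  a degradation confounder visible to PCA and removable by covariate
  adjustment. The magnitude is a free parameter (default 0.05) because no
  quantitative estimate of the effect exists; calibrators are exempt.
- **Planted effects**: multiplicative fold changes on a contrast's
  positive group. Defaults plant a miR-21-like feature (+2 log2 in both
  tumor-vs-normal and exosome-vs-serum — the concordant-export scenario)
  and a miR-122-like feature (+1.95 in cancer vs control serum, ~4-fold;
  +2.929 log2 for HBV in serum, the reported serum HBV association).

`simulate_mrna()` adds a gene expression layer in which planted repressed
genes track their miRNA with slope `repression_slope` (≤ 0) plus Gaussian
noise, and a predicted-target table whose planted pairs score U(−1, −0.45)
— safely below the −0.4 cut — while decoys score U(−1, 0), deliberately
straddling it. `simulate_survival()` draws exponential event times with
the high group's hazard multiplied by $e^\beta$ and independent uniform
censoring whose range is solved numerically to hit the requested expected
censoring fraction.

Everything is deterministic given the config seed, and the generator never
touches global RNG state.

**What the generator does not emulate**: read-level artefacts (adapter or
ligation bias), sequence-realistic miRNAs or isomiR structure, per-feature
dispersion heterogeneity, batch effects beyond sample age, and
calibrator–depth coupling. Tests passing on this generator therefore
demonstrate the correctness and calibration of the statistical machinery
under its stated model, not robustness to every artefact of real
sequencing data.

## Numerical and scale choices

Test and benchmark problem sizes are chosen so the whole suite runs in a
few minutes on one CPU while keeping Monte-Carlo error small relative to
the margins tested: null calibration at 5000 features × 10/group, FDR
control over 100 replicates of 500 features, concordant-miRNA recovery
over 100 simulated cohorts of 30 patients, survival screens over 100–200
replicates of 100 features × 78 patients. Replicate-level claims (e.g.
"the planted feature is found in ≥ 80% of replicates") use enough
replicates that the observed rate concentrates near its expectation.

## Known limitations

- **Compositional bias**: CPM normalization transfers strong one-sided
  expression shifts to all other features (a global increase in one group
  deflates everything else's CPM). With 10% of features planted four-fold
  in one direction, the empirical FDR of the BH-selected set is inflated
  well above its nominal level — equally for this engine and for the
  reference implementation — which is precisely why spike-in calibrator
  normalization exists for absolute shifts. The FDR benchmark therefore
  uses sign-balanced Gaussian effects; interpret CPM-based contrasts on
  compositionally distorted data with care.
- The moderated-t machinery assumes a common variance model across
  features after the mean–variance trend; single shared NB dispersion in
  the generator makes this favourable.
- The anticorrelation filter is a sign test with no strength requirement.
- Cox fits are single-covariate by design (the screen's question is
  marginal); no Efron ties, time-dependent covariates or proportionality
  diagnostics.
- isomiRs are ordinary features; no collapsing rules are applied.
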