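---
title: "gimeth: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gimeth: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference problem

Expression–methylation correlations in observational cohorts are
directionless and confounded: methylation can silence a gene, expression
of a regulator can recruit methylation machinery to distant loci, and
cell-composition differences or shared genetics can induce correlation
with no causal link at all. `gimeth` uses genetic instruments as causal
anchors. Because genotypes are fixed at conception, an association
between a gene's *genetically predicted* expression and methylation at a
distant CpG supports the direction gene → CpG — provided the instrument
affects methylation *only through* that gene's expression. The entire
pipeline is organised around earning that proviso empirically.

## The instrument

For gene *j* with cis-window SNP dosages **D** (gene body ± 100 kb,
boundaries inclusive), the instrument is `GI_j = D β_j` with β estimated
by a two-step LASSO on a training third of the cohort:

1. LASSO over all cis SNPs with unpenalized covariates (age, sex,
   cohort, cell fractions, five expression PCs); penalty chosen to
   minimise five-fold cross-validated MSE.
2. LASSO again on only the step-1 survivors; penalty chosen by the
   one-standard-error rule — the largest penalty whose CV error is
   within one SE of the minimum — under the constraint that at least one
   SNP keeps a non-zero weight (otherwise the largest penalty retaining
   one SNP is used). The sparser model trades a little accuracy for
   fewer LD-entangled SNPs.

Validation on the held-out two thirds uses the one-degree-of-freedom
ANOVA F for the instrument's added explanatory power over covariates;
`F > 10` (the conventional weak-instrument cutoff, strict inequality) is
required. Penalized predictors are standardized internally so the
penalty is scale-free; reported weights are per dosage unit. Fold
assignment is a seeded shuffle followed by modulo, and path ties resolve
toward the sparser model, so fits are reproducible.

**Effect scale.** The scan reports φ in SD methylation per SD
expression. A raw `Dβ` instrument does not have that scale — LASSO
shrinkage makes `var(GI) < cov(expr, GI)`, which would inflate φ̂ — so
each instrument is calibrated by the slope of test-set expression on the
instrument (the two-stage-least-squares convention). In the
neighbour-conditioned model the marginal calibration is again wrong
(neighbouring instruments carry part of the shared signal), so
conditional estimates are rescaled by the *partial* slope of expression
on the instrument within the same conditioning design. In simulation
this removed a ~13 % upward bias of conditional φ̂ for regulators with a
correlated neighbour; test statistics are scale-free and unaffected.

## The trans scan and its calibration

Every valid instrument is tested against every CpG in trans — another
chromosome, or more than 10 Mb (strict) from both TSS and TES and
outside the gene body — by OLS with covariate adjustment. The scan is
computed by residualizing both sides on the covariates once, which is
algebraically identical to per-pair OLS; p-values and signed z-scores
are computed in log space so genome-wide-significant records survive
floating point.

Ensembles of millions of test statistics are rarely calibrated: cryptic
structure inflates or shifts the null. We model the z ensemble as a
three-component Gaussian mixture — a null `N(bias, inflation²)` plus a
left and right tail component — fit by EM (initialised at median/MAD
with tails at ±4; log-likelihood tolerance 1e-6; 1000 iterations max).
Two numerical safeguards matter in practice:

* tail-component means are constrained ≥ 1.5 away from the null mean,
  otherwise on a pure-null ensemble the spare components drift into the
  bulk and siphon variance;
* after convergence the null location/scale are re-estimated as
  median/MAD over points with posterior null probability > 0.5. The raw
  EM null σ is a few percent low whenever a wide null overlaps the tail
  components — harmless for rough recovery, but a 2 % scale error
  becomes a 20 % error in a 0.001 tail probability.

Non-convergence falls back to plain median/MAD with a flag. Ensembles
below 1000 records skip correction entirely (identity calibration): on
~100 z-scores the mixture is unidentifiable, and in development it
estimated inflation 0.67 on a null scan, turning p = 0.009 into
p = 4 × 10⁻⁶. The correction is fit once on the pooled scan (a per-gene
switch exists but is not the default) and is *not* re-estimated inside
cascade refits, keeping stages comparable.

Corrected statistics are `z' = (z − bias)/inflation`; the scan-wide
threshold is Bonferroni, `α / (#instruments × #probes)`.

## The specificity cascade

Directed is not specific: neighbouring genes share eQTLs and LD, so one
gene's instrument often predicts several genes' expression. Stages, in
order:

1. **Neighbour conditioning.** For each significant pair, re-fit with
   the instruments of genes whose bodies lie within 1 Mb (interval gap,
   inclusive) as covariates. Index genes whose instrument correlates
   > 0.95 with any *unpruned* neighbour are excluded outright (the
   conservative reading — exclusion is judged before pruning); the
   conditioning set itself is pruned greedily at |r| ≤ 0.95 (worst pair,
   drop the member with the larger mean |r|, ties to the earlier
   column).
2. **Residual pleiotropy.** If an index gene shares target CpGs (at the
   laxer gene-level threshold, `α / #probes`) with a neighbouring
   significant gene *and* its instrument adds `F > 5` on that
   neighbour's expression over the covariates and the neighbour's pruned
   conditioning set (index instrument excluded from that set), the index
   gene is removed.
3. **Long-range joint models.** CpGs claimed by ≥ 2 genes from one
   chromosome are re-fit with all those instruments jointly; pairs that
   lose scan-wide significance are removed.
4. **WBC variants.** Survivors are re-fit with user-supplied
   white-blood-cell-associated SNP dosages as covariates, catching
   cell-composition confounding that measured fractions missed.

"Lost significance" in stages 3–4 means the scan-wide threshold (the
stricter choice; the source procedure does not specify). Conditional
refits are run on everything eligible at the gene-level threshold so
stage 2's target sets exist; cascade flags only ever remove scan-wide
hits, preserving the monotonicity final ⊆ conditional ⊆ marginal.

## Power

For effect φ (SD methylation per SD expression), instrument R² `r2`,
and n samples, the instrument explains `r2_m = φ² · r2` of methylation
variance — the generator's convention that methylation has unit *total*
variance with the expression term included. (The alternative convention,
unit conditional noise, gives `φ²r2/(φ²r2+1)`; the two differ by < 4 %
over the grid we validate on, but only one matches the simulated world,
and agreement with simulation is the contract.) Power is the upper tail
of a non-central `F(1, n−2, ncp = n·r2_m/(1−r2_m))` beyond the central
critical value. The denominator df deliberately ignores the covariate
count — covariates reduce residual variance in practice, making the
formula slightly conservative. The corrected-analysis power substitutes
the partial R² given pruned neighbour instruments. `mc_power()` is the
independent Monte-Carlo oracle (population-scale structural equations;
an early draft standardized expression per sample inside the oracle and
systematically depressed low-power cells by ~8 % relative — the estimand
is population power at a given population correlation).

## The synthetic world

The generator emulates the statistical structure of a multi-biobank
blood cohort, not its biology:

* **Genotypes**: latent Gaussian per LD block (compound symmetry at the
  block's target correlation), thresholded at Hardy–Weinberg quantiles
  to dosages {0, 1, 2}; MAF ∈ [0.01, 0.5].
* **Expression**: unit-variance latent per gene = cis-genetic score
  (rescaled so its realized variance equals `h2_cis`; defaults span
  0.01–0.3 with a median near 0.04, matching instruments whose median
  test-set R² is ~0.04) + covariate effects + noise; a Poisson
  pseudo-count matrix (exponentiated, library-scaled) exists solely so
  the median-CPM ≥ 1 filter is exercisable.
* **Methylation**: unit-variance latent per probe = Σ φ·std(expression)
  (trans pairs only, enforced) + covariate effects + scenario terms +
  noise; trans effects of 0.25–1 SD per SD are the realistic range, with
  no distribution asserted across genes (a free parameter). Latent scale
  by default — the pipeline rank-INTs methylation regardless — with an
  optional inverse-logit beta squash for I/O realism.
* **Cell composition**: a unit-variance biological latent drives
  softmax cell fractions; the *measured* fractions derive from a noisy
  copy (reliability 0.6 by default). Ordinary covariate effects route
  through measured values (so covariate adjustment removes them
  exactly); only the confounding scenario routes through the true
  latent, which is what leaves residual confounding for the WBC filter
  to remove.
* **Scenarios**: `shared_eqtl` (a SNP carrying fraction `share` of two
  genes' cis variance; `share` ≈ the true instrument correlation),
  `direct_snp_to_cpg` (horizontal pleiotropy bypassing expression), and
  `cell_composition_confounder` (SNP → cell latent → both sides).
* Covariate effect coding: continuous covariates per SD; discrete
  covariates (sex, cohort) centred-level coded so an effect of e
  separates groups by exactly e.

Truth tables (true regulators, realized cis weights, true genetic
scores, the cell latent) ride along in a `truth` component and a
separate `truth/` directory that no pipeline stage reads.

**What a green test does not establish.** The generator has no
recombination maps, no sequence content, no array chemistry, no batch
effects beyond cohort offsets, Gaussian noise throughout, and covariate
measurement error only where a scenario injects it. Passing tests
demonstrate that the *procedure* does what it claims under its stated
assumptions — not that those assumptions hold in any particular cohort.

Degenerate corner worth knowing: with total variance fixed at 1, φ = 1
leaves a probe with zero residual noise; after rank-INT it *equals* the
regulator's expression. The false-positive battery uses φ = 1 (strong
signal, as specified); effect-recovery checks use φ = 0.75, where
recovery is non-trivial.

# Numerical and design choices

* **Coordinates**: annotations are 1-based points in memory; BED output
  converts to 0-based half-open. Window membership is closed
  ([−100 kb, +100 kb] inclusive; a SNP exactly at the boundary is in),
  trans distance and region chaining are strict.
* **PC covariates**: "five PCs" presumes genome-scale feature counts.
  `covariate_design()` allows one PC per 100 features
  (`min(k, floor(p/100))`): with tens of features a global PC *is* an
  individual gene or probe, and conditioning on it deletes the signal
  under study. At real scale the cap never binds. Scan PCs come from the
  methylation matrix by default (a config switch selects expression
  PCs); instrument PCs are learned on training samples and projected.
* **Rank-INT**: Blom offset 3/8, average ranks for ties, within cohort;
  constant-within-cohort input is an error naming the cohort.
* **PC sign**: largest-magnitude loading positive; decompositions are
  deterministic.
* **Split**: per cohort×sex stratum, seeded shuffle, `round(ratio·n)` to
  training — both sets stay balanced to within one sample per stratum.
* **Zero-cell odds ratios**: Haldane–Anscombe +0.5 for reporting; the
  p-value stays the exact conditional test.
* **GC background**: bins of width 0.05 on [0, 1]; bin drawn from the
  targets' empirical distribution, probe uniform within the universe
  bin; an empty universe bin borrows from the nearest non-empty one with
  a warning. Peak/segment overlap is 1-bp point overlap against
  half-open intervals.
* **Chromatin-state ties**: canonical Roadmap 15-state order, tie
  flagged.
* **Binomial skew test**: two-sided (exact), eligibility ≥ 10 targets,
  BH across eligible genes.
* **Determinism**: every stochastic step draws from a child seed derived
  from the master seed; identical config + cohort reproduce all outputs
  byte for byte (run logs carry seeds and the package version, no
  timestamps).

# Known limitations

* Instruments rest on the exclusion assumption; the cascade removes the
  *detectable* violations (neighbour pleiotropy, long-range LD, cell
  composition tagged by known SNPs) but cannot rule out horizontal
  pleiotropy through unmeasured paths — the `direct_snp_to_cpg` scenario
  exists precisely to show the cascade does **not** catch it when the
  pleiotropic SNP is the instrument's own.
* Heterogeneity/Egger-style pleiotropy tests are out of scope:
  instruments here rarely contain enough independent variants.
* The r > 0.95 exclusion trades recall for specificity; in worlds with
  strongly shared cis architecture roughly a third of true regulators
  are excluded rather than conditioned (their bystanders are still
  controlled).
* Cohorts are treated as unrelated individuals; no kinship/mixed models.
* The EM mixture assumes a dominant, roughly Gaussian null; ensembles
  where most tests are non-null would mis-calibrate.
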