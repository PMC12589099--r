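---
title: "Inferring protein-metabolite relationships from cohort covariation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring protein-metabolite relationships from cohort covariation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The idea

In a genetically heterogeneous cohort — diversity-outbred mice are the
motivating example — natural variation in protein abundance propagates
to the metabolites those proteins produce, consume or transport. Across
enough individuals, a functional protein-metabolite relationship leaves
a statistical fingerprint: their abundances covary. `pmcov` turns that
principle into a pipeline with five stages:

1. **Covariation architecture.** All pairwise Pearson correlations
   between proteins and metabolites within a tissue, computed on
   pairwise-complete log2 relative abundances, with Benjamini-Hochberg
   control at 5% FDR. Significant pairs are classed *co-operative*
   (r > 0) or *antagonistic* (r < 0).
2. **Knowledge recapitulation.** Measured metabolites are mapped through
   an ontology ancestor closure (conjugates, charge states, salt adducts,
   class-level ancestors below a broad-level cutoff) onto reference
   reaction, pathway and transporter edges, and the fraction of mappable
   known edges matched by significant co-operative pairs is reported,
   with a right-sided Fisher test for enrichment.
3. **Predictor nomination.** Per metabolite, a relaxed LASSO on the full
   protein matrix nominates a sparse set of protein predictors;
   post-selection OLS refits give each nominated edge a p-value, BH
   correction per tissue a global FDR; tissue-wide coefficient outliers
   beyond 3 interquartile ranges from the quartiles are flagged
   *extreme*; metabolites are scored 1-10 per tissue for validation
   priority; edges are annotated against reaction/transporter/pathway
   knowledge and, through physical interactors, against local metabolic
   networks ("May act through ...").
4. **Network statistics.** Hop-distance enrichment of top-ranked pairs in
   the combined protein-metabolite + protein-protein graph, Fisher
   accessory-member tests linking candidate proteins to established
   pathways, protein-class enrichment among metabolite correlates, and
   stratified differential analysis between extremes of a regulator's
   abundance.
5. **Evaluation.** ROC and precision-recall of pairwise and LASSO
   scorings against truth edges, and fold enrichment of significant
   nominations over random discovery.

Because the real cohort matrices and knowledge-base releases are not
shipped, a synthetic cohort generator with planted ground truth is a
first-class module: every downstream stage is validated against
constructions where the answer is known.

## The synthetic cohort generator

`simulate_cohort()` draws, per tissue, `n_latent_factors` (default 10)
standard-normal factor scores per individual — a stand-in for shared
genetic variation — and gives every protein a loading vector so that the
latent component has SD `latent_sd_protein` per protein, plus
independent Gaussian noise of SD `noise_sd_protein`. The defaults (0.5
and 0.5) give proteins a total log2-ratio SD of about 0.7 with half the
variance shared, consistent with the spread and heritability reported
for cohort-scale proteomes. Unplanted metabolites get an analogous
background with a smaller heritable share (`latent_sd_metabolite` 0.3,
`noise_sd_metabolite` 0.5), reflecting the extra layers of regulation
and measurement between enzyme abundance and metabolite pools.

Planted relationships overwrite this background:

* `planted_enzyme()` / `planted_transporter()`: the metabolite is
  `beta` times the *measured* upstream protein plus noise, so with zero
  metabolite noise the pair correlates exactly 1.
* `planted_adaptor_chain(adaptor, enzyme, metabolite, beta_a, beta_e)`:
  the enzyme's *activity* is `beta_a` times the adaptor plus noise; the
  metabolite responds to that activity; the stored enzyme column is the
  activity plus per-feature readout noise. The readout noise is the
  deliberate modelling choice here: measured enzyme abundance is an
  imperfect proxy for effective activity (post-translational control,
  the very mechanism substrate adaptors exert), which is why the adaptor
  carries predictive signal beyond the measured enzyme and can be
  nominated by the LASSO alongside it. The induced adaptor-metabolite
  association has sign `sign(beta_a) * sign(beta_e)` — the composition
  of the two steps. A degradative adaptor (`beta_a < 0`) acting through
  a producing enzyme (`beta_e > 0`) therefore yields the negative
  adaptor-metabolite edge characteristic of the substrate-adaptor
  pattern.
* `planted_null()`: the metabolite is pure noise — an explicit negative
  control pair.

Missingness is applied last, completely at random, per matrix
(default 2%, matching the high completeness of isobaric-label
proteomics); informative missingness is deliberately not modelled.
Configurations leaving any feature fewer than three observations are
rejected. One RNG stream per tissue is derived from the master seed, so
adding a tissue never perturbs an existing one, and identical
configurations are bit-identical.

`simulate_reference_knowledge()` builds matching toy knowledge: a
small ontology whose six top levels are broad (and excluded from
ancestor mapping, mirroring practice with real chemical ontologies),
per-metabolite identity chains, reaction/transporter edge tables
carrying every planted direct relationship (optionally at one or two
ancestor steps of indirection), protein-protein interaction edges
carrying each adaptor-enzyme pair — adaptors never appear in reaction
tables, reproducing the "known only through a physical interactor"
situation — plus configurable decoy edges.

What the generator does *not* emulate: batch effects, reporter-ion
compression, non-Gaussian heavy tails, informative missingness,
nonlinear or saturating dose-response, and genotype structure beyond a
generic factor model. Passing tests therefore demonstrate the
statistical machinery is correct and well-calibrated under the stated
model, not that real cohorts satisfy that model. The Gaussian log-scale
error model for metabolites is an assumption; nothing in the real
acquisition pipeline guarantees it.

## Parameters that matter

* `alpha` (0.05): FDR level for pairwise significance, applied within
  each tissue's family of all protein-metabolite pairs (a pooled family
  is available via `adjust_bh(family = "pooled")`).
* `min_obs` (20): minimum pairwise-complete samples per correlation. At
  cohort scale this keeps the t-distribution p-values stable; pairs
  below it are omitted rather than tested.
* Ontology cutoff `excluded_top_levels` (6, root = level 1): ancestors
  at or above this level are too broad to map edges through. Declared
  levels are used when present; otherwise longest-path depth from the
  roots is computed.
* `lasso_config()`: master seed 1e8; 90/10 train/validation split;
  10-fold squared-error CV; relaxed-fit mixing over gamma in
  {0, 0.25, 0.5, 0.75, 1}; unit weights. The (gamma, lambda) pair is
  chosen by minimum CV error, then the one-standard-error rule is
  applied along the chosen gamma's path — the most regularized model
  within one SE of the minimum. Predictors are standardized inside the
  solver and coefficients reported on the original log2 scale
  (`standardize_internally = FALSE` disables this); the data themselves
  are never pre-scaled. Proteins missing in more than 10% of samples
  are dropped from the design and the remainder mean-imputed, since the
  solver needs a complete design; metabolites with fewer than 30
  complete-case samples are skipped.
* Outlier fences: quartiles under the linear-interpolation convention
  (R's type 7), fences at Q1 − 3·IQR and Q3 + 3·IQR, *strictly* beyond
  flags — a value exactly on the fence does not. The convention is
  stated because outlier counts depend on it.
* Accessory-member test: parallel edges collapse to one before counting
  (a flag preserves multiplicity); the four counts partition all
  significant edges — candidate-to-pathway, pathway-touching without
  the candidate (internal pathway edges included here),
  candidate-touching without the pathway, and neither.
* Top-k ranking for hop enrichment: adjusted p ascending, ties broken
  by |r| descending, then pair IDs — deterministic by construction.
  Expected counts condition on k alone (marginal hypergeometric
  expectation), not jointly across distance strata.
* Stratified differential: top/bottom 10% by the stratifier, boundary
  ties resolved by sample order; fold changes on the linear scale
  (log2 back-transformed); Welch t-tests on log2 values; only
  enrichment, never depletion, is tested.

## Numerical and design choices

p-values are clamped to the smallest positive normal double before BH,
so exact-zero correlations of duplicated features cannot produce zero
p-values. Fisher tests report the sample odds ratio `ad/bc` with exact
hypergeometric tails (right-sided everywhere the analyses test
enrichment; a two-sided option exists). Recapitulation counts
co-operative pairs only by default — known enzyme-substrate
relationships are expected to covary positively — with
`include_antagonistic = TRUE` to widen. A metabolite whose closure
reaches several reference nodes recapitulates all of them; the
ambiguity inflates recapitulation slightly and is accepted. In the ROC
comparison, pairs a method never scores (zero LASSO coefficient) carry
the worst score rather than being dropped, so both methods are compared
on one universe. Post-selection OLS refits are per metabolite on its
selected proteins; rank-deficient designs drop aliased columns with
p = 1. The per-metabolite reading of the OLS refit is used throughout;
the transposed per-protein reading (refitting each protein on its
metabolites) is noted as an alternative but not implemented.

The validation score is `1 + 9 * evidence / max_evidence` per tissue
(so zero-evidence metabolites with predictors score exactly 1, the
best-evidenced metabolite exactly 10), summed across tissues.

## Problem sizes used in the checks

The acceptance-style tests and `scripts/acceptance.R` run at the scales
the generator defaults describe: recovery on a 163-individual,
2,000-protein cohort with 10 planted predictors per metabolite (|beta|
between 0.5 and 2, with a designated top predictor at 2 so that the
rank-1 property is well-posed — with all ten slopes drawn i.i.d. the
top two are frequently near-tied and rank 1 becomes a coin flip); null
calibration on all-null cohorts of 500 proteins; adaptor-chain
propagation on 150-individual, 120-protein cohorts in a regime where
chain and metabolite noise are small (0.15) but enzyme readout noise is
substantial (0.4) — for this pattern the adaptor's conditional signal
beyond the measured enzyme *is* the readout noise, so that is what
"high SNR" means here; and the
LASSO-vs-pairwise comparison on 150 x 100 designs with 45 decoys
tracking 5 true predictors. The test suite uses 50 metabolites and 20
seeds where rates are asserted; the acceptance script reports the same
quantities at 10 metabolites/seeds.

## Known limitations

Pairwise correlation cannot distinguish direct from confounded
relationships; the LASSO stage mitigates but does not eliminate this,
and on strongly co-regulated proteins it may select a proxy rather than
the causal protein. The 1-SE rule is conservative: weak true predictors
(|beta| near 0.5 at metabolite noise 0.5) are sometimes pruned, which
is the price of its low false-selection rate (null metabolites select
nothing in the large majority of fits). Mean imputation of sporadic
protein missingness slightly attenuates coefficients. The generator's
linearity means none of the checks exercise saturation or thresholding;
the ontology machinery assumes an acyclic parent graph and errors on
cycles rather than repairing them.
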