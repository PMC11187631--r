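---
title: "hergsuite: models, design choices and validation strategy"
author: "hergsuite authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hergsuite: models, design choices and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hergsuite)
```

## The problem

Pharmacological blockade of the hERG potassium channel prolongs the cardiac
QT interval and is a leading cause of drug withdrawal. `hergsuite` builds
quantitative structure–activity relationship (QSAR) models that predict
hERG blockade from chemical structure alone, in three complementary
framings:

* **binary** — blocker vs nonblocker, split at IC50 = 10 µM (pIC50 = 5);
* **multiclass** — strong (pIC50 ≥ 6), moderate/weak (5 ≤ pIC50 < 6),
  nonblocker (pIC50 < 5);
* **regression** — the pIC50 value itself.

All activity handling is on the pIC50 scale, pIC50 = −log10(IC50 in molar),
with a single unit-conversion point (`toMolar()`): higher values mean
exponentially greater potency.

## Curation model

Raw bioactivity tables mix qualifiers, duplicated measurements, salts and
junk. `curateDataset()` applies, in order:

1. **Structure standardization** (`normalizeStructure()`): stereo
   descriptors stripped, carbon-free counter-ions removed, remaining
   charges neutralized where a proton can be added/removed
   (charge-separated groups such as nitro or quaternary ammonium are left
   intact), canonicalization through OpenBabel. Structures with no organic
   fragment are removed as *inorganic*; two or more distinct organic
   fragments is a *mixture*. Flattening stereoisomers and then letting
   duplicate resolution merge them (rather than deleting stereo-bearing
   records outright) is a deliberate choice: it preserves the measurement
   while acknowledging the fingerprints cannot see stereochemistry.
2. **Qualifier filtering** (`applyQualifierFilter()`): a censored ">" at
   less than 10 µM says nothing about the class and is excluded; ">" at or
   above 10 µM proves inactivity; "<" at or below 10 µM proves activity;
   "<" above 10 µM is excluded. Regression keeps exact values only, since a
   censored IC50 has no usable numeric value. The `<=`/`>=` tokens are
   folded into `<`/`>`: the rules above only reason about which side of the
   boundary is proven, so the conservative superset is safe.
3. **Labeling**: the binary boundary is *IC50 ≥ 10 µM ⇒ nonblocker*
   (pIC50 ≤ 5), taking the operational phrasing of the rule; pIC50 = 5 is
   therefore a binary nonblocker but a multiclass moderate/weak — the one
   documented asymmetry between the two labelings. Records kept through a
   proven-activity qualifier are labeled by the qualifier for the binary
   task; for the multiclass task the point pIC50 decides the tier (a "<" at
   v ≤ 10 µM guarantees pIC50 ≥ 5, i.e. at least moderate/weak, but cannot
   distinguish moderate from strong — we use the censored point value and
   accept the tier may be understated).
4. **Duplicate resolution**, keyed on the standardized canonical SMILES
   (assay types are merged before deduplication, one key per structure).
   Classification groups keep one representative of a strict majority label
   and are removed wholesale on ties. Regression groups with pIC50 sample
   SD (n−1 denominator) above 0.2 are removed; surviving groups collapse to
   the arithmetic mean, which is unbiased once the SD gate has passed.
   Before removal, `experimentalMae()` records the mean absolute deviation
   of duplicates from their group mean — an estimate of the irreducible
   experimental error that gives context to regression RMSE/MAE.

Every removal is counted in a `CurationReport`; the counts plus kept
compounds always balance the input record count. The report includes a
`duplicate_merged` counter for same-outcome rows collapsed into their
representative — without it the balance could not be exact.

Threshold comparisons use a 1e−12 pIC50 guard band so that floating-point
unit conversion (10 × 1e−6 ≠ 1e−5 in binary arithmetic) can never move a
measurement across a boundary; the band is far below any meaningful
activity difference.

## Fingerprints

Hashed circular fingerprints are computed in-package on the standardized,
canonicalized structure: atom environments of radius 0..r (default 2, i.e.
ECFP-4 style diameter 4) are hashed into `nbits` buckets (default 1024).
The ECFP flavor uses atom-type invariants (element, degree, implicit H
count, formal charge, ring membership); the FCFP flavor uses simplified
pharmacophore flags (H-bond donor/acceptor, charge signs, halogen, ring).
Canonicalizing first makes fingerprints invariant to SMILES rewriting
(kekulized vs aromatic input). MACCS keys come from OpenBabel (166 defined
keys, truncated from its padded 256-bit word).

Computing the hashed fingerprints in-package rather than through a binding
buys the one thing attribution maps need: an explicit **bit → atom
environment map** (`bitAtomMap()`). Two environments may collide on one
hashed bit; both are recorded and attribution mass is split equally between
them — unbiased with respect to the collision.

Default descriptor: ECFP radius 2, 1024 bits (the configuration behind the
best binary models in this family of tools); FCFP and 2048-bit variants are
one argument away.

## Learners and validation

Five algorithm families sit behind `trainModel()`: random forest (ranger),
k-nearest neighbors (in-package, so that full class-probability matrices
and a regression variant exist behind one interface), RBF-kernel SVM
(e1071; epsilon-SVR for regression), and two gradient-boosting variants via
xgboost — `gbt_light` grows leaf-wise (histogram + lossguide, the LightGBM
growth policy) and `gbt_extreme` depth-wise. All fits are single-threaded
and seeded; bundles serialize to RDS (boosters as raw bytes) and reload
with bit-identical predictions.

Defaults worth noting: the SVM uses cost 10 and gamma 10/nbits — on sparse
binary fingerprints the conventional 1/p radius underfits badly (R² ≈ 0.17
vs ≈ 0.76 on the reference synthetic data).

Validation utilities follow standard QSAR practice:

* `stratifiedSplit()` — 80/20 stratified shuffle split, seed 42 by
  default; regression stratifies on binned responses.
* `crossValidate()` — stratified 5-fold CV; every compound appears in
  exactly one validation fold.
* `yRandomization()` — 20 rounds of response scrambling (round r uses
  seed + r, reproducible but uncorrelated), each scrambled model evaluated
  against the true labels of the untouched test split. A real model should
  sit far above the scrambled distribution, which should be
  indistinguishable from chance.
* `tuneHyperparameters()` — sequential model-based optimization: Latin
  hypercube initial design, Gaussian-process surrogate (kernlab) and
  expected-improvement proposals, full trial log returned. Search spaces
  are editable box constraints per algorithm (`defaultSearchSpace()`).
* Metrics (`evaluateClassification()`, `evaluateRegression()`) are
  implemented from the confusion-matrix / residual formulas and
  cross-checked in the test suite against brute-force oracles; multiclass
  sensitivity/specificity/precision/AUC are macro-averaged one-vs-rest
  (the most common convention; balanced accuracy is mean per-class
  recall) and MCC uses the multi-category generalization, which reduces
  to the classic binary formula.

## Applicability domain

`fitAD()` implements the distance-to-training-set domain: the cutoff is
Dc = mean + z·sd of the training compounds' leave-self-out mean
k-nearest-neighbor Euclidean distances (defaults k = 1, z = 0.5, both
exposed). A query is reliable when its mean distance to the k nearest
training fingerprints does not exceed Dc. Every prediction row carries the
flag, the raw distance and the cutoff, so users can grade reliability
themselves rather than trusting a bare boolean.

## Weighted consensus

The three tasks are combined by encoding labels as levels — nonblocker 0,
weak 1, moderate/weak 2, strong 3, binary blocker 3 — and scoring

score = 0.6·L(binary) + w_m·L(multiclass) + w_r·L(regression),

where an auxiliary weight is 0.2 if that model's blocker/nonblocker
dichotomy agrees with the binary model and 0.1 otherwise; the regression
prediction enters through the four-level mapping (strong ≥ 6, moderate
[5, 6), weak [4.5, 5), nonblocker < 4.5). A score at or above 2 is called
blocker. The exact operand encoding of the published combination rule is
not restated anywhere in text form, so this reconstruction was chosen to
reproduce the documented behaviors: unanimous agreement lands at 3.0 or 0,
the binary model alone (1.8) cannot reach the threshold, and any auxiliary
support tips a binary blocker over 2 — the documented failure mode where
the heavily weighted binary model steers the final call. Every weight, the
encoding and the threshold are config (`consensusConfig()`).
`cohensKappa()` provides the chance-corrected agreement statistic used to
justify combining the models.

## Shapley attribution and atom maps

For the gradient-boosting models, `shapAttributions()` uses the exact
tree-path algorithm (per-bit contributions on the margin scale; base +
row sum equals the margin output). Other learners get a seeded
permutation-sampling estimator against a background sample — slower and
approximate, therefore opt-in. The test suite checks tree attributions
against a brute-force Shapley oracle that enumerates all 2^6 feature
subsets with the cover-weighted tree-conditional value function evaluated
directly on the dumped tree structure.

`atomAttribution()` projects bit attributions onto atoms: each on-bit's
attribution is split equally across its (possibly colliding) environments
and, within an environment, equally across its atoms, so the atom weights
conserve the total attribution mass exactly. Positive weights push towards
blocker (rendered red by convention), negative away (green). The
alternative `method = "masking"` reports, per atom, the drop in blocker
probability when the atom's bits are cleared — the two mechanisms answer
subtly different questions (credit assignment vs counterfactual removal)
and both are provided because the fragment-map literature uses both.

## Chemical-space diagnostics

* `assayCorrelation()` — Pearson r with two-sided t-distribution p-values
  between per-assay mean pIC50 of compounds measured in two assay contexts
  (SP patch-clamp, HEK293, CHO), the check that justifies pooling assays.
* `crossSetTanimoto()` — mean pairwise Tanimoto between two sets
  (self-pairs excluded when the sets coincide), e.g. train vs test
  diversity.
* `findCliffs()` — activity cliffs: pairs at or above 80% similarity
  (MACCS by default) with opposing classes or ≥ 1 log unit potency gap
  (both gates config).
* `continuityDiscontinuity()` — raw SAR smoothness scores: per compound,
  continuity is the potency-weighted (w = pIC50_i·pIC50_j) mean reciprocal
  similarity, discontinuity the mean |ΔpIC50|·similarity over neighbors at
  or above the cutoff. Z-normalization against a reference panel is out of
  scope; raw scores are comparable within a dataset.
* `embed2D()` — a deterministic 2D embedding by classical MDS (principal
  coordinates) of 1 − Tanimoto distances, used for chemical-space
  overview plots.

## The synthetic data generator

`makeLibrary()` enumerates substituent pairs on three built-in scaffolds
(para-benzene, pyridine, anilide) and canonicalizes/deduplicates —
guaranteed-valid chemistry without a generative model. `plantActivity()`
assigns the latent activity

pIC50 = 4.5 + 1.5 × (number of set signal bits) + N(0, 0.3),

with two signal bits auto-picked at intermediate prevalence. The 4.5
intercept puts unexposed compounds below every class boundary and each
signal hit clears the strong-blocker boundary, so expected label and
curation counts are closed-form; the noise default (0.3 pIC50 units) is on
the order of the inter-laboratory spread of public hERG IC50 data. On
disjoint compound subsets it injects exact duplicates (10%), conflicting
duplicates on the other side of 10 µM (5%), censored qualifier rows
rewritten so every task must exclude them (5%) and sodium-salt forms (5%).
Every anomaly is bookkept in the table's `truth` slot, which is how the
test suite checks curation record-by-record.

What the generator deliberately does **not** emulate: real hERG
pharmacophores, scaffold diversity of public databases, correlated
assay-specific biases, or property distributions of drug-like space.
Passing tests on this fixture demonstrates the machinery is correct — the
bookkeeping, the learning of a genuine bit-level signal, the collapse
under Y-randomization — not that models trained on it transfer to real
compounds; headline metrics on public hERG extracts additionally depend on
the source data and tuned hyperparameters.

## Problem sizes and numerical choices

The test suite and the acceptance script run on 120–300-compound
fixtures with 60–100 boosting rounds — sizes chosen so the planted signal
is comfortably learnable while the whole validation cycle stays
interactive. The boundary guard band is 1e−12 pIC50 units; tree-SHAP
additivity is asserted at 1e−6 (the float32 precision of the boosting
backend); conservation and distance oracles at 1e−9. kNN ties break by
reference order, making predictions deterministic. The 2D embedding fixes
reflection signs so repeated calls are identical.

## Known limitations

* Stereochemistry is invisible to the models by design (flattened during
  curation); enantiomer-specific blockade cannot be represented.
* The FCFP pharmacophore typing is rule-based and simplified (no
  aromaticity perception beyond ring membership, no tautomer-aware
  donor/acceptor assignment).
* Exact Shapley attributions are only available for the boosting models;
  the sampling estimator's variance makes per-atom maps for SVM/kNN/RF
  qualitative.
* The consensus reconstruction reproduces the documented behaviors but
  the original operand encoding could not be verified against a printed
  formula; all parts are overridable.
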