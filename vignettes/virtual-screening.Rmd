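---
title: "Cascade ligand-based virtual screening with vscascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade ligand-based virtual screening with vscascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Given a large library of natural-product-like molecules and curated sets of
inhibitors with measured IC50 values against a target enzyme, the task is to
nominate a short, high-confidence list of library molecules likely to be
potent inhibitors — without running a single assay. `vscascade` implements
a multi-stage ("cascade") ligand-based screen for this setting:

1. **Consensus classification.** A battery of binary QSAR classifiers
   (highly vs weakly active), trained on three fingerprint representations
   with four algorithm families, must agree (by default unanimously) that a
   molecule is highly active.
2. **Averaged-regression potency cut.** Regression QSAR models predict
   pIC50; predictions are averaged in pIC50 space and only molecules with an
   implied IC50 strictly below 10 uM survive (pIC50 = 6 − log10 IC50 in uM,
   so the cut sits at pIC50 = 5).
3. **SOM HP rule.** A self-organizing map trained on the labeled inhibitors
   records, per grid cell, the proportion HP of its molecules that are
   highly active. Candidates mapping into cells with HP ≥ 0.8 survive;
   candidates landing in cells no labeled molecule occupied are reported as
   unmapped and dropped rather than silently scored 0.
4. **Aggregator filter.** Candidates matching a reference list of known
   colloidal aggregators (exact canonical-SMILES identity or MACCS Tanimoto
   at a configurable threshold, default 1.0) are removed.

Each stage short-circuits: a molecule failing stage *k* is not evaluated
further, and every input molecule appears exactly once in the audit trail.
Survivors are ranked by ascending predicted IC50.

## Data model and curation

Compound libraries enter as SMILES tables (CSV) or SD files. Curation
(`standardize_smiles`) disconnects alkali/alkaline-earth counter-ions of
simple salts, keeps the largest organic fragment (most heavy atoms; ties go
to the longer, then lexicographically smaller canonical SMILES), and reports
canonical isomeric SMILES. Charged acids and bases are recorded as-is — the
source datasets report measured species, and neutralization rules are a
modeling choice we deliberately avoid. Deduplication keys on the canonical
isomeric SMILES, so E/Z and R/S isomers are distinct molecules; whether
stereo-duplicate pairs should instead collapse is data-dependent, and the
stereo-aware key is the conservative default.

Chemistry is executed by OpenBabel (through ChemmineR/ChemmineOB and the
`obabel` CLI for batched fingerprints). Canonical SMILES are therefore
OpenBabel-canonical; all invariants the package relies on (idempotent
canonicalization, stereo awareness) are asserted in the test suite rather
than assumed.

## Featurization

Three binary fingerprints (`fingerprints`): 166-key MACCS, a 1024-bit
linear-path topological fingerprint (`path1024`, OpenBabel FP2), and
1024-bit ECFP4 (circular, radius 2; OpenBabel produces 4096 bits, folded by
OR over index mod 1024). Classification models drop the lowest-variance
quarter of bits (`variance_filter`; count = floor(d/4), ties broken toward
the lower column index for determinism).

Two open 2D descriptor sets (`descriptors`): `physchem_2d` (21 global
properties: MW, logP, TPSA, molar refractivity, H-bond counts,
element/ring/rotatable-bond counts, aromatic fraction, ...) and
`fragment_counts` (32 SMARTS-matched functional-group and ring-motif
counts). Providers are pluggable (`register_descriptor_provider`) so a 3D or
commercial set can be added without touching the modeling code. Regression
descriptors are screened by pairwise Pearson correlation (`pcc_filter`,
default |r| > 0.95; the member less correlated with the response is dropped,
greedily over pairs by descending |r|), ranked by random-forest recursive
feature elimination (`rfrfe_rank`, one feature per step), and range-scaled
to [0.1, 0.9] (`autoscale_fit`/`autoscale_apply`; constant features map to
0.5; new data are deliberately not clipped, so out-of-range test values are
visible downstream).

## Datasets and splitting

Labeling schemes are comparator/threshold pairs over IC50 in uM
(`activity_scheme`); four built-ins cover the common cases, including
gapped schemes (high < 0.1, weak > 10) whose mid-range molecules are
excluded *before* splitting. `stratified_split` sizes the test set as
round-half-up(n × fraction) — the only rule consistent with all printed
train:test pairs we reproduce (e.g. 3455 × 0.25 = 863.75 → 864) — and
allocates per-class test counts by largest remainder, so class proportions
deviate from exact proportionality by less than one molecule. Regression
responses are stratified over five response-quantile bins. `repeated_splits`
derives the i-th repeat from seed base_seed + i − 1, giving the
10-repeat protocol its determinism.

## Models and tuning

`qsar_fit` is the single fitting entry point (returns a classed object with
`print`/`summary`/`predict` methods). Grid search runs inside repeated
stratified 5-fold cross-validation; selection minimizes mean CV MSE for
regression. For classification the selection metric is not dictated by the
regression protocol, so we select by mean CV MCC — the same statistic used
to report performance. For regression with an RFE ranking, the number of
top-ranked descriptors joins the grid as a hyperparameter. Backends: e1071
(RBF-SVM; C, gamma, epsilon), randomForest (n_estimators, max_leaf_nodes),
xgboost (n_estimators, max_depth, subsample, colsample_bytree), and an
in-package multilayer perceptron (`mlp_fit`) — four ReLU hidden layers
(default widths 256/128/64/32), Adam at learning rate 1e-4, no dropout or
weight penalty by default. The MLP's epoch count is selected by early
stopping (patience 50 epochs on validation accuracy or MSE) inside repeated
5-fold CV; the final model trains on all data for the median stopped epoch.
The epoch-selection loop defaults to 5 repeats at desk scale
(`epoch_repeats = 50` restores the heavier protocol).

Default grids are configuration, not claims: published tuning ranges for
this protocol live in supplementary material we do not reproduce, so the
exposed defaults are conventional ranges, and every value can be overridden.

`qsar_stack` implements stacked generalization over the three
fingerprint-specific classifiers of one algorithm: base positive-class
probabilities feed a logistic-regression meta-learner. Meta-features are
out-of-fold probabilities by default (each base configuration is refit per
fold), because in-sample base probabilities from near-interpolating learners
would hand the meta-learner leaked labels; `oof = FALSE` restores the
literal single-pass reading. The meta-learner is an unpenalized `glm`; on
cleanly separable synthetic data it can sit at the separation boundary, so
predictions guard against degenerate coefficients by falling back to the
mean base probability (this never triggers on realistic, noisy data).

## The SOM and the HP statistic

`som_fit` trains a classic online Kohonen map: best-matching unit by
Euclidean distance (ties to the lower row-major cell index), Gaussian
neighborhood, learning rate and radius decaying exponentially from 0.5 to
0.01 and from max(width, height)/2 to 0.5. The default 10 × 11 grid follows
the usual heuristic of about 5·sqrt(n) cells at the dataset sizes the
package targets; dimensions are exposed because the right grid is
data-dependent. The map trains on the full labeled set — HP needs both
classes — with the same fingerprint kind the classification stage uses
(default ECFP4), not a separate featurization. HP ≥ 0.8 is inclusive: a
reported candidate at HP 0.82 should be kept by "over 80%", and a strict
flag exists for the other reading. Conservation (sum of per-cell highly
active counts over total equals the global active fraction) and
non-increasing quantization error are asserted as tests.

## The synthetic study

`generate_library`/`assign_activity`/`generate_benchmark` create the data
every stage is validated on: scaffold + substituent molecules whose
activity is linear in substructure indicators,
pIC50 = β0 + Σk βk·1[substructure k] + ε, ε ~ N(0, σ²) — Gaussian in pIC50,
hence log-normal in IC50, which is how potency noise behaves. Defaults
(frozen as the package's study conditions): n = 2000, β0 = 4.2, σ = 0.2,
effects +1.8 (arylsulfonamide), +1.7 (trifluoromethyl), +1.6 (carboxamide),
−1.5 (nitro), all matched as SMARTS on the realized structures so the
indicators reflect actual chemistry, not the construction recipe. The
effect patterns are detectable by all three fingerprint kinds and counted
by `fragment_counts`, so the featurization stage can in principle learn
them. No effect combination lands a deterministic pIC50 within 2.5σ of the
10 uM class boundary (nearest values 4.5 and 5.7), so labels are nearly
noiseless and "zero planted-inactive pass-through" is a fair ask.

Substituents are drawn with scaffold-dependent propensity: four of the
eight scaffolds form "active series" whose first substituent is a
pharmacophore with probability 0.9 (0.05 elsewhere). Real screening
datasets are built from congeneric series in which potency-driving groups
concentrate on a few chemotypes; without this correlation, activity does
not cluster in fingerprint space and no SOM — however well trained — can
exhibit high-HP cells, which would misrepresent the method the map is
meant to validate. What passing the synthetic study shows, and what it
does not: it demonstrates that every stage recovers a clean, strong,
fingerprint-visible signal under realistic noise; it does not show
performance on real assay data, where activity cliffs, assay
heterogeneity, and scaffold hopping violate the generator's linear model.

## Numerical choices and degenerate inputs

MCC returns 0 when any denominator factor is zero (e.g. single-class
predictions); R² is an error for constant observations rather than a
silent NaN; Tanimoto of two empty fingerprints is 0 by convention;
equidistant SOM candidates go to the lower row-major cell; grid-search ties
keep the first grid row, and RFE importance ties drop the higher column
index — every tie-break is deterministic so a seed fully fixes the
pipeline. Unparsable SMILES are rejected with reasons (`parse_error`,
`inorganic`) and counted, never dropped silently.

## Problem sizes

The shipped validation uses a 2000-molecule labeled set (80/20 split), a
400-molecule external set, and a 1000-molecule screening library, with
deliberately small tuning grids (two-point SVM and boosting grids,
single-repeat CV); the full grids and the 10 × 5-fold protocol are
available through arguments. At these sizes the complete recovery benchmark
(`run_recovery_benchmark`) — generation, featurization, six classifiers, a
stack, two regressors, an RFE ranking, a 10 × 11 SOM and the four-stage
cascade — completes in roughly two minutes on one CPU.

## Known limitations

* Canonicalization, fingerprints and descriptors are OpenBabel's; numbers
  will differ from RDKit-based implementations of the same operations
  (e.g. MACCS key definitions differ slightly between toolkits).
* The third fingerprint is a linear-path topological fingerprint, not the
  Avalon generator, which has no open implementation outside RDKit.
* No 3D descriptors ship with the package; the provider registry is the
  intended extension point.
* The aggregator filter is only as good as the supplied reference list; the
  bundled 50-molecule file is a synthetic stand-in for testing, not a
  curated aggregator database.
* Murcko scaffolds keep atoms multiply bonded to the ring-linker core
  (exocyclic carbonyls and methylenes); toolkits differ on this convention.
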