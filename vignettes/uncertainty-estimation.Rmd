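---
title: "Flagging unreliable molecular property predictions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flagging unreliable molecular property predictions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Property predictors used in mass-spectrometry workflows — retention indices
for gas chromatography, retention times for reversed-phase HPLC, collision
cross-sections for ion mobility — return point estimates. Identification
pipelines then accept or reject candidate structures by comparing predicted
and observed values against a fixed tolerance. When a molecule lies outside
the region of chemical space where the model is competent (its
*applicability domain*), the point estimate can be badly wrong while looking
exactly like every other prediction.

`molUQ` attaches to each prediction the probability that its absolute error
exceeds a threshold. This formulation — rather than predicting a standard
deviation — is deliberate. Across large prediction tables, ensemble errors
are much closer to exponential than to normal in magnitude (heavy-tailed;
sometimes close to Cauchy). A consumer who interprets a predicted sigma
through a normal lens will grossly underestimate the probability of large
errors. A calibrated "probability the error exceeds D_t" is directly usable:
flagged predictions are simply excluded from candidate scoring.

# The model

## Labels: the error threshold D_t

Given out-of-fold ensemble errors Δ_i = ŷ_i − y_i on a data set, the
threshold D_t for a *satisfied fraction* f is the empirical f-quantile of
|Δ| (linear-interpolation, type-7 quantile; the convention matters only at
the margin of one observation). A prediction is **unsatisfactory** iff
|Δ| > D_t, strictly — so with the default f = 0.85, 15% of predictions are
unsatisfactory, up to 1/n for continuous errors. `computeThreshold()` is
monotone in f and equivariant under rescaling of the errors; ties sit on
the satisfactory side.

## Features

All features are computed per molecule from (a) the ensemble predictions
and (b) a *training reference* — the molecules the base models were
trained on. Nothing about the base models themselves is needed; the
interface is a prediction table.

**Ensemble spread.** With ŷ the (optionally weighted) ensemble mean:
M_s1 = mean|p_j − ŷ| (mean absolute deviation), M_s2 = RMS deviation,
M_m = range. Jensen's inequality gives M_s1 ≤ M_s2; the RMS about the mean
never exceeds the range, so M_s1 ≤ M_s2 ≤ M_m row-wise — a property-tested
invariant.

**Similarity to the training set.** Four measures, each summarised by the
value at the most similar training molecule:

* Tanimoto similarity of circular count fingerprints (radius 3, folded to
  8192 positions). Counts are binarized here; the Tanimoto value is
  unaffected by multiplicities.
* Cosine similarity of the same fingerprints on raw counts (the additive
  fingerprint), where multiplicities do matter.
* Euclidean distance in the 20-component PCA of the scaled descriptor
  matrix (S_max,e is a minimum distance; larger means farther from the
  domain).
* Maximum-common-substructure similarity S = X/(A + B − X), X = atoms +
  bonds of the connected MCS, A and B the atoms + bonds of the two
  molecules (heavy atoms only). Matching rules: elements equal, aromatic
  atoms only match aromatic atoms, bond orders equal, ring bonds only
  match ring bonds. MCS is one to two orders of magnitude slower than the
  fingerprint measures and is off by default in the pipeline; every pair
  gets a configurable timeout (default 10 s) and a timed-out search
  returns its best-so-far value flagged as a lower bound.

**Clustering.** k-means (k = 20 by default, Euclidean metric) on the same
PC space. Features: the cluster id N_cl (one-hot encoded for the tree
model), the cluster's error statistics MAE_cl and MdAE_cl computed from
training-fold molecules only, and D_cl = D/D_mean, the molecule's distance
to its centroid normalised by the cluster's mean member distance. The
distance-quartile profile (per-cluster MAE by distance quartile) is the
diagnostic that motivates D_cl: errors typically grow from the cluster
core to its periphery.

## Meta-classifiers

The **logistic** model uses six features on their raw scales — MAE_cl,
D_cl, S_max,t, S_max,e, M_s1, and ŷ/1000 — plus an intercept, fitted by
unregularised maximum likelihood; standard errors come from the inverse
observed information. Raw scales keep coefficients interpretable and
comparable across refits. Collinear or constant columns (which arise in
degenerate inputs, e.g. a query set identical to the reference) are
dropped with a warning rather than silently producing NA coefficients.
With six parameters and thousands of rows, overfitting is negligible, so
in-sample evaluation is acceptable for the linear model.

The **gradient-boosting** model uses all features (100 trees, depth 3,
learning rate 0.1, binary-logistic objective, single-threaded for
reproducibility) and reports gain-based importances. Trees can memorize a
table, so `simulateStudy()` evaluates the boosted model with 5-fold
cross-validated predictions.

Both report a probability; the decision threshold p = 0.15 (roughly the
F1 optimum at the 15% working point) turns it into a flag. `evaluate`
counts a positive call at probability ≥ p, and precision/recall with a
zero denominator are defined as 0 with a warning.

# Data preparation

SMILES are standardized by deleting stereo descriptors (`@`, `/`, `\`) and
canonicalizing with OpenBabel, so identical structures give identical
strings and re-standardization is a fixed point. Molecules are filtered by
three rules before featurization: fewer than 10 rings
(smallest-set-of-smallest-rings count, equal to the bond-graph circuit
rank), SMILES no longer than 250 characters (applied to the input string,
since the limit guards the *source* data), and elements restricted to
B, C, N, O, F, Si, P, S, Cl, Br, I with implicit hydrogens. Duplicated
SMILES keep one record chosen uniformly under a seed. Charged or radical
species that parse and pass the element rule are kept.

Aromaticity is read from the canonical SMILES (lowercase atoms); a bond is
aromatic iff both ends are aromatic and the bond is cyclic. Ring
membership of bonds is perceived as "not a bridge". This model is
deliberately simple and is applied identically on both sides of every
comparison, which is what the similarity measures require.

The descriptor set (47 descriptors) combines OpenBabel whole-molecule
properties (MW, logP, TPSA, H-bond counts, molar refractivity),
functional-group counts, fixed-order element counts, and graph-topological
measures (ring/aromatic counts, degree statistics, Wiener index, graph
diameter). The method is descriptor-set-agnostic — what matters is a
consistent, reasonably diverse 2D descriptor space — so the set is
implementation-defined and its names are recorded in the matrix metadata.
Descriptors are min-max scaled to [0, 1] *on the training reference*;
query values are deliberately not clipped, so out-of-domain molecules keep
large, meaningful Euclidean distances. Scaler, PCA and clusters are fitted
on the training reference only, avoiding leakage from queries into the
features (this is stricter than fitting on the pooled set; a pooled fit
changes nothing qualitative but couples the feature space to the queries).

PCA retains c = min(20, d, n−1) components; component signs follow the
convention that each component's largest-magnitude loading is positive, so
repeated runs are bit-identical.

# Numerical choices

* **k-means**: Lloyd's algorithm with k-means++ seeding, best of 10
  restarts by within-cluster sum of squares, at most 300 iterations,
  terminating on a stable assignment (so centroids equal their members'
  means exactly at convergence); a 1e-6 centroid-shift tolerance bounds
  the tail of the iteration. Empty clusters are re-seeded from the point
  farthest from its centroid. The seed is exposed and recorded because
  clustering is stochastic; all statistics that depend on it
  (MAE_cl, D_mean) are tied to the recorded seed.
* **Cluster tie-breaks**: nearest centroid with ties to the lowest index.
  Clusters without training members fall back to global MAE/MdAE with a
  warning; distance-quartile profiles skip clusters with fewer than 4
  members.
* **MCS search**: exact branch-and-bound over candidate atom pairs
  (include/exclude branching), with an optimistic score bound and the
  wall-clock timeout described above.
* **Quantiles** everywhere are type-7 (R's default), documented so that
  unsatisfactory counts are reproducible to the observation.
* **Cauchy fitting** is by numeric maximum likelihood (Nelder-Mead on
  location and log-scale); exponential and normal fits are closed-form.

# The synthetic data generator

The generator exists so that every stage — standardization, filtering,
descriptors, fingerprints, PCA, clustering, similarity, spread, labels,
meta-models — runs and is tested end to end without any external data.

`generateMoleculeLibrary()` enumerates a few thousand small molecules
(linear/branched alkanes; alcohols, amines, ethers, halides, nitriles,
acids, aldehydes; substituted benzenes, pyridines, furans, thiophenes,
cycloalkanes) and samples a seeded subset. `simulateTrueProperty()`
produces a retention-index-like surrogate: 100 + 20·(heavy atoms) +
35·(heteroatoms) + N(0, 15) noise — positive values with the size-driven
trend real retention properties show.

`simulateEnsemble()` draws, per molecule, a latent difficulty u (uniform,
or supplied), sets the error scale s = s0·exp(γu), and adds to the true
value a shared bias (one draw per molecule, magnitude scale κ·s, identical
across members — the correlated component that bootstrapped or same-family
models exhibit) plus independent per-model noise (scale (1−κ)·s). The
default tail is Laplace, so |Δ| is exponential — matching the observed
error shape; a normal tail is available for contrast (under normal tails
with flat difficulty, spread and error are independent and the spread
feature is powerless — a property test). Defaults, fixed once as the study
conditions: m = 5 models, s0 = 15, γ = 2, κ = 0.5.

`simulateStudy()` couples difficulty to chemistry: u is the rank of a
complexity score (size, heteroatoms, rings), and the training reference is
drawn with weight exp(−3u) — a roughly 20:1 gradient from the easiest to
the hardest molecules. The bias reflects how real training sets are
composed (common chemistry is densely covered, rare polyfunctional
scaffolds are sparse) and is what makes the cluster and distance features
genuinely informative about difficulty. The default study uses a
2000-molecule library split 65/35 into reference and query; that size
keeps a full run around a minute while leaving AUC estimates stable to a
few hundredths.

**What passing tests do and do not show.** The generator reproduces the
*statistical* structure the method assumes — exponential-tailed,
difficulty-driven errors; correlated ensemble members; difficulty coupled
to chemical-space position. It does not mimic real RI/RT/CCS value
distributions, and its combinatorial library is far more homologous than
NIST-scale chemistry: nearest-neighbour fingerprint similarities stay high
even for "hard" molecules, so the similarity features carry weaker signal
here (AUC ≈ 0.5–0.6) than on real data, while spread (≈ 0.66–0.75),
cluster statistics and the combined models land in realistic ranges.
Passing the suite demonstrates correctness of the machinery and the
qualitative predictor ordering (combined ≥ best single; spread ≫ centroid
distance), not field performance on laboratory data.

# Design decisions that were genuinely open

* **Fold construction** is molecule-level: all records of one canonical
  SMILES share a fold, so a molecule is never predicted by a model that
  saw it in training. The out-of-fold table is built first; the reference
  side of each fold's features is fitted on the other folds only.
* **Cluster error statistics from training folds**: computing MAE_cl on
  queries would leak the labels into the features.
* **Length filter on the input SMILES** rather than the canonical form:
  the rule exists to bound the source data; canonicalization can change
  lengths either way.
* **Intercept in the logistic model**: fitted and reported separately; a
  no-intercept fit would silently fold the base rate into the features.
* **Fixed gradient boosting instead of an AutoML search**: boosted trees
  are what such searches select for this problem class; fixing them keeps
  runs deterministic and dependencies minimal.
* **MCS off by default**: it is the weakest and slowest similarity
  measure; it stays available (with timeouts) for tasks where the
  fingerprint measures saturate.
* **Ensemble weights equal by default**; a weighted mean is supported for
  ensembles calibrated elsewhere.

# Known limitations

* The MCS search is exponential in the worst case; the timeout converts
  that into a flagged lower bound rather than a hang, but near-timeout
  values are not exact.
* The aromaticity model (lowercase canonical SMILES + cyclic bonds) does
  not attempt Hückel perception; exotic aromatic systems may be treated
  as aliphatic. Both sides of any comparison use the same model.
* Cluster statistics assume the training reference carries its own
  out-of-fold predictions; a bare SMILES reference (supported in the CLI)
  borrows error statistics from overlapping table rows.
* Probability calibration is not addressed: the meta-model probability is
  used at a fixed decision threshold, and conformal-style guarantees are
  out of scope.
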