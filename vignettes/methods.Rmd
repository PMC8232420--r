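---
title: "Methods: AMW-based DILI screening, the CART learner, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AMW-based DILI screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diliamw)
```

## The screening model

The package discriminates drugs with liver-injury liability (DILI) from
safe drugs using constitutional descriptors. The central statistic is the
average molecular weight,

$$\mathrm{AMW} = \frac{\sum_e n_e m_e}{\sum_e n_e},$$

the molecular weight divided by the total atom count, hydrogens included
in both numerator and denominator. AMW is intensive (multiplying a
formula does not change it) and rises with halogen and heteroatom
content. The screening rule is a two-node decision stump read off a CART
tree fitted to a 432:220 DILI/no-DILI cohort:

* AMW ≥ 7.4 → DILI-positive (the boundary value itself is positive:
  routing is "< left, ≥ right" throughout the package);
* AMW < 7.4 and MLOGP < −0.454 → DILI-negative;
* AMW < 7.4 otherwise → indeterminate, which a strict two-class mode
  maps to negative (this is exactly AMW-alone screening).

`rule_classifier()` implements the rule; `grow_tree()` can re-derive it
from data.

## Chemistry conventions

**Atomic masses.** IUPAC conventional (abridged 2021) standard atomic
weights, ≥ 4 decimals, in a user-overridable table (`atomic_masses()`).
The original AMW values came from proprietary software whose mass table
is unspecified; molecules near the 7.4 boundary can flip under a
different convention, so the table is explicit and swappable, and exact
per-drug agreement with the source study cannot be guaranteed.

**SMILES scope.** Organic subset plus bracket atoms; aromaticity is read
from lowercase symbols, never perceived; stereo markers are accepted and
ignored (composition-level descriptors do not depend on them); anything
else fails loudly rather than risk a silent wrong atom count. Implicit
hydrogens follow default valences (B 3, C 4, N 3/5, O 2, P 3/5,
S 2/4/6, halogens 1); aromatic atoms spend one valence on the ring π
system and never promote to a higher valence state (so an N-methylated
aromatic nitrogen correctly carries no hydrogen). Bracket atoms carry
only the hydrogens written in the bracket, which is where formal charge
enters.

**Standardization.** Desalting removes components whose Hill formula
(with charge) is on an explicit, versioned salt list seeded with common
pharmaceutical counterions (halides, alkali/alkaline-earth cations,
ammonium, sulfate, nitrate, phosphate, common sulfonates and
carboxylate counterions, water). Composition-level matching means
maleate and fumarate are deliberately not distinguished. Neutralization
protonates anionic O/N/S and deprotonates protonated amines; quaternary
ammonium cannot be neutralized and is left charged with a log entry. If
several non-salt components remain, the largest by heavy-atom count is
kept and the choice logged. The operation is idempotent. Peptide and
nucleic-acid exclusion is annotation-driven (input flags) because no
structural criterion is defined; the metal rule is structural: any
element outside {H, B, C, N, O, F, Si, P, S, Cl, Br, I} after
standardization excludes the drug.

**Moriguchi logP.** The 13-parameter regression is implemented with its
published coefficients; the intercept is taken as −1.014 (some secondary
sources print −1.041). Pattern-valued parameters that the original
leaves to chemical judgement use documented conservative heuristics: the
intramolecular hydrogen-bond flag fires only for donor/acceptor
substituents on adjacent aromatic atoms; aromatic polar substituents are
counted as substituent first-atoms that are heteroatoms/halogens or
carbonyl/nitrile carbons; N–O adjacency contributes to the proximity
parameter even inside nitro groups (this combination reproduces
experimental values for nitroarenes), while the nitro nitrogen is
excluded from the quaternary-N penalty. The pipeline treats MLOGP as an
opaque numeric feature everywhere, and a precomputed column always takes
precedence — the calculator is a convenience, not a dependency of the
screening rule.

## The CART learner

Binary classification trees with Gini impurity
$G = 1 - p_+^2 - p_-^2$, built from scratch so every semantic is pinned:

* **Splits** are midpoints between consecutive distinct sorted values;
  quality is the count-weighted decrease
  $nG - n_LG_L - n_RG_R$.
* **Tie-breaking**: lowest feature index, then smallest threshold —
  chosen for determinism (the source names the CART package it used but
  not its tie behaviour). Sample order never affects the fitted tree.
* **Stopping**: `max_depth`; `min_split` 20; `min_leaf` 7; and a split
  must achieve at least `cp * n * G_root` decrease (`cp` 0.01) — the
  defaults of the conventional CART implementation the analysis cites,
  all overridable.
* **Imbalance**: no class weighting; the source's low specificity "as
  expected from the imbalanced dataset" implies unweighted fitting. Leaf
  ties predict the positive (DILI) class.
* **Missing values** are rejected at fit time; surrogate-split behaviour
  would be unverifiable.
* **Importance** is Mean Decrease in Gini: per-feature sums of
  count-weighted decreases, normalized by the training-set size; unused
  features are exactly 0 and the total equals the tree's normalized
  impurity reduction.
* **Depth selection** uses stratified k-fold CV maximizing balanced
  accuracy (the score the analysis reports throughout; plain accuracy is
  available), ties to the smallest depth.

Model selection and validation follow the published protocol: a
stratified 3-group split, trees trained on each pair of groups with
depth chosen by inner 5-fold CV, evaluated on the held-out group, all
repeated 10 times (`nested_cv()`); and a final model fitted on the whole
cohort with 5-fold depth selection (`final_model()`), whose
resubstitution metrics and CV scores are reported separately and labeled
— the source is ambiguous about which of the two its headline accuracy
is (its own printed confusion matrix gives 514/652 = 0.788, which rounds
to 0.79 against a printed 0.78; the discrepancy is documented, not
reconciled). One master seed drives a hash chain of per-repeat/per-fold
sub-seeds (`derive_seed()`), so any single run is re-derivable. It is
assumed the 10 repetitions re-randomize the outer split each time.

## Metrics

Positive class = DILI everywhere. Accuracy, sensitivity, specificity,
balanced accuracy $(= (se + sp)/2)$ and MCC follow their standard
definitions; any metric with a zero denominator is reported as
*undefined* (`NA`), never coerced to 0 — small ATC categories make this
reachable. Printed values round half away from zero to 2 decimals; full
precision is retained internally. ROC curves treat higher AMW as more
DILI-like, consistent with the ≥ 7.4 rule; AUC is the trapezoid area and
equals pairwise concordance with ties counted ½. ATC-stratified reports
count a multi-code drug once per code and pool every (drug, code)
evaluation into the Total row; drugs without codes are tallied
separately (the published Total row shows such drugs were dropped from
stratification).

## Descriptor-space hygiene

`near_zero_variance_filter()` uses the conventional defaults of the
filter function the analysis names: drop constants, and columns with
most-frequent/second-most-frequent ratio > 19 **and** < 10% distinct
values. `linear_combination_filter()` removes, scanning left to right,
columns that are exact linear combinations (relative tolerance 1e-8) of
columns already kept, leaving a full-rank matrix. PCA is mean-centered
without variance scaling (the default of the function the analysis
names; a scaling flag is provided), computed by SVD, with each
component's sign fixed so its largest-magnitude loading is positive.
Both filters are idempotent. The original chemical-space comparison used
12,262 downloaded reference compounds; that retrieval is out of scope
and the module works on any numeric matrix.

## The synthetic cohort: what it is and is not

Real inputs (structures of the 652 drugs, 2,473 proprietary
descriptors, ATC assignments) are not redistributable, so the generator
emits cohorts with the *statistical structure the analysis assumes*:

* class sizes 432:220; Most fraction 175/432;
* class-conditional AMW from a **shifted log-normal** (shift 6.0) whose
  (meanlog, sdlog) are solved in closed form from the class means
  7.99/7.49 **and** the threshold-7.4 operating point 64%/71%. A
  symmetric distribution cannot put the no-DILI mean at 7.49 with 71% of
  mass below 7.4; the math forces sdlog > 1.107 for that class, i.e. a
  heavy right tail. This calibration is computed once from the stated
  numbers and frozen — it is the stated world, not a tuning dial. The
  shift 6.0 was chosen as a plausible floor for drug-like molecules;
  real drugs extend lower (valproate is ~5.5), which the model does not
  reproduce;
* Most/Less subclasses shift the DILI log-mean by ±δ with the Less shift
  solved to preserve the overall class mean (default Most +0.10), giving
  the Most class the higher above-threshold odds ratio seen in the
  published contingency table;
* an MLOGP-like feature is class-conditionally normal (DILI 2.5 ± 1.5,
  no-DILI 0.5 ± 1.8 — lipophilicity higher for DILI drugs, consistent
  with the known logP association); it is *not* calibrated to the
  97%-purity second node, which the package reproduces only from the
  printed counts;
* noise features are independent standard normals (optionally
  equicorrelated);
* ATC codes are assigned by sampling category weights that depend on
  whether the AMW screen classifies the drug correctly (affinity 2 for
  the easy strata emulating B/J/M/S, 0.7 for the hard strata emulating
  C/G/R/V). Conditioning on correctness leaves the marginal AMW
  distributions untouched while producing per-category accuracies near
  0.85–0.9 and 0.5, the magnitudes of the published stratification.

Ground truth is emitted with every cohort, including the Bayes boundary
(lower crossing of the prior-weighted class densities, ≈ 6.66 at
defaults) and the population-optimal single Gini split (≈ 6.63) —
within 0.04 of each other in the calibrated world, which is what makes
root-threshold recovery a meaningful test. A green recovery test
establishes that the learner finds the generating boundary in *this*
world; it says nothing about real drugs, whose AMW distributions,
tails, and descriptor correlations are unpublished.

## Numerical choices

* Split-quality comparisons use exact count arithmetic
  $(p^2 + q^2)/n$ sums; implementation and test oracle share only this
  formula and the documented tie rule, not search code.
* Tree JSON serialization writes 17 significant digits, which
  round-trips doubles exactly.
* Quartiles use linear interpolation (type 7); box-plot fences are
  1.5 × IQR.
* `stratified_split()` deals shuffled class members round-robin, so
  group class proportions match the cohort's within one sample.
* RNG is isolated: generators save and restore the global seed state,
  and every protocol sub-seed is derived below 2³¹.

## Known limitations

* The deeper printed tree nodes (PCR, VE2sign_Dz(p), C-001, MATS5m) and
  the published importance magnitudes require the proprietary
  descriptor matrix and are out of scope; only the AMW/MLOGP rule is
  reproduced.
* MLOGP from structure is a best-effort implementation of a regression
  whose pattern definitions are partly judgement calls; supply a
  precomputed column for production use.
* The SMILES parser does not kekulize, perceive aromaticity, or handle
  tautomers/stereochemistry; it targets pharmaceutical organic-subset
  input and fails loudly elsewhere.
* Synthetic ATC strata model assignment bias only; real strata differ
  in chemistry, not just in screen correctness.
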