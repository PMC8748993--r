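---
title: "Detecting and predicting short hydrogen bonds in proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and predicting short hydrogen bonds in proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short hydrogen bonds (SHBs) are contacts in which the donor and
acceptor heteroatoms sit within 2.7 Å of each other — well inside the
sum of their van der Waals radii and distinctly shorter than the
2.8–3.2 Å of a normal hydrogen bond (NHB).  At these separations the
bond acquires pronounced covalent and quantum character (shared
protons, low proton-transfer barriers in the low-barrier subclass),
and SHBs are repeatedly implicated in enzyme catalysis, signaling and
protein stability.  Resolving them experimentally requires atomic
resolution (≲ 1.1 Å), which most deposited structures do not reach:
the coordinate error of a 2 Å structure is comparable to the 0.5 Å
that separates the two bond classes.

`shbpred` addresses this with a two-part pipeline:

1. **Geometric survey.** In a high-resolution structure, enumerate
   side-chain donors and N/O acceptors, measure every donor–acceptor
   contact, and label it SHB / NHB / unlabeled from explicit distance
   and angle windows.
2. **Classifier.** From labeled surveys, train an ensemble of
   gradient-boosted decision trees on 21 *categorical* features of
   each bond — deliberately excluding the geometry itself — so that
   the class of a hydrogen bond can be predicted for structures whose
   geometry is not trustworthy.

## Geometric criteria

A pair donor–H···acceptor is labeled from the heavy-atom separation
$R$ and the angle at the hydrogen:

* SHB: $2.3 \le R \le 2.7$ Å and angle $\ge 135^\circ$;
* NHB: $2.8 \le R \le 3.2$ Å and angle $\ge 135^\circ$;
* anything else, including the deliberate 2.7–2.8 Å buffer, is
  *unlabeled* — reported, but excluded from training and evaluation so
  the two classes stay geometrically separated.

All window boundaries are inclusive.  Donors are side-chain N/O atoms
only (Ser OG, Thr OG1, Tyr OH, Trp NE1, His ND1/NE2 when protonated,
Lys NZ, Arg NE/NH1/NH2, Asn ND2, Gln NE2); backbone amides, sulfur and
carbon donors are excluded.  Acceptors are every backbone carbonyl
oxygen plus the side-chain O/N acceptor set, with His ring nitrogens
accepting only when unprotonated.  When a donor carries several
hydrogens, the hydrogen maximizing the angle defines the recorded
geometry, and records are kept at atom-pair granularity, so a
bidentate arrangement (e.g. an Arg–Asp pair) legitimately contributes
two records.  Same-residue pairs are excluded as artifacts; adjacent
residues are allowed.  Detection uses a 3.2 Å spatial grid whose
record set is, by construction and by test, identical to the
brute-force all-pairs scan.

## Structure preparation

* **Reading.** PDB dialect only, first MODEL, highest-occupancy
  alternate location (ties resolved toward altLoc `A`), crystallographic
  waters removed, ligand HETATM records kept aside from the residue
  chains.  Resolution, R-factor and R-free are read from REMARK 2/3;
  the quality filter passes a structure with resolution ≤ 1.1 Å,
  R-factor ≤ 0.20 and R-free − R-factor ≤ 0.07, reporting missing
  fields as warnings rather than failures because minimized or edited
  files frequently lack header records.  A permissive mode relaxes the
  R-factor ceiling to 0.28 for the tail of otherwise acceptable
  refinements.
* **Hydrogen placement** is geometric and idealized: O–H 0.96 Å, N–H
  1.01 Å, sp² N–H in the plane of the attached group, Lys NZ
  tetrahedral.  Rotatable hydroxyls (Ser/Thr/Tyr) are oriented by a
  10° torsion scan choosing the orientation that maximizes the best
  donor–H–acceptor angle to any N/O atom within 3.5 Å.  That scan
  *biases borderline contacts toward acceptance* — it points the proton
  at the nearest acceptor — so the pipeline treats placement as
  opt-in (`place_h = FALSE` by default) and expects experimentally or
  force-field protonated inputs when available.  Existing hydrogens
  are never moved, and heavy atoms are never altered.  His tautomer
  defaults to NE2-protonated, the common convention when no hydrogen
  is observed.
* **Secondary structure** uses the Kabsch–Sander electrostatic model:
  $E = 0.084\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})\cdot 332$
  kcal/mol, a backbone hydrogen bond when $E < -0.5$, with the amide
  hydrogen idealized along the preceding C=O direction when absent.
  The 8-letter alphabet is collapsed to 4 classes — helix (3₁₀/α/π
  turn patterns), sheet (bridges), turn (isolated turns), coil
  (default) — because the classifier uses secondary structure only as
  a coarse, low-importance feature.  Assignment is total: every
  standard residue receives exactly one label.

## The 21 features

Donor and acceptor residue identity; donor and acceptor heteroatom
element (N/O); donor and acceptor group formal charge at pH-7
conventions (carboxylates −1, Arg/Lys +1, otherwise 0 — the package
applies fixed conventions rather than a protonation model); acceptor
location (backbone / side chain; donors are side-chain by
construction); donor and acceptor secondary structure; and the residue
identities at offsets −3…−1, +1…+3 around the donor and around the
acceptor in their own chains.  Context is indexed by the chain's
serial position rather than author numbering, so numbering gaps and
insertion codes cannot shift the window; positions beyond a terminus
give the distinct token `TER`, and non-standard residues `UNK`.
Donor element is retained even though it is a deterministic function
of the donor residue, for fidelity to the printed feature inventory.
$R$ and the angle are *not* features: they define the label, and the
model must predict shortness without seeing them.

Encoding is one-hot against fixed, closed vocabularies (326 indicator
columns), with the encoding map persisted alongside the model so that
split-gain importances can be aggregated back to the 21 parent
features and unseen values at prediction time fall back to `UNK` with
a warning.

## The classifier

Labeled surveys are strongly imbalanced (≈ 18.7% SHB), so the model
uses undersampling: each of 10 ensemble members trains on all SHBs
plus an equal-size random subset of NHBs, and the final probability is
the unweighted mean of the member probabilities.  Each member is a
stagewise boosted ensemble of regression trees fit to the gradient of
the binomial deviance, with shrinkage 0.01, 5000 trees, bag fraction
0.5, and the interaction depth tuned over 1–15 by stratified 10-fold
cross-validation minimizing the mean held-out binomial deviance (ties
to the smaller depth).  The "validation error" is interpreted as the
binomial deviance — the loss being boosted; misclassification rate is
available as a configuration alternative.  Boosting is delegated to
xgboost (`binary:logistic`, `eta` = shrinkage, `max_depth` =
interaction depth, `subsample` = bag fraction, single thread), which
satisfies the stagewise-gradient contract and exposes the per-feature
split-gain (Gain) importances the analysis needs.  One nuance of the
delegation: `max_depth` counts tree levels where some boosting
implementations count total splits; at the depths that matter here
(1–3) both admit the same interaction orders.

Member seeds are `base seed + member index` and are recorded in the
model manifest, so all 10 undersamples are reproducible.  Probabilities
are calibrated to the balanced 50/50 prior by construction; an
optional correction to a population prevalence
($p' = p\pi/(p\pi + (1-p)(1-\pi))$) is provided but off by default,
because the recommended operating thresholds are defined on
uncorrected outputs.

A hydrogen bond is called SHB when its probability is **greater than
or equal to** the threshold.  The default threshold is 0.870, the
recommended operating point; `threshold_table()` reports precision
(TP/(TP+FP), `NA` when nothing is predicted positive) and recall
(TP/(TP+FN)) over a grid spanning precision-oriented (0.996) to
recall-oriented (0.062) choices, and
`find_threshold_for_precision()` inverts the table.

### Profiles and problem sizes

Two parameter profiles are built in.  The **paper profile** (5000
trees, depths 1–15, 10-fold CV) reproduces the full training protocol
and is intended for real surveys.  The **fast profile** (500 trees,
depths 1–6, 5-fold CV, same shrinkage and bag fraction) keeps the same
learning dynamics at desk scale and is the package default; the test
suite runs the fast profile on tables of 800–5000 rows, and its
parameter-recovery checks use n = 5000 with a 10-member ensemble.
These sizes were chosen so a full suite run completes on one CPU in a
few minutes while leaving the stochastic tolerances comfortably
satisfiable.

## The synthetic generator

`generate_feature_table()` emulates the statistical structure the
classifier assumes, not real proteins.  Each row samples a donor, an
acceptor (side-chain, or backbone with probability 0.35), secondary
structures and context residues; its SHB probability is

$$\mathrm{logit}^{-1}\big(\mathrm{logit}(p_{\mathrm{donor}}) +
\delta\,\mathbb{1}[\text{acceptor is side-chain Asp/Glu}]\big),$$

overridden by the motif probability for Ser/Thr–Xxx–Asp arrangements
(donor and acceptor two sequence positions apart, reflected in the
context window).  Defaults: per-donor probabilities Tyr 0.86, Ser
0.53, Thr 0.40, His 0.29, and ≤ 0.15 for the N-donor group (Arg, Lys
0.10; Asn, Gln 0.12; Trp 0.14, chosen inside the reported "below 15%"
band); shift δ = 1.92, the logit difference between a Thr donor's
0.738 (carboxylate acceptor) and 0.292 (neutral acceptor); motif
override 0.825.  The interaction structure is deliberately minimal —
one acceptor shift and one motif override — which is exactly enough to
exercise depth tuning (the shift is additive on the logit scale, so
stumps could represent it asymptotically, but at 500 trees the
cross-validated deviance measurably favors depth ≥ 2) and importance
ranking.

Balanced tables are produced by rejection-sampling drawn rows to a
50/50 class marginal.  Rebalancing by label re-weights the
*conditional* probabilities by Bayes' rule, so for calibration
experiments that compare predicted probabilities against the
generating table the donor mix is chosen to make the natural marginal
≈ 0.5 (e.g. Tyr 0.27, Ser 0.25, Thr 0.20, His 0.14, Arg 0.14 with the
table above gives 0.499), leaving conditionals essentially
undistorted.  What passing these tests shows is parameter recovery
under the model's own assumptions — independent rows, clean
categorical signals; it does not establish performance on real
structures, whose features are correlated through packing, chains and
crystal contacts.

`simulate_toy_structure()` plants a single hydrogen bond at an exact
(R, angle): an extended host peptide (φ = ψ = 180°, hence planar and
free of internal backbone hydrogen bonds) carries the donor residue
with its side-chain donor atom extended perpendicular to the backbone
plane, and a free acceptor fragment with idealized internal geometry
approaches from the far side.  The perpendicular arrangement
guarantees no unintended atom pair falls inside the 3.2 Å cutoff, so
detection must recover exactly the planted record — the package's
sharpest end-to-end oracle (|ΔR| ≤ 0.01 Å, |Δangle| ≤ 0.5° after a
PDB write/read round trip).  Donor side chains are represented by
anchor + donor atom + hydrogen rather than full rotamers; that is
sufficient because detection and featurization address atoms by name.

## Numerical and design choices

* Undersampling draws NHB row indices without replacement under a
  per-member seed; sampled indices are sorted so row order is
  deterministic.
* CV folds are stratified by label; a degenerate fold triggers a
  logged re-draw with an incremented seed.
* Binomial deviance clamps probabilities at $10^{-12}$.
* Depth ties break to the smaller depth; the CV table reports
  per-depth standard errors so "within one SE" comparisons are
  possible.
* Bifurcated bonds (one hydrogen reaching two acceptors) are kept as
  separate records; no deduplication is attempted.
* `split_by_name()` implements the stated uniqueness rule only — one
  representative per normalized molecule name into the training pool,
  the remainder into the test pool — and is deterministic.
* Zero labeled records yield an `NA` SHB fraction, never 0.

## Known limitations

* No force-field minimization or pKa prediction; group charges are
  fixed pH-7 conventions, and the His tautomer is a convention, not an
  inference.
* PDB only (no mmCIF); protein–protein bonds only (no ligand or water
  partners, no S/C-mediated bonds, no backbone donors).
* The hydroxyl torsion scan biases borderline geometries toward
  detection, which is why it is opt-in.
* Reported headline performance of this class of model (precision ≈
  80% at recall ≈ 75% at threshold 0.870 on a held-out survey of 1260
  structures) depends on a bulk PDB-derived dataset; the package's own
  tests establish the arithmetic, geometric and statistical properties
  above on synthetic data, not those survey-level numbers.
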