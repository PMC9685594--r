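---
title: "Methods: predicting FAIMS compensation voltages from peptide sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting FAIMS compensation voltages from peptide sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faimscv)
```

## Overview

FAIMS transmits a peptide ion efficiently only in a narrow compensation
voltage (CV) window, so targeted acquisitions need a per-peptide CV. This
package models the CV of maximum transmission as a function of sequence and
charge, in three layers: descriptors, profile statistics, and regression
models embedded in a two-stage pilot/refine workflow. This vignette explains
each layer's assumptions, the tunable parameters, the numerical choices, and
what the synthetic benchmark can and cannot establish.

## Descriptors

Each peptide ion (bare canonical sequence + observed charge 1–8) maps to a
76-value descriptor vector under the default feature registry:

* **charge** (1): used as a single numeric feature, not one-hot, so its
  influence is summarized by one standardized coefficient.
* **composition** (18): counts and mole percents for nine overlapping
  residue classes (Tiny, Small, Aliphatic, Aromatic, NonPolar, Polar,
  Charged, Basic, Acidic). Classes overlap by definition, so counts do not
  partition the sequence.
* **physicochemical** (7): average molecular weight (Da), isoelectric point,
  net charge at pH 7, mean Kyte–Doolittle hydropathy, Ikai aliphatic index,
  Guruprasad instability index, and Boman protein-interaction index, all
  from pinned published per-residue tables as tabulated in this package.
* **QSAR means** (50): the arithmetic mean over the sequence of each
  component of eight residue-scale families — Cruciani (3), MS-WHIM (3),
  z-scales (5), T-scales (5), ProtFP (8), ST-scales (8), VHSE (8) and
  BLOSUM indices (10).

Ten families are shipped (the above plus FASGAI, 6, and Kidera factors, 10,
66 components in all); the default selection is the unique natural subset of
the standard families whose component counts sum to exactly 50, giving the
canonical 1 + 18 + 7 + 50 = 76 layout. Any selection can be pinned through
`feature_registry(qsar_families = ...)` and serialized with
`write_registry()`, so a model bundle always knows exactly which features it
was trained on.

Modification annotations (MaxQuant underscore/bracket syntax) are stripped
before featurization: the residue tables cover canonical residues only, and
profile identities collapse modified forms onto (stripped sequence, charge)
for the same reason. Descriptors are emitted raw; standardization is a model
concern so that a model bundle can be applied to new data with its stored
training statistics.

### Numerical choices

* The isoelectric point is found by bisection on the Henderson–Hasselbalch
  net-charge function over pH 0–14 (60 iterations, interval tolerance
  1e−8); the net charge at the returned pI is zero to well within 1e−4
  charge units. The pKa set defaults to the EMBOSS values with a
  Lehninger-style alternative; the set name is recorded in the registry
  because switching sets shifts the pI/charge features.
* Sequences of length 1 have no residue pairs, so the instability index is
  defined as 0 there, with a warning.
* No published Boman value exists for proline; 0 is used by convention.
* Descriptor molecular weight uses average masses (the physicochemical
  convention); PRM precursor m/z uses monoisotopic masses (the MS
  convention). Both tables are pinned package data.

## Profile statistics

A CV profile maps grid CVs to strictly positive intensities; absence means
no detection. CVs are compared after rounding to 0.1 V, the settable
resolution of the instrument. Observations of the same (ion, CV) from
multiple runs are summed before profile construction, mirroring label-free
intensity aggregation.

The training target of choice is the **intensity-weighted average CV** over
all detected bins. Because acquisition grids are coarse (3–5 V), the
weighted mean recovers sub-grid information about the true optimum that the
argmax (peak CV) discards; both targets are available in
`make_training_table()`. The weighted mean is computed over the whole
profile rather than a peak sub-region: FAIMS transmission profiles are
unimodal to good approximation, and no principled peak-region rule exists
for 3–11 point profiles.

`peak_cv()` must break intensity ties; ties are resolved toward the
weighted-average CV (the best available estimate of the optimum) and any
residual exact tie toward the more negative CV, so the statistic is
deterministic.

## Regression models

* **Lasso** (`fit_lasso`): L1-penalized least squares on features
  standardized by training mean/SD (zero-variance features map to zero and
  keep coefficient 0). The penalty is either fixed or chosen by 5-fold
  cross-validated MAE at the plain minimum — the one-standard-error rule is
  off because the goal here is predictive calibration, not maximal sparsity.
  Coefficients are reported on the standardized scale so that "volts per SD
  of feature" is comparable across features.
* **Stacked ensemble** (`fit_stacked_ensemble`): three pinned base learners
  — gradient-boosted trees (150 rounds, learning rate 0.08, depth 4,
  row/column subsampling 0.8), a 300-tree random forest, and an L1 linear
  model — fitted per fold of a seed-controlled 5-fold split; the
  meta-learner is a linear blend with free intercept and non-negative
  weights fitted on the out-of-fold base predictions (solved exactly as
  non-negative least squares on centered designs). Non-negativity keeps the
  blend interpretable and prevents the meta-learner from amplifying
  anti-correlated noise. Everything (folds, tree seeds, fold seeds) derives
  from one integer seed, and the model bundle records it: identical seed and
  table give bit-identical predictions. A constant training target is
  handled as a degenerate case (the L1 path is undefined there) by an exact
  constant model.
* **Evaluation**: MAE and R² (computed against the evaluation set's own
  mean), plus accumulation curves of absolute error grouped by snapping
  targets to the acquisition grid — the standard way to see whether errors
  concentrate in particular CV regions.

## Two-stage workflow

Stage 1 predicts from the 76 descriptors alone. The pilot plan is the
prediction and ±5 V, rounded to 0.1 V, unclamped (out-of-range plans warn
rather than silently move — an instrument operator should see them). The
empirical constraint is the most intense pilot CV, ties toward the plan
center; "closest to the observed peak intensity" is read as the argmax over
the three pilot CVs because a 3-point pilot supports no reliable
interpolation. Stage 2 trains the same ensemble on 77 inputs — descriptors
plus constraint CV — rather than, say, regressing a target offset; this is
the simplest mechanism that lets the model learn how much to trust the
constraint in different feature regimes. Ions with no pilot detection fall
back to the stage-1 CV with `covered = FALSE`, because a PRM list must
assign some CV to every target.

Two pilot mechanisms exist because plan CVs are continuous while archived
data live on the acquisition grid: `simulate_pilot()` acquires at the plan
CVs themselves from the generative model (a prospective pilot), and the CLI
`refine` subcommand snaps the stage-1 prediction to the observed grid before
planning (a retrospective pilot on archival data, which can only look up CVs
that were actually acquired).

## The synthetic benchmark

`sim_config()` defaults define the benchmark conditions:

| parameter | default | why |
|---|---|---|
| grid | −20 to −70 V in −5 V steps | short-gradient style acquisition grid |
| peak width σ | 5 V | reproduces ~20 V detectable spans at a 5% threshold |
| relative threshold | 5% of peak amplitude | detectability window definition |
| detection floor | 2 × 10⁴ a.u. | absolute noise floor; see below |
| amplitude | log-normal, meanlog log(10⁶), sdlog 1.2 | typical LFQ intensity spread over ~3 decades |
| noise | log-normal, CV 20% | run-to-run quantification noise |
| optimum model | −21 − 12·z + descriptor effects | places 2+ near −45 V, 3+ near −57 V, charge dominant |
| descriptor effects | +3 V/SD MS-WHIM1, −2 V/SD z3 | surface-electrostatics means as secondary determinants |
| residual SD | 4 V | feature-unexplained spread; see below |

Two defaults deserve their rationale spelled out:

* **Detection floor.** With purely relative censoring (detect when observed
  ≥ threshold × amplitude) the amplitude cancels and every peptide would
  show the same span distribution regardless of intensity. Real data show
  intense peptides with wider detectable spans, which is an absolute
  sensitivity phenomenon: the instrument's noise floor truncates weak
  profiles sooner. The generator therefore censors below
  max(threshold × amplitude, floor). The relative threshold still defines
  the ground-truth detectability window used for coverage accounting.
* **Residual SD 4 V.** The residual is the part of the true optimum that no
  sequence feature explains. It bounds stage-1 accuracy from below
  (test MAE ≥ E|N(0, s)| ≈ 0.8·s) and is what the pilot constraint can
  recover. A ±5 V three-point pilot quantizes the residual to ~2.5 V bins,
  so with a small residual the constraint has almost nothing left to add,
  while sequence-only models on real FAIMS data show several volts of MAE.
  4 V makes the benchmark's stage-1 error magnitude and the stage-1→stage-2
  improvement ratio match that regime; it is a property of the modeled
  system, not a tuning knob, and tests hold it fixed.

The generator emulates: bell-shaped unimodal transmission, charge-dominated
optima with secondary descriptor effects, amplitude-dependent detectable
spans, and censoring on discrete CV grids. It does **not** emulate real
FAIMS physics (dispersion-voltage and gas-flow effects, conformer
multiplicity, bimodal profiles), modification effects, retention-time
structure, or inter-run alignment artifacts. Passing tests therefore show
that the estimators and the workflow are correct and well-ordered under the
assumed statistical structure — they do not certify prediction accuracy on
real instrument data, which requires training on CV-resolved measurements.

## Problem sizes

The test-suite benchmarks use 220–2000 simulated peptides (2000 for the
end-to-end model-ordering checks, with an 80/20 ion-level split;
500–1000 for phenomenology checks; a 500 × 20 table for Lasso support
recovery), sizes at which the reported orderings are stable across seeds
while a full run stays in the minutes range on a single core.
`scripts/acceptance.R` recomputes all headline quantities at the same sizes.

## Known limitations

* QSAR residue-scale values are pinned as tabulated in this package; scale
  variants circulating in the literature differ in sign conventions and
  normalization for some families, and two of the ten families are
  best-effort tabulations. Swap in a custom table via the registry if your
  downstream use depends on a specific published normalization.
* The eight-model comparison grid (data set × single-observation filter ×
  target definition) is exposed through `make_training_table()` switches;
  the package does not automate multi-dataset management.
* Modified peptides are featurized by their stripped sequence; a modified
  and an unmodified form share one prediction.
* Inclusion lists are vendor-neutral CSV; vendor-specific exporters and raw
  file reading are out of scope.
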