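# faimscv

Predicting optimal FAIMS compensation voltages for peptide ions.

## The problem

A FAIMS (high-field asymmetric waveform ion mobility spectrometry) device
sits between the electrospray source and the mass spectrometer and transmits
only those ions whose differential mobility matches the applied compensation
voltage (CV). Most tryptic peptides are transmitted efficiently only within a
narrow CV window (roughly 20 V wide), so targeted experiments such as
parallel reaction monitoring (PRM) lose sensitivity badly when a target's CV
is guessed wrong — yet the optimal CV is usually unknown for peptides chosen
from non-FAIMS data or from sequence databases.

`faimscv` is for proteomics researchers who need per-peptide CV assignments
for PRM inclusion lists, and for anyone studying the molecular determinants
of FAIMS transmission. It provides:

- a 76-parameter descriptor vector per peptide ion: charge (1) + residue-class
  composition counts/mole-percents (18) + basic physicochemical properties
  (7) + per-sequence means of standard QSAR residue scales (50 from
  Cruciani, MS-WHIM, z-scales, T-scales, ProtFP, ST-scales, VHSE and
  BLOSUM-index families);
- CV-profile statistics from CV-resolved intensity data: intensity-weighted
  average CV, peak CV, detectable CV span, top-bin intensity fraction;
- an interpretable Lasso model and a stacked-ensemble regressor (gradient
  boosted trees + random forest + L1 linear, blended by a
  non-negativity-constrained meta-learner on out-of-fold predictions) that
  map descriptors to the CV of maximum transmission;
- a two-stage workflow: the stage-1 prediction seeds a 3-CV pilot run at
  {CV − 5, CV, CV + 5} V; the most intense pilot CV becomes an empirical
  constraint feeding a refined 77-input stage-2 model;
- a synthetic benchmark generator (Gaussian-in-CV transmission, log-normal
  amplitudes and noise, relative + absolute detection censoring) so the whole
  pipeline is testable without instrument data;
- long-format TSV readers (including a MaxQuant-style run-table adapter),
  PRM inclusion-list CSV output, and a `faimscv` command-line interface.

## The model

For ion $i$ with descriptor vector $x_i \in \mathbb{R}^{76}$, the training
target is the intensity-weighted average CV of its transmission profile,
$\bar{v}_i = \sum_g I_{ig} v_g / \sum_g I_{ig}$ over detected grid CVs
$v_g$. The linear model solves the Lasso problem

$$\hat\beta = \arg\min_\beta \tfrac{1}{2n}\lVert \bar v - \beta_0 - Z\beta
\rVert_2^2 + \lambda \lVert\beta\rVert_1$$

on standardized features $Z$, with $\lambda$ selected by 5-fold
cross-validated MAE. The stacked ensemble replaces the single linear map
with base learners $f_1, f_2, f_3$ and a constrained blend
$\hat v = a + \sum_k w_k f_k(x)$, $w_k \ge 0$, where $w$ is fitted on
out-of-fold base predictions. Stage 2 appends the pilot constraint CV as a
77th input. Charge is by far the strongest single coefficient, followed by
3D electrostatic-potential descriptors (MS-WHIM components).

## Worked example

```r
library(faimscv)

cfg <- sim_config(n_peptides = 600, seed = 42)
sim <- simulate_cv_dataset(cfg)
tab <- make_training_table(sim$profiles, target = "weighted",
                           include_single_observations = FALSE)
model <- fit_lasso(tab, penalty = "cv", seed = 42)
head(standardized_coefficients(model), 5)
#>                       feature coefficient
#> 1                      charge   -7.471316
#> 2         qsar_mswhim_MSWHIM1    2.057967
#> 3             qsar_zscales_Z3   -1.050818
#> 4              comp_Small_pct   -0.388163
#> 5 qsar_blosum-indices_BLOSUM8    0.169890

ion <- peptide_ion("ELVISLIVESK", 2)
cv_hat <- predict(model, t(featurize(ion)))
round_cv(cv_hat)          # -48.5  (volts; predicted transmission optimum)
plan_pilot(cv_hat)        # -53.5 -48.5 -43.5  (3-CV pilot acquisition)
precursor_mz(ion)         # 615.3712  (monoisotopic m/z for the PRM list)
```

The standardized coefficients read as volts of CV shift per standard
deviation of the feature: each extra charge unit pushes the optimum several
volts more negative, and the MS-WHIM/z-scale surface-electrostatics means
carry the largest sequence-derived effects — charge distribution over the
peptide surface governs FAIMS transmission. The same steps run from a shell
via `faimscv simulate`, `faimscv train`, `faimscv predict`,
`faimscv plan-pilot` and `faimscv make-prm` (see `exec/faimscv`).

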