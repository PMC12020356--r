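---
title: "Modeling PFAS sorption in soils: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling PFAS sorption in soils: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasorption)
```

## The problem

Per- and polyfluoroalkyl substances (PFAS) partition between soil solids
and pore water; the solid–liquid distribution coefficient
$K_d = C_s / C_w$ [L kg$^{-1}$] is the single most used parameter for
assessing their mobility toward groundwater. Measured $K_d$ values
scatter over five orders of magnitude across compounds and soils, and
literature records are heterogeneous: some studies report $K_d$
directly, others report the organic-carbon-normalized coefficient
$K_{OC}$ or only isotherm fit parameters, and soil characterization is
frequently incomplete. `pfasorption` implements a complete modeling
chain for this situation: speciation-aware molecular descriptors,
dataset harmonization, imputation of missing soil covariates, a
stacking ensemble regression for $\log_{10} K_d$, model-agnostic
sensitivity analysis, and batch prediction over gridded soil tables.

## Speciation descriptors

Most PFAS are ionizable acids or bases; which species is present at a
given soil pH controls the electrostatic part of sorption. For a
compound with acid constants $pK_{a,1} \le pK_{a,2}$ the relative
abundances follow the Henderson–Hasselbalch closed forms. Monoprotic:

$$A_{\mathrm{HA}} = \frac{1}{1 + 10^{\,\mathrm{pH} - pK_a}},\qquad
  A_{\mathrm{A^-}} = \frac{10^{\,\mathrm{pH} - pK_a}}{1 + 10^{\,\mathrm{pH} - pK_a}}.$$

Diprotic compounds use the standard three-term $\alpha$ fractions in
$10^{\mathrm{pH}-pK_{a,1}}$ and $10^{2\mathrm{pH}-pK_{a,1}-pK_{a,2}}$;
compounds without an ionizable group (fluorotelomer alcohols) have a
single species. The implementation evaluates the terms in log space and
shifts by the maximum before exponentiating, so abundances remain exact
at extreme pH (closure $\sum_i A_i = 1$ holds to $10^{-12}$ across a
pH 0–14 sweep for every bundled compound; this is tested).

Two descriptors summarize speciation at the soil's pH:

* **Effective molecular weight** $\overline{MW} = \sum_i A_i \, MW_i$,
  where each deprotonation step removes one proton mass (1.008 g
  mol$^{-1}$) from the species molecular weight. Species MW is
  bookkept this way rather than re-derived from per-species formulas:
  it is exactly equivalent and needs no structure handling.
* **Charge density** $= F \sum_i A_i z_i \, / \, \overline{MW}$
  [C g$^{-1}$], with the Faraday constant $F = 96485$ C mol$^{-1}$
  (CODATA, rounded). It is positive for net-cationic, about zero for
  neutral or zwitterionic, and negative for net-anionic speciation.
  Fully deprotonated trifluoroacetate (anion mass 113.01 g mol$^{-1}$)
  gives $-96485/113.01 \approx -854$ C g$^{-1}$, the most negative
  value attainable among the bundled compounds.

The bundled registry covers 51 compounds across eleven subfamilies.
Identities, formulas and subfamily memberships are curated; molecular
weights are recomputed from the empirical formulas with standard atomic
weights (a test cross-checks them). Where an authoritative per-compound
measurement was not available (log $K_{OW}$, solubility, exact
$pK_a$, and the speciation diagrams of the cationic/zwitterionic
compounds), entries carry literature-typical curated values and are
marked `provisional = TRUE`; betaines are encoded as permanent
zwitterions ($z = 0$), quaternary ammonium compounds as permanent
cations ($z = +1$), and aminated sulfonamides as diprotic
$+1 \rightarrow 0 \rightarrow -1$ systems. Users with better values
should load their own table through `read_pfas_registry()`; the code
never estimates physicochemical properties itself.

## Harmonizing literature records

`harmonize_sorption()` resolves one $K_d$ per record with the
preference **direct > from $K_{OC}$ > from isotherm**, mirroring the
preference for directly reported low-concentration measurements:

* $K_d = K_{OC} \cdot f_{OC}$ with $f_{OC} = C_{org}/100$; records with
  $C_{org} \le 0$ cannot be converted and are rejected with a reason
  code.
* Isotherm fits are evaluated at an aqueous concentration of 10% of
  the compound's water solubility: Freundlich
  $K_d = K_F (0.1 S)^{n-1}$ (equal to $K_F$ for a linear isotherm),
  Langmuir $K_d = Q_{max} K_L / (1 + 0.1 S K_L)$. The 10% rule is
  applied to the aqueous-phase concentration; the alternative (total
  concentration) is not used and this convention is the documented
  assumption.

Soil plausibility screens reject impossible records (pH outside 0–14,
percentages outside 0–100); reported sand/silt/clay triplets must close
to $100 \pm 2\%$ and are renormalized to exactly 100. All rejections
are row-level with machine-readable reasons — nothing is silently
dropped.

**Outlier screening.** Per-compound mean $\log K_{OC}$ is regressed on
$\log K_{OW}$; compounds whose absolute residual exceeds 2× the
residual RMSE of that fit are flagged (`compound_trend`), and entries
more than 1.5 log units from their compound's median $\log K_{OC}$ are
flagged (`entry_deviation`). Both thresholds replace the expert
judgment used when such datasets are curated by hand and are
configurable. The compound screen is deliberately single-pass: one
gross outlier inflates the RMSE and is still caught, while the rest of
the compounds stay within threshold; iteratively re-fitting after
exclusion shrinks the RMSE to sampling noise and starts flagging
ordinary 2-sigma compounds, which defeats the purpose of an advisory
screen. The cost is that several outliers of comparable magnitude can
partially mask one another — flags are advisory and ship with full
diagnostics, and dropping flagged rows is a separate, visible step.

## Imputing missing soil properties

Missing soil covariates (pH, CEC, $C_{org}$, textures) are filled by a
K-nearest-neighbour imputer trained on a complete reference table.
Properties are min-max scaled to the reference bounds; the distance
between a query and a reference row is Euclidean over the query's
*observed* coordinates, rescaled by $\sqrt{p / p_{obs}}$ so queries
with different missingness patterns are comparable (the nan-aware
convention). Defaults: $k = 5$, uniform neighbour weights, ties broken
by reference row order for determinism. These follow the common KNN
imputer convention; they are assumptions, exposed as arguments.
Imputed values are convex combinations of reference values and
therefore always in range; textures are renormalized to 100 after
imputation. Coordinates, when present, are metadata only — never
imputation features.

## The stacking model

The nine features, in fixed order: effective MW, log $K_{OW}$, charge
density, pH, CEC [cmol$_+$ kg$^{-1}$], $C_{org}$ [%], sand, silt, clay
[%]. Features (never the target) are min-max scaled with bounds from
the training split only. The data is split 80/20 by a seeded holdout
(floor rule for the test share: 1,227 rows give 982/245).

Layer one fits four base learners on the scaled features:

| learner | implementation | defaults |
|---|---|---|
| ridge regression | closed-form penalized normal equations | $\alpha = 1.0$, intercept unpenalized |
| random forest | `ranger` | 500 trees, unrestricted depth |
| extremely randomized trees | `ranger` (`extratrees`, no bagging) | 500 trees |
| gradient boosting | `xgboost` | 500 rounds, $\eta = 0.05$, depth 3 |

Layer two is a single-hidden-layer perceptron (`nnet`, 16 logistic
hidden units, linear output, weight decay $10^{-4}$, up to 2,000
iterations) that maps the base-prediction vector
$Z = (\hat y_1, \dots, \hat y_4)$, min-max scaled, to the final
$\log K_d$. Hidden units are logistic because that is the activation
the installed single-hidden-layer perceptron provides; at 16 units on a
4-dimensional smooth input the choice of sigmoid is immaterial.

**Leakage control.** The meta-model is trained on *out-of-fold* base
predictions (an internal 5-fold scheme), then the base learners are
refit on the full training set. Training the meta-model on in-sample
base predictions — the literal reading of "train the base models, then
feed their predictions to the meta-model" — lets it exploit the base
learners' in-sample optimism and overfits; that variant remains
available via `pssm_config(stack_oof = FALSE)` for fidelity
comparisons. A test checks that shuffling held-out labels cannot beat
the true labels, i.e. no target information reaches prediction time.

Every stochastic component (split, fold assignment, forests, boosting,
perceptron initialization) is derived from the single `seed` argument;
refitting with the same seed and data reproduces predictions
bit-for-bit (tested).

Ridge hyperparameter note: the closed form solves
$\min_\beta \|y - \beta_0 - X\beta\|^2 + \alpha\|\beta\|^2$ exactly on
the scaled features, keeping the "$\alpha = 1.0$" contract transparent;
a test verifies it against numerical minimization of the same
objective.

## Evaluation metrics

With observations $o$ and predictions $p$:
$\mathrm{RMSE} = \sqrt{\mathrm{mean}((o-p)^2)}$;
$\mathrm{NRMSE} = \mathrm{RMSE} / (\max o - \min o)$;
$\mathrm{RPD} = \mathrm{sd}(o)/\mathrm{RMSE}$ with the sample (n−1) SD.
NRMSE is range-normalized by default because that convention is
consistent with the reported pairing of NRMSE ≈ 0.07 and RPD ≈ 3.16 on
data spanning about 5.3 log units; mean- and SD-normalization are
selectable (`normalizer`) so the convention can be re-checked against
any dataset. The identity
$\mathrm{RPD}\cdot\mathrm{NRMSE} = \mathrm{sd}(o)/\mathrm{range}(o)$ is
tested on random vectors. Residual skewness uses the Fisher moment
coefficient $g_1 = m_3/m_2^{3/2}$. The predicted-vs-observed line is
OLS of $p$ on $o$. CV-NRMSE comes from `cross_validate()`, which
refits the whole stack per fold.

## Sensitivity analysis

`shapley_exact()` enumerates all $2^9 = 512$ feature coalitions — no
approximation is needed at nine features — and computes exact Shapley
values under the interventional expectation: features outside the
coalition are replaced by background-row values and predictions
averaged. The interventional (marginal) form is used rather than the
conditional one because it is the standard, tractable choice in the
SHAP framework. Local accuracy
($\sum_i \phi_i + E[f] = f(x)$), the dummy axiom and symmetry are all
verified in tests, including the closed form
$\phi_i = w_i (x_i - \bar b_i)$ for linear models. The default
background is a seed-fixed subsample (≤ 100 rows) of training data.
`partial_dependence()` averages predictions over the sample while one
feature sweeps a grid within its observed range.

## Mapping

`predict_kd_map()` applies a fitted model to a table of grid cells
(lat/lon plus soil properties), optionally imputing missing soil
fields first. Cells that still lack a feature are returned as
`nodata`; cells outside the training feature ranges are predicted but
flagged `out_of_domain`, because tree ensembles do not extrapolate
reliably. Input and output are plain CSV-shaped tables; rasterization
is deliberately left to GIS tools so the package carries no geospatial
binary dependencies.

## The synthetic-data generator

The generators make every stage testable offline and define the
conditions under which the pipeline's recovery claims are made.

`gen_reference_soils()` draws: $C_{org}$ log-normal (meanlog 0, sdlog
1.2) truncated to [0.03, 54]%, hence skewed low with median < 2%; pH
truncated-normal on [2.8, 9.0] with its centre at
$6.2 - \log_{10} C_{org}$ (sd 0.95), so organic topsoils run acidic
and overall mean pH is ≈ 6.2; textures from a Dirichlet
(2.2, 2.0, 1.2) scaled to 100 with clay ≤ 69% by rejection; CEC
$= 2 + 2.2\,C_{org} + 0.15\,\mathrm{clay} + N(0,3^2)$, truncated to
[0.1, 140]. The ranges are the documented applicability ranges of the
modeled dataset; the cross-property correlations (CEC with $C_{org}$
and clay, pH with $C_{org}$) are what give a KNN imputer something to
work with, as in real topsoil repositories.

`gen_sorption_dataset()` samples compounds from the registry and soils
from the reference generator, computes the speciation descriptors at
each soil's pH, and emits
$$\log K_d = 0.2 + 0.45 \log K_{OW} + 0.6 \log_{10} C_{org}
           + 5\times10^{-4}\,\mathrm{cd} - 0.15\,\mathrm{pH}
           + \varepsilon,\quad \varepsilon \sim N(0, 0.3^2).$$
The coefficients were fixed once to reproduce the dispersion of the
compiled field dataset this emulates — $\log K_d$ spanning roughly
five orders of magnitude with sd ≈ 0.95 — with effect directions
(hydrophobicity and organic carbon up, pH down, electrostatics minor)
matching what sensitivity analyses of such data report. The noiseless
latent target is returned for recovery tests, and whole compounds can
be displaced by a fixed offset to plant outliers.

What the generator does *not* emulate: study-to-study measurement
bias, heteroscedastic noise, correlated repeat measurements from one
soil, nonlinearity beyond the speciation terms, and subfamily-specific
sorption mechanisms (e.g. the anomalous phosphinic-acid behaviour seen
in field data). Passing recovery tests therefore demonstrates that the
pipeline machinery is correct and well calibrated under its stated
conditions — not that the fitted synthetic models transfer to field
data.

## Problem sizes and numerical choices

The test suite runs the full-default pipeline at n = 1,200 entries
(the scale of the compiled dataset it emulates) for the recovery
check, and reduced configurations (100-tree forests, 3 folds) for
plumbing tests; exact Shapley checks use 25–40 background rows. These
sizes keep the whole suite under a few minutes on one core while
leaving every default hyperparameter exercised at least once.
Degenerate inputs are handled explicitly: constant feature columns are
refused by name at scaling time; a constant target trains and predicts
that constant; constant observations make NRMSE/RPD undefined and
raise an error rather than returning infinities; an exactly collinear
compound set produces zero outlier flags (the threshold has an
absolute floor of $10^{-8}$ log units against float noise).

## Known limitations

* Registry property values for provisional entries are curated
  stand-ins, adequate for method development, not for compound-specific
  risk assessment.
* The model is empirical: predictions outside the training feature
  ranges are flagged, not blocked, and should be treated as
  extrapolation.
* Saturated-zone, room-temperature sorption only: no air–water
  interface partitioning, no temperature dependence, no ionic-strength
  correction.
* The outlier screen can mask multiple comparable outliers
  (single-pass by design); inspect the attached diagnostics rather
  than trusting flags blindly.
* Welch ANOVA + Games–Howell grouping assumes approximately normal
  within-group residuals; with heavy tails, interpret the letter
  display qualitatively.
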