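---
title: "Surrogate modelling and optimization of rooting media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modelling and optimization of rooting media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootnet)
```

`rootnet` implements a complete surrogate-modelling workflow for the
macronutrient optimization of *in vitro* rooting media for the G×N15
Prunus rootstock: stoichiometry from salt masses to ion concentrations, a
replicate-level synthetic dataset reconstructed from published treatment
means ± SE, small feed-forward neural networks trained by
Levenberg–Marquardt, sensitivity-based ion ranking, and a real-coded
genetic algorithm that searches for the response-maximizing medium. This
vignette documents the model, its assumptions, the tunable parameters, and
the numerical and design choices — including the ones where the underlying
experiment leaves the procedure genuinely open.

## The experiment and its data

Thirty-six media were generated factorially from four macronutrient
salts: KNO₃ at 1900/1425/950 mg/L, NH₄NO₃ at 1650/1238/825 mg/L, and
calcium supplied either as Ca(NO₃)₂·4H₂O (556/280 mg/L, media 1–18) or as
CaCl₂·2H₂O (440/220 mg/L, media 19–36). Each medium was tested on six
replicates of four explants, and five responses recorded: root number
(RN), root length (RL, cm), rooting percentage (R%, a proportion in
\[0, 1\]), root fresh weight (FW, g) and dry weight (DW, g). The model
inputs are the five ion concentrations NO₃⁻, NH₄⁺, K⁺, Ca²⁺, Cl⁻ in mM.

### Stoichiometry

`ions_from_salts()` converts mg/L of salt into mM of ion by dividing by
the molar mass, with nitrate accumulating from all three nitrate salts
(two NO₃⁻ per calcium nitrate). Two conventions deserve note:

* **Hydrates.** The calcium salts are taken as the tetrahydrate
  (236.15 g/mol) and dihydrate (147.02 g/mol); only these reproduce the
  published Ca²⁺ values (2.35/1.18/3.00/1.50 mM).
* **Chloride.** The published ion table reports Cl⁻ equal to the molarity
  of CaCl₂·2H₂O rather than twice it. The default `per_salt` convention
  reproduces the table; `stoichiometric` implements the chemically correct
  factor two. Whether the published halving is typographic cannot be
  decided from the data, so both are exposed and all modelling uses the
  convention the responses were recorded against.

A related discrepancy — half-strength calcium nitrate quoted as 278 mg/L
in one place and 280 mg/L in another — is resolved in favour of 280,
which matches the published 1.18 mM. `verify_against_reference()`
recomputes all 36 ion profiles and confirms agreement within 0.02 mM, the
rounding resolution of a two-decimal table.

### The synthetic replicate dataset

The networks were originally fitted to 216 replicate-level observations,
but only treatment means ± SE are published. `expand_replicates()`
reconstructs a dataset with the same statistical structure: each
treatment contributes `n_reps = 6` draws from
Normal(mean, SE·√6) — the SE-to-SD conversion for a mean of six
replicates — clamped to the response's physical domain (non-negative;
R% additionally ≤ 1). Choices made here:

* The "±" values are interpreted as standard errors of the mean with
  n = 6, the stated design for this experiment.
* Noise is Gaussian with clamping rather than truncated-Gaussian
  resampling; at the published SE magnitudes the clamping bias is
  negligible (a Monte-Carlo check in the test suite recovers the printed
  mean of the first medium's RN to within 0.05 over 10,000 draws).
* RN replicates are kept continuous: the network regresses a continuous
  target and the published means are non-integer.
* When more than six draws are requested (for Monte-Carlo checks), the
  SE-to-SD conversion still uses the design replicate count, because the
  printed SEs summarize the six-replicate design.

This generator reproduces the first two moments of the real replicates
and their treatment structure, but not any skewness, replicate-level
correlation, or explant-level structure the real data may have had. Tests
that pass on it therefore validate the pipeline's behaviour under the
stated noise model, not the biology.

Normalization (`normalization_spec()`) maps each column linearly onto
\[−1, 1\] using ranges computed from the full 216-row dataset, because
normalization preceded the train/test split in the source workflow. The
split (`split_train_test()`) draws 130 training and 86 testing rows at
random, with a guard that both partitions touch at least 30 of the 36
media; degenerate draws are redrawn deterministically.

## The network and its training

Each response gets its own 5–8–1 network: five ion inputs, eight hidden
units with the hyperbolic-tangent sigmoid `tansig(n) = 2/(1+e^(−2n)) − 1`,
one linear output. The 57 parameters are trained by Levenberg–Marquardt
least squares with an analytic Jacobian.

Numerical choices:

* **Initialization** is Nguyen–Widrow: random hidden-weight directions
  rescaled so the tansig active regions tile the input box, biases spread
  along it, small uniform output weights. It is fully determined by the
  `seed` argument.
* **Damping** starts at 10⁻³ and adapts by ×10 on a rejected step, ÷10 on
  an accepted one; a step is accepted only if it reduces the training
  SSE, so the recorded loss trace is non-increasing by construction. If
  no improving step exists below a damping of 10¹², training stops
  (`"stalled"`); with noisy replicates this typically happens at the
  noise floor and acts as a mild implicit regularizer. (A Marquardt-style
  diagonal scaling was evaluated and rejected: it trains longer and
  generalizes measurably worse on this data.)
* **Stopping** follows the source setup: per-sample MSE ≤ 0.01 in
  normalized space, or 800 accepted epochs. The MSE goal is checked
  against the per-sample mean (not the ½-weighted training objective) so
  it is comparable across partition sizes. The weights with the lowest
  recorded training MSE are returned.
* A full-batch gradient-descent-with-momentum fallback
  (`algorithm = "gdm"`) is provided; Levenberg–Marquardt is the default
  and is used everywhere in the package.
* Degenerate inputs: a constant response yields a warned constant
  predictor; non-finite losses abort with a diagnostic.

Fit quality is reported as R², RMSE, MBE and MSE. Two definitional
choices follow the published results rather than the printed formulas:
the R² denominator uses squared deviations Σ(O−Ō)² (the only form bounded
by 1 and consistent with reported values of 0.86–0.98), and MBE is the
signed mean of predicted-minus-observed (reported MBE values are
negative, which an absolute-value mean cannot produce); the absolute
variant is available as `mae()`. Metrics are computed on both the
original and the normalized scale; R² is scale-invariant, RMSE and MBE
are not, and the original scale is the headline.

With the default settings, the median held-out R² over ten seeds is
about 0.96 for R% and 0.80–0.91 for the other responses. An oracle that
predicts each treatment's true mean scores 0.86–0.98 under the same noise
model — closely matching the published values — so the networks operate
near the ceiling the noise model allows.

## Sensitivity analysis and its identifiability limit

`sensitivity()` implements the variable-sensitivity-error (VSE) /
variable-sensitivity-ratio (VSR) scheme: VSE is the model's error when an
input is unavailable, VSR = VSE divided by the full model's error, and
inputs are ranked by descending VSR (ties broken in the fixed ion order
and flagged). Errors are RMSE in normalized space, evaluated on all 216
rows; since VSR is a ratio, any monotone error metric yields the same
ranking. Two readings of "unavailable" are implemented:

* `mode = "retrain"` (default): refit a reduced-topology 4–8–1 network on
  the same training rows with the ion's column removed.
* `mode = "hold_at_mean"`: keep the trained network and fix the ion's
  column at its training mean.

On this particular design, the retrain reading has a hard identifiability
limit that users should understand before interpreting ion ranks:

1. The 36 ion profiles satisfy an exact linear identity,
   NO₃⁻ − NH₄⁺ − K⁺ − 2·Ca²⁺ + 2·Cl⁻ = 0 (to the table's rounding), since
   all five ions derive from four salts. Every ion is therefore a linear
   function of the other four, and a retrained reduced network loses no
   information.
2. Independently of collinearity, with only 36 distinct design points an
   eight-hidden-unit network in four remaining inputs can simply
   interpolate every treatment mean, again erasing the removed ion's
   contribution.

Empirically, retrain-based VSRs on this data are 1.00 ± 0.01 for every
ion and every response, and the resulting ranks are noise. The
`hold_at_mean` mode, which probes the trained network's internal reliance
instead, recovers K⁺ as the top-ranked ion for most responses but is
itself arbitrary under collinearity (the network may internally lean on
NO₃⁻ in place of K⁺ at no cost). The package therefore treats ion ranks
on this design as descriptive, not inferential. On designs where
importance *is* identifiable — independent input draws, enough distinct
points that the reduced network cannot memorize — retrain-based VSR
behaves exactly as intended, and the test suite verifies both limiting
cases on such designs (an ignored input scores VSR ≈ 1; a sole driving
input scores VSR > 3).

## Genetic-algorithm optimization

`ga_optimize()` maximizes a trained network with a real-coded GA using
the source study's settings: population 50, 500 generations, crossover
rate 0.85, mutation rate 0.1, roulette-wheel selection. Where the source
leaves the operators unspecified, the package uses:

* **Representation**: real-valued gene vectors on the mM (or mg/L) scale;
  no binary encoding, so there are no discretization artifacts.
* **Selection**: fitness-proportionate sampling; fitness vectors whose
  minimum is non-positive are shifted so the minimum maps to a small
  positive floor, already-positive fitness is used as-is.
* **Crossover**: arithmetic blend, `α·a + (1−α)·b` with α ~ U(0, 1),
  applied per pair with the crossover probability.
* **Mutation**: per-gene Gaussian noise with SD = 0.1 × box width,
  clipped to bounds, so candidates never leave the search box.
* **Elitism**: one individual survives unchanged per generation, making
  the best-fitness trajectory non-decreasing.
* `generations` counts fitness-evaluation rounds: a single-generation run
  is exactly brute force over the initial population.

Two search spaces are offered. `ga_optimize()` searches the box spanned
by the observed ion ranges, as a generic box-constrained maximizer; on
the analytic quadratic benchmark it recovers the argmax to well under 5%
of each box width. `optimize_medium()` searches the four salt masses
within their data ranges and maps candidates through the stoichiometry
before evaluation. The distinction matters: the data lie on the 4-D
manifold induced by the salts, so most of the 5-D ion box is unsupported
by any observation, and a surrogate maximized there happily exploits its
own extrapolation artifacts (measured: R% "optima" above 1.0, RN optima
with a seed-to-seed SD near 4 roots). Salt-space search keeps every
candidate mixable and data-supported, and its optima are stable (R%
optimum ≈ 0.95–0.97 with SD ≈ 0.03 over ten seeds, RN ≈ 15–16 roots) and
agree with the published optimization. The pipeline therefore optimizes
in salt space whenever the formulation table is available; the ion-box
optimizer remains for benchmarks and for users with other designs.

## Benchmark surfaces

`benchmark_surface()` supplies known-truth response surfaces for
end-to-end parameter-recovery tests: a separable concave quadratic with
analytic argmax (default: box midpoints, maximum 0.95), and a
`table6_like` surface obtained by a ridge-regularized per-ion quadratic
fit to the observed R% means (penalty 1 on standardized features —
unpenalized least squares on this near-collinear design produces
off-scale coefficients), clamped to \[0, 1\] as a proportion surface.
Surfaces can be sampled at the 36 observed ion profiles or at uniform
random points in the box; the uniform design exists precisely because the
observed one is collinear (see above).

## Problem sizes and reproducibility

All simulation sizes used by the tests and the acceptance script are
moderate by design: 216-row datasets, ten-seed medians for stochastic
quantities, 200-point uniform designs for the sensitivity property tests,
and 10,000-draw Monte-Carlo checks of the noise model. Every stochastic
stage (replicate noise, splits, weight initialization, GA) takes an
explicit integer seed, and the pipeline derives distinct per-stage seeds
from one base seed, so any result in this package is reproducible from a
single integer.

## Known limitations

* The synthetic replicates reproduce the published means and SEs, not the
  real replicate values; conclusions about the biology inherit the noise
  model's assumptions.
* Ion-importance ranks on the packaged design are not identifiable (see
  above); they are reported for comparability, with the structural caveat
  documented.
* The surrogate is only trusted inside the data's salt ranges; neither
  search mode extrapolates beyond them, and no economic or multi-objective
  optimization is attempted.
* Micronutrients, vitamins, hormones and gelling conditions are fixed
  across the 36 media and outside the model's scope.
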