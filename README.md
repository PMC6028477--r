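# rootnet

Surrogate modelling and optimization of macronutrient culture media for
*in vitro* rooting of the Prunus rootstock G×N15 (Garnem).

Micropropagated fruit-tree rootstocks must form adventitious roots on a
defined gel medium before they can be hardened off, and rooting is acutely
sensitive to the medium's macronutrient balance. `rootnet` models five
rooting responses — root number (RN), root length (RL, cm), rooting
percentage (R%, a proportion), root fresh and dry weight (FW, DW, g) — as
functions of the five macronutrient ion concentrations NO₃⁻, NH₄⁺, K⁺,
Ca²⁺ and Cl⁻ (mM), and then searches for the medium composition that
maximizes each response. It is aimed at plant tissue-culture researchers
who want a transparent, reproducible implementation of the ANN–GA
medium-optimization workflow.

## The model

Each response is fitted by a single-hidden-layer feed-forward network with
topology 5–8–1. Hidden unit *i* computes

    S_i = Σ_n w_ni x_n + b_i,    y_i = tansig(S_i) = 2 / (1 + e^(−2 S_i)) − 1,

and the output is a linear (purelin) combination of the eight hidden
activations. Inputs and the response are min–max normalized to \[−1, 1\].
Training minimizes squared error by Levenberg–Marquardt with an analytic
Jacobian, stopping at a per-sample MSE of 0.01 (normalized space) or after
800 epochs. Fits are scored by R², RMSE and the signed mean bias error
(MBE) on held-out data.

Around the network the package provides:

* **Stoichiometry** — `ions_from_salts()` converts salt masses (mg/L of
  KNO₃, NH₄NO₃, Ca(NO₃)₂·4H₂O, CaCl₂·2H₂O) into the five-ion profile (mM),
  and `verify_against_reference()` cross-checks the packaged 36-medium salt
  table against the published ion table.
* **Synthetic replicates** — `expand_replicates()` reconstructs the
  replicate-level dataset (36 treatments × 6 replicates = 216 rows) from
  the published means ± SE, drawing per-replicate noise with
  SD = SE·√6 and clamping to each response's physical domain;
  `split_train_test()` makes the 130/86 train/test partition.
* **Sensitivity** — `sensitivity()` ranks ions by the variable sensitivity
  ratio (VSR): the model's error with an ion unavailable divided by the
  full model's error.
* **Optimization** — `ga_optimize()` maximizes a trained model over the
  ion box with a real-coded genetic algorithm (population 50, 500
  generations, roulette-wheel selection, arithmetic crossover 0.85,
  Gaussian mutation 0.1, one elite); `optimize_medium()` runs the same GA
  over the four salt masses so every candidate is a mixable medium.
* **Pipeline** — `reproduce()` runs everything end to end from one seed.

## Worked example

```r
library(rootnet)

treatments <- gn15_treatments()                       # 36 media, means ± SE
reps  <- expand_replicates(treatments, "Rpct", seed = 1)   # 216 rows
spec  <- normalization_spec(reps)                     # [-1, 1] ranges
parts <- split_train_test(reps, seed = 2)             # 130 / 86

fit <- rootnet(value ~ no3 + nh4 + k + ca + cl, parts$train,
               ranges = spec, seed = 3)
fit
#> Feed-forward surrogate network (tansig hidden / linear output)
#> Topology: 5-8-1 | epochs: 5 | stop: mse_goal | train MSE (norm): 0.00973

r_squared(parts$test$value, predict(fit, parts$test))
#> [1] 0.959

optimize_medium(fit, seed = 4)
#> Salt-space GA optimum (mapped through stoichiometry)
#> Optimal salt masses (mg/L):
#>         kno3_mg_l       nh4no3_mg_l cano3_2_4h2o_mg_l   cacl2_2h2o_mg_l
#>             950.0            1650.0             505.2               0.0
#> Induced ion concentrations (mM):
#>    no3    nh4      k     ca     cl
#> 34.290 20.615  9.397  2.139  0.000
#> Predicted response at optimum: 0.9465
```

The network explains ~96% of the held-out variance in rooting percentage,
and the optimizer lands in the low-K⁺ / high-NH₄⁺ region — half-strength
KNO₃ with full-strength NH₄NO₃ — where the best-rooting media sit, with a
predicted rooting fraction of about 0.95.

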