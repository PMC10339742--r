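# qsarmix

Quantitative structure–activity relationship (QSAR) modelling for
enzyme-inhibition data, built around an ε-support-vector regression with a
composite ("mixed") kernel. The package ships the full pipeline used to
model a series of amide-derivative xanthine oxidase (XO) inhibitors —
descriptor selection, model fitting, swarm-based hyperparameter tuning, and
cross-validated evaluation — together with a synthetic descriptor-matrix
generator so every stage is testable without proprietary descriptor
software.

## Who it is for

Cheminformatics practitioners who have a compounds × descriptors table and
a measured potency (IC50) per compound, and want a reproducible,
leakage-free comparison of linear and kernel regression models at small
sample sizes (tens of compounds, hundreds of descriptors).

## The model

Potency is modelled on the activity scale `y = −lg(IC50)` (IC50 in μM).
Two descriptor-selection routes are provided:

- **Heuristic method (HM)** — pre-filter (drop descriptors missing for any
  compound, zero-variance descriptors, and the weaker member of any pair
  with `|r| > 0.8`), then greedy forward stepwise multilinear regression
  maximizing the Fisher criterion
  `F = (R²/k) / ((1−R²)/(n−k−1))`,
  with leave-one-out cross-validated R² deciding where the model stops
  growing.
- **Gradient-boosted importance** — an xgboost regression ensemble scored
  by split gain (default) or coverage, keeping the smallest top-ranked set
  whose cumulative normalized importance reaches 85%.

The flagship regressor is an ε-SVR trained on the mixed kernel

```
κ(x, z) = w · exp(−γ‖x−z‖²) + (1−w) · (⟨x,z⟩ + 1)^p + b · ⟨x,z⟩
```

with `w ∈ [0,1]`, `b ≥ 0` (a convex-plus-conic combination of
positive-semidefinite kernels, hence itself a valid kernel). The RBF term
fits, the polynomial and linear terms generalize; `w` and `b` trade the
two off. The ε-SVR dual (box constraints `0 ≤ α, α* ≤ C`, equality
`Σ(α−α*) = 0`) is solved by a sequential-minimal-optimization solver
written for this package (second-order working-set selection, exact
piecewise-quadratic pair subproblem), and is verified in the test suite
against a generic interior-point QP reference and against libsvm.

Hyperparameters — `(C, γ, p, w, b)` for the mixed-kernel SVR,
`(NT, MD, MS, ML)` for the random-forest baseline — are tuned by a
global-best particle swarm with mixed integer/real coordinates and a
linearly decreasing inertia weight
`w(gen) = (w_init − w_end)(NGEN − gen)/NGEN + w_end`,
minimizing k-fold cross-validated RMSE.

Models are compared by training/test R² and RMSE plus the leave-one-out
cross-validated `Rcv²` (the Q² form: R² of the pooled held-out
predictions). All scaling is refitted inside every fold.

## Worked example

```r
library(qsarmix)

# the packaged XO-inhibitor potency table (30 compounds)
tab <- xo_compound_table()
head(tab[, c("id", "r1_group", "ic50_um", "activity")], 3)
#>   id r1_group ic50_um   activity
#> 1  1   Propyl   16.17 -1.2087100
#> 2  2   Propyl    0.13  0.8860566
#> 3  3   Propyl    0.06  1.2218487

# synthetic descriptor matrix with a planted 4-descriptor linear signal
spec <- synthetic_spec(n_compounds = 54, n_descriptors = 200,
                       n_informative = 4, snr = 10, seed = 101)
d <- generate_synthetic(spec)

# stepwise selection on the pre-filtered matrix
kept  <- prefilter(d$descriptors, d$activity)
curve <- stepwise_select(d$descriptors[, kept], d$activity, max_k = 6)
chosen <- choose_model(curve)
chosen
#> -lg(IC50) =  - 0.01*D0057 - 97.69*D0095 + 0.10*D0073 + 98.50*D0174 + 0.01
#> n = 54, k = 4, R2 = 0.9882, R2cv = 0.9858, F = 1030.08
setequal(chosen$descriptors, d$truth$informative)
#> [1] TRUE

# on a dataset with a quadratic term the linear model underfits and the
# mixed-kernel SVR does not (same descriptors, same LOOCV protocol)
d2 <- generate_synthetic(synthetic_spec(n_compounds = 54,
                                        n_descriptors = 200,
                                        n_informative = 4,
                                        nonlinearity = "quadratic",
                                        snr = 10, seed = 202))
x2 <- d2$descriptors[, d2$truth$informative]
lin <- loocv(function(xtr, ytr) {
  f <- fit_ols(xtr, ytr); function(xte) predict(f, xte)
}, x2, d2$activity)
ks <- kernel_spec("mix", gamma = 1, p = 2, w = 0.5, b = 0.1)
mix <- loocv(function(xtr, ytr) {
  f <- svr(xtr, ytr, kernel = ks, C = 100, epsilon = 0.01)
  function(xte) predict(f, xte)
}, x2, d2$activity)
round(c(linear = lin$r2_cv, mix = mix$r2_cv), 3)
#> linear    mix
#>  0.707  0.972
```

The stepwise route recovers exactly the four planted descriptors (with a
LOOCV R² of 0.986 at size 4), and on quadratic activities the mixed-kernel
SVR cross-validates at 0.97 where the linear model stalls at 0.71 —
the same qualitative ordering the method was designed to exploit.

The full pipeline (generate/load → split → select → tune → fit panel →
evaluate) runs from one config:

```r
run_pipeline("config.yaml")          # or a named list; see ?run_pipeline
```

or from the shell:

```sh
Rscript scripts/run_pipeline.R --config config.yaml --seed 1 --outdir results
```

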