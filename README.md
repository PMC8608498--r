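# boostjm

Likelihood-based boosting for joint models of longitudinal and
time-to-event data.

## What problem does this solve?

Cohort studies routinely record a biomarker repeatedly over time alongside
a possibly censored event time — CD4 counts and death, eGFR and kidney
failure. Modelling either outcome alone is biased: separate survival
models mishandle the time-varying biomarker, and separate longitudinal
models ignore event-dependent follow-up. Joint models couple the two
through a shared trajectory, but classical fitting (EM over the joint
likelihood) offers no variable selection and fails outright when the
number of candidate covariates exceeds the number of subjects.

boostjm fits the joint model

- longitudinal: `y_ij = β0 + β_t t_ij + β_l' x_li + γ_0i + γ_ti t_ij + ε_ij`,
  with correlated random intercepts/slopes `(γ_0i, γ_ti) ~ N(0, Q)`;
- survival: hazard `λ_i(t) = λ0(t) exp(β_s' x_si + α η_l(t, x_li))`, with a
  piecewise-constant baseline `λ0` so a full (non-partial) likelihood is
  available in closed form;

by **component-wise likelihood-based boosting**: at each iteration,
Fisher-scoring candidate updates are computed per covariate, only the best
one is applied, scaled by a small step length (ν = 0.1). The association
parameter α competes in the survival selection pool like any covariate;
the baseline hazard gets an exact occurrence/exposure update each
iteration. Early stopping — the stopping tuple `(m_l, m_s)` is chosen by
k-fold cross-validated joint likelihood — yields shrunken estimates and
implicit variable selection in both submodels, and works for p > n. A
correction step keeps the random effects exactly uncorrelated with the
observed covariates, preventing cluster confounding.

Two variants are provided: `variant = "full"` boosts both submodels;
`variant = "two-stage"` fits the longitudinal side by plain maximum
likelihood (internal profile-likelihood optimizer) and boosts only the
survival side — much faster when interest is in the time-to-event model.

A synthetic-data generator (`simulate_joint()`) draws joint data from this
exact model with inversion-sampled event times under the baseline hazard
`2.5 t^1.5` and calibrated ~50% censoring, so every claim the package
makes is testable without external data.

## Worked example

```r
library(boostjm)

cfg <- sim_config(n = 200, n_i = 5, p_l = 6, p_s = 6,
                  beta_l = c(1, 2, 1), beta_s = c(1, 2, -2), seed = 42)
sim <- simulate_joint(cfg)   # 3 informative + 3 noise covariates per submodel
sim
#> <sim_joint> n = 200  n_i = 5  censoring = 54 %

jd  <- as_joint_data(sim)
ctl <- boost_control(m_max_s = 200, grid_l = c(25, 50), m_max_l = 50,
                     K = 8, cv_folds = 5, seed = 1)
fit <- jm_boost(jd, ctl, variant = "two-stage")
fit
#> <jm_boost_fit> variant: two-stage
#>   stopping tuple: m_l = NA  m_s = 187
#>   alpha = 0.2737   joint logLik = 1075
#>   selected covariates: longitudinal 6 / 6 , survival 3 / 6

tidy(fit)
#> # A tibble: 15 × 4
#>    submodel term        estimate selected
#>  1 long     (Intercept)   1.04   TRUE
#>  2 long     time          2.03   TRUE
#>  3 long     x_l1          0.973  TRUE
#>  4 long     x_l2          1.93   TRUE
#>  5 long     x_l3          1.06   TRUE
#>  ...
#>  9 surv     alpha         0.274  TRUE
#> 10 surv     x_s1          0.636  TRUE
#> 11 surv     x_s2          1.04   TRUE
#> 12 surv     x_s3         -1.17   TRUE
#> 13 surv     x_s4          0      FALSE

evaluate_selection(fit, sim$truth)
#> # A tibble: 2 × 5
#>   submodel    tp   fdr n_informative n_selected
#> 1 long         1   0.5             3          6
#> 2 surv         1   0               3          3
```

Reading the output: the two-stage first stage is unregularized maximum
likelihood, so all six longitudinal coefficients are nonzero (the three
noise effects are near zero); boosting with early stopping on the survival
side selects exactly the three informative covariates (TP = 1, FDR = 0)
and shrinks their effects and the association α toward zero — the expected
behaviour of a regularized full-likelihood fit. `autoplot(fit)` draws the
coefficient paths, `plot_cv_surface(fit)` the cross-validated likelihood
over the stopping iterations.

A thin command-line interface ships in `exec/boostjm`
(`simulate`, `fit`, `cv`, `evaluate` subcommands).

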