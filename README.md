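# spslreg

Instrumental-variable dose–response analysis for randomized trials via a
Stein-like combination of OLS and two-stage least squares.

## The problem

In psychotherapy trials, the *dose* of treatment — e.g. the number of
sessions a patient attends — is chosen partly by the patient, so it is
correlated with unmeasured prognostic factors: it is an **endogenous**
predictor, and ordinary least squares (OLS) estimates of the dose effect
are biased. Randomized treatment offer and its interactions with baseline
covariates provide **instrumental variables**, and two-stage least squares
(TSLS) removes the bias — at the cost of (sometimes much) larger variance,
especially when the instruments are weak.

`spslreg` fits both and combines them. The **semi-parametric Stein-like
(SPSL) estimator** is the affine combination

```
b_spsl = alpha * b_tsls + (1 - alpha) * b_ols
```

with the weight chosen to minimize the estimated trace mean squared error
tr[a² MSE(b_tsls) + 2a(1−a) CSE + (1−a)² MSE(b_ols)], where CSE is the
cross squared error coupling the two estimators. Empirically the TSLS fit
is shrunk toward OLS by the Stein factor
τ̂ / ‖b_ols − b_tsls‖² (τ̂ = estimated TSLS variance excess), with the
standard positive-part truncation so the combination never overshoots past
OLS: weak instruments push the fit toward OLS, strong instruments and
clear confounding toward TSLS.

The package also provides:

* first-stage partial-F instrument diagnostics and pairs-bootstrap SEs;
* a standardized trial simulator with controlled endogeneity
  (η = Cor(S, U)) and instrument strength (κ = Cor(S, B + R + RB)), plus a
  Monte Carlo evaluation harness;
* chained-equations multiple imputation with Rubin's-rules pooling for
  incomplete outcomes;
* a command-line interface (`fit`, `simulate`, `mc`, `impute-fit`).

## Worked example

Simulate a 400-subject two-arm trial with strong confounding and strong
instruments (true standardized dose effect 0.25), then fit all three
estimators with the two-part formula interface (`outcome ~ predictors |
instruments`; shared terms are the exogenous block):

```r
library(spslreg)

d <- simulate_trial(solve_scenario(scenario(eta = 0.5, kappa = 0.5, n = 400)),
                    seed = 42)
fit <- spsl(Y ~ S + B - 1 | R + R:B + B - 1, data = d)
fit
#> Stein-like combined instrumental-variable fit
#> Call: spsl(formula = Y ~ S + B - 1 | R + R:B + B - 1, data = d)
#> n = 400, endogenous: S
#>       OLS   TSLS   SPSL
#> S  0.5943 0.2639 0.3033
#> B -0.0034 0.2461 0.2164
#> alpha_hat = 0.8809
```

The confounded OLS dose effect (0.59) is badly biased upward; TSLS (0.26)
is close to the truth; with a first-stage F of 33.9 the instruments are
strong, the estimated weight on TSLS is 0.88, and the SPSL estimate (0.30)
sits near TSLS while borrowing stability from OLS.

```r
first_stage_f(as_regression_data(d))
#> First-stage partial F for S: F = 33.87, df1 = 2, df2 = 397, p = 2.62e-14

bootstrap_se(as_regression_data(d), "SPSL", B = 1000, seed = 1)
#>      S      B
#> 0.1323 0.1320
```

`run_monte_carlo(scenario(...), m, seed)` repeats this over many simulated
trials and reports bias, variance and RMSE per estimator; across the full
η × κ grid the SPSL trace RMSE never exceeds the TSLS one, and its weight
on TSLS grows with instrument strength.

For incomplete outcomes, `ampute_mar()` / `impute_chained()` /
`pool_rubin()` (or the one-call `impute_fit()`) implement multiple
imputation with Rubin's-rules pooled standard errors.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "spsl.R", package = "spslreg"))')
Rscript "$CLI" fit --data trial.csv --outcome Y --endogenous S \
        --exogenous B --instruments R,RB --estimator all \
        --bootstrap 1000 --seed 1 --out fits.json
```

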