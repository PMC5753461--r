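# hccscreen

Longitudinal biomarker screening algorithms for hepatocellular carcinoma
(HCC) surveillance, with the evaluation framework needed to compare them on
serial screening data.

Patients with cirrhosis are screened for HCC at repeated visits, most
commonly with serum α-fetoprotein (AFP). The standard rule — flag a visit
when AFP exceeds a fixed population threshold — ignores both the patient's
own AFP history and routinely co-measured laboratory values. This package
implements two alternatives and the machinery to evaluate all three on
longitudinal cohorts:

* **Parametric empirical Bayes (PEB) rule.** Control-population AFP follows
  a random-intercept model on the log2 scale,
  Y<sub>ij</sub> | θ<sub>i</sub> ~ N(θ<sub>i</sub>, σ²),
  θ<sub>i</sub> ~ N(θ̄, τ²). After standardizing
  Z<sub>ij</sub> = (Y<sub>ij</sub> − θ̄)/√(σ² + τ²), screen *j* of patient
  *i* is positive when

  Z<sub>ij</sub> > μ̂<sub>ij</sub> + z<sub>1−f₀</sub> √(1 − B₁B<sub>j</sub>),

  where μ̂<sub>ij</sub> = B<sub>j</sub> Z̄<sub>ij</sub> shrinks the mean of
  the patient's prior standardized values toward 0,
  B<sub>j</sub> = τ²/(σ²/(j−1) + τ²), and B₁ = τ²/(σ² + τ²) is the
  intra-class correlation of repeated log2(AFP). The rule holds the
  per-screen false positive rate at f₀ at every screen index and learns
  from a patient's prior false positives.

* **Six-month risk prediction model.** A logistic model of HCC diagnosis
  within six months of a visit on linear-spline (hinge) bases of log2(AFP),
  log2(ALT), platelets, age, AFP×ALT and AFP×PLT interactions, and the
  annualized rate of change of log2(AFP) when the previous test is within
  a year. It is fitted by cross-sectional resampling — one random visit per
  patient per iteration, 100 iterations — and predictions average the 100
  per-iteration logistic risks.

Both algorithms sit inside an **OR rule** (AFP ≥ 400 ng/ml always refers to
imaging) and are evaluated longitudinally: patient-level true positive rate
within a detection window (τ₁, τ₂) months before diagnosis, screening-level
false positive rate, predictive values, risk-percentile curves, decile
risk, first-positive timing and per-patient false-positive burden. A
synthetic cohort generator with the assumed random-intercept structure
(defaults: θ̄ = 2.92, σ² = 0.71, τ² = 1.90, so ICC = 0.73; ~12 months
between visits) makes the whole pipeline testable without registry access.

## Worked example

```r
library(hccscreen)

cfg <- sim_config(n_controls = 1000, n_cases = 150)
experiment <- run_experiment(cfg, algorithms = c("afp_only", "peb"),
                             windows = c("C1", "D1"), fpr_target = 0.10,
                             calibrate_on = "validation", seed = 42)
experiment
#> <hcc_experiment> afp_only + peb on 575 training / 575 validation patients (FPR target 0.10, calibrated on validation)
#> # A tibble: 4 × 8
#>   algorithm window   tpr    fpr   ppv   npv burden n_cases
#>   <chr>     <chr>  <dbl>  <dbl> <dbl> <dbl>  <dbl>   <int>
#> 1 afp_only  C1     0.347 0.0997 0.21  0.928 0.0299      75
#> 2 peb       C1     0.493 0.0997 0.248 0.935 0.0168      75
#> 3 afp_only  D1     0.347 0.0997 0.251 0.875 0.03        75
#> 4 peb       D1     0.493 0.0997 0.277 0.879 0.018       75

experiment$first_positive
#> # A tibble: 1 × 6
#>   algorithm_a algorithm_b first_a first_b  same n_cases
#>   <chr>       <chr>         <dbl>   <dbl> <dbl>   <int>
#> 1 afp_only    peb           0.125   0.375   0.5      40
```

Reading the tables: at a matched 10% screening-level false positive rate
the PEB rule detects 49% of the 75 evaluable HCC cases within two years of
diagnosis (window C1) against 35% for the fixed AFP threshold, concentrates
false positives in fewer patients (1.7% vs 3.0% of patients with more than
two false positives), and among cases flagged by either rule it is first
at 37.5% of cases versus 12.5% (50% flagged at the same visit). The fitted
PEB parameters are in `experiment$fits$peb`:

```r
experiment$fits$peb
#> <peb_params> theta_bar = 2.9952, sigma2 = 0.7227, tau2 = 2.2559 (ICC/B1 = 0.757)
```

Percentile curves and plots:

```r
scores <- dplyr::filter(experiment$scores, algorithm == "peb")
curves <- performance_curves(scores, detection_window("C1"))
autoplot(curves)
plot_decile_risk(decile_risk(scores, detection_window("C1")))
```

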