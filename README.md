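# ursaconflict

Tools for asking whether hunting controls human–bear conflicts *through
population size*: an R implementation of the full inference chain from a
hunted black bear population's age-at-harvest records to a ranked set of
linear models explaining yearly complaint counts.

The package is aimed at wildlife biologists and quantitative ecologists who
work with harvest-based population monitoring. Its components are:

* **Harvest-record cleaning** — correct hunter sex-misreporting of females
  (reported female totals are rescaled by `1/(1 − r)`, default `r = 0.11`,
  with the excess moved out of the male records proportionally to the male
  age distribution), pool ages into a plus group (default 3+), and build
  the previous-year total-kill covariate (PREVKILL).
* **Population reconstruction** — a cohort-based (Downing-style)
  virtual-population estimator: the pre-hunt abundance of a birth cohort at
  age *a* is its cumulative observed harvest at ages ≥ *a*,

  N̂_c(a) = Σ_{a′ ≥ a} H_c(a′),

  scaled up for non-hunting mortality (estimates divided by `1 − f`,
  default `f = 0.35`), with the last 2 data years flagged unreliable and
  the 6+-year-old-female count (POPF6) withheld for the last 5.
* **Food index** — yearly natural-food ratings from categorical surveys:
  per species, the product of 0–4 abundance and production scores,
  respondent-averaged, summed over 14 species; plus a poor/normal/abundant
  categorization.
* **Complaint imputation** — total complaints in years when only on-site
  visits were recorded, via a linear regression of the phone-handled
  fraction on calendar year through anchor years: `total = onsite/(1 − p̂)`.
* **Model competition** — multiple linear regression of COMPLAINTS on
  POP / FOOD / POLICY / PREVKILL / POPLEVEL / POPF6 candidates, ranked by
  small-sample AIC with explicit formulas,

  AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1),  w_i = exp(−Δ_i/2) / Σ_j exp(−Δ_j/2),

  with k = slopes + 2, adjusted R², variance inflation factors and
  residual-ACF diagnostics.
* **Synthetic data** — an individual-based simulator of a harvested,
  age-structured population (births → natural deaths → pre-hunt census →
  harvest) whose default trajectory roughly doubles from 10,000 and then
  halves over four decades, with sex misreporting, masked phone complaints
  and respondent-level food surveys, so every estimator can be validated
  against known truth.

## Worked example

```r
library(ursaconflict)
res <- run_pipeline(sim_config(seed = 1), verbose = FALSE)
print(res)
#> conflict_pipeline over 39 years
#> top model, set 1: POP + FOOD + POLICY (adj R2 0.89, weight 0.50)
#> top model, set 2: POP + FOOD + POLICY (adj R2 0.89, weight 0.30)

res$aicc1   # candidate models within 4 AICc units of the best, set 1
#>                           model k  n  AICc delta weight cum_weight   r2 adj_r2
#>             POP + FOOD + POLICY 5 36 523.2   0.0   0.50       0.50 0.90   0.89
#>  POP + FOOD + POLICY + PREVKILL 6 36 524.2   1.0   0.31       0.80 0.91   0.90
#>  POP + FOOD + POLICY + POPLEVEL 6 36 526.1   2.8   0.12       0.93 0.90   0.89

res$diagnostics$set1$vif
#>      POP     FOOD   POLICY
#> 1.220193 1.031967 1.237041
```

The simulated complaints were generated as a linear function of population
size (positive), food rating (negative — bears seek human foods when wild
foods fail) and the policy indicator (negative), plus noise; the
competition correctly puts that structure at ΔAICc = 0, explains ~90% of
year-to-year variance, shows no collinearity concern (all VIF < 1.3), and
the previous-year kill enters only as an uninformative extra parameter
(ΔAICc ≈ +1 with no adjusted-R² gain) — the same qualitative pattern the
method is designed to detect in real harvest systems. The reconstruction
covariates driving this fit end two years before the last simulated
harvest, and the lag-1 residual autocorrelation (0.12) sits well inside the
white-noise bounds (±0.33).

Individual stages are available directly: `correct_sex()`, `pool_ages()`,
`build_prevkill()`, `reconstruct()`, `adjust_nonharvest()`,
`derive_covariates()`, `species_score()`, `yearly_rating()`,
`categorize_years()`, `fit_phone_trend()`, `impute_totals()`,
`assemble_design()`, `fit_ols()`, `akaike_table()`, `vif()`, `acf_check()`,
and the simulator pair `simulate_truth()` / `render_observables()`. See the
vignette (`vignettes/bear-complaint-pipeline.Rmd`) for the models, design
choices and validation strategy.

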