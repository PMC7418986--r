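---
title: "From age-at-harvest records to complaint models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From age-at-harvest records to complaint models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ursaconflict)
```

## The problem

Wildlife agencies that manage a hunted black bear population receive yearly
complaint calls about bears — garbage raids, birdfeeders, property damage,
perceived threats. Whether hunting controls such conflicts *through
population size* is hard to test: it needs a long complaint series, a
population trajectory estimated independently of the complaints, a measure
of natural food conditions (scarce wild food drives bears toward people),
and a way of coping with changes in how complaints were recorded.
`ursaconflict` implements that full chain as reusable, tested components:

1. clean age-at-harvest records (sex-misreport correction, plus-group
   pooling, previous-year kill),
2. reconstruct the pre-hunt population trajectory from those records,
3. index yearly natural-food abundance from categorical surveys,
4. impute complaint totals for years when only on-site visits were logged,
5. rank linear complaint models by small-sample AIC.

Every step can be exercised on data from the package's individual-based
simulator, so each estimator is validated against known truth rather than
against another estimator.

## Population reconstruction

The data are counts of harvested bears by year, sex and exact age (ages
read from tooth cementum annuli). Under the virtual-population identity —
every animal alive at some census eventually appears in the harvest record —
the pre-hunt abundance of a birth cohort at age $a$ equals the cohort's
cumulative harvest at ages $\ge a$:

$$\hat N_{c}(a) \;=\; \sum_{a' \ge a} H_{c}(a'),$$

where $H_c(a')$ is the observed harvest of cohort $c$ at age $a'$ within
the data window. `reconstruct()` computes this per sex on exact ages and
pools ages at or above `plus_age` (default 3) for reporting.

Three practical corrections surround the identity:

* **Sex misreporting.** Hunters misreport a fraction $r$ of harvested
  females as males (the working default is $r = 0.11$, estimated in the
  field from known-sex radio-collared bears), and essentially never the
  reverse. `correct_sex()` rescales each year's female total to
  $F' = F/(1-r)$ and moves the excess out of the male records,
  proportionally to the male age distribution that year — the misreported
  females sit in the male column, so their ages are distributed like
  recorded males. The correction is a deterministic totals-level rescaling
  (not a probabilistic back-assignment), conserves yearly grand totals
  exactly, and commutes with plus-group pooling; corrected counts may be
  fractional, which the downstream arithmetic accepts.
* **Reliability window.** Recent cohorts have had little time to be
  harvested, so the last `reliable_offset` (default 2) data years are
  dropped outright rather than down-weighted: data through year $T$ support
  covariates through $T-2$. The count of females aged 6+ (POPF6)
  accumulates old-female harvests over many more future years, so it is
  withheld for the final `popf6_offset` (default 5) data years.
* **Non-hunting mortality.** Reconstruction counts only bears that die by
  harvest. If a fraction $f$ of total mortality is non-hunting (default
  $f = 0.35$), `adjust_nonharvest()` divides every cell by $1-f$. The
  scale-up is uniform across years, so year-to-year ratios — the shape the
  complaint models consume — are untouched; it is applied to all cells
  before composition summaries, which is equivalent for any ratio.

The estimator is a *minimum-population* method: animals alive at the end of
the data, or dying of unobserved causes at rates that vary over time, are
missed. Its contract is therefore trend fidelity over reliable years, not
absolute abundance; the validation below measures exactly that. Levels near
the end of the series are biased low because cohorts still alive contribute
nothing yet — a further reason the terminal years are excluded.

## Food index

Each year, observers score each of 14 fruit-producing species (or species
groups) twice on integer 0–4 scales: prevalence (`abundance`) and fruit
crop (`production`). The two are multiplied (0–16), averaged over
respondents per species, and summed over species, giving a yearly rating
in [0, 224]. All 14 species must be scored — a missing species is an error,
not an imputation target. The species are equally weighted, and the known
non-linearity of the 0–4 production scale (each step represents roughly
2–4 times the fruit biomass of the one below) is deliberately not rescaled:
the index is used as the quantitative covariate exactly as collected.

`categorize_years()` labels years poor / normal / abundant. No canonical
cutpoints exist for this survey, so the default is empirical terciles of
the observed ratings with ties resolved toward "normal" (so a degenerate
all-equal series is all "normal"); fixed numeric cutpoints can be supplied
when an agency has its own convention.

## Complaint imputation

In early record-keeping years only complaints that triggered an on-site
visit were logged; later, phone-only handling was recorded too, and its
share grew roughly linearly. `fit_phone_trend()` fits ordinary least
squares of the phone-handled fraction on calendar year through the anchor
years where both counts exist (by default 1984–85 and 1996–98, the pattern
of roughly 59–61% rising to 74–77%); `impute_totals()` then estimates each
masked year's total as $\mathrm{onsite}/(1-\hat p)$. The regression is on
the raw fraction, matching the straight-line treatment the anchors support
over an in-range span; a logit link is available for extrapolation-heavy
uses. Predictions outside $[0, 1)$ for a masked year are an error — the
trend must not be extrapolated out of range silently.

## Model competition

`assemble_design()` aligns COMPLAINTS with POP, FOOD, PREVKILL (previous
year's harvest plus nuisance kills — undefined in the first data year,
which is dropped), POLICY (0 before the policy year, 1 from it onward;
default 1998 even though the policy phased in over three years), and either
POPLEVEL (indicator of POP above 15,000; candidate set 1) or POPF6
(candidate set 2, whose span is shorter because POPF6 is withheld near the
series end).

`fit_ols()` wraps `stats::lm()` and records the Gaussian maximum-likelihood
log-likelihood computed from the residual sum of squares,

$$\ell = -\tfrac{n}{2}\left(\log 2\pi + \log \tfrac{RSS}{n} + 1\right),$$

with the full constant retained (constants cancel in differences and
weights, but absolute AICc values then match the standard convention). The
parameter count is $k = \text{slopes} + 2$: intercept and residual variance
both count, so a four-slope model has $k = 6$.

`akaike_table()` computes, from explicit formulas,

$$AICc = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}, \qquad
  w_i = \frac{e^{-\Delta_i/2}}{\sum_j e^{-\Delta_j/2}},$$

ranks models, accumulates weights in rank order, and reports rows with
$\Delta AICc$ at or below a cutoff (default 4 in the pipeline). Weights are
normalized over the full candidate set before any cutoff is applied.

The candidate sets are user-overridable; the defaults are every subset
containing a population measure: set 1 is POP plus all subsets of
{FOOD, POLICY, PREVKILL, POPLEVEL} (16 models), set 2 is every non-empty
combination of {POP, POPF6} crossed with subsets of {FOOD, POLICY,
PREVKILL} (24 models). Candidates that are unidentifiable on a particular
data set (e.g. POPLEVEL constant over the span) are skipped with a warning
rather than aborting the competition.

Diagnostics are computed from their defining formulas: variance inflation
factors $VIF_j = 1/(1-R^2_j)$ from regressing predictor $j$ on the others
(reported as `Inf` under perfect collinearity), and the residual
autocorrelation function with approximate white-noise bounds
$\pm 1.96/\sqrt{n}$. No multiple-testing correction is applied anywhere:
the analysis is information-theoretic ranking, not hypothesis testing.

## The synthetic-data generator

`simulate_truth()` runs an individual-based yearly cycle — births, natural
deaths, pre-hunt census, harvest — recording every individual's sex, birth
year and fate. The census sits after natural mortality and before harvest
because that is the quantity age-at-harvest reconstruction estimates.
Individual fates (rather than a matrix projection) make exact oracle
tallies possible: the true pre-hunt abundance is literally a count over
individual records.

The default configuration emulates a four-decade statewide system: about
10,000 bears split evenly by sex across a geometric age structure; light
harvest for the first 14 years so the population roughly doubles; heavy
harvest for the next 13 so it roughly halves again; partial relaxation
after that. Yearly natural-food ratings are drawn around a mean of 66
(s.d. 7) with episodic failure years (probability 0.2, rating dropped
by 20), reproducing both the typical level and the episodic-failure
character of categorical food surveys; in a poor-food year (rating below
55) harvest rates are multiplied by 1.35, since scarce wild food makes
bears more vulnerable over bait. Female reproduction is annual (expected
1.05 cubs per adult female from age 4) rather than biennial; reconstruction
and regression are insensitive to reproductive scheduling, only to the
resulting abundance path.

`render_observables()` applies the observation process: each harvested
female is independently relabelled male with probability 0.11; true
complaint totals — generated as a linear function of population size, food
rating and policy period plus Gaussian noise on the count scale (intercept
1700, 0.2 per bear, −30 per rating unit, −500 under the new policy, s.d.
300), rounded and clipped at zero — are split into phone and on-site counts
by a linear phone-fraction trend and the phone counts are withheld in the
masked years (1981–83 and 1986–95 by default); nuisance kills are drawn as
a fraction of complaints (7% before the policy change, 4% after); and the
latent food rating is rendered as a respondent-level survey in which both
0–4 scores are Binomial(4, q) draws with $16q^2$ equal to the species'
share of the yearly rating, so the survey index is unbiased for the latent
rating. A `deterministic` phone-split mode divides counts exactly by the
trend fraction, which makes imputation round-trips exact and is used in
tests. The linear complaint model is a modelling choice for the generator —
the field data carry no generative model for complaints — so end-to-end
tests show recovery of a known linear structure, not that real complaints
are linear.

What the generator does *not* emulate: spatial structure and local
hotspots, bait-site behaviour and learning, crop-field dynamics,
translocation, under-recording by busy staff, and the link between
nuisance kills and specific individuals (kills are drawn as counts, not
removed from the population; they are small relative to it). Passing tests
therefore demonstrate the estimators' correctness under the stated
generative assumptions, not the realism of those assumptions.

## Validation design and problem sizes

The test suite ties every estimator to an independent oracle:

* **Exact reconstruction oracle.** In a harvest-only world (no births, no
  natural mortality, harvest probability 0.5, starting ages 0–8 so nobody
  ages out of the 0–30 range) every individual is all but surely harvested
  within a 40-year window, and reconstruction must equal the individual-
  level tally cell by cell, exactly. Problem size: 5,000 individuals over
  40 years.
* **Trend recovery.** 100 replicates, each with a constant harvest rate
  drawn uniformly from 0.15–0.25 and adult natural mortality from 0.10–0.20
  (cub mortality doubled). The study-shaped trajectory — growth, decline,
  plateau — is driven through recruitment (birth-rate multipliers 1.3 /
  0.75 / 1.0 across the three eras) rather than through the harvest rate,
  for two reasons: the trend-fidelity contract of a virtual-population
  method assumes the eventually-harvested fraction is stable, which holds
  when mortality rates are constant, and food-driven swings in reproduction
  are a realistic trend mechanism for this species. The baseline birth rate
  is set to the stationary value for the drawn rates via a deterministic
  expected-value projection of the simulator's yearly cycle (breeding from
  age 2 in these replicates, so the tested harvest range is demographically
  sustainable). Starting abundance 8,000. The acceptance contract is a
  median Pearson correlation of at least 0.95 between adjusted POP and the
  true pre-hunt totals over reliable years.
* **Model-competition recovery.** Covariates come from one default
  simulated trajectory (n = 36 design years); responses are regenerated 200
  times under the set-1 top-model structure with coefficients 1700
  (intercept), 0.2 (POP), −40 (FOOD), −900 (POLICY), 1700 (POPLEVEL) and
  residual s.d. 650. The residual scale matches the between-year spread
  implied by the study system at this complaint magnitude; each slope was
  then sized *a priori* so its partial t-statistic on the realized
  covariates is near 3.5 — clearly detectable but not overwhelming, given
  in particular the collinearity of POPLEVEL with POP. A weaker effect
  makes "recovery" meaningless (an information criterion *should* prefer
  dropping an undetectable term), a much stronger one makes the check
  trivial. The contract is that the generating model attains
  $\Delta AICc = 0$ in at least 70% of replicates.
* **Imputation round-trip.** With the deterministic phone split and masked
  years 1981–83/1986–95, imputed totals must equal true totals to numerical
  precision.
* **End-to-end sign recovery.** 100 full pipeline runs on 35-year,
  800-bear simulations with low complaint noise (s.d. 50) must recover the
  generating signs of POP, FOOD and POLICY in the fitted top model in at
  least 95% of replicates. The smaller population keeps the suite fast;
  the complaint coefficients are rescaled accordingly (intercept 2500,
  2 per bear) so expected complaints stay positive at that scale, and the
  POPLEVEL threshold is set to 1,000 so the indicator varies over the span.

The replicate counts and population sizes above were chosen as the smallest
problem sizes at which the stochastic contracts are stable from seed to
seed.

## Numerical choices and degenerate inputs

* Sex correction errors (naming the year) when a year's male harvest
  cannot absorb the shift; it does not clip.
* `build_prevkill()` refuses gaps inside the year span — no silent filling.
* Tercile ties go to "normal"; an all-equal rating series is all "normal".
* A perfect linear fit (RSS numerically zero) reports $R^2 = 1$ and an
  infinite log-likelihood; ranking such a model against others is
  meaningless and `akaike_table()` will rank it first by construction.
* `AICc` requires $n - k - 1 > 0$ and errors otherwise; VIF reports `Inf`
  under perfect collinearity instead of erroring; the ACF requires at
  least 5 residuals and errors on constant residuals.
* Imputation errors when a masked year's predicted phone fraction falls
  outside $[0, 1)$; exactly 0 is allowed (the total is then the on-site
  count).
* Population extinction inside the simulated span truncates the output
  with a warning rather than erroring, so downstream code sees a shorter
  but well-formed series.

## Limitations

Reconstruction uncertainty is not quantified (the method yields point
trajectories); the non-hunting-mortality fraction is treated as constant
over four decades; the candidate model lists, while covering every model
the defaults are meant to support, are linear in the numeric food rating
only; and the simulator's complaint process is a stand-in. Where real
age-at-harvest data are analysed, the reconstruction's absolute level
should be corroborated against independent estimates (mark–recapture or
integrated models) before being interpreted as abundance rather than
trend.
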