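#' Simulation configuration for a harvested, age-structured population
#'
#' Builds the configuration object consumed by [simulate_truth()] and
#' [render_observables()]. Defaults describe a four-decade statewide black
#' bear system: roughly 10,000 bears at the start, light harvest through the
#' 1980s so the population about doubles, then heavy harvest from the
#' mid-1990s that roughly halves it again, annual categorical food surveys
#' with episodic failure years, a nuisance-policy change in 1998, and
#' complaint counts linear in population size, food rating and policy.
#'
#' @param years Integer vector of consecutive calendar years (span >= 5).
#' @param initial_total Total abundance at the start of the first year,
#'   split 50/50 by sex across a geometric stable age distribution. Ignored
#'   when `initial_abundance` is supplied.
#' @param initial_abundance Optional data frame with columns `sex` ("F"/"M"),
#'   `age` (integer years) and `count` (non-negative integers) giving the
#'   starting population explicitly.
#' @param birth_rate Expected cubs per adult female per year.
#' @param birth_year_multiplier Optional named numeric vector (names =
#'   years) scaling the birth rate per year, e.g. to emulate food-driven
#'   swings in reproduction; defaults to 1 everywhere.
#' @param breeding_age Minimum female age (years) for reproduction.
#' @param natural_mortality Per-year natural mortality probability by age;
#'   either a scalar or a vector indexed by age 0, 1, 2, ... (last element
#'   recycled for older ages). Individuals older than `max_age` die.
#' @param max_age Maximum attainable age in years.
#' @param harvest_rate_base Baseline per-year harvest probability.
#' @param harvest_year_multiplier Named numeric vector (names = years)
#'   scaling the baseline harvest rate per year; defaults to a low-then-high
#'   schedule that produces the double-then-halve trajectory.
#' @param harvest_sex_multiplier Named numeric `c(F = , M = )` scaling
#'   harvest rates by sex (males are more vulnerable to hunting).
#' @param harvest_age_multiplier Harvest-rate multiplier by age (vector
#'   indexed by age 0, 1, ...; last element recycled). Cubs are rarely shot.
#' @param food_mean,food_sd Mean and standard deviation of the yearly
#'   natural-food rating in non-failure years (survey-index scale, 0-224).
#' @param food_failure_prob Probability that a year is a food-failure year.
#' @param food_failure_drop Amount subtracted from the rating in failure years.
#' @param poor_food_threshold Rating below which a year counts as a poor food
#'   year for hunter-bait attraction.
#' @param food_effect_on_harvest Multiplier applied to harvest rates in poor
#'   food years (bears hit baits harder when wild food is scarce).
#' @param sex_misreport_rate Probability that a harvested female is recorded
#'   as male.
#' @param policy_change_year First calendar year of the revised nuisance
#'   policy.
#' @param complaint_coefficients Named list with elements `intercept`, `pop`
#'   (slope per bear), `food` (slope per rating unit), `policy` (shift under
#'   the new policy) and `sd` (Gaussian noise standard deviation on the
#'   count scale).
#' @param phone_fraction_trend Named numeric `c(intercept = , slope = )` for
#'   the fraction of complaints handled by phone as a linear function of
#'   calendar year.
#' @param phone_split `"binomial"` draws recorded phone complaints
#'   binomially; `"deterministic"` splits exactly by the trend fraction
#'   (fractional counts), which makes imputation round-trips exact.
#' @param masked_phone_years Years in which phone-handled complaints go
#'   unrecorded (observed series keeps on-site counts only).
#' @param nuisance_kill_rate Named numeric `c(pre = , post = )`: fraction of
#'   complaints resulting in a bear killed, before/after the policy change.
#' @param n_species Number of fruit-producing species (groups) surveyed.
#' @param n_respondents Survey respondents per species-year.
#' @param seed Integer seed; all randomness in the simulator derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$years[1:5]
sim_config <- function(years = 1981:2019,
                       initial_total = 10000,
                       initial_abundance = NULL,
                       birth_rate = 1.05,
                       birth_year_multiplier = NULL,
                       breeding_age = 4,
                       natural_mortality = c(0.2, rep(0.1, 30)),
                       max_age = 30,
                       harvest_rate_base = 0.15,
                       harvest_year_multiplier = NULL,
                       harvest_sex_multiplier = c(F = 0.85, M = 1.15),
                       harvest_age_multiplier = c(0.3, rep(1, 30)),
                       food_mean = 66,
                       food_sd = 7,
                       food_failure_prob = 0.2,
                       food_failure_drop = 20,
                       poor_food_threshold = 55,
                       food_effect_on_harvest = 1.35,
                       sex_misreport_rate = 0.11,
                       policy_change_year = 1998,
                       complaint_coefficients = list(intercept = 1700,
                                                     pop = 0.2,
                                                     food = -30,
                                                     policy = -500,
                                                     sd = 300),
                       phone_fraction_trend = c(intercept = -25.0036,
                                                slope = 0.0129),
                       phone_split = c("binomial", "deterministic"),
                       masked_phone_years = c(1981:1983, 1986:1995),
                       nuisance_kill_rate = c(pre = 0.07, post = 0.04),
                       n_species = 14,
                       n_respondents = 25,
                       seed = 1L) {
  stopifnot(is.numeric(years), length(years) >= 5,
            all(diff(years) == 1))
  years <- as.integer(years)
  phone_split <- match.arg(phone_split)

  if (is.null(initial_abundance)) {
    initial_abundance <- .stable_initial_abundance(initial_total, max_age)
  }
  stopifnot(is.data.frame(initial_abundance),
            all(c("sex", "age", "count") %in% names(initial_abundance)))
  if (any(initial_abundance$count < 0) ||
      any(initial_abundance$count != round(initial_abundance$count))) {
    stop("initial abundances must be non-negative integers")
  }

  probs <- c(natural_mortality, harvest_rate_base, sex_misreport_rate,
             food_failure_prob, nuisance_kill_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  stopifnot(birth_rate >= 0, food_effect_on_harvest > 0,
            is.numeric(policy_change_year), length(policy_change_year) == 1)

  if (is.null(harvest_year_multiplier)) {
    harvest_year_multiplier <- .default_harvest_schedule(years)
  }
  if (is.null(names(harvest_year_multiplier)) ||
      !all(as.character(years) %in% names(harvest_year_multiplier))) {
    stop("harvest_year_multiplier must be named by every simulated year")
  }
  if (is.null(birth_year_multiplier)) {
    birth_year_multiplier <- stats::setNames(rep(1, length(years)),
                                             as.character(years))
  }
  if (is.null(names(birth_year_multiplier)) ||
      !all(as.character(years) %in% names(birth_year_multiplier))) {
    stop("birth_year_multiplier must be named by every simulated year")
  }

  cfg <- list(years = years,
              initial_abundance = initial_abundance,
              birth_rate = birth_rate,
              birth_year_multiplier = birth_year_multiplier,
              breeding_age = as.integer(breeding_age),
              natural_mortality = natural_mortality,
              max_age = as.integer(max_age),
              harvest_rate_base = harvest_rate_base,
              harvest_year_multiplier = harvest_year_multiplier,
              harvest_sex_multiplier = harvest_sex_multiplier,
              harvest_age_multiplier = harvest_age_multiplier,
              food_mean = food_mean,
              food_sd = food_sd,
              food_failure_prob = food_failure_prob,
              food_failure_drop = food_failure_drop,
              poor_food_threshold = poor_food_threshold,
              food_effect_on_harvest = food_effect_on_harvest,
              sex_misreport_rate = sex_misreport_rate,
              policy_change_year = as.integer(policy_change_year),
              complaint_coefficients = complaint_coefficients,
              phone_fraction_trend = phone_fraction_trend,
              phone_split = phone_split,
              masked_phone_years = intersect(masked_phone_years, years),
              nuisance_kill_rate = nuisance_kill_rate,
              n_species = as.integer(n_species),
              n_respondents = as.integer(n_respondents),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Geometric stable age structure (annual survival ~0.8), sexes even.
.stable_initial_abundance <- function(total, max_age) {
  s <- 0.8
  w <- s^(0:max_age)
  w <- w / sum(w)
  per_sex <- round(total / 2 * w)
  data.frame(sex = rep(c("F", "M"), each = max_age + 1),
             age = rep(0:max_age, 2),
             count = rep(per_sex, 2),
             stringsAsFactors = FALSE)
}

# Low harvest pressure first, a heavy-harvest era from the mid-1990s, then a
# partial relaxation: the schedule that drives growth, decline and slow
# recovery in the default trajectory.
.default_harvest_schedule <- function(years) {
  n <- length(years)
  rel <- seq_along(years)
  mult <- rep(1, n)
  mult[rel <= 14] <- 0.45                 # growth era
  mult[rel > 14 & rel <= 27] <- 1.28      # reduction era
  mult[rel > 27] <- 0.78                  # partial relaxation
  names(mult) <- as.character(years)
  mult
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", length(x$years), "years (",
      x$years[1], "-", x$years[length(x$years)], "), initial N =",
      sum(x$initial_abundance$count),
      ", seed =", x$seed, "\n")
  invisible(x)
}
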