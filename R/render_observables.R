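#' Derive observed data streams from simulated truth
#'
#' Applies the observation process to a [simulate_truth()] result: harvested
#' individuals become age-at-harvest records with a fraction of females
#' recorded as males; true complaint totals are split into phone-handled and
#' on-site-visited counts by a linear phone-fraction trend, with phone counts
#' withheld in the configured masked years; nuisance-kill counts are drawn as
#' a fraction of complaints; and the latent yearly food rating is rendered as
#' a respondent-level categorical survey (14 species, paired 0-4 abundance
#' and production scores whose product, respondent-averaged and summed over
#' species, has the latent rating as its expectation).
#'
#' Misreporting relabels sex but never changes counts, so observed yearly
#' harvest totals equal true harvest totals.
#'
#' @param truth A `sim_truth` object.
#' @param config The [sim_config()] used to generate it.
#' @return An object of class `observed_data`: a list with
#'   \describe{
#'     \item{age_harvest}{data frame `(year, sex, age, count)` of recorded
#'       harvests (sex as reported by hunters).}
#'     \item{yearly}{data frame `(year, complaints_onsite, complaints_phone,
#'       nuisance_kills)`; `complaints_phone` is `NA` in masked years.}
#'     \item{food_survey}{data frame `(year, species, respondent, abundance,
#'       production)` with integer 0-4 scores.}
#'   }
#' @export
render_observables <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  years <- truth$complaints$year

  # --- age-at-harvest with sex misreporting -------------------------------
  ind <- truth$individuals
  harv <- ind[!is.na(ind$death_cause) & ind$death_cause == "harvest" &
                ind$death_year %in% years, , drop = FALSE]
  recorded_sex <- harv$sex
  fem <- which(harv$sex == "F")
  if (length(fem) > 0 && config$sex_misreport_rate > 0) {
    flip <- stats::runif(length(fem)) < config$sex_misreport_rate
    recorded_sex[fem[flip]] <- "M"
  }
  age <- harv$death_year - harv$birth_year
  agg <- stats::aggregate(list(count = rep(1L, nrow(harv))),
                          by = list(year = harv$death_year,
                                    sex = recorded_sex, age = age),
                          FUN = sum)
  agg <- agg[order(agg$year, agg$sex, agg$age), ]
  rownames(agg) <- NULL

  # --- complaints: phone / on-site split and masking ----------------------
  total <- truth$complaints$complaints
  p <- config$phone_fraction_trend[["intercept"]] +
    config$phone_fraction_trend[["slope"]] * years
  p <- pmin(pmax(p, 0.02), 0.98)
  if (config$phone_split == "binomial") {
    phone <- stats::rbinom(length(years), size = round(total), prob = p)
  } else {
    phone <- total * p
  }
  onsite <- total - phone

  # --- nuisance kills -----------------------------------------------------
  rate <- ifelse(years >= config$policy_change_year,
                 config$nuisance_kill_rate[["post"]],
                 config$nuisance_kill_rate[["pre"]])
  nuisance <- stats::rbinom(length(years), size = round(total), prob = rate)

  phone[years %in% config$masked_phone_years] <- NA

  yearly <- data.frame(year = years,
                       complaints_onsite = onsite,
                       complaints_phone = phone,
                       nuisance_kills = nuisance)

  # --- food survey --------------------------------------------------------
  survey <- .render_food_survey(truth$food_rating, config)

  out <- list(age_harvest = agg, yearly = yearly, food_survey = survey)
  class(out) <- "observed_data"
  out
}

# Respondents score abundance and production independently Binomial(4, q)
# with q chosen per species so that E[abundance x production] = 16 q^2 equals
# the species' share of the latent yearly rating. Species shares are drawn
# once from a mildly heterogeneous weight vector.
.render_food_survey <- function(food_rating, config) {
  ns <- config$n_species
  nr <- config$n_respondents
  w <- stats::rgamma(ns, shape = 6)
  w <- w / sum(w)
  rows <- vector("list", nrow(food_rating))
  for (i in seq_len(nrow(food_rating))) {
    target <- pmin(pmax(food_rating$rating[i] * w, 0), 16)
    q <- sqrt(target / 16)
    abund <- stats::rbinom(ns * nr, 4, rep(q, each = nr))
    prod <- stats::rbinom(ns * nr, 4, rep(q, each = nr))
    rows[[i]] <- data.frame(year = food_rating$year[i],
                            species = rep(seq_len(ns), each = nr),
                            respondent = rep(seq_len(nr), ns),
                            abundance = abund,
                            production = prod)
  }
  do.call(rbind, rows)
}

#' @export
print.observed_data <- function(x, ...) {
  cat("observed_data:", nrow(x$yearly), "years,",
      sum(x$age_harvest$count), "recorded harvests,",
      sum(is.na(x$yearly$complaints_phone)), "masked phone years\n")
  invisible(x)
}
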