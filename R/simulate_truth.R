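#' Simulate individual fates in a harvested age-structured population
#'
#' Runs an individual-based yearly cycle — births, natural deaths, pre-hunt
#' census, harvest — over the configured span, recording every individual's
#' sex, birth year and fate. Because truth is kept at the individual level,
#' downstream estimators (population reconstruction in particular) can be
#' checked against exact tallies rather than approximations.
#'
#' The yearly event order is fixed: cubs are born, natural mortality strikes
#' (including newborns), the pre-hunt population is censused, and then the
#' harvest removes individuals. "Pre-hunt abundance" therefore counts
#' animals after natural mortality but before that year's hunt, which is the
#' quantity age-at-harvest reconstruction estimates.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_truth`: a list with
#'   \describe{
#'     \item{individuals}{data frame `(id, sex, birth_year, death_year,
#'       death_cause)`; `death_cause` is `"harvest"`, `"natural"` or
#'       `"censored"` (alive at the end, `death_year = NA`).}
#'     \item{abundance}{pre-hunt abundance by `(year, sex, age)` (exact ages).}
#'     \item{food_rating}{data frame `(year, rating)` of the latent yearly
#'       natural-food rating.}
#'     \item{complaints}{data frame `(year, complaints)` of true yearly
#'       complaint totals.}
#'     \item{truncated}{`TRUE` if the population went extinct before the
#'       final year (output covers years up to extinction).}
#'   }
#' @export
#' @examples
#' truth <- simulate_truth(sim_config(years = 1981:1990, initial_total = 500,
#'                                    seed = 42))
#' head(truth$abundance)
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  years <- config$years
  n_years <- length(years)

  nat_mort <- .rate_by_age(config$natural_mortality, config$max_age)
  h_age <- .rate_by_age(config$harvest_age_multiplier, config$max_age)
  h_year <- config$harvest_year_multiplier[as.character(years)]
  h_sex <- config$harvest_sex_multiplier

  # latent yearly food ratings, drawn up front
  rating <- stats::rnorm(n_years, config$food_mean, config$food_sd) -
    stats::rbinom(n_years, 1, config$food_failure_prob) * config$food_failure_drop
  rating <- pmax(rating, 5)

  init <- config$initial_abundance
  sex <- rep(init$sex, init$count)
  birth_year <- rep(years[1] - init$age, init$count)
  death_year <- rep(NA_integer_, length(sex))
  cause <- rep(NA_character_, length(sex))
  alive <- rep(TRUE, length(sex))

  ab_year <- ab_sex <- ab_age <- ab_count <- list()
  truncated <- FALSE
  last_year <- years[n_years]

  for (i in seq_len(n_years)) {
    y <- years[i]

    # births
    n_af <- sum(alive & sex == "F" & (y - birth_year) >= config$breeding_age)
    n_born <- stats::rpois(1, config$birth_rate *
                             config$birth_year_multiplier[[as.character(y)]] *
                             n_af)
    if (n_born > 0) {
      sex <- c(sex, sample(c("F", "M"), n_born, replace = TRUE))
      birth_year <- c(birth_year, rep(y, n_born))
      death_year <- c(death_year, rep(NA_integer_, n_born))
      cause <- c(cause, rep(NA_character_, n_born))
      alive <- c(alive, rep(TRUE, n_born))
    }

    # natural mortality (individuals beyond max_age die with certainty)
    idx <- which(alive)
    age <- y - birth_year[idx]
    p_nat <- ifelse(age > config$max_age, 1, nat_mort[pmin(age, config$max_age) + 1])
    dies <- stats::runif(length(idx)) < p_nat
    death_year[idx[dies]] <- y
    cause[idx[dies]] <- "natural"
    alive[idx[dies]] <- FALSE

    # pre-hunt census
    idx <- which(alive)
    if (length(idx) == 0) {
      truncated <- TRUE
      last_year <- years[max(i - 1, 1)]
      warning("population extinct before final year; output truncated at ",
              last_year)
      break
    }
    age <- y - birth_year[idx]
    tab <- table(sex = sex[idx], age = factor(age, levels = 0:config$max_age))
    nz <- which(tab > 0, arr.ind = TRUE)
    ab_year[[i]] <- rep(y, nrow(nz))
    ab_sex[[i]] <- rownames(tab)[nz[, 1]]
    ab_age[[i]] <- as.integer(colnames(tab)[nz[, 2]])
    ab_count[[i]] <- as.integer(tab[nz])

    # harvest
    food_mult <- if (rating[i] < config$poor_food_threshold)
      config$food_effect_on_harvest else 1
    p_h <- config$harvest_rate_base * h_year[i] * h_sex[sex[idx]] *
      h_age[pmin(age, config$max_age) + 1] * food_mult
    p_h <- pmin(p_h, 1)
    shot <- stats::runif(length(idx)) < p_h
    death_year[idx[shot]] <- y
    cause[idx[shot]] <- "harvest"
    alive[idx[shot]] <- FALSE
  }

  cause[alive] <- "censored"

  abundance <- data.frame(year = unlist(ab_year),
                          sex = unlist(ab_sex),
                          age = unlist(ab_age),
                          count = unlist(ab_count),
                          stringsAsFactors = FALSE)
  keep <- years <= last_year
  food_rating <- data.frame(year = years[keep], rating = rating[keep])

  pop <- tapply(abundance$count, abundance$year, sum)
  pop <- pop[as.character(years[keep])]
  cc <- config$complaint_coefficients
  mu <- cc$intercept + cc$pop * as.numeric(pop) +
    cc$food * food_rating$rating +
    cc$policy * as.numeric(years[keep] >= config$policy_change_year)
  if (any(mu < 0)) {
    warning("negative expected complaints in ", sum(mu < 0),
            " year(s); clipped at 0")
  }
  complaints <- pmax(0, round(mu + stats::rnorm(sum(keep), 0, cc$sd)))

  out <- list(individuals = data.frame(id = seq_along(sex),
                                       sex = sex,
                                       birth_year = birth_year,
                                       death_year = death_year,
                                       death_cause = cause,
                                       stringsAsFactors = FALSE),
              abundance = abundance,
              food_rating = food_rating,
              complaints = data.frame(year = years[keep],
                                      complaints = as.numeric(complaints)),
              truncated = truncated,
              config = config)
  class(out) <- "sim_truth"
  out
}

# expand a scalar-or-vector per-age rate to length max_age + 1
.rate_by_age <- function(x, max_age) {
  if (length(x) == 1) return(rep(x, max_age + 1))
  c(x, rep(x[length(x)], max(0, max_age + 1 - length(x))))[1:(max_age + 1)]
}

#' @export
print.sim_truth <- function(x, ...) {
  yrs <- range(x$abundance$year)
  cat("sim_truth:", nrow(x$individuals), "individuals,",
      yrs[1], "-", yrs[2],
      if (x$truncated) "(truncated: extinction)" else "", "\n")
  invisible(x)
}
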