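#' Cohort-based population reconstruction from age-at-harvest data
#'
#' Estimates pre-hunt abundance by year, sex and age from age-at-harvest
#' records under the virtual-population identity: every reconstructed animal
#' eventually appears in the harvest record. For each sex and birth cohort
#' `c`, the pre-hunt abundance at age `a` (calendar year `c + a`) is the
#' cohort's cumulative observed harvest at ages `a` and above within the data
#' window. The estimate is therefore a minimum population: animals dying of
#' other causes, or still alive when the data end, are not counted. Because
#' the uncounted fraction is roughly constant when mortality rates are
#' stable, the trajectory's shape is trustworthy even though its level is
#' biased low (the level is corrected by [adjust_nonharvest()]).
#'
#' Reconstruction runs on exact ages internally; ages at or above `plus_age`
#' are pooled for reporting. The final `reliable_offset` years are flagged
#' unreliable — recent cohorts have had too little time to appear in the
#' harvest — and are excluded from covariate output, so data through year `T`
#' support estimates up to year `T - reliable_offset` (e.g. pre-hunt 2017
#' from data through the 2019 harvest).
#'
#' @param table Age-at-harvest data frame `(year, sex, age, count)` with
#'   exact integer ages; fractional counts (from sex correction) allowed.
#' @param plus_age First age of the pooled reporting class (default 3).
#' @param reliable_offset Number of terminal data years flagged unreliable
#'   (default 2).
#' @return An object of class `reconstruction`: a list with
#'   \describe{
#'     \item{abundance}{data frame `(year, sex, age, estimate)`, exact ages.}
#'     \item{pooled}{data frame `(year, sex, ageclass, estimate)` with the
#'       plus group.}
#'     \item{years, reliable_years}{all data years; years not flagged.}
#'     \item{nonhunt_fraction}{scale-up applied so far (0 for raw output).}
#'   }
#' @seealso [adjust_nonharvest()], [derive_covariates()]
#' @export
#' @examples
#' tab <- data.frame(year = c(1, 2, 3), sex = "F", age = c(0, 1, 2),
#'                   count = c(2, 3, 1))
#' reconstruct(tab, reliable_offset = 0)$abundance
reconstruct <- function(table, plus_age = 3, reliable_offset = 2) {
  .validate_age_harvest(table, allow_fractional = TRUE)
  age_num <- suppressWarnings(as.numeric(as.character(table$age)))
  if (any(is.na(age_num))) {
    stop("reconstruct requires exact integer ages (pool afterwards)")
  }
  table$age <- age_num
  y1 <- min(table$year)
  y2 <- max(table$year)
  max_age <- max(table$age)

  parts <- lapply(c("F", "M"), function(s) {
    tb <- table[table$sex == s, , drop = FALSE]
    if (nrow(tb) == 0) return(NULL)
    cohorts <- seq(y1 - max_age, y2)
    ages <- 0:max_age
    H <- matrix(0, nrow = length(cohorts), ncol = length(ages),
                dimnames = list(cohorts, ages))
    coh <- tb$year - tb$age
    H[cbind(match(coh, cohorts), match(tb$age, ages))] <- tb$count
    # cumulative future harvest within each cohort: N(a) = sum_{a' >= a} H(a')
    N <- t(apply(H, 1, function(r) rev(cumsum(rev(r)))))
    grid <- expand.grid(cohort = cohorts, age = ages)
    est <- data.frame(year = grid$cohort + grid$age,
                      sex = s,
                      age = grid$age,
                      estimate = as.vector(N),
                      stringsAsFactors = FALSE)
    est[est$year >= y1 & est$year <= y2 & est$estimate > 0, ]
  })
  abundance <- do.call(rbind, parts)
  abundance <- abundance[order(abundance$year, abundance$sex, abundance$age), ]
  rownames(abundance) <- NULL

  out <- list(abundance = abundance,
              years = y1:y2,
              reliable_years = y1:(y2 - reliable_offset),
              plus_age = plus_age,
              reliable_offset = reliable_offset,
              nonhunt_fraction = 0)
  out$pooled <- .pool_estimates(abundance, plus_age)
  class(out) <- "reconstruction"
  out
}

.pool_estimates <- function(abundance, plus_age) {
  lab <- ifelse(abundance$age >= plus_age, paste0(plus_age, "plus"),
                as.character(abundance$age))
  out <- stats::aggregate(list(estimate = abundance$estimate),
                          by = list(year = abundance$year,
                                    sex = abundance$sex, ageclass = lab),
                          FUN = sum)
  out[order(out$year, out$sex, .age_order(out$ageclass)), ]
}

#' Scale reconstruction up for non-hunting mortality
#'
#' Cohort reconstruction counts only animals that eventually die by harvest.
#' If a fraction `f` of total mortality is non-hunting, the full population
#' is the harvest-accounted population divided by `1 - f`; every abundance
#' cell is scaled by that constant. Year-to-year ratios — the trajectory's
#' shape — are unchanged.
#'
#' @param result A `reconstruction` object.
#' @param nonhunt_fraction Fraction of total mortality not due to hunting,
#'   in `[0, 1)`. The study value is 0.35.
#' @return The rescaled `reconstruction` object.
#' @export
adjust_nonharvest <- function(result, nonhunt_fraction = 0.35) {
  stopifnot(inherits(result, "reconstruction"))
  if (nonhunt_fraction < 0 || nonhunt_fraction >= 1) {
    stop("nonhunt_fraction must lie in [0, 1)")
  }
  scale <- 1 / (1 - nonhunt_fraction)
  result$abundance$estimate <- result$abundance$estimate * scale
  result$pooled$estimate <- result$pooled$estimate * scale
  result$nonhunt_fraction <- 1 - (1 - result$nonhunt_fraction) *
    (1 - nonhunt_fraction)
  result
}

#' Yearly covariates from a reconstruction
#'
#' Emits, for each reliable year, the total reconstructed pre-hunt population
#' (POP), the reconstructed number of females aged 6 and over (POPF6, from
#' the exact-age table), and a high/low indicator POPLEVEL for whether POP
#' exceeds a threshold (default 15,000). POPF6 accumulates harvests of old
#' females over many future years, so it is reported only up to
#' `T - popf6_offset` (default 5 years before the last data year) and is
#' `NA` afterwards.
#'
#' @param result A `reconstruction` object (typically after
#'   [adjust_nonharvest()]).
#' @param poplevel_threshold Population size separating low from high years.
#' @param popf6_offset Extra terminal years in which POPF6 is withheld.
#' @return Data frame `(year, POP, POPF6, POPLEVEL)` over reliable years.
#' @export
derive_covariates <- function(result, poplevel_threshold = 15000,
                              popf6_offset = 5) {
  stopifnot(inherits(result, "reconstruction"))
  yrs <- result$reliable_years
  ab <- result$abundance[result$abundance$year %in% yrs, ]
  pop <- tapply(ab$estimate, factor(ab$year, levels = yrs), sum,
                default = 0)
  f6 <- ab[ab$sex == "F" & ab$age >= 6, ]
  popf6 <- tapply(f6$estimate, factor(f6$year, levels = yrs), sum,
                  default = 0)
  popf6_last <- max(result$years) - popf6_offset
  popf6[yrs > popf6_last] <- NA
  data.frame(year = yrs,
             POP = as.numeric(pop),
             POPF6 = as.numeric(popf6),
             POPLEVEL = as.integer(pop > poplevel_threshold))
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("reconstruction:", length(x$years), "data years,",
      length(x$reliable_years), "reliable;",
      "non-hunting mortality fraction", x$nonhunt_fraction, "\n")
  invisible(x)
}
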