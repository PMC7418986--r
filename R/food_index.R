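#' Per-species food abundance score
#'
#' Each survey respondent rates a species' prevalence (abundance, 0-4) and
#' its fruit production (0-4); the two are multiplied, giving a 0-16 score
#' per respondent, and averaged over respondents.
#'
#' @param survey Food-survey data frame `(year, species, respondent,
#'   abundance, production)` with integer 0-4 scores.
#' @param year,species The cell to score.
#' @return Mean respondent score in `[0, 16]`.
#' @export
species_score <- function(survey, year, species) {
  .validate_food_survey(survey)
  rows <- survey$year == year & survey$species == species
  if (!any(rows)) {
    stop("no respondents for year ", year, ", species ", species)
  }
  mean(survey$abundance[rows] * survey$production[rows])
}

#' Yearly natural-food rating
#'
#' Sums the per-species scores over the full species list for one year; all
#' listed species must be scored (no imputation of missing species).
#'
#' @param survey Food-survey data frame (see [species_score()]).
#' @param year Year to rate.
#' @param species Species identifiers expected each year (default 1-14).
#' @return Yearly rating in `[0, 16 * length(species)]`.
#' @export
yearly_rating <- function(survey, year, species = 1:14) {
  .validate_food_survey(survey)
  present <- unique(survey$species[survey$year == year])
  missing <- setdiff(species, present)
  if (length(missing) > 0) {
    stop("year ", year, ": no scores for species ",
         paste(missing, collapse = ", "))
  }
  sum(vapply(species, function(s) species_score(survey, year, s), numeric(1)))
}

#' Yearly ratings for all surveyed years
#'
#' @inheritParams yearly_rating
#' @return Data frame `(year, rating)`.
#' @export
food_yearly <- function(survey, species = 1:14) {
  .validate_food_survey(survey)
  years <- sort(unique(survey$year))
  data.frame(year = years,
             rating = vapply(years, function(y)
               yearly_rating(survey, y, species), numeric(1)))
}

#' Categorize yearly food ratings as poor, normal or abundant
#'
#' By default the observed distribution of ratings is split at its empirical
#' terciles: below the lower tercile is poor, above the upper is abundant,
#' in between (including ties with the cutpoints) is normal. Fixed numeric
#' cutpoints may be supplied instead.
#'
#' @param ratings Data frame `(year, rating)` or a year-named numeric vector.
#' @param method `"terciles"` (default, needs >= 3 years) or `"fixed"`.
#' @param cutpoints For `method = "fixed"`: two strictly increasing numbers
#'   `(c1, c2)`; ratings below `c1` are poor, above `c2` abundant.
#' @return Data frame `(year, rating, category)` with `category` a factor
#'   with levels poor, normal, abundant.
#' @export
#' @examples
#' categorize_years(c("1990" = 10, "1991" = 20, "1992" = 30))
categorize_years <- function(ratings, method = c("terciles", "fixed"),
                             cutpoints = NULL) {
  method <- match.arg(method)
  if (!is.data.frame(ratings)) {
    ratings <- data.frame(year = as.integer(names(ratings)),
                          rating = as.numeric(ratings))
  }
  stopifnot(all(c("year", "rating") %in% names(ratings)))
  if (method == "terciles") {
    if (nrow(ratings) < 3) stop("terciles need at least 3 years of ratings")
    cutpoints <- unname(stats::quantile(ratings$rating, c(1/3, 2/3)))
  } else {
    if (is.null(cutpoints) || length(cutpoints) != 2 ||
        !(cutpoints[1] < cutpoints[2])) {
      stop("cutpoints must be two strictly increasing numbers")
    }
  }
  category <- ifelse(ratings$rating < cutpoints[1], "poor",
                     ifelse(ratings$rating > cutpoints[2], "abundant",
                            "normal"))
  data.frame(year = ratings$year, rating = ratings$rating,
             category = factor(category,
                               levels = c("poor", "normal", "abundant")))
}

.validate_food_survey <- function(survey) {
  if (!is.data.frame(survey) ||
      !all(c("year", "species", "respondent", "abundance", "production")
           %in% names(survey))) {
    stop("food survey must have columns year, species, respondent, ",
         "abundance, production")
  }
  sc <- c(survey$abundance, survey$production)
  if (any(sc < 0 | sc > 4 | sc != round(sc))) {
    stop("abundance and production scores must be integers in 0-4")
  }
  invisible(survey)
}
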