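#' Correct sex misreporting in age-at-harvest records
#'
#' Hunters misidentify the sex of some harvested females (recorded as males)
#' but rarely the reverse. Given the misreport rate `r`, the true female
#' total satisfies `F_true * (1 - r) = F_reported`, so each year's female
#' total is rescaled to `F / (1 - r)` and the excess is moved out of the male
#' records, allocated across ages in proportion to that year's male age
#' distribution (the misreported females sit in the male column, so their
#' ages are distributed like recorded males). Yearly grand totals are
#' conserved exactly; corrected counts may be fractional.
#'
#' @param table Age-at-harvest data frame `(year, sex, age, count)`; `age`
#'   may be exact integer ages or pooled class labels.
#' @param misreport_rate Fraction of harvested females recorded as males,
#'   in `[0, 1)`. The study value is 0.11.
#' @return A data frame with the same shape and corrected counts.
#' @export
#' @examples
#' tab <- data.frame(year = 2000, sex = c("F", "M"), age = c(2, 2),
#'                   count = c(89, 100))
#' correct_sex(tab, 0.11)  # female total becomes 100, male 89
correct_sex <- function(table, misreport_rate) {
  .validate_age_harvest(table, allow_fractional = TRUE)
  stopifnot(is.numeric(misreport_rate), length(misreport_rate) == 1,
            misreport_rate >= 0, misreport_rate < 1)
  if (misreport_rate == 0) return(table)

  parts <- lapply(split(table, table$year), function(tb) {
    y <- tb$year[1]
    f_rows <- tb$sex == "F"
    m_rows <- tb$sex == "M"
    f_tot <- sum(tb$count[f_rows])
    m_tot <- sum(tb$count[m_rows])
    shift <- f_tot * misreport_rate / (1 - misreport_rate)
    if (shift == 0) return(tb)
    if (shift > m_tot) {
      stop("year ", y, ": male harvest (", m_tot,
           ") cannot absorb the sex-correction shift (", round(shift, 2), ")")
    }
    male_share <- tb$count[m_rows] / m_tot
    deduction <- shift * male_share
    tb$count[m_rows] <- tb$count[m_rows] - deduction
    # add the reclaimed females at the male age distribution
    add <- data.frame(year = y, sex = "F", age = tb$age[m_rows],
                      count = deduction, stringsAsFactors = FALSE)
    tb <- rbind(tb, add)
    agg <- stats::aggregate(count ~ year + sex + age, data = tb, FUN = sum)
    agg
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$year, out$sex, .age_order(out$age)), ]
  rownames(out) <- NULL
  out[, c("year", "sex", "age", "count")]
}

#' Pool older ages into a plus group
#'
#' Merges all ages at or above `plus_age` into a single class labelled
#' `"<plus_age>plus"` (e.g. `"3plus"`), leaving younger exact ages as-is.
#' Counts are conserved within every (year, sex).
#'
#' @param table Age-at-harvest data frame `(year, sex, age, count)` with
#'   integer ages.
#' @param plus_age First age of the pooled class (>= 1); the study pools
#'   ages 3 and above.
#' @return A data frame `(year, sex, age, count)` where `age` is a character
#'   label (`"0"`, `"1"`, ..., `"3plus"`).
#' @export
pool_ages <- function(table, plus_age = 3) {
  .validate_age_harvest(table, allow_fractional = TRUE)
  stopifnot(plus_age >= 1)
  age_num <- suppressWarnings(as.numeric(as.character(table$age)))
  if (any(is.na(age_num))) stop("pool_ages requires exact integer ages")
  lab <- ifelse(age_num >= plus_age, paste0(plus_age, "plus"),
                as.character(age_num))
  out <- stats::aggregate(list(count = table$count),
                          by = list(year = table$year, sex = table$sex,
                                    age = lab),
                          FUN = sum)
  out <- out[order(out$year, out$sex, .age_order(out$age)), ]
  rownames(out) <- NULL
  out
}

#' Assemble the previous-year total-kill covariate
#'
#' PREVKILL for year `y` is the total human-caused kill in year `y - 1`:
#' hunter harvest plus bears killed in conflict situations. The first
#' covered year has no previous-year value and is reported as `NA`.
#'
#' @param harvest_by_year Data frame `(year, count)` or named numeric vector
#'   of yearly harvest totals.
#' @param nuisance_by_year Same format, yearly nuisance-kill totals.
#' @return A data frame `(year, kill, prevkill)` over the common span, with
#'   `kill` the total human-caused kill that year.
#' @export
#' @examples
#' build_prevkill(c("1994" = 4000, "1995" = 4800),
#'                c("1994" = 300, "1995" = 280))
build_prevkill <- function(harvest_by_year, nuisance_by_year) {
  h <- .as_year_series(harvest_by_year, "harvest_by_year")
  nk <- .as_year_series(nuisance_by_year, "nuisance_by_year")
  span <- intersect(h$year, nk$year)
  if (length(span) == 0) stop("harvest and nuisance series do not overlap")
  span <- sort(span)
  full <- seq(span[1], span[length(span)])
  missing <- setdiff(full, span)
  if (length(missing) > 0) {
    stop("missing year(s) inside span: ", paste(missing, collapse = ", "))
  }
  kill <- h$count[match(span, h$year)] + nk$count[match(span, nk$year)]
  data.frame(year = span,
             kill = kill,
             prevkill = c(NA, kill[-length(kill)]))
}

.as_year_series <- function(x, what) {
  if (is.data.frame(x)) {
    cols <- intersect(c("count", "kill", "total"), names(x))
    if (!"year" %in% names(x) || length(cols) == 0) {
      stop(what, " must have columns year and count")
    }
    df <- data.frame(year = as.integer(x$year), count = x[[cols[1]]])
  } else if (!is.null(names(x))) {
    df <- data.frame(year = as.integer(names(x)), count = as.numeric(x))
  } else {
    stop(what, " must be a data frame or a year-named vector")
  }
  if (anyNA(df$count)) stop(what, " contains missing counts")
  if (anyDuplicated(df$year)) stop(what, " has duplicate years")
  df[order(df$year), ]
}

# sort key putting exact ages numerically first and plus groups last
.age_order <- function(age) {
  num <- suppressWarnings(as.numeric(as.character(age)))
  plus <- is.na(num)
  num[plus] <- suppressWarnings(
    as.numeric(sub("plus", "", as.character(age)[plus]))) + 0.5
  num
}

.validate_age_harvest <- function(table, allow_fractional = FALSE) {
  if (!is.data.frame(table) ||
      !all(c("year", "sex", "age", "count") %in% names(table))) {
    stop("age-at-harvest table must have columns year, sex, age, count")
  }
  if (nrow(table) == 0) stop("age-at-harvest table is empty")
  if (!all(table$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'")
  }
  bad <- which(table$count < 0)
  if (length(bad) > 0) stop("negative count in row ", bad[1])
  if (!allow_fractional && any(table$count != round(table$count))) {
    stop("counts must be integers")
  }
  key <- paste(table$year, table$sex, table$age)
  if (anyDuplicated(key)) {
    stop("duplicate (year, sex, age) key: ", key[anyDuplicated(key)])
  }
  num <- suppressWarnings(as.numeric(as.character(table$age)))
  if (any(!is.na(num) & (num < 0 | num > 30))) {
    stop("ages must lie in 0-30")
  }
  invisible(table)
}
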