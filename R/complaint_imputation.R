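#' Fit the phone-fraction trend
#'
#' In early record-keeping years only complaints that prompted an on-site
#' visit were recorded; the fraction handled by phone must be reconstructed
#' before totals can be compared across eras. This fits an ordinary
#' least-squares line of the phone-handled fraction on calendar year through
#' the anchor years where both counts were recorded (the study anchors:
#' 1984-85 at 59-61% rising to 1996-98 at 74-77%).
#'
#' @param anchors Data frame `(year, fraction)` or year-named numeric vector
#'   of observed phone fractions; at least two distinct years.
#' @param link `"identity"` regresses the fraction directly (the default,
#'   matching the study's straight-line treatment); `"logit"` regresses its
#'   log-odds and back-transforms predictions.
#' @return An object of class `phone_trend` with elements `intercept`,
#'   `slope` (on the link scale), `link`, `anchors` and `fitted`.
#' @export
#' @examples
#' fit_phone_trend(c("1984" = 0.59, "1998" = 0.77))
fit_phone_trend <- function(anchors, link = c("identity", "logit")) {
  link <- match.arg(link)
  if (!is.data.frame(anchors)) {
    anchors <- data.frame(year = as.integer(names(anchors)),
                          fraction = as.numeric(anchors))
  }
  stopifnot(all(c("year", "fraction") %in% names(anchors)))
  if (length(unique(anchors$year)) < 2) {
    stop("at least two distinct anchor years are required")
  }
  if (any(anchors$fraction <= 0 | anchors$fraction >= 1)) {
    if (link == "logit") stop("logit link needs fractions strictly in (0, 1)")
  }
  y <- if (link == "logit") stats::qlogis(anchors$fraction) else
    anchors$fraction
  fit <- stats::lm(y ~ year, data = data.frame(year = anchors$year, y = y))
  out <- list(intercept = unname(stats::coef(fit)[1]),
              slope = unname(stats::coef(fit)[2]),
              link = link,
              anchors = anchors,
              fitted = unname(stats::fitted(fit)))
  class(out) <- "phone_trend"
  out
}

#' Predict phone fractions from a fitted trend
#'
#' @param trend A `phone_trend` object.
#' @param years Calendar years to predict.
#' @return Numeric vector of predicted phone fractions.
#' @export
predict_phone_fraction <- function(trend, years) {
  stopifnot(inherits(trend, "phone_trend"))
  eta <- trend$intercept + trend$slope * years
  if (trend$link == "logit") stats::plogis(eta) else eta
}

#' Impute total complaints in on-site-only years
#'
#' In years where only on-site-visited complaints were recorded, the total
#' is estimated as `onsite / (1 - p)` with `p` the predicted phone fraction.
#' Years with recorded phone counts are returned untouched
#' (`total = onsite + phone`).
#'
#' @param series Data frame `(year, onsite, phone)`; `phone` is `NA` in
#'   masked years. Columns named `complaints_onsite`/`complaints_phone` are
#'   also accepted.
#' @param trend A `phone_trend` object from [fit_phone_trend()].
#' @return Data frame `(year, onsite, phone, total, imputed)`.
#' @export
#' @examples
#' tr <- fit_phone_trend(c("1984" = 0.6, "1996" = 0.6))
#' impute_totals(data.frame(year = 1990, onsite = 400, phone = NA), tr)
impute_totals <- function(series, trend) {
  stopifnot(inherits(trend, "phone_trend"))
  nm <- names(series)
  names(series)[nm == "complaints_onsite"] <- "onsite"
  names(series)[nm == "complaints_phone"] <- "phone"
  stopifnot(all(c("year", "onsite", "phone") %in% names(series)))
  masked <- is.na(series$phone)
  p_hat <- predict_phone_fraction(trend, series$year)
  if (any(masked & (p_hat < 0 | p_hat >= 1))) {
    bad <- series$year[masked & (p_hat < 0 | p_hat >= 1)]
    stop("predicted phone fraction outside (0, 1) for year(s): ",
         paste(bad, collapse = ", "))
  }
  total <- ifelse(masked, series$onsite / (1 - p_hat),
                  series$onsite + series$phone)
  data.frame(year = series$year,
             onsite = series$onsite,
             phone = series$phone,
             total = total,
             imputed = masked)
}

#' @export
print.phone_trend <- function(x, ...) {
  cat("phone_trend (", x$link, "): intercept ", signif(x$intercept, 5),
      ", slope ", signif(x$slope, 5), " per year, ",
      nrow(x$anchors), " anchors\n", sep = "")
  invisible(x)
}
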