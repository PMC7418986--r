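#' Assemble the yearly design table for the complaint regressions
#'
#' Aligns the complaint response with the reconstruction covariates, food
#' rating and previous-year kill into one row per year. Two candidate-model
#' sets are supported: set 1 carries the high/low population indicator
#' POPLEVEL (and runs over all years with reconstruction covariates); set 2
#' replaces it with the count of females aged 6+ (POPF6), whose shorter
#' reliable window truncates the span (1982-2014 for data through 2019).
#' POLICY is coded 0 before the policy year and 1 from it onward. The first
#' data year never enters (PREVKILL is undefined there).
#'
#' @param covariates Data frame `(year, POP, POPF6, POPLEVEL)` from
#'   [derive_covariates()].
#' @param food Data frame `(year, rating)` from [food_yearly()].
#' @param complaints Data frame `(year, total)` (or the output of
#'   [impute_totals()]).
#' @param kills Data frame `(year, kill, prevkill)` from [build_prevkill()].
#' @param set Candidate set, 1 or 2.
#' @param policy_year First year of the revised nuisance policy.
#' @return Data frame with columns `year`, `COMPLAINTS`, `POP`, `FOOD`,
#'   `PREVKILL`, `POLICY` and `POPLEVEL` (set 1) or `POPF6` (set 2), with
#'   attribute `"set"`.
#' @export
assemble_design <- function(covariates, food, complaints, kills, set = 1,
                            policy_year = 1998) {
  stopifnot(set %in% c(1, 2))
  resp_col <- intersect(c("total", "COMPLAINTS", "complaints"),
                        names(complaints))[1]
  if (is.na(resp_col)) stop("complaints must have a total count column")

  years <- Reduce(intersect, list(covariates$year, food$year,
                                  complaints$year, kills$year))
  years <- sort(years)
  df <- data.frame(year = years,
                   COMPLAINTS = complaints[[resp_col]][match(years, complaints$year)],
                   POP = covariates$POP[match(years, covariates$year)],
                   FOOD = food$rating[match(years, food$year)],
                   PREVKILL = kills$prevkill[match(years, kills$year)],
                   POLICY = as.integer(years >= policy_year))
  if (set == 1) {
    df$POPLEVEL <- covariates$POPLEVEL[match(years, covariates$year)]
  } else {
    df$POPF6 <- covariates$POPF6[match(years, covariates$year)]
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) == 0) stop("no complete years shared by all inputs")
  if (any(diff(df$year) != 1)) {
    gap <- df$year[which(diff(df$year) != 1)[1]] + 1
    stop("gap in design-table span at year ", gap)
  }
  rownames(df) <- NULL
  attr(df, "set") <- set
  df
}

#' Ordinary least-squares fit of a complaint model
#'
#' Fits a linear model by least squares (via [stats::lm()]) and packages the
#' quantities model competition needs: the Gaussian maximum-likelihood
#' log-likelihood computed from the residual sum of squares,
#' `loglik = -n/2 * (log(2 pi) + log(RSS/n) + 1)`, the parameter count
#' `k = slopes + 2` (intercept and residual variance both count), and R2 /
#' adjusted R2 (`1 - (1 - R2)(n - 1)/(n - p - 1)` with `p` slopes).
#'
#' @param design Design table from [assemble_design()] (any data frame
#'   containing the model variables works).
#' @param formula Model formula, e.g.
#'   `COMPLAINTS ~ POP + FOOD + POLICY + POPLEVEL`.
#' @return An object of class `conflict_fit`: list with `label`,
#'   `coefficients`, `residuals`, `rss`, `n`, `p`, `k`, `loglik`, `r2`,
#'   `adj_r2`, `response`, `lm` (the underlying fit).
#' @export
fit_ols <- function(design, formula) {
  fit <- stats::lm(formula, data = design)
  X <- stats::model.matrix(fit)
  p <- ncol(X) - 1
  n <- nrow(X)
  if (fit$rank < ncol(X)) {
    stop("rank-deficient design for model: ", deparse(formula))
  }
  if (n <= p + 1) stop("too few rows (n = ", n, ") for ", p, " slopes")
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  y <- stats::model.response(stats::model.frame(fit))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  adj_r2 <- if (p == 0) r2 else 1 - (1 - r2) * (n - 1) / (n - p - 1)
  loglik <- if (rss <= .Machine$double.eps * n) Inf else
    -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  rhs <- attr(stats::terms(fit), "term.labels")
  out <- list(label = if (length(rhs) == 0) "(intercept only)" else
                paste(rhs, collapse = " + "),
              formula = formula,
              coefficients = stats::coef(fit),
              residuals = as.numeric(res),
              rss = rss, n = n, p = p, k = p + 2,
              loglik = loglik,
              r2 = r2, adj_r2 = adj_r2,
              response = as.numeric(y),
              lm = fit)
  class(out) <- "conflict_fit"
  out
}

#' Rank candidate fits by small-sample AIC
#'
#' Computes, from explicit formulas, `AICc = -2 loglik + 2k +
#' 2k(k + 1)/(n - k - 1)`, differences from the best model, Akaike weights
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` (normalized over the full
#' candidate set), and cumulative weights in rank order. Rows with
#' `delta <= max_delta` are returned (weights are computed before
#' filtering, so a truncated table's weights still refer to the full set).
#'
#' @param fits List of `conflict_fit` objects on identical response rows.
#' @param max_delta Report only models within this AICc difference of the
#'   best (default `Inf`; the study prints `<= 4`).
#' @return Data frame `(model, k, n, AICc, delta, weight, cum_weight, r2,
#'   adj_r2)`, ranked, of class `aicc_table`.
#' @export
#' @examples
#' d <- data.frame(COMPLAINTS = rnorm(20), POP = rnorm(20), FOOD = rnorm(20))
#' fits <- list(fit_ols(d, COMPLAINTS ~ POP), fit_ols(d, COMPLAINTS ~ FOOD))
#' akaike_table(fits)
akaike_table <- function(fits, max_delta = Inf) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "conflict_fit")))
  n <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(n)) != 1) {
    stop("all candidate fits must use the same rows (differing n)")
  }
  resp <- vapply(fits, function(f) sum(f$response^2), numeric(1))
  if (max(abs(resp - resp[1])) > 1e-8 * (1 + abs(resp[1]))) {
    stop("all candidate fits must share the same response values")
  }
  k <- vapply(fits, `[[`, numeric(1), "k")
  if (any(n - k - 1 <= 0)) {
    stop("AICc undefined: n - k - 1 <= 0 for some model")
  }
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ord <- order(aicc)
  out <- data.frame(model = vapply(fits, `[[`, character(1), "label")[ord],
                    k = k[ord], n = n[ord],
                    AICc = aicc[ord], delta = delta[ord],
                    weight = w[ord], cum_weight = cumsum(w[ord]),
                    r2 = vapply(fits, `[[`, numeric(1), "r2")[ord],
                    adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2")[ord],
                    stringsAsFactors = FALSE)
  out <- out[out$delta <= max_delta, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("aicc_table", "data.frame")
  out
}

#' Default candidate model formulas
#'
#' Set 1: every model contains POP, with all subsets of FOOD, POLICY,
#' PREVKILL and POPLEVEL (16 models). Set 2: every non-empty combination of
#' POP and POPF6, with all subsets of FOOD, POLICY and PREVKILL (24 models).
#' Both sets contain every model the study reports in its ranking table.
#'
#' @param set Candidate set, 1 or 2.
#' @return List of formulas with response `COMPLAINTS`.
#' @export
candidate_formulas <- function(set = 1) {
  stopifnot(set %in% c(1, 2))
  subsets <- function(vars) {
    out <- list(character(0))
    for (v in vars) out <- c(out, lapply(out, c, v))
    out
  }
  if (set == 1) {
    cores <- list("POP")
    extras <- subsets(c("FOOD", "POLICY", "PREVKILL", "POPLEVEL"))
  } else {
    cores <- list("POP", "POPF6", c("POP", "POPF6"))
    extras <- subsets(c("FOOD", "POLICY", "PREVKILL"))
  }
  combos <- unlist(lapply(cores, function(core)
    lapply(extras, function(e) c(core, e))), recursive = FALSE)
  lapply(combos, function(vars)
    stats::as.formula(paste("COMPLAINTS ~", paste(vars, collapse = " + "))))
}

#' Fit and rank a candidate set on a design table
#'
#' Candidates whose design is unidentifiable on the given data (for example
#' a high/low indicator that never varies over the span) are skipped with a
#' warning; weights are normalized over the candidates actually fitted.
#'
#' @param design Design table from [assemble_design()].
#' @param formulas List of candidate formulas; defaults to
#'   [candidate_formulas()] for the table's set.
#' @param max_delta Passed to [akaike_table()].
#' @return An `aicc_table`.
#' @export
fit_candidates <- function(design, formulas = NULL, max_delta = Inf) {
  if (is.null(formulas)) {
    formulas <- candidate_formulas(attr(design, "set") %||% 1)
  }
  fits <- lapply(formulas, function(f)
    tryCatch(fit_ols(design, f), error = function(e) e$message))
  bad <- vapply(fits, is.character, logical(1))
  if (all(bad)) {
    stop("no candidate model could be fitted: ", fits[[1]])
  }
  if (any(bad)) {
    warning("skipped ", sum(bad), " unidentifiable candidate model(s)")
  }
  akaike_table(fits[!bad], max_delta)
}

#' Variance inflation factors
#'
#' For each slope predictor `j`, `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes
#' from regressing predictor `j` on the other predictors (with intercept).
#' Perfectly collinear predictors report `Inf` rather than erroring.
#'
#' @param design Data frame containing the model variables.
#' @param formula Model formula with at least two slope predictors.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design, formula) {
  X <- stats::model.matrix(formula, data = design)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2) stop("VIF needs at least two slope predictors")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Residual autocorrelation check
#'
#' Computes the sample autocorrelation of regression residuals at lags 0 to
#' `max_lag`, `r_h = sum (e_t - ebar)(e_{t+h} - ebar) / sum (e_t - ebar)^2`,
#' with approximate 95% white-noise bounds `+/- 1.96 / sqrt(n)`, and flags
#' whether each lag lies within bounds.
#'
#' @param residuals Numeric vector of residuals (length >= 5).
#' @param max_lag Largest lag to report (default 5).
#' @return Data frame `(lag, acf, bound, within)`.
#' @export
acf_check <- function(residuals, max_lag = 5) {
  e <- as.numeric(residuals)
  n <- length(e)
  if (n < 5) stop("need at least 5 residuals")
  ec <- e - mean(e)
  denom <- sum(ec^2)
  if (denom == 0) stop("residuals are constant (zero variance)")
  max_lag <- min(max_lag, n - 1)
  r <- vapply(0:max_lag, function(h)
    sum(ec[seq_len(n - h)] * ec[seq_len(n - h) + h]) / denom, numeric(1))
  bound <- 1.96 / sqrt(n)
  data.frame(lag = 0:max_lag, acf = r, bound = bound,
             within = abs(r) <= bound)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.aicc_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$AICc <- round(y$AICc, 1)
  y$delta <- round(y$delta, 1)
  y$weight <- round(y$weight, digits)
  y$cum_weight <- round(y$cum_weight, digits)
  y$r2 <- round(y$r2, digits)
  y$adj_r2 <- round(y$adj_r2, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
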