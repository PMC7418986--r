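# a deterministic little design table for arithmetic checks
demo_design <- function(n = 20, seed = 3) {
  set.seed(seed)
  data.frame(year = seq_len(n) + 1981,
             COMPLAINTS = rnorm(n, 1000, 100),
             POP = rnorm(n, 15000, 2000),
             FOOD = rnorm(n, 60, 8),
             PREVKILL = rnorm(n, 3000, 400),
             POLICY = as.integer(seq_len(n) > n / 2),
             POPLEVEL = rbinom(n, 1, 0.5))
}

test_that("fit_ols matches closed-form R2 and adjusted R2", {
  d <- demo_design()
  f <- fit_ols(d, COMPLAINTS ~ POP + FOOD)
  s <- summary(stats::lm(COMPLAINTS ~ POP + FOOD, d))
  expect_equal(f$r2, unname(s$r.squared))
  expect_equal(f$adj_r2, unname(s$adj.r.squared))
  expect_equal(f$adj_r2, 1 - (1 - f$r2) * (f$n - 1) / (f$n - f$p - 1))
  expect_equal(f$loglik, as.numeric(stats::logLik(f$lm)))
  # worked case: n = 10, p = 2, R2 = 0.75 gives adjusted 0.6786
  expect_equal(1 - 0.25 * 9 / 7, 0.6786, tolerance = 5e-5)
})

test_that("perfect and intercept-only fits hit the R2 boundaries", {
  d <- demo_design()
  d$Y <- 3 * d$POP + 7
  f <- fit_ols(d, Y ~ POP)
  expect_equal(f$r2, 1)
  expect_equal(f$adj_r2, 1)
  expect_true(all(abs(f$residuals) < 1e-8))
  f0 <- fit_ols(d, COMPLAINTS ~ 1)
  expect_equal(f0$r2, 0)
  expect_equal(f0$k, 2)
})

test_that("parameter count follows the slopes-plus-two convention", {
  d <- demo_design(n = 30)
  d$POPF6 <- rnorm(30, 2000, 300)
  listed <- list("POP + FOOD + POLICY + POPLEVEL" = 6,
                 "POP + FOOD + POLICY" = 5,
                 "POP + FOOD + POLICY + POPLEVEL + PREVKILL" = 7,
                 "POP + FOOD + POLICY + PREVKILL" = 6,
                 "POPF6 + FOOD + POLICY" = 5,
                 "POPF6 + FOOD + POLICY + PREVKILL" = 6,
                 "POP + POPF6 + FOOD + POLICY" = 6)
  for (rhs in names(listed)) {
    f <- fit_ols(d, stats::as.formula(paste("COMPLAINTS ~", rhs)))
    expect_equal(f$k, listed[[rhs]])
  }
})

test_that("AICc formula, deltas and weights follow the closed forms", {
  d <- demo_design(n = 25)
  fits <- list(fit_ols(d, COMPLAINTS ~ POP),
               fit_ols(d, COMPLAINTS ~ POP + FOOD),
               fit_ols(d, COMPLAINTS ~ POP + FOOD + POLICY))
  tab <- akaike_table(fits)
  for (i in seq_len(nrow(tab))) {
    f <- fits[[match(tab$model[i], vapply(fits, `[[`, "", "label"))]]
    expect_equal(tab$AICc[i],
                 -2 * f$loglik + 2 * f$k +
                   2 * f$k * (f$k + 1) / (f$n - f$k - 1))
  }
  expect_equal(tab$delta[1], 0)
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$cum_weight, cumsum(tab$weight))
  expect_true(all(diff(tab$AICc) >= 0))
  # single model: delta 0, weight 1
  t1 <- akaike_table(fits[1])
  expect_equal(t1$weight, 1)
  # two models delta {0, 2}: weights {0.731, 0.269}
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(round(w, 3), c(0.731, 0.269))
})

test_that("delta ordering is invariant to constant log-likelihood shifts", {
  d <- demo_design(n = 25)
  fits <- list(fit_ols(d, COMPLAINTS ~ POP),
               fit_ols(d, COMPLAINTS ~ POP + FOOD))
  tab <- akaike_table(fits)
  shifted <- lapply(fits, function(f) { f$loglik <- f$loglik + 37; f })
  tab2 <- akaike_table(shifted)
  expect_equal(tab2$delta, tab$delta)
  expect_equal(tab2$weight, tab$weight)
})

test_that("adjusted R2 never exceeds R2 with at least one slope", {
  d <- demo_design(n = 30)
  for (rhs in c("POP", "POP + FOOD", "POP + FOOD + POLICY + PREVKILL")) {
    f <- fit_ols(d, stats::as.formula(paste("COMPLAINTS ~", rhs)))
    expect_lte(f$adj_r2, f$r2)
  }
})

test_that("VIF matches the closed form and flags collinearity", {
  set.seed(8)
  n <- 400000
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
  d <- data.frame(Y = rnorm(n), A = x1, B = x2)
  v <- vif(d, Y ~ A + B)
  expect_equal(unname(v["A"]), 1 / (1 - 0.64), tolerance = 0.02)
  # orthogonal predictors: VIF 1
  d2 <- data.frame(Y = rnorm(8), A = rep(c(-1, 1), 4),
                   B = rep(c(-1, -1, 1, 1), 2))
  expect_equal(unname(vif(d2, Y ~ A + B)), c(1, 1))
  # duplicated predictor: infinite
  d3 <- data.frame(Y = rnorm(10), A = rnorm(10))
  d3$B <- d3$A
  expect_true(all(is.infinite(vif(d3, Y ~ A + B))))
  # agrees with the standard implementation
  if (requireNamespace("car", quietly = TRUE)) {
    d4 <- demo_design(n = 30)
    f <- stats::lm(COMPLAINTS ~ POP + FOOD + PREVKILL, d4)
    expect_equal(unname(vif(d4, COMPLAINTS ~ POP + FOOD + PREVKILL)),
                 unname(car::vif(f)), tolerance = 1e-8)
  }
})

test_that("residual ACF matches its formula and the standard implementation", {
  set.seed(9)
  e <- rnorm(36)
  out <- acf_check(e, max_lag = 4)
  expect_equal(out$acf[1], 1)
  expect_equal(out$bound, rep(1.96 / 6, 5))
  ref <- as.numeric(stats::acf(e, lag.max = 4, plot = FALSE,
                               demean = TRUE)$acf)
  expect_equal(out$acf, ref)
  # alternating residuals approach lag-1 autocorrelation -1 and get flagged
  alt <- rep(c(1, -1), 50)
  out2 <- acf_check(alt, max_lag = 1)
  expect_lt(out2$acf[2], -0.9)
  expect_false(out2$within[2])
  expect_error(acf_check(rep(2, 10)), "constant")
  expect_error(acf_check(rnorm(3)), "at least 5")
})

test_that("candidate sets contain every reported model", {
  f1 <- vapply(candidate_formulas(1), function(f)
    paste(sort(attr(stats::terms(f), "term.labels")), collapse = "+"), "")
  f2 <- vapply(candidate_formulas(2), function(f)
    paste(sort(attr(stats::terms(f), "term.labels")), collapse = "+"), "")
  key <- function(...) paste(sort(c(...)), collapse = "+")
  expect_true(key("POP", "FOOD", "POLICY", "POPLEVEL") %in% f1)
  expect_true(key("POP", "FOOD", "POLICY") %in% f1)
  expect_true(key("POP", "FOOD", "POLICY", "POPLEVEL", "PREVKILL") %in% f1)
  expect_true(key("POPF6", "FOOD", "POLICY") %in% f2)
  expect_true(key("POP", "POPF6", "FOOD", "POLICY") %in% f2)
  expect_equal(length(f1), 16)
  expect_equal(length(f2), 24)
  expect_false(any(duplicated(f1)))
  expect_false(any(duplicated(f2)))
})

test_that("design assembly encodes POLICY and POPLEVEL and checks spans", {
  cov <- data.frame(year = 1995:2004, POP = seq(14000, 16000, length.out = 10),
                    POPF6 = 2000, POPLEVEL = as.integer(
                      seq(14000, 16000, length.out = 10) > 15000))
  food <- data.frame(year = 1995:2004, rating = 60)
  comp <- data.frame(year = 1995:2004, total = 2000)
  kills <- data.frame(year = 1995:2004, kill = 3000,
                      prevkill = c(NA, rep(3000, 9)))
  d <- assemble_design(cov, food, comp, kills, set = 1, policy_year = 1998)
  expect_equal(d$POLICY[d$year == 1997], 0L)
  expect_equal(d$POLICY[d$year == 1998], 1L)
  expect_false(1995 %in% d$year)  # PREVKILL undefined in the first year
  expect_true(all(c("POPLEVEL") %in% names(d)))
  expect_false("POPF6" %in% names(d))
  d2 <- assemble_design(cov, food, comp, kills, set = 2, policy_year = 1998)
  expect_true("POPF6" %in% names(d2))
  expect_false("POPLEVEL" %in% names(d2))
  # a hole in the food series is a gap, not silently dropped
  expect_error(assemble_design(cov, food[food$year != 2000, ], comp, kills,
                               set = 1),
               "gap")
})

test_that("rank mismatch and tiny samples are rejected", {
  d <- demo_design(n = 6)
  expect_error(fit_ols(d, COMPLAINTS ~ POP + FOOD + POLICY + PREVKILL +
                         POPLEVEL), "few")
  f <- fit_ols(demo_design(n = 8), COMPLAINTS ~ POP + FOOD + POLICY +
                 PREVKILL + POPLEVEL)
  expect_error(akaike_table(list(f)), "AICc undefined")
})
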