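test_that("no-event limit: zero rates freeze the population", {
  cfg <- sim_config(years = 1981:1990, initial_total = 400,
                    birth_rate = 0, natural_mortality = 0,
                    harvest_rate_base = 0,
                    harvest_year_multiplier = stats::setNames(rep(1, 10),
                                                              1981:1990),
                    seed = 3)
  truth <- suppressWarnings(simulate_truth(cfg))
  pop <- tapply(truth$abundance$count, truth$abundance$year, sum)
  expect_true(all(pop == sum(cfg$initial_abundance$count)))
  expect_true(all(truth$individuals$death_cause == "censored"))
  expect_true(all(is.na(truth$individuals$death_year)))
})

test_that("certain-event limit: harvest rate 1 empties the population in year 1", {
  init <- data.frame(sex = rep(c("F", "M"), each = 3), age = rep(0:2, 2),
                     count = 50)
  cfg <- sim_config(years = 1981:1990, initial_abundance = init,
                    birth_rate = 0, natural_mortality = 0,
                    harvest_rate_base = 1,
                    harvest_year_multiplier = stats::setNames(rep(1, 10),
                                                              1981:1990),
                    harvest_sex_multiplier = c(F = 1, M = 1),
                    harvest_age_multiplier = 1, seed = 3)
  truth <- suppressWarnings(simulate_truth(cfg))
  expect_true(all(truth$individuals$death_year == 1981))
  expect_true(all(truth$individuals$death_cause == "harvest"))
  expect_true(truth$truncated)
  expect_warning(simulate_truth(cfg), "extinct")
})

test_that("abundance table equals an independent tally over individual fates", {
  cfg <- small_config(seed = 11)
  truth <- simulate_truth(cfg)
  for (y in c(1981, 1988, 1995, 2000)) {
    expect_equal(sum(truth$abundance$count[truth$abundance$year == y]),
                 tally_pre_hunt(truth$individuals, y))
  }
  # a few random cells, exact ages
  expect_equal(truth$abundance$count[truth$abundance$year == 1990 &
                                       truth$abundance$sex == "F" &
                                       truth$abundance$age == 2][1],
               tally_pre_hunt_cell(truth$individuals, 1990, "F", 2))
})

test_that("identical seed gives identical truth and observables", {
  cfg <- small_config(seed = 21)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$individuals, t2$individuals)
  expect_identical(t1$complaints, t2$complaints)
  o1 <- render_observables(t1, cfg)
  o2 <- render_observables(t2, cfg)
  expect_identical(o1$age_harvest, o2$age_harvest)
  expect_identical(o1$yearly, o2$yearly)
  expect_identical(o1$food_survey, o2$food_survey)
})

test_that("misreporting relabels sex but conserves yearly harvest counts", {
  cfg <- small_config(seed = 31)
  truth <- simulate_truth(cfg)
  obs <- render_observables(truth, cfg)
  ind <- truth$individuals
  harv <- ind[!is.na(ind$death_cause) & ind$death_cause == "harvest", ]
  true_by_year <- table(harv$death_year)
  obs_by_year <- tapply(obs$age_harvest$count, obs$age_harvest$year, sum)
  expect_equal(as.numeric(obs_by_year[names(true_by_year)]),
               as.numeric(true_by_year))
  # with misreporting off, sex-specific counts match the truth
  cfg0 <- small_config(seed = 31, sex_misreport_rate = 0)
  obs0 <- render_observables(truth, cfg0)
  true_f <- sum(harv$sex == "F")
  expect_equal(sum(obs0$age_harvest$count[obs0$age_harvest$sex == "F"]),
               true_f)
  # with it on, recorded females are fewer
  expect_lt(sum(obs$age_harvest$count[obs$age_harvest$sex == "F"]), true_f)
})

test_that("deterministic phone split makes observed counts exactly linear", {
  cfg <- small_config(seed = 41, phone_split = "deterministic",
                      masked_phone_years = integer(0))
  truth <- simulate_truth(cfg)
  obs <- render_observables(truth, cfg)
  p <- cfg$phone_fraction_trend[["intercept"]] +
    cfg$phone_fraction_trend[["slope"]] * obs$yearly$year
  expect_equal(obs$yearly$complaints_phone,
               truth$complaints$complaints * p)
  expect_equal(obs$yearly$complaints_onsite + obs$yearly$complaints_phone,
               truth$complaints$complaints)
})

test_that("noise-free complaints follow the linear predictor exactly", {
  cc <- list(intercept = 5000, pop = 0.2, food = -30, policy = -500, sd = 0)
  cfg <- small_config(seed = 51, complaint_coefficients = cc)
  truth <- simulate_truth(cfg)
  pop <- tapply(truth$abundance$count, truth$abundance$year, sum)
  mu <- cc$intercept + cc$pop * as.numeric(pop) +
    cc$food * truth$food_rating$rating +
    cc$policy * as.numeric(truth$food_rating$year >= cfg$policy_change_year)
  expect_equal(truth$complaints$complaints, round(mu))
})

test_that("food survey scores recover the latent rating on average", {
  cfg <- small_config(seed = 61, n_respondents = 200)
  truth <- simulate_truth(cfg)
  obs <- render_observables(truth, cfg)
  rated <- food_yearly(obs$food_survey)
  expect_equal(rated$rating, truth$food_rating$rating, tolerance = 0.12)
  expect_gt(stats::cor(rated$rating, truth$food_rating$rating), 0.97)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(years = 1981:1983), "length")
  expect_error(sim_config(sex_misreport_rate = 1.2), "probabilities")
  expect_error(sim_config(initial_abundance = data.frame(
    sex = "F", age = 1, count = -3)), "non-negative")
})
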