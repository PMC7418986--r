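# Small configurations and tables shared across tests.

# a fast small-population configuration for pipeline-level tests; complaint
# coefficients rescaled so expected complaints stay positive at this scale
small_config <- function(seed = 1,
                         complaint_coefficients = list(intercept = 2500,
                                                       pop = 2, food = -30,
                                                       policy = -500,
                                                       sd = 300),
                         ...) {
  sim_config(years = 1981:2000, initial_total = 800, seed = seed,
             complaint_coefficients = complaint_coefficients, ...)
}

# harvest-only world: no births, no natural mortality, a harvest rate high
# enough that every individual is all but surely shot within the window, so
# reconstruction should reproduce the truth exactly. Starting ages are kept
# low so no one can age out or exceed the 0-30 harvest-age range.
harvest_only_config <- function(seed = 1, n0 = 5000, years = 1981:2020,
                                harvest_rate = 0.5) {
  ages <- 0:8
  per_cell <- round(n0 / (2 * length(ages)))
  init <- data.frame(sex = rep(c("F", "M"), each = length(ages)),
                     age = rep(ages, 2),
                     count = per_cell)
  sim_config(years = years,
             initial_abundance = init,
             birth_rate = 0,
             natural_mortality = 0,
             harvest_rate_base = harvest_rate,
             harvest_year_multiplier = stats::setNames(rep(1, length(years)),
                                                       years),
             harvest_sex_multiplier = c(F = 1, M = 1),
             harvest_age_multiplier = 1,
             food_effect_on_harvest = 1,
             sex_misreport_rate = 0,
             seed = seed)
}

# independent tally of pre-hunt abundance from individual records: alive at
# the pre-hunt census of year y means born <= y and (death year > y, or died
# in y by harvest since harvest follows the census)
tally_pre_hunt <- function(individuals, year) {
  alive <- individuals$birth_year <= year &
    (is.na(individuals$death_year) | individuals$death_year > year |
       (individuals$death_year == year & individuals$death_cause == "harvest"))
  sum(alive)
}

tally_pre_hunt_cell <- function(individuals, year, sex_, age_) {
  alive <- individuals$birth_year <= year &
    (is.na(individuals$death_year) | individuals$death_year > year |
       (individuals$death_year == year & individuals$death_cause == "harvest"))
  sum(alive & individuals$sex == sex_ &
        (year - individuals$birth_year) == age_)
}

# stationary birth rate for a given harvest rate / natural mortality pair
# (breeding from age 2), from a deterministic expected-value projection of
# the simulator's yearly cycle
stationary_birth_rate <- function(h, m) {
  -0.4071 + 2.2461 * h + 4.3745 * m + 26.1805 * h * m
}

toy_harvest_table <- function() {
  data.frame(year = rep(2000:2002, each = 4),
             sex = rep(c("F", "F", "M", "M"), 3),
             age = rep(c(1, 4, 1, 4), 3),
             count = c(10, 5, 12, 6, 8, 4, 9, 5, 7, 3, 8, 4))
}

# settings matched to the small population's scale (the POPLEVEL threshold
# must fall inside the reconstructed range to be identifiable)
small_settings <- function(...) {
  pipeline_settings(poplevel_threshold = 1000, ...)
}
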