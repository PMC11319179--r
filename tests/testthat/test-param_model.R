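test_that("parameter bundles round-trip through JSON unchanged", {
  f <- withr::local_tempfile(fileext = ".json")
  write_parameters(params_urban, f)
  p2 <- load_parameters(f)
  expect_equal(p2$setting, params_urban$setting, tolerance = 1e-12)
  expect_equal(p2$costs$state_annual_cost,
               params_urban$costs$state_annual_cost, tolerance = 1e-12)
  expect_equal(p2$utilities$state_utility,
               params_urban$utilities$state_utility, tolerance = 1e-12)
  for (b in seq_along(p2$transitions$P))
    expect_equal(p2$transitions$P[[b]], params_urban$transitions$P[[b]],
                 tolerance = 1e-12)
  for (nm in names(p2$strategies))
    expect_equal(p2$strategies[[nm]][names(p2$strategies[[nm]]) != "name"],
                 params_urban$strategies[[nm]][
                   names(params_urban$strategies[[nm]]) != "name"],
                 tolerance = 1e-12)
  expect_equal(length(health_states()), 13)
})

test_that("validation errors name the offending field", {
  expect_error(screening_strategy("FCG", 1.2, 0.8, 1, 1, 1), "sensitivity")
  expect_error(screening_strategy("FCG", 0.9, -0.1, 1, 1, 1), "specificity")
  p <- params_urban
  p$setting$prevalence <- 1.5
  expect_error(validate_parameters(p), "prevalence")
  p <- params_urban
  p$costs$state_annual_cost[["DEATH"]] <- 10
  expect_error(validate_parameters(p), "DEATH")
  p <- params_urban
  p$discount$rate <- 0.2  # above the sensitivity range's upper end
  expect_error(validate_parameters(p), "sensitivity_range")
})

test_that("transition tables reject bad rows and structural violations", {
  long <- data.frame(from_state = "DM_NO_COMP", to_state = "DM_NO_COMP",
                     age_low = 18, age_high = 80, probability = 0.9)
  expect_error(transition_table(long), "row sum")
  long <- data.frame(
    from_state = c("DM_NO_COMP", "DM_NO_COMP"),
    to_state = c("DM_NO_COMP", "DM_ESRD"),  # ESRD only from DKD
    age_low = 18, age_high = 80, probability = c(0.9, 0.1))
  expect_error(transition_table(long), "forbidden")
  # near-1 row sums are renormalized exactly
  long <- data.frame(
    from_state = c("DM_NO_COMP", "DM_NO_COMP"),
    to_state = c("DM_NO_COMP", "DEATH"),
    age_low = 18, age_high = 80, probability = c(0.9, 0.1) * (1 + 1e-8))
  tt <- transition_table(long)
  expect_equal(sum(tt$P[[1]]["DM_NO_COMP", ]), 1, tolerance = 1e-15)
})

test_that("missed-diagnosis HRs scale by vascular class and re-close rows", {
  tt <- mini_table(p_dkd = 0.05, p_stroke = 0.04, p_death = 0.02)
  out <- apply_missed_diagnosis_hr(tt, missed_diagnosis_hr())
  P <- out$P[[1]]
  expect_equal(P["DM_NO_COMP", "DM_DKD"], 0.05 * 1.391)       # microvascular
  expect_equal(P["DM_NO_COMP", "DM_STROKE"], 0.04 * 1.287)    # macrovascular
  expect_equal(P["DM_NO_COMP", "DEATH"], 0.02 * 1.290)
  expect_equal(rowSums(P), setNames(rep(1, 13), health_states()),
               tolerance = 1e-12)
  # identity multipliers are a bitwise no-op
  expect_identical(apply_missed_diagnosis_hr(tt, missed_diagnosis_hr(1, 1, 1)),
                   tt)
})

test_that("rural HRs match the published multipliers and urban is identity", {
  tt <- mini_table(p_stroke = 0.04, p_blind = 0.01)
  rural <- list(label = "rural", prevalence = 0.1,
                rural_hr = default_rural_hr())
  out <- apply_rural_hr(tt, rural)
  expect_equal(out$P[[1]]["DM_NO_COMP", "DM_STROKE"], 0.05)   # 0.04 * 1.25
  expect_equal(out$P[[1]]["DM_DR", "DM_BLINDNESS"], 0.0209)   # 0.01 * 2.09
  urban <- list(label = "urban", prevalence = 0.1, rural_hr = numeric())
  expect_identical(apply_rural_hr(tt, urban), tt)
  bad <- list(label = "rural", prevalence = 0.1,
              rural_hr = c(NOT_A_STATE = 2))
  expect_error(apply_rural_hr(tt, bad), "unknown transition identifier")
})

test_that("overflowing outflows are rescaled proportionally to sum 1", {
  # outflows 0.9 pre-HR; a large micro HR pushes them past 1
  long <- data.frame(
    from_state = rep("DM_NO_COMP", 3),
    to_state = c("DM_NO_COMP", "DM_DKD", "DM_DR"),
    age_low = 18, age_high = 80, probability = c(0.1, 0.45, 0.45))
  tt <- transition_table(long)
  hr <- missed_diagnosis_hr(hr_micro = 1.1 / 0.9, hr_macro = 1, hr_death = 1)
  expect_warning(out <- apply_missed_diagnosis_hr(tt, hr), "rescaled")
  P <- out$P[[1]]
  expect_equal(P["DM_NO_COMP", "DM_NO_COMP"], 0)
  expect_equal(P["DM_NO_COMP", "DM_DKD"], 0.55 / 1.1)
  expect_equal(sum(P["DM_NO_COMP", ]), 1, tolerance = 1e-12)
})

test_that("HR applications keep rows stochastic and commute when uncapped", {
  rural <- list(label = "rural", prevalence = 0.1,
                rural_hr = default_rural_hr())
  for (seed in 1:5) {
    p <- generate_parameter_set(synthetic_spec(seed = seed, "rural"))
    a <- apply_rural_hr(apply_missed_diagnosis_hr(p$transitions,
                                                  p$missed_hr), rural)
    b <- apply_missed_diagnosis_hr(apply_rural_hr(p$transitions, rural),
                                   p$missed_hr)
    for (band in seq_along(a$P)) {
      expect_equal(rowSums(a$P[[band]]),
                   setNames(rep(1, 13), health_states()), tolerance = 1e-9)
      expect_equal(a$P[[band]], b$P[[band]], tolerance = 1e-12)
    }
  }
})

test_that("parameter paths read and write consistently", {
  ids <- c("setting.prevalence", "discount.rate", "costs.ogtt_cost",
           "costs.state_annual_cost.DM_CVD",
           "utilities.state_utility.DM_DR",
           "strategies.FCG.sensitivity", "missed_hr.hr_micro")
  for (id in ids) {
    v <- get_param(params_urban, id)
    p2 <- set_param(params_urban, id, v * 0.9)
    expect_equal(get_param(p2, id), v * 0.9, tolerance = 1e-12)
  }
  # transition paths scale all bands proportionally and re-close rows
  v <- get_param(params_urban, "transitions.DM_NO_COMP.DM_CVD")
  p2 <- set_param(params_urban, "transitions.DM_NO_COMP.DM_CVD", 1.2 * v)
  expect_equal(get_param(p2, "transitions.DM_NO_COMP.DM_CVD"), 1.2 * v,
               tolerance = 1e-12)
  for (b in seq_along(p2$transitions$P))
    expect_equal(rowSums(p2$transitions$P[[b]]),
                 setNames(rep(1, 13), health_states()), tolerance = 1e-12)
})

test_that("transition CSV import matches the in-memory constructor", {
  f <- withr::local_tempfile(fileext = ".csv")
  long <- tt_to_long(mini_table())
  write.csv(long, f, row.names = FALSE)
  expect_equal(read_transition_csv(f)$P[[1]], mini_table()$P[[1]],
               tolerance = 1e-12)
})
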