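test_that("discount factors follow 1/(1+r)^t", {
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_equal(discount_factor(0.05, 1), 0.952381, tolerance = 1e-6)
  expect_equal(discount_factor(0.05, 10), (1 / 1.05)^10, tolerance = 1e-12)
  expect_error(discount_factor(-0.1, 1), "non-negative")
  expect_error(discount_factor(0.05, 1.5), "integer")
})

test_that("half-cycle correction is the trapezoid rule over the trace", {
  const <- matrix(0.5, 4, 3)
  expect_equal(half_cycle_correct(const), const[1:3, ])
  lin <- matrix(c(1, 0), 2, 1)
  expect_equal(half_cycle_correct(lin), matrix(0.5, 1, 1))
  set.seed(3)
  occ <- matrix(runif(60), 10, 6)
  w <- runif(6)
  hc_total <- sum(half_cycle_correct(occ) %*% w)
  trap <- sum(vapply(1:9, function(t)
    (sum(occ[t, ] * w) + sum(occ[t + 1, ] * w)) / 2, 0))
  expect_equal(hc_total, trap, tolerance = 1e-12)
  expect_warning(half_cycle_correct(matrix(1, 1, 2)), "single row")
})

test_that("two-state fixture matches its geometric closed form", {
  toy <- toy_fixture("two_state", q = 0.1, start_age = 75)
  oc <- run_cohort(toy, "diagnosed", half_cycle = FALSE)
  expect_equal(oc$total_qaly, sum(0.9^(0:4)), tolerance = 1e-9)
  expect_equal(oc$total_qaly, 4.0951, tolerance = 1e-9)
  oc5 <- run_cohort(toy, "diagnosed", half_cycle = FALSE,
                    discount_rate = 0.05)
  expect_equal(oc5$total_qaly, sum((0.9 / 1.05)^(0:4)), tolerance = 1e-9)
  # immortal cohort accrues exactly the horizon length
  im <- toy_fixture("two_state", q = 0, start_age = 18)
  oc0 <- run_cohort(im, "diagnosed", half_cycle = FALSE)
  expect_equal(oc0$total_qaly, 62, tolerance = 1e-9)
  expect_equal(run_cohort(im, "diagnosed")$total_qaly, 62, tolerance = 1e-9)
})

test_that("four-state chain matches an independent matrix-geometric sum", {
  toy <- toy_fixture("four_state_chain", start_age = 70,
                     discount_rate = 0.05)
  oc <- run_cohort(toy, "diagnosed")
  # oracle: explicit occupancy powers + trapezoid accrual, written
  # independently of the engine
  P <- toy$transitions$P[[1]]
  u <- toy$utilities$state_utility[colnames(P)]
  cc <- toy$costs$state_annual_cost[colnames(P)]
  v <- as.numeric(colnames(P) == "DM_NO_COMP")
  qaly <- cost <- 0
  for (t in 0:9) {
    vt <- v; for (k in seq_len(t)) vt <- vt %*% P
    vt1 <- vt %*% P
    qaly <- qaly + (sum(vt * u) + sum(vt1 * u)) / 2 / 1.05^t
    cost <- cost + (sum(vt * cc) + sum(vt1 * cc)) / 2 / 1.05^t
  }
  expect_equal(oc$total_qaly, qaly, tolerance = 1e-9)
  expect_equal(oc$total_cost, cost, tolerance = 1e-9)
})

test_that("cohort traces conserve mass and death is monotone", {
  for (arm in c("diagnosed", "missed", "negative")) {
    oc <- run_cohort(params_rural, arm, start_age = 40)
    tr <- oc$traces[[1]]
    expect_equal(rowSums(tr$occupancy), rep(1, tr$cycles + 1),
                 tolerance = 1e-9)
    expect_true(all(diff(tr$occupancy[, "DEATH"]) >= -1e-12))
    expect_true(all(tr$occupancy >= -1e-12 & tr$occupancy <= 1 + 1e-12))
  }
  # start at the horizon: zero-cycle outcome
  oc80 <- run_cohort(params_urban, "diagnosed", start_age = 80)
  expect_equal(oc80$total_qaly, 0)
  expect_equal(oc80$total_cost, 0)
})

test_that("forward recursion and backward value sweep agree", {
  for (p in list(params_urban, params_rural)) {
    for (arm in c("diagnosed", "missed", "negative")) {
      fwd <- run_cohort(p, arm)
      bwd <- arm_value(p, arm)
      expect_equal(fwd$total_cost, unname(bwd["cost"]), tolerance = 1e-9)
      expect_equal(fwd$total_qaly, unname(bwd["qaly"]), tolerance = 1e-9)
    }
  }
})

test_that("discounted totals are non-increasing in the discount rate", {
  rates <- c(0, 0.03, 0.05, 0.08)
  q <- vapply(rates, function(r)
    run_cohort(params_urban, "diagnosed", discount_rate = r)$total_qaly, 0)
  cst <- vapply(rates, function(r)
    run_cohort(params_urban, "diagnosed", discount_rate = r)$total_cost, 0)
  expect_true(all(diff(q) <= 1e-12))
  expect_true(all(diff(cst) <= 1e-12))
})

test_that("missed diagnosis never improves quality-adjusted survival", {
  for (p in list(params_urban, params_rural)) {
    expect_lte(run_cohort(p, "missed")$total_qaly,
               run_cohort(p, "diagnosed")$total_qaly)
  }
})

test_that("microsimulation is seed-reproducible and matches the cohort", {
  m1 <- run_microsimulation(params_urban, "diagnosed", 500, seed = 7)
  m2 <- run_microsimulation(params_urban, "diagnosed", 500, seed = 7)
  expect_identical(m1, m2)
  # degenerate walk: one immortal individual accrues the horizon exactly
  im <- toy_fixture("two_state", q = 0, start_age = 18)
  m <- run_microsimulation(im, "diagnosed", 1, seed = 1, half_cycle = FALSE)
  expect_equal(m$total_qaly, 62, tolerance = 1e-12)
  # two-state toy: Monte Carlo mean within 3 SE of the cohort expectation
  toy <- toy_fixture("two_state", q = 0.1, start_age = 70,
                     discount_rate = 0.03)
  mc <- run_microsimulation(toy, "diagnosed", 20000, seed = 5)
  ch <- run_cohort(toy, "diagnosed")
  expect_lt(abs(mc$total_qaly - ch$total_qaly), 3 * mc$mc_se_qaly)
  expect_error(run_microsimulation(params_urban, "diagnosed", 0, seed = 1),
               "at least 1")
})

test_that("strategy outcomes are the classification-weighted arm mixture", {
  p <- params_urban
  s <- p$strategies$POCT_HBA1C
  out <- run_strategy(p, s)
  cls <- classify(p$setting$prevalence, s)
  vd <- run_cohort(p, "diagnosed")
  vm <- run_cohort(p, "missed")
  vn <- run_cohort(p, "negative")
  w <- c(cls$p_diagnosed, cls$p_missed,
         cls$p_misdiagnosed + cls$p_true_negative)
  expect_equal(out$total_qaly,
               sum(w * c(vd$total_qaly, vm$total_qaly, vn$total_qaly)),
               tolerance = 1e-9)
  expect_equal(out$total_cost,
               sum(w * c(vd$total_cost, vm$total_cost, vn$total_cost)) +
                 screening_stage_cost(p$setting$prevalence, s, p$costs),
               tolerance = 1e-9)
})

test_that("a perfect test leaves no missed or misdiagnosed contribution", {
  p <- params_urban
  s <- screening_strategy("POCT_HBA1C", 1, 1, 3, 1, 1)
  out <- run_strategy(p, s)
  prev <- p$setting$prevalence
  vd <- run_cohort(p, "diagnosed")
  vn <- run_cohort(p, "negative")
  expect_equal(out$total_qaly,
               prev * vd$total_qaly + (1 - prev) * vn$total_qaly,
               tolerance = 1e-9)
  # vanishing prevalence: outcome converges to the non-diabetic model
  p2 <- p
  p2$setting$prevalence <- 1e-9
  out2 <- run_strategy(p2, s)
  expect_equal(out2$total_qaly, vn$total_qaly, tolerance = 1e-6)
})
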