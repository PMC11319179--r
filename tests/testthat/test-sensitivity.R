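test_that("beta fits carry the event counts and their moments", {
  d <- fit_beta(90, 10)
  expect_equal(d$alpha / (d$alpha + d$beta_count), 0.9)
  d11 <- fit_beta(1, 1)
  expect_equal(d11$alpha, 1)
  expect_equal(d11$beta_count, 1)
  expect_error(fit_beta(0, 0), "positive")
  # zero-count continuity correction keeps the distribution proper
  d0 <- fit_beta(0, 20)
  expect_equal(d0$alpha, 0.5)
  set.seed(21)
  n <- 1e5
  x <- rbeta(n, d$alpha, d$beta_count)
  m <- 0.9
  v <- (90 * 10) / (100^2 * 101)
  expect_lt(abs(mean(x) - m), 3 * sqrt(v / n))
  mu4 <- mean((x - mean(x))^4)
  expect_lt(abs(var(x) - v), 3 * sqrt((mu4 - v^2) / n))
})

test_that("lognormal fits put the median at the point and sd at 10% of mean", {
  d <- fit_lognormal(1000)
  expect_equal(d$mu, log(1000), tolerance = 1e-9)
  expect_equal(d$mu, 6.907755, tolerance = 1e-6)
  expect_error(fit_lognormal(-5), "positive")
  set.seed(22)
  for (point in c(12, 1000, 48000)) {
    x <- rlnorm(1e5, fit_lognormal(point)$mu, fit_lognormal(point)$sigma)
    expect_lt(abs(median(x) - point) / point, 0.01)
    expect_true(sd(x) / mean(x) > 0.09 && sd(x) / mean(x) < 0.11)
  }
})

test_that("one-way sensitivity endpoints equal direct full-model re-runs", {
  p <- params_urban
  ranges <- list(
    param_range("discount.rate", p$discount$rate, low = 0, high = 0.08,
                source = "reported_95CI"),
    param_range("setting.prevalence", p$setting$prevalence,
                is_probability = TRUE),
    # a parameter with no causal path into the POCT-vs-FCG comparison
    param_range("strategies.VENOUS_HBA1C.cost_direct_medical",
                p$strategies$VENOUS_HBA1C$cost_direct_medical))
  tor <- owsa(p, ranges, comparison = c("FCG", "POCT_HBA1C"))
  # independent oracle: run_strategy + compute_icur at each discount rate
  icur_at_rate <- function(r) {
    p2 <- p
    p2$discount$rate <- r
    compute_icur(run_strategy(p2, "FCG"), run_strategy(p2, "POCT_HBA1C"),
                 p2$wtp)$icur
  }
  row <- tor[tor$parameter_id == "discount.rate", ]
  expect_equal(row$icur_low, icur_at_rate(0), tolerance = 1e-9)
  expect_equal(row$icur_high, icur_at_rate(0.08), tolerance = 1e-9)
  # no-effect parameter has zero bar width
  expect_equal(tor[tor$parameter_id ==
                     "strategies.VENOUS_HBA1C.cost_direct_medical",
                   "width"], 0, tolerance = 1e-9)
  # sorted by descending width
  expect_true(all(diff(tor$width) <= 1e-12))
})

test_that("a cost parameter linear in the ICUR gives symmetric endpoints", {
  # toy: both strategies identical except POCT adds a pure screening cost,
  # so ICUR = dC/dE is linear in that cost
  toy <- toy_fixture("two_state", q = 0.1, start_age = 70)
  toy$strategies$POCT_HBA1C$sensitivity <- 0.9
  toy$strategies$POCT_HBA1C$cost_direct_medical <- 10
  toy$strategies$FCG$sensitivity <- 0.6
  toy$utilities$state_utility["NON_DM"] <- 1
  toy$missed_hr <- missed_diagnosis_hr(1.391, 1.287, 1.29)
  r <- param_range("strategies.POCT_HBA1C.cost_direct_medical", 10)
  tor <- owsa(toy, list(r), comparison = c("FCG", "POCT_HBA1C"))
  base <- attr(tor, "icur_base")
  expect_equal(tor$icur_high - base, base - tor$icur_low, tolerance = 1e-6)
})

test_that("PSA draws are reproducible and degenerate draws hit the base case", {
  dists <- default_psa_config(params_urban)
  a <- psa(params_urban, dists, n_iter = 20, seed = 33)
  b <- psa(params_urban, dists, n_iter = 20, seed = 33)
  expect_identical(a$samples, b$samples)
  expect_identical(a$deltas, b$deltas)
  # near-degenerate distributions reproduce the deterministic base result
  degen <- lapply(names(dists), function(id) {
    v <- get_param(params_urban, id)
    fit_uniform(v - 1e-11, v + 1e-11)
  })
  names(degen) <- names(dists)
  degen[["discount.rate"]] <- fit_uniform(0.05 - 1e-11, 0.05 + 1e-11)
  d <- psa(params_urban, degen, n_iter = 3, seed = 1)
  base <- screen_cea(params_urban)
  for (nm in names(base$outcomes)) {
    expect_equal(d$samples$cost[d$samples$strategy == nm],
                 rep(base$outcomes[[nm]]$total_cost, 3), tolerance = 1e-6)
    expect_equal(d$samples$utility[d$samples$strategy == nm],
                 rep(base$outcomes[[nm]]$total_qaly, 3), tolerance = 1e-6)
  }
})

test_that("the CEAC equals brute-force net-monetary-benefit counting", {
  ps <- psa(params_urban, n_iter = 30, seed = 44)
  grid <- c(0, 500, 5000, 37653, 1e6)
  cc <- ceac(ps, grid)
  for (pr in ps$comparisons) {
    d <- ps$deltas[ps$deltas$reference == pr[1] &
                     ps$deltas$comparator == pr[2], ]
    for (l in grid) {
      brute <- sum(l * d$delta_utility - d$delta_cost > 0) / nrow(d)
      got <- cc$probability[cc$lambda == l & cc$reference == pr[1] &
                              cc$comparator == pr[2]]
      expect_equal(got, brute)
    }
    # lambda = 0 reduces NMB to -dC; lambda -> infinity to P(dE > 0)
    expect_equal(cc$probability[cc$lambda == 0 & cc$comparator == pr[2] &
                                  cc$reference == pr[1]],
                 mean(d$delta_cost < 0))
    expect_equal(cc$probability[cc$lambda == 1e6 & cc$comparator == pr[2] &
                                  cc$reference == pr[1]],
                 mean(1e6 * d$delta_utility - d$delta_cost > 0))
  }
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_error(ceac(ps, numeric(0)), "non-empty")
})

test_that("uniformly dominant samples give probability 1 at every lambda", {
  deltas <- data.frame(draw = 1:10, reference = "FCG",
                       comparator = "POCT_HBA1C",
                       delta_cost = -runif(10, 1, 5),
                       delta_utility = runif(10, 0.01, 0.1))
  cc <- ceac(deltas, c(0, 1000, 37653))
  expect_true(all(cc$probability == 1))
})
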