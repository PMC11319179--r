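#' Discount factor at integer cycle boundaries
#'
#' The first cycle (t = 0) is undiscounted; cycle t is weighted by
#' \code{1/(1+rate)^t}.
#'
#' @param rate Annual discount rate (proportion, >= 0).
#' @param t Integer cycle index (vectorized).
#' @return Numeric multiplier(s).
#' @export
discount_factor <- function(rate, t) {
  if (any(rate < 0)) stop("discount rate must be non-negative")
  if (any(t < 0) || any(t != floor(t))) stop("t must be a non-negative integer")
  1 / (1 + rate)^t
}

#' Half-cycle correction of a cohort trace
#'
#' Annual-cycle state-transition models overstate time spent in the origin
#' state if occupancy is read at cycle starts. Averaging occupancy at cycle
#' start and cycle end (the trapezoid rule over the trace) removes the
#' first-order discretization bias.
#'
#' @param occupancy Matrix, one row per cycle boundary (T+1 rows for T
#'   cycles), one column per state.
#' @return Matrix of T rows: the effective occupancy for each cycle. A
#'   single-row input is returned unchanged with a warning.
#' @export
half_cycle_correct <- function(occupancy) {
  occupancy <- as.matrix(occupancy)
  n <- nrow(occupancy)
  if (n < 2) {
    warning("trace has a single row; no half-cycle correction possible")
    return(occupancy)
  }
  (occupancy[-n, , drop = FALSE] + occupancy[-1, , drop = FALSE]) / 2
}

# Arm-specific transition table and start state.  The rural hazard ratios
# apply to every arm in a rural setting; missed-diagnosis hazard ratios only
# to the missed arm.  The negative arms walk the same table from NON_DM,
# whose only exit is background mortality.
arm_table <- function(params, arm) {
  base <- apply_rural_hr(params$transitions, params$setting)
  switch(arm,
         diagnosed = list(tt = base, start = "DM_NO_COMP"),
         missed = list(tt = apply_missed_diagnosis_hr(base, params$missed_hr),
                       start = "DM_NO_COMP"),
         negative = list(tt = base, start = "NON_DM"),
         stop("unknown arm: ", arm))
}

# Forward recursion for one start age.  Returns a cohort_trace.
run_trace <- function(tt, start_age, horizon_age, start_state, cost_vec,
                      util_vec, rate, half_cycle = TRUE) {
  states <- health_states()
  T_n <- max(0L, as.integer(horizon_age - start_age))
  occ <- matrix(0, T_n + 1L, length(states), dimnames = list(NULL, states))
  occ[1L, start_state] <- 1
  if (T_n > 0L) {
    for (t in seq_len(T_n)) {
      P <- tt$P[[band_for_age(tt, start_age + t - 1L)]]
      occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% P
    }
    hc <- if (half_cycle) half_cycle_correct(occ)
          else occ[-(T_n + 1L), , drop = FALSE]
    df <- discount_factor(rate, 0:(T_n - 1L))
    per_cost <- as.vector(hc %*% cost_vec) * df
    per_qaly <- as.vector(hc %*% util_vec) * df
  } else {
    per_cost <- per_qaly <- numeric(0)
  }
  structure(list(occupancy = occ, cycles = T_n, start_age = start_age,
                 per_cycle_cost = per_cost, per_cycle_qaly = per_qaly,
                 total_cost = sum(per_cost), total_qaly = sum(per_qaly)),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace: start age %g, %d annual cycles\n",
              x$start_age, x$cycles))
  cat(sprintf("  discounted totals: cost %.2f USD, %.4f QALY\n",
              x$total_cost, x$total_qaly))
  invisible(x)
}

#' Export a cohort trace as a data frame
#'
#' @param x A \code{cohort_trace}.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return Data frame with cycle, age, one occupancy column per state, and
#'   the discounted per-cycle cost and QALY accruals (NA on the final
#'   boundary row, which closes the last cycle).
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  T_n <- x$cycles
  data.frame(cycle = 0:T_n, age = x$start_age + 0:T_n,
             x$occupancy,
             cost = c(x$per_cycle_cost, NA_real_)[seq_len(T_n + 1L)],
             qaly = c(x$per_cycle_qaly, NA_real_)[seq_len(T_n + 1L)],
             check.names = FALSE)
}

#' Run one arm of the model as a deterministic cohort
#'
#' Propagates state occupancy through the annual transition matrices from
#' each baseline age stratum until the cohort reaches the horizon age,
#' accruing half-cycle-corrected, discounted costs and QALYs, and averages
#' strata by their population weights.
#'
#' @param params A validated \code{\link{cea_parameters}}.
#' @param arm \code{"diagnosed"} (treated diabetic, base transitions),
#'   \code{"missed"} (untreated diabetic, missed-diagnosis hazard ratios
#'   applied) or \code{"negative"} (non-diabetic, background mortality
#'   only). Rural hazard ratios apply to all arms in a rural setting.
#' @param start_age Optional single start age overriding the baseline
#'   population (useful for toy fixtures and closed-form checks).
#' @param half_cycle Apply half-cycle correction (default TRUE).
#' @param discount_rate Override of \code{params$discount$rate}.
#' @return Object of class \code{arm_outcome}: population-weighted
#'   \code{total_cost} and \code{total_qaly} (screening-stage cost not
#'   included) plus one \code{cohort_trace} per age stratum.
#' @export
run_cohort <- function(params, arm = c("diagnosed", "missed", "negative"),
                       start_age = NULL, half_cycle = TRUE,
                       discount_rate = NULL) {
  arm <- match.arg(arm)
  at <- arm_table(params, arm)
  rate <- if (is.null(discount_rate)) params$discount$rate else discount_rate
  cost_vec <- params$costs$state_annual_cost[health_states()]
  util_vec <- params$utilities$state_utility[health_states()]
  if (is.null(start_age)) {
    strata <- stats::aggregate(weight ~ age, params$baseline_population, sum)
  } else {
    strata <- data.frame(age = start_age, weight = 1)
  }
  traces <- lapply(strata$age, function(a)
    run_trace(at$tt, a, params$horizon_age, at$start, cost_vec, util_vec,
              rate, half_cycle))
  structure(list(
    arm = arm,
    total_cost = sum(strata$weight * vapply(traces, `[[`, 0, "total_cost")),
    total_qaly = sum(strata$weight * vapply(traces, `[[`, 0, "total_qaly")),
    traces = traces, weights = strata$weight, ages = strata$age),
    class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("Arm outcome [%s]: cost %.2f USD, %.4f QALY", x$arm,
              x$total_cost, x$total_qaly))
  if (!is.null(x$mc_se_cost))
    cat(sprintf(" (MC SE: cost %.3f, QALY %.5f)", x$mc_se_cost,
                x$mc_se_qaly))
  cat("\n")
  invisible(x)
}

# Backward value sweep: expected discounted (cost, qaly) from every state at
# every integer age, in one pass.  Algebraically identical to the forward
# recursion with half-cycle correction: the accrual of a transition cycle is
# the mean of origin and destination rewards, and value-to-go is discounted
# one cycle per year of age.  Returns the population-weighted arm totals.
arm_value <- function(params, arm, half_cycle = TRUE, discount_rate = NULL) {
  at <- arm_table(params, arm)
  tt <- at$tt
  rate <- if (is.null(discount_rate)) params$discount$rate else discount_rate
  states <- health_states()
  cost_vec <- params$costs$state_annual_cost[states]
  util_vec <- params$utilities$state_utility[states]
  strata <- stats::aggregate(weight ~ age, params$baseline_population, sum)
  amin <- min(strata$age)
  horizon <- params$horizon_age
  Vc <- Vq <- rep(0, length(states))
  ages <- if (horizon - 1 >= amin) seq(horizon - 1, amin) else integer(0)
  value_at <- matrix(NA_real_, length(ages) + 1L, 2L)
  # value_at[k, ] holds (cost, qaly) from the start state at age horizon-k+1
  res_c <- res_q <- stats::setNames(rep(NA_real_, horizon - amin + 1L),
                                    as.character(amin:horizon))
  res_c[as.character(horizon)] <- 0
  res_q[as.character(horizon)] <- 0
  for (a in ages) {
    P <- tt$P[[band_for_age(tt, a)]]
    if (half_cycle) {
      acc_c <- 0.5 * cost_vec + 0.5 * as.vector(P %*% cost_vec)
      acc_q <- 0.5 * util_vec + 0.5 * as.vector(P %*% util_vec)
    } else {
      acc_c <- cost_vec
      acc_q <- util_vec
    }
    Vc <- acc_c + as.vector(P %*% Vc) / (1 + rate)
    Vq <- acc_q + as.vector(P %*% Vq) / (1 + rate)
    names(Vc) <- names(Vq) <- states
    res_c[as.character(a)] <- Vc[at$start]
    res_q[as.character(a)] <- Vq[at$start]
  }
  keep <- as.character(pmin(strata$age, horizon))
  c(cost = sum(strata$weight * res_c[keep]),
    qaly = sum(strata$weight * res_q[keep]))
}

#' Run one arm as a seeded individual-level microsimulation
#'
#' Each simulated individual draws a start age from the baseline population
#' and walks the arm's transition matrix with per-cycle categorical draws
#' until the horizon age. A transition is assumed to happen mid-cycle, so
#' the transition cycle accrues half the origin-state and half the
#' destination-state reward (the individual-level analogue of half-cycle
#' correction). Bit-reproducible for a fixed seed; the caller's RNG state is
#' left untouched.
#'
#' @inheritParams run_cohort
#' @param n_individuals Number of simulated individuals (>= 1).
#' @param seed Integer RNG seed.
#' @return An \code{arm_outcome} whose totals are Monte Carlo means, with
#'   standard errors in \code{mc_se_cost} / \code{mc_se_qaly}.
#' @export
run_microsimulation <- function(params, arm = c("diagnosed", "missed",
                                                "negative"),
                                n_individuals, seed, half_cycle = TRUE,
                                discount_rate = NULL) {
  arm <- match.arg(arm)
  if (n_individuals < 1) stop("n_individuals must be at least 1")
  at <- arm_table(params, arm)
  rate <- if (is.null(discount_rate)) params$discount$rate else discount_rate
  states <- health_states()
  ns <- length(states)
  cost_vec <- params$costs$state_annual_cost[states]
  util_vec <- params$utilities$state_utility[states]
  start_idx <- match(at$start, states)
  horizon <- params$horizon_age
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  bp <- params$baseline_population
  ages <- bp$age[sample.int(nrow(bp), n_individuals, replace = TRUE,
                            prob = bp$weight)]
  tot_c <- tot_q <- numeric(n_individuals)
  # cumulative transition rows per band, computed once
  cum <- lapply(at$tt$P, function(m) t(apply(m, 1, cumsum)))
  for (a0 in sort(unique(ages))) {
    who <- which(ages == a0)
    T_n <- max(0L, as.integer(horizon - a0))
    if (T_n == 0L) next
    st <- rep.int(start_idx, length(who))
    cst <- qal <- numeric(length(who))
    for (t in 0:(T_n - 1L)) {
      b <- band_for_age(at$tt, a0 + t)
      u <- stats::runif(length(st))
      nxt <- integer(length(st))
      for (s in unique(st)) {
        idx <- st == s
        nxt[idx] <- findInterval(u[idx], cum[[b]][s, ]) + 1L
      }
      df <- 1 / (1 + rate)^t
      if (half_cycle) {
        cst <- cst + 0.5 * (cost_vec[st] + cost_vec[nxt]) * df
        qal <- qal + 0.5 * (util_vec[st] + util_vec[nxt]) * df
      } else {
        cst <- cst + cost_vec[st] * df
        qal <- qal + util_vec[st] * df
      }
      st <- nxt
    }
    tot_c[who] <- cst
    tot_q[who] <- qal
  }
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  structure(list(arm = arm, total_cost = mean(tot_c),
                 total_qaly = mean(tot_q),
                 mc_se_cost = se(tot_c), mc_se_qaly = se(tot_q),
                 n_individuals = n_individuals, seed = seed),
            class = "arm_outcome")
}

#' Evaluate one screening strategy end to end
#'
#' Classifies the population through the decision tree, runs the four arms
#' (diagnosed and missed through the diabetic model, misdiagnosed and true
#' negative through the non-diabetic model), mixture-weights the arm
#' outcomes by the classification fractions and adds the screening-stage
#' cost (incurred at time zero, undiscounted).
#'
#' @param params A validated \code{\link{cea_parameters}}.
#' @param strategy A \code{\link{screening_strategy}} (or the name of one
#'   in \code{params$strategies}).
#' @param mode \code{"cohort"} (deterministic expectation, the primary
#'   engine) or \code{"microsim"} (individual-level Monte Carlo).
#' @param n_individuals,seed Microsimulation size and seed (microsim only).
#' @return List of class \code{strategy_outcome}: \code{total_cost},
#'   \code{total_qaly}, the \code{classification}, the per-arm outcomes and
#'   the screening-stage cost.
#' @export
run_strategy <- function(params, strategy, mode = c("cohort", "microsim"),
                         n_individuals = 10000, seed = 1) {
  mode <- match.arg(mode)
  if (is.character(strategy)) {
    strategy <- params$strategies[[strategy]]
    if (is.null(strategy)) stop("unknown strategy name")
  }
  cls <- classify(params$setting$prevalence, strategy)
  if (mode == "cohort") {
    vd <- arm_value(params, "diagnosed")
    vm <- arm_value(params, "missed")
    vn <- arm_value(params, "negative")
    arms <- list(diagnosed = vd, missed = vm, negative = vn)
    ac <- c(vd["cost"], vm["cost"], vn["cost"])
    aq <- c(vd["qaly"], vm["qaly"], vn["qaly"])
  } else {
    od <- run_microsimulation(params, "diagnosed", n_individuals, seed)
    om <- run_microsimulation(params, "missed", n_individuals, seed + 1L)
    on_ <- run_microsimulation(params, "negative", n_individuals, seed + 2L)
    arms <- list(diagnosed = od, missed = om, negative = on_)
    ac <- c(od$total_cost, om$total_cost, on_$total_cost)
    aq <- c(od$total_qaly, om$total_qaly, on_$total_qaly)
  }
  w <- c(cls$p_diagnosed, cls$p_missed,
         cls$p_misdiagnosed + cls$p_true_negative)
  scost <- screening_stage_cost(params$setting$prevalence, strategy,
                                params$costs)
  structure(list(strategy = strategy$name,
                 total_cost = sum(w * ac) + scost,
                 total_qaly = sum(w * aq),
                 classification = cls, arms = arms,
                 screening_cost = scost, mode = mode),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("Strategy %s [%s]: lifetime cost %.2f USD, %.4f QALY\n",
              x$strategy, x$mode, x$total_cost, x$total_qaly))
  cat(sprintf("  screening stage: %.2f USD per capita\n", x$screening_cost))
  invisible(x)
}
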