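#' Age-banded annual transition table
#'
#' Holds one row-stochastic transition matrix per age band over the thirteen
#' health states. Rows not specified in \code{long} default to a self-loop of
#' 1 (absorbing), so partially specified tables are still stochastic.
#'
#' @param long Data frame with columns \code{from_state}, \code{to_state},
#'   \code{age_low}, \code{age_high}, \code{probability}. Age bands are
#'   \code{[age_low, age_high)} except the last, which is closed.
#' @param normalize_tol Rows whose sum differs from 1 by more than this before
#'   normalization raise an error; smaller discrepancies are renormalized.
#' @return Object of class \code{transition_table} with elements
#'   \code{age_bands} (data frame \code{age_low}, \code{age_high}) and
#'   \code{P} (list of matrices, one per band).
#' @export
transition_table <- function(long, normalize_tol = 1e-6) {
  req <- c("from_state", "to_state", "age_low", "age_high", "probability")
  if (!all(req %in% names(long)))
    stop("transition table needs columns: ", paste(req, collapse = ", "))
  states <- health_states()
  bad <- setdiff(unique(c(long$from_state, long$to_state)), states)
  if (length(bad))
    stop("unknown health state(s) in transition table: ",
         paste(bad, collapse = ", "))
  bands <- unique(long[, c("age_low", "age_high")])
  bands <- bands[order(bands$age_low), , drop = FALSE]
  rownames(bands) <- NULL
  if (any(bands$age_high <= bands$age_low))
    stop("age_high must exceed age_low in every band")
  if (nrow(bands) > 1 &&
      any(bands$age_low[-1] != bands$age_high[-nrow(bands)]))
    stop("age bands must form an ordered partition")
  mask <- allowed_transitions()
  P <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    m <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
    diag(m) <- 1  # default: unspecified rows are absorbing
    rows <- long[long$age_low == bands$age_low[b], , drop = FALSE]
    for (f in unique(rows$from_state)) {
      sub <- rows[rows$from_state == f, , drop = FALSE]
      m[f, ] <- 0
      m[f, sub$to_state] <- sub$probability
    }
    if (any(m < 0) || any(m > 1))
      stop(sprintf("probabilities outside [0,1] in age band [%g,%g)",
                   bands$age_low[b], bands$age_high[b]))
    viol <- m > 0 & !mask
    if (any(viol)) {
      idx <- which(viol, arr.ind = TRUE)[1, ]
      stop(sprintf("structurally forbidden transition %s -> %s",
                   states[idx[1]], states[idx[2]]))
    }
    rs <- rowSums(m)
    off <- abs(rs - 1) > normalize_tol
    if (any(off))
      stop(sprintf(
        "row sum != 1 (%.8f) for state %s in age band [%g,%g)",
        rs[which(off)[1]], states[which(off)[1]],
        bands$age_low[b], bands$age_high[b]))
    P[[b]] <- m / rs
  }
  structure(list(age_bands = bands, P = P), class = "transition_table")
}

# Index of the age band containing `age` (last band closed above).
band_for_age <- function(tt, age) {
  b <- findInterval(age, tt$age_bands$age_low)
  nb <- nrow(tt$age_bands)
  if (b < 1 || age > tt$age_bands$age_high[nb])
    stop("age ", age, " outside the table's age range")
  min(b, nb)
}

# Long-format view of a transition table (non-zero and diagonal entries).
tt_to_long <- function(tt) {
  states <- health_states()
  out <- list()
  for (b in seq_along(tt$P)) {
    m <- tt$P[[b]]
    idx <- which(m > 0 | row(m) == col(m), arr.ind = TRUE)
    keep <- m[idx] > 0
    idx <- idx[keep, , drop = FALSE]
    out[[b]] <- data.frame(
      from_state = states[idx[, 1]], to_state = states[idx[, 2]],
      age_low = tt$age_bands$age_low[b], age_high = tt$age_bands$age_high[b],
      probability = m[idx], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read a transition table from CSV
#'
#' @param path CSV with columns
#'   \code{from_state,to_state,age_low,age_high,probability}.
#' @return A \code{\link{transition_table}}.
#' @export
read_transition_csv <- function(path) {
  transition_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Screening strategy description
#'
#' @param name One of \code{\link{strategy_names}}.
#' @param sensitivity,specificity Test operating characteristics in [0,1].
#' @param cost_direct_medical,cost_direct_nonmedical,cost_indirect Per-test
#'   cost components in USD (registration/test/staff time; travel and
#'   lodging; participant time valued at the average wage).
#' @param cut_point_text Informational description of the positivity cut-point.
#' @return List of class \code{screening_strategy}.
#' @export
screening_strategy <- function(name, sensitivity, specificity,
                               cost_direct_medical, cost_direct_nonmedical,
                               cost_indirect, cut_point_text = "") {
  s <- list(name = name, sensitivity = sensitivity, specificity = specificity,
            cut_point_text = cut_point_text,
            cost_direct_medical = cost_direct_medical,
            cost_direct_nonmedical = cost_direct_nonmedical,
            cost_indirect = cost_indirect)
  class(s) <- "screening_strategy"
  validate_strategy(s)
  s
}

validate_strategy <- function(s) {
  if (!is.character(s$name) || length(s$name) != 1)
    stop("strategy name must be a single string")
  for (f in c("sensitivity", "specificity")) {
    v <- s[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(sprintf("%s: %s must be a probability in [0,1]", s$name, f))
  }
  for (f in c("cost_direct_medical", "cost_direct_nonmedical",
              "cost_indirect")) {
    v <- s[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop(sprintf("%s: %s must be a non-negative cost", s$name, f))
  }
  invisible(s)
}

#' Default rural hazard-ratio multipliers
#'
#' Rural residents face elevated complication risks relative to urban
#' residents: cardiovascular disease 1.15, stroke 1.25, blindness 2.09,
#' foot ulcer 1.42, end-stage renal disease 1.15. Transitions into states
#' not listed are unscaled.
#'
#' @return Named numeric vector keyed by destination state.
#' @export
default_rural_hr <- function() {
  c(DM_CVD = 1.15, DM_STROKE = 1.25, DM_BLINDNESS = 2.09,
    DM_DFU = 1.42, DM_ESRD = 1.15)
}

#' Missed-diagnosis hazard ratios
#'
#' Untreated (missed) diabetics progress faster: microvascular complications
#' HR 1.391, macrovascular 1.287, death 1.290, from a ten-year cohort of
#' patients at HbA1c 7--8\%.
#'
#' @param hr_micro,hr_macro,hr_death Positive multipliers.
#' @return List of class \code{missed_hr}.
#' @export
missed_diagnosis_hr <- function(hr_micro = 1.391, hr_macro = 1.287,
                                hr_death = 1.290) {
  h <- list(hr_micro = hr_micro, hr_macro = hr_macro, hr_death = hr_death)
  if (any(unlist(h) <= 0)) stop("hazard ratios must be positive")
  class(h) <- "missed_hr"
  h
}

#' Assemble and validate a full parameter bundle
#'
#' @param setting List with \code{label} ("urban" or "rural"),
#'   \code{prevalence} of undiagnosed type 2 diabetes in (0,1), and
#'   \code{rural_hr} (named multipliers; must all be 1 for urban).
#' @param strategies Named list of \code{\link{screening_strategy}} objects.
#' @param transitions A \code{\link{transition_table}}. The \code{NON_DM}
#'   row doubles as the non-diabetic model: its death entry is the
#'   age-specific background mortality.
#' @param costs List: \code{state_annual_cost} (named USD/year, direct
#'   medical only for complication states; \code{DEATH} must be 0),
#'   \code{ogtt_cost} (per confirmatory test), \code{currency_rate}
#'   (CNY per USD, default 6.4; informational — all stored values are USD).
#' @param utilities List: \code{state_utility} (named QALY weights in [0,1],
#'   \code{DEATH} = 0).
#' @param missed_hr A \code{\link{missed_diagnosis_hr}}.
#' @param discount List: \code{rate} (default 0.05),
#'   \code{sensitivity_range} (default \code{c(0, 0.08)}).
#' @param wtp List: \code{gdp_per_capita} (default 12551),
#'   \code{multiplier} (default 3), \code{lambda} (defaults to their
#'   product, 37653 USD/QALY).
#' @param baseline_population Data frame \code{age}, \code{sex},
#'   \code{weight}; weights sum to 1, ages within [18, horizon_age].
#' @param horizon_age Simulation stops once the cohort reaches this age
#'   (default 80).
#' @param cycle_length Cycle length in years; fixed at 1.
#' @return Object of class \code{cea_parameters}.
#' @export
cea_parameters <- function(setting, strategies, transitions, costs,
                           utilities, missed_hr = missed_diagnosis_hr(),
                           discount = list(rate = 0.05,
                                           sensitivity_range = c(0, 0.08)),
                           wtp = list(gdp_per_capita = 12551, multiplier = 3),
                           baseline_population,
                           horizon_age = 80, cycle_length = 1) {
  if (is.null(wtp$lambda))
    wtp$lambda <- wtp$multiplier * wtp$gdp_per_capita
  if (is.null(setting$rural_hr))
    setting$rural_hr <-
      if (identical(setting$label, "rural")) default_rural_hr() else numeric()
  if (is.null(costs$currency_rate)) costs$currency_rate <- 6.4
  p <- structure(list(setting = setting, strategies = strategies,
                      transitions = transitions, costs = costs,
                      utilities = utilities, missed_hr = missed_hr,
                      discount = discount, wtp = wtp,
                      baseline_population = baseline_population,
                      horizon_age = horizon_age, cycle_length = cycle_length),
                 class = "cea_parameters")
  validate_parameters(p)
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant (probability bounds, row stochasticity,
#' state coverage of costs and utilities, population weights, discount and
#' willingness-to-pay consistency). Utility ordering (no complication state
#' more desirable than uncomplicated diabetes, which is itself no better
#' than non-diabetic) is checked with a warning rather than an error.
#'
#' @param p A \code{cea_parameters} object.
#' @return \code{p}, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_parameters <- function(p) {
  states <- health_states()
  st <- p$setting
  if (!st$label %in% c("urban", "rural")) stop("setting.label must be urban or rural")
  if (!is.numeric(st$prevalence) || st$prevalence <= 0 || st$prevalence >= 1)
    stop("setting.prevalence must lie in (0,1)")
  if (length(st$rural_hr)) {
    bad <- setdiff(names(st$rural_hr), states)
    if (length(bad)) stop("setting.rural_hr: unknown transition identifier ",
                          paste(bad, collapse = ", "))
    if (any(st$rural_hr <= 0)) stop("setting.rural_hr values must be positive")
    if (st$label == "urban" && any(st$rural_hr != 1))
      stop("setting.rural_hr must be all 1.0 for the urban setting")
  }
  if (length(p$strategies) < 1) stop("at least one screening strategy required")
  for (s in p$strategies) validate_strategy(s)
  if (!inherits(p$transitions, "transition_table"))
    stop("transitions must be a transition_table")
  for (b in seq_along(p$transitions$P)) {
    rs <- rowSums(p$transitions$P[[b]])
    if (any(abs(rs - 1) > 1e-9))
      stop("transitions: row sums deviate from 1 in band ", b)
  }
  cc <- p$costs$state_annual_cost
  if (!all(states %in% names(cc))) stop("costs.state_annual_cost must cover every state")
  if (any(cc < 0)) stop("costs.state_annual_cost must be non-negative")
  if (cc[["DEATH"]] != 0) stop("costs.state_annual_cost.DEATH must be 0")
  if (p$costs$ogtt_cost < 0) stop("costs.ogtt_cost must be non-negative")
  u <- p$utilities$state_utility
  if (!all(states %in% names(u))) stop("utilities.state_utility must cover every state")
  if (any(u < 0 | u > 1)) stop("utilities.state_utility must lie in [0,1]")
  if (u[["DEATH"]] != 0) stop("utilities.state_utility.DEATH must be 0")
  comp <- setdiff(states, c("NON_DM", "DM_NO_COMP", "DEATH"))
  if (u[["NON_DM"]] < u[["DM_NO_COMP"]] || any(u[comp] > u[["DM_NO_COMP"]]))
    warning("utility ordering violated: expected NON_DM >= DM_NO_COMP >= complications")
  hr <- p$missed_hr
  if (any(c(hr$hr_micro, hr$hr_macro, hr$hr_death) <= 0))
    stop("missed_hr values must be positive")
  d <- p$discount
  if (d$rate < 0 || d$rate > 1) stop("discount.rate must lie in [0,1]")
  sr <- d$sensitivity_range
  if (!(sr[1] >= 0 && sr[1] <= d$rate && d$rate <= sr[2] && sr[2] <= 1))
    stop("discount.sensitivity_range must satisfy 0 <= low <= rate <= high <= 1")
  w <- p$wtp
  if (!is.null(w$gdp_per_capita) && !is.null(w$multiplier) &&
      abs(w$lambda - w$multiplier * w$gdp_per_capita) > 1e-9)
    stop("wtp.lambda must equal multiplier * gdp_per_capita")
  bp <- p$baseline_population
  if (!all(c("age", "sex", "weight") %in% names(bp)))
    stop("baseline_population needs columns age, sex, weight")
  if (abs(sum(bp$weight) - 1) > 1e-9)
    stop("baseline_population weights must sum to 1")
  if (any(bp$age < 18 | bp$age > p$horizon_age))
    stop("baseline_population ages must lie in [18, horizon_age]")
  if (p$cycle_length != 1) stop("cycle_length is fixed at 1 year")
  invisible(p)
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Screening CEA parameter set\n")
  cat(sprintf("  setting: %s, undiagnosed prevalence %.3f\n",
              x$setting$label, x$setting$prevalence))
  cat(sprintf("  strategies: %s\n",
              paste(vapply(x$strategies, `[[`, "", "name"), collapse = ", ")))
  cat(sprintf("  age bands: %d over [%g, %g]; horizon age %g\n",
              nrow(x$transitions$age_bands),
              min(x$transitions$age_bands$age_low),
              max(x$transitions$age_bands$age_high), x$horizon_age))
  cat(sprintf("  discount rate %.1f%%; WTP lambda %s USD/QALY\n",
              100 * x$discount$rate, format(x$wtp$lambda, big.mark = ",")))
  invisible(x)
}

#' Write a parameter bundle to JSON
#'
#' Transition tables are stored in long form
#' (\code{from_state,to_state,age_low,age_high,probability}); everything
#' else mirrors the in-memory structure. All monetary values are USD.
#'
#' @param p A validated \code{cea_parameters} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{load_parameters}}
#' @export
write_parameters <- function(p, path) {
  obj <- unclass(p)
  obj$strategies <- lapply(p$strategies, unclass)
  obj$missed_hr <- unclass(p$missed_hr)
  obj$transitions <- tt_to_long(p$transitions)
  obj$costs$state_annual_cost <- as.list(p$costs$state_annual_cost)
  obj$utilities$state_utility <- as.list(p$utilities$state_utility)
  obj$setting$rural_hr <- as.list(p$setting$rural_hr)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Load and validate a parameter bundle from JSON
#'
#' @param path File written by \code{\link{write_parameters}} (schema in
#'   \code{system.file("schema/parameters.schema.json", package =
#'   "screencea")}).
#' @return A validated \code{cea_parameters} object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  strategies <- lapply(obj$strategies, function(s) {
    structure(as.list(s), class = "screening_strategy")
  })
  tt <- transition_table(as.data.frame(obj$transitions))
  costs <- obj$costs
  costs$state_annual_cost <- unlist(costs$state_annual_cost)
  utilities <- obj$utilities
  utilities$state_utility <- unlist(utilities$state_utility)
  setting <- obj$setting
  setting$rural_hr <- if (length(setting$rural_hr))
    unlist(setting$rural_hr) else numeric()
  cea_parameters(
    setting = setting, strategies = strategies, transitions = tt,
    costs = costs, utilities = utilities,
    missed_hr = do.call(missed_diagnosis_hr, as.list(obj$missed_hr)),
    discount = obj$discount, wtp = obj$wtp,
    baseline_population = as.data.frame(obj$baseline_population),
    horizon_age = obj$horizon_age, cycle_length = obj$cycle_length)
}

# Scale off-diagonal transitions by per-destination multipliers, cap each
# product at 1, and re-close every row through the self-loop.  If the scaled
# outflow exceeds 1 the outflows are rescaled proportionally (self-loop 0)
# with a warning.  `mult` is a named vector keyed by destination state;
# missing destinations multiply by 1.
scale_transitions <- function(tt, mult) {
  states <- health_states()
  m_full <- stats::setNames(rep(1, length(states)), states)
  m_full[names(mult)] <- mult
  if (all(m_full == 1)) return(tt)  # bitwise no-op for identity multipliers
  for (b in seq_along(tt$P)) {
    P <- tt$P[[b]]
    for (f in states) {
      row <- P[f, ]
      off <- setdiff(states, f)
      scaled <- pmin(row[off] * m_full[off], 1)
      s <- sum(scaled)
      if (s > 1) {
        warning(sprintf(
          "outflow from %s exceeds 1 (%.6f) after HR scaling in band %d; rescaled",
          f, s, b))
        scaled <- scaled / s
        s <- 1
      }
      P[f, off] <- scaled
      P[f, f] <- 1 - s
    }
    tt$P[[b]] <- P
  }
  tt
}

#' Apply missed-diagnosis hazard ratios to a transition table
#'
#' Every transition into a microvascular state is multiplied by
#' \code{hr_micro}, into a macrovascular state by \code{hr_macro}, and into
#' death by \code{hr_death}; products are capped at 1 and each row is
#' re-closed through its self-loop (outflows exceeding 1 are rescaled
#' proportionally with a warning).
#'
#' @param tt A \code{\link{transition_table}}.
#' @param hr A \code{\link{missed_diagnosis_hr}}.
#' @return The adjusted \code{transition_table}.
#' @export
apply_missed_diagnosis_hr <- function(tt, hr) {
  cls <- state_class()
  mult <- ifelse(cls == "microvascular", hr$hr_micro,
                 ifelse(cls == "macrovascular", hr$hr_macro, 1))
  names(mult) <- names(cls)
  mult["DEATH"] <- hr$hr_death
  scale_transitions(tt, mult)
}

#' Apply rural hazard ratios to a transition table
#'
#' Transitions into the destinations listed in \code{setting$rural_hr}
#' (defaults: cardiovascular disease 1.15, stroke 1.25, blindness 2.09,
#' foot ulcer 1.42, end-stage renal disease 1.15) are multiplied; the urban
#' setting returns the table unchanged. Same capping and row-closure
#' contract as \code{\link{apply_missed_diagnosis_hr}}.
#'
#' @param tt A \code{\link{transition_table}}.
#' @param setting The \code{setting} element of a \code{cea_parameters}.
#' @return The adjusted \code{transition_table}.
#' @export
apply_rural_hr <- function(tt, setting) {
  if (identical(setting$label, "urban")) return(tt)
  hr <- setting$rural_hr
  if (!length(hr)) return(tt)
  bad <- setdiff(names(hr), health_states())
  if (length(bad))
    stop("unknown transition identifier in rural_hr: ",
         paste(bad, collapse = ", "))
  scale_transitions(tt, hr)
}

# --- parameter path accessors (used by OWSA and PSA) -----------------------

# Supported ids:
#   setting.prevalence | discount.rate | costs.ogtt_cost
#   costs.state_annual_cost.<STATE> | utilities.state_utility.<STATE>
#   strategies.<NAME>.<field> | missed_hr.<field> | setting.rural_hr.<STATE>
#   transitions.<FROM>.<TO>   (band-mean probability; setting scales all
#                              bands proportionally and re-closes the rows)
get_param <- function(p, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  switch(parts[1],
    setting = if (parts[2] == "rural_hr") p$setting$rural_hr[[parts[3]]]
              else p$setting[[parts[2]]],
    discount = p$discount[[parts[2]]],
    costs = if (parts[2] == "state_annual_cost")
              p$costs$state_annual_cost[[parts[3]]]
            else p$costs[[parts[2]]],
    utilities = p$utilities$state_utility[[parts[3]]],
    strategies = p$strategies[[parts[2]]][[parts[3]]],
    missed_hr = p$missed_hr[[parts[2]]],
    transitions = {
      from <- parts[2]; to <- parts[3]
      mean(vapply(p$transitions$P, function(m) m[from, to], 0))
    },
    stop("unknown parameter id: ", id))
}

set_param <- function(p, id, value) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  switch(parts[1],
    setting = if (parts[2] == "rural_hr")
                p$setting$rural_hr[[parts[3]]] <- value
              else p$setting[[parts[2]]] <- value,
    discount = p$discount[[parts[2]]] <- value,
    costs = if (parts[2] == "state_annual_cost")
              p$costs$state_annual_cost[[parts[3]]] <- value
            else p$costs[[parts[2]]] <- value,
    utilities = p$utilities$state_utility[[parts[3]]] <- value,
    strategies = p$strategies[[parts[2]]][[parts[3]]] <- value,
    missed_hr = p$missed_hr[[parts[2]]] <- value,
    transitions = {
      from <- parts[2]; to <- parts[3]
      base <- get_param(p, id)
      if (base <= 0) stop("cannot scale a zero transition: ", id)
      fac <- value / base
      for (b in seq_along(p$transitions$P)) {
        m <- p$transitions$P[[b]]
        m[from, to] <- min(m[from, to] * fac, 1)
        off <- setdiff(colnames(m), from)
        s <- sum(m[from, off])
        if (s > 1) { m[from, off] <- m[from, off] / s; s <- 1 }
        m[from, from] <- 1 - s
        p$transitions$P[[b]] <- m
      }
    },
    stop("unknown parameter id: ", id))
  p
}
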