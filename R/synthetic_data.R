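#' Specification for a synthetic parameter set
#'
#' Controls the magnitudes of the generated bundle. Defaults emulate the
#' structure of a Chinese urban/rural screening analysis: undiagnosed
#' prevalence near 10--14\% (urban) or 9--13\% (rural), HbA1c-based tests
#' markedly more sensitive than fasting capillary glucose (whose screening
#' sensitivity in Chinese populations is around 65\%), costs spanning a few
#' hundred USD/year for uncomplicated diabetes to around ten thousand for
#' end-stage renal disease, a strictly ordered utility ladder, and
#' Gompertz-like background mortality rising with age.
#'
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param setting \code{"urban"} or \code{"rural"}.
#' @param prevalence_range Interval for the prevalence draw.
#' @param ess Not used by the generator itself; convenience default carried
#'   to PSA configuration.
#' @return List of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(seed = 1, setting = c("urban", "rural"),
                           prevalence_range = NULL, ess = 1000) {
  setting <- match.arg(setting)
  if (is.null(prevalence_range))
    prevalence_range <- if (setting == "urban") c(0.10, 0.14)
                        else c(0.09, 0.13)
  structure(list(seed = seed, setting = setting,
                 prevalence_range = prevalence_range, ess = ess),
            class = "synthetic_spec")
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# 5-year age bands over [18, 80] used by generated tables.
default_age_bands <- function() {
  lows <- seq(18, 78, by = 5)
  data.frame(age_low = lows, age_high = c(lows[-1], 80))
}

# Gompertz-like annual background mortality at the band midpoints.
background_mortality <- function(bands = default_age_bands()) {
  mid <- (bands$age_low + bands$age_high) / 2
  pmin(0.0004 * exp(0.085 * (mid - 20)), 0.5)
}

#' Generate a complete synthetic parameter bundle
#'
#' Produces a \code{\link{cea_parameters}} passing every validation:
#' age-banded transition tables with rising background mortality,
#' progression restricted to the structurally allowed paths, one shared
#' transition probability into the lumped multi-complication state, ordered
#' utilities, lognormal-magnitude costs and three screening strategies
#' (POCT HbA1c, venous HbA1c, FCG) with HbA1c sensitivities above FCG's.
#' The rural variant embeds the default rural hazard ratios and higher
#' non-medical and indirect screening costs.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A validated \code{cea_parameters}.
#' @examples
#' params <- generate_parameter_set(synthetic_spec(seed = 42))
#' params
#' @export
generate_parameter_set <- function(spec = synthetic_spec()) {
  with_seed(spec$seed, {
    rural <- spec$setting == "rural"
    jit <- function(x, f = 0.3) x * stats::runif(length(x), 1 - f, 1 + f)
    prevalence <- stats::runif(1, spec$prevalence_range[1],
                               spec$prevalence_range[2])

    # screening strategies: HbA1c tests more sensitive than FCG
    rural_up <- if (rural) 1.6 else 1.0
    strategies <- list(
      POCT_HBA1C = screening_strategy(
        "POCT_HBA1C",
        sensitivity = stats::runif(1, 0.86, 0.94),
        specificity = stats::runif(1, 0.85, 0.93),
        cost_direct_medical = jit(3.5, 0.2),
        cost_direct_nonmedical = jit(0.8, 0.2) * rural_up,
        cost_indirect = jit(0.9, 0.2) * rural_up,
        cut_point_text = "HbA1c >= 43.6 mmol/mol (6.14%)"),
      VENOUS_HBA1C = screening_strategy(
        "VENOUS_HBA1C",
        sensitivity = stats::runif(1, 0.80, 0.90),
        specificity = stats::runif(1, 0.88, 0.96),
        cost_direct_medical = jit(7.0, 0.2),
        cost_direct_nonmedical = jit(2.5, 0.2) * rural_up,
        cost_indirect = jit(3.0, 0.2) * rural_up,
        cut_point_text = "HbA1c >= 44.8 mmol/mol (6.25%)"),
      FCG = screening_strategy(
        "FCG",
        sensitivity = stats::runif(1, 0.60, 0.70),
        specificity = stats::runif(1, 0.80, 0.90),
        cost_direct_medical = jit(1.2, 0.2),
        cost_direct_nonmedical = jit(0.6, 0.2) * rural_up,
        cost_indirect = jit(0.7, 0.2) * rural_up,
        cut_point_text = "fasting capillary glucose >= 6.1 mmol/L"))

    bands <- default_age_bands()
    q_bg <- background_mortality(bands)
    # annual incidence of each primary complication from uncomplicated
    # diabetes (age-constant), progression rates, one shared
    # multi-complication rate, and per-state excess mortality multipliers
    inc <- jit(c(DM_CVD = 0.010, DM_STROKE = 0.008, DM_DKD = 0.012,
                 DM_DFU = 0.005, DM_DR = 0.015, DM_DPN = 0.012))
    prog <- jit(c(DM_ESRD = 0.030, DM_AMPUTATION = 0.050,
                  DM_BLINDNESS = 0.020))
    p_multi <- jit(0.030)
    mort_mult <- c(DM_NO_COMP = 1.3, DM_CVD = 2.0, DM_STROKE = 2.2,
                   DM_DKD = 1.8, DM_ESRD = 4.0, DM_DFU = 1.8,
                   DM_AMPUTATION = 2.5, DM_DR = 1.4, DM_BLINDNESS = 1.6,
                   DM_DPN = 1.5, DM_MULTI_COMP = 3.0)

    long <- list()
    emit <- function(from, to, b, p) long[[length(long) + 1L]] <<-
      data.frame(from_state = from, to_state = to,
                 age_low = bands$age_low[b], age_high = bands$age_high[b],
                 probability = p, stringsAsFactors = FALSE)
    for (b in seq_len(nrow(bands))) {
      q <- q_bg[b]
      emit("NON_DM", "DEATH", b, q)
      emit("NON_DM", "NON_DM", b, 1 - q)
      d <- min(q * mort_mult[["DM_NO_COMP"]], 0.9)
      for (s in names(inc)) emit("DM_NO_COMP", s, b, inc[[s]])
      emit("DM_NO_COMP", "DM_MULTI_COMP", b, p_multi)
      emit("DM_NO_COMP", "DEATH", b, d)
      emit("DM_NO_COMP", "DM_NO_COMP", b, 1 - sum(inc) - p_multi - d)
      pre <- c(DM_ESRD = "DM_DKD", DM_AMPUTATION = "DM_DFU",
               DM_BLINDNESS = "DM_DR")
      for (s in setdiff(names(mort_mult), "DM_NO_COMP")) {
        d <- min(q * mort_mult[[s]], 0.9)
        out <- d
        if (s != "DM_MULTI_COMP") {
          emit(s, "DM_MULTI_COMP", b, p_multi)
          out <- out + p_multi
        }
        prog_to <- names(pre)[match(s, pre)]
        if (!is.na(prog_to)) {
          emit(s, prog_to, b, prog[[prog_to]])
          out <- out + prog[[prog_to]]
        }
        emit(s, "DEATH", b, d)
        emit(s, s, b, 1 - out)
      }
    }
    tt <- transition_table(do.call(rbind, long))

    # annual direct medical costs per state (USD)
    cost_base <- c(NON_DM = 0, DM_NO_COMP = 400, DM_CVD = 2000,
                   DM_STROKE = 2100, DM_DKD = 1500, DM_ESRD = 10000,
                   DM_DFU = 1400, DM_AMPUTATION = 3800, DM_DR = 700,
                   DM_BLINDNESS = 1500, DM_DPN = 700, DM_MULTI_COMP = 4500,
                   DEATH = 0)
    state_cost <- ifelse(cost_base > 0, jit(cost_base), 0)
    names(state_cost) <- names(cost_base)

    # strictly ordered utility ladder; rural utilities slightly lower
    u_nodm <- stats::runif(1, 0.90, 0.96)
    u_dm <- u_nodm - stats::runif(1, 0.05, 0.10)
    dec <- c(DM_CVD = 0.13, DM_STROKE = 0.20, DM_DKD = 0.12,
             DM_ESRD = 0.33, DM_DFU = 0.17, DM_AMPUTATION = 0.29,
             DM_DR = 0.11, DM_BLINDNESS = 0.28, DM_DPN = 0.15)
    dec <- jit(dec, 0.15)
    u_comp <- u_dm - dec
    u_multi <- min(u_comp) - stats::runif(1, 0.02, 0.05)
    util <- c(NON_DM = u_nodm, DM_NO_COMP = u_dm, u_comp,
              DM_MULTI_COMP = max(u_multi, 0.05), DEATH = 0)
    if (rural) util[names(util) != "DEATH"] <-
      util[names(util) != "DEATH"] * 0.985
    util <- pmin(pmax(util, 0), 1)

    cea_parameters(
      setting = list(label = spec$setting, prevalence = prevalence,
                     rural_hr = if (rural) default_rural_hr()
                                else numeric()),
      strategies = strategies, transitions = tt,
      costs = list(state_annual_cost = state_cost,
                   ogtt_cost = jit(12, 0.2), currency_rate = 6.4),
      utilities = list(state_utility = util[health_states()]),
      missed_hr = missed_diagnosis_hr(),
      baseline_population = generate_baseline_population())
  })
}

#' Generate a baseline adult population
#'
#' Single-year ages 18--79 with weights following a plausible adult age
#' pyramid (flat through middle age, declining from 50), split near parity
#' between sexes.
#'
#' @param n_bands Number of 5-year age bands used to shape the pyramid
#'   (default 13, covering [18, 80)).
#' @param band_weights Optional non-negative weights per band (recycled or
#'   truncated to \code{n_bands}); defaults to the pyramid above.
#' @param male_fraction Fraction male (default 0.51).
#' @return Data frame \code{age}, \code{sex}, \code{weight} with weights
#'   summing to 1.
#' @export
generate_baseline_population <- function(n_bands = 13, band_weights = NULL,
                                         male_fraction = 0.51) {
  if (n_bands < 1) stop("n_bands must be at least 1")
  lows <- 18 + 5 * (seq_len(n_bands) - 1)
  highs <- pmin(lows + 5, 80)
  keep <- lows < 80
  lows <- lows[keep]; highs <- highs[keep]
  if (is.null(band_weights))
    band_weights <- c(10, 10, 10, 10, 10, 9, 8, 7, 6, 5, 4, 3,
                      2)[seq_along(lows)]
  band_weights <- rep_len(band_weights, length(lows))
  if (any(band_weights < 0) || sum(band_weights) <= 0)
    stop("band_weights must be non-negative with positive sum")
  rows <- list()
  for (b in seq_along(lows)) {
    ages <- lows[b]:(highs[b] - 1)
    w <- band_weights[b] / length(ages)
    rows[[b]] <- data.frame(
      age = rep(ages, each = 2), sex = rep(c("male", "female"),
                                           length(ages)),
      weight = rep(w * c(male_fraction, 1 - male_fraction), length(ages)))
  }
  out <- do.call(rbind, rows)
  out$weight <- out$weight / sum(out$weight)
  out
}

#' Closed-form toy fixtures
#'
#' Minimal parameter bundles whose discounted totals have documented closed
#' forms, for verifying the cohort engine.
#'
#' \describe{
#'   \item{two_state}{A single live state (\code{DM_NO_COMP}, utility 1,
#'     cost 0 by default) with constant annual death probability \code{q}.
#'     With discount rate r, no half-cycle correction and T cycles from one
#'     start age, total QALY is the geometric sum
#'     \code{sum_t ((1-q)/(1+r))^t, t = 0..T-1}; e.g. q = 0.1, r = 0,
#'     T = 5 gives 4.0951.}
#'   \item{four_state_chain}{A progression chain \code{DM_NO_COMP ->
#'     DM_DKD -> DM_ESRD -> DEATH} with age-constant probabilities; totals
#'     equal the matrix-geometric sum \code{sum_t v P^t r / (1+rate)^t}.}
#' }
#'
#' @param name \code{"two_state"} or \code{"four_state_chain"}.
#' @param q Annual death probability for \code{two_state} (default 0.1).
#' @param start_age Single baseline age (default 75, i.e. 5 cycles to the
#'   age-80 horizon).
#' @param discount_rate Annual discount rate (default 0).
#' @return A validated \code{cea_parameters}.
#' @export
toy_fixture <- function(name = c("two_state", "four_state_chain"),
                        q = 0.1, start_age = 75, discount_rate = 0) {
  name <- match.arg(name)
  bands <- data.frame(age_low = 18, age_high = 80)
  zero_cost <- stats::setNames(rep(0, 13), health_states())
  perfect <- function(nm) screening_strategy(nm, 1, 1, 0, 0, 0)
  strategies <- list(POCT_HBA1C = perfect("POCT_HBA1C"),
                     VENOUS_HBA1C = perfect("VENOUS_HBA1C"),
                     FCG = perfect("FCG"))
  pop <- data.frame(age = start_age, sex = "female", weight = 1)
  if (name == "two_state") {
    long <- data.frame(
      from_state = c("DM_NO_COMP", "DM_NO_COMP"),
      to_state = c("DM_NO_COMP", "DEATH"),
      age_low = 18, age_high = 80, probability = c(1 - q, q))
    util <- zero_cost
    util[c("NON_DM", "DM_NO_COMP")] <- 1
    cost <- zero_cost
  } else {
    long <- data.frame(
      from_state = c("DM_NO_COMP", "DM_NO_COMP", "DM_NO_COMP",
                     "DM_DKD", "DM_DKD", "DM_DKD",
                     "DM_ESRD", "DM_ESRD"),
      to_state = c("DM_NO_COMP", "DM_DKD", "DEATH",
                   "DM_DKD", "DM_ESRD", "DEATH",
                   "DM_ESRD", "DEATH"),
      age_low = 18, age_high = 80,
      probability = c(0.75, 0.20, 0.05, 0.65, 0.25, 0.10, 0.80, 0.20))
    util <- zero_cost
    util[c("NON_DM", "DM_NO_COMP", "DM_DKD", "DM_ESRD")] <-
      c(1, 1, 0.8, 0.6)
    cost <- zero_cost
    cost[c("DM_DKD", "DM_ESRD")] <- c(1000, 5000)
  }
  cea_parameters(
    setting = list(label = "urban", prevalence = 0.5, rural_hr = numeric()),
    strategies = strategies,
    transitions = transition_table(long),
    costs = list(state_annual_cost = cost, ogtt_cost = 0,
                 currency_rate = 6.4),
    utilities = list(state_utility = util),
    missed_hr = missed_diagnosis_hr(1, 1, 1),
    discount = list(rate = discount_rate,
                    sensitivity_range = c(0, max(0.08, discount_rate))),
    baseline_population = pop)
}
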