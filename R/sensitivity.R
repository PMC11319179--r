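#' One-way sensitivity range for a parameter
#'
#' @param parameter_id Dotted path into the parameter bundle, e.g.
#'   \code{"setting.prevalence"}, \code{"costs.state_annual_cost.DM_CVD"},
#'   \code{"strategies.POCT_HBA1C.sensitivity"} or
#'   \code{"transitions.DM_NO_COMP.DM_CVD"} (band-mean probability).
#' @param base Base value (as returned by the bundle).
#' @param low,high Endpoints; when omitted with \code{source = "pm20pct"},
#'   base +/- 20\% is used, with probabilities clipped to [0,1].
#' @param source \code{"reported_95CI"} (explicit endpoints) or
#'   \code{"pm20pct"}.
#' @param is_probability Clip the +/-20\% endpoints to [0,1].
#' @return List of class \code{param_range}.
#' @export
param_range <- function(parameter_id, base, low = NULL, high = NULL,
                        source = c("pm20pct", "reported_95CI"),
                        is_probability = FALSE) {
  source <- match.arg(source)
  if (source == "pm20pct") {
    low <- 0.8 * base
    high <- 1.2 * base
    if (is_probability) {
      low <- max(0, low)
      high <- min(1, high)
    }
  }
  if (is.null(low) || is.null(high))
    stop("reported_95CI ranges need explicit low and high")
  if (!(low <= base && base <= high))
    stop(sprintf("%s: need low <= base <= high", parameter_id))
  structure(list(parameter_id = parameter_id, base = base, low = low,
                 high = high, source = source,
                 is_probability = is_probability),
            class = "param_range")
}

# Enumerate the perturbable parameters of a bundle with their base values
# and whether they live on the probability scale.
enumerate_parameters <- function(params) {
  ids <- list()
  add <- function(id, prob) ids[[length(ids) + 1L]] <<-
    list(id = id, prob = prob)
  add("setting.prevalence", TRUE)
  for (nm in names(params$strategies)) {
    add(sprintf("strategies.%s.sensitivity", nm), TRUE)
    add(sprintf("strategies.%s.specificity", nm), TRUE)
    for (f in c("cost_direct_medical", "cost_direct_nonmedical",
                "cost_indirect"))
      if (get_param(params, sprintf("strategies.%s.%s", nm, f)) > 0)
        add(sprintf("strategies.%s.%s", nm, f), FALSE)
  }
  for (s in health_states())
    if (params$costs$state_annual_cost[[s]] > 0)
      add(sprintf("costs.state_annual_cost.%s", s), FALSE)
  if (params$costs$ogtt_cost > 0) add("costs.ogtt_cost", FALSE)
  for (s in setdiff(health_states(), "DEATH"))
    if (params$utilities$state_utility[[s]] > 0)
      add(sprintf("utilities.state_utility.%s", s), TRUE)
  for (f in c("hr_micro", "hr_macro", "hr_death"))
    add(sprintf("missed_hr.%s", f), FALSE)
  for (s in names(params$setting$rural_hr))
    add(sprintf("setting.rural_hr.%s", s), FALSE)
  P1 <- params$transitions$P[[1]]
  off <- which(P1 > 0 & row(P1) != col(P1), arr.ind = TRUE)
  for (k in seq_len(nrow(off)))
    add(sprintf("transitions.%s.%s", rownames(P1)[off[k, 1]],
                colnames(P1)[off[k, 2]]), TRUE)
  ids
}

#' Default one-way sensitivity ranges for every model parameter
#'
#' Base +/- 20\% for every cost, probability, utility and hazard ratio
#' (probabilities clipped to [0,1]), plus the discount rate over its stated
#' sensitivity range (default 0 to 8\%).
#'
#' @param params A validated \code{\link{cea_parameters}}.
#' @return List of \code{\link{param_range}} objects.
#' @export
default_owsa_ranges <- function(params) {
  ranges <- lapply(enumerate_parameters(params), function(e)
    param_range(e$id, get_param(params, e$id), is_probability = e$prob))
  sr <- params$discount$sensitivity_range
  ranges[[length(ranges) + 1L]] <- param_range(
    "discount.rate", params$discount$rate, low = sr[1], high = sr[2],
    source = "reported_95CI")
  ranges
}

# Lifetime (cost, qaly) totals per strategy with the three arm values
# computed once and shared across strategies.
strategy_totals <- function(params) {
  vd <- arm_value(params, "diagnosed")
  vm <- arm_value(params, "missed")
  vn <- arm_value(params, "negative")
  prev <- params$setting$prevalence
  out <- lapply(params$strategies, function(s) {
    cls <- classify(prev, s)
    w <- c(cls$p_diagnosed, cls$p_missed,
           cls$p_misdiagnosed + cls$p_true_negative)
    list(strategy = s$name,
         total_cost = sum(w * c(vd["cost"], vm["cost"], vn["cost"])) +
           screening_stage_cost(prev, s, params$costs),
         total_qaly = sum(w * c(vd["qaly"], vm["qaly"], vn["qaly"])))
  })
  names(out) <- vapply(params$strategies, `[[`, "", "name")
  out
}

pipeline_icur <- function(params, reference, comparator) {
  tot <- strategy_totals(params)
  compute_icur(tot[[reference]], tot[[comparator]], params$wtp)$icur
}

#' One-way sensitivity analysis (tornado data)
#'
#' Re-runs the full pipeline at the low and high endpoint of each parameter
#' range, holding everything else at base, and records the incremental
#' cost-utility ratio of the chosen comparison. Entries are sorted by
#' descending bar width (ties broken by parameter id).
#'
#' @param params A validated \code{\link{cea_parameters}}.
#' @param ranges List of \code{\link{param_range}}s, e.g.
#'   \code{\link{default_owsa_ranges}(params)}.
#' @param comparison Character pair \code{c(reference, comparator)} naming
#'   strategies in \code{params$strategies}.
#' @return Data frame of class \code{tornado}: \code{parameter_id},
#'   \code{low}, \code{high}, \code{icur_low}, \code{icur_high},
#'   \code{width}, plus the base-case ICUR as attribute \code{icur_base}.
#' @export
owsa <- function(params, ranges = default_owsa_ranges(params),
                 comparison = c("FCG", "POCT_HBA1C")) {
  stopifnot(length(comparison) == 2)
  eval_at <- function(id, value) {
    tryCatch(
      suppressWarnings(pipeline_icur(set_param(params, id, value),
                                     comparison[1], comparison[2])),
      error = function(e) {
        warning(sprintf("endpoint skipped for %s: %s", id,
                        conditionMessage(e)))
        NA_real_
      })
  }
  rows <- lapply(ranges, function(r) {
    data.frame(parameter_id = r$parameter_id, low = r$low, high = r$high,
               icur_low = eval_at(r$parameter_id, r$low),
               icur_high = eval_at(r$parameter_id, r$high),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$width <- abs(out$icur_high - out$icur_low)
  out <- out[order(-out$width, out$parameter_id), ]
  rownames(out) <- NULL
  attr(out, "icur_base") <- suppressWarnings(
    pipeline_icur(params, comparison[1], comparison[2]))
  attr(out, "comparison") <- comparison
  class(out) <- c("tornado", "data.frame")
  out
}

#' Beta distribution from event counts
#'
#' For a probability parameter reported as events out of a sample,
#' \code{alpha} is the number of events and \code{beta_count} the number of
#' non-events; the distribution mean is \code{alpha/(alpha+beta_count)}.
#' A half count is added to both when either is zero (continuity
#' correction).
#'
#' @param events,non_events Non-negative counts, not both zero.
#' @return List of class \code{psa_dist}, kind \code{"beta"}.
#' @export
fit_beta <- function(events, non_events) {
  if (events < 0 || non_events < 0) stop("counts must be non-negative")
  if (events + non_events == 0) stop("at least one count must be positive")
  if (events == 0 || non_events == 0) {
    events <- events + 0.5
    non_events <- non_events + 0.5
  }
  structure(list(kind = "beta", alpha = events, beta_count = non_events),
            class = "psa_dist")
}

#' Lognormal distribution for a cost parameter
#'
#' The point estimate is taken as the median (so \code{mu = log(point)})
#' and the dispersion is set so the draw's standard deviation is 10\% of
#' its mean: \code{sigma = sqrt(log(1 + cv^2))} with \code{cv = 0.1}
#' (about 0.09975; \code{sigma = 0.1} differs by under 0.3\% and can be
#' requested via \code{sigma}).
#'
#' @param point_estimate Positive cost.
#' @param cv Coefficient of variation of the draws (default 0.10).
#' @param sigma Optional explicit log-sd overriding \code{cv}.
#' @return List of class \code{psa_dist}, kind \code{"lognormal"}.
#' @export
fit_lognormal <- function(point_estimate, cv = 0.10, sigma = NULL) {
  if (point_estimate <= 0) stop("point_estimate must be positive")
  if (is.null(sigma)) sigma <- sqrt(log(1 + cv^2))
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(kind = "lognormal", mu = log(point_estimate),
                 sigma = sigma), class = "psa_dist")
}

#' Uniform distribution on an interval
#'
#' Fallback for parameters whose distribution cannot be derived from the
#' literature (utilities and hazard ratios by default).
#'
#' @param low,high Bounds with \code{low < high}.
#' @return List of class \code{psa_dist}, kind \code{"uniform"}.
#' @export
fit_uniform <- function(low, high) {
  if (!(low < high)) stop("need low < high")
  structure(list(kind = "uniform", low = low, high = high),
            class = "psa_dist")
}

# One random draw from a psa_dist.
draw_psa_dist <- function(d) {
  switch(d$kind,
         beta = stats::rbeta(1, d$alpha, d$beta_count),
         lognormal = stats::rlnorm(1, d$mu, d$sigma),
         uniform = stats::runif(1, d$low, d$high),
         stop("unknown distribution kind: ", d$kind))
}

#' Default probabilistic-sensitivity distributions for a parameter bundle
#'
#' Probabilities (prevalence, sensitivity, specificity, transition
#' probabilities) get beta distributions with counts implied by an assumed
#' effective sample size; costs get lognormal distributions (median at the
#' point estimate, sd 10\% of the mean); utilities and hazard ratios get
#' uniform +/-20\% distributions (utilities clipped to 1); the discount
#' rate is uniform over its sensitivity range.
#'
#' @param params A validated \code{\link{cea_parameters}}.
#' @param ess Effective sample size behind each beta distribution
#'   (default 1000).
#' @return Named list mapping parameter id to \code{psa_dist}.
#' @export
default_psa_config <- function(params, ess = 1000) {
  dists <- list()
  for (e in enumerate_parameters(params)) {
    base <- get_param(params, e$id)
    is_util <- startsWith(e$id, "utilities.")
    is_hr <- startsWith(e$id, "missed_hr.") ||
      startsWith(e$id, "setting.rural_hr.")
    dists[[e$id]] <-
      if (is_util) fit_uniform(0.8 * base, min(1, 1.2 * base))
      else if (is_hr) fit_uniform(0.8 * base, 1.2 * base)
      else if (e$prob) fit_beta(base * ess, (1 - base) * ess)
      else fit_lognormal(base)
  }
  sr <- params$discount$sensitivity_range
  dists[["discount.rate"]] <- fit_uniform(sr[1], sr[2])
  dists
}

#' Probabilistic sensitivity analysis
#'
#' Draws every parameter jointly and independently from its assigned
#' distribution, re-runs the full pipeline per draw and records each
#' strategy's (cost, utility) and the pairwise incremental differences.
#' Probability draws are clipped to [0,1] (count reported); draws that
#' still fail validation are rejected and redrawn (count reported).
#'
#' @param params A validated \code{\link{cea_parameters}}.
#' @param dists Named list of \code{psa_dist} per parameter id, e.g.
#'   \code{\link{default_psa_config}(params)}.
#' @param n_iter Number of joint draws (default 1000).
#' @param seed Integer RNG seed; the sample list is reproducible from it.
#' @param comparisons List of character pairs \code{c(reference,
#'   comparator)}; defaults to every strategy vs FCG plus venous vs POCT.
#' @return Object of class \code{cea_psa}: \code{samples} (one row per
#'   draw and strategy: draw, strategy, cost, utility), \code{deltas}
#'   (draw, reference, comparator, delta_cost, delta_utility),
#'   \code{n_clipped}, \code{n_rejected}, \code{lambda}, \code{seed}.
#' @export
psa <- function(params, dists = default_psa_config(params), n_iter = 1000,
                seed = 1, comparisons = NULL) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  nm <- names(params$strategies)
  if (is.null(comparisons)) {
    ref <- if ("FCG" %in% nm) "FCG" else nm[1]
    comparisons <- lapply(setdiff(nm, ref), function(s) c(ref, s))
    if (all(c("POCT_HBA1C", "VENOUS_HBA1C") %in% nm))
      comparisons <- c(comparisons, list(c("POCT_HBA1C", "VENOUS_HBA1C")))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  ids <- names(dists)
  prob_id <- vapply(ids, function(id)
    startsWith(id, "transitions.") || id == "setting.prevalence" ||
      grepl("\\.(sensitivity|specificity)$", id) ||
      startsWith(id, "utilities."), TRUE)
  n_clipped <- 0L
  n_rejected <- 0L
  samples <- vector("list", n_iter)
  deltas <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    tot <- NULL
    for (attempt in 1:100) {
      p_i <- params
      ok <- TRUE
      for (k in seq_along(ids)) {
        v <- draw_psa_dist(dists[[k]])
        if (prob_id[k]) {
          v2 <- min(1, max(0, v))
          if (v2 != v) n_clipped <- n_clipped + 1L
          v <- v2
        }
        p_i <- tryCatch(set_param(p_i, ids[k], v),
                        error = function(e) { ok <<- FALSE; p_i })
        if (!ok) break
      }
      if (ok) {
        tot <- tryCatch(
          suppressWarnings({
            validate_parameters(p_i)
            strategy_totals(p_i)
          }),
          error = function(e) NULL)
      }
      if (!is.null(tot)) break
      n_rejected <- n_rejected + 1L
    }
    if (is.null(tot)) stop("could not obtain a valid draw after 100 attempts")
    samples[[i]] <- data.frame(
      draw = i, strategy = nm,
      cost = vapply(tot[nm], `[[`, 0, "total_cost"),
      utility = vapply(tot[nm], `[[`, 0, "total_qaly"),
      stringsAsFactors = FALSE)
    deltas[[i]] <- do.call(rbind, lapply(comparisons, function(pr)
      data.frame(draw = i, reference = pr[1], comparator = pr[2],
                 delta_cost = tot[[pr[2]]]$total_cost -
                   tot[[pr[1]]]$total_cost,
                 delta_utility = tot[[pr[2]]]$total_qaly -
                   tot[[pr[1]]]$total_qaly,
                 stringsAsFactors = FALSE)))
  }
  structure(list(samples = do.call(rbind, samples),
                 deltas = do.call(rbind, deltas),
                 comparisons = comparisons, n_iter = n_iter, seed = seed,
                 n_clipped = n_clipped, n_rejected = n_rejected,
                 lambda = params$wtp$lambda),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %d)\n",
              x$n_iter, x$seed))
  cat(sprintf("  clipped probability draws: %d; rejected draws: %d\n",
              x$n_clipped, x$n_rejected))
  for (pr in x$comparisons) {
    d <- x$deltas[x$deltas$reference == pr[1] &
                    x$deltas$comparator == pr[2], ]
    nmb <- x$lambda * d$delta_utility - d$delta_cost
    cat(sprintf("  %s vs %s: P(cost-effective at lambda=%s) = %.3f\n",
                pr[2], pr[1], format(x$lambda, big.mark = ","),
                mean(nmb > 0)))
  }
  invisible(x)
}

#' @export
summary.cea_psa <- function(object, ...) {
  agg <- stats::aggregate(cbind(delta_cost, delta_utility) ~
                            reference + comparator, object$deltas, mean)
  agg$p_cost_effective <- mapply(function(r, cmp) {
    d <- object$deltas[object$deltas$reference == r &
                         object$deltas$comparator == cmp, ]
    mean(object$lambda * d$delta_utility - d$delta_cost > 0)
  }, agg$reference, agg$comparator)
  agg
}

#' @describeIn psa Incremental cost-utility scatter per comparison.
#' @param x A \code{cea_psa} object.
#' @param y Ignored.
#' @param ... Passed to \code{plot}.
#' @export
plot.cea_psa <- function(x, y, ...) {
  n <- length(x$comparisons)
  op <- graphics::par(mfrow = c(1, n))
  on.exit(graphics::par(op))
  for (pr in x$comparisons) {
    d <- x$deltas[x$deltas$reference == pr[1] &
                    x$deltas$comparator == pr[2], ]
    graphics::plot(d$delta_utility, d$delta_cost, pch = 20, cex = 0.5,
                   xlab = "Incremental QALY", ylab = "Incremental cost (USD)",
                   main = sprintf("%s vs %s", pr[2], pr[1]), ...)
    graphics::abline(h = 0, v = 0, lty = 3)
    graphics::abline(a = 0, b = x$lambda, col = "grey40")
  }
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the comparator
#' is cost-effective against its reference: the fraction of PSA draws with
#' strictly positive net monetary benefit \code{lambda * dE - dC}.
#'
#' @param samples A \code{\link{psa}} result (or its \code{deltas} data
#'   frame).
#' @param lambda_grid Non-empty numeric vector of thresholds (USD/QALY);
#'   default 0 to 3x the bundle's threshold in 101 points.
#' @return Data frame of class \code{cea_ceac}: \code{lambda},
#'   \code{reference}, \code{comparator}, \code{probability}.
#' @export
ceac <- function(samples, lambda_grid = NULL) {
  deltas <- if (inherits(samples, "cea_psa")) samples$deltas else samples
  if (is.null(lambda_grid) && inherits(samples, "cea_psa"))
    lambda_grid <- seq(0, 3 * samples$lambda, length.out = 101)
  if (is.null(lambda_grid) || length(lambda_grid) == 0)
    stop("lambda_grid must be non-empty")
  if (nrow(deltas) == 0) stop("no PSA samples")
  pairs <- unique(deltas[, c("reference", "comparator")])
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    d <- deltas[deltas$reference == pairs$reference[k] &
                  deltas$comparator == pairs$comparator[k], ]
    prob <- vapply(lambda_grid, function(l)
      mean(l * d$delta_utility - d$delta_cost > 0), 0)
    rows[[k]] <- data.frame(lambda = lambda_grid,
                            reference = pairs$reference[k],
                            comparator = pairs$comparator[k],
                            probability = prob, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cea_ceac", "data.frame")
  out
}

#' @export
plot.cea_ceac <- function(x, y, ...) {
  pairs <- unique(x[, c("reference", "comparator")])
  graphics::plot(NULL, xlim = range(x$lambda), ylim = c(0, 1),
                 xlab = "Willingness to pay (USD/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability", ...)
  for (k in seq_len(nrow(pairs))) {
    d <- x[x$reference == pairs$reference[k] &
             x$comparator == pairs$comparator[k], ]
    graphics::lines(d$lambda, d$probability, col = k, lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", col = seq_len(nrow(pairs)),
                   lwd = 2, legend = sprintf("%s vs %s", pairs$comparator,
                                             pairs$reference))
  invisible(x)
}
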