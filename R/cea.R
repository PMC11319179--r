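#' Cost-utility ratio of a single strategy
#'
#' @param cost Total discounted cost (USD).
#' @param utility Total discounted QALYs; must be positive.
#' @return \code{cost / utility} in USD per QALY.
#' @export
cost_utility_ratio <- function(cost, utility) {
  if (!is.numeric(utility) || any(utility <= 0))
    stop("utility must be positive for a cost-utility ratio")
  cost / utility
}

#' Incremental cost-utility comparison of two strategies
#'
#' Computes the incremental cost, incremental utility and their ratio
#' (ICUR) for a comparator strategy against a reference, with dominance
#' handling: the comparator is \emph{dominant} if it saves cost and gains
#' QALYs, \emph{dominated} if it adds cost and loses QALYs (the ICUR is
#' then negative and reported signed). Otherwise the verdict is judged
#' against the willingness-to-pay threshold: in the north-east quadrant
#' cost-effective iff ICUR <= lambda, in the south-west quadrant iff the
#' savings per QALY forgone exceed lambda.
#'
#' @param ref_outcome,comp_outcome Objects with \code{total_cost} and
#'   \code{total_qaly} (e.g. \code{strategy_outcome}s), or bare lists with
#'   those fields. Deltas are comparator minus reference.
#' @param wtp Willingness-to-pay threshold in USD/QALY, or a \code{wtp}
#'   list with element \code{lambda}.
#' @return List of class \code{cea_result}: \code{reference},
#'   \code{comparator}, \code{delta_cost}, \code{delta_utility},
#'   \code{icur} (NA when delta_utility is 0), \code{verdict}.
#' @export
compute_icur <- function(ref_outcome, comp_outcome, wtp = 37653) {
  lambda <- if (is.list(wtp)) wtp$lambda else wtp
  dc <- comp_outcome$total_cost - ref_outcome$total_cost
  de <- comp_outcome$total_qaly - ref_outcome$total_qaly
  icur <- if (de != 0) dc / de else NA_real_
  verdict <-
    if (de > 0 && dc < 0) "dominant"
    else if (de < 0 && dc > 0) "dominated"
    else if (de == 0) {
      if (dc < 0) "cost_effective" else "not_cost_effective"
    } else if (de > 0) {
      if (icur <= lambda) "cost_effective" else "not_cost_effective"
    } else {  # de < 0, dc <= 0: savings per QALY forgone vs lambda
      if (dc < 0 && icur >= lambda) "cost_effective" else "not_cost_effective"
    }
  structure(list(reference = ref_outcome$strategy %||% "reference",
                 comparator = comp_outcome$strategy %||% "comparator",
                 delta_cost = dc, delta_utility = de, icur = icur,
                 lambda = lambda, verdict = verdict),
            class = "cea_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost %.2f USD, dQALY %.4f, ICUR %s -> %s\n",
              x$comparator, x$reference, x$delta_cost, x$delta_utility,
              if (is.na(x$icur)) "undefined" else sprintf("%.2f", x$icur),
              x$verdict))
  invisible(x)
}

# Normalise outcome input for full_comparison: named list of outcomes or a
# data frame with columns strategy, cost, utility.
as_outcome_list <- function(outcomes) {
  if (is.data.frame(outcomes)) {
    out <- lapply(seq_len(nrow(outcomes)), function(i)
      list(strategy = outcomes$strategy[i],
           total_cost = outcomes$cost[i], total_qaly = outcomes$utility[i]))
    names(out) <- outcomes$strategy
    return(out)
  }
  if (is.null(names(outcomes)))
    names(outcomes) <- vapply(outcomes, `[[`, "", "strategy")
  outcomes
}

#' Pairwise cost-utility comparison table
#'
#' Builds the standard report: per-strategy lifetime cost, utility and C/U
#' ratio, then pairwise incremental comparisons — each other strategy
#' against the FCG reference, and venous HbA1c against POCT HbA1c when both
#' are present (mirroring the usual presentation for these three
#' strategies). With other strategy sets, every strategy is compared
#' against the first.
#'
#' @param outcomes Named list of \code{strategy_outcome}s (or any lists
#'   with \code{total_cost}/\code{total_qaly}), or a data frame with
#'   columns \code{strategy}, \code{cost}, \code{utility}.
#' @param wtp Willingness-to-pay threshold (scalar USD/QALY or \code{wtp}
#'   list).
#' @return Object of class \code{cea_comparison}: \code{table} (one row
#'   per strategy/comparison with columns strategy, comparator, cost,
#'   incr_cost, utility, incr_utility, cu_ratio, icur, verdict) and
#'   \code{comparisons} (the underlying \code{cea_result}s).
#' @export
full_comparison <- function(outcomes, wtp = 37653) {
  outcomes <- as_outcome_list(outcomes)
  if (length(outcomes) < 2) stop("need at least two strategies to compare")
  nm <- names(outcomes)
  ref_name <- if ("FCG" %in% nm) "FCG" else nm[1]
  pairs <- lapply(setdiff(nm, ref_name), function(s) c(ref_name, s))
  if (all(c("POCT_HBA1C", "VENOUS_HBA1C") %in% nm))
    pairs <- c(pairs, list(c("POCT_HBA1C", "VENOUS_HBA1C")))
  comparisons <- lapply(pairs, function(pr)
    compute_icur(outcomes[[pr[1]]], outcomes[[pr[2]]], wtp))
  rows <- list()
  rows[[1]] <- data.frame(
    strategy = ref_name, comparator = NA_character_,
    cost = outcomes[[ref_name]]$total_cost, incr_cost = NA_real_,
    utility = outcomes[[ref_name]]$total_qaly, incr_utility = NA_real_,
    cu_ratio = cost_utility_ratio(outcomes[[ref_name]]$total_cost,
                                  outcomes[[ref_name]]$total_qaly),
    icur = NA_real_, verdict = NA_character_, stringsAsFactors = FALSE)
  for (cmp in comparisons) {
    o <- outcomes[[cmp$comparator]]
    rows[[length(rows) + 1L]] <- data.frame(
      strategy = cmp$comparator, comparator = cmp$reference,
      cost = o$total_cost, incr_cost = cmp$delta_cost,
      utility = o$total_qaly, incr_utility = cmp$delta_utility,
      cu_ratio = cost_utility_ratio(o$total_cost, o$total_qaly),
      icur = cmp$icur, verdict = cmp$verdict, stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), comparisons = comparisons,
                 lambda = if (is.list(wtp)) wtp$lambda else wtp),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("Cost-utility comparison (WTP lambda = %s USD/QALY)\n",
              format(x$lambda, big.mark = ",")))
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Fit the full screening cost-effectiveness model
#'
#' The front door of the package: evaluates every screening strategy in
#' \code{params} through the decision tree and the Markov disease models,
#' then assembles the pairwise incremental cost-utility comparison against
#' the willingness-to-pay threshold.
#'
#' @param params A validated \code{\link{cea_parameters}} bundle, e.g. from
#'   \code{\link{load_parameters}} or \code{\link{generate_parameter_set}}.
#' @param mode \code{"cohort"} for the deterministic cohort recursion
#'   (default) or \code{"microsim"} for individual-level Monte Carlo.
#' @param n_individuals,seed Microsimulation controls (ignored for cohort
#'   mode).
#' @return Object of class \code{screen_cea}: per-strategy outcomes,
#'   the \code{\link{full_comparison}} result, and the inputs used.
#' @examples
#' params <- generate_parameter_set(synthetic_spec(seed = 1))
#' fit <- screen_cea(params)
#' fit
#' summary(fit)
#' @export
screen_cea <- function(params, mode = c("cohort", "microsim"),
                       n_individuals = 10000, seed = 1) {
  mode <- match.arg(mode)
  validate_parameters(params)
  outcomes <- lapply(params$strategies, function(s)
    run_strategy(params, s, mode = mode, n_individuals = n_individuals,
                 seed = seed))
  names(outcomes) <- vapply(params$strategies, `[[`, "", "name")
  cmp <- full_comparison(outcomes, params$wtp)
  structure(list(outcomes = outcomes, comparison = cmp, params = params,
                 mode = mode, setting = params$setting$label),
            class = "screen_cea")
}

#' @export
print.screen_cea <- function(x, ...) {
  cat(sprintf("Screening cost-effectiveness model (%s setting, %s mode)\n\n",
              x$setting, x$mode))
  print(x$comparison)
  invisible(x)
}

#' @describeIn screen_cea Per-strategy and incremental summary with verdicts.
#' @param object,... A fitted \code{screen_cea} object.
#' @export
summary.screen_cea <- function(object, ...) {
  out <- list(setting = object$setting, mode = object$mode,
              table = object$comparison$table,
              lambda = object$comparison$lambda,
              screening_costs = vapply(object$outcomes, `[[`, 0,
                                       "screening_cost"))
  class(out) <- "summary.screen_cea"
  out
}

#' @export
print.summary.screen_cea <- function(x, ...) {
  cat(sprintf("Setting: %s  (mode: %s)\n", x$setting, x$mode))
  cat(sprintf("Willingness to pay: %s USD/QALY\n\n",
              format(x$lambda, big.mark = ",")))
  cat("Screening-stage cost per capita (USD):\n")
  print(round(x$screening_costs, 2))
  cat("\nLifetime discounted outcomes and pairwise comparisons:\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @describeIn screen_cea Cost-utility plane of the fitted strategies.
#' @param x A fitted \code{screen_cea} object.
#' @param y Ignored.
#' @export
plot.screen_cea <- function(x, y, ...) {
  costs <- vapply(x$outcomes, `[[`, 0, "total_cost")
  qalys <- vapply(x$outcomes, `[[`, 0, "total_qaly")
  graphics::plot(qalys, costs, pch = 19,
                 xlab = "Lifetime QALYs (discounted)",
                 ylab = "Lifetime cost (USD, discounted)",
                 main = sprintf("Cost-utility plane (%s)", x$setting), ...)
  graphics::text(qalys, costs, names(x$outcomes), pos = 3, cex = 0.8)
  invisible(x)
}
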