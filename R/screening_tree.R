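#' Classify a screened population through the decision tree
#'
#' One-shot screening at baseline: screen-positives receive a confirmatory
#' oral glucose tolerance test (OGTT), treated as a perfect gold standard.
#' The population therefore splits into four arms: diagnosed (true diabetic,
#' screen positive), missed (true diabetic, screen negative), misdiagnosed
#' (non-diabetic, screen positive, ruled out by OGTT) and true negative.
#'
#' @param prevalence Prevalence of undiagnosed type 2 diabetes, in (0,1).
#' @param strategy A \code{\link{screening_strategy}}.
#' @return List of class \code{classification_result} with fractions
#'   \code{p_diagnosed}, \code{p_missed}, \code{p_misdiagnosed},
#'   \code{p_true_negative} (summing to 1).
#' @examples
#' s <- screening_strategy("POCT_HBA1C", 0.9, 0.8, 3, 1, 1)
#' classify(0.10, s)
#' @export
classify <- function(prevalence, strategy) {
  if (!is.numeric(prevalence) || length(prevalence) != 1 ||
      prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0,1)")
  se <- strategy$sensitivity
  sp <- strategy$specificity
  res <- list(p_diagnosed = prevalence * se,
              p_missed = prevalence * (1 - se),
              p_misdiagnosed = (1 - prevalence) * (1 - sp),
              p_true_negative = (1 - prevalence) * sp)
  class(res) <- "classification_result"
  res
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Decision-tree classification (fractions of the screened cohort)\n")
  cat(sprintf("  diagnosed     %.6f\n  missed        %.6f\n", x$p_diagnosed,
              x$p_missed))
  cat(sprintf("  misdiagnosed  %.6f\n  true negative %.6f\n",
              x$p_misdiagnosed, x$p_true_negative))
  invisible(x)
}

#' Expected screening-stage cost per screened person
#'
#' Everybody pays the strategy's per-test cost (direct medical plus direct
#' non-medical plus indirect); screen-positives — true positives and false
#' positives alike — additionally incur the confirmatory OGTT cost.
#'
#' @inheritParams classify
#' @param costs The \code{costs} element of a \code{cea_parameters} (uses
#'   \code{ogtt_cost}).
#' @return Expected USD per capita at baseline (not discounted; screening
#'   happens at time zero).
#' @export
screening_stage_cost <- function(prevalence, strategy, costs) {
  per_test <- strategy$cost_direct_medical + strategy$cost_direct_nonmedical +
    strategy$cost_indirect
  p_pos <- prevalence * strategy$sensitivity +
    (1 - prevalence) * (1 - strategy$specificity)
  per_test + p_pos * costs$ogtt_cost
}
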