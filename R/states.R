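#' Health states of the disease-progression models
#'
#' The diabetic model tracks type 2 diabetes without complications, six
#' primary complications (cardiovascular disease, stroke, diabetic kidney
#' disease, diabetic foot ulcer, diabetic retinopathy, diabetic peripheral
#' neuropathy), three progressed complications reachable only from their
#' precursor (end-stage renal disease from kidney disease, amputation from
#' foot ulcer, blindness from retinopathy), a lumped multi-complication
#' state and death. The non-diabetic model uses only \code{NON_DM} and
#' \code{DEATH}.
#'
#' @return Character vector of the thirteen state labels, in canonical order.
#' @export
health_states <- function() {
  c("NON_DM", "DM_NO_COMP", "DM_CVD", "DM_STROKE", "DM_DKD", "DM_ESRD",
    "DM_DFU", "DM_AMPUTATION", "DM_DR", "DM_BLINDNESS", "DM_DPN",
    "DM_MULTI_COMP", "DEATH")
}

#' Vascular class of each health state
#'
#' Classes drive hazard-ratio adjustment: transitions into macrovascular
#' states are scaled by the macrovascular HR, microvascular states by the
#' microvascular HR, and death by the mortality HR. The lumped
#' multi-complication state carries no class tag and is left unscaled.
#'
#' @return Named character vector mapping state to one of
#'   \code{"none"}, \code{"macrovascular"}, \code{"microvascular"},
#'   \code{"terminal"}.
#' @export
state_class <- function() {
  c(NON_DM = "none", DM_NO_COMP = "none",
    DM_CVD = "macrovascular", DM_STROKE = "macrovascular",
    DM_DKD = "microvascular", DM_ESRD = "microvascular",
    DM_DFU = "microvascular", DM_AMPUTATION = "microvascular",
    DM_DR = "microvascular", DM_BLINDNESS = "microvascular",
    DM_DPN = "microvascular",
    DM_MULTI_COMP = "none", DEATH = "terminal")
}

# Logical mask of structurally allowed transitions.  TRUE means the
# transition may carry positive probability.  Encodes: DEATH absorbing;
# NON_DM only to itself or DEATH; progressed complications reachable only
# from their precursor; every diabetic state may stay, move to the lumped
# multi-complication state, or die.
allowed_transitions <- function() {
  s <- health_states()
  m <- matrix(FALSE, length(s), length(s), dimnames = list(s, s))
  m["NON_DM", c("NON_DM", "DEATH")] <- TRUE
  m["DM_NO_COMP", c("DM_NO_COMP", "DM_CVD", "DM_STROKE", "DM_DKD", "DM_DFU",
                    "DM_DR", "DM_DPN", "DM_MULTI_COMP", "DEATH")] <- TRUE
  simple <- c("DM_CVD", "DM_STROKE", "DM_ESRD", "DM_AMPUTATION",
              "DM_BLINDNESS", "DM_DPN")
  for (st in simple) m[st, c(st, "DM_MULTI_COMP", "DEATH")] <- TRUE
  m["DM_DKD", c("DM_DKD", "DM_ESRD", "DM_MULTI_COMP", "DEATH")] <- TRUE
  m["DM_DFU", c("DM_DFU", "DM_AMPUTATION", "DM_MULTI_COMP", "DEATH")] <- TRUE
  m["DM_DR",  c("DM_DR", "DM_BLINDNESS", "DM_MULTI_COMP", "DEATH")] <- TRUE
  m["DM_MULTI_COMP", c("DM_MULTI_COMP", "DEATH")] <- TRUE
  m["DEATH", "DEATH"] <- TRUE
  m
}

#' Screening strategy labels
#'
#' @return Character vector \code{c("POCT_HBA1C", "VENOUS_HBA1C", "FCG")}:
#'   point-of-care fingertip HbA1c, laboratory venous HbA1c, and fasting
#'   capillary glucose.
#' @export
strategy_names <- function() c("POCT_HBA1C", "VENOUS_HBA1C", "FCG")
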