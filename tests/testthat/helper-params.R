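# Shared fixtures, generated once per test run.
params_urban <- generate_parameter_set(synthetic_spec(seed = 101, "urban"))
params_rural <- generate_parameter_set(synthetic_spec(seed = 101, "rural"))

# A minimal hand-built transition table for HR-algebra tests: one age band,
# one micro and one macro destination reachable from uncomplicated diabetes.
mini_table <- function(p_dkd = 0.05, p_stroke = 0.04, p_death = 0.02,
                       p_blind = 0.01) {
  long <- data.frame(
    from_state = c("DM_NO_COMP", "DM_NO_COMP", "DM_NO_COMP", "DM_NO_COMP",
                   "DM_DR", "DM_DR"),
    to_state = c("DM_NO_COMP", "DM_DKD", "DM_STROKE", "DEATH",
                 "DM_BLINDNESS", "DM_DR"),
    age_low = 18, age_high = 80,
    probability = c(1 - p_dkd - p_stroke - p_death, p_dkd, p_stroke,
                    p_death, p_blind, 1 - p_blind))
  transition_table(long)
}

# Printed per-strategy lifetime costs and utilities of the three screening
# strategies in the two settings (the published summary table; used to
# exercise the incremental arithmetic of the comparison layer).
table1_path <- system.file("extdata", "table1_strategies.csv",
                           package = "screencea")
if (table1_path == "") table1_path <-
  file.path("..", "..", "inst", "extdata", "table1_strategies.csv")
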