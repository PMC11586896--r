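# shared fixtures: the five-dose grid and a prior calibrated to the
# standard elicitation (built once per test run; reduced Monte-Carlo
# draws keep this quick while staying well inside the tolerances the
# tests use)
std_grid <- dose_grid(c(0.2, 0.4, 0.6, 0.8, 1))

std_target <- elicitation_target(pi_E = c(0.3, 0.5, 0.6, 0.65, 0.7),
                                 pi_T = c(0.05, 0.1, 0.15, 0.2, 0.25),
                                 ess = 0.9)

std_prior <- calibrate_prior(std_target, std_grid, n_draws = 2e4,
                             seed = 104729L)

# short-chain trial configuration used by simulation-heavy tests
short_config <- function(design = "proposed", ...) {
  trial_config(std_grid, std_prior, design = design,
               n_burn = 100L, n_keep = 250L, ...)
}
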