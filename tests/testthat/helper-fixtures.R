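# shared fixtures, all generated in code

# minimal 2-case, 2-rater, 3-class table
tiny_table <- function() {
  response_table(data.frame(
    case = c(0, 0, 1, 1), rater = c(0, 1, 0, 1),
    truth = c(2, 2, 0, 0), response = c(2, 1, 0, 0)))
}

# random parameter set for any variant, deterministic in seed
random_params <- function(spec, n_cases, n_raters, seed = 1) {
  cfg <- simulation_config(n_raters = n_raters, n_cases = n_cases,
                           n_classes = spec$n_classes,
                           variant = spec$variant,
                           alpha_prior = if (spec$alpha_prior == "none") NULL
                                         else spec$alpha_prior,
                           seed = seed,
                           beta_by_response = spec$beta_by_response)
  draw_parameters(cfg)
}

# small simulated study plus its generating truth
small_sim <- function(variant = "mdnrm_r", alpha_prior = "gamma",
                      n_raters = 3, n_cases = 25, seed = 7) {
  cfg <- simulation_config(n_raters = n_raters, n_cases = n_cases,
                           n_classes = 3, variant = variant,
                           alpha_prior = alpha_prior, seed = seed)
  generate_dataset(cfg)
}

all_mdnrm_variants <- c("mdnrm_orig", "mdnrm_a", "mdnrm_b", "mdnrm_r")
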