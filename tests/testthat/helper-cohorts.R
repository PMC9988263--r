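# Shared fixtures, all generated in code.

# generating population for recovery experiments: group locations within the
# bulk of the hierarchical priors so the experiment simulates from the model
recovery_generative <- function(n_subjects = 15, drugs = "placebo",
                                seed = 11, ...) {
  generative_config(
    n_subjects = n_subjects, drugs = drugs, seed = seed,
    group_loc = c(eta_pos = -0.4, eta_neg = -0.9, rho = 0.1, alpha = 0.2,
                  tau = 0, beta = 0, nu = 0.2, nu_max = 0.5),
    group_scale = c(eta_pos = 0.4, eta_neg = 0.4, rho = 0.1, alpha = 0.1,
                    tau = 0.5, beta = 0.2, nu = 0.2, nu_max = 0.2),
    ...)
}

# generating population for model-recovery: scaled sensitivity and drift
# saturation clearly expressed (near rho = 1 model 4 collapses onto model 1)
modelrec_generative <- function(seed, n_subjects = 10) {
  generative_config(
    n_subjects = n_subjects, drugs = "placebo", seed = seed,
    group_loc = c(eta_pos = -0.2, eta_neg = -0.9, rho = 0.5, alpha = 0.2,
                  tau = 0, beta = 0, nu = 0.8, nu_max = 0.5),
    group_scale = c(eta_pos = 0.4, eta_neg = 0.4, rho = 0.1, alpha = 0.1,
                    tau = 0.5, beta = 0.2, nu = 0.2, nu_max = 0.2))
}

small_cohort <- function(n_subjects = 4, drugs = "placebo", seed = 7,
                         n_blocks = 5, spec = 4) {
  generate_cohort(recovery_generative(n_subjects, drugs, seed),
                  task_config(n_blocks = n_blocks), spec = spec)
}

quick_fit <- function(data, spec = 4, iter = 400, warmup = 150, seed = 5,
                      chains = 1) {
  suppressWarnings(fit_rlddm(data, spec = spec, chains = chains, iter = iter,
                             warmup = warmup, seed = seed))
}

# one small shared fit reused across posterior tests (built on first use)
.fixture_env <- new.env()
shared_small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    coh <- small_cohort(n_subjects = 6, seed = 19)
    .fixture_env$fit <- quick_fit(coh, iter = 500, warmup = 200, seed = 20)
    .fixture_env$cohort <- coh
  }
  .fixture_env$fit
}
shared_small_cohort <- function() {
  shared_small_fit()
  .fixture_env$cohort
}
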