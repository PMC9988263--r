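test_that("parameter transforms are exact inverses with the stated identities", {
  u <- c(eta_pos = 0, eta_neg = -1.2, rho = 0, alpha = 0.4, tau = 0,
         beta = 0.3, nu = -0.5, nu_max = 1.1)
  p <- to_native(u, tau_ref = 0.8)
  expect_equal(unname(p["eta_pos"]), 0.5)      # logistic(0)
  expect_equal(unname(p["rho"]), 1)            # exp(0)
  expect_equal(unname(p["tau"]), 0.4)          # logistic(0) * 0.8
  back <- to_unconstrained(p, tau_ref = 0.8)
  expect_equal(unname(back), unname(u), tolerance = 1e-12)
  # tau stays below the reference for any raw value
  for (raw in c(-20, -1, 0, 3, 20)) {
    uu <- u; uu["tau"] <- raw
    expect_lt(to_native(uu, tau_ref = 0.41)[["tau"]], 0.41)
  }
  expect_error(to_native(u), "tau_ref")
  # matrix interface round trip
  U <- rbind(u, u + 0.3)
  expect_equal(to_unconstrained(to_native(U, 0.5), 0.5), U,
               tolerance = 1e-12)
})

test_that("prior draws match the documented hyperparameters", {
  pr <- sample_prior(40000, seed = 123)
  cat_ <- prior_catalog()
  expect_lt(max(abs(colMeans(pr$mu) - cat_$mu_loc)), 0.02)
  expect_lt(max(abs(apply(pr$mu, 2, sd) - cat_$mu_scale)), 0.02)
  # half-normal scales: E|X| = scale * sqrt(2/pi)
  expect_lt(max(abs(colMeans(pr$sigma) - cat_$sigma_scale * sqrt(2 / pi))),
            0.02)
  expect_lt(max(abs(colMeans(pr$drug_scale) - 0.1 * sqrt(2 / pi))), 0.005)
  expect_lt(max(abs(apply(pr$z, 2, sd) - 1)), 0.02)
  # bias location prior is tighter than the learning-rate one
  expect_lt(sd(pr$mu[, "beta"]), sd(pr$mu[, "eta_pos"]))
})

test_that("the model likelihood decomposes into RL-derived drifts and Wiener densities", {
  coh <- small_cohort(n_subjects = 2, seed = 13)
  prep <- prepare_data(coh)
  pars <- c(eta_pos = 0.35, eta_neg = 0.25, rho = 1.3, alpha = 1.3,
            tau = 0.2, beta = 0.55, nu = 1.1, nu_max = 1.4)
  for (spec_id in c(1, 4)) {
    ll <- loglik_rlddm(prep, pars, spec = spec_id)
    # independent composition in R: Q trajectory -> drift -> Wiener density
    for (k in seq_len(nrow(prep$sessions))) {
      i <- prep$trials$subject_id == prep$sessions$subject_id[k] &
        prep$trials$drug == prep$sessions$drug[k]
      tr <- prep$trials[i, ]
      ser <- run_rl(tr$choice, tr$outcome, as.list(pars), spec = spec_id)
      drift <- if (model_spec(spec_id)$drift_mapping == "sigmoid")
        drift_sigmoid(ser$q_high, ser$q_low, pars["nu"], pars["nu_max"])
      else drift_linear(ser$q_high, ser$q_low, pars["nu"])
      ref <- sum(vapply(seq_len(nrow(tr)), function(t)
        wiener_logpdf(tr$rt_s[t],
                      ifelse(tr$choice[t] == "high", "upper", "lower"),
                      pars["alpha"], pars["tau"], pars["beta"], drift[t]),
        numeric(1)))
      expect_equal(unname(ll[k]), ref, tolerance = 1e-10)
    }
  }
})

test_that("setting rho to one collapses the scaled variants onto the static ones", {
  coh <- small_cohort(n_subjects = 3, seed = 17)
  pars <- c(eta_pos = 0.4, eta_neg = 0.3, rho = 1, alpha = 1.2, tau = 0.2,
            beta = 0.5, nu = 1.3, nu_max = 1.6)
  expect_lt(max(abs(loglik_rlddm(coh, pars, spec = 2) -
                      loglik_rlddm(coh, pars, spec = 1))), 1e-10)
  expect_lt(max(abs(loglik_rlddm(coh, pars, spec = 4) -
                      loglik_rlddm(coh, pars, spec = 3))), 1e-10)
})

test_that("data preparation derives session structure and rejects invalid input", {
  coh <- small_cohort(n_subjects = 2, seed = 5)
  prep <- prepare_data(coh)
  expect_equal(nrow(prep$sessions), 2L)
  expect_equal(sum(prep$sessions$n_trials), sum(coh$trial_type == "test"))
  for (k in seq_len(nrow(prep$sessions))) {
    i <- prep$trials$subject_id == prep$sessions$subject_id[k]
    expect_equal(prep$sessions$min_rt[k], min(prep$trials$rt_s[i]))
  }
  empty <- coh[coh$trial_type == "neutral", ]
  expect_error(prepare_data(empty), "no completed test trials")
  bad <- coh; bad$rt_s[bad$trial_type == "test"][1] <- -0.1
  expect_error(prepare_data(bad), "positive")
  expect_error(fit_rlddm(empty, spec = 1), "no completed test trials")
})

test_that("posterior sampling returns well-formed, seed-reproducible draws", {
  coh <- small_cohort(n_subjects = 3, seed = 23)
  fit <- quick_fit(coh, iter = 250, warmup = 100, seed = 31)
  n_keep <- 150
  expect_s3_class(fit, "rlddm_fit")
  expect_equal(dim(fit$draws$mu), c(n_keep, 8L))
  expect_equal(dim(fit$draws$sess_native), c(n_keep, 3L, 8L))
  expect_true(all(is.finite(fit$rhat)))
  # native draws respect their ranges, tau below each session's minimum RT
  P <- fit$draws$sess_native
  expect_true(all(P[, , 1] > 0 & P[, , 1] < 1))   # eta_pos
  expect_true(all(P[, , 4] > 0))                  # alpha
  for (k in 1:3) expect_true(all(P[, k, 5] < fit$sessions$min_rt[k]))
  # identical seed, identical data -> identical draws
  fit2 <- quick_fit(coh, iter = 250, warmup = 100, seed = 31)
  expect_identical(fit$draws$mu, fit2$draws$mu)
  expect_identical(fit$draws$sess_native, fit2$draws$sess_native)
  # different seed -> different draws
  fit3 <- quick_fit(coh, iter = 250, warmup = 100, seed = 32)
  expect_false(identical(fit$draws$mu, fit3$draws$mu))
  # summary table covers active parameters
  s <- summary(fit)
  expect_true(all(paste0("mu_", fit$active) %in% s$quantity))
  expect_output(print(fit), "Hierarchical RL-DDM")
})

test_that("convergence report flags the documented thresholds", {
  fit <- shared_small_fit()
  conv <- convergence_report(fit, quiet = TRUE)
  expect_true(conv$status %in% c("ok", "warn", "fail"))
  expect_equal(conv$max_rhat, max(fit$rhat))
  # thresholds: fabricate rhat vectors around the rule
  f2 <- fit; f2$rhat <- c(a = 1.005)
  expect_equal(convergence_report(f2, quiet = TRUE)$status, "ok")
  f2$rhat <- c(a = 1.05)
  expect_equal(convergence_report(f2, quiet = TRUE)$status, "warn")
  f2$rhat <- c(a = 1.2)
  expect_equal(convergence_report(f2, quiet = TRUE)$status, "fail")
})
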