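test_that("highest density intervals are narrowest mass-covering windows", {
  expect_equal(as.numeric(hdi(rep(2.5, 100))), c(2.5, 2.5))
  set.seed(4)
  x <- rnorm(1e5)
  h <- hdi(x)
  expect_equal(as.numeric(h), c(-1.96, 1.96), tolerance = 0.05)
  expect_gte(mean(x >= h["lower"] & x <= h["upper"]), 0.95)
  # narrower than the central interval for a skewed sample
  y <- rexp(1e5)
  hy <- hdi(y)
  ci <- quantile(y, c(0.025, 0.975))
  expect_lt(hy["upper"] - hy["lower"], ci[2] - ci[1])
  expect_error(hdi(numeric(0)), "two samples")
  expect_error(hdi(1), "two samples")
  expect_error(hdi(rnorm(10), mass = 1.5), "mass")
})

test_that("a known boundary-separation drug shift is recovered by the group contrast", {
  shifts <- matrix(0, 2, 8,
                   dimnames = list(c("placebo", "levodopa"),
                                   reliefrl:::PAR_NAMES))
  shifts["levodopa", "alpha"] <- 0.3
  gen <- recovery_generative(n_subjects = 10,
                             drugs = c("placebo", "levodopa"),
                             seed = 41, drug_shifts = shifts)
  coh <- generate_cohort(gen, task_config(), spec = 4)
  fit <- quick_fit(coh, iter = 600, warmup = 250, seed = 42)
  ctr <- contrast_drug(fit, "alpha", "levodopa", "placebo")
  expect_false(ctr$encloses_zero)
  expect_gt(ctr$mean, 0)
  expect_lt(abs(ctr$mean - 0.3), 0.25)
  # a parameter without a generated shift straddles zero
  null_ctr <- contrast_drug(fit, "beta", "levodopa", "placebo")
  expect_true(null_ctr$encloses_zero)
  # the flag is exactly the zero-enclosure predicate
  for (ct in list(ctr, null_ctr)) {
    expect_equal(ct$encloses_zero,
                 unname(ct$hdi["lower"] <= 0 && 0 <= ct$hdi["upper"]))
  }
  # self-contrast is exactly null
  self <- contrast_drug(fit, "alpha", "levodopa", "levodopa")
  expect_true(self$encloses_zero)
  expect_equal(self$mean, 0)
  expect_error(contrast_drug(fit, "nope", "levodopa", "placebo"), "parameter")
  expect_error(contrast_drug(fit, "alpha", "levodopa", "drugX"), "condition")
})

test_that("a learning-rate drug shift is detected directionally despite parameter trade-offs", {
  # an eta+ shift expresses itself jointly with correlated drift-scaling
  # effects, so the single-parameter interval stays wide; the posterior
  # mass must still move toward the generated positive shift
  shifts <- matrix(0, 2, 8,
                   dimnames = list(c("placebo", "levodopa"),
                                   reliefrl:::PAR_NAMES))
  shifts["levodopa", "eta_pos"] <- 1.0
  gen <- generative_config(
    n_subjects = 15, drugs = c("placebo", "levodopa"), seed = 31,
    drug_shifts = shifts,
    group_loc = c(eta_pos = -1.5, eta_neg = -0.9, rho = 0.5, alpha = 0.2,
                  tau = 0, beta = 0, nu = 1.0, nu_max = 0.5),
    group_scale = c(eta_pos = 0.4, eta_neg = 0.4, rho = 0.1, alpha = 0.1,
                    tau = 0.5, beta = 0.2, nu = 0.2, nu_max = 0.2))
  coh <- generate_cohort(gen, task_config(n_blocks = 10), spec = 4)
  fit <- quick_fit(coh, iter = 800, warmup = 350, seed = 32)
  ctr <- contrast_drug(fit, "eta_pos", "levodopa", "placebo")
  expect_gt(ctr$mean, 0)
  expect_gt(mean(ctr$draws > 0), 0.6)
})

test_that("posterior predictive choice proportions are calibrated summaries", {
  fit <- shared_small_fit()
  ppc <- posterior_predict_choice(fit, task_config(), n_rep = 120, seed = 2)
  expect_length(ppc$statistic, 120L)
  expect_true(all(ppc$statistic >= 0 & ppc$statistic <= 1))
  expect_gte(ppc$p_one_sided, 0)
  expect_lte(ppc$p_one_sided, 1)
  expect_gte(ppc$p_two_sided, 0)
  expect_lte(ppc$p_two_sided, 1)
  expect_true(ppc$hdi["lower"] <= ppc$mean && ppc$mean <= ppc$hdi["upper"])
  # the replicated statistic should not be wildly inconsistent with the
  # fitted data's own statistic
  expect_gt(ppc$p_two_sided, 0.01)
})

test_that("a fully biased agent saturates the preference statistic", {
  p <- c(eta_pos = 0.3, eta_neg = 0.3, rho = 1, alpha = 1.2, tau = 0.2,
         beta = 0.9999, nu = 0, nu_max = 1)
  sched <- generate_schedule(task_config(), seed = 1)
  ag <- simulate_agent(p, sched, spec = 1, seed = 2)
  blk <- sched$block[match(ag$trial_index, sched$trial_index)]
  stat <- mean(ag$choice[blk >= 4] == "high")
  expect_equal(stat, 1)
})

test_that("extracted prediction errors replay the Q recursion at posterior means", {
  fit <- shared_small_fit()
  pe <- extract_pe(fit)
  expect_equal(nrow(pe), nrow(fit$trials))
  sp <- subject_params(fit)
  for (kk in unique(paste(pe$subject_id, pe$drug))) {
    i <- paste(pe$subject_id, pe$drug) == kk
    srow <- sp[paste(sp$subject_id, sp$drug) == kk, ]
    ser <- run_rl(pe$choice[i], pe$outcome[i],
                  as.list(setNames(as.numeric(srow[1, reliefrl:::PAR_NAMES]),
                                   reliefrl:::PAR_NAMES)), spec = fit$spec)
    expect_equal(pe$delta[i], ser$delta, tolerance = 1e-12)
    # first test trial: delta is +/- rho exactly (Q starts at zero)
    first_delta <- pe$delta[i][1]
    expected <- ifelse(pe$outcome[i][1] == "win", 1, -1) * srow$rho
    expect_equal(first_delta, expected, tolerance = 1e-12)
  }
  # scaled-model sign property: wins carry positive, losses negative PEs
  expect_true(all(pe$delta[pe$outcome == "win"] > 0))
  expect_true(all(pe$delta[pe$outcome == "lose"] < 0))
  # unseen subject is rejected
  other <- shared_small_cohort()
  other$subject_id <- paste0("X", other$subject_id)
  expect_error(extract_pe(fit, other), "absent")
})
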