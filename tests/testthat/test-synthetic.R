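test_that("session schedules carry the exact block composition", {
  sched <- generate_schedule(task_config(), seed = 1)
  expect_equal(nrow(sched), 45L)
  expect_equal(sum(sched$trial_type == "test"), 20L)
  expect_equal(sum(sched$trial_type == "control"), 20L)
  expect_equal(sum(sched$trial_type == "neutral"), 5L)
  for (b in 1:5) {
    blk <- sched$trial_type[sched$block == b]
    expect_equal(sum(blk == "test"), 4L)
    expect_equal(sum(blk == "control"), 4L)
    expect_equal(blk[length(blk)], "neutral")
  }
  one <- generate_schedule(task_config(n_blocks = 1), seed = 2)
  expect_equal(nrow(one), 9L)
  expect_equal(one$trial_type[9], "neutral")
  expect_identical(generate_schedule(task_config(), seed = 5),
                   generate_schedule(task_config(), seed = 5))
  expect_error(task_config(n_blocks = 0), "positive")
  expect_error(task_config(p_win_high = 1.5), "probabilities")
})

test_that("realized win frequency of the high option matches its contingency", {
  # an agent biased almost entirely toward the high option
  p <- c(eta_pos = 0.3, eta_neg = 0.3, rho = 1, alpha = 1.2, tau = 0.2,
         beta = 0.999, nu = 0, nu_max = 1)
  ag <- simulate_agent(p, 10000, spec = 1, seed = 123)
  high <- ag$choice == "high"
  expect_gt(mean(high), 0.99)
  wf <- mean(ag$outcome[high] == "win")
  expect_lt(abs(wf - 0.75), 3 * sqrt(0.75 * 0.25 / sum(high)))
})

test_that("agent simulation honors the RT floor, symmetry, learning, and seeding", {
  p0 <- c(eta_pos = 0.3, eta_neg = 0.3, rho = 1, alpha = 1.2, tau = 0.25,
          beta = 0.5, nu = 0, nu_max = 1)
  ag <- simulate_agent(p0, 4000, spec = 1, seed = 9)
  expect_true(all(ag$rt > 0.25))
  # zero drift scaling, unbiased start: both options equally likely
  expect_lt(abs(mean(ag$choice == "high") - 0.5), 3 * sqrt(0.25 / 4000))
  # strong learning and drift coupling: preference for the better option
  p1 <- c(eta_pos = 0.7, eta_neg = 0.3, rho = 1, alpha = 1.2, tau = 0.25,
          beta = 0.5, nu = 3, nu_max = 2)
  ag1 <- simulate_agent(p1, 2000, spec = 1, seed = 10)
  expect_gt(mean(ag1$choice == "high"), 0.55)
  # bit-identical replay under a fixed seed
  expect_identical(simulate_agent(p1, 200, spec = 4, seed = 11),
                   simulate_agent(p1, 200, spec = 4, seed = 11))
  # Q trajectory identical to run_rl on the realized sequence
  ser <- run_rl(ag1$choice, ifelse(ag1$outcome == "win", 1, -1),
                as.list(p1), spec = 1)
  expect_equal(ag1$q_high, ser$q_high, tolerance = 1e-12)
  expect_equal(ag1$delta, ser$delta, tolerance = 1e-12)
  bad <- p1; bad["eta_pos"] <- 1.5
  expect_error(simulate_agent(bad, 10, spec = 1, seed = 1), "learning rates")
})

test_that("zero-noise pain generation is an exact affine function of the PE", {
  gen <- generative_config(noise_sd_vas = 0, noise_sd_beh = 0)
  pe <- data.frame(delta = c(-1.5, -0.2, 0, 1))
  pain <- simulate_pain(pe, gen, seed = 1, drug = "placebo")
  expect_equal(pain$vas_modulation,
               gen$vas_offsets[["placebo"]] + gen$beta_pe_vas * pe$delta,
               tolerance = 1e-12)
  expect_equal(pain$beh_modulation,
               gen$beh_offsets[["placebo"]] + gen$beta_pe_beh * pe$delta,
               tolerance = 1e-12)
  # unit PE moves the VAS modulation by the configured slope (-0.36)
  expect_equal(pain$vas_modulation[4] - pain$vas_modulation[3], -0.36)
  expect_error(simulate_pain(data.frame(x = 1), gen), "delta")
})

test_that("regression on simulated pain output recovers the generating slope", {
  gen <- generative_config(seed = 1)
  set.seed(2)
  pe <- data.frame(delta = rnorm(2000, 0, 1))
  pain <- simulate_pain(pe, gen, seed = 3, drug = "placebo")
  fit <- lm(pain$vas_modulation ~ pe$delta)
  est <- coef(summary(fit))["pe$delta", ]
  expect_lt(abs(est["Estimate"] - gen$beta_pe_vas), 2 * est["Std. Error"])
})

test_that("cohort generation yields the full design, matched controls, and seeded determinism", {
  gen <- generative_config(n_subjects = 3, seed = 4)
  coh <- generate_cohort(gen, task_config(), spec = 4)
  expect_equal(nrow(coh), 3 * 3 * 45)
  key <- paste(coh$subject_id, coh$drug)
  expect_equal(length(unique(key)), 9L)
  # control win/lose counts match realized test outcomes in every session
  for (kk in unique(key)) {
    ss <- coh[key == kk, ]
    t_out <- table(factor(ss$outcome[ss$trial_type == "test" &
                                       ss$choice != "none"],
                          levels = c("win", "lose")))
    c_out <- table(factor(ss$outcome[ss$trial_type == "control"],
                          levels = c("win", "lose")))
    expect_equal(as.numeric(t_out), as.numeric(c_out))
  }
  expect_identical(coh, generate_cohort(generative_config(n_subjects = 3,
                                                          seed = 4),
                                        task_config(), spec = 4))
  # minimal cohort
  tiny <- generate_cohort(generative_config(n_subjects = 1,
                                            drugs = "placebo", seed = 1),
                          task_config(), spec = 1)
  expect_equal(nrow(tiny), 45L)
  expect_true(all(tiny$vas_rating >= 0 & tiny$vas_rating <= 200))
  expect_error(generative_config(n_subjects = 0), "n_subjects")
  expect_error(generative_config(drugs = c("a", "a")), "unique")
  expect_error(generative_config(noise_sd_vas = -1), "noise")
})

test_that("cohort tables survive a CSV round trip unchanged", {
  coh <- small_cohort(n_subjects = 2, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_trials(coh, path)
  back <- read_trials(path)
  for (col in names(back)) {
    expect_equal(back[[col]], coh[[col]], info = col)
  }
})

test_that("subject scales of zero collapse every subject onto the group intercept", {
  gen <- generative_config(
    n_subjects = 3, drugs = "placebo", seed = 6,
    group_scale = setNames(rep(0, 8), reliefrl:::PAR_NAMES))
  coh <- generate_cohort(gen, task_config(), spec = 4)
  tp <- attr(coh, "true_params")
  expect_equal(unname(apply(tp, 2, sd)), rep(0, 8))
  expect_equal(unname(tp[1, "beta"]), 0.5)
})
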