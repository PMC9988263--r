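mk_session <- function(subject = "S01", drug = "placebo", test_vas,
                       ctrl_vas, test_out = rep("win", length(test_vas)),
                       ctrl_out = rep("win", length(ctrl_vas))) {
  n_t <- length(test_vas); n_c <- length(ctrl_vas)
  data.frame(
    subject_id = subject, drug = drug, session_order = 1L,
    block = 1L, trial_index = seq_len(n_t + n_c),
    trial_type = c(rep("test", n_t), rep("control", n_c)),
    choice = c(rep("high", n_t), rep("none", n_c)),
    outcome = c(test_out, ctrl_out),
    rt_s = 0.8, vas_rating = c(test_vas, ctrl_vas),
    beh_delta_c = c(test_vas, ctrl_vas) / 100)
}

test_that("modulation subtracts the outcome-matched control mean per session", {
  ses <- mk_session(test_vas = 92, ctrl_vas = c(100, 100, 100))
  m <- compute_modulation(ses)
  expect_equal(m$vas_modulation, -8)
  expect_false(m$missing_controls)
  # values equal to the control mean give exactly zero modulation
  ses2 <- mk_session(test_vas = c(110, 110), ctrl_vas = c(100, 120))
  expect_equal(compute_modulation(ses2)$vas_modulation, c(0, 0))
  # win and lose trials each use their own control pool
  ses3 <- mk_session(test_vas = c(90, 130), ctrl_vas = c(100, 120),
                     test_out = c("win", "lose"),
                     ctrl_out = c("win", "lose"))
  expect_equal(compute_modulation(ses3)$vas_modulation, c(-10, 10))
  expect_error(compute_modulation(ses3[, -which(names(ses3) == "outcome")]),
               "missing columns")
})

test_that("unmatched outcomes are flagged missing, never zero-filled", {
  ses <- mk_session(test_vas = c(90, 130), ctrl_vas = 100,
                    test_out = c("win", "lose"), ctrl_out = "win")
  m <- compute_modulation(ses)
  expect_equal(m$missing_controls, c(FALSE, TRUE))
  expect_true(is.na(m$vas_modulation[2]))
})

test_that("modulation is invariant to session-constant rating offsets", {
  coh <- small_cohort(n_subjects = 3, seed = 29)
  m1 <- compute_modulation(coh)
  shifted <- coh
  key <- paste(shifted$subject_id, shifted$drug)
  offs <- setNames(seq_along(unique(key)) * 3, unique(key))
  shifted$vas_rating <- shifted$vas_rating + offs[key]
  shifted$beh_delta_c <- shifted$beh_delta_c + offs[key] / 10
  m2 <- compute_modulation(shifted)
  expect_equal(m2$vas_modulation, m1$vas_modulation, tolerance = 1e-10)
  expect_equal(m2$beh_modulation, m1$beh_modulation, tolerance = 1e-10)
})

test_that("noiseless records return the generating PE slope to numerical precision", {
  set.seed(6)
  recs <- do.call(rbind, lapply(1:4, function(s) {
    pe <- rnorm(40)
    data.frame(subject_id = sprintf("S%02d", s), drug = "placebo",
               vas_modulation = 2.45 - 0.36 * pe,
               beh_modulation = -0.03 - 0.06 * pe, pe = pe)
  }))
  tab_v <- suppressWarnings(
    suppressMessages(fit_pe_model(recs, "vas", include_drug = FALSE)))
  expect_equal(tab_v$estimate[tab_v$term == "pe"], -0.36, tolerance = 1e-8)
  tab_b <- suppressWarnings(
    suppressMessages(fit_pe_model(recs, "beh", include_drug = FALSE)))
  expect_equal(tab_b$estimate[tab_b$term == "pe"], -0.06, tolerance = 1e-8)
  expect_error(fit_pe_model(recs[recs$subject_id == "S01", ], "vas"),
               "two subjects")
})

test_that("permuting PE labels centers the recovered slope at zero", {
  coh <- small_cohort(n_subjects = 6, seed = 33)
  recs <- join_pe(compute_modulation(coh), attr(coh, "pe_truth"))
  slopes <- replicate(20, {
    perm <- recs
    perm$pe <- sample(perm$pe)
    tab <- suppressMessages(fit_pe_model(perm, "vas", include_drug = FALSE))
    tab$estimate[tab$term == "pe"]
  })
  tab0 <- suppressMessages(fit_pe_model(recs, "vas", include_drug = FALSE))
  se0 <- tab0$se[tab0$term == "pe"]
  expect_lt(abs(mean(slopes)), 2 * se0 / sqrt(20) + 0.05)
})

test_that("PE regression handles drug terms and reports Wald intervals", {
  coh <- generate_cohort(recovery_generative(
    n_subjects = 8, drugs = c("placebo", "levodopa"), seed = 37),
    task_config(), spec = 4)
  recs <- join_pe(compute_modulation(coh), attr(coh, "pe_truth"))
  tab <- suppressMessages(fit_pe_model(recs, "vas"))
  expect_true("pe" %in% tab$term)
  expect_true(any(grepl("drug", tab$term)))
  expect_true(all(tab$ci_lower < tab$ci_upper))
  expect_equal(tab$ci_upper - tab$estimate, 1.96 * tab$se, tolerance = 1e-10)
})

test_that("late-block preference summarizes per-subject learning against chance", {
  # saturated chooser
  allhigh <- mk_session(test_vas = rep(100, 8), ctrl_vas = rep(100, 8))
  allhigh$block <- rep(c(4L, 5L), each = 8)
  pref <- suppressWarnings(choice_preference(allhigh, blocks = c(4, 5)))
  expect_equal(pref$per_subject$prop_high, 1.0)
  # symmetric random choosers across many subjects
  set.seed(8)
  rnd <- do.call(rbind, lapply(1:40, function(s) {
    d <- mk_session(subject = sprintf("S%02d", s),
                    test_vas = rep(100, 10), ctrl_vas = 100)
    d$block <- 4L
    d$choice[d$trial_type == "test"] <- sample(c("high", "low"), 10, TRUE)
    d
  }))
  pref_rnd <- choice_preference(rnd, blocks = 4)
  expect_equal(pref_rnd$group$mean, 0.5, tolerance = 0.08)
  expect_gt(pref_rnd$group$p_chance, 0.05)
  # subjects with no eligible trials are excluded with a warning
  mixed <- rbind(rnd, {
    d <- mk_session(subject = "S99", test_vas = 100, ctrl_vas = 100)
    d$block <- 1L
    d
  })
  expect_warning(choice_preference(mixed, blocks = 4), "S99")
  expect_error(choice_preference(rnd, blocks = 99), "eligible")
})
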