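#' Task configuration for the relief-gambling session
#'
#' Defaults describe one session of the wheel-of-fortune relief gamble:
#' 5 blocks of 4 active test trials, 4 passive control trials and 1 neutral
#' trial (45 trials, 20 of them test trials); one choice option carries a
#' 75% win (relief) contingency, the other 25%; wins lower the tonic heat
#' stimulus by 3 degrees C, losses raise it by 1 degree C.
#'
#' @param n_blocks,tests_per_block,controls_per_block,neutrals_per_block
#'   Trial counts per session.
#' @param p_win_high,p_win_low Win probability of the high- and
#'   low-contingency options (per-option contingencies; they need not sum
#'   to 1).
#' @param relief_delta,increase_delta Temperature change (degrees C) on win
#'   and loss outcomes.
#' @return A `task_config` list.
#' @export
task_config <- function(n_blocks = 5, tests_per_block = 4,
                        controls_per_block = 4, neutrals_per_block = 1,
                        p_win_high = 0.75, p_win_low = 0.25,
                        relief_delta = -3, increase_delta = 1) {
  if (n_blocks < 1 || tests_per_block < 1 || controls_per_block < 1 ||
      neutrals_per_block < 0)
    stop("trial counts must be positive")
  for (p in c(p_win_high, p_win_low))
    if (p < 0 || p > 1) stop("win probabilities must lie in [0, 1]")
  cfg <- list(n_blocks = n_blocks, tests_per_block = tests_per_block,
              controls_per_block = controls_per_block,
              neutrals_per_block = neutrals_per_block,
              p_win_high = p_win_high, p_win_low = p_win_low,
              relief_delta = relief_delta, increase_delta = increase_delta)
  class(cfg) <- "task_config"
  cfg
}

#' Generative configuration for the synthetic cohort
#'
#' Describes the population the synthetic-cohort generator draws from:
#' group-level locations and scales of the eight RL-DDM parameters on the
#' unconstrained scale, additive per-drug shifts (also unconstrained, zero
#' by default, matching the finding that no drug effect on the model
#' parameters was resolvable), and the linear coupling of trial-wise
#' prediction errors to the two pain-modulation outcomes.
#'
#' Pain generation follows `modulation = slope * PE + drug offset +
#' Gaussian noise` (negative = inhibition). Default slopes are -0.36 (VAS
#' units per PE unit) and -0.06 (degrees C per PE unit); default noise SDs
#' follow the printed dispersion of the modulation measures (21.51 VAS
#' units, 0.64 degrees C).
#'
#' The default population is calibrated so the emergent behavior matches
#' the study's group-level learning signature: a late-block preference for
#' the high-contingency option around 64% with substantial between-subject
#' spread (some subjects near chance, some near-deterministic), and median
#' test-trial RTs below one second.
#'
#' @param n_subjects Number of subjects (default 28).
#' @param drugs Character vector of condition labels; the first is the
#'   reference condition.
#' @param group_loc,group_scale Named numeric vectors (length 8, canonical
#'   parameter order) of unconstrained group locations and scales.
#' @param drug_shifts Matrix (`length(drugs)` x 8, rows named by drug) of
#'   additive unconstrained shifts; the reference row is ignored and the
#'   default is all zero.
#' @param tau_ref Reference scale (seconds) for the generator's
#'   non-decision-time transform.
#' @param beta_pe_vas,beta_pe_beh PE slopes of the VAS and behavioral
#'   modulation.
#' @param noise_sd_vas,noise_sd_beh Gaussian noise SDs of the two outcomes
#'   (>= 0).
#' @param vas_offsets,beh_offsets Named per-drug offsets of the modulation.
#' @param miss_rate Probability that a test trial has no button press
#'   (dropped at analysis; default 0).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration and this seed.
#' @return A `generative_config` list.
#' @export
generative_config <- function(
    n_subjects = 28,
    drugs = c("placebo", "levodopa", "naltrexone"),
    group_loc = c(eta_pos = -0.8, eta_neg = -0.9, rho = 0.1, alpha = 0.2,
                  tau = 0, beta = 0, nu = 0, nu_max = 0.5),
    group_scale = c(eta_pos = 1, eta_neg = 0.4, rho = 0.1, alpha = 0.1,
                    tau = 0.5, beta = 0.2, nu = 0.5, nu_max = 0.2),
    drug_shifts = NULL,
    tau_ref = 0.6,
    beta_pe_vas = -0.36, beta_pe_beh = -0.06,
    noise_sd_vas = 21.51, noise_sd_beh = 0.64,
    vas_offsets = NULL, beh_offsets = NULL,
    miss_rate = 0, seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  if (anyDuplicated(drugs)) stop("drug labels must be unique")
  if (noise_sd_vas < 0 || noise_sd_beh < 0) stop("noise SDs must be >= 0")
  group_loc <- group_loc[PAR_NAMES]
  group_scale <- group_scale[PAR_NAMES]
  if (any(is.na(group_loc)) || any(is.na(group_scale)))
    stop("group_loc and group_scale must name all eight parameters")
  if (is.null(drug_shifts)) {
    drug_shifts <- matrix(0, length(drugs), 8,
                          dimnames = list(drugs, PAR_NAMES))
  }
  if (is.null(vas_offsets))
    vas_offsets <- setNames(rep(2.45, length(drugs)), drugs)
  if (is.null(beh_offsets))
    beh_offsets <- setNames(rep(-0.03, length(drugs)), drugs)
  cfg <- list(n_subjects = n_subjects, drugs = drugs, group_loc = group_loc,
              group_scale = group_scale, drug_shifts = drug_shifts,
              tau_ref = tau_ref, beta_pe_vas = beta_pe_vas,
              beta_pe_beh = beta_pe_beh, noise_sd_vas = noise_sd_vas,
              noise_sd_beh = noise_sd_beh, vas_offsets = vas_offsets,
              beh_offsets = beh_offsets, miss_rate = miss_rate,
              seed = as.integer(seed))
  class(cfg) <- "generative_config"
  cfg
}

#' Generate a pseudorandomized session schedule
#'
#' Builds the ordered trial skeleton of one session: within each block the
#' test and control trials are interleaved by a seeded shuffle and the
#' neutral trial(s) close the block. Outcomes are not part of the skeleton;
#' test-trial outcomes are realized by the agent and control outcomes are
#' matched to them afterwards.
#'
#' @param config A [task_config()].
#' @param seed Integer seed for the within-block shuffle.
#' @return Data.frame with `block`, `trial_index`, `trial_type`; the task
#'   config is attached as attribute `task`.
#' @export
generate_schedule <- function(config = task_config(), seed = 1L) {
  if (!inherits(config, "task_config")) stop("config must be a task_config")
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(config$n_blocks), function(b) {
    inter <- sample(c(rep("test", config$tests_per_block),
                      rep("control", config$controls_per_block)))
    data.frame(block = b,
               trial_type = c(inter, rep("neutral",
                                         config$neutrals_per_block)))
  }))
  rows$trial_index <- seq_len(nrow(rows))
  rows <- rows[, c("block", "trial_index", "trial_type")]
  attr(rows, "task") <- config
  rows
}

check_native_params <- function(p) {
  p <- p[PAR_NAMES]
  if (any(is.na(p))) stop("params must name all eight parameters")
  if (p[["eta_pos"]] <= 0 || p[["eta_pos"]] >= 1 ||
      p[["eta_neg"]] <= 0 || p[["eta_neg"]] >= 1)
    stop("learning rates must lie in (0, 1)")
  if (p[["beta"]] <= 0 || p[["beta"]] >= 1)
    stop("beta must lie in (0, 1)")
  if (any(p[c("rho", "alpha", "nu_max")] <= 0))
    stop("rho, alpha, nu_max must be positive")
  if (p[["nu"]] < 0) stop("nu must be non-negative")
  if (p[["tau"]] < 0) stop("tau must be non-negative")
  p
}

#' Simulate an RL-DDM agent playing a session
#'
#' Plays the test trials of a schedule with a drift-diffusion choice rule
#' over learned Q values: at each test trial the decision-time Q difference
#' is mapped to a drift rate (linear or sigmoid per the model spec), a
#' diffusion path yields the choice (upper boundary = high-contingency
#' option) and reaction time, the probabilistic contingency realizes the
#' outcome, and the Q values are updated with dual learning rates.
#'
#' @param params Named native-scale parameter vector (all eight canonical
#'   names; `rho`/`nu_max` are ignored by variants that do not use them).
#' @param schedule Schedule from [generate_schedule()] (or an integer
#'   number of test trials).
#' @param spec A [model_spec()] or id.
#' @param seed Integer seed; fixed seed gives bit-identical replay.
#' @param dt Simulation step (seconds).
#' @return Data.frame, one row per test trial: `trial` (test-trial counter),
#'   `trial_index` (position in the schedule, if one was given), `choice`,
#'   `outcome`, `rt`, decision-time `q_high`, `q_low`, and `delta`.
#' @export
simulate_agent <- function(params, schedule, spec, seed, dt = 1e-3) {
  spec <- model_spec(spec)
  p <- check_native_params(params)
  if (is.data.frame(schedule)) {
    task <- attr(schedule, "task") %||% task_config()
    idx <- schedule$trial_index[schedule$trial_type == "test"]
    n <- length(idx)
  } else {
    task <- task_config()
    n <- as.integer(schedule)
    idx <- seq_len(n)
  }
  res <- .rlddm_sim_agent_cpp(n, task$p_win_high, task$p_win_low,
                              as.numeric(p), spec_scaled(spec),
                              spec_sigmoid(spec), dt, as.integer(seed))
  data.frame(trial = seq_len(n), trial_index = idx,
             choice = ifelse(res$choice == 1L, "high", "low"),
             outcome = ifelse(res$outcome == 1L, "win", "lose"),
             rt = res$rt, q_high = res$q_high, q_low = res$q_low,
             delta = res$delta)
}

#' Synthesize PE-linked pain-modulation values
#'
#' Generates per-test-trial endogenous pain-modulation values (VAS units
#' and degrees C) as an affine function of the trial prediction error plus
#' Gaussian noise: `modulation = slope * PE + drug offset + noise`.
#' Negative values indicate pain inhibition.
#'
#' @param pe_series Data.frame with a `delta` column (one PE per completed
#'   test trial), e.g. from [run_rl()] or [simulate_agent()].
#' @param gen A [generative_config()].
#' @param seed Integer seed.
#' @param drug Condition label selecting the offsets (default: first
#'   configured drug).
#' @return Data.frame with `vas_modulation` and `beh_modulation`, one row
#'   per test trial.
#' @export
simulate_pain <- function(pe_series, gen = generative_config(), seed = 1L,
                          drug = gen$drugs[1]) {
  if (!"delta" %in% names(pe_series)) stop("pe_series must carry a delta column")
  n <- nrow(pe_series)
  set.seed(seed)
  data.frame(
    vas_modulation = gen$vas_offsets[[drug]] +
      gen$beta_pe_vas * pe_series$delta + rnorm(n, 0, gen$noise_sd_vas),
    beh_modulation = gen$beh_offsets[[drug]] +
      gen$beta_pe_beh * pe_series$delta + rnorm(n, 0, gen$noise_sd_beh)
  )
}

# typical rating response to the phasic temperature change, VAS units /
# degrees C of within-trial sensitization, used to embed modulation values
# into absolute trial measurements
VAS_OUTCOME_EFFECT <- c(win = -40, lose = 25, neutral = 0)
BEH_OUTCOME_EFFECT <- c(win = 0.2, lose = 0.4, neutral = 0.3)

#' Generate a full synthetic cohort
#'
#' Draws per-subject parameters from the configured population, simulates
#' every subject-session with the RL-DDM agent, matches control-trial
#' outcomes to the realized test outcomes of the same session (shuffled
#' copy), and embeds PE-linked pain modulation into absolute VAS ratings
#' and behavioral temperature adjustments. Ratings are built around a
#' subject-session baseline near the calibrated tonic target (VAS 150) plus
#' an outcome response, so that test-minus-control-mean differencing
#' ([compute_modulation()]) recovers the generated modulation.
#'
#' @param gen A [generative_config()].
#' @param task A [task_config()].
#' @param spec Generating model variant (default 4: scaled sensitivity,
#'   sigmoid drift mapping).
#' @return Trial table in the canonical schema (`subject_id`, `drug`,
#'   `session_order`, `block`, `trial_index`, `trial_type`, `choice`,
#'   `outcome`, `rt_s`, `vas_rating`, `beh_delta_c`), with the generating
#'   subject-session parameters attached as attribute `true_params` and the
#'   per-trial PE series as attribute `pe_truth`.
#' @export
generate_cohort <- function(gen = generative_config(), task = task_config(),
                            spec = 4) {
  spec <- model_spec(spec)
  set.seed(gen$seed)
  n_drugs <- length(gen$drugs)
  subj_ids <- sprintf("S%02d", seq_len(gen$n_subjects))
  # subject-level unconstrained deviates (shared across drug sessions)
  z <- matrix(rnorm(gen$n_subjects * 8), gen$n_subjects, 8,
              dimnames = list(subj_ids, PAR_NAMES))
  orders <- matrix(0L, gen$n_subjects, n_drugs)
  for (i in seq_len(gen$n_subjects))
    orders[i, ] <- if (n_drugs == 1) 1L else sample(seq_len(n_drugs))
  rows <- list()
  true_params <- list()
  pe_truth <- list()
  for (i in seq_len(gen$n_subjects)) {
    baseline_vas <- rnorm(1, 150, 8)
    for (g in seq_len(n_drugs)) {
      drug <- gen$drugs[g]
      u <- gen$group_loc + gen$group_scale * z[i, ] + gen$drug_shifts[drug, ]
      p <- to_native(setNames(u, PAR_NAMES), tau_ref = gen$tau_ref)
      sched <- generate_schedule(task, seed = sample.int(2^31 - 2, 1))
      agent <- simulate_agent(p, sched, spec, seed = sample.int(2^31 - 2, 1))
      # optional missed responses
      miss <- runif(nrow(agent)) < gen$miss_rate
      pain <- simulate_pain(agent, gen, seed = sample.int(2^31 - 2, 1),
                            drug = drug)
      # control outcomes: shuffled copy of realized (completed) test outcomes
      ctrl_pool <- sample(agent$outcome[!miss])
      n_ctrl <- sum(sched$trial_type == "control")
      ctrl_out <- rep(ctrl_pool, length.out = n_ctrl)
      if (length(ctrl_pool) == 0) ctrl_out <- rep("neutral", n_ctrl)

      df <- sched
      df$subject_id <- subj_ids[i]
      df$drug <- drug
      df$session_order <- orders[i, g]
      df$choice <- "none"
      df$outcome <- "neutral"
      df$rt_s <- NA_real_
      df$vas_rating <- NA_real_
      df$beh_delta_c <- NA_real_

      is_test <- df$trial_type == "test"
      is_ctrl <- df$trial_type == "control"
      is_neut <- df$trial_type == "neutral"

      df$choice[is_test] <- ifelse(miss, "none", agent$choice)
      df$outcome[is_test] <- ifelse(miss, "neutral", agent$outcome)
      df$rt_s[is_test] <- ifelse(miss, NA_real_, agent$rt)
      df$outcome[is_ctrl] <- ctrl_out
      # button-press latency in passive trials (no decision process)
      df$rt_s[!is_test] <- round(exp(rnorm(sum(!is_test), log(0.5), 0.25)), 4)

      eff_v <- VAS_OUTCOME_EFFECT[df$outcome]
      eff_b <- BEH_OUTCOME_EFFECT[df$outcome]
      noise_v <- rnorm(nrow(df), 0, gen$noise_sd_vas)
      noise_b <- rnorm(nrow(df), 0, gen$noise_sd_beh)
      df$vas_rating <- baseline_vas + eff_v + noise_v
      df$beh_delta_c <- eff_b + noise_b
      # test trials carry the PE-linked modulation on top of the control level
      df$vas_rating[is_test] <- baseline_vas + eff_v[is_test] +
        pain$vas_modulation
      df$beh_delta_c[is_test] <- eff_b[is_test] + pain$beh_modulation
      df$vas_rating <- pmin(pmax(df$vas_rating, 0), 200)
      df$vas_rating[is_test][miss] <- baseline_vas
      df$beh_delta_c[is_test][miss] <- 0.3

      key <- paste(subj_ids[i], drug, sep = ".")
      true_params[[key]] <- p
      pe <- agent
      pe$subject_id <- subj_ids[i]
      pe$drug <- drug
      pe_truth[[key]] <- pe[!miss, ]
      rows[[key]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("subject_id", "drug", "session_order", "block",
                 "trial_index", "trial_type", "choice", "outcome", "rt_s",
                 "vas_rating", "beh_delta_c")]
  out$vas_rating <- round(out$vas_rating, 2)
  out$beh_delta_c <- round(out$beh_delta_c, 3)
  out$rt_s <- round(out$rt_s, 4)
  attr(out, "true_params") <- do.call(rbind, true_params)
  pe_all <- do.call(rbind, pe_truth)
  rownames(pe_all) <- NULL
  attr(out, "pe_truth") <- pe_all
  attr(out, "task") <- task
  out
}
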