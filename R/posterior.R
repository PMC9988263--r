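# Posterior summaries: HDIs, drug contrasts, posterior predictive checks
# of choice proportions, and trial-wise prediction-error extraction.

#' Highest density interval
#'
#' Narrowest contiguous interval containing the requested posterior mass,
#' computed by the sorted-window method (smallest window over the order
#' statistics).
#'
#' @param samples Numeric vector of draws (at least 2).
#' @param mass Interval mass (default 0.95).
#' @return Named vector `c(lower, upper)` with attribute `mass`.
#' @examples
#' hdi(rnorm(10000))
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2) stop("need at least two samples")
  if (mass <= 0 || mass > 1) stop("mass must lie in (0, 1]")
  sorted <- sort(samples)
  m <- max(1, ceiling(mass * n))
  if (m >= n) {
    out <- c(lower = sorted[1], upper = sorted[n])
  } else {
    starts <- seq_len(n - m)
    widths <- sorted[starts + m] - sorted[starts]
    i <- which.min(widths)
    out <- c(lower = sorted[i], upper = sorted[i + m])
  }
  attr(out, "mass") <- mass
  out
}

#' Group-level drug contrast with HDI
#'
#' Draw-wise difference of the group-level drug effect of one parameter
#' between two conditions (the reference condition has effect zero),
#' summarized by its 95% highest density interval and a flag for whether
#' the interval encloses zero.
#'
#' @param fit An `rlddm_fit`.
#' @param parameter One of the active parameter names (e.g. `"eta_pos"`).
#' @param drug_a,drug_b Condition labels to contrast (`a - b`).
#' @param mass HDI mass (default 0.95).
#' @return List with `hdi`, `mean`, `encloses_zero`, and the draw vector.
#' @export
contrast_drug <- function(fit, parameter, drug_a, drug_b, mass = 0.95) {
  if (!parameter %in% fit$active)
    stop("unknown or inactive parameter: ", parameter)
  for (dr in c(drug_a, drug_b))
    if (!dr %in% fit$drugs) stop("condition not in fit: ", dr)
  p <- match(parameter, PAR_NAMES)
  nd <- nrow(fit$draws$mu)
  eff <- function(dr) {
    gi <- match(dr, fit$drugs)
    if (gi == 1) rep(0, nd) else fit$draws$d[, gi - 1, p]
  }
  dvec <- eff(drug_a) - eff(drug_b)
  h <- hdi(dvec, mass)
  list(parameter = parameter, drug_a = drug_a, drug_b = drug_b,
       mean = mean(dvec), hdi = h,
       encloses_zero = unname(h["lower"] <= 0 && 0 <= h["upper"]),
       draws = dvec)
}

#' Posterior predictive check of the late-learning choice proportion
#'
#' Simulates replicated datasets from posterior parameter draws (every
#' subject-session replayed by the RL-DDM agent on a fresh schedule) and
#' computes, per replicate, the proportion of choices of the
#' high-contingency option in the last two blocks. Returns the replicate
#' distribution, its mean and HDI, and posterior predictive p-values for
#' the observed statistic (one-sided fraction of replicates at or above
#' the observed value, and the two-sided `2 * min(p, 1 - p)`).
#'
#' @param fit An `rlddm_fit`.
#' @param task [task_config()] matching the fitted sessions.
#' @param n_rep Number of replicated datasets (default 500).
#' @param seed Integer seed.
#' @param drug Optional condition label to restrict the statistic to.
#' @return List with `statistic` (replicate vector), `mean`, `hdi`,
#'   `observed`, `p_one_sided`, `p_two_sided`.
#' @export
posterior_predict_choice <- function(fit, task = task_config(), n_rep = 500,
                                     seed = 1L, drug = NULL) {
  set.seed(seed)
  sess <- fit$sessions
  keep <- if (is.null(drug)) seq_len(nrow(sess)) else which(sess$drug == drug)
  if (!length(keep)) stop("no sessions for condition ", drug)
  nd <- dim(fit$draws$sess_native)[1]
  late_blocks <- task$n_blocks - 1:0
  draw_ids <- sample.int(nd, n_rep, replace = n_rep > nd)
  stat <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    j <- draw_ids[r]
    n_high <- 0L; n_tot <- 0L
    for (k in keep) {
      p <- setNames(fit$draws$sess_native[j, k, ], PAR_NAMES)
      sched <- generate_schedule(task, seed = sample.int(2^31 - 2, 1))
      ag <- simulate_agent(p, sched, fit$spec,
                           seed = sample.int(2^31 - 2, 1))
      blk <- sched$block[match(ag$trial_index, sched$trial_index)]
      late <- blk %in% late_blocks
      n_high <- n_high + sum(ag$choice[late] == "high")
      n_tot <- n_tot + sum(late)
    }
    stat[r] <- n_high / n_tot
  }
  tr <- fit$trials[fit$trials$subject_id %in% sess$subject_id[keep] &
                     paste(fit$trials$subject_id, fit$trials$drug) %in%
                     paste(sess$subject_id[keep], sess$drug[keep]), ]
  obs_late <- tr$block %in% late_blocks
  observed <- if (any(obs_late))
    mean(tr$choice[obs_late] == "high") else NA_real_
  p1 <- mean(stat >= observed)
  list(statistic = stat, mean = mean(stat), hdi = hdi(stat),
       observed = observed, p_one_sided = p1,
       p_two_sided = 2 * min(p1, 1 - p1))
}

#' Extract trial-wise prediction errors from a fitted model
#'
#' Plugs the posterior-mean subject-session parameters into the Q-learning
#' recursion over each session's realized choices and outcomes, returning
#' the decision-time expected values and the trial prediction errors used
#' by the pain-modulation analysis.
#'
#' @param fit An `rlddm_fit` (the winning model).
#' @param data Optional canonical trial table; defaults to the fitted
#'   trials. Every subject-session in `data` must be present in the fit.
#' @return Data.frame of class `pe_series`: `subject_id`, `drug`,
#'   `trial_index`, `block`, `choice`, `outcome`, `q_high`, `q_low`,
#'   `delta`.
#' @export
extract_pe <- function(fit, data = NULL) {
  tr <- if (is.null(data)) fit$trials else prepare_data(data, fit$drugs)$trials
  sp <- subject_params(fit)
  out <- list()
  for (kk in unique(paste(tr$subject_id, tr$drug))) {
    i <- which(paste(tr$subject_id, tr$drug) == kk)
    srow <- sp[paste(sp$subject_id, sp$drug) == kk, ]
    if (nrow(srow) != 1)
      stop("subject-session absent from fit: ", kk)
    pars <- setNames(as.numeric(srow[1, PAR_NAMES]), PAR_NAMES)
    ser <- run_rl(tr$choice[i], tr$outcome[i],
                  as.list(pars), spec = fit$spec)
    out[[kk]] <- data.frame(
      subject_id = tr$subject_id[i], drug = tr$drug[i],
      trial_index = tr$trial_index[i], block = tr$block[i],
      choice = ser$choice, outcome = tr$outcome[i],
      q_high = ser$q_high, q_low = ser$q_low, delta = ser$delta)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("pe_series", "data.frame")
  out
}
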