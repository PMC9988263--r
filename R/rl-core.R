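#' Model variants of the RL-DDM family
#'
#' The four model variants combine two parameterizations of outcome
#' sensitivity with two mappings from the expected-value difference to the
#' drift rate:
#'
#' | id | outcome sensitivity | drift mapping |
#' |----|---------------------|---------------|
#' | 1  | static              | linear        |
#' | 2  | scaled              | linear        |
#' | 3  | static              | sigmoid       |
#' | 4  | scaled              | sigmoid       |
#'
#' "Static" fixes the signed outcome at +1 (relief win) / -1 (pain increase
#' loss); "scaled" multiplies it by an individual sensitivity `rho`.
#' The sigmoid mapping bounds the trial drift rate at `+/- nu_max`.
#'
#' @param id Integer model id in 1:4, or a `model_spec` (returned unchanged).
#' @return A `model_spec` object: list with `id`, `outcome_sensitivity`
#'   (`"static"` or `"scaled"`) and `drift_mapping` (`"linear"` or
#'   `"sigmoid"`).
#' @examples
#' model_spec(4)
#' @export
model_spec <- function(id) {
  if (inherits(id, "model_spec")) return(id)
  if (!is.numeric(id) || length(id) != 1 || !id %in% 1:4)
    stop("model id must be one of 1, 2, 3, 4")
  id <- as.integer(id)
  spec <- list(
    id = id,
    outcome_sensitivity = if (id %in% c(2L, 4L)) "scaled" else "static",
    drift_mapping = if (id %in% c(3L, 4L)) "sigmoid" else "linear"
  )
  class(spec) <- "model_spec"
  spec
}

#' @exportS3Method base::print
print.model_spec <- function(x, ...) {
  cat(sprintf("RL-DDM model %d: %s outcome sensitivity, %s drift mapping\n",
              x$id, x$outcome_sensitivity, x$drift_mapping))
  invisible(x)
}

spec_scaled <- function(spec) as.integer(spec$outcome_sensitivity == "scaled")
spec_sigmoid <- function(spec) as.integer(spec$drift_mapping == "sigmoid")

#' Single Q-value update with dual learning rates
#'
#' Updates the expected value of the chosen option from the signed trial
#' outcome. The prediction error is `delta = rho * R - Q_chosen`; the update
#' uses `eta_pos` when `delta > 0` and `eta_neg` when `delta <= 0` (ties take
#' the negative learning rate). Only the chosen option's Q changes.
#'
#' @param state Numeric vector `c(q_high, q_low)` of current expected values.
#' @param choice `"high"` or `"low"`: which option was chosen.
#' @param reward Signed unit outcome: `+1` (win / relief) or `-1`
#'   (loss / pain increase).
#' @param eta_pos,eta_neg Learning rates in (0, 1) for positive and
#'   non-positive prediction errors.
#' @param rho Outcome sensitivity (> 0); use 1 for the static variants.
#' @return List with `state` (updated `c(q_high, q_low)`) and `delta`
#'   (the prediction error).
#' @examples
#' update_q(c(0, 0), "high", +1, eta_pos = 0.5, eta_neg = 0.3)
#' @export
update_q <- function(state, choice, reward, eta_pos, eta_neg, rho = 1) {
  stopifnot(length(state) == 2, reward %in% c(-1, 1))
  if (eta_pos <= 0 || eta_pos >= 1 || eta_neg <= 0 || eta_neg >= 1)
    stop("learning rates must lie strictly in (0, 1)")
  if (rho <= 0) stop("rho must be positive")
  choice <- match.arg(choice, c("high", "low"))
  i <- if (choice == "high") 1L else 2L
  delta <- rho * reward - state[i]
  eta <- if (delta > 0) eta_pos else eta_neg
  state[i] <- state[i] + eta * delta
  list(state = state, delta = delta)
}

#' Run a Q-learning sequence over realized choices and outcomes
#'
#' Replays dual-learning-rate Q updating over a realized sequence of test
#' trials, returning for every trial the expected values *at decision time*
#' (before that trial's update), the chosen option, the signed outcome, and
#' the prediction error. Q values start at zero; the unchosen option's value
#' is carried forward unchanged.
#'
#' @param choices Character (`"high"`/`"low"`) or integer (1/0) vector of
#'   choices per test trial.
#' @param outcomes Numeric vector of signed unit outcomes (+1 win, -1 lose),
#'   or character `"win"`/`"lose"`.
#' @param params Named list or vector with `eta_pos`, `eta_neg` and, for
#'   scaled variants, `rho`.
#' @param spec A [model_spec()] (or id); only the outcome-sensitivity half of
#'   the spec matters here.
#' @return A data.frame of class `pe_series` with columns `trial`, `choice`,
#'   `outcome`, `q_high`, `q_low` (decision-time values), `delta`.
#' @examples
#' run_rl(c("high", "high", "low"), c(1, -1, 1),
#'        list(eta_pos = 0.4, eta_neg = 0.3, rho = 1.2), spec = 4)
#' @export
run_rl <- function(choices, outcomes, params, spec = 1) {
  spec <- model_spec(spec)
  if (length(choices) != length(outcomes))
    stop("choices and outcomes must have equal length")
  if (is.character(choices)) choices <- as.integer(choices == "high")
  if (is.character(outcomes)) outcomes <- ifelse(outcomes == "win", 1, -1)
  n <- length(choices)
  params <- as.list(params)
  rho <- if (spec$outcome_sensitivity == "scaled") params$rho else 1
  out <- data.frame(trial = integer(0), choice = character(0),
                    outcome = numeric(0), q_high = numeric(0),
                    q_low = numeric(0), delta = numeric(0))
  if (n > 0) {
    q <- c(0, 0)
    qh <- ql <- dl <- numeric(n)
    for (t in seq_len(n)) {
      qh[t] <- q[1]; ql[t] <- q[2]
      up <- update_q(q, if (choices[t] == 1L) "high" else "low", outcomes[t],
                     params$eta_pos, params$eta_neg, rho)
      q <- up$state
      dl[t] <- up$delta
    }
    out <- data.frame(trial = seq_len(n),
                      choice = ifelse(choices == 1L, "high", "low"),
                      outcome = outcomes, q_high = qh, q_low = ql, delta = dl)
  }
  attr(out, "final_q") <- if (n > 0) q else c(0, 0)
  class(out) <- c("pe_series", "data.frame")
  out
}
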