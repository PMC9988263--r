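# Trial-wise endogenous pain modulation and its link to prediction errors.

#' Compute trial-wise endogenous pain modulation
#'
#' For every completed test trial, subtracts the mean of the same
#' subject-session's control trials with the matching outcome (win
#' controls for winning test trials, lose controls for losing ones) from
#' the test-trial value, separately for the VAS rating and the behavioral
#' temperature measure. Negative values indicate pain inhibition. Control
#' means pool all blocks of the session. Test trials without a matching
#' control outcome are flagged missing, never zero-filled.
#'
#' @param trials Canonical trial table.
#' @return Data.frame of `ModulationRecord`s: `subject_id`, `drug`,
#'   `session_order`, `block`, `trial_index`, `outcome`,
#'   `vas_modulation`, `beh_modulation`, `missing_controls`.
#' @examples
#' coh <- generate_cohort(generative_config(n_subjects = 2, seed = 1))
#' head(compute_modulation(coh))
#' @export
compute_modulation <- function(trials) {
  need <- c("subject_id", "drug", "trial_type", "outcome", "vas_rating",
            "beh_delta_c")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"session_order" %in% names(trials)) trials$session_order <- NA_integer_
  if (!"block" %in% names(trials)) trials$block <- NA_integer_
  if (!"trial_index" %in% names(trials))
    trials$trial_index <- seq_len(nrow(trials))
  is_test <- trials$trial_type == "test" & trials$outcome %in% c("win", "lose")
  is_ctrl <- trials$trial_type == "control" &
    trials$outcome %in% c("win", "lose")
  key <- paste(trials$subject_id, trials$drug, trials$outcome)
  ctrl_vas <- tapply(trials$vas_rating[is_ctrl], key[is_ctrl], mean)
  ctrl_beh <- tapply(trials$beh_delta_c[is_ctrl], key[is_ctrl], mean)
  tt <- trials[is_test, ]
  tkey <- paste(tt$subject_id, tt$drug, tt$outcome)
  out <- data.frame(
    subject_id = tt$subject_id, drug = tt$drug,
    session_order = tt$session_order, block = tt$block,
    trial_index = tt$trial_index, outcome = tt$outcome,
    vas_modulation = tt$vas_rating - as.numeric(ctrl_vas[tkey]),
    beh_modulation = tt$beh_delta_c - as.numeric(ctrl_beh[tkey]))
  out$missing_controls <- !(tkey %in% names(ctrl_vas))
  rownames(out) <- NULL
  out
}

#' Mixed-effects regression of pain modulation on prediction errors
#'
#' Fits `modulation ~ pe * drug + (1 | subject)` (or `modulation ~ pe +
#' (1 | subject)` without the drug terms) by REML via `lme4::lmer`, with
#' large-sample Wald intervals on the fixed effects. A negative PE slope
#' means unexpectedly good outcomes (relief) enhance pain inhibition.
#'
#' Because every test trial's modulation subtracts the *same* session
#' control mean for its outcome type, residuals of trials sharing a
#' subject-session-outcome cell are correlated by construction. By default
#' an additional random intercept for that cell absorbs this shared
#' differencing noise, which keeps the PE-slope standard error honest;
#' `cluster_controls = FALSE` drops the term and reduces the model to the
#' plain subject-random-intercept specification.
#'
#' @param records Modulation records joined with a `pe` column (e.g.
#'   [compute_modulation()] merged with [extract_pe()] on subject,
#'   condition and trial index).
#' @param response `"vas"` or `"beh"`: which modulation measure to model.
#' @param include_drug Include drug main effects and the PE x drug
#'   interaction (default `TRUE` when more than one condition is present).
#' @param include_order Add session order (1-3) as a fixed covariate.
#' @param cluster_controls Add a `(1 | subject:drug:outcome)` random
#'   intercept for the shared control-mean noise (default `TRUE` when an
#'   `outcome` column is present).
#' @return Data.frame with `term`, `estimate`, `se`, `ci_lower`,
#'   `ci_upper`; the fitted `lmerMod` is attached as attribute `model`.
#' @export
fit_pe_model <- function(records, response = c("vas", "beh"),
                         include_drug = NULL, include_order = FALSE,
                         cluster_controls = TRUE) {
  response <- match.arg(response)
  ycol <- paste0(response, "_modulation")
  need <- c(ycol, "pe", "subject_id", "drug")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  records <- records[is.finite(records[[ycol]]) & is.finite(records$pe), ]
  if (length(unique(records$subject_id)) < 2)
    stop("need at least two subjects for a mixed model")
  include_drug <- include_drug %||% (length(unique(records$drug)) > 1)
  records$drug <- factor(records$drug,
                         levels = if ("placebo" %in% records$drug)
                           c("placebo", setdiff(sort(unique(records$drug)),
                                                "placebo"))
                         else sort(unique(records$drug)))
  rhs <- if (include_drug) "pe * drug" else "pe"
  if (include_order && "session_order" %in% names(records))
    rhs <- paste(rhs, "+ session_order")
  ranef <- "(1 | subject_id)"
  if (cluster_controls && "outcome" %in% names(records)) {
    records$.cell <- interaction(records$subject_id, records$drug,
                                 records$outcome, drop = TRUE)
    ranef <- paste(ranef, "+ (1 | .cell)")
  }
  fml <- stats::as.formula(paste(ycol, "~", rhs, "+", ranef))
  fit <- tryCatch(
    lme4::lmer(fml, data = records, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) stop("mixed-model fit failed: ",
                             conditionMessage(e), call. = FALSE))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  out <- data.frame(term = names(est), estimate = as.numeric(est),
                    se = as.numeric(se),
                    ci_lower = as.numeric(est - 1.96 * se),
                    ci_upper = as.numeric(est + 1.96 * se))
  rownames(out) <- NULL
  attr(out, "model") <- fit
  out
}

#' Join modulation records with a prediction-error series
#'
#' @param records Output of [compute_modulation()].
#' @param pe_series Output of [extract_pe()] (or a generator `pe_truth`
#'   table with a `delta` column).
#' @return `records` with a `pe` column; rows without a matching PE are
#'   dropped.
#' @export
join_pe <- function(records, pe_series) {
  if (!"delta" %in% names(pe_series)) stop("pe_series must carry delta")
  k1 <- paste(records$subject_id, records$drug, records$trial_index)
  k2 <- paste(pe_series$subject_id, pe_series$drug, pe_series$trial_index)
  records$pe <- pe_series$delta[match(k1, k2)]
  records[!is.na(records$pe), ]
}

#' Late-learning preference for the high-contingency option
#'
#' Per-subject proportion of completed test-trial choices of the
#' high-contingency option within the stated blocks (default: the last two
#' of five), with a group summary per condition and a mixed-effects
#' logistic test of the intercept against chance (choice log-odds zero).
#'
#' @param trials Canonical trial table.
#' @param blocks Blocks entering the statistic (default `c(4, 5)`).
#' @return List with `per_subject` (subject x condition proportions),
#'   `group` (per condition: mean, SD, n, chance-test p-value), and the
#'   block window used. Subjects without eligible trials are excluded with
#'   a warning.
#' @export
choice_preference <- function(trials, blocks = c(4, 5)) {
  tt <- trials[trials$trial_type == "test" &
                 trials$choice %in% c("high", "low") &
                 trials$block %in% blocks, ]
  if (nrow(tt) == 0) stop("no eligible test trials in the stated blocks")
  all_subj <- unique(trials$subject_id[trials$trial_type == "test"])
  dropped <- setdiff(all_subj, unique(tt$subject_id))
  if (length(dropped))
    warning("excluded subjects with no eligible trials: ",
            paste(dropped, collapse = ", "))
  tt$high <- as.integer(tt$choice == "high")
  per <- aggregate(high ~ subject_id + drug, data = tt, FUN = mean)
  names(per)[names(per) == "high"] <- "prop_high"
  group <- do.call(rbind, lapply(split(tt, tt$drug), function(dd) {
    props <- tapply(dd$high, dd$subject_id, mean)
    p_chance <- tryCatch({
      m <- suppressMessages(
        lme4::glmer(high ~ 1 + (1 | subject_id), data = dd,
                    family = stats::binomial))
      z <- lme4::fixef(m)[1] / sqrt(diag(as.matrix(vcov(m))))[1]
      2 * pnorm(-abs(z))
    }, error = function(e)
      binom.test(sum(dd$high), nrow(dd))$p.value,
    warning = function(w)
      binom.test(sum(dd$high), nrow(dd))$p.value)
    data.frame(drug = dd$drug[1], mean = mean(props), sd = sd(props),
               n = length(props), p_chance = as.numeric(p_chance))
  }))
  rownames(group) <- NULL
  list(per_subject = per, group = group, blocks = blocks)
}
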