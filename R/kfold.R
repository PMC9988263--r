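# K-fold cross-validated predictive accuracy (ELPD) over subjects.
#
# Held-out subjects have no subject-level posterior, so their predictive
# density is computed by new-subject simulation: for every retained
# posterior draw, a fresh standardized deviate is drawn from the group
# distribution of that draw and the pointwise (choice, RT) log density of
# the held-out trials is evaluated; the pointwise log predictive density is
# the log of the Monte Carlo average across draws. A plug-in alternative
# (group means, no new-subject noise) is available for sensitivity
# analysis.

#' Split subjects into cross-validation folds
#'
#' Disjoint folds covering all subjects, sizes differing by at most one
#' (2-3 subjects per fold at 28 subjects and k = 10).
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the assignment shuffle.
#' @return List of length `k` of subject-id vectors.
#' @export
kfold_split <- function(subject_ids, k = 10, seed = 1L) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (k > n) stop("k must not exceed the number of subjects")
  if (k < 2) stop("k must be at least 2")
  set.seed(seed)
  shuffled <- sample(subject_ids)
  # sizes differ by <= 1: round-robin assignment over the shuffled order
  split(shuffled, rep(seq_len(k), length.out = n))
}

new_subject_pointwise <- function(fit, choice, outcome, rt, min_rt,
                                  drug, method = c("new_subject", "plugin"),
                                  seed = 1L) {
  method <- match.arg(method)
  nd <- nrow(fit$draws$mu)
  G <- length(fit$drugs)
  gi <- match(drug, fit$drugs)
  if (is.na(gi)) stop("unknown drug label for held-out session")
  scaled <- spec_scaled(fit$spec)
  sigmoid <- spec_sigmoid(fit$spec)
  set.seed(seed)
  U <- fit$draws$mu
  if (method == "new_subject") {
    U <- U + fit$draws$sigma * matrix(rnorm(nd * 8), nd, 8)
  }
  if (gi > 1) {
    j <- gi - 1
    U <- U + fit$draws$d[, j, ]
    if (method == "new_subject") {
      ew <- matrix(rnorm(nd * 8), nd, 8)
      if (!is.null(fit$draws$r) && j == 2) {
        r <- fit$draws$r
        ew <- r * matrix(rnorm(nd * 8), nd, 8) + sqrt(1 - r^2) * ew
      }
      U <- U + fit$draws$t[, j, ] * ew
    }
  }
  P <- matrix(0, nd, 8)
  P[, 1] <- plogis(U[, 1]); P[, 2] <- plogis(U[, 2])
  P[, 3] <- if (scaled) exp(U[, 3]) else 1
  P[, 4] <- exp(U[, 4])
  P[, 5] <- plogis(U[, 5]) * min_rt
  P[, 6] <- plogis(U[, 6])
  P[, 7] <- exp(U[, 7])
  P[, 8] <- if (sigmoid) exp(U[, 8]) else 1
  llmat <- .rlddm_pointwise_draws_cpp(as.integer(choice),
                                      as.integer(outcome), as.numeric(rt),
                                      P, scaled, sigmoid)
  apply(llmat, 2, log_mean_exp)
}

#' K-fold expected log pointwise predictive density of one model
#'
#' For each fold the model is re-fit on the training subjects and the log
#' pointwise predictive density of every held-out (choice, RT) pair is
#' accumulated; the total ELPD is the sum over all held-out trials.
#'
#' @param spec Model variant ([model_spec()] or id).
#' @param data Canonical trial table.
#' @param folds Fold list from [kfold_split()].
#' @param profile,chains,iter,warmup Fit settings passed to [fit_rlddm()].
#' @param method Held-out predictive construction: `"new_subject"`
#'   (default; held-out parameters drawn from the group distribution per
#'   posterior draw) or `"plugin"` (group means only).
#' @param seed Integer seed.
#' @param drugs Optional condition ordering.
#' @return An `elpd_result`: `elpd`, pointwise table (`subject_id`, `drug`,
#'   `trial_index`, `lppd`, `fold`), the folds, and the spec id.
#' @export
kfold_elpd <- function(spec, data, folds, profile = "desk", chains = NULL,
                       iter = NULL, warmup = NULL,
                       method = c("new_subject", "plugin"), seed = 1L,
                       drugs = NULL) {
  spec <- model_spec(spec)
  method <- match.arg(method)
  prep <- prepare_data(data, drugs = drugs)
  all_subj <- unique(prep$sessions$subject_id)
  cov <- sort(unique(unlist(folds)))
  if (!setequal(cov, all_subj) || anyDuplicated(unlist(folds)))
    stop("folds must partition the subject set")
  pw <- list()
  for (f in seq_along(folds)) {
    ho <- folds[[f]]
    train <- prep$trials[!prep$trials$subject_id %in% ho, ]
    if (nrow(train) == 0) stop("fold ", f, " leaves no training subjects")
    fit <- fit_rlddm(train, spec = spec, profile = profile, chains = chains,
                     iter = iter, warmup = warmup, seed = seed + f,
                     drugs = prep$drugs)
    ho_tr <- prep$trials[prep$trials$subject_id %in% ho, ]
    key <- paste(ho_tr$subject_id, ho_tr$drug)
    for (kk in unique(key)) {
      i <- which(key == kk)
      lppd <- new_subject_pointwise(
        fit,
        choice = as.integer(ho_tr$choice[i] == "high"),
        outcome = ifelse(ho_tr$outcome[i] == "win", 1L, -1L),
        rt = ho_tr$rt_s[i], min_rt = min(ho_tr$rt_s[i]),
        drug = ho_tr$drug[i][1], method = method, seed = seed + f)
      pw[[length(pw) + 1]] <- data.frame(
        subject_id = ho_tr$subject_id[i], drug = ho_tr$drug[i],
        trial_index = ho_tr$trial_index[i], lppd = lppd, fold = f)
    }
  }
  pw <- do.call(rbind, pw)
  pw <- pw[order(pw$subject_id, pw$drug, pw$trial_index), ]
  rownames(pw) <- NULL
  out <- list(spec_id = spec$id, elpd = sum(pw$lppd), pointwise = pw,
              folds = folds, method = method)
  class(out) <- "elpd_result"
  out
}

#' @exportS3Method base::print
print.elpd_result <- function(x, ...) {
  cat(sprintf("K-fold ELPD for model %d: %.2f (%d held-out trials, %d folds)\n",
              x$spec_id, x$elpd, nrow(x$pointwise), length(x$folds)))
  invisible(x)
}

#' Compare models by K-fold ELPD
#'
#' Ranks models by total ELPD and reports, for each, the difference to the
#' best model and the standard error of that difference (computed from the
#' pointwise difference vector). A difference is flagged decisive when its
#' absolute value is at least twice its standard error.
#'
#' @param results List of `elpd_result` objects scored on identical folds.
#' @return Data.frame ordered by ELPD with `model`, `elpd`, `elpd_diff`,
#'   `se_diff`, `decisive`.
#' @export
compare_elpd <- function(results) {
  if (length(results) < 2) stop("need at least two models to compare")
  keys <- lapply(results, function(r)
    paste(r$pointwise$subject_id, r$pointwise$drug, r$pointwise$trial_index))
  for (r in seq_along(results)) {
    if (!identical(keys[[r]], keys[[1]]))
      stop("models were not scored on identical folds/trials")
  }
  elpds <- vapply(results, `[[`, numeric(1), "elpd")
  best <- which.max(elpds)
  out <- data.frame(
    model = vapply(results, `[[`, numeric(1), "spec_id"),
    elpd = elpds,
    elpd_diff = NA_real_, se_diff = NA_real_, decisive = FALSE)
  for (r in seq_along(results)) {
    dvec <- results[[r]]$pointwise$lppd - results[[best]]$pointwise$lppd
    out$elpd_diff[r] <- sum(dvec)
    out$se_diff[r] <- if (r == best) 0 else sqrt(length(dvec) * var(dvec))
    out$decisive[r] <- r != best &&
      elpd_decisive(out$elpd_diff[r], out$se_diff[r])
  }
  out <- out[order(-out$elpd), ]
  rownames(out) <- NULL
  out
}

#' Decision rule on a single ELPD difference
#'
#' @param elpd_diff Difference in ELPD between two models.
#' @param se_diff Standard error of the difference.
#' @return `TRUE` when `|elpd_diff| >= 2 * se_diff` (a decisive difference).
#' @export
elpd_decisive <- function(elpd_diff, se_diff) {
  if (se_diff < 0) stop("se_diff must be non-negative")
  if (se_diff == 0) return(abs(elpd_diff) > 0)
  abs(elpd_diff) >= 2 * se_diff
}
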