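# Hierarchical Bayesian estimation of the RL-DDM family.
#
# Model (per parameter theta, on the unconstrained scale):
#   u[s, g] = mu + sigma * z[s]                          (reference condition)
#           + d[g] + t[g] * w[s, g]                      (non-reference drugs)
# with z[s] ~ N(0,1), w[s, ] = L e[s, ], e ~ N(0,1) iid, and L the Cholesky
# factor of the drug-effect correlation (LKJ(1) prior). This is the
# non-centered parameterization: group location/scale and standardized
# subject deviates are sampled separately.
#
# Posterior sampling uses blockwise adaptive Metropolis-within-Gibbs with
# per-coordinate random-walk proposals (Robbins-Monro scale adaptation
# toward 0.44 acceptance during warmup, frozen afterwards). Likelihood
# evaluations go through the compiled Wiener first-passage density.

active_par_names <- function(spec) {
  spec <- model_spec(spec)
  nm <- c("eta_pos", "eta_neg", "alpha", "tau", "beta", "nu")
  if (spec$outcome_sensitivity == "scaled") nm <- c(nm, "rho")
  if (spec$drift_mapping == "sigmoid") nm <- c(nm, "nu_max")
  PAR_NAMES[PAR_NAMES %in% nm]
}

#' Prepare a trial table for model fitting
#'
#' Keeps completed test trials (a recorded high/low choice and a positive
#' RT), orders them within subject-session, and derives per-session
#' minimum RTs (the reference scale of the non-decision-time transform).
#'
#' @param data Canonical trial table (see [read_trials()]).
#' @param drugs Optional character vector fixing the condition order; the
#'   first entry is the reference condition. Defaults to `"placebo"` first
#'   when present, otherwise the sorted observed labels.
#' @return List with `trials` (ordered test-trial data.frame), `sessions`
#'   (one row per subject-condition with `min_rt` and `n_trials`), and
#'   `drugs`.
#' @export
prepare_data <- function(data, drugs = NULL) {
  req <- c("subject_id", "drug", "trial_type", "choice", "outcome", "rt_s")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"block" %in% names(data)) data$block <- 1L
  if (!"trial_index" %in% names(data)) data$trial_index <- seq_len(nrow(data))
  tr <- data[data$trial_type == "test" & data$choice %in% c("high", "low") &
               !is.na(data$rt_s), ]
  if (nrow(tr) == 0) stop("no completed test trials in data")
  if (any(tr$rt_s <= 0)) stop("reaction times must be positive")
  if (is.null(drugs)) {
    lv <- sort(unique(tr$drug))
    drugs <- if ("placebo" %in% lv) c("placebo", setdiff(lv, "placebo")) else lv
  }
  if (!all(tr$drug %in% drugs)) stop("data contains unknown drug labels")
  tr <- tr[order(tr$subject_id, match(tr$drug, drugs), tr$trial_index), ]
  key <- paste(tr$subject_id, tr$drug)
  sess <- tr[!duplicated(key), c("subject_id", "drug")]
  sess$min_rt <- as.numeric(tapply(tr$rt_s, key, min)[unique(key)])
  sess$n_trials <- as.integer(table(key)[unique(key)])
  rownames(sess) <- NULL
  list(trials = tr, sessions = sess, drugs = drugs)
}

# prior hyperparameters as flat lookup vectors
.prior <- function() {
  cat_ <- prior_catalog()
  list(mu_loc = setNames(cat_$mu_loc, PAR_NAMES),
       mu_scale = setNames(cat_$mu_scale, PAR_NAMES),
       sigma_scale = setNames(cat_$sigma_scale, PAR_NAMES),
       d_scale = setNames(cat_$drug_loc_scale, PAR_NAMES),
       t_scale = setNames(rep(0.1, 8), PAR_NAMES))
}

#' Fit an RL-DDM variant hierarchically
#'
#' Samples the posterior of the hierarchical RL-DDM: subject-session
#' parameters are non-centered deviations from group-level locations, with
#' additive drug effects (reference coding: the first condition is the
#' reference and each other condition gets its own effect) whose
#' subject-level deviates share an LKJ(1)-prior correlation. Priors follow
#' the catalog in [prior_catalog()]. Sampling is blockwise adaptive
#' Metropolis-within-Gibbs (random-walk proposals on the unconstrained
#' scale, scale-adapted during warmup); split-R-hat is reported for every
#' group-level quantity, with a warning above 1.01 and failure above 1.1.
#'
#' @param data Canonical trial table, or the result of [prepare_data()].
#' @param spec Model variant ([model_spec()] or id 1-4).
#' @param profile `"desk"` (2 chains x 1500 iterations, 500 warmup;
#'   default) or `"paper"` (4 chains x 4000, 1000 warmup). Explicit
#'   `chains`/`iter`/`warmup` override the profile.
#' @param chains,iter,warmup MCMC geometry overrides.
#' @param seed Integer seed; fixed seed and data give identical draws.
#' @param drugs Optional condition ordering (first = reference).
#' @return An object of class `rlddm_fit` with posterior draws of the
#'   group-level quantities, per-session native-scale parameter draws,
#'   split-R-hat diagnostics, and the prepared data.
#' @export
fit_rlddm <- function(data, spec = 4, profile = c("desk", "paper"),
                      chains = NULL, iter = NULL, warmup = NULL, seed = 1L,
                      drugs = NULL) {
  spec <- model_spec(spec)
  profile <- match.arg(profile)
  geom <- if (profile == "paper") c(4L, 4000L, 1000L) else c(2L, 1500L, 500L)
  chains <- as.integer(chains %||% geom[1])
  iter <- as.integer(iter %||% geom[2])
  warmup <- as.integer(warmup %||% geom[3])
  if (iter <= warmup) stop("iter must exceed warmup")

  prep <- if (is.list(data) && all(c("trials", "sessions") %in% names(data)))
    data else prepare_data(data, drugs = drugs)
  tr <- prep$trials
  sess <- prep$sessions
  drugs <- prep$drugs
  G <- length(drugs)
  if (G - 1 > 2) stop("at most three conditions are supported")
  subs <- unique(sess$subject_id)
  S <- length(subs)
  sess$si <- match(sess$subject_id, subs)
  sess$gi <- match(sess$drug, drugs)
  ns <- nrow(sess)
  skey <- paste(tr$subject_id, tr$drug)
  sess_of_trial <- match(skey, paste(sess$subject_id, sess$drug))
  sess_data <- lapply(seq_len(ns), function(k) {
    i <- which(sess_of_trial == k)
    list(choice = as.integer(tr$choice[i] == "high"),
         outcome = as.integer(ifelse(tr$outcome[i] == "win", 1L, -1L)),
         rt = as.numeric(tr$rt_s[i]))
  })
  idx_by_subject <- split(seq_len(ns), sess$si)
  idx_by_drug <- split(seq_len(ns), sess$gi)

  act <- active_par_names(spec)
  pr <- .prior()
  scaled <- spec_scaled(spec)
  sigmoid <- spec_sigmoid(spec)

  sess_ll <- function(k, prow) {
    sum(.rlddm_pointwise_cpp(sess_data[[k]]$choice, sess_data[[k]]$outcome,
                             sess_data[[k]]$rt, prow, scaled, sigmoid))
  }

  # native parameter row for session k given unconstrained values u (vec 8)
  nat_row <- function(u, k) {
    p <- numeric(8)
    p[1] <- plogis(u[1]); p[2] <- plogis(u[2])
    p[3] <- if (scaled) exp(u[3]) else 1
    p[4] <- exp(u[4])
    p[5] <- plogis(u[5]) * sess$min_rt[k]
    p[6] <- plogis(u[6])
    p[7] <- exp(u[7])
    p[8] <- if (sigmoid) exp(u[8]) else 1
    p
  }

  run_chain <- function(chain) {
    set.seed(seed * 1000L + chain)
    # ---- state ----
    mu <- pr$mu_loc + rnorm(8, 0, 0.1 * pmax(pr$mu_scale, 0.2))
    lsig <- log(pmax(pr$sigma_scale * 0.4, 0.02)) + rnorm(8, 0, 0.1)
    z <- matrix(rnorm(S * 8, 0, 0.1), S, 8)
    d <- matrix(0, max(G - 1, 1), 8)
    lt <- matrix(log(0.05), max(G - 1, 1), 8)
    e <- array(rnorm(S * max(G - 1, 1) * 8, 0, 0.1), c(S, max(G - 1, 1), 8))
    y <- rep(0, 8)  # atanh of the drug-effect correlation (G - 1 == 2 only)

    u_row <- function(k) {
      s <- sess$si[k]; g <- sess$gi[k]
      u <- mu + exp(lsig) * z[s, ]
      if (g > 1) {
        j <- g - 1
        w <- if (G - 1 == 2 && j == 2)
          tanh(y) * e[s, 1, ] + sqrt(1 - tanh(y)^2) * e[s, 2, ]
        else e[s, j, ]
        u <- u + d[j, ] + exp(lt[j, ]) * w
      }
      u
    }
    refresh <- function(K) {
      for (k in K) {
        U[k, ] <<- u_row(k)
        P[k, ] <<- nat_row(U[k, ], k)
        ll[k] <<- sess_ll(k, P[k, ])
      }
    }
    U <- matrix(0, ns, 8); P <- matrix(0, ns, 8); ll <- numeric(ns)
    refresh(seq_len(ns))

    # ---- proposal bookkeeping ----
    # each update block: name, affected sessions, prior function, getter/setter
    scales <- new.env()
    acc <- new.env()
    getsc <- function(id) get0(id, scales, ifnotfound = 0.25)
    bump <- function(id, accepted) {
      a <- get0(id, acc, ifnotfound = c(0, 0))
      assign(id, a + c(accepted, 1), acc)
    }
    adapt <- function(batch) {
      for (id in ls(acc)) {
        a <- get(id, acc)
        if (a[2] == 0) next
        step <- min(0.25, 1 / sqrt(batch))
        cur <- log(getsc(id))
        cur <- cur + if (a[1] / a[2] > 0.44) step else -step
        assign(id, exp(cur), scales)
        assign(id, c(0, 0), acc)
      }
    }

    mh <- function(id, K, lp_cur, lp_prop, apply_fun, revert_fun) {
      # generic accept/reject given prior log-density terms; likelihood
      # over sessions K is recomputed inside apply_fun via refresh()
      ll_old <- ll[K]; U_old <- U[K, , drop = FALSE]
      P_old <- P[K, , drop = FALSE]
      apply_fun()
      refresh(K)
      logr <- (sum(ll[K]) + lp_prop) - (sum(ll_old) + lp_cur)
      if (is.finite(logr) && log(runif(1)) < logr) {
        bump(id, 1)
        TRUE
      } else {
        revert_fun()
        U[K, ] <<- U_old; P[K, ] <<- P_old; ll[K] <<- ll_old
        bump(id, 0)
        FALSE
      }
    }

    all_K <- seq_len(ns)
    n_keep <- iter - warmup
    keep_mu <- matrix(NA_real_, n_keep, 8)
    keep_sig <- matrix(NA_real_, n_keep, 8)
    keep_d <- if (G > 1) array(NA_real_, c(n_keep, G - 1, 8)) else NULL
    keep_t <- if (G > 1) array(NA_real_, c(n_keep, G - 1, 8)) else NULL
    keep_r <- if (G - 1 == 2) matrix(NA_real_, n_keep, 8) else NULL
    keep_P <- array(NA_real_, c(n_keep, ns, 8))
    keep_lp <- numeric(n_keep)

    for (it in seq_len(iter)) {
      for (pn in act) {
        p <- match(pn, PAR_NAMES)
        # group location
        id <- paste0("mu.", p)
        old <- mu[p]; new <- old + getsc(id) * rnorm(1)
        mh(id, all_K,
           dnorm(old, pr$mu_loc[p], pr$mu_scale[p], log = TRUE),
           dnorm(new, pr$mu_loc[p], pr$mu_scale[p], log = TRUE),
           function() mu[p] <<- new, function() mu[p] <<- old)
        # group scale (log parameterization, half-normal prior + Jacobian)
        id <- paste0("lsig.", p)
        old <- lsig[p]; new <- old + getsc(id) * rnorm(1)
        hn <- function(x, s) -exp(2 * x) / (2 * s^2) + x
        mh(id, all_K, hn(old, pr$sigma_scale[p]), hn(new, pr$sigma_scale[p]),
           function() lsig[p] <<- new, function() lsig[p] <<- old)
        # subject deviates
        for (s in seq_len(S)) {
          id <- paste0("z.", s, ".", p)
          old <- z[s, p]; new <- old + getsc(id) * rnorm(1)
          mh(id, idx_by_subject[[s]],
             dnorm(old, log = TRUE), dnorm(new, log = TRUE),
             function() z[s, p] <<- new, function() z[s, p] <<- old)
        }
        if (G > 1) {
          for (j in seq_len(G - 1)) {
            Kd <- idx_by_drug[[j + 1]]
            id <- paste0("d.", j, ".", p)
            old <- d[j, p]; new <- old + getsc(id) * rnorm(1)
            mh(id, Kd, dnorm(old, 0, pr$d_scale[p], log = TRUE),
               dnorm(new, 0, pr$d_scale[p], log = TRUE),
               function() d[j, p] <<- new, function() d[j, p] <<- old)
            id <- paste0("lt.", j, ".", p)
            old <- lt[j, p]; new <- old + getsc(id) * rnorm(1)
            hn <- function(x, s) -exp(2 * x) / (2 * s^2) + x
            mh(id, Kd, hn(old, pr$t_scale[p]), hn(new, pr$t_scale[p]),
               function() lt[j, p] <<- new, function() lt[j, p] <<- old)
            for (s in seq_len(S)) {
              # e[s, 1, ] feeds all non-reference sessions of s;
              # e[s, 2, ] only the third condition
              Ke <- intersect(idx_by_subject[[s]],
                              if (G - 1 == 2 && j == 1)
                                unlist(idx_by_drug[-1]) else Kd)
              if (!length(Ke)) next
              id <- paste0("e.", s, ".", j, ".", p)
              old <- e[s, j, p]; new <- old + getsc(id) * rnorm(1)
              mh(id, Ke, dnorm(old, log = TRUE), dnorm(new, log = TRUE),
                 function() e[s, j, p] <<- new,
                 function() e[s, j, p] <<- old)
            }
          }
          if (G - 1 == 2) {
            Ky <- unlist(idx_by_drug[-1])
            id <- paste0("y.", p)
            old <- y[p]; new <- old + getsc(id) * rnorm(1)
            lkj <- function(v) log1p(-tanh(v)^2)  # uniform corr + Jacobian
            mh(id, Ky, lkj(old), lkj(new),
               function() y[p] <<- new, function() y[p] <<- old)
          }
        }
      }
      if (it <= warmup && it %% 50 == 0) adapt(it / 50)
      if (it > warmup) {
        i <- it - warmup
        keep_mu[i, ] <- mu
        keep_sig[i, ] <- exp(lsig)
        if (G > 1) {
          keep_d[i, , ] <- d[seq_len(G - 1), , drop = FALSE]
          keep_t[i, , ] <- exp(lt[seq_len(G - 1), , drop = FALSE])
        }
        if (G - 1 == 2) keep_r[i, ] <- tanh(y)
        keep_P[i, , ] <- P
        keep_lp[i] <- sum(ll)
      }
    }
    list(mu = keep_mu, sigma = keep_sig, d = keep_d, t = keep_t, r = keep_r,
         P = keep_P, lp = keep_lp)
  }

  res <- lapply(seq_len(chains), run_chain)

  comb <- function(f) do.call(rbind, lapply(res, `[[`, f))
  comb_arr <- function(f) {
    if (is.null(res[[1]][[f]])) return(NULL)
    do.call(abind_first, lapply(res, `[[`, f))
  }
  draws <- list(mu = comb("mu"), sigma = comb("sigma"),
                d = comb_arr("d"), t = comb_arr("t"),
                r = if (!is.null(res[[1]]$r)) comb("r") else NULL,
                sess_native = comb_arr("P"),
                lp = unlist(lapply(res, `[[`, "lp")))
  colnames(draws$mu) <- colnames(draws$sigma) <- PAR_NAMES
  n_keep <- iter - warmup

  # split-R-hat over group-level scalars
  rhat <- c()
  for (pn in act) {
    p <- match(pn, PAR_NAMES)
    rhat[paste0("mu_", pn)] <-
      split_rhat(matrix(draws$mu[, p], n_keep, chains))
    rhat[paste0("sigma_", pn)] <-
      split_rhat(matrix(draws$sigma[, p], n_keep, chains))
    if (G > 1) for (j in seq_len(G - 1)) {
      rhat[paste0("d_", drugs[j + 1], "_", pn)] <-
        split_rhat(matrix(draws$d[, j, p], n_keep, chains))
    }
  }
  fit <- list(spec = spec, drugs = drugs, sessions = sess, trials = tr,
              draws = draws, rhat = rhat, chains = chains, iter = iter,
              warmup = warmup, seed = seed, profile = profile,
              active = act)
  class(fit) <- "rlddm_fit"
  conv <- convergence_report(fit, quiet = TRUE)
  fit$convergence <- conv
  if (conv$status == "fail")
    warning("chains did not converge: max R-hat = ",
            round(conv$max_rhat, 3))
  fit
}

abind_first <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1], 1L)),
                           d[-1]))
  at <- 0
  for (x in xs) {
    n <- dim(x)[1]
    if (length(d) == 3) out[at + seq_len(n), , ] <- x
    else out[at + seq_len(n), ] <- x
    at <- at + n
  }
  out
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, from the usual between/within variance decomposition.
#'
#' @param x Matrix of draws, one column per chain.
#' @return Scalar R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[half + seq_len(half), , drop = FALSE])
  m <- ncol(sp)
  if (var(as.numeric(sp)) < 1e-300) return(1)
  means <- colMeans(sp)
  vars <- apply(sp, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  vhat <- (half - 1) / half * W + B / half
  sqrt(vhat / W)
}

#' Convergence report for a fitted model
#'
#' Flags group-level quantities with split-R-hat above 1.01 (warn) or 1.1
#' (fail).
#'
#' @param fit An `rlddm_fit`.
#' @param quiet Suppress the printed summary.
#' @return List with `status` (`"ok"`, `"warn"`, `"fail"`), `max_rhat`,
#'   and the per-quantity table.
#' @export
convergence_report <- function(fit, quiet = FALSE) {
  r <- fit$rhat
  status <- if (max(r) > 1.1) "fail" else if (max(r) > 1.01) "warn" else "ok"
  out <- list(status = status, max_rhat = max(r),
              table = data.frame(quantity = names(r), rhat = as.numeric(r)))
  if (!quiet) {
    cat(sprintf("convergence: %s (max split-R-hat %.3f over %d quantities)\n",
                status, max(r), length(r)))
  }
  invisible(out)
}

#' @exportS3Method base::print
print.rlddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical RL-DDM fit (model %d): %d subjects, %d sessions, %d trials\n",
              x$spec$id, length(unique(x$sessions$subject_id)),
              nrow(x$sessions), nrow(x$trials)))
  cat(sprintf("  %d chains x %d iterations (%d warmup), profile '%s'\n",
              x$chains, x$iter, x$warmup, x$profile))
  cat(sprintf("  max split-R-hat: %.3f (%s)\n", x$convergence$max_rhat,
              x$convergence$status))
  invisible(x)
}

#' Posterior summary of group-level parameters
#'
#' @param object An `rlddm_fit`.
#' @param prob Credible-interval mass (default 0.95, central interval).
#' @param ... Unused.
#' @return Data.frame with posterior mean, SD, and interval bounds of each
#'   active group-level location and scale (unconstrained scale), plus drug
#'   effects when present.
#' @exportS3Method base::summary
summary.rlddm_fit <- function(object, prob = 0.95, ...) {
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  row <- function(name, v) {
    data.frame(quantity = name, mean = mean(v), sd = sd(v),
               lower = quantile(v, qs[1]), upper = quantile(v, qs[2]),
               rhat = unname(object$rhat[name])[1] %||% NA_real_)
  }
  out <- list()
  for (pn in object$active) {
    p <- match(pn, PAR_NAMES)
    out[[length(out) + 1]] <- row(paste0("mu_", pn), object$draws$mu[, p])
    out[[length(out) + 1]] <- row(paste0("sigma_", pn),
                                  object$draws$sigma[, p])
    if (!is.null(object$draws$d)) {
      for (j in seq_along(object$drugs[-1])) {
        out[[length(out) + 1]] <-
          row(paste0("d_", object$drugs[j + 1], "_", pn),
              object$draws$d[, j, p])
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Posterior-mean native parameters per subject-session
#'
#' @param fit An `rlddm_fit`.
#' @return Data.frame: one row per subject-condition with the posterior
#'   means of the eight native-scale parameters.
#' @export
subject_params <- function(fit) {
  pm <- apply(fit$draws$sess_native, c(2, 3), mean)
  colnames(pm) <- PAR_NAMES
  cbind(fit$sessions[, c("subject_id", "drug", "min_rt", "n_trials")],
        as.data.frame(pm))
}

#' Composed log-likelihood of a trial table at fixed parameters
#'
#' Evaluates the model's log-likelihood (sum over completed test trials of
#' the Wiener log density at the trial drift implied by the Q trajectory)
#' for given per-session native parameters. This is the same quantity the
#' sampler uses, exposed for verification and scoring.
#'
#' @param data Canonical trial table or [prepare_data()] result.
#' @param params Data.frame mapping `subject_id` and `drug` to native
#'   parameter columns (as from [subject_params()]), or a single named
#'   vector applied to every session.
#' @param spec Model variant.
#' @return Named numeric vector of per-session log-likelihoods.
#' @export
loglik_rlddm <- function(data, params, spec = 4) {
  spec <- model_spec(spec)
  prep <- if (is.list(data) && all(c("trials", "sessions") %in% names(data)))
    data else prepare_data(data)
  tr <- prep$trials
  sess <- prep$sessions
  out <- numeric(nrow(sess))
  for (k in seq_len(nrow(sess))) {
    i <- tr$subject_id == sess$subject_id[k] & tr$drug == sess$drug[k]
    p <- if (is.data.frame(params)) {
      r <- params[params$subject_id == sess$subject_id[k] &
                    params$drug == sess$drug[k], ]
      if (nrow(r) != 1) stop("params must match each session exactly once")
      as.numeric(r[1, PAR_NAMES])
    } else as.numeric(params[PAR_NAMES])
    out[k] <- sum(.rlddm_pointwise_cpp(
      as.integer(tr$choice[i] == "high"),
      as.integer(ifelse(tr$outcome[i] == "win", 1L, -1L)),
      as.numeric(tr$rt_s[i]), p, spec_scaled(spec), spec_sigmoid(spec)))
  }
  names(out) <- paste(sess$subject_id, sess$drug)
  out
}
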