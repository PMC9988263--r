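# Parameter bookkeeping shared by the generator and the hierarchical model.
#
# Native-scale parameters, in canonical order:
#   eta_pos, eta_neg : learning rates, (0,1), logistic transform
#   rho              : outcome sensitivity, > 0, exp transform
#   alpha            : boundary separation, > 0, exp transform
#   tau              : non-decision time, (0, reference RT), logistic * ref
#   beta             : a-priori bias, (0,1), logistic transform
#   nu               : drift scaling, > 0, exp transform
#   nu_max           : drift bound, > 0, exp transform

PAR_NAMES <- c("eta_pos", "eta_neg", "rho", "alpha", "tau", "beta",
               "nu", "nu_max")
PAR_TRANSFORM <- c(eta_pos = "logistic", eta_neg = "logistic", rho = "exp",
                   alpha = "exp", tau = "logistic_scaled", beta = "logistic",
                   nu = "exp", nu_max = "exp")

#' Map unconstrained parameter draws to the native scale
#'
#' Learning rates and the bias use a logistic transform to (0, 1);
#' `rho`, `alpha`, `nu` and `nu_max` use an exponential transform to
#' (0, Inf); the non-decision time uses a logistic transform scaled by a
#' per-subject-session reference (the observed minimum reaction time when
#' fitting), which keeps `tau` strictly below every observed RT.
#'
#' @param u Named numeric vector, or matrix with columns named after (a
#'   subset of) `eta_pos, eta_neg, rho, alpha, tau, beta, nu, nu_max`, of
#'   unconstrained values.
#' @param tau_ref Reference scale (seconds) for the non-decision time:
#'   the minimum RT of the subject-session when fitting. Scalar or one
#'   value per row of `u`.
#' @return Native-scale values of the same shape.
#' @seealso [to_unconstrained()] for the inverse.
#' @export
to_native <- function(u, tau_ref = NULL) {
  f <- function(name, x) {
    switch(PAR_TRANSFORM[[name]],
           logistic = plogis(x),
           exp = exp(x),
           logistic_scaled = {
             if (is.null(tau_ref))
               stop("tau_ref (minimum RT) is required to transform tau")
             plogis(x) * tau_ref
           })
  }
  if (is.matrix(u)) {
    out <- u
    for (nm in colnames(u)) out[, nm] <- f(nm, u[, nm])
    out
  } else {
    vapply(names(u), function(nm) f(nm, u[[nm]]), numeric(1))
  }
}

#' Map native parameters back to the unconstrained scale
#'
#' Exact inverse of [to_native()].
#'
#' @param p Named numeric vector or matrix of native-scale values.
#' @inheritParams to_native
#' @return Unconstrained values of the same shape.
#' @export
to_unconstrained <- function(p, tau_ref = NULL) {
  f <- function(name, x) {
    switch(PAR_TRANSFORM[[name]],
           logistic = qlogis(x),
           exp = log(x),
           logistic_scaled = qlogis(x / tau_ref))
  }
  if (is.matrix(p)) {
    out <- p
    for (nm in colnames(p)) out[, nm] <- f(nm, p[, nm])
    out
  } else {
    vapply(names(p), function(nm) f(nm, p[[nm]]), numeric(1))
  }
}

# Prior catalog for the hierarchical model (all on the unconstrained scale).
# Locations are normal, scales half-normal; subject-level standardized
# deviates are standard normal and the drug-effect correlation gets an
# LKJ(1) prior (uniform over correlation matrices).
prior_catalog <- function() {
  data.frame(
    parameter = PAR_NAMES,
    mu_loc    = c(0, 0, 0.1, 0, 0, 0, 0.2, 0.5),
    mu_scale  = c(1, 1, 0.1, 0.1, 1, 0.5, 0.2, 0.2),
    sigma_scale = c(1, 1, 0.1, 0.1, 1, 0.1, 0.1, 0.1),
    drug_loc_scale = c(1, 1, 0.5, 0.5, 1, 0.5, 0.5, 0.5),
    drug_sigma_scale = 0.1,
    row.names = PAR_NAMES
  )
}

#' Sample from the hierarchical prior
#'
#' Draws group-level locations and scales, drug-effect locations and
#' scales, and standardized subject deviates from the model's prior, on the
#' unconstrained scale. Useful for prior-predictive checks.
#'
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return List of arrays: `mu`, `sigma` (`n` x 8), `drug_loc`,
#'   `drug_scale` (`n` x 8, per non-reference condition), `z` (`n` x 8).
#' @export
sample_prior <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cat_ <- prior_catalog()
  draw <- function(loc, scale) {
    matrix(rnorm(n * 8, rep(loc, each = n), rep(scale, each = n)), n, 8,
           dimnames = list(NULL, PAR_NAMES))
  }
  list(
    mu = draw(cat_$mu_loc, cat_$mu_scale),
    sigma = abs(draw(0, cat_$sigma_scale)),
    drug_loc = draw(0, cat_$drug_loc_scale),
    drug_scale = abs(draw(0, cat_$drug_sigma_scale)),
    z = draw(0, 1)
  )
}
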