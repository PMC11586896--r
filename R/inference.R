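#' Assemble an outcome dataset
#'
#' One row per participant-outcome: standardized dose, subgroup indicator
#' and a binary outcome (efficacy response or dose-limiting toxicity).
#'
#' @param d standardized doses (values on the trial's dose grid).
#' @param k subgroup indicators in {0, 1}.
#' @param y binary outcomes.
#' @return data frame with columns \code{d}, \code{k}, \code{y}.
#' @export
outcome_data <- function(d, k, y) {
  stopifnot(length(d) == length(k), length(k) == length(y),
            all(y %in% c(0, 1)), all(k %in% c(0, 1)))
  data.frame(d = as.numeric(d), k = as.integer(k), y = as.integer(y))
}

#' Sample the posterior of a dose-outcome model
#'
#' Fits the Bernoulli-logit dose-efficacy or dose-toxicity model to
#' accumulated trial data by Gibbs sampling with Polya-Gamma data
#' augmentation.  Subgroup coefficients carry spike-and-slab priors: a
#' latent inclusion indicator selects between the normal slab and an
#' exact point mass at zero, and is updated from its conditional with the
#' slab integrated out, so the draws target the exact joint posterior of
#' the coefficients and inclusion indicators.  With zero rows of data the
#' returned draws are prior draws.
#'
#' @param data an \code{\link{outcome_data}} data frame (possibly 0
#'   rows).
#' @param prior a \code{\link{prior_spec}}.
#' @param model \code{"efficacy"} or \code{"toxicity"}.
#' @param subgroup_terms if \code{FALSE}, the subgroup columns are
#'   dropped entirely (the pooled / independent comparison designs fit
#'   the same models without subgroup effects).
#' @param n_burn,n_keep burn-in and retained draws (single chain, no
#'   thinning).
#' @param seed RNG seed; identical seeds give identical draws.
#' @return object of class \code{obd_fit}: list with draw matrices
#'   \code{beta} (n_keep x p) and \code{gamma}, the model label, and the
#'   prior slice used.
#' @export
sample_posterior <- function(data, prior, model = c("efficacy", "toxicity"),
                             subgroup_terms = TRUE,
                             n_burn = 5000L, n_keep = 15000L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_burn > 0L, n_keep > 0L)
  sl <- prior_slice(prior, model)
  keep_cols <- if (subgroup_terms) seq_along(sl$b) else which(!sl$spike_slab)
  b <- sl$b[keep_cols]; sigma <- sl$sigma[keep_cols]
  ss <- sl$spike_slab[keep_cols]; p_incl <- sl$p_incl[keep_cols]
  p <- length(b)

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  if (nrow(data) == 0L) {
    gamma <- matrix(1, n_keep, p)
    for (l in which(ss)) gamma[, l] <- stats::rbinom(n_keep, 1L, p_incl[l])
    beta <- matrix(stats::rnorm(n_keep * p, rep(b, each = n_keep),
                                rep(sigma, each = n_keep)), n_keep, p) * gamma
  } else {
    X <- design_row(data$d, subgroup_contrast(data$k), model)[, keep_cols,
                                                             drop = FALSE]
    draws <- .ss_gibbs_cpp(X, data$y, b, sigma, as.integer(ss), p_incl,
                           as.integer(n_burn), as.integer(n_keep))
    beta <- draws$beta; gamma <- draws$gamma
  }
  coef_names <- model_coef_names(model)[keep_cols]
  dimnames(beta) <- dimnames(gamma) <- list(NULL, coef_names)
  structure(list(beta = beta, gamma = gamma, model = model,
                 subgroup_terms = subgroup_terms, keep_cols = keep_cols,
                 spike_slab = ss, n = nrow(data),
                 prior = list(b = b, sigma = sigma, p_incl = p_incl)),
            class = "obd_fit")
}

model_coef_names <- function(model) {
  if (model == "efficacy") c("(Intercept)", "d", "d^2", "x", "x:d", "x:d^2")
  else c("(Intercept)", "d", "x", "x:d")
}

#' @export
print.obd_fit <- function(x, ...) {
  cat("Bayesian dose-", x$model, " model fit (",
      nrow(x$beta), " posterior draws, n = ", x$n, ")\n", sep = "")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.obd_fit <- function(object, ...) colMeans(object$beta)

#' @export
summary.obd_fit <- function(object, ...) {
  qs <- t(apply(object$beta, 2L, stats::quantile,
                probs = c(0.025, 0.5, 0.975)))
  out <- data.frame(mean = colMeans(object$beta), qs, check.names = FALSE)
  incl <- posterior_inclusion_probabilities(object)
  out$p_incl <- NA_real_
  out[names(incl), "p_incl"] <- incl
  class(out) <- c("summary.obd_fit", "data.frame")
  out
}

#' @export
print.summary.obd_fit <- function(x, ...) {
  print.data.frame(round(x, 4))
  invisible(x)
}

#' Posterior inclusion probabilities of the subgroup effects
#'
#' @param fit an \code{obd_fit}.
#' @return named vector: posterior mean of the inclusion indicator for
#'   each spike-and-slab coefficient.
#' @export
posterior_inclusion_probabilities <- function(fit) {
  stopifnot(inherits(fit, "obd_fit"))
  colMeans(fit$gamma[, fit$spike_slab, drop = FALSE])
}

#' Posterior draws of outcome probabilities
#'
#' @param object an \code{obd_fit}.
#' @param d standardized dose(s) at which to evaluate.
#' @param k subgroup indicator(s) in {0, 1} (recycled against \code{d});
#'   ignored by fits without subgroup terms.
#' @param type \code{"draws"} (matrix of per-draw probabilities, one
#'   column per dose), \code{"map"} (kernel-density MAP point estimate
#'   per dose) or \code{"mean"} (posterior mean per dose).
#' @param ... unused.
#' @return matrix of draws or vector of point estimates.
#' @export
predict.obd_fit <- function(object, d, k = 0, type = c("draws", "map", "mean"),
                            ...) {
  type <- match.arg(type)
  n <- max(length(d), length(k))
  d <- rep_len(d, n); k <- rep_len(k, n)
  X <- design_row(d, subgroup_contrast(k), object$model)[, object$keep_cols,
                                                         drop = FALSE]
  pi_draws <- inv_logit(object$beta %*% t(X))
  switch(type,
         draws = pi_draws,
         map = .map_kde_cpp(pi_draws),
         mean = colMeans(pi_draws))
}

#' Export posterior draws for audit
#'
#' Writes a long-format CSV with columns draw, model, coefficient,
#' value, included.
#'
#' @param fit an \code{obd_fit}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  p <- ncol(fit$beta)
  M <- nrow(fit$beta)
  long <- data.frame(
    draw = rep(seq_len(M), p),
    model = fit$model,
    coefficient = rep(colnames(fit$beta), each = M),
    value = as.vector(fit$beta),
    included = as.integer(as.vector(fit$gamma)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
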