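#' Prior specification for the dose-outcome models
#'
#' A \code{prior_spec} holds, for each coefficient of the efficacy model
#' (6 coefficients) and the toxicity model (4 coefficients): the prior mean
#' \code{b}, prior sd \code{sigma}, whether the coefficient carries a
#' spike-and-slab prior, and the prior inclusion probability
#' \code{p_incl}.  Spike-and-slab priors are used exactly for the subgroup
#' effects: efficacy coefficients 4-6 (x, x d, x d^2) and toxicity
#' coefficients 3-4 (x, x d); all other coefficients have plain normal
#' priors and \code{p_incl = 1}.
#'
#' @param efficacy,toxicity data frames with columns \code{b},
#'   \code{sigma}, \code{spike_slab}, \code{p_incl} and 6 / 4 rows.
#' @return an object of class \code{prior_spec}.
#' @export
prior_spec <- function(efficacy, toxicity) {
  check <- function(df, n, ss_expected) {
    stopifnot(is.data.frame(df), nrow(df) == n,
              all(c("b", "sigma", "spike_slab", "p_incl") %in% names(df)))
    if (any(df$sigma <= 0)) stop("prior sds must be > 0", call. = FALSE)
    if (any(df$p_incl < 0 | df$p_incl > 1))
      stop("inclusion probabilities must be in [0, 1]", call. = FALSE)
    if (!identical(as.logical(df$spike_slab), ss_expected))
      stop("spike-and-slab flags must mark exactly the subgroup effects",
           call. = FALSE)
    df
  }
  structure(list(
    efficacy = check(efficacy, 6L, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)),
    toxicity = check(toxicity, 4L, c(FALSE, FALSE, TRUE, TRUE))
  ), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification\n  efficacy model:\n")
  print(cbind(coef = c("1", "d", "d^2", "x", "x:d", "x:d^2"),
              round(x$efficacy[c("b", "sigma", "p_incl")], 4)),
        row.names = FALSE)
  cat("  toxicity model:\n")
  print(cbind(coef = c("1", "d", "x", "x:d"),
              round(x$toxicity[c("b", "sigma", "p_incl")], 4)),
        row.names = FALSE)
  invisible(x)
}

prior_df <- function(b, sigma, spike_slab, p_incl) {
  data.frame(b = b, sigma = sigma, spike_slab = spike_slab, p_incl = p_incl)
}

#' Default subgroup-effect priors
#'
#' Subgroup effects get mean-zero slabs with sd 2.5 (a standard weakly
#' informative choice for logistic regression coefficients) and prior
#' inclusion probability 0.5, reflecting genuine a-priori uncertainty
#' about whether the dose-outcome curves differ by subgroup.  The same
#' hyperparameters are used for all five subgroup coefficients, including
#' the efficacy x:d^2 interaction.
#'
#' @return list with elements \code{b}, \code{sigma}, \code{p_incl}.
#' @export
default_subgroup_priors <- function() {
  list(b = 0, sigma = 2.5, p_incl = 0.5)
}

#' Elicitation target for prior calibration
#'
#' @param pi_E,pi_T elicited mean outcome probabilities at each dose of
#'   the grid (toxicity targets must be nondecreasing in dose).
#' @param ess target prior effective sample size (observations-worth of
#'   information the prior should carry; values below 1 give a very
#'   weakly informative prior).
#' @return object of class \code{elicitation_target}.
#' @export
elicitation_target <- function(pi_E, pi_T, ess) {
  stopifnot(length(pi_E) == length(pi_T),
            all(pi_E > 0 & pi_E < 1), all(pi_T > 0 & pi_T < 1),
            ess > 0)
  if (any(diff(pi_T) < 0))
    stop("elicited toxicity probabilities must be nondecreasing",
         call. = FALSE)
  structure(list(pi_E = pi_E, pi_T = pi_T, ess = ess),
            class = "elicitation_target")
}

# extract the slice of a prior_spec for one model as plain vectors
prior_slice <- function(prior, model) {
  df <- prior[[model]]
  list(b = df$b, sigma = df$sigma,
       spike_slab = as.logical(df$spike_slab), p_incl = df$p_incl)
}

# draw n coefficient vectors from the marginal prior of one model
# (spike-slab coefficients marginalized over their inclusion indicator)
draw_prior_coefficients <- function(prior, model, n) {
  sl <- prior_slice(prior, model)
  p <- length(sl$b)
  beta <- matrix(stats::rnorm(n * p, rep(sl$b, each = n),
                              rep(sl$sigma, each = n)), n, p)
  for (l in which(sl$spike_slab)) {
    gam <- stats::rbinom(n, 1L, sl$p_incl[l])
    beta[, l] <- beta[, l] * gam
  }
  beta
}

# Beta moment-matched prior effective sample size of a probability sample:
# a + b = m(1 - m)/v - 1
beta_moment_ess <- function(p) {
  m <- mean(p); v <- stats::var(p)
  if (v <= .Machine$double.eps) return(Inf)
  m * (1 - m) / v - 1
}

#' Prior effective sample size
#'
#' Monte-Carlo estimate of the information content of a prior
#' specification, expressed as an equivalent number of observations.
#' Coefficients are drawn from the prior (subgroup coefficients
#' marginalized over inclusion), outcome probabilities are evaluated at
#' every dose of the grid for the subgroup-averaged curve (contrast x =
#' 0), each probability's prior distribution is moment-matched to a
#' Beta(a, b), and the average of a + b over all doses and both outcomes
#' is returned.  A degenerate (zero-variance) prior returns \code{Inf}.
#'
#' @param prior a \code{\link{prior_spec}}.
#' @param grid a \code{\link{dose_grid}}.
#' @param n_draws number of Monte-Carlo prior draws.
#' @param seed RNG seed.
#' @return positive scalar (possibly \code{Inf}).
#' @export
ess_estimate <- function(prior, grid, n_draws = 1e5, seed = 1L) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  ess <- c(
    ess_one_model(draw_prior_coefficients(prior, "efficacy", n_draws),
                  grid, "efficacy"),
    ess_one_model(draw_prior_coefficients(prior, "toxicity", n_draws),
                  grid, "toxicity"))
  mean(ess)
}

ess_one_model <- function(beta, grid, model) {
  Xd <- design_row(grid$standardized, 0, model)
  eta <- beta %*% t(Xd)
  apply(inv_logit(eta), 2L, beta_moment_ess)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Calibrate prior hyperparameters to elicited targets
#'
#' Derives weakly informative prior hyperparameters whose prior-predictive
#' mean outcome probabilities and effective sample size are close to
#' elicited targets.  Prior means of the non-subgroup coefficients are
#' obtained by least squares of the model's linear predictor (at contrast
#' x = 0) against the logit of the elicited probabilities over the dose
#' grid; a single shared sd for the non-subgroup coefficients is then
#' found by bisection so that the Monte-Carlo ESS (see
#' \code{\link{ess_estimate}}) hits the target.  Because the mean of a
#' logit-normal prior drifts toward 0.5 as its sd grows, the least-squares
#' step is iterated a few times against mean-corrected logits so the
#' prior-predictive means land on the elicited probabilities rather than
#' on the logit-scale fit.  Subgroup coefficients always take the
#' \code{\link{default_subgroup_priors}} hyperparameters.
#'
#' @param target an \code{\link{elicitation_target}}.
#' @param grid a \code{\link{dose_grid}} with as many doses as the target
#'   has probabilities.
#' @param n_draws Monte-Carlo draws used for ESS and mean evaluation.
#' @param seed RNG seed (calibration is deterministic given the seed).
#' @param ess_tol bisection stops when the estimated ESS is within this
#'   tolerance of the target.
#' @param mean_iter number of mean-correction sweeps.
#' @return a calibrated \code{\link{prior_spec}} with attributes
#'   \code{ess} (achieved ESS) and \code{slab_sd} (shared non-subgroup
#'   sd).
#' @export
calibrate_prior <- function(target, grid, n_draws = 1e5, seed = 1L,
                            ess_tol = 0.02, mean_iter = 4L) {
  stopifnot(inherits(target, "elicitation_target"),
            inherits(grid, "dose_grid"),
            length(target$pi_E) == length(grid))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  XE <- design_row(grid$standardized, 0, "efficacy")[, 1:3]
  XT <- design_row(grid$standardized, 0, "toxicity")[, 1:2]
  # common random numbers: same standard normals across all candidate sds,
  # making the ESS exactly monotone in s and the bisection well posed
  ZE <- matrix(stats::rnorm(n_draws * 3L), n_draws, 3L)
  ZT <- matrix(stats::rnorm(n_draws * 2L), n_draws, 2L)

  pred <- function(bE, bT, s) {
    list(pE = inv_logit((ZE * s + rep(bE, each = n_draws)) %*% t(XE)),
         pT = inv_logit((ZT * s + rep(bT, each = n_draws)) %*% t(XT)))
  }
  ess_of <- function(bE, bT, s) {
    pp <- pred(bE, bT, s)
    mean(c(apply(pp$pE, 2L, beta_moment_ess),
           apply(pp$pT, 2L, beta_moment_ess)))
  }
  ls_fit <- function(X, eta) drop(solve(crossprod(X), crossprod(X, eta)))

  etaE <- logit(target$pi_E)
  etaT <- logit(target$pi_T)
  bE <- ls_fit(XE, etaE); bT <- ls_fit(XT, etaT)

  s <- NA_real_
  for (it in seq_len(mean_iter + 1L)) {
    # bisection on the shared slab sd: ESS strictly decreasing in s
    lo <- 0.05; hi <- 50
    if (ess_of(bE, bT, lo) < target$ess || ess_of(bE, bT, hi) > target$ess)
      stop("calibration-failure: target ESS ", target$ess,
           " not bracketed by sd range [0.05, 50]", call. = FALSE)
    for (b_it in 1:60) {
      s <- (lo + hi) / 2
      e <- ess_of(bE, bT, s)
      if (abs(e - target$ess) < ess_tol) break
      if (e > target$ess) lo <- s else hi <- s
    }
    if (it > mean_iter) break
    # mean correction: shift the logit targets by the current drift and
    # refit the least-squares means
    pp <- pred(bE, bT, s)
    etaE <- etaE + (logit(target$pi_E) - logit(colMeans(pp$pE)))
    etaT <- etaT + (logit(target$pi_T) - logit(colMeans(pp$pT)))
    bE <- ls_fit(XE, etaE); bT <- ls_fit(XT, etaT)
  }

  sub <- default_subgroup_priors()
  spec <- prior_spec(
    efficacy = prior_df(b = c(bE, rep(sub$b, 3)),
                        sigma = c(rep(s, 3), rep(sub$sigma, 3)),
                        spike_slab = c(rep(FALSE, 3), rep(TRUE, 3)),
                        p_incl = c(rep(1, 3), rep(sub$p_incl, 3))),
    toxicity = prior_df(b = c(bT, rep(sub$b, 2)),
                        sigma = c(rep(s, 2), rep(sub$sigma, 2)),
                        spike_slab = c(rep(FALSE, 2), rep(TRUE, 2)),
                        p_incl = c(rep(1, 2), rep(sub$p_incl, 2))))
  attr(spec, "ess") <- ess_of(bE, bT, s)
  attr(spec, "slab_sd") <- s
  spec
}

#' Prior-predictive mean outcome probabilities
#'
#' Monte-Carlo prior-predictive mean of the outcome probability at each
#' dose (contrast x = 0), used to check a calibrated prior against its
#' elicitation target.
#'
#' @inheritParams ess_estimate
#' @return list with per-dose mean vectors \code{pi_E} and \code{pi_T}.
#' @export
prior_predictive_means <- function(prior, grid, n_draws = 1e5, seed = 1L) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  mean_one <- function(model) {
    beta <- draw_prior_coefficients(prior, model, n_draws)
    Xd <- design_row(grid$standardized, 0, model)
    colMeans(inv_logit(beta %*% t(Xd)))
  }
  list(pi_E = mean_one("efficacy"), pi_T = mean_one("toxicity"))
}
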