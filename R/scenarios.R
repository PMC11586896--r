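#' Define a simulation scenario
#'
#' A scenario fixes the true per-dose, per-subgroup efficacy and toxicity
#' probabilities from which trial outcomes are simulated.  Outcomes are
#' independent Bernoulli draws unless a conditional-efficacy pair is
#' supplied, in which case toxicity is drawn from its marginal and
#' efficacy from \eqn{\pi_{E|T=y_T}}, inducing positive association when
#' \eqn{\pi_{E|T=1} > \pi_{E|T=0}}; the marginal efficacy probabilities
#' are then derived by the law of total probability, so the stated
#' marginals always satisfy
#' \eqn{\pi_E = \pi_{E|1}\pi_T + \pi_{E|0}(1-\pi_T)} exactly.
#'
#' @param pi_E J x 2 matrix of true efficacy probabilities (columns are
#'   subgroups k = 0, 1); ignored (derived) when \code{cond_E} is given.
#' @param pi_T J x 2 matrix of true toxicity probabilities.
#' @param cond_E optional list with J x 2 matrices \code{given_T1} and
#'   \code{given_T0}.
#' @param name scenario label.
#' @param class qualitative class label, e.g. \code{"homogeneous"} or
#'   \code{"heterogeneous-obd"}.
#' @return object of class \code{obd_scenario}.
#' @export
scenario <- function(pi_E = NULL, pi_T, cond_E = NULL, name = "scenario",
                     class = NA_character_) {
  pi_T <- as.matrix(pi_T)
  if (!is.null(cond_E)) {
    g1 <- as.matrix(cond_E$given_T1); g0 <- as.matrix(cond_E$given_T0)
    stopifnot(all(dim(g1) == dim(pi_T)), all(dim(g0) == dim(pi_T)))
    pi_E <- g1 * pi_T + g0 * (1 - pi_T)
  }
  pi_E <- as.matrix(pi_E)
  stopifnot(all(dim(pi_E) == dim(pi_T)), ncol(pi_T) == 2L,
            all(pi_E >= 0 & pi_E <= 1), all(pi_T >= 0 & pi_T <= 1))
  dn <- list(paste0("dose", seq_len(nrow(pi_T))), c("k0", "k1"))
  dimnames(pi_E) <- dimnames(pi_T) <- dn
  if (!is.null(cond_E)) {
    cond_E <- lapply(cond_E, function(m) {
      m <- as.matrix(m); dimnames(m) <- dn; m
    })
  }
  structure(list(pi_E = pi_E, pi_T = pi_T, cond_E = cond_E,
                 name = name, class = class),
            class = "obd_scenario")
}

#' @export
print.obd_scenario <- function(x, ...) {
  cat("Scenario ", x$name, if (!is.na(x$class)) paste0(" (", x$class, ")"),
      if (!is.null(x$cond_E)) " [correlated outcomes]", "\n", sep = "")
  cat("true efficacy probabilities:\n"); print(round(x$pi_E, 3))
  cat("true toxicity probabilities:\n"); print(round(x$pi_T, 3))
  tob <- true_obd(x)
  cat("true OBD (k0, k1):", ifelse(is.na(tob), "none", tob), "\n")
  invisible(x)
}

#' True optimal biological dose of a scenario
#'
#' Among doses whose true efficacy probability exceeds the efficacy floor
#' and whose true toxicity probability is below the toxicity cap, the OBD
#' is the dose maximizing the true expected utility; \code{NA} when no
#' dose qualifies in that subgroup.
#'
#' @param scn an \code{obd_scenario}.
#' @param nu a \code{\link{utility_table}}.
#' @param thresholds a \code{\link{decision_thresholds}}.
#' @return integer vector of length 2 (subgroups k = 0, 1).
#' @export
true_obd <- function(scn, nu = utility_table(),
                     thresholds = decision_thresholds()) {
  vapply(1:2, function(i) {
    ok <- which(scn$pi_E[, i] > thresholds$pi_E_floor &
                  scn$pi_T[, i] < thresholds$pi_T_bar)
    if (length(ok) == 0L) return(NA_integer_)
    u <- expected_utility(scn$pi_E[ok, i], scn$pi_T[ok, i], nu)
    ok[which.max(u)]
  }, integer(1))
}

#' Draw one participant's outcomes under a scenario
#'
#' @param scn an \code{obd_scenario}.
#' @param j dose index.
#' @param k subgroup indicator in {0, 1}.
#' @return named numeric vector \code{c(y_E, y_T)}.  Uses the current RNG
#'   stream.
#' @export
draw_outcomes <- function(scn, j, k) {
  i <- k + 1L
  y_T <- as.integer(stats::runif(1) < scn$pi_T[j, i])
  p_E <- if (is.null(scn$cond_E)) scn$pi_E[j, i]
         else if (y_T == 1L) scn$cond_E$given_T1[j, i]
         else scn$cond_E$given_T0[j, i]
  y_E <- as.integer(stats::runif(1) < p_E)
  c(y_E = y_E, y_T = y_T)
}

# Solve model-form coefficients through anchor probabilities:
# efficacy through (dose 1, middle dose, dose J), toxicity through
# (dose 1, dose J), on the logit scale.
eff_curve <- function(p_lo, p_mid, p_hi, grid) {
  d <- grid$standardized
  anchors <- c(1L, ceiling(length(d) / 2), length(d))
  V <- cbind(1, d[anchors], d[anchors]^2)
  beta <- solve(V, logit(c(p_lo, p_mid, p_hi)))
  inv_logit(cbind(1, d, d^2) %*% beta)[, 1]
}

tox_curve <- function(p_lo, p_hi, grid) {
  d <- grid$standardized
  V <- cbind(1, d[c(1L, length(d))])
  beta <- solve(V, logit(c(p_lo, p_hi)))
  inv_logit(cbind(1, d) %*% beta)[, 1]
}

#' Build the eight-scenario simulation suite
#'
#' Constructs eight scenarios on a dose grid, spanning the qualitative
#' classes used to compare subgroup-aware, pooled and independent
#' dose-finding: scenarios 1, 5 and 6 have identical dose-outcome curves
#' in both subgroups (homogeneous); scenarios 2, 3 and 7 have
#' subgroup-specific curves leading to different true OBDs (with scenario
#' 3 placing one subgroup's doses just outside the acceptability
#' thresholds so no dose is acceptable there, and scenario 7 tabulated
#' without a model form); scenarios 4 and 8 have subgroup-specific curves
#' but a common OBD, with scenario 8 adding positive efficacy-toxicity
#' correlation.  Curves for scenarios 1-6 and 8 follow the quadratic
#' efficacy / linear toxicity model forms through anchor probabilities.
#'
#' @param grid a \code{\link{dose_grid}} (defaults to the 0.2-1.0
#'   five-dose grid).
#' @return named list of eight \code{obd_scenario} objects.
#' @export
build_scenario_suite <- function(grid = dose_grid(c(0.2, 0.4, 0.6, 0.8, 1))) {
  e <- function(lo, mid, hi) eff_curve(lo, mid, hi, grid)
  t_ <- function(lo, hi) tox_curve(lo, hi, grid)
  two <- function(a, b) cbind(k0 = a, k1 = b)

  s <- list()
  # homogeneous curves, OBD at the top dose
  s$s1 <- scenario(pi_E = two(e(0.25, 0.55, 0.70), e(0.25, 0.55, 0.70)),
                   pi_T = two(t_(0.05, 0.20), t_(0.05, 0.20)),
                   name = "1", class = "homogeneous")
  # subgroup 1 substantially more toxic: OBDs differ (high vs low)
  s$s2 <- scenario(pi_E = two(e(0.25, 0.55, 0.70), e(0.35, 0.60, 0.70)),
                   pi_T = two(t_(0.05, 0.20), t_(0.20, 0.75)),
                   name = "2", class = "heterogeneous-obd")
  # subgroup 1 just outside the thresholds everywhere: no acceptable dose
  s$s3 <- scenario(pi_E = two(e(0.20, 0.60, 0.68), e(0.28, 0.55, 0.65)),
                   pi_T = two(t_(0.05, 0.25), t_(0.30, 0.60)),
                   name = "3", class = "heterogeneous-obd")
  # efficacy curves differ in shape but the OBD coincides
  s$s4 <- scenario(pi_E = two(e(0.25, 0.55, 0.70), e(0.15, 0.50, 0.75)),
                   pi_T = two(t_(0.05, 0.20), t_(0.04, 0.22)),
                   name = "4", class = "heterogeneous-curves-common-obd")
  # homogeneous, steep toxicity: OBD at a low dose
  s$s5 <- scenario(pi_E = two(e(0.30, 0.62, 0.72), e(0.30, 0.62, 0.72)),
                   pi_T = two(t_(0.10, 0.75), t_(0.10, 0.75)),
                   name = "5", class = "homogeneous")
  # homogeneous, efficacy plateau: OBD in the middle of the grid
  s$s6 <- scenario(pi_E = two(e(0.20, 0.60, 0.62), e(0.20, 0.60, 0.62)),
                   pi_T = two(t_(0.10, 0.45), t_(0.10, 0.45)),
                   name = "6", class = "homogeneous")
  # tabulated probabilities, no model form; OBDs differ
  s$s7 <- scenario(
    pi_E = two(c(0.20, 0.35, 0.50, 0.60, 0.60),
               c(0.30, 0.50, 0.55, 0.55, 0.55)),
    pi_T = two(c(0.05, 0.07, 0.10, 0.15, 0.22),
               c(0.10, 0.20, 0.40, 0.55, 0.65)),
    name = "7", class = "heterogeneous-obd")
  # positively correlated outcomes, subgroup-specific curves, common OBD
  pi_T8 <- two(t_(0.05, 0.25), t_(0.08, 0.30))
  base0 <- e(0.22, 0.52, 0.68); base1 <- e(0.15, 0.48, 0.72)
  s$s8 <- scenario(
    pi_T = pi_T8,
    cond_E = list(given_T1 = two(pmin(base0 + 0.20, 0.95),
                                 pmin(base1 + 0.20, 0.95)),
                  given_T0 = two(base0, base1)),
    name = "8", class = "heterogeneous-curves-common-obd")
  s
}

#' An all-toxic stress scenario
#'
#' Every dose has true toxicity probability at or above \code{p_tox} in
#' both subgroups; used to check that the design stops with no
#' acceptable dose.
#'
#' @param grid a \code{\link{dose_grid}}.
#' @param p_tox toxicity probability at the lowest dose.
#' @return an \code{obd_scenario}.
#' @export
scenario_all_toxic <- function(grid = dose_grid(c(0.2, 0.4, 0.6, 0.8, 1)),
                               p_tox = 0.6) {
  J <- length(grid)
  tox <- tox_curve(p_tox, min(p_tox + 0.25, 0.95), grid)
  scenario(pi_E = cbind(k0 = rep(0.5, J), k1 = rep(0.5, J)),
           pi_T = cbind(k0 = tox, k1 = tox),
           name = "all-toxic", class = "stress")
}

#' Write / read scenario files
#'
#' Scenarios serialize to YAML with tabulated probabilities per dose and
#' subgroup (and conditional-efficacy tables when present).
#'
#' @param scn an \code{obd_scenario}.
#' @param path file path.
#' @return \code{read_scenario} returns an \code{obd_scenario};
#'   \code{write_scenario} returns \code{path} invisibly.
#' @export
write_scenario <- function(scn, path) {
  obj <- list(name = scn$name, class = scn$class,
              pi_E = apply(scn$pi_E, 2L, identity, simplify = FALSE),
              pi_T = apply(scn$pi_T, 2L, identity, simplify = FALSE))
  if (!is.null(scn$cond_E))
    obj$cond_E <- lapply(scn$cond_E, function(m)
      apply(m, 2L, identity, simplify = FALSE))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  as_mat <- function(x) do.call(cbind, lapply(x, unlist))
  cond <- if (!is.null(obj$cond_E)) lapply(obj$cond_E, as_mat)
  scenario(pi_E = if (is.null(cond)) as_mat(obj$pi_E),
           pi_T = as_mat(obj$pi_T), cond_E = cond,
           name = obj$name %||% "scenario",
           class = obj$class %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
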