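#' Utility table for the four efficacy/toxicity outcomes
#'
#' Utilities are on a 0-100 scale with the anchors fixed by convention:
#' efficacy without toxicity scores 100 (best outcome) and toxicity
#' without efficacy scores 0 (worst outcome).  The two free values encode
#' the efficacy-toxicity trade-off.
#'
#' @param nu00 utility of no efficacy, no toxicity.
#' @param nu11 utility of efficacy with toxicity.
#' @return object of class \code{utility_table}: a 2 x 2 matrix indexed
#'   by (efficacy outcome a, toxicity outcome b).
#' @examples
#' utility_table()          # the 0 / 40 / 60 / 100 trade-off
#' @export
utility_table <- function(nu00 = 40, nu11 = 60) {
  nu <- matrix(c(nu00, 0, 100, nu11), 2, 2, byrow = TRUE,
               dimnames = list(a = c("0", "1"), b = c("0", "1")))
  if (any(nu < 0 | nu > 100))
    stop("utilities must lie in [0, 100]", call. = FALSE)
  structure(nu, class = c("utility_table", "matrix"))
}

#' Expected utility under the independence working model
#'
#' \eqn{U = \sum_{a,b} \nu_{a,b}\, \pi_E^a (1-\pi_E)^{1-a}\,
#' \pi_T^b (1-\pi_T)^{1-b}}: the utility of each of the four joint
#' outcomes weighted by its probability under independent Bernoulli
#' efficacy and toxicity.  Vectorized over \code{pi_E} / \code{pi_T}.
#'
#' @param pi_E,pi_T outcome probabilities in [0, 1].
#' @param nu a \code{\link{utility_table}}.
#' @return expected utilities in [0, 100].
#' @export
expected_utility <- function(pi_E, pi_T, nu = utility_table()) {
  stopifnot(all(pi_E >= 0 & pi_E <= 1), all(pi_T >= 0 & pi_T <= 1))
  nu["0", "0"] * (1 - pi_E) * (1 - pi_T) +
    nu["0", "1"] * (1 - pi_E) * pi_T +
    nu["1", "0"] * pi_E * (1 - pi_T) +
    nu["1", "1"] * pi_E * pi_T
}

#' Maximum a posteriori probability estimate from posterior draws
#'
#' The per-draw outcome probabilities form an empirical posterior
#' distribution on [0, 1]; its mode is estimated by a Gaussian kernel
#' density (Silverman's bandwidth) evaluated on a 512-point lattice over
#' [0, 1] with boundary reflection, and the estimate is clamped to the
#' observed range of the draws.
#'
#' @param p numeric vector of at least 100 probability draws.
#' @return scalar MAP estimate in [min(p), max(p)].
#' @export
map_probability <- function(p) {
  if (length(p) < 100L)
    stop("insufficient-draws: MAP estimation needs >= 100 draws",
         call. = FALSE)
  .map_kde_cpp(as.matrix(as.numeric(p)))[1L]
}

#' Decision thresholds
#'
#' @param pi_T_bar upper toxicity threshold: doses must have
#'   \eqn{\pi_T < \bar\pi_T} with high posterior probability.
#' @param pi_E_floor lower efficacy threshold.
#' @param p_T,p_E required posterior evidence levels for the toxicity and
#'   efficacy conditions (small values reflect feasible phase I/II sample
#'   sizes).
#' @return object of class \code{decision_thresholds}.
#' @export
decision_thresholds <- function(pi_T_bar = 0.35, pi_E_floor = 0.3,
                                p_T = 0.1, p_E = 0.1) {
  vals <- c(pi_T_bar = pi_T_bar, pi_E_floor = pi_E_floor,
            p_T = p_T, p_E = p_E)
  if (any(vals <= 0 | vals >= 1))
    stop("thresholds must lie strictly in (0, 1)", call. = FALSE)
  structure(as.list(vals), class = "decision_thresholds")
}

#' Admissibility of each dose for one subgroup, from probability draws
#'
#' A dose j is admissible when it passes the safety condition and an
#' efficacy-or-escalation condition:
#' \itemize{
#'   \item Condition 1: \eqn{P(\pi_T(d_j) < \bar\pi_T) > p_T};
#'   \item Condition 2a: \eqn{P(\pi_E(d_j) > \underline\pi_E) > p_E} and
#'     j has been tried;
#'   \item Condition 2b: j is the next dose above the highest tried
#'     level.
#' }
#' During the trial a dose needs 1 and (2a or 2b); at the final analysis
#' only 1 and 2a count, so an untried escalation dose can never be
#' selected as the OBD.
#'
#' @param pi_E_draws,pi_T_draws M x J matrices of per-draw outcome
#'   probabilities at each dose.
#' @param thresholds a \code{\link{decision_thresholds}}.
#' @param tried integer vector of tried dose indices (possibly empty).
#' @param final logical; final-analysis rule if \code{TRUE}.
#' @return data frame with one row per dose and logical columns
#'   \code{cond1}, \code{cond2a}, \code{cond2b}, \code{admissible}.
#' @export
admissible_doses <- function(pi_E_draws, pi_T_draws, thresholds,
                             tried = integer(), final = FALSE) {
  stopifnot(ncol(pi_E_draws) == ncol(pi_T_draws))
  J <- ncol(pi_T_draws)
  j <- seq_len(J)
  cond1 <- colMeans(pi_T_draws < thresholds$pi_T_bar) > thresholds$p_T
  cond2a <- (colMeans(pi_E_draws > thresholds$pi_E_floor) >
               thresholds$p_E) & (j %in% tried)
  max_tried <- if (length(tried)) max(tried) else 0L
  cond2b <- !final & (j == max_tried + 1L)
  data.frame(dose = j, cond1 = cond1, cond2a = cond2a, cond2b = cond2b,
             admissible = cond1 & (cond2a | cond2b))
}

#' Per-subgroup admissible sets from fitted models
#'
#' Applies \code{\link{admissible_doses}} to both subgroups using the
#' posterior draws of a fitted efficacy and toxicity model.
#'
#' @param fit_E,fit_T \code{obd_fit} objects for the two outcomes.
#' @param grid a \code{\link{dose_grid}}.
#' @param thresholds a \code{\link{decision_thresholds}}.
#' @param tried list of two integer vectors: tried dose indices for
#'   subgroups k = 0 and k = 1.
#' @param final logical; final-analysis rule.
#' @return list of two admissibility data frames, one per subgroup.
#' @export
admissible_set <- function(fit_E, fit_T, grid, thresholds,
                           tried = list(integer(), integer()),
                           final = FALSE) {
  lapply(1:2, function(i) {
    k <- i - 1L
    admissible_doses(predict(fit_E, grid$standardized, k),
                     predict(fit_T, grid$standardized, k),
                     thresholds, tried = tried[[i]], final = final)
  })
}

#' Estimated expected utility of every dose for one subgroup
#'
#' Per-dose MAP estimates of the outcome probabilities are plugged into
#' the expected-utility formula.
#'
#' @inheritParams admissible_set
#' @param k subgroup indicator.
#' @param nu a \code{\link{utility_table}}.
#' @return numeric vector of length J.
#' @export
dose_utilities <- function(fit_E, fit_T, grid, k, nu = utility_table()) {
  pe <- predict(fit_E, grid$standardized, k, type = "map")
  pt <- predict(fit_T, grid$standardized, k, type = "map")
  expected_utility(pe, pt, nu)
}

#' Select the dose maximizing estimated utility over an admissible set
#'
#' Ties are broken toward the lower dose (conservative dosing).
#'
#' @param utilities numeric vector of per-dose estimated utilities.
#' @param admissible integer vector of admissible dose indices.
#' @return dose index, or \code{NA_integer_} when the set is empty.
#' @export
select_dose <- function(utilities, admissible) {
  if (length(admissible) == 0L) return(NA_integer_)
  u <- utilities[admissible]
  admissible[which.max(round(u, 10))]  # which.max takes first (= lowest dose) on ties
}

#' Final OBD selection for both subgroups
#'
#' Applies the final-analysis admissibility rule (Conditions 1 and 2a)
#' and picks the admissible dose with the largest estimated expected
#' utility in each subgroup; \code{NA} means no OBD is declared for that
#' subgroup.
#'
#' @inheritParams admissible_set
#' @param nu a \code{\link{utility_table}}.
#' @return integer vector of length 2 (subgroups k = 0, 1), \code{NA}
#'   where no dose is acceptable.
#' @export
select_obd <- function(fit_E, fit_T, grid, thresholds, nu = utility_table(),
                       tried = list(integer(), integer())) {
  adm <- admissible_set(fit_E, fit_T, grid, thresholds, tried = tried,
                        final = TRUE)
  vapply(1:2, function(i) {
    u <- dose_utilities(fit_E, fit_T, grid, k = i - 1L, nu = nu)
    select_dose(u, adm[[i]]$dose[adm[[i]]$admissible])
  }, integer(1))
}
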