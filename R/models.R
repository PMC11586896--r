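#' Standardize a dose grid
#'
#' Doses are standardized to centered natural-log doses,
#' \eqn{d_j = \log\delta_j - J^{-1}\sum_q \log\delta_q}, the scale on which
#' the dose-efficacy and dose-toxicity models are parameterized.  Centering
#' makes the intercepts interpretable as the logit outcome probability at
#' the geometric-mean dose.
#'
#' @param raw_doses numeric vector of J >= 2 strictly increasing positive
#'   dose values, in whatever units the trial uses.
#' @return An object of class \code{dose_grid}: a list with elements
#'   \code{raw} and \code{standardized}, both length J.
#' @examples
#' dose_grid(c(0.2, 0.4, 0.6, 0.8, 1.0))
#' @export
dose_grid <- function(raw_doses) {
  raw_doses <- as.numeric(raw_doses)
  if (length(raw_doses) < 2L)
    stop("need at least two doses", call. = FALSE)
  if (any(!is.finite(raw_doses)) || any(raw_doses <= 0))
    stop("raw doses must be finite and > 0", call. = FALSE)
  if (any(diff(raw_doses) <= 0))
    stop("raw doses must be strictly increasing (no duplicates)",
         call. = FALSE)
  d <- log(raw_doses) - mean(log(raw_doses))
  structure(list(raw = raw_doses, standardized = d),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("Dose grid (", length(x$raw), " levels)\n", sep = "")
  print(data.frame(raw = x$raw, standardized = round(x$standardized, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
length.dose_grid <- function(x) length(x$raw)

#' Subgroup contrast code
#'
#' The binary subgroup indicator k in {0, 1} enters the models through the
#' contrast code x = 2k - 1 in {-1, +1}, so subgroup effects are symmetric
#' deviations from the subgroup-averaged curve.
#'
#' @param k subgroup indicator(s), 0 or 1.
#' @return numeric vector of contrast codes in {-1, +1}.
#' @export
subgroup_contrast <- function(k) {
  if (!all(k %in% c(0, 1))) stop("subgroup k must be 0 or 1", call. = FALSE)
  2 * as.numeric(k) - 1
}

# numerically stable inverse logit; MCMC can visit extreme linear
# predictors, so eta is clipped at +/- 35 before exponentiation
inv_logit <- function(eta) {
  stats::plogis(pmin(pmax(eta, -35), 35))
}

logit <- function(p) stats::qlogis(p)

#' Model design rows
#'
#' Row(s) of the design matrix for the two dose-outcome models at
#' standardized dose d and contrast x: the efficacy model is quadratic in
#' dose with subgroup main effect and subgroup-by-dose and
#' subgroup-by-dose-squared interactions, \code{(1, d, d^2, x, x d, x d^2)};
#' the toxicity model is linear in dose, \code{(1, d, x, x d)}.
#'
#' @param d standardized dose(s).
#' @param x subgroup contrast(s) in {-1, +1} (0 gives the
#'   subgroup-averaged curve, used for prior calibration).
#' @param model \code{"efficacy"} or \code{"toxicity"}.
#' @return matrix with \code{length(d)} rows.
#' @export
design_row <- function(d, x, model = c("efficacy", "toxicity")) {
  model <- match.arg(model)
  n <- max(length(d), length(x))
  d <- rep_len(d, n); x <- rep_len(x, n)
  if (model == "efficacy") {
    cbind(1, d, d^2, x, x * d, x * d^2,
          deparse.level = 0)
  } else {
    cbind(1, d, x, x * d, deparse.level = 0)
  }
}

n_coef <- function(model) if (model == "efficacy") 6L else 4L

#' Efficacy probability under the dose-efficacy model
#'
#' Evaluates \eqn{\pi_{kE}(d) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 d +
#' \beta_2 d^2 + x_k(\beta_3 + \beta_4 d + \beta_5 d^2))}.
#'
#' @param beta numeric vector of 6 coefficients (intercept, d, d^2, x,
#'   x d, x d^2).
#' @param d standardized dose(s).
#' @param k subgroup indicator(s) in {0, 1}.
#' @return probabilities in (0, 1).
#' @export
efficacy_probability <- function(beta, d, k) {
  stopifnot(length(beta) == 6L, all(is.finite(beta)))
  x <- subgroup_contrast(k)
  inv_logit(drop(design_row(d, x, "efficacy") %*% beta))
}

#' Toxicity probability under the dose-toxicity model
#'
#' Evaluates \eqn{\pi_{kT}(d) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 d +
#' x_k(\beta_2 + \beta_3 d))}.  The model is linear in dose, reflecting the
#' expectation that toxicity is monotone in dose.
#'
#' @param beta numeric vector of 4 coefficients (intercept, d, x, x d).
#' @param d standardized dose(s).
#' @param k subgroup indicator(s) in {0, 1}.
#' @return probabilities in (0, 1).
#' @export
toxicity_probability <- function(beta, d, k) {
  stopifnot(length(beta) == 4L, all(is.finite(beta)))
  x <- subgroup_contrast(k)
  inv_logit(drop(design_row(d, x, "toxicity") %*% beta))
}

#' Outcome probability surface over a dose grid
#'
#' Evaluates one dose-outcome model at every (dose, subgroup) pair of a
#' grid.
#'
#' @param beta coefficient vector (length 6 for efficacy, 4 for toxicity).
#' @param grid a \code{\link{dose_grid}}.
#' @param model \code{"efficacy"} or \code{"toxicity"}.
#' @return J x 2 matrix of probabilities; columns are subgroups k = 0, 1.
#' @export
probability_surface <- function(beta, grid,
                                model = c("efficacy", "toxicity")) {
  model <- match.arg(model)
  fn <- if (model == "efficacy") efficacy_probability else
    toxicity_probability
  out <- vapply(c(0, 1), function(k) fn(beta, grid$standardized, rep(k, length(grid))),
                numeric(length(grid)))
  dimnames(out) <- list(paste0("dose", seq_along(grid$raw)),
                        c("k0", "k1"))
  out
}
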