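test_that("default subgroup priors are mean-zero 2.5-sd slabs with p = 0.5", {
  sub <- default_subgroup_priors()
  expect_equal(sub$b, 0)
  expect_equal(sub$sigma, 2.5)
  expect_equal(sub$p_incl, 0.5)
  # and they land on every subgroup coefficient of a calibrated spec
  expect_equal(std_prior$efficacy$b[4:6], rep(0, 3))
  expect_equal(std_prior$efficacy$sigma[4:6], rep(2.5, 3))
  expect_equal(std_prior$toxicity$sigma[3:4], rep(2.5, 2))
  expect_equal(std_prior$toxicity$p_incl[3:4], rep(0.5, 2))
  # non-subgroup coefficients are plain normal (always included)
  expect_false(any(std_prior$toxicity$spike_slab[1:2]))
  expect_equal(std_prior$toxicity$p_incl[1:2], rep(1, 2))
})

test_that("prior_spec validates spike-slab structure", {
  eff <- std_prior$efficacy
  tox <- std_prior$toxicity
  bad <- eff; bad$spike_slab <- rep(FALSE, 6)
  expect_error(prior_spec(bad, tox), "subgroup effects")
  bad2 <- tox; bad2$sigma[1] <- -1
  expect_error(prior_spec(eff, bad2), "sds")
})

test_that("spike-slab marginal prior has the right point mass and slab", {
  set.seed(5)
  beta <- obdsub:::draw_prior_coefficients(std_prior, "toxicity", 4e4)
  x_coef <- beta[, 3]  # subgroup main effect: 0.5 spike at zero
  p_zero <- mean(x_coef == 0)
  expect_equal(p_zero, 0.5, tolerance = 0.02)
  slab <- x_coef[x_coef != 0]
  expect_equal(mean(slab), 0, tolerance = 0.05)
  expect_equal(sd(slab), 2.5, tolerance = 0.05)
})

test_that("Beta moment matching recovers a + b from samples", {
  set.seed(6)
  x <- rbeta(2e5, 3, 7)
  expect_equal(obdsub:::beta_moment_ess(x), 10, tolerance = 0.15)
  # exact on stated moments: m(1-m)/v - 1
  expect_equal(obdsub:::beta_moment_ess(c(0.2, 0.4, 0.2, 0.4)),
               0.3 * 0.7 / stats::var(c(0.2, 0.4, 0.2, 0.4)) - 1)
})

test_that("ESS decreases monotonically in a slab-sd multiplier", {
  scale_prior <- function(f) {
    eff <- std_prior$efficacy; tox <- std_prior$toxicity
    eff$sigma[1:3] <- eff$sigma[1:3] * f
    tox$sigma[1:2] <- tox$sigma[1:2] * f
    prior_spec(eff, tox)
  }
  ess <- vapply(c(0.5, 1, 2, 4),
                function(f) ess_estimate(scale_prior(f), std_grid,
                                         n_draws = 2e4, seed = 9),
                numeric(1))
  expect_true(all(diff(ess) < 0))
})

test_that("degenerate priors report infinite ESS", {
  eff <- std_prior$efficacy; tox <- std_prior$toxicity
  eff$sigma[1:3] <- 1e-12; tox$sigma[1:2] <- 1e-12
  expect_equal(ess_estimate(prior_spec(eff, tox), std_grid,
                            n_draws = 1e3, seed = 2), Inf)
})

test_that("calibration hits elicited means and target ESS", {
  pp <- prior_predictive_means(std_prior, std_grid, n_draws = 2e4,
                               seed = 31)
  expect_true(all(abs(pp$pi_E - std_target$pi_E) < 0.05))
  expect_true(all(abs(pp$pi_T - std_target$pi_T) < 0.05))
  ess <- ess_estimate(std_prior, std_grid, n_draws = 2e4, seed = 32)
  expect_equal(ess, 0.9, tolerance = 0.3 / 0.9)
})

test_that("calibration is deterministic given the seed", {
  a <- calibrate_prior(std_target, std_grid, n_draws = 5e3, seed = 42)
  b <- calibrate_prior(std_target, std_grid, n_draws = 5e3, seed = 42)
  expect_identical(a$efficacy, b$efficacy)
  expect_identical(a$toxicity, b$toxicity)
})

test_that("targets on an exact logistic curve are interpolated", {
  d <- std_grid$standardized
  pi_T <- plogis(-2 + 1.2 * d)
  tgt <- elicitation_target(pi_E = plogis(0.3 + 0.8 * d + 0.1 * d^2),
                            pi_T = pi_T, ess = 0.9)
  pr <- calibrate_prior(tgt, std_grid, n_draws = 5e3, seed = 3,
                        mean_iter = 0L)
  # with no mean-correction sweeps the least-squares fit is exact
  expect_equal(plogis(drop(cbind(1, d) %*% pr$toxicity$b[1:2])), pi_T,
               tolerance = 1e-8)
})

test_that("elicitation targets are validated", {
  expect_error(elicitation_target(c(0.3, 0.5), c(0.2, 0.1), 0.9),
               "nondecreasing")
  expect_error(elicitation_target(c(0.3, 1.2), c(0.1, 0.2), 0.9))
})
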