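test_that("posterior draws respect the point-mass spike exactly", {
  set.seed(8)
  dat <- outcome_data(d = sample(std_grid$standardized, 40, TRUE),
                      k = rep(0:1, 20), y = rbinom(40, 1, 0.3))
  fit <- sample_posterior(dat, std_prior, "toxicity",
                          n_burn = 200, n_keep = 400, seed = 4)
  ss <- fit$beta[, fit$spike_slab, drop = FALSE]
  gam <- fit$gamma[, fit$spike_slab, drop = FALSE]
  expect_true(all(ss[gam == 0] == 0))
  expect_true(all(ss[gam == 1] != 0))
  # non-spike coefficients are always included
  expect_true(all(fit$gamma[, !fit$spike_slab] == 1))
})

test_that("same seed gives identical draws; different seed differs", {
  set.seed(9)
  dat <- outcome_data(d = sample(std_grid$standardized, 30, TRUE),
                      k = rep(0:1, 15), y = rbinom(30, 1, 0.4))
  f1 <- sample_posterior(dat, std_prior, "efficacy", n_burn = 100,
                         n_keep = 200, seed = 77)
  f2 <- sample_posterior(dat, std_prior, "efficacy", n_burn = 100,
                         n_keep = 200, seed = 77)
  f3 <- sample_posterior(dat, std_prior, "efficacy", n_burn = 100,
                         n_keep = 200, seed = 78)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$gamma, f2$gamma)
  expect_false(identical(f1$beta, f3$beta))
})

test_that("with no data the sampler reproduces the prior", {
  empty <- outcome_data(numeric(), integer(), integer())
  fit <- sample_posterior(empty, std_prior, "toxicity",
                          n_burn = 100, n_keep = 20000, seed = 12)
  incl <- posterior_inclusion_probabilities(fit)
  expect_equal(unname(incl), c(0.5, 0.5), tolerance = 0.02)
  # intercept moments match the prior within 3 Monte-Carlo SEs
  b0 <- std_prior$toxicity$b[1]; s0 <- std_prior$toxicity$sigma[1]
  mc_se <- s0 / sqrt(20000)
  expect_lt(abs(mean(fit$beta[, 1]) - b0), 3 * mc_se)
  expect_equal(sd(fit$beta[, 1]), s0, tolerance = 0.05)
})

test_that("posterior mean probabilities match a grid-quadrature oracle", {
  # two-point design, reduced toxicity model (intercept + slope): the
  # posterior is a 2-D integral we can evaluate by brute-force quadrature
  set.seed(13)
  d_pts <- c(-0.8, 0.6)
  n_per <- 25L
  y <- c(rbinom(n_per, 1, 0.25), rbinom(n_per, 1, 0.55))
  dat <- outcome_data(rep(d_pts, each = n_per), rep(0L, 2 * n_per), y)

  b <- std_prior$toxicity$b[1:2]; s <- std_prior$toxicity$sigma[1:2]
  gr <- seq(-6, 6, length.out = 161)
  g1 <- b[1] + s[1] * gr; g2 <- b[2] + s[2] * gr
  ll <- matrix(0, 161, 161)
  for (i in seq_along(g1)) {
    for (j in seq_along(g2)) {
      p1 <- plogis(g1[i] + g2[j] * d_pts[1])
      p2 <- plogis(g1[i] + g2[j] * d_pts[2])
      ll[i, j] <- sum(dbinom(y[1:n_per], 1, p1, log = TRUE)) +
        sum(dbinom(y[(n_per + 1):(2 * n_per)], 1, p2, log = TRUE)) +
        dnorm(gr[i], log = TRUE) + dnorm(gr[j], log = TRUE)
    }
  }
  w <- exp(ll - max(ll)); w <- w / sum(w)
  pi_oracle <- vapply(d_pts, function(dd) {
    pmat <- plogis(outer(g1, g2 * dd, "+"))
    sum(w * pmat)
  }, numeric(1))

  fit <- sample_posterior(dat, std_prior, "toxicity",
                          subgroup_terms = FALSE,
                          n_burn = 1000, n_keep = 8000, seed = 21)
  pi_mcmc <- predict(fit, d_pts, 0, type = "mean")
  expect_equal(unname(pi_mcmc), pi_oracle, tolerance = 0.015)
})

test_that("posterior concentrates on the truth as n grows", {
  truth <- c(-1.0, 0.9, 0, 0)
  bias_at <- function(n, seed) {
    set.seed(seed)
    d <- sample(std_grid$standardized, n, TRUE)
    k <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, toxicity_probability(truth, d, k))
    fit <- sample_posterior(outcome_data(d, k, y), std_prior, "toxicity",
                            n_burn = 500, n_keep = 2000, seed = seed + 1)
    pts <- predict(fit, std_grid$standardized, 0, type = "mean")
    mean(abs(pts - toxicity_probability(truth, std_grid$standardized,
                                        rep(0, 5))))
  }
  biases <- c(bias_at(50, 31), bias_at(500, 32), bias_at(2000, 33))
  expect_lt(biases[3], biases[1])
  expect_lt(biases[3], 0.03)
})

test_that("inclusion probabilities equal the tally of gamma draws", {
  set.seed(14)
  dat <- outcome_data(sample(std_grid$standardized, 30, TRUE),
                      rep(0:1, 15), rbinom(30, 1, 0.3))
  fit <- sample_posterior(dat, std_prior, "efficacy", n_burn = 100,
                          n_keep = 300, seed = 6)
  incl <- posterior_inclusion_probabilities(fit)
  oracle <- colSums(fit$gamma[, fit$spike_slab]) / nrow(fit$gamma)
  expect_equal(unname(incl), unname(oracle))
})

test_that("draws export to a long-format audit CSV", {
  dat <- outcome_data(c(-0.5, 0.5), c(0, 1), c(0, 1))
  fit <- sample_posterior(dat, std_prior, "toxicity", n_burn = 50,
                          n_keep = 100, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(fit, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 100 * 4)
  expect_setequal(names(tab),
                  c("draw", "model", "coefficient", "value", "included"))
})
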