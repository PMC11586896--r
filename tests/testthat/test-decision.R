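test_that("utility table fixes the anchor outcomes", {
  nu <- utility_table()
  expect_equal(unname(nu["1", "0"]), 100)
  expect_equal(unname(nu["0", "1"]), 0)
  expect_error(utility_table(nu00 = 140), "0, 100")
})

test_that("expected utility enumerates the four outcomes", {
  nu <- utility_table(nu00 = 40, nu11 = 60)
  expect_equal(expected_utility(1, 0, nu), 100)
  expect_equal(expected_utility(0, 1, nu), 0)
  # hand enumeration: .5*.8*100 + .5*.2*60 + .5*.8*40 + .5*.2*0 = 62
  expect_equal(expected_utility(0.5, 0.2, nu), 62)
  # brute-force oracle over random triples
  set.seed(15)
  for (i in 1:200) {
    pe <- runif(1); pt <- runif(1)
    nu_i <- utility_table(nu00 = runif(1, 0, 100), nu11 = runif(1, 0, 100))
    brute <- 0
    for (a in 0:1) for (b in 0:1)
      brute <- brute + nu_i[a + 1, b + 1] * pe^a * (1 - pe)^(1 - a) *
        pt^b * (1 - pt)^(1 - b)
    expect_equal(expected_utility(pe, pt, nu_i), brute, tolerance = 1e-12)
  }
})

test_that("expected utility is monotone for the standard trade-off", {
  nu <- utility_table()
  pe <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(expected_utility(pe, 0.3, nu)) > 0))
  pt <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(expected_utility(0.4, pt, nu)) < 0))
})

test_that("MAP estimate finds modes and respects draw bounds", {
  expect_equal(map_probability(rep(0.3, 200)), 0.3)
  set.seed(16)
  x <- rbeta(1e5, 20, 10)
  expect_equal(map_probability(x), 19 / 28, tolerance = 0.02)
  # bimodal: taller mode wins
  xm <- c(rnorm(3000, 0.25, 0.03), rnorm(1500, 0.7, 0.03))
  xm <- pmin(pmax(xm, 0), 1)
  expect_equal(map_probability(xm), 0.25, tolerance = 0.03)
  expect_error(map_probability(runif(50)), "insufficient-draws")
  for (i in 1:10) {
    p <- rbeta(500, runif(1, 0.5, 5), runif(1, 0.5, 5))
    m <- map_probability(p)
    expect_gte(m, min(p)); expect_lte(m, max(p))
  }
})

test_that("admissibility matches a direct counting oracle", {
  set.seed(17)
  M <- 1000; J <- 5
  pe <- matrix(rbeta(M * J, 2, 2), M, J)
  pt <- matrix(rbeta(M * J, 1.5, 4), M, J)
  for (i in 1:50) {
    th <- decision_thresholds(pi_T_bar = runif(1, 0.2, 0.6),
                              pi_E_floor = runif(1, 0.1, 0.5),
                              p_T = runif(1, 0.05, 0.5),
                              p_E = runif(1, 0.05, 0.5))
    tried <- sort(sample(J, sample(0:J, 1)))
    final <- runif(1) < 0.5
    adm <- admissible_doses(pe, pt, th, tried = tried, final = final)
    for (j in 1:J) {
      c1 <- sum(pt[, j] < th$pi_T_bar) / M > th$p_T
      c2a <- (sum(pe[, j] > th$pi_E_floor) / M > th$p_E) && (j %in% tried)
      c2b <- !final &&
        j == (if (length(tried)) max(tried) else 0L) + 1L
      expect_identical(adm$admissible[j], c1 && (c2a || c2b))
    }
  }
})

test_that("admissibility tightens as evidence requirements rise", {
  set.seed(18)
  pe <- matrix(rbeta(500 * 5, 2, 2), 500, 5)
  pt <- matrix(rbeta(500 * 5, 1.5, 4), 500, 5)
  tried <- 1:3
  lax <- admissible_doses(pe, pt, decision_thresholds(p_T = 0.05, p_E = 0.05),
                          tried = tried)
  strict <- admissible_doses(pe, pt,
                             decision_thresholds(p_T = 0.6, p_E = 0.6),
                             tried = tried)
  expect_true(all(strict$admissible <= lax$admissible))
  # final set is a subset of the during-trial set
  fin <- admissible_doses(pe, pt, decision_thresholds(), tried = tried,
                          final = TRUE)
  dur <- admissible_doses(pe, pt, decision_thresholds(), tried = tried,
                          final = FALSE)
  expect_true(all(fin$admissible <= dur$admissible))
})

test_that("escalation condition only opens the next untried level", {
  M <- 200
  pe <- matrix(0.9, M, 5); pt <- matrix(0.05, M, 5)
  adm <- admissible_doses(pe, pt, decision_thresholds(), tried = 1:2)
  # dose 3 admissible via 2b; doses 4-5 untried and beyond next level
  expect_true(adm$admissible[3])
  expect_false(adm$admissible[4])
  expect_false(adm$admissible[5])
  # at the final analysis the untried dose 3 is no longer admissible
  fin <- admissible_doses(pe, pt, decision_thresholds(), tried = 1:2,
                          final = TRUE)
  expect_false(fin$admissible[3])
  expect_true(all(fin$admissible[1:2]))
})

test_that("dose selection maximizes utility with low-dose tie-breaking", {
  expect_identical(select_dose(c(10, 20, 30), integer()), NA_integer_)
  expect_identical(select_dose(c(10, 20, 30), 2L), 2L)
  expect_identical(select_dose(c(10, 50, 50, 20), c(2L, 3L)), 2L)
  expect_identical(select_dose(c(10, 50, 60, 20), c(2L, 3L)), 3L)
})

test_that("final OBD selection declares none when nothing qualifies", {
  set.seed(19)
  dat_T <- outcome_data(rep(std_grid$standardized[1:2], each = 10),
                        rep(0:1, 10), rbinom(20, 1, 0.9))
  dat_E <- outcome_data(rep(std_grid$standardized[1:2], each = 10),
                        rep(0:1, 10), rbinom(20, 1, 0.5))
  fit_E <- sample_posterior(dat_E, std_prior, "efficacy", n_burn = 200,
                            n_keep = 500, seed = 8)
  fit_T <- sample_posterior(dat_T, std_prior, "toxicity", n_burn = 200,
                            n_keep = 500, seed = 9)
  obd <- select_obd(fit_E, fit_T, std_grid, decision_thresholds(),
                    tried = list(1:2, 1:2))
  expect_true(all(is.na(obd)))
})
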