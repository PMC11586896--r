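test_that("run-in escalation rule tallies DLTs as specified", {
  esc <- obdsub:::run_in_escalate
  # zero DLTs at the current dose: escalate at any count
  expect_true(esc(2L, 0L))
  expect_true(esc(6L, 0L))
  # one DLT: escalation requires six treated at the current dose
  expect_false(esc(2L, 1L))
  expect_false(esc(5L, 1L))
  expect_true(esc(6L, 1L))
  expect_true(esc(8L, 1L))
  # two or more DLTs: never escalate during run-in
  expect_false(esc(6L, 2L))
  expect_false(esc(12L, 2L))
})

test_that("run-in starts at the lowest dose with both subgroups together", {
  scn <- scenario(pi_E = matrix(0.5, 5, 2), pi_T = matrix(0, 5, 2))
  cfg <- short_config()
  res <- run_trial(cfg, scn, seed = 31)
  p <- res$participants
  run_in <- p[p$cohort <= 3, ]
  expect_equal(sort(unique(run_in$cohort)), 1:3)
  # cohort 1 at dose 1; toxicity-free outcomes escalate one level per cohort
  expect_true(all(run_in$dose[run_in$cohort == 1] == 1))
  expect_true(all(run_in$dose[run_in$cohort == 2] == 2))
  expect_true(all(run_in$dose[run_in$cohort == 3] == 3))
  # paired composition: one participant per subgroup per cohort
  for (co in 1:3)
    expect_equal(sort(run_in$k[run_in$cohort == co]), c(0, 1))
})

test_that("run-in never escalates past a toxic dose", {
  scn <- scenario(pi_E = matrix(0.5, 5, 2),
                  pi_T = matrix(c(0, 1), 5, 2, byrow = FALSE))
  # subgroup 0 never has DLTs, subgroup 1 always does -> 2 DLTs at dose 1
  # in cohort 1 blocks escalation for every later run-in cohort
  res <- run_trial(short_config(), scn, seed = 32)
  run_in <- res$participants[res$participants$cohort <= 3, ]
  expect_true(all(run_in$dose == 1))
})

test_that("trials are deterministic given the seed and respect caps", {
  suite <- build_scenario_suite(std_grid)
  cfg <- short_config()
  r1 <- run_trial(cfg, suite$s6, seed = 33)
  r2 <- run_trial(cfg, suite$s6, seed = 33)
  expect_identical(r1$participants, r2$participants)
  expect_identical(r1$obd, r2$obd)
  expect_lte(nrow(r1$participants), 60L)
  expect_lte(sum(r1$participants$k == 0), 30L)
  expect_lte(sum(r1$participants$k == 1), 30L)
  # counts bookkeeping sums to enrollment
  expect_equal(sum(r1$counts[, , "n"]), nrow(r1$participants))
})

test_that("dose assignments never skip above one level past the tried set", {
  suite <- build_scenario_suite(std_grid)
  for (seed in 34:36) {
    res <- run_trial(short_config(), suite$s4, seed = seed)
    p <- res$participants
    for (k in 0:1) {
      doses <- p$dose[p$k == k]
      seen <- integer()
      for (j in doses) {
        expect_lte(j, max(c(seen, 0L)) + 1L)
        seen <- union(seen, j)
      }
    }
  }
})

test_that("an all-toxic truth stops the trial with no OBD", {
  scn <- scenario_all_toxic(std_grid, p_tox = 0.85)
  res <- run_trial(short_config(), scn, seed = 37)
  expect_true(all(is.na(res$obd)))
  expect_lt(nrow(res$participants), 60L)
})

test_that("cold start without run-in still begins at the lowest dose", {
  scn <- scenario(pi_E = matrix(0.6, 5, 2), pi_T = matrix(0.05, 5, 2))
  cfg <- short_config(run_in = FALSE)
  res <- run_trial(cfg, scn, seed = 38)
  first <- res$participants[res$participants$cohort == 1, ]
  expect_true(all(first$dose == 1L))
})

test_that("pooled design selects a single common OBD", {
  suite <- build_scenario_suite(std_grid)
  res <- run_trial(short_config("pooled"), suite$s1, seed = 39)
  expect_equal(res$obd[1], res$obd[2])
})

test_that("independent design never uses cross-subgroup data", {
  suite <- build_scenario_suite(std_grid)
  scn <- suite$s2
  # altering the other subgroup's truth must leave a subgroup's trial
  # untouched: each single-subgroup trial runs from its own subseed and
  # only reads its own scenario column
  scn_mod <- scn
  scn_mod$pi_E[, 1] <- rev(scn$pi_E[, 1])
  scn_mod$pi_T[, 1] <- c(0.9, 0.9, 0.9, 0.9, 0.9)
  cfg <- short_config("independent")
  r_orig <- run_trial(cfg, scn, seed = 40)
  r_mod <- run_trial(cfg, scn_mod, seed = 40)
  p1_orig <- r_orig$participants[r_orig$participants$k == 1, -1]
  p1_mod <- r_mod$participants[r_mod$participants$k == 1, -1]
  expect_equal(p1_orig$dose, p1_mod$dose)
  expect_equal(p1_orig$y_T, p1_mod$y_T)
  expect_equal(r_orig$obd[2], r_mod$obd[2])
})

test_that("decision log records utilities and admissibility when asked", {
  suite <- build_scenario_suite(std_grid)
  res <- run_trial(short_config(log_decisions = TRUE), suite$s6, seed = 41)
  expect_false(is.null(res$decisions))
  expect_setequal(names(res$decisions),
                  c("cohort", "subgroup", "dose", "utility", "admissible",
                    "chosen"))
  # chosen doses were admissible at the time
  expect_true(all(res$decisions$admissible[res$decisions$chosen]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_decisions_csv(res, path)
  expect_true(file.exists(path))
})

test_that("trial configuration round-trips through YAML", {
  cfg <- trial_config(std_grid, std_prior, design = "pooled",
                      run_in_cohorts = 4L, n_burn = 123L, n_keep = 456L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trial_config(cfg, path)
  back <- read_trial_config(path)
  expect_equal(back$grid$raw, cfg$grid$raw)
  expect_equal(back$prior$efficacy, cfg$prior$efficacy, tolerance = 1e-9)
  expect_equal(back$design, "pooled")
  expect_equal(back$n_keep, 456L)
  expect_equal(back$thresholds, cfg$thresholds)
})
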