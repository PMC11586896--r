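#' Trial configuration
#'
#' Bundles everything needed to run one trial: the dose grid, calibrated
#' prior, decision thresholds, utility table, design variant, enrollment
#' caps, run-in settings and MCMC lengths.
#'
#' @param grid a \code{\link{dose_grid}}.
#' @param prior a \code{\link{prior_spec}}.
#' @param thresholds a \code{\link{decision_thresholds}}.
#' @param nu a \code{\link{utility_table}}.
#' @param design \code{"proposed"} (subgroup-aware spike-and-slab
#'   models), \code{"pooled"} (subgroups ignored: reduced models on
#'   combined data, one OBD for both subgroups) or \code{"independent"}
#'   (two disjoint single-subgroup trials with reduced models).
#' @param max_per_subgroup maximum participants per subgroup (total cap
#'   is twice this).
#' @param run_in enable the rule-based run-in.
#' @param run_in_cohorts number of run-in cohorts before model-based
#'   assignment takes over.
#' @param cohort_composition \code{"paired"} enrolls one participant
#'   from each subgroup per cohort; \code{"unrestricted"} draws subgroup
#'   labels i.i.d. Bernoulli(0.5).
#' @param pool_tried if \code{TRUE} the escalation condition (2b) uses
#'   the union of tried doses across subgroups; default keeps a
#'   per-subgroup tried set.
#' @param n_burn,n_keep MCMC burn-in and retained draws per model refit.
#' @param estimator point estimate of the outcome probabilities plugged
#'   into the utility: kernel-density \code{"map"} (default) or the
#'   posterior \code{"mean"}.
#' @param admissibility if \code{FALSE} (ablation for sensitivity
#'   analysis), the posterior safety and efficacy conditions are
#'   disabled: every dose up to one level above the highest tried dose
#'   is assignable and the utility-maximizing one is chosen.  Used to
#'   quantify how much the admissibility rules curb overdosing.
#' @param log_decisions keep a per-cohort record of utilities,
#'   admissibility flags and the chosen dose.
#' @return object of class \code{trial_config}.
#' @export
trial_config <- function(grid, prior,
                         thresholds = decision_thresholds(),
                         nu = utility_table(),
                         design = c("proposed", "pooled", "independent"),
                         max_per_subgroup = 30L,
                         run_in = TRUE, run_in_cohorts = 3L,
                         cohort_composition = c("paired", "unrestricted"),
                         pool_tried = FALSE,
                         n_burn = 5000L, n_keep = 15000L,
                         estimator = c("map", "mean"),
                         admissibility = TRUE,
                         log_decisions = FALSE) {
  structure(list(grid = grid, prior = prior, thresholds = thresholds,
                 nu = nu, design = match.arg(design),
                 max_per_subgroup = as.integer(max_per_subgroup),
                 run_in = isTRUE(run_in),
                 run_in_cohorts = as.integer(run_in_cohorts),
                 cohort_composition = match.arg(cohort_composition),
                 pool_tried = isTRUE(pool_tried),
                 n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
                 estimator = match.arg(estimator),
                 admissibility = isTRUE(admissibility),
                 log_decisions = isTRUE(log_decisions)),
            class = "trial_config")
}

new_fit_seed <- function() sample.int(2147483646L, 1L)

# run-in escalation rule: escalate one level when no DLTs have been seen
# at the current dose, or when at least six have been treated there with
# at most one DLT
run_in_escalate <- function(n_cur, dlt_cur) {
  dlt_cur == 0L || (n_cur >= 6L && dlt_cur <= 1L)
}

# draw this cohort's subgroup labels among the enrollable subgroups
cohort_labels <- function(enrollable, composition) {
  if (length(enrollable) == 0L) return(integer())
  if (length(enrollable) == 1L) return(enrollable)
  if (composition == "paired") c(0L, 1L)
  else as.integer(stats::runif(2L) < 0.5)
}

# mutable enrollment record kept in parallel vectors (appending rows to a
# data frame is too slow for simulation studies)
new_state <- function() {
  env <- new.env(parent = emptyenv())
  env$cohort <- integer(); env$k <- integer(); env$dose <- integer()
  env$y_E <- integer(); env$y_T <- integer()
  env$tried <- list(integer(), integer())
  env
}

enroll_one <- function(state, scn, cohort, k, j) {
  y <- draw_outcomes(scn, j, k)
  m <- length(state$cohort) + 1L
  state$cohort[m] <- cohort; state$k[m] <- k; state$dose[m] <- j
  state$y_E[m] <- y[["y_E"]]; state$y_T[m] <- y[["y_T"]]
  if (!(j %in% state$tried[[k + 1L]]))
    state$tried[[k + 1L]] <- sort(c(state$tried[[k + 1L]], j))
  invisible(state)
}

state_df <- function(state) {
  data.frame(id = seq_along(state$cohort), cohort = state$cohort,
             k = state$k, dose = state$dose,
             y_E = state$y_E, y_T = state$y_T)
}

fit_both_models <- function(state, config, subgroup_terms) {
  d <- config$grid$standardized[state$dose]
  list(E = sample_posterior(outcome_data(d, state$k, state$y_E),
                            config$prior, "efficacy",
                            subgroup_terms = subgroup_terms,
                            n_burn = config$n_burn, n_keep = config$n_keep,
                            seed = new_fit_seed()),
       T = sample_posterior(outcome_data(d, state$k, state$y_T),
                            config$prior, "toxicity",
                            subgroup_terms = subgroup_terms,
                            n_burn = config$n_burn, n_keep = config$n_keep,
                            seed = new_fit_seed()))
}

# per-subgroup decision quantities from one pair of fits; computes the
# probability draws once and reuses them for admissibility and utilities
subgroup_decision <- function(fits, grid, thresholds, nu, tried, k,
                              final = FALSE, estimator = "map",
                              rules = TRUE) {
  pe <- predict(fits$E, grid$standardized, k)
  pt <- predict(fits$T, grid$standardized, k)
  adm <- admissible_doses(pe, pt, thresholds, tried = tried, final = final)
  if (!rules) {
    j <- adm$dose
    max_tried <- if (length(tried)) max(tried) else 0L
    adm$admissible <- if (final) j %in% tried else j <= max_tried + 1L
  }
  util <- if (estimator == "mean")
    expected_utility(colMeans(pe), colMeans(pt), nu)
  else expected_utility(.map_kde_cpp(pe), .map_kde_cpp(pt), nu)
  list(adm = adm, util = util,
       pick = select_dose(util, adm$dose[adm$admissible]))
}

#' Run one simulated trial
#'
#' Conducts a complete trial against a scenario's true outcome
#' probabilities: rule-based run-in (both subgroups share a dose, first
#' cohort at the lowest dose, escalation by at most one level per cohort
#' and only while DLT counts permit), then model-based assignment in
#' cohorts with both posteriors refit on all accumulated data before
#' every cohort, per-subgroup admissible sets, utility-maximizing dose
#' assignment, closing/reopening of subgroups, and final OBD selection.
#' The trial ends early when neither subgroup has an admissible dose.
#' With the run-in disabled, the empty tried set makes the lowest dose
#' the only dose satisfying the escalation condition, so the first
#' model-based cohort still starts at the bottom of the grid.
#'
#' @param config a \code{\link{trial_config}}.
#' @param scn an \code{\link{scenario}}.
#' @param seed RNG seed; trials are deterministic given the seed.
#' @return object of class \code{trial_result}: participant-level data,
#'   per-subgroup selected OBD (\code{NA} = none declared), tried sets,
#'   stopping reason and (optionally) the decision log.
#' @export
run_trial <- function(config, scn, seed = 1L) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  if (config$design == "independent") run_trial_independent(config, scn)
  else run_trial_joint(config, scn)
}

run_trial_joint <- function(config, scn) {
  grid <- config$grid
  J <- length(grid)
  with_subgroup <- config$design == "proposed"
  pooled <- config$design == "pooled"
  state <- new_state()
  decisions <- list()
  cohort <- 0L
  stop_reason <- "max-enrollment"
  n_k <- function(k) sum(state$k == k)
  under_cap <- function() which(c(n_k(0L), n_k(1L)) <
                                  config$max_per_subgroup) - 1L

  # ---- rule-based run-in: shared dose, start at the lowest level ----
  j_cur <- 1L
  if (config$run_in) {
    for (rc in seq_len(config$run_in_cohorts)) {
      cohort <- cohort + 1L
      for (k in cohort_labels(under_cap(), config$cohort_composition))
        enroll_one(state, scn, cohort, k, j_cur)
      at_cur <- state$dose == j_cur
      if (j_cur < J &&
          run_in_escalate(sum(at_cur), sum(state$y_T[at_cur])))
        j_cur <- j_cur + 1L
    }
  }

  # ---- model-based assignment ----
  repeat {
    if (length(under_cap()) == 0L) break
    fits <- fit_both_models(state, config, with_subgroup)
    tried_eff <- if (config$pool_tried || pooled) {
      both <- sort(unique(c(state$tried[[1L]], state$tried[[2L]])))
      list(both, both)
    } else state$tried
    dec0 <- subgroup_decision(fits, grid, config$thresholds, config$nu,
                              tried_eff[[1L]], k = 0L,
                              estimator = config$estimator,
                              rules = config$admissibility)
    dec <- list(dec0, if (pooled) dec0 else
      subgroup_decision(fits, grid, config$thresholds, config$nu,
                        tried_eff[[2L]], k = 1L,
                        estimator = config$estimator,
                        rules = config$admissibility))
    pick <- c(dec[[1L]]$pick, dec[[2L]]$pick)
    if (all(is.na(pick))) { stop_reason <- "no-acceptable-dose"; break }

    enrollable <- intersect(which(!is.na(pick)) - 1L, under_cap())
    if (length(enrollable) == 0L) break
    cohort <- cohort + 1L
    labels <- cohort_labels(enrollable, config$cohort_composition)
    for (k in labels) enroll_one(state, scn, cohort, k, pick[k + 1L])
    if (config$log_decisions)
      decisions[[length(decisions) + 1L]] <- data.frame(
        cohort = cohort, subgroup = rep(0:1, each = J),
        dose = rep(seq_len(J), 2L),
        utility = c(dec[[1L]]$util, dec[[2L]]$util),
        admissible = c(dec[[1L]]$adm$admissible, dec[[2L]]$adm$admissible),
        chosen = c(pick[1L] == seq_len(J) & 0L %in% labels,
                   pick[2L] == seq_len(J) & 1L %in% labels))
  }

  # ---- final analysis ----
  obd <- c(NA_integer_, NA_integer_)
  if (length(state$cohort) > 0L && stop_reason != "no-acceptable-dose") {
    fits <- fit_both_models(state, config, with_subgroup)
    tried_fin <- if (pooled) {
      both <- sort(unique(c(state$tried[[1L]], state$tried[[2L]])))
      list(both, both)
    } else state$tried
    fin0 <- subgroup_decision(fits, grid, config$thresholds, config$nu,
                              tried_fin[[1L]], k = 0L, final = TRUE,
                              estimator = config$estimator,
                              rules = config$admissibility)
    fin1 <- if (pooled) fin0 else
      subgroup_decision(fits, grid, config$thresholds, config$nu,
                        tried_fin[[2L]], k = 1L, final = TRUE,
                        estimator = config$estimator,
                        rules = config$admissibility)
    obd <- c(fin0$pick, fin1$pick)
  }

  trial_result(state_df(state), obd, stop_reason, state$tried, config, scn,
               decisions = if (length(decisions))
                 do.call(rbind, decisions) else NULL)
}

run_trial_independent <- function(config, scn) {
  # each subgroup's trial runs from its own derived seed, so neither
  # depends on the other's data or random draws in any way
  subseeds <- sample.int(2147483646L, 2L)
  sub <- lapply(0:1, function(k) {
    old <- .Random.seed_guard(subseeds[k + 1L])
    on.exit(old(), add = TRUE)
    run_single_subgroup(config, scn, k)
  })
  parts <- rbind(sub[[1L]]$participants, sub[[2L]]$participants)
  parts$id <- seq_len(nrow(parts))
  trial_result(parts,
               obd = c(sub[[1L]]$obd, sub[[2L]]$obd),
               stop_reason = paste0("k0:", sub[[1L]]$stop_reason,
                                    ";k1:", sub[[2L]]$stop_reason),
               tried = list(sub[[1L]]$tried, sub[[2L]]$tried),
               config, scn, decisions = NULL)
}

# one subgroup's trial under the independent design: reduced models,
# cohorts of two from the same subgroup, per-subgroup cap
run_single_subgroup <- function(config, scn, k) {
  grid <- config$grid
  J <- length(grid)
  state <- new_state()
  cohort <- 0L
  stop_reason <- "max-enrollment"

  j_cur <- 1L
  if (config$run_in) {
    for (rc in seq_len(config$run_in_cohorts)) {
      cohort <- cohort + 1L
      enroll_one(state, scn, cohort, k, j_cur)
      enroll_one(state, scn, cohort, k, j_cur)
      at_cur <- state$dose == j_cur
      if (j_cur < J &&
          run_in_escalate(sum(at_cur), sum(state$y_T[at_cur])))
        j_cur <- j_cur + 1L
    }
  }

  repeat {
    if (length(state$cohort) >= config$max_per_subgroup) break
    fits <- fit_both_models(state, config, subgroup_terms = FALSE)
    dec <- subgroup_decision(fits, grid, config$thresholds, config$nu,
                             state$tried[[k + 1L]], k = k,
                             estimator = config$estimator,
                             rules = config$admissibility)
    if (is.na(dec$pick)) { stop_reason <- "no-acceptable-dose"; break }
    cohort <- cohort + 1L
    n_cohort <- min(2L, config$max_per_subgroup - length(state$cohort))
    for (i in seq_len(n_cohort))
      enroll_one(state, scn, cohort, k, dec$pick)
  }

  obd <- NA_integer_
  if (length(state$cohort) > 0L && stop_reason != "no-acceptable-dose") {
    fits <- fit_both_models(state, config, subgroup_terms = FALSE)
    fin <- subgroup_decision(fits, grid, config$thresholds, config$nu,
                             state$tried[[k + 1L]], k = k, final = TRUE,
                             estimator = config$estimator,
                             rules = config$admissibility)
    obd <- fin$pick
  }
  list(participants = state_df(state), obd = obd,
       stop_reason = stop_reason, tried = state$tried[[k + 1L]])
}

trial_result <- function(parts, obd, stop_reason, tried, config, scn,
                         decisions = NULL) {
  J <- length(config$grid)
  counts <- array(0L, dim = c(J, 2L, 3L),
                  dimnames = list(paste0("dose", seq_len(J)), c("k0", "k1"),
                                  c("n", "responses", "dlts")))
  for (kk in 1:2) {
    sel <- parts$k == kk - 1L
    counts[, kk, "n"] <- tabulate(parts$dose[sel], J)
    counts[, kk, "responses"] <- tabulate(parts$dose[sel & parts$y_E == 1L], J)
    counts[, kk, "dlts"] <- tabulate(parts$dose[sel & parts$y_T == 1L], J)
  }
  structure(list(participants = parts, obd = obd, stop_reason = stop_reason,
                 tried = tried, counts = counts, design = config$design,
                 scenario = scn$name, decisions = decisions),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Trial result (", x$design, " design, scenario ", x$scenario, ")\n",
      sep = "")
  cat("  enrolled:", nrow(x$participants),
      sprintf("(k0: %d, k1: %d)", sum(x$participants$k == 0),
              sum(x$participants$k == 1)), "\n")
  cat("  selected OBD: k0 =", ifelse(is.na(x$obd[1]), "none", x$obd[1]),
      ", k1 =", ifelse(is.na(x$obd[2]), "none", x$obd[2]), "\n")
  cat("  stop reason:", x$stop_reason, "\n")
  invisible(x)
}

#' @export
summary.trial_result <- function(object, ...) {
  tab <- cbind(as.data.frame.table(object$counts[, , "n"],
                                   responseName = "n"),
               responses = as.vector(object$counts[, , "responses"]),
               dlts = as.vector(object$counts[, , "dlts"]))
  names(tab)[1:2] <- c("dose", "subgroup")
  tab
}

#' Write the participant-level record of a trial
#'
#' @param result a \code{trial_result}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
write_participants_csv <- function(result, path) {
  utils::write.csv(result$participants, path, row.names = FALSE)
  invisible(path)
}

#' Write the decision log of a trial
#'
#' Requires the trial to have been run with \code{log_decisions = TRUE}
#' in its configuration.
#'
#' @param result a \code{trial_result}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
write_decisions_csv <- function(result, path) {
  if (is.null(result$decisions))
    stop("trial was run without log_decisions = TRUE", call. = FALSE)
  utils::write.csv(result$decisions, path, row.names = FALSE)
  invisible(path)
}
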