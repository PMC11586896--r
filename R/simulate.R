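#' Run a simulation study over scenarios and design variants
#'
#' Replicates the operating-characteristics comparison: for each
#' (scenario, design) pair, \code{n_reps} independent trials are run with
#' per-replicate seeds derived reproducibly from \code{base_seed}, and
#' per-trial outcomes (selected OBDs, enrollment, overdose and DLT
#' counts) are collected.  The pooled design selects one common OBD from
#' combined data; the independent design runs two disjoint
#' single-subgroup trials and never uses cross-subgroup data.
#'
#' @param scenarios named list of \code{\link{scenario}} objects.
#' @param designs character vector among \code{"proposed"},
#'   \code{"pooled"}, \code{"independent"}.
#' @param n_reps replicates per scenario and design.
#' @param base_seed integer; all replicate seeds derive from it.
#' @param config_args list of arguments passed on to
#'   \code{\link{trial_config}} (e.g. shortened \code{n_burn} /
#'   \code{n_keep} for large studies); \code{grid} and \code{prior} are
#'   required unless defaults are wanted.
#' @param grid,prior,thresholds,nu shared trial components; a calibrated
#'   prior is built from the default elicitation when \code{prior} is
#'   missing.
#' @param cores number of worker processes (forked; replicate-level,
#'   order-independent aggregation).
#' @return object of class \code{oc_study} with the per-trial table and
#'   study metadata; summarize with \code{\link{tabulate_oc}}.
#' @export
run_study <- function(scenarios, designs = c("proposed", "pooled",
                                             "independent"),
                      n_reps = 100L, base_seed = 1L,
                      grid = dose_grid(c(0.2, 0.4, 0.6, 0.8, 1)),
                      prior = NULL,
                      thresholds = decision_thresholds(),
                      nu = utility_table(),
                      config_args = list(), cores = 1L) {
  if (is.null(prior))
    prior <- calibrate_prior(default_elicitation(length(grid)), grid,
                             seed = 104729L)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, "", "name")
  jobs <- expand.grid(scenario = names(scenarios), design = designs,
                      rep = seq_len(n_reps), stringsAsFactors = FALSE)
  old <- .Random.seed_guard(base_seed)
  on.exit(old(), add = TRUE)
  # common random numbers: one seed per (scenario, replicate), shared by
  # all designs, so design contrasts are paired comparisons
  key <- expand.grid(scenario = names(scenarios), rep = seq_len(n_reps),
                     stringsAsFactors = FALSE)
  key$seed <- sample.int(2147483646L, nrow(key))
  jobs$seed <- key$seed[match(paste(jobs$scenario, jobs$rep),
                              paste(key$scenario, key$rep))]

  run_one <- function(i) {
    cfg <- do.call(trial_config,
                   c(list(grid = grid, prior = prior,
                          thresholds = thresholds, nu = nu,
                          design = jobs$design[i]),
                     config_args))
    scn <- scenarios[[jobs$scenario[i]]]
    res <- run_trial(cfg, scn, seed = jobs$seed[i])
    trial_metrics(res, scn, thresholds, nu)
  }
  rows <- if (cores > 1L)
    parallel::mclapply(seq_len(nrow(jobs)), run_one, mc.cores = cores)
  else lapply(seq_len(nrow(jobs)), run_one)

  trials <- cbind(jobs[c("scenario", "design", "rep")],
                  do.call(rbind, rows))
  structure(list(trials = trials, scenarios = scenarios,
                 designs = designs, n_reps = n_reps,
                 J = length(grid), base_seed = base_seed,
                 thresholds = thresholds, nu = nu),
            class = "oc_study")
}

default_elicitation <- function(J = 5L) {
  stopifnot(J == 5L)
  elicitation_target(pi_E = c(0.3, 0.5, 0.6, 0.65, 0.7),
                     pi_T = c(0.05, 0.1, 0.15, 0.2, 0.25),
                     ess = 0.9)
}

# per-trial operating-characteristic contributions; "overdose" counts
# assignments to doses whose true toxicity probability is at or above
# the toxicity cap for the participant's subgroup
trial_metrics <- function(res, scn, thresholds, nu) {
  tob <- true_obd(scn, nu, thresholds)
  p <- res$participants
  per_k <- lapply(0:1, function(k) {
    pk <- p[p$k == k, , drop = FALSE]
    toxic <- scn$pi_T[pk$dose, k + 1L] >= thresholds$pi_T_bar
    at_obd <- if (is.na(tob[k + 1L])) 0L else sum(pk$dose == tob[k + 1L])
    data.frame(n = nrow(pk), at_obd = at_obd, overdosed = sum(toxic),
               dlts = sum(pk$y_T))
  })
  data.frame(obd0 = res$obd[1L], obd1 = res$obd[2L],
             true_obd0 = tob[1L], true_obd1 = tob[2L],
             n0 = per_k[[1L]]$n, n1 = per_k[[2L]]$n,
             at_obd0 = per_k[[1L]]$at_obd, at_obd1 = per_k[[2L]]$at_obd,
             overdosed0 = per_k[[1L]]$overdosed,
             overdosed1 = per_k[[2L]]$overdosed,
             dlts = per_k[[1L]]$dlts + per_k[[2L]]$dlts,
             n = nrow(p))
}

#' Tabulate operating characteristics
#'
#' Aggregates a study into the standard operating-characteristic tables:
#' the per-dose OBD selection distribution (with \code{"none"} for no
#' declared OBD), percent correct selection (PCS; selecting \code{none}
#' counts as correct when no dose is truly acceptable), the probability
#' that both subgroups' OBDs are correct, the probability the two
#' selected OBDs differ, and mean enrollment, participants at the true
#' OBD, overdose and DLT summaries.  Binomial standard errors accompany
#' every proportion.
#'
#' @param study an \code{oc_study}.
#' @return list with data frames \code{selection} (scenario x design x
#'   subgroup x dose) and \code{summary} (scenario x design x subgroup),
#'   plus \code{pairwise} (scenario x design: both-correct and
#'   differing-OBD probabilities).
#' @export
tabulate_oc <- function(study) {
  tr <- study$trials
  J <- study$J
  lev <- c("none", as.character(seq_len(J)))
  key <- interaction(tr$scenario, tr$design, drop = TRUE)
  sel <- list(); smry <- list(); pair <- list()
  for (g in levels(key)) {
    sub <- tr[key == g, , drop = FALSE]
    m <- nrow(sub)
    scn <- sub$scenario[1L]; des <- sub$design[1L]
    for (k in 0:1) {
      obd <- sub[[paste0("obd", k)]]
      tob <- sub[[paste0("true_obd", k)]][1L]
      chosen <- factor(ifelse(is.na(obd), "none", obd), levels = lev)
      prop <- as.vector(table(chosen)) / m
      sel[[length(sel) + 1L]] <- data.frame(
        scenario = scn, design = des, subgroup = k, dose = lev,
        selection_prob = prop,
        se = sqrt(prop * (1 - prop) / m))
      correct <- if (is.na(tob)) is.na(obd) else !is.na(obd) & obd == tob
      pcs <- mean(correct)
      smry[[length(smry) + 1L]] <- data.frame(
        scenario = scn, design = des, subgroup = k, true_obd = tob,
        pcs = pcs, pcs_se = sqrt(pcs * (1 - pcs) / m),
        mean_n = mean(sub[[paste0("n", k)]]),
        mean_at_obd = mean(sub[[paste0("at_obd", k)]]),
        mean_overdosed = mean(sub[[paste0("overdosed", k)]]))
    }
    corr0 <- correct_vec(sub$obd0, sub$true_obd0[1L])
    corr1 <- correct_vec(sub$obd1, sub$true_obd1[1L])
    both <- mean(corr0 & corr1)
    differ <- mean(!is.na(sub$obd0) & !is.na(sub$obd1) &
                     sub$obd0 != sub$obd1 |
                     xor(is.na(sub$obd0), is.na(sub$obd1)))
    pair[[length(pair) + 1L]] <- data.frame(
      scenario = scn, design = des,
      both_correct = both, both_correct_se = sqrt(both * (1 - both) / m),
      differing_obd = differ,
      mean_n = mean(sub$n),
      mean_dlt_prop = mean(sub$dlts / pmax(sub$n, 1L)))
  }
  list(selection = do.call(rbind, sel),
       summary = do.call(rbind, smry),
       pairwise = do.call(rbind, pair))
}

correct_vec <- function(obd, tob) {
  if (is.na(tob)) is.na(obd) else !is.na(obd) & obd == tob
}

#' @export
print.oc_study <- function(x, ...) {
  cat("Operating-characteristics study: ", length(x$scenarios),
      " scenario(s) x ", length(x$designs), " design(s) x ", x$n_reps,
      " replicate(s)\n", sep = "")
  tab <- tabulate_oc(x)
  print(tab$pairwise, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot OBD selection distributions
#'
#' Grouped barplot of the per-dose selection proportions for each design,
#' one panel per subgroup, for a single scenario (the layout of the
#' standard operating-characteristics figure).
#'
#' @param x an \code{oc_study}.
#' @param scenario scenario name to plot (default: first).
#' @param ... passed to \code{barplot}.
#' @return invisibly, the selection table of the plotted scenario.
#' @export
plot.oc_study <- function(x, scenario = NULL, ...) {
  sel <- tabulate_oc(x)$selection
  scenario <- scenario %||% sel$scenario[1L]
  sel <- sel[sel$scenario == scenario, ]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)
  for (k in 0:1) {
    sk <- sel[sel$subgroup == k, ]
    m <- do.call(rbind, lapply(split(sk$selection_prob, sk$design),
                               as.vector))
    colnames(m) <- unique(sk$dose)
    graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                      legend.text = rownames(m),
                      main = paste0("scenario ", scenario, ", subgroup ", k),
                      xlab = "selected OBD (none = no dose acceptable)",
                      ylab = "selection proportion", ...)
  }
  invisible(sel)
}

#' Write tidy operating characteristics to CSV
#'
#' @param study an \code{oc_study}.
#' @param path output CSV (selection table; the summary table is written
#'   alongside with suffix \code{_summary}).
#' @return \code{path}, invisibly.
#' @export
write_oc_csv <- function(study, path) {
  tab <- tabulate_oc(study)
  utils::write.csv(tab$selection, path, row.names = FALSE)
  utils::write.csv(merge(tab$summary, tab$pairwise,
                         by = c("scenario", "design")),
                   sub("\\.csv$", "_summary.csv", path), row.names = FALSE)
  invisible(path)
}
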