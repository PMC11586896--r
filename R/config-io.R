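#' Serialize and restore a trial configuration
#'
#' A trial is fully reproducible from one YAML file: raw doses, decision
#' thresholds, the utility table's free values, every prior
#' hyperparameter, and the engine settings.
#'
#' @param config a \code{\link{trial_config}}.
#' @param path YAML file path.
#' @return \code{write_trial_config} returns \code{path} invisibly;
#'   \code{read_trial_config} returns a \code{trial_config}.
#' @export
write_trial_config <- function(config, path) {
  obj <- list(
    raw_doses = config$grid$raw,
    thresholds = unclass(config$thresholds),
    utility = list(nu00 = unname(config$nu["0", "0"]),
                   nu11 = unname(config$nu["1", "1"])),
    prior = list(efficacy = as.list(config$prior$efficacy),
                 toxicity = as.list(config$prior$toxicity)),
    design = config$design,
    max_per_subgroup = config$max_per_subgroup,
    run_in = config$run_in,
    run_in_cohorts = config$run_in_cohorts,
    cohort_composition = config$cohort_composition,
    pool_tried = config$pool_tried,
    n_burn = config$n_burn, n_keep = config$n_keep)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_trial_config
#' @export
read_trial_config <- function(path) {
  obj <- yaml::read_yaml(path)
  as_df <- function(x) data.frame(b = unlist(x$b), sigma = unlist(x$sigma),
                                  spike_slab = unlist(x$spike_slab),
                                  p_incl = unlist(x$p_incl))
  trial_config(
    grid = dose_grid(unlist(obj$raw_doses)),
    prior = prior_spec(as_df(obj$prior$efficacy), as_df(obj$prior$toxicity)),
    thresholds = do.call(decision_thresholds, obj$thresholds),
    nu = utility_table(nu00 = obj$utility$nu00, nu11 = obj$utility$nu11),
    design = obj$design,
    max_per_subgroup = obj$max_per_subgroup,
    run_in = obj$run_in, run_in_cohorts = obj$run_in_cohorts,
    cohort_composition = obj$cohort_composition,
    pool_tried = obj$pool_tried,
    n_burn = obj$n_burn, n_keep = obj$n_keep)
}
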