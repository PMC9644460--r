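#' Write posterior draws and run log
#'
#' Draws go to `<stem>.csv` (columns `chain,iteration,<parameters...>`); the
#' configuration, seed, diagnostics and flags go to a companion
#' `<stem>_runlog.json`.
#'
#' @param fit a `distress_fit`.
#' @param stem output path stem (without extension).
#' @return invisibly, the two paths written.
#' @export
write_fit <- function(fit, stem) {
  csv <- paste0(stem, ".csv")
  utils::write.csv(fit$draws, csv, row.names = FALSE)
  log <- paste0(stem, "_runlog.json")
  jsonlite::write_json(list(
    config = fit$config[c("chains", "iterations", "warmup_frac", "seed",
                          "sampler")],
    pinned = as.list(fit$pinned),
    accept_rate = fit$accept_rate,
    diagnostics = fit$diagnostics,
    flags = fit$flags
  ), log, auto_unbox = TRUE, digits = NA)
  invisible(c(draws = csv, runlog = log))
}

#' Read posterior draws written by [write_fit()]
#'
#' @param path the draws CSV.
#' @return draws data.frame (`chain`, `iteration`, parameter columns).
#' @export
read_fit_draws <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("chain", "iteration") %in% names(df))) {
    stop("draws CSV must have chain and iteration columns")
  }
  df
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study sequence on one observation set: unconstrained fit,
#' convergence diagnostics, counterfactual prevalence under constant
#' incidence, both constrained fits (incidence trend pinned; effectiveness
#' trend pinned) with a per-stream fit-comparison table, posterior predictive
#' checks per stream, and a plain-text report. All randomness flows from the
#' single master seed, which is recorded in every output.
#'
#' Output files (under `outdir`): `posterior.csv` + `posterior_runlog.json`,
#' `counterfactual.json` + `counterfactual.csv`, `constrained_fit.json`,
#' `ppc.json`, `report.txt`.
#'
#' @param obs an `observation_set`, or a path to an observation CSV.
#' @param outdir output directory (created if absent).
#' @param priors a `prior_spec`, or a path to a priors YAML.
#' @param chains,iterations,warmup_frac,seed sampler configuration; the study
#'   default is 4 chains of 4000 iterations with half discarded as warmup.
#' @param n_draws posterior draws used for the counterfactual and checks.
#' @param reference_years counterfactual reference years.
#' @param constrained also fit the two constrained variants.
#' @return invisibly, a list with the fit, counterfactual result, constrained
#'   comparison table, and PPC p-values.
#' @export
run_full_analysis <- function(obs, outdir, priors = default_priors(),
                              chains = 4, iterations = 4000,
                              warmup_frac = 0.5, seed = 1L, n_draws = 1000,
                              reference_years = c(2008, 2019),
                              constrained = TRUE) {
  if (is.character(obs)) obs <- read_observations(obs)
  obs <- observation_set(obs)
  if (is.character(priors)) priors <- read_priors(priors)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  fit <- fit_distress_model(obs, priors = priors, chains = chains,
                            iterations = iterations,
                            warmup_frac = warmup_frac, seed = seed)
  write_fit(fit, file.path(outdir, "posterior"))

  cf <- counterfactual_prevalence(fit, reference_years = reference_years,
                                  n_draws = n_draws, seed = seed)
  utils::write.csv(cf$per_draw, file.path(outdir, "counterfactual.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(reference_years = reference_years,
                            seed = as.integer(seed),
                            summary = cbind(quantity = rownames(cf$summary),
                                            cf$summary)),
                       file.path(outdir, "counterfactual.json"),
                       auto_unbox = TRUE, digits = NA)

  cmp <- NULL
  if (constrained) {
    fit_di <- fit_distress_model(obs, priors = priors, chains = chains,
                                 iterations = iterations,
                                 warmup_frac = warmup_frac, seed = seed,
                                 pinned = c(delta_i = 0))
    fit_dr <- fit_distress_model(obs, priors = priors, chains = chains,
                                 iterations = iterations,
                                 warmup_frac = warmup_frac, seed = seed,
                                 pinned = c(delta_r = 0))
    streams <- intersect(stream_names(), unique(obs$stream))
    cmp <- data.frame(stream = streams)
    cmp$unconstrained <- vapply(streams, function(st)
      stream_mean_loglik(fit, stream = st, seed = seed), numeric(1))
    cmp$pin_delta_i <- vapply(streams, function(st)
      stream_mean_loglik(fit_di, stream = st, seed = seed), numeric(1))
    cmp$pin_delta_r <- vapply(streams, function(st)
      stream_mean_loglik(fit_dr, stream = st, seed = seed), numeric(1))
    jsonlite::write_json(cmp, file.path(outdir, "constrained_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  streams <- intersect(stream_names(), unique(obs$stream))
  ppc <- lapply(streams, function(st)
    posterior_predictive_check(fit, stream = st,
                               n_draws = min(n_draws, nrow(fit$draws)),
                               seed = seed)$p_value)
  names(ppc) <- streams
  jsonlite::write_json(ppc, file.path(outdir, "ppc.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- c(
    "Distress dynamics analysis report",
    config_label(chains, iterations, warmup_frac, seed),
    sprintf("observations: %d records (%s)", nrow(obs),
            paste(names(table(obs$stream)), table(obs$stream),
                  sep = "=", collapse = ", ")),
    sprintf("max split-R-hat: %.3f",
            max(fit$diagnostics$rhat, na.rm = TRUE)),
    sprintf("P(delta_i > 0) = %.4f",
            posterior_probability(fit, function(d) d$delta_i > 0)),
    sprintf("P(delta_r < 0) = %.4f",
            posterior_probability(fit, function(d) d$delta_r < 0)),
    sprintf("counterfactual prevalence difference (constant incidence): %.4f (95%% CrI %.4f-%.4f)",
            cf$summary["difference", "median"],
            cf$summary["difference", "lower95"],
            cf$summary["difference", "upper95"]),
    sprintf("persons averted: %.0f; relative reduction: %.2f%%",
            cf$summary["persons_averted", "median"],
            100 * cf$summary["relative_reduction", "median"]),
    paste0("ppc p-values: ",
           paste(names(ppc), sprintf("%.3f", unlist(ppc)),
                 sep = "=", collapse = ", ")),
    if (length(fit$flags) > 0) paste("flags:", paste(fit$flags,
                                                     collapse = "; "))
  )
  writeLines(report[!vapply(report, is.null, logical(1))],
             file.path(outdir, "report.txt"))

  invisible(list(fit = fit, counterfactual = cf, constrained = cmp,
                 ppc = ppc))
}

# report header line; flags the study-default MCMC configuration
config_label <- function(chains, iterations, warmup_frac, seed) {
  sprintf("configuration: %d chains x %d iterations, warmup fraction %.2f, seed %d%s",
          chains, iterations, warmup_frac, as.integer(seed),
          if (chains == 4 && iterations == 4000 && warmup_frac == 0.5)
            " (study default)" else "")
}
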