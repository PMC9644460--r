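#' Equal-tailed credible interval
#'
#' Quantile interval at probabilities `(1 - level)/2` and `1 - (1 - level)/2`
#' (default quantile rule, type 7).
#'
#' @param values numeric vector of per-draw values (length >= 2).
#' @param level interval probability in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' credible_interval(1:100, 0.95)
#' @export
credible_interval <- function(values, level = 0.95) {
  if (length(values) < 2) stop("need at least 2 values")
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  q <- stats::quantile(values, c(a, 1 - a), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Posterior probability of a parameter predicate
#'
#' Fraction of retained draws satisfying `predicate`, a function of the draws
#' data.frame returning a logical vector (e.g.
#' `function(d) d$delta_i > 0`).
#'
#' @param fit a `distress_fit` (or draws data.frame).
#' @param predicate function of the draws data.frame.
#' @return probability in `[0, 1]`.
#' @export
posterior_probability <- function(fit, predicate) {
  draws <- if (inherits(fit, "distress_fit")) fit$draws else fit
  if (nrow(draws) == 0) stop("no posterior draws")
  ok <- predicate(draws)
  if (!is.logical(ok) || length(ok) != nrow(draws)) {
    stop("predicate must return one logical per draw")
  }
  mean(ok)
}

#' Pointwise posterior quantile bands of trajectories
#'
#' Simulates the trajectory for `n_draws` randomly selected posterior draws
#' and returns the pointwise 2.5/25/50/75/97.5 percentiles of the requested
#' quantities at each stored time (the 50% and 95% bands of the study's
#' figures). Draws whose simulation fails are skipped and counted.
#'
#' @param fit a `distress_fit`.
#' @param n_draws number of posterior draws (default 1000, capped at the
#'   number retained).
#' @param quantities trajectory columns, e.g. `c("prevalence", "i", "r")`.
#' @param t_end,dt_store,times stored grid, as in [simulate_trajectory()].
#' @param seed optional seed for the draw selection.
#' @return data.frame with columns `quantity, time, q2.5, q25, q50, q75,
#'   q97.5`; attribute `skipped` counts failed simulations.
#' @export
trajectory_bands <- function(fit, n_draws = 1000, quantities = "prevalence",
                             t_end = 12, dt_store = 0.5, times = NULL,
                             seed = NULL) {
  stopifnot(inherits(fit, "distress_fit"))
  n_avail <- nrow(fit$draws)
  if (n_draws > n_avail) stop("n_draws exceeds available posterior draws")
  if (is.null(times)) times <- seq(0, t_end, by = dt_store)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- if (n_draws == n_avail) seq_len(n_avail) else
    sample.int(n_avail, n_draws)
  sims <- array(NA_real_, dim = c(length(times), length(quantities),
                                  n_draws))
  skipped <- 0
  for (j in seq_along(idx)) {
    traj <- tryCatch(simulate_trajectory(draw_parameters(fit, idx[j]),
                                         times = times),
                     error = function(e) NULL)
    if (is.null(traj)) {
      skipped <- skipped + 1
      next
    }
    for (q in seq_along(quantities)) sims[, q, j] <- traj[[quantities[q]]]
  }
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  out <- do.call(rbind, lapply(seq_along(quantities), function(q) {
    qs <- t(apply(sims[, q, , drop = FALSE], 1, stats::quantile,
                  probs = probs, na.rm = TRUE, names = FALSE))
    data.frame(quantity = quantities[q], time = times,
               q2.5 = qs[, 1], q25 = qs[, 2], q50 = qs[, 3],
               q75 = qs[, 4], q97.5 = qs[, 5])
  }))
  attr(out, "skipped") <- skipped
  out
}

#' Counterfactual prevalence under constant incidence
#'
#' For each posterior draw, re-simulates the model with the incidence trend
#' removed (`delta_i` set to 0) and everything else unchanged, and summarises
#' the counterfactual change in prevalence over the study period:
#' \itemize{
#'   \item `difference`: counterfactual prevalence at the start year minus at
#'     the end year (positive when prevalence would have fallen had
#'     individual-level risk stayed constant);
#'   \item `persons_averted`: `difference` times that draw's population at
#'     the end year;
#'   \item `relative_reduction`: `difference` divided by that draw's
#'     prevalence at the start year;
#'   \item `difference_vs_factual`: factual minus counterfactual prevalence
#'     at the end year (the alternative reading, reported alongside).
#' }
#' Reference times are the start of each reference year (t = year - 2008),
#' so the default spans start-of-2008 to end-of-2019 (t = 0 to 12).
#'
#' @param fit an unconstrained `distress_fit`.
#' @param reference_years `c(start, end)` calendar years (default 2008,
#'   2019; the end year is evaluated at its end, i.e. t = end - 2008 + 1).
#' @param n_draws posterior draws used (default 1000, capped).
#' @param seed optional seed for draw selection.
#' @return object of class `counterfactual_result`: list with `per_draw`
#'   (data.frame of the per-draw quantities) and `summary` (median, 50% and
#'   95% credible intervals for each).
#' @export
counterfactual_prevalence <- function(fit, reference_years = c(2008, 2019),
                                      n_draws = 1000, seed = NULL) {
  stopifnot(inherits(fit, "distress_fit"), length(reference_years) == 2)
  t0 <- reference_years[1] - 2008
  t1 <- reference_years[2] - 2008 + 1  # end of the final reference year
  stopifnot(t0 >= 0, t1 > t0)
  n_avail <- nrow(fit$draws)
  n_draws <- min(n_draws, n_avail)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- if (n_draws == n_avail) seq_len(n_avail) else
    sample.int(n_avail, n_draws)
  times <- sort(unique(c(t0, t1)))
  per <- data.frame(draw = idx, difference = NA_real_,
                    persons_averted = NA_real_,
                    relative_reduction = NA_real_,
                    difference_vs_factual = NA_real_)
  for (j in seq_along(idx)) {
    p <- draw_parameters(fit, idx[j])
    cf <- unclass(p)
    cf[["delta_i"]] <- 0
    traj_cf <- simulate_trajectory(as_model_parameters(cf), times = times)
    traj_f <- simulate_trajectory(p, times = times)
    prev_cf0 <- traj_cf$prevalence[traj_cf$time == t0]
    prev_cf1 <- traj_cf$prevalence[traj_cf$time == t1]
    prev_f1 <- traj_f$prevalence[traj_f$time == t1]
    P_end <- traj_cf$P[traj_cf$time == t1]
    per$difference[j] <- prev_cf0 - prev_cf1
    per$persons_averted[j] <- (prev_cf0 - prev_cf1) * P_end
    per$relative_reduction[j] <- (prev_cf0 - prev_cf1) / prev_cf0
    per$difference_vs_factual[j] <- prev_f1 - prev_cf1
  }
  summarise <- function(v) {
    c(median = stats::median(v),
      credible_interval(v, 0.5),
      stats::setNames(credible_interval(v, 0.95), c("lower95", "upper95")))
  }
  smry <- t(vapply(per[-1], summarise, numeric(5)))
  colnames(smry) <- c("median", "lower50", "upper50", "lower95", "upper95")
  structure(list(per_draw = per, summary = as.data.frame(smry),
                 reference_years = reference_years, n_draws = n_draws),
            class = "counterfactual_result")
}

#' @export
print.counterfactual_result <- function(x, digits = 4, ...) {
  cat(sprintf("Counterfactual (constant incidence, delta_i = 0), %d-%d, %d draws\n",
              x$reference_years[1], x$reference_years[2], x$n_draws))
  s <- x$summary
  cat(sprintf("  prevalence difference: %.4f (95%% CrI %.4f-%.4f)\n",
              s["difference", "median"], s["difference", "lower95"],
              s["difference", "upper95"]))
  cat(sprintf("  persons averted:       %.0f (95%% CrI %.0f-%.0f)\n",
              s["persons_averted", "median"],
              s["persons_averted", "lower95"],
              s["persons_averted", "upper95"]))
  cat(sprintf("  relative reduction:    %.2f%% (95%% CrI %.2f%%-%.2f%%)\n",
              100 * s["relative_reduction", "median"],
              100 * s["relative_reduction", "lower95"],
              100 * s["relative_reduction", "upper95"]))
  invisible(x)
}

#' Posterior predictive chi-square check
#'
#' For each of `n_draws` posterior draws, simulates the stream's expected
#' counts, draws a replicated data set from the negative-binomial observation
#' model, and compares chi-square discrepancies
#' `T(y) = sum_t (y_t - m_t)^2 / Var_t` of the observed and replicated data
#' (`Var_t = m_t (1 + 1/beta)` by default, or Pearson `Var_t = m_t`). The
#' Bayesian p-value is the fraction of draws with `T(y_rep) >= T(y)`; values
#' near 0 or 1 flag misfit.
#'
#' @param fit a `distress_fit`.
#' @param obs observation set checked (default: the fitted data).
#' @param stream stream name to check.
#' @param n_draws posterior draws used.
#' @param variance `"negbin"` (default) or `"pearson"`.
#' @param seed optional seed.
#' @return list with `p_value`, per-draw discrepancies `T_obs` and `T_rep`,
#'   and the stream checked.
#' @export
posterior_predictive_check <- function(fit, obs = fit$obs, stream = "distress",
                                       n_draws = 1000,
                                       variance = c("negbin", "pearson"),
                                       seed = NULL) {
  stopifnot(inherits(fit, "distress_fit"))
  variance <- match.arg(variance)
  obs <- observation_set(obs)
  sub <- obs[obs$stream == stream, , drop = FALSE]
  if (nrow(sub) == 0) stop("stream '", stream, "' not present in obs")
  sub <- observation_set(sub)
  n_avail <- nrow(fit$draws)
  n_draws <- min(n_draws, n_avail)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- if (n_draws == n_avail) seq_len(n_avail) else
    sample.int(n_avail, n_draws)
  tt <- sort(unique(observation_time(sub$year)))
  T_obs <- T_rep <- numeric(n_draws)
  for (j in seq_along(idx)) {
    p <- draw_parameters(fit, idx[j])
    traj <- simulate_trajectory(p, times = tt)
    m <- observation_means(traj, sub)
    beta <- unclass(p)[[paste0("beta_", stream)]]
    v <- if (variance == "negbin") m * (1 + 1 / beta) else m
    y_rep <- rnegbin(length(m), m, beta)
    T_obs[j] <- sum((sub$value - m)^2 / v)
    T_rep[j] <- sum((y_rep - m)^2 / v)
  }
  list(p_value = mean(T_rep >= T_obs), T_obs = T_obs, T_rep = T_rep,
       stream = stream, variance = variance, n_draws = n_draws)
}

#' Posterior-mean per-stream log-likelihood
#'
#' Mean over posterior draws of one stream's summed log-likelihood — the
#' fit-comparison statistic used to contrast constrained models (e.g. pinning
#' the incidence trend versus the effectiveness trend).
#'
#' @param fit a `distress_fit`.
#' @param obs observation set (default: the fitted data).
#' @param stream stream name.
#' @param n_draws posterior draws used.
#' @param seed optional seed for the draw selection.
#' @return scalar mean log-likelihood.
#' @export
stream_mean_loglik <- function(fit, obs = fit$obs, stream = "distress",
                               n_draws = 500, seed = NULL) {
  stopifnot(inherits(fit, "distress_fit"))
  obs <- observation_set(obs)
  sub <- obs[obs$stream == stream, , drop = FALSE]
  if (nrow(sub) == 0) stop("stream '", stream, "' not present in obs")
  sub <- observation_set(sub)
  n_avail <- nrow(fit$draws)
  n_draws <- min(n_draws, n_avail)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- if (n_draws == n_avail) seq_len(n_avail) else
    sample.int(n_avail, n_draws)
  tt <- sort(unique(observation_time(sub$year)))
  ll <- numeric(n_draws)
  for (j in seq_along(idx)) {
    p <- draw_parameters(fit, idx[j])
    traj <- simulate_trajectory(p, times = tt)
    m <- observation_means(traj, sub)
    beta <- unclass(p)[[paste0("beta_", stream)]]
    ll[j] <- if (any(m <= 0)) -Inf else sum(negbin_logpmf(sub$value, m, beta))
  }
  mean(ll)
}
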