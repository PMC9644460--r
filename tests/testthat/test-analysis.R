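make_fake_fit <- function(draws) {
  # minimal distress_fit around given draws, for analysis-only tests
  structure(list(draws = draws,
                 obs = observation_set(data.frame(stream = character(),
                                                  year = numeric(),
                                                  value = numeric())),
                 pinned = NULL,
                 config = list(chains = max(draws$chain),
                               iterations = max(draws$iteration),
                               warmup_frac = 0.5, seed = 1,
                               sampler = "test")),
            class = "distress_fit")
}

fit_from_params <- function(plist) {
  pars <- do.call(rbind, lapply(plist, function(p) unclass(p)[param_names()]))
  draws <- data.frame(chain = 1L, iteration = seq_len(nrow(pars)), pars,
                      check.names = FALSE)
  make_fake_fit(draws)
}

test_that("credible intervals follow the documented quantile rule", {
  ci <- credible_interval(1:100, 0.95)
  expect_equal(unname(ci), c(3.475, 97.525))
  expect_equal(unname(credible_interval(rep(7, 10), 0.5)), c(7, 7))
  # nesting at any level
  x <- stats::rlnorm(500)
  ci50 <- credible_interval(x, 0.5)
  ci95 <- credible_interval(x, 0.95)
  expect_gte(ci50[1], ci95[1])
  expect_lte(ci50[2], ci95[2])
  expect_error(credible_interval(numeric(0), 0.95), "2 values")
  expect_error(credible_interval(1:10, 1.2))
})

test_that("posterior probabilities count draws", {
  draws <- data.frame(chain = 1, iteration = 1:4, delta_i = c(-1, 1, 2, 3))
  fit <- make_fake_fit(draws)
  expect_equal(posterior_probability(fit, function(d) d$delta_i > 0), 0.75)
  expect_equal(posterior_probability(fit, function(d) rep(TRUE, nrow(d))), 1)
  # complement rule
  p <- posterior_probability(fit, function(d) d$delta_i > 1.5)
  q <- posterior_probability(fit, function(d) !(d$delta_i > 1.5))
  expect_equal(p + q, 1)
  expect_error(posterior_probability(fit, function(d) 1:2), "logical")
})

test_that("trajectory bands collapse for identical draws and nest by level", {
  p <- default_truth()
  fit1 <- fit_from_params(replicate(20, p, simplify = FALSE))
  b <- trajectory_bands(fit1, n_draws = 20, quantities = c("prevalence", "M"))
  traj <- simulate_trajectory(p, t_end = 12, dt_store = 0.5)
  sel <- b$quantity == "prevalence"
  expect_equal(b$q50[sel], traj$prevalence, tolerance = 1e-12)
  expect_equal(b$q2.5[sel], b$q97.5[sel], tolerance = 1e-12)

  # varied draws: quantile ordering and nesting inside the min/max envelope
  set.seed(2)
  plist <- lapply(1:30, function(k) {
    x <- unclass(p)
    x["i0"] <- x["i0"] * stats::runif(1, 0.8, 1.2)
    as_model_parameters(x)
  })
  fit2 <- fit_from_params(plist)
  b2 <- trajectory_bands(fit2, n_draws = 30, quantities = "M")
  expect_true(all(b2$q2.5 <= b2$q25 & b2$q25 <= b2$q50 &
                    b2$q50 <= b2$q75 & b2$q75 <= b2$q97.5))
  sims <- vapply(plist, function(pp)
    simulate_trajectory(pp, t_end = 12, dt_store = 0.5)$M,
    numeric(length(unique(b2$time))))
  expect_true(all(b2$q2.5 >= apply(sims, 1, min) - 1e-9))
  expect_true(all(b2$q97.5 <= apply(sims, 1, max) + 1e-9))

  expect_error(trajectory_bands(fit2, n_draws = 1000), "exceeds")
})

test_that("counterfactual equals factual when the trend is already zero", {
  p0 <- unclass(default_truth())
  p0["delta_i"] <- 0
  fit <- fit_from_params(replicate(10, as_model_parameters(p0),
                                   simplify = FALSE))
  cf <- counterfactual_prevalence(fit, n_draws = 10)
  # delta_i = 0 in every draw: counterfactual is the factual run bitwise
  expect_true(all(cf$per_draw$difference_vs_factual == 0))
  # difference distribution degenerates at the factual 2008 -> 2019 change
  traj <- simulate_trajectory(as_model_parameters(p0), times = c(0, 12))
  fact_change <- traj$prevalence[1] - traj$prevalence[2]
  expect_equal(cf$per_draw$difference, rep(fact_change, 10),
               tolerance = 1e-12)
})

test_that("counterfactual per-draw identities hold", {
  set.seed(5)
  plist <- lapply(1:15, function(k) {
    x <- unclass(default_truth())
    x["delta_i"] <- stats::runif(1, 0, 0.04)
    x["r0"] <- stats::runif(1, 0.1, 0.3)
    as_model_parameters(x)
  })
  fit <- fit_from_params(plist)
  cf <- counterfactual_prevalence(fit, n_draws = 15)
  for (j in 1:15) {
    x <- unclass(plist[[j]])
    x["delta_i"] <- 0
    traj <- simulate_trajectory(as_model_parameters(x), times = c(0, 12))
    diff_j <- traj$prevalence[1] - traj$prevalence[2]
    expect_equal(cf$per_draw$difference[j], diff_j, tolerance = 1e-10)
    # persons averted = difference x P(2019), recomputed independently
    expect_equal(cf$per_draw$persons_averted[j], diff_j * traj$P[2],
                 tolerance = 1e-10)
    # relative reduction x prevalence(2008) = difference
    expect_equal(cf$per_draw$relative_reduction[j] * traj$prevalence[1],
                 diff_j, tolerance = 1e-12)
  }
  # summaries are quantiles of the stored per-draw values
  expect_equal(cf$summary["difference", "median"],
               stats::median(cf$per_draw$difference))
  expect_equal(cf$summary["difference", "lower95"],
               unname(stats::quantile(cf$per_draw$difference, 0.025)))
})

test_that("posterior predictive check discrepancy matches a direct loop", {
  obs <- generate_observations(seed = 14)
  fit <- fit_from_params(replicate(8, default_truth(), simplify = FALSE))
  ppc <- posterior_predictive_check(fit, obs = obs, stream = "distress",
                                    n_draws = 8, seed = 31)
  sub <- obs[obs$stream == "distress", ]
  tt <- (sub$year - 2008) + 0.5
  traj <- simulate_trajectory(default_truth(), times = sort(tt))
  m <- traj$M[match(tt, traj$time)]
  v <- m * (1 + 1 / 400)
  T_direct <- 0
  for (r in seq_along(m)) T_direct <- T_direct + (sub$value[r] - m[r])^2 / v[r]
  expect_equal(ppc$T_obs, rep(T_direct, 8), tolerance = 1e-10)
  expect_true(all(ppc$p_value >= 0 & ppc$p_value <= 1))
})

test_that("gross misfit is detected by the predictive check", {
  obs <- as.data.frame(generate_observations(seed = 14))
  k <- which(obs$stream == "distress")[3]
  obs$value[k] <- obs$value[k] * 100
  obs <- observation_set(obs)
  fit <- fit_from_params(replicate(40, default_truth(), simplify = FALSE))
  ppc <- posterior_predictive_check(fit, obs = obs, stream = "distress",
                                    n_draws = 40, seed = 32)
  expect_lt(ppc$p_value, 0.05)
  expect_error(posterior_predictive_check(fit, obs = obs, stream = "population",
                                          n_draws = 2, seed = 1), NA)
  bad <- observation_set(data.frame(stream = "distress", year = 2013,
                                    value = 1))
  expect_error(posterior_predictive_check(fit, obs = bad, stream = "services"),
               "not present")
})

test_that("stream mean log-likelihood ranks parameter quality", {
  obs <- generate_observations(seed = 14)
  good <- fit_from_params(replicate(5, default_truth(), simplify = FALSE))
  off <- unclass(default_truth())
  off["i0"] <- 0.03  # halved incidence: distress stream badly underpredicted
  bad <- fit_from_params(replicate(5, as_model_parameters(off),
                                   simplify = FALSE))
  ll_good <- stream_mean_loglik(good, obs = obs, stream = "distress",
                                n_draws = 5)
  ll_bad <- stream_mean_loglik(bad, obs = obs, stream = "distress",
                               n_draws = 5)
  expect_gt(ll_good, ll_bad)
})
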