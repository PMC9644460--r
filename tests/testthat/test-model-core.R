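test_that("exogenous drivers follow linear and exponential trends", {
  p <- default_truth()
  # constant case: zero slopes and trends reproduce initial values at any t
  p0 <- model_parameters(prev0 = 0.1, P0 = 1e6, g = 0, D0 = 1e4, h = 0,
                         gamma = 1.4, i0 = 0.05, delta_i = 0, s = 0.3,
                         C0 = 1e4, u = 0, r0 = 0.2, delta_r = 0)
  drv <- exogenous_drivers(p0, c(0, 3.7, 12))
  expect_equal(drv$P, rep(1e6, 3))
  expect_equal(drv$D, rep(1e4, 3))
  expect_equal(drv$C, rep(1e4, 3))
  expect_equal(drv$i, rep(0.05, 3))
  expect_equal(drv$r, rep(0.2, 3))

  # linear population growth after one year
  expect_equal(exogenous_drivers(p, 1)$P, 16167328 + 308538)
  expect_equal(exogenous_drivers(p, 1)$P, 16475866)

  # exponential incidence trend
  p2 <- as_model_parameters(replace(unclass(p), c("i0", "delta_i"),
                                    c(0.05, 0.02)))
  expect_equal(exogenous_drivers(p2, 11)$i, 0.05 * exp(0.22),
               tolerance = 1e-12)
  expect_equal(exogenous_drivers(p2, 11)$i, 0.0623038, tolerance = 1e-5)

  # r(t) clipped at 1 with a warning
  p3 <- as_model_parameters(replace(unclass(p), c("r0", "delta_r"),
                                    c(0.9, 0.2)))
  expect_warning(drv3 <- exogenous_drivers(p3, c(0, 10)), "clipped")
  expect_equal(drv3$r[2], 1)

  # negative drivers outside the fitted horizon raise
  p4 <- as_model_parameters(replace(unclass(p), "g", -16167328))
  expect_error(exogenous_drivers(p4, 2), "non-positive")
})

test_that("background mortality rate inverts the total-mortality identity", {
  # no distressed population: k = D/P
  expect_equal(background_mortality_rate(P = 1000, M = 0, D = 10,
                                         gamma = 1.37), 0.01)
  # hazard ratio 1 removes the M-dependence
  expect_equal(background_mortality_rate(P = 1000, M = 700, D = 10,
                                         gamma = 1), 0.01)
  # study-scale values
  M <- 0.1464 * 16167328
  k <- background_mortality_rate(P = 16167328, M = M, D = 136840,
                                 gamma = 1.37)
  expect_equal(k, 136840 / 17043080, tolerance = 1e-6)
  expect_equal(k, 0.0080291, tolerance = 1e-4)
  # substituting back reproduces D exactly
  expect_equal(k * (16167328 - M) + 1.37 * k * M, 136840)
  expect_error(background_mortality_rate(P = 10, M = 20, D = 1, gamma = 1.4))
})

test_that("empty stock is a fixed point", {
  p <- model_parameters(prev0 = 0, P0 = 1e6, g = 1e4, D0 = 1e4, h = 10,
                        gamma = 1.4, i0 = 0, delta_i = 0, s = 0.3, C0 = 0,
                        u = 0, r0 = 0.2, delta_r = 0)
  traj <- simulate_trajectory(p, t_end = 12, dt_store = 1)
  expect_equal(traj$M, rep(0, nrow(traj)))
  expect_equal(traj$prevalence, rep(0, nrow(traj)))
})

test_that("constant-coefficient run matches the closed-form solution", {
  p <- const_coef_params()
  traj <- simulate_trajectory(p, t_end = 30, dt_store = 0.5)
  expect_equal(traj$M, analytic_const_coef(p, traj$time), tolerance = 1e-6)
  # equilibrium M* = i P / (i + k + s) = 0.05e6 / 0.37
  expect_equal(traj$M[traj$time == 30], 0.05 * 1e6 / 0.37, tolerance = 1e-4)
})

test_that("integrator matches an independent fine-step Euler oracle", {
  p <- model_parameters(prev0 = 0.1464, P0 = 16167328, g = 308538,
                        D0 = 136840, h = 2228.7, gamma = 1.37, i0 = 0.06,
                        delta_i = 0.01, s = 0.31, C0 = 305315, u = 43696,
                        r0 = 0.1845, delta_r = 0)
  times <- seq(0, 12, by = 1)
  traj <- simulate_trajectory(p, times = times)
  oracle <- euler_oracle(p, times, dt = 1e-4)
  expect_lt(max(abs(traj$M[-1] - oracle[-1]) / oracle[-1]), 1e-4)
})

test_that("integrator agrees with deSolve lsoda", {
  skip_if_not_installed("deSolve")
  p <- unclass(default_truth())
  deriv <- function(t, y, parms) {
    P <- p[["P0"]] + p[["g"]] * t
    D <- p[["D0"]] + p[["h"]] * t
    C <- p[["C0"]] + p[["u"]] * t
    i <- p[["i0"]] * exp(p[["delta_i"]] * t)
    r <- min(p[["r0"]] * exp(p[["delta_r"]] * t), 1)
    k <- D / (P + (p[["gamma"]] - 1) * y[1])
    list(i * (P - y[1]) - p[["gamma"]] * k * y[1] - p[["s"]] * y[1] - r * C)
  }
  times <- seq(0, 12, by = 0.5)
  ref <- deSolve::lsoda(c(M = p[["prev0"]] * p[["P0"]]), times, deriv,
                        NULL, rtol = 1e-10, atol = 1e-6)[, "M"]
  traj <- simulate_trajectory(default_truth(), times = times)
  expect_equal(traj$M, unname(ref), tolerance = 1e-6)
})

test_that("trajectory invariants hold across prior draws", {
  pr <- default_priors()
  set.seed(42)
  n_ok <- 0
  for (rep in 1:25) {
    x <- vapply(param_names(), function(j) prior_draw(pr[[j]]), numeric(1))
    p <- tryCatch(as_model_parameters(x), error = function(e) NULL)
    if (is.null(p)) next
    traj <- tryCatch(simulate_trajectory(p, t_end = 12, dt_store = 0.5),
                     error = function(e) NULL)
    if (is.null(traj)) next
    n_ok <- n_ok + 1
    # conservation/bounds
    expect_true(all(traj$M >= -1e-4))
    expect_true(all(traj$M <= traj$P * (1 + 1e-10)))
    expect_equal(traj$prevalence, traj$M / traj$P)
    # mortality identity at all stored points
    lhs <- traj$k * (traj$P - traj$M) + p[["gamma"]] * traj$k * traj$M
    expect_equal(lhs, traj$D, tolerance = 1e-8)
  }
  expect_gte(n_ok, 10)
})

test_that("tightening the tolerance does not change the solution materially", {
  p <- default_truth()
  a <- simulate_trajectory(p, t_end = 12, dt_store = 12, rtol = 1e-8,
                           atol = 1e-4)
  b <- simulate_trajectory(p, t_end = 12, dt_store = 12, rtol = 1e-10,
                           atol = 1e-6)
  expect_equal(a$M[a$time == 12], b$M[b$time == 12], tolerance = 1e-7)
})

test_that("M responds monotonically to effectiveness and incidence", {
  base <- unclass(default_truth())
  t_end <- 12
  M_at <- function(x) {
    traj <- simulate_trajectory(as_model_parameters(x), t_end = t_end,
                                dt_store = 1)
    traj$M[-1]
  }
  m0 <- M_at(base)
  # increasing r0 never increases M(t)
  up_r <- replace(base, "r0", 0.4)
  expect_true(all(M_at(up_r) <= m0))
  # increasing i0 never decreases M(t)
  up_i <- replace(base, "i0", 0.08)
  expect_true(all(M_at(up_i) >= m0))
})

test_that("recovery overdraw is capped and flagged", {
  # enormous treated-recovery flow relative to a nearly empty stock
  p <- model_parameters(prev0 = 0.001, P0 = 1e6, g = 0, D0 = 1e4, h = 0,
                        gamma = 1.2, i0 = 0.001, delta_i = 0, s = 0.1,
                        C0 = 5e5, u = 0, r0 = 0.9, delta_r = 0)
  traj <- simulate_trajectory(p, t_end = 5, dt_store = 0.5)
  expect_true(attr(traj, "recovery_capped"))
  expect_true(all(traj$M >= 0))
})

test_that("trajectory CSV round-trips", {
  traj <- simulate_trajectory(default_truth(), t_end = 12, dt_store = 1)
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(traj), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(read_trajectory(write_observations(
    generate_observations(seed = 1), tempfile(fileext = ".csv"))), "header")
})

test_that("parameter validation enforces the type invariants", {
  base <- unclass(default_truth())
  expect_error(as_model_parameters(replace(base, "prev0", 1.5)), "prev0")
  expect_error(as_model_parameters(replace(base, "gamma", 0.9)), "gamma")
  expect_error(as_model_parameters(replace(base, "P0", -1)), "P0")
  expect_error(as_model_parameters(replace(base, "beta_distress", 0)),
               "beta")
  expect_error(as_model_parameters(base[-1]), "missing")
  # gamma = 1 (boundary) is admissible
  expect_silent(as_model_parameters(replace(base, "gamma", 1)))
})
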