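# shared fixtures and oracles, all built in code

# parameter vector with constant coefficients: gamma = 1 makes k = D/P
# independent of M, so the stock ODE is linear with constant coefficients and
# has the closed form M(t) = M* + (M0 - M*) exp(-(i + k + s) t),
# M* = i P / (i + k + s)
const_coef_params <- function(prev0 = 0.05, P = 1e6, i = 0.05, s = 0.31,
                              k = 0.01) {
  model_parameters(prev0 = prev0, P0 = P, g = 0, D0 = k * P, h = 0,
                   gamma = 1, i0 = i, delta_i = 0, s = s, C0 = 0, u = 0,
                   r0 = 0.5, delta_r = 0, beta = 400)
}

analytic_const_coef <- function(params, t) {
  i <- params[["i0"]]
  s <- params[["s"]]
  k <- params[["D0"]] / params[["P0"]]
  rate <- i + k + s
  Mstar <- i * params[["P0"]] / rate
  M0 <- params[["prev0"]] * params[["P0"]]
  Mstar + (M0 - Mstar) * exp(-rate * t)
}

# independent fixed-step Euler integrator of the full nonlinear model
euler_oracle <- function(params, times, dt = 1e-4) {
  p <- unclass(params)
  M <- p[["prev0"]] * p[["P0"]]
  t <- 0
  out <- numeric(length(times))
  idx <- 1
  while (idx <= length(times) && times[idx] <= t + 1e-12) {
    out[idx] <- M
    idx <- idx + 1
  }
  t_end <- max(times)
  while (t < t_end - 1e-12) {
    P <- p[["P0"]] + p[["g"]] * t
    D <- p[["D0"]] + p[["h"]] * t
    C <- p[["C0"]] + p[["u"]] * t
    i <- p[["i0"]] * exp(p[["delta_i"]] * t)
    r <- min(p[["r0"]] * exp(p[["delta_r"]] * t), 1)
    k <- D / (P + (p[["gamma"]] - 1) * M)
    dM <- i * (P - M) - p[["gamma"]] * k * M - p[["s"]] * M - r * C
    M <- M + dt * dM
    t <- t + dt
    while (idx <= length(times) && times[idx] <= t + 1e-12) {
      out[idx] <- M
      idx <- idx + 1
    }
  }
  out
}

# small fast fit for tests that only need a working posterior object
small_fit <- function(obs, seed = 1, ...) {
  fit_distress_model(obs, chains = 2, iterations = 300, seed = seed, ...)
}

# memoised recovery study shared by the acceptance tests: 20 synthetic data
# sets at the study's observation sparsity, each fitted at reduced chain
# length (4 x 1000)
.accept_cache <- new.env(parent = emptyenv())

recovery_study <- function() {
  if (!is.null(.accept_cache$study)) return(.accept_cache$study)
  reps <- lapply(1:20, function(r) {
    obs <- generate_observations(seed = 1000 + r)
    fit <- fit_distress_model(obs, chains = 4, iterations = 1000,
                              seed = 2000 + r)
    list(obs = obs, fit = fit)
  })
  .accept_cache$study <- reps
  reps
}
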