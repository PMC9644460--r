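#' Exogenous driver values at time t
#'
#' The population, total mortality, and services-provision drivers increase
#' linearly (slopes `g`, `h`, `u`); per-capita incidence and treatment
#' effectiveness follow exponential trends at constant fractional rates
#' (`delta_i`, `delta_r`). Time is measured in years since the start of 2008.
#' `r(t)` is clipped at 1 (a proportion) with a warning when the exponential
#' trend exceeds it.
#'
#' @param params a [model_parameters()] vector.
#' @param t numeric vector of times (years since start of 2008), `t >= 0`.
#' @return data.frame with columns `t, P, D, C, i, r`.
#' @examples
#' p <- default_truth()
#' exogenous_drivers(p, c(0, 1, 11.5))
#' @export
exogenous_drivers <- function(params, t) {
  stopifnot(all(t >= 0))
  P <- params[["P0"]] + params[["g"]] * t
  D <- params[["D0"]] + params[["h"]] * t
  C <- params[["C0"]] + params[["u"]] * t
  if (any(P <= 0)) stop("population driver P(t) is non-positive")
  if (any(D <= 0)) stop("mortality driver D(t) is non-positive")
  if (any(C < 0)) stop("services driver C(t) is negative")
  i <- params[["i0"]] * exp(params[["delta_i"]] * t)
  r <- params[["r0"]] * exp(params[["delta_r"]] * t)
  if (any(r > 1)) {
    warning("treatment effectiveness r(t) clipped at 1")
    r <- pmin(r, 1)
  }
  data.frame(t = t, P = P, D = D, C = C, i = i, r = r)
}

#' Background per-capita mortality rate
#'
#' Inverts the total-mortality identity `D = k (P - M) + gamma k M`, so that
#' `k = D / (P + (gamma - 1) M)`. Substituting the result back reproduces `D`
#' exactly.
#'
#' @param P total population (persons).
#' @param M persons with high/very-high distress, `0 <= M <= P`.
#' @param D total deaths per year, positive.
#' @param gamma mortality hazard ratio, `>= 1`.
#' @return background mortality rate `k` (per year); vectorised.
#' @examples
#' background_mortality_rate(P = 1000, M = 0, D = 10, gamma = 1.37)  # 0.01
#' @export
background_mortality_rate <- function(P, M, D, gamma) {
  stopifnot(all(M >= 0), all(M <= P), all(D > 0), all(gamma >= 1))
  denom <- P + (gamma - 1) * M
  if (any(denom <= 0)) stop("mortality-rate denominator is non-positive")
  D / denom
}

#' Simulate the distress-prevalence trajectory
#'
#' Integrates the one-stock model
#' \deqn{dM/dt = i(t) (P(t) - M) - \gamma k(t) M - s M - r(t) C(t)}
#' with `M(0) = prev0 * P0` and the background mortality rate `k(t)`
#' recomputed from the instantaneous state at every integrator evaluation.
#' Integration uses an embedded Cash-Karp Runge-Kutta 4(5) scheme with
#' adaptive steps (relative tolerance `rtol`, absolute tolerance `atol` in
#' persons). The state-independent treated-recovery flow `r C` can formally
#' overdraw the stock; it is capped continuously within one person of an
#' empty stock (a ramp, keeping the derivative continuous for the adaptive
#' scheme) and the trajectory is flagged (`attr(x, "recovery_capped")`);
#' similarly `attr(x, "r_clipped")` flags clipping of `r(t)` at 1. The
#' fitted regime triggers neither guard.
#'
#' @param params a [model_parameters()] vector (dispersions ignored).
#' @param t_end end of the simulation horizon, years since start of 2008.
#' @param dt_store spacing of the stored output grid (years).
#' @param times optional explicit vector of store times (overrides `t_end` /
#'   `dt_store`); must be non-negative and sorted.
#' @param rtol,atol integration tolerances.
#' @return a `distress_trajectory`: data.frame with columns
#'   `time, M, P, D, C, i, r, k, prevalence` (times in decimal years since
#'   2008.0).
#' @examples
#' traj <- simulate_trajectory(default_truth(), t_end = 12, dt_store = 0.5)
#' head(traj)
#' @export
simulate_trajectory <- function(params, t_end = 12, dt_store = 0.5,
                                times = NULL, rtol = 1e-8, atol = 1e-4) {
  params <- as_model_parameters(params)
  if (is.null(times)) {
    stopifnot(t_end > 0, dt_store > 0, dt_store <= t_end)
    times <- seq(0, t_end, by = dt_store)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  }
  stopifnot(all(times >= 0), !is.unsorted(times))
  dyn <- unclass(params)[param_names(with_beta = FALSE)]
  sol <- ode_solve_cpp(as.numeric(dyn), as.numeric(times), rtol, atol)
  if (sol$status != 0) {
    stop(switch(as.character(sol$status),
                "1" = "exogenous driver became non-positive during integration",
                "2" = "mortality-rate denominator became non-positive",
                "3" = "integration failed (non-finite state or step limit)"))
  }
  M <- sol$M
  if (any(!is.finite(M))) stop("non-finite state in trajectory")
  drv <- exogenous_drivers_quiet(params, times)
  k <- drv$D / (drv$P + (params[["gamma"]] - 1) * M)
  out <- data.frame(time = times, M = M, P = drv$P, D = drv$D, C = drv$C,
                    i = drv$i, r = drv$r, k = k, prevalence = M / drv$P)
  if (any(out$M < -atol) || any(out$M > out$P * (1 + 1e-10))) {
    stop("trajectory violates 0 <= M <= P beyond tolerance")
  }
  structure(out, class = c("distress_trajectory", "data.frame"),
            r_clipped = isTRUE(sol$r_clipped),
            recovery_capped = isTRUE(sol$recovery_capped))
}

# drivers without the clipping warning (flag already carried by the solver)
exogenous_drivers_quiet <- function(params, t) {
  suppressWarnings(exogenous_drivers(params, t))
}

#' @export
print.distress_trajectory <- function(x, ...) {
  cat("Distress model trajectory: ", nrow(x), " stored times, t in [",
      format(min(x$time)), ", ", format(max(x$time)), "] years since 2008.0\n",
      sep = "")
  if (isTRUE(attr(x, "r_clipped"))) cat("  note: r(t) clipped at 1\n")
  if (isTRUE(attr(x, "recovery_capped"))) {
    cat("  note: recovery outflow capped at empty stock\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
plot.distress_trajectory <- function(x, quantity = "prevalence", ...) {
  graphics::plot(x$time + 2008, x[[quantity]], type = "l",
                 xlab = "Year", ylab = quantity, ...)
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' Header `time,M,P,D,C,i,r,k,prevalence`, one row per stored time, times in
#' decimal years since 2008.0.
#'
#' @param traj a `distress_trajectory`.
#' @param path file path.
#' @return `read_trajectory` returns a `distress_trajectory` (flags not
#'   preserved); `write_trajectory` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "M", "P", "D", "C", "i", "r", "k", "prevalence")
  if (!identical(names(df), need)) {
    stop("trajectory CSV must have header ", paste(need, collapse = ","))
  }
  structure(df, class = c("distress_trajectory", "data.frame"))
}
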