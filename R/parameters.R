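#' Dynamic-model parameter names
#'
#' The 13 dynamic parameters of the stock-and-flow model, in canonical order,
#' optionally followed by the four per-stream negative-binomial dispersions.
#'
#' @param with_beta logical; append the per-stream dispersion names.
#' @return character vector of parameter names.
#' @export
param_names <- function(with_beta = TRUE) {
  dyn <- c("prev0", "P0", "g", "D0", "h", "gamma", "i0", "delta_i",
           "s", "C0", "u", "r0", "delta_r")
  if (!with_beta) return(dyn)
  c(dyn, paste0("beta_", stream_names()))
}

#' Observation stream names
#'
#' @return character vector: distress, population, mortality, services.
#' @export
stream_names <- function() c("distress", "population", "mortality", "services")

#' Construct a validated model parameter vector
#'
#' Bundles the dynamic parameters of the one-stock distress model together
#' with the per-stream negative-binomial dispersions `beta`.
#'
#' Units: `prev0` is the initial proportion of adults with high/very-high
#' distress (M0 = prev0 * P0); `P0` persons; `g` persons/year; `D0`
#' deaths/year; `h` deaths/year^2; `gamma` dimensionless mortality hazard
#' ratio (>= 1); `i0` per-capita incidence /year; `delta_i` fractional trend
#' /year; `s` natural recovery rate /year; `C0` patients treated/year; `u`
#' patients/year^2; `r0` initial treatment effectiveness (proportion);
#' `delta_r` fractional trend /year; `beta` one positive inverse-scale
#' dispersion per observation stream (variance = mean * (1 + 1/beta)).
#'
#' @param prev0,P0,g,D0,h,gamma,i0,delta_i,s,C0,u,r0,delta_r dynamic
#'   parameters (see Details).
#' @param beta named numeric vector of positive dispersions, one per stream
#'   (`distress`, `population`, `mortality`, `services`), or a single value
#'   recycled to all four streams.
#' @return an object of class `distress_params`: a named numeric vector.
#' @examples
#' p <- model_parameters(prev0 = 0.1464, P0 = 16167328, g = 308538,
#'                       D0 = 136840, h = 2228.7, gamma = 1.37, i0 = 0.06,
#'                       delta_i = 0.02, s = 0.31, C0 = 305315, u = 43696,
#'                       r0 = 0.1845, delta_r = 0, beta = 400)
#' @export
model_parameters <- function(prev0, P0, g, D0, h, gamma, i0, delta_i, s,
                             C0, u, r0, delta_r, beta = 400) {
  if (length(beta) == 1L) beta <- rep(beta, 4L)
  if (is.null(names(beta)) || !setequal(names(beta), stream_names())) {
    if (length(beta) != 4L) stop("`beta` must have one entry per stream")
    names(beta) <- stream_names()
  }
  beta <- beta[stream_names()]
  x <- c(prev0 = prev0, P0 = P0, g = g, D0 = D0, h = h, gamma = gamma,
         i0 = i0, delta_i = delta_i, s = s, C0 = C0, u = u, r0 = r0,
         delta_r = delta_r)
  x <- c(x, stats::setNames(as.numeric(beta), paste0("beta_", stream_names())))
  validate_parameters(x)
  structure(x, class = "distress_params")
}

#' Coerce a named vector or list to `distress_params`
#'
#' @param x named numeric vector or list containing all parameter names from
#'   [param_names()].
#' @return a `distress_params` vector.
#' @export
as_model_parameters <- function(x) {
  x <- unlist(x)
  nm <- param_names()
  if (!all(nm %in% names(x))) {
    stop("missing parameters: ", paste(setdiff(nm, names(x)), collapse = ", "))
  }
  x <- x[nm]
  validate_parameters(x)
  structure(x, class = "distress_params")
}

validate_parameters <- function(x) {
  nm <- param_names()
  if (!all(nm %in% names(x))) {
    stop("missing parameters: ", paste(setdiff(nm, names(x)), collapse = ", "))
  }
  if (any(!is.finite(x))) stop("parameters must be finite")
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  chk(x[["prev0"]] >= 0 && x[["prev0"]] <= 1, "prev0 must lie in [0, 1]")
  chk(x[["r0"]] >= 0 && x[["r0"]] <= 1, "r0 must lie in [0, 1]")
  chk(x[["P0"]] > 0, "P0 must be positive")
  chk(x[["D0"]] > 0, "D0 must be positive")
  chk(x[["C0"]] >= 0, "C0 must be non-negative")
  chk(x[["i0"]] >= 0, "i0 must be non-negative")
  chk(x[["s"]] >= 0, "s must be non-negative")
  # gamma = 1 (no excess hazard) is the admissible boundary case; the fitted
  # prior puts zero mass on it.
  chk(x[["gamma"]] >= 1, "gamma must be >= 1")
  betas <- x[paste0("beta_", stream_names())]
  chk(all(betas > 0), "all dispersions beta must be positive")
  invisible(x)
}

#' @export
print.distress_params <- function(x, digits = 4, ...) {
  cat("Distress model parameters:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

# ---- unconstrained reparameterisation for sampling ------------------------
# log for positive parameters, logit for proportions, log(gamma - 1) for the
# hazard ratio, identity for unbounded slopes/trends. Jacobian terms are the
# standard change-of-variable corrections so densities stated on the natural
# scale can be sampled on the unconstrained scale.

.transform_kind <- function() {
  c(prev0 = "logit", P0 = "log", g = "identity", D0 = "log", h = "identity",
    gamma = "log1m", i0 = "log", delta_i = "identity", s = "log",
    C0 = "log", u = "identity", r0 = "logit", delta_r = "identity",
    beta_distress = "log", beta_population = "log", beta_mortality = "log",
    beta_services = "log")
}

to_unconstrained <- function(x) {
  kind <- .transform_kind()[names(x)]
  u <- numeric(length(x))
  names(u) <- names(x)
  for (j in seq_along(x)) {
    u[j] <- switch(kind[j],
      log = log(x[[j]]),
      logit = stats::qlogis(x[[j]]),
      log1m = log(x[[j]] - 1),
      identity = x[[j]])
  }
  u
}

to_constrained <- function(u) {
  kind <- .transform_kind()[names(u)]
  x <- numeric(length(u))
  names(x) <- names(u)
  for (j in seq_along(u)) {
    x[j] <- switch(kind[j],
      log = exp(u[[j]]),
      logit = stats::plogis(u[[j]]),
      log1m = 1 + exp(u[[j]]),
      identity = u[[j]])
  }
  x
}

# log |dx/du| summed over components, evaluated at unconstrained u
log_jacobian <- function(u) {
  kind <- .transform_kind()[names(u)]
  lj <- 0
  for (j in seq_along(u)) {
    lj <- lj + switch(kind[j],
      log = u[[j]],
      log1m = u[[j]],
      logit = {
        p <- stats::plogis(u[[j]])
        log(p) + log1p(-p)
      },
      identity = 0)
  }
  lj
}
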