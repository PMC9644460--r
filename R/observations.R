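#' Construct an observation set
#'
#' The four observed count streams: `distress` (adults with high/very-high
#' psychological distress, survey years only), `population` (mid-year adult
#' population), `mortality` (total adult deaths per year) and `services`
#' (adults with high/very-high distress receiving subsidised mental-health
#' care per year).
#'
#' @param records data.frame with columns `stream` (one of
#'   [stream_names()]), `year` (calendar year) and `value` (non-negative
#'   integer count). `(stream, year)` pairs must be unique.
#' @return data.frame of class `observation_set`.
#' @export
observation_set <- function(records) {
  records <- as.data.frame(records)
  need <- c("stream", "year", "value")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  records <- records[need]
  records$stream <- as.character(records$stream)
  bad <- !records$stream %in% stream_names()
  if (any(bad)) {
    stop("unknown stream(s) ", paste(unique(records$stream[bad]),
                                     collapse = ", "),
         "; allowed: ", paste(stream_names(), collapse = ", "))
  }
  if (nrow(records) > 0) {
    v <- records$value
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop("values must be non-negative integers")
    }
    records$value <- as.numeric(round(v))
    key <- paste(records$stream, records$year)
    if (anyDuplicated(key)) {
      stop("duplicate (stream, year) pairs: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
  }
  structure(records, class = c("observation_set", "data.frame"))
}

#' Read / write an observation set CSV
#'
#' CSV dialect: header `stream,year,value`; streams named
#' `distress|population|mortality|services`; values non-negative integer
#' counts. Parse errors report the offending line.
#'
#' @param path file path.
#' @param obs an `observation_set`.
#' @return `read_observations` returns an `observation_set`;
#'   `write_observations` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observations file not found: ", path)
  df <- utils::read.csv(path, colClasses = c("character", "numeric",
                                             "numeric"))
  if (!identical(names(df), c("stream", "year", "value"))) {
    stop("observations CSV must have header stream,year,value (got: ",
         paste(names(df), collapse = ","), ")")
  }
  lineno <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- !df$stream %in% stream_names()
  if (any(bad)) {
    stop("line ", lineno[which(bad)[1]], ": unknown stream '",
         df$stream[which(bad)[1]], "'; allowed: ",
         paste(stream_names(), collapse = ", "))
  }
  bad <- !is.finite(df$value) | df$value < 0 | df$value != round(df$value)
  if (any(bad)) {
    stop("line ", lineno[which(bad)[1]], ": value '",
         df$value[which(bad)[1]], "' is not a non-negative integer")
  }
  key <- paste(df$stream, df$year)
  if (anyDuplicated(key)) {
    stop("line ", lineno[which(duplicated(key))[1]],
         ": duplicate (stream, year) record")
  }
  observation_set(df)
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Evaluation time of a record: mid-year (the population stream is a 30 June
# snapshot; yearly flow totals are approximated by the mid-year rate).
observation_time <- function(year) (year - 2008) + 0.5

#' Expected value of each observed record under a trajectory
#'
#' Maps each record to the model quantity it measures at the record's
#' mid-year evaluation time `t = (year - 2008) + 0.5`: `distress` to `M`,
#' `population` to `P`, `mortality` to `D`, `services` to `C`. Values are
#' taken from the stored grid, with linear interpolation between stored
#' times; an error is raised for records outside the trajectory.
#'
#' @param traj a `distress_trajectory` covering all observation times.
#' @param obs an `observation_set`.
#' @return numeric vector of expected counts, one per record of `obs`.
#' @export
observation_means <- function(traj, obs) {
  if (nrow(obs) == 0) return(numeric(0))
  tt <- observation_time(obs$year)
  if (any(tt < min(traj$time) - 1e-9) || any(tt > max(traj$time) + 1e-9)) {
    stop("observation time outside the simulated trajectory")
  }
  col <- c(distress = "M", population = "P", mortality = "D",
           services = "C")[obs$stream]
  out <- numeric(nrow(obs))
  for (cl in unique(col)) {
    sel <- col == cl
    # exact stored times when available; linear interpolation otherwise
    pos <- match(tt[sel], traj$time)
    if (anyNA(pos)) {
      if (nrow(traj) < 2) stop("observation time outside the simulated trajectory")
      out[sel] <- stats::approx(traj$time, traj[[cl]], xout = tt[sel],
                                rule = 1)$y
    } else {
      out[sel] <- traj[[cl]][pos]
    }
  }
  out
}

#' Negative-binomial log-pmf (gamma-Poisson, inverse-scale form)
#'
#' Parameterised by its mean `m` and inverse scale `beta`: the count is
#' Poisson with a Gamma(shape `beta * m`, rate `beta`) mixing distribution,
#' so `E[y] = m` and `Var[y] = m (1 + 1/beta)`. `beta -> Inf` recovers the
#' Poisson.
#'
#' @param y non-negative integer counts.
#' @param mean positive expected counts.
#' @param beta positive inverse-scale dispersion.
#' @return log-probabilities, vectorised.
#' @details The gamma-Poisson pmf
#'   `exp(lgamma(y + a) - lgamma(a) - lgamma(y + 1)) * (beta/(1+beta))^a *
#'   (1/(1+beta))^y` with shape `a = beta * mean` is evaluated through
#'   [stats::dnbinom()] (`size = a`, `prob = beta/(1+beta)`), whose
#'   saddle-point algorithm stays accurate when `a` is very large, where the
#'   direct `lgamma` difference loses all precision.
#' @examples
#' negbin_logpmf(3, mean = 5, beta = 2)
#' @export
negbin_logpmf <- function(y, mean, beta) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    stop("y must be non-negative integers")
  }
  if (any(mean <= 0)) stop("mean must be positive")
  if (any(beta <= 0)) stop("beta must be positive")
  stats::dnbinom(y, size = beta * mean, prob = beta / (1 + beta), log = TRUE)
}

#' Draw negative-binomial counts (mean / inverse-scale form)
#'
#' @param n number of draws.
#' @param mean positive mean.
#' @param beta positive inverse-scale dispersion.
#' @return integer-valued numeric vector.
#' @export
rnegbin <- function(n, mean, beta) {
  stats::rnbinom(n, size = beta * mean, mu = mean)
}

#' Total log-likelihood of an observation set
#'
#' Simulates the trajectory once (stored exactly at the observation times),
#' maps records to expected counts and sums the negative-binomial log-pmfs
#' using each stream's dispersion. Deviations are treated as independent, so
#' the total is the sum over records. Returns `-Inf` (not an error) if any
#' expected mean is non-positive.
#'
#' @param params a [model_parameters()] vector (including dispersions).
#' @param obs an `observation_set`; an empty set gives log-likelihood 0.
#' @return scalar log-likelihood.
#' @export
total_log_likelihood <- function(params, obs) {
  params <- as_model_parameters(params)
  if (nrow(obs) == 0) return(0)
  tt <- sort(unique(observation_time(obs$year)))
  traj <- simulate_trajectory(params, times = tt)
  m <- observation_means(traj, obs)
  if (any(m <= 0)) return(-Inf)
  beta <- unclass(params)[paste0("beta_", obs$stream)]
  sum(negbin_logpmf(obs$value, m, beta))
}

# ---- fast path used by the sampler ----------------------------------------
# Precompile an observation set: the ODE is needed only for the distress
# stream; population/mortality/services means are closed-form in t.
precompile_obs <- function(obs) {
  tt <- observation_time(obs$year)
  list(
    y = obs$value,
    stream = obs$stream,
    t = tt,
    is_distress = obs$stream == "distress",
    distress_t = sort(unique(tt[obs$stream == "distress"])),
    n = nrow(obs)
  )
}

# dyn: numeric vector of the 13 dynamic parameters in canonical order;
# betas: named beta_<stream> vector. Returns -Inf on any invalid regime.
loglik_fast <- function(dyn, betas, pre, rtol = 1e-8, atol = 1e-4) {
  if (pre$n == 0) return(0)
  m <- numeric(pre$n)
  P0 <- dyn[2]; g <- dyn[3]; D0 <- dyn[4]; h <- dyn[5]
  C0 <- dyn[10]; u <- dyn[11]
  sel <- pre$stream == "population"
  m[sel] <- P0 + g * pre$t[sel]
  sel <- pre$stream == "mortality"
  m[sel] <- D0 + h * pre$t[sel]
  sel <- pre$stream == "services"
  m[sel] <- C0 + u * pre$t[sel]
  if (any(pre$is_distress)) {
    sol <- ode_solve_cpp(dyn, pre$distress_t, rtol, atol)
    if (sol$status != 0) return(-Inf)
    M <- sol$M[match(pre$t[pre$is_distress], pre$distress_t)]
    m[pre$is_distress] <- M
  }
  if (any(m <= 0) || any(!is.finite(m))) return(-Inf)
  b <- betas[paste0("beta_", pre$stream)]
  sum(stats::dnbinom(pre$y, size = b * m, prob = b / (1 + b), log = TRUE))
}
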