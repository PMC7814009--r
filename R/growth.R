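#' Growth-model parameters
#'
#' Central parameterisation used for the crayfish invasion simulations: a
#' per-capita growth rate of `offspring_rate = exp(g)` offspring per animal
#' and per year (central 200, spread +-100), a carrying capacity `N_max`
#' (default 192,000 animals, the total population estimate), a strong-Allee
#' threshold `A` (default -3.1; negative thresholds accelerate growth at
#' low density), a step size `dt` in years (default 1/365: the per-step
#' updates are stated without an explicit time unit, so `g` is scaled by
#' `dt` per step and a daily step keeps the discrete updates in the smooth
#' regime `g*dt <= 1`), `N0` founders (default 1, a clonal population) and
#' a simulation horizon in years.
#'
#' @param offspring_rate Offspring per animal per year; `g = log(offspring_rate)`.
#' @param N_max Carrying capacity (animals).
#' @param A Allee threshold (animals; negative for the established value -3.1).
#' @param dt Years per step.
#' @param N0 Founding population size.
#' @param horizon Years simulated.
#' @return A list of class `growth_params` (includes `g`).
#' @export
growth_params <- function(offspring_rate = 200, N_max = 192000, A = -3.1,
                          dt = 1 / 365, N0 = 1, horizon = 6) {
  stopifnot(offspring_rate > 0, dt > 0, N0 >= 1, horizon > 0)
  structure(list(offspring_rate = offspring_rate, g = log(offspring_rate),
                 N_max = N_max, A = A, dt = dt, N0 = N0, horizon = horizon),
            class = "growth_params")
}

#' Variability parameters for converting population size to genetic variability
#'
#' @param mu Mutation rate per basepair per year (default 3.6e-9, the
#'   arthropod reference rate).
#' @param G Genome length in basepairs (default 3,511,656,756, the marbled
#'   crayfish assembly).
#' @param snv_per_specimen Mean SNV count per sequenced specimen.
#' @param current_N Census size of the current population.
#' @return A list of class `variability_params`.
#' @export
variability_params <- function(mu = 3.6e-9, G = 3511656756,
                               snv_per_specimen = NULL, current_N = NULL) {
  stopifnot(mu > 0, G > 0)
  structure(list(mu = mu, G = G, snv_per_specimen = snv_per_specimen,
                 current_N = current_N),
            class = "variability_params")
}

#' One step of discrete exponential growth
#'
#' `N_{i+1} = N_i * exp(g * dt)`; composing steps over any partition of an
#' interval matches the closed form `N(t) = N(t0) * exp(g (t - t0))`
#' exactly.
#'
#' @param N Current population size (>= 0).
#' @param g Per-year log growth rate.
#' @param dt Step length in years.
#' @return The next population size.
#' @export
step_exponential <- function(N, g, dt) {
  stopifnot(all(N >= 0))
  N * exp(g * dt)
}

#' One step of discrete logistic growth
#'
#' `N_{i+1} = N_i + (g*dt) * N_i * (1 - N_i / N_max)`; `N_max` is a fixed
#' point, approached monotonically from below when `0 < g*dt <= 1`.
#'
#' @param N Current population size.
#' @param g Per-year log growth rate.
#' @param N_max Carrying capacity.
#' @param dt Step length in years (the update uses the per-step rate `g*dt`).
#' @return The next population size.
#' @export
step_logistic <- function(N, g, N_max, dt) {
  stopifnot(all(N >= 0), N_max > 0)
  if (g * dt > 1) {
    warning("g*dt > 1: discrete logistic update may overshoot (oscillatory regime)")
  }
  N + (g * dt) * N * (1 - N / N_max)
}

#' One step of growth with a strong Allee effect
#'
#' `Delta N = N * (g*dt) * (1 - A / N)`.  With a negative threshold `A` the
#' multiplier `(1 - A/N)` exceeds 1, so each increment strictly exceeds the
#' pure-exponential increment for the same `g*dt`.  `N = 0` is absorbing.
#'
#' @param N Current population size.
#' @param g Per-year log growth rate.
#' @param A Allee threshold.
#' @param dt Step length in years.
#' @return The next population size.
#' @export
step_allee <- function(N, g, A, dt) {
  stopifnot(all(N >= 0))
  ifelse(N == 0, 0, N + N * (g * dt) * (1 - A / N))
}

#' Simulate a population-growth trajectory
#'
#' Steps the chosen discrete model from `params$N0` over the horizon with
#' step `params$dt`.
#'
#' @param model `"exponential"`, `"logistic"` or `"allee"`.
#' @param params A [growth_params()].
#' @return A data frame of class `growth_trajectory` with columns `time`
#'   (years, strictly increasing) and `N`, and attributes `model`,
#'   `params`.
#' @export
simulate_growth <- function(model = c("exponential", "logistic", "allee"),
                            params = growth_params()) {
  model <- match.arg(model)
  stopifnot(inherits(params, "growth_params"))
  n_steps <- ceiling(params$horizon / params$dt)
  times <- seq(0, by = params$dt, length.out = n_steps + 1L)
  N <- numeric(n_steps + 1L)
  N[1] <- params$N0
  for (i in seq_len(n_steps)) {
    N[i + 1L] <- switch(model,
      exponential = step_exponential(N[i], params$g, params$dt),
      logistic = step_logistic(N[i], params$g, params$N_max, params$dt),
      allee = step_allee(N[i], params$g, params$A, params$dt))
  }
  out <- data.frame(time = times, N = N)
  attr(out, "model") <- model
  attr(out, "params") <- params
  class(out) <- c("growth_trajectory", "data.frame")
  out
}

#' Run the discrete logistic model to convergence
#'
#' Steps the logistic update from `params$N0` until the per-step increment
#' falls below `tol`, returning the converged population size (the carrying
#' capacity for any `0 < g*dt <= 1` and `0 < N0 < N_max`).
#'
#' @param params A [growth_params()].
#' @param tol Convergence tolerance on `|N_{i+1} - N_i|` (animals).
#' @param max_steps Safety cap on iterations.
#' @return The converged population size.
#' @export
logistic_equilibrium <- function(params = growth_params(), tol = 1e-6,
                                 max_steps = 1e7) {
  stopifnot(inherits(params, "growth_params"))
  N <- params$N0
  for (i in seq_len(max_steps)) {
    N_next <- step_logistic(N, params$g, params$N_max, params$dt)
    if (abs(N_next - N) < tol) return(N_next)
    N <- N_next
  }
  stop("logistic iteration did not converge within max_steps", call. = FALSE)
}

#' @method print growth_trajectory
#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf("%s growth trajectory: %d steps over %.2f years, N %.3g -> %.4g\n",
              attr(x, "model"), nrow(x) - 1L, max(x$time), x$N[1],
              x$N[nrow(x)]))
  invisible(x)
}

#' @method plot growth_trajectory
#' @export
plot.growth_trajectory <- function(x, log = "y", ...) {
  plot(x$time, pmax(x$N, .Machine$double.xmin), type = "l", log = log,
       xlab = "time (years)", ylab = "population size N(t)", ...)
  invisible(x)
}

#' Genetic variability of the current (census) population
#'
#' `v_now = snv_per_specimen * current_N`: the mean per-specimen SNV count
#' multiplied by the census size estimate, with the order of magnitude
#' (one significant figure) reported alongside.
#'
#' @param vp A [variability_params()] with `snv_per_specimen` and
#'   `current_N` set.
#' @return A list with `value` and `magnitude` (value rounded to one
#'   significant figure).
#' @export
variability_current <- function(vp) {
  stopifnot(inherits(vp, "variability_params"))
  if (is.null(vp$snv_per_specimen) || is.null(vp$current_N)) {
    stop("snv_per_specimen and current_N must both be set", call. = FALSE)
  }
  v <- vp$snv_per_specimen * vp$current_N
  list(value = v, magnitude = signif(v, 1))
}

#' Convert a growth trajectory to a genetic-variability curve
#'
#' Two documented strategies map census size to the population's total
#' genetic variability (expected SNV content):
#' \describe{
#'   \item{`"cumulative"` (default)}{\eqn{v(t) = \mu G \int_0^t N(s)\,ds},
#'     the expected total number of mutation events that have occurred in
#'     the population since founding (each lineage mutates at \eqn{\mu G}
#'     per year; integrating census size counts lineage-years).  Evaluated
#'     by the cumulative trapezoid rule over the trajectory grid.}
#'   \item{`"census_age"`}{\eqn{v(t) = N(t)\,\mu G\,t}, the expected
#'     per-lineage mutation load since founding multiplied by census size.}
#' }
#' The strategy used is recorded in the result's metadata.
#'
#' @param traj A `growth_trajectory`.
#' @param vp A [variability_params()].
#' @param strategy `"cumulative"` or `"census_age"`.
#' @return A data frame of class `variability_curve` with columns `time`,
#'   `N`, `v`; attributes `strategy`, `mu`, `G`, `model`.
#' @export
variability_trajectory <- function(traj, vp = variability_params(),
                                   strategy = c("cumulative", "census_age")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(traj, "growth_trajectory"),
            inherits(vp, "variability_params"))
  muG <- vp$mu * vp$G
  v <- switch(strategy,
    cumulative = {
      dt <- diff(traj$time)
      mid <- (traj$N[-1] + traj$N[-nrow(traj)]) / 2
      muG * c(0, cumsum(mid * dt))
    },
    census_age = traj$N * muG * traj$time)
  out <- data.frame(time = traj$time, N = traj$N, v = v)
  attr(out, "strategy") <- strategy
  attr(out, "mu") <- vp$mu
  attr(out, "G") <- vp$G
  attr(out, "model") <- attr(traj, "model")
  class(out) <- c("variability_curve", "data.frame")
  out
}

#' @method print variability_curve
#' @export
print.variability_curve <- function(x, ...) {
  cat(sprintf("Variability curve (%s model, strategy '%s'): v(%.2f y) = %.3g\n",
              attr(x, "model"), attr(x, "strategy"), max(x$time),
              x$v[nrow(x)]))
  invisible(x)
}

#' @method plot variability_curve
#' @export
plot.variability_curve <- function(x, v_target = NULL, ...) {
  plot(x$time, pmax(x$v, .Machine$double.xmin), type = "l", log = "y",
       xlab = "time (years)", ylab = "total genetic variability v(t)", ...)
  if (!is.null(v_target)) abline(h = v_target, lty = 2)
  invisible(x)
}

#' First time a variability curve reaches a target level
#'
#' The smallest `t` with `v(t) >= v_target`, located on the curve's grid
#' and refined by bisection (root of the interpolated `v(t) - v_target`)
#' between the bracketing steps to a tolerance of 1e-3 years.
#'
#' @param curve A `variability_curve` (monotone nondecreasing `v`).
#' @param v_target Target variability level.
#' @param tol Time tolerance in years.
#' @return The intersection time in years, or `NA` (with a warning
#'   reporting the horizon) when the curve never reaches the target.
#' @export
intersection_time <- function(curve, v_target, tol = 1e-3) {
  stopifnot(inherits(curve, "variability_curve"), v_target >= 0)
  if (v_target <= curve$v[1]) return(curve$time[1])
  hit <- which(curve$v >= v_target)
  if (!length(hit)) {
    warning(sprintf("curve never reaches the target within the %.2f-year horizon",
                    max(curve$time)))
    return(NA_real_)
  }
  i <- hit[1]
  f <- approxfun(curve$time[c(i - 1L, i)], curve$v[c(i - 1L, i)] - v_target)
  uniroot(f, lower = curve$time[i - 1L], upper = curve$time[i],
          tol = tol)$root
}

#' Intersection time with an error band from the growth-rate spread
#'
#' Recomputes the intersection at the central offspring rate and at the
#' ends of its spread (default 200 +- 100 offspring per animal per year);
#' the band is reported as the half-width of the two extreme times.  For
#' the logistic model, the carrying-capacity SE (34.98%) can additionally
#' widen the band via `N_max_se_frac`.
#'
#' @param model Growth model passed to [simulate_growth()].
#' @param params Central [growth_params()].
#' @param vp A [variability_params()].
#' @param v_target Target variability.
#' @param spread Absolute spread on `offspring_rate` (default 100).
#' @param strategy Variability strategy (see [variability_trajectory()]).
#' @param N_max_se_frac Optional relative SE applied to `N_max` at the band
#'   ends (logistic model only).
#' @return A list of class `intersection_estimate`: `t_star`, `band`
#'   (+- half-width), `t_low_rate`, `t_high_rate`, `strategy`, `model`.
#' @export
intersection_band <- function(model = "exponential",
                              params = growth_params(),
                              vp = variability_params(),
                              v_target, spread = 100,
                              strategy = c("cumulative", "census_age"),
                              N_max_se_frac = NULL) {
  strategy <- match.arg(strategy)
  t_at <- function(rate, nmax_mult = 1) {
    p <- params
    p$offspring_rate <- rate
    p$g <- log(rate)
    p$N_max <- params$N_max * nmax_mult
    curve <- variability_trajectory(simulate_growth(model, p), vp, strategy)
    intersection_time(curve, v_target)
  }
  t_star <- t_at(params$offspring_rate)
  lo_mult <- if (!is.null(N_max_se_frac) && model == "logistic")
    1 - N_max_se_frac else 1
  hi_mult <- if (!is.null(N_max_se_frac) && model == "logistic")
    1 + N_max_se_frac else 1
  t_high_rate <- t_at(params$offspring_rate + spread, hi_mult)
  t_low_rate <- t_at(max(params$offspring_rate - spread, 1.5), lo_mult)
  band <- (t_low_rate - t_high_rate) / 2
  structure(list(t_star = t_star, band = band, t_low_rate = t_low_rate,
                 t_high_rate = t_high_rate, strategy = strategy,
                 model = model),
            class = "intersection_estimate")
}

#' @method print intersection_estimate
#' @export
print.intersection_estimate <- function(x, ...) {
  cat(sprintf("Variability intersection (%s model, strategy '%s'): t* = %.2f (+- %.2f) years\n",
              x$model, x$strategy, x$t_star, x$band))
  invisible(x)
}
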