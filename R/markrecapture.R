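#' Schnabel multi-day mark-recapture population estimate
#'
#' For a closed population sampled on consecutive days with persistent
#' marks, the Schnabel estimator pools catches across traps and computes
#' \deqn{\hat N = \sum_t C_t M_t / \sum_t R_t,}
#' where \eqn{C_t} is the day-\eqn{t} catch, \eqn{M_t} the marked animals at
#' large before day \eqn{t} and \eqn{R_t} the marked animals in the catch.
#' The standard error uses the classical Poisson treatment of the recapture
#' total: \eqn{SE = \hat N / \sqrt{\sum_t R_t}}.
#'
#' @param survey A `trap_survey`, or a data frame with columns `C`, `M`,
#'   `R` (one row per day).
#' @param chapman With zero recaptures the plain estimator is undefined;
#'   `chapman = TRUE` applies the +1 correction
#'   \eqn{\hat N = \sum C_t M_t / (\sum R_t + 1)}.
#' @return A list of class `schnabel_estimate`: `N_hat`, `SE`,
#'   `sum_R` (recapture total), `daily` (the pooled table), `method`.
#' @export
schnabel <- function(survey, chapman = FALSE) {
  daily <- if (inherits(survey, "trap_survey")) survey$daily else survey
  stopifnot(all(c("C", "M", "R") %in% names(daily)))
  if (nrow(daily) < 2L) stop("need at least 2 survey days", call. = FALSE)
  if (any(daily$R > pmin(daily$C, daily$M))) {
    stop("invalid survey: R_t must not exceed min(C_t, M_t)", call. = FALSE)
  }
  sum_R <- sum(daily$R)
  num <- sum(daily$C * daily$M)
  if (sum_R == 0 && !chapman) {
    stop("zero recaptures: Schnabel estimate undefined; ",
         "consider the Chapman-style correction (chapman = TRUE)",
         call. = FALSE)
  }
  N_hat <- if (chapman) num / (sum_R + 1) else num / sum_R
  SE <- if (sum_R > 0) N_hat / sqrt(sum_R) else Inf
  structure(list(N_hat = N_hat, SE = SE, sum_R = sum_R, daily = daily,
                 method = if (chapman) "schnabel-chapman" else "schnabel"),
            class = "schnabel_estimate")
}

#' @method print schnabel_estimate
#' @export
print.schnabel_estimate <- function(x, ...) {
  cat(sprintf("Schnabel mark-recapture estimate: N = %.0f (SE = %.0f), %d recaptures over %d days\n",
              x$N_hat, x$SE, x$sum_R, nrow(x$daily)))
  invisible(x)
}

#' @method coef schnabel_estimate
#' @export
coef.schnabel_estimate <- function(object, ...) {
  c(N_hat = object$N_hat, SE = object$SE)
}

#' Fit the mark-recapture saturation curve y = a(1 - exp(-c x))
#'
#' Nonlinear least squares (Levenberg–Marquardt, via
#' [minpack.lm::nlsLM()]) of the two-parameter negative exponential used to
#' predict the cumulative-marking plateau when saturation is not reached
#' within the survey.  Initialisation: `a0 = 1.2 * max(y)` and `c0` from a
#' log-linearisation of the first informative point.
#'
#' @param x Sampling occasions (days).
#' @param y Cumulative number of distinct marked animals (nondecreasing).
#' @param monotone Enforce the nondecreasing-`y` precondition of cumulative
#'   mark counts; set `FALSE` for calibration on freely perturbed data.
#' @return A list of class `saturation_fit`: `a`, `c`, `se` (named vector),
#'   `rss`, and the underlying `nls` fit.
#' @export
fit_saturation <- function(x, y, monotone = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (monotone && any(diff(y[order(x)]) < -1e-9)) {
    stop("y must be nondecreasing in x", call. = FALSE)
  }
  a0 <- 1.2 * max(y)
  y1 <- y[which(y > 0)[1]]
  x1 <- x[which(y > 0)[1]]
  c0 <- if (!is.na(y1) && y1 < a0) -log(1 - y1 / a0) / x1 else 1
  # keep the rate start inside the well-conditioned region; the optimiser
  # can grow it from there (plateau data drives c upward)
  c0 <- max(min(c0, 2 / max(x)), 1e-6)
  fit <- minpack.lm::nls.lm(
    par = c(a = a0, cc = c0),
    fn = function(p) y - p[1] * (1 - exp(-p[2] * x)),
    lower = c(1e-9, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 5000))
  if (!fit$info %in% c(1:4, 6, 7)) {
    stop("saturation fit did not converge: ", fit$message, call. = FALSE)
  }
  cf <- fit$par
  rss <- sum(fit$fvec^2)
  dof <- length(x) - 2L
  se <- tryCatch({
    covm <- rss / dof * solve(fit$hessian)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) c(NA_real_, NA_real_))
  structure(list(a = unname(cf["a"]), c = unname(cf["cc"]),
                 se = c(a = unname(se[1]), c = unname(se[2])),
                 rss = rss, fit = fit,
                 data = data.frame(x = x, y = y)),
            class = "saturation_fit")
}

#' @method print saturation_fit
#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation fit y = a(1 - exp(-c x)): a = %.2f (SE %.2f), c = %.4f (SE %.4f), RSS = %.3g\n",
              x$a, x$se["a"], x$c, x$se["c"], x$rss))
  invisible(x)
}

#' @method coef saturation_fit
#' @export
coef.saturation_fit <- function(object, ...) {
  c(a = object$a, c = object$c)
}

#' @method predict saturation_fit
#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  object$a * (1 - exp(-object$c * x))
}

#' @method plot saturation_fit
#' @export
plot.saturation_fit <- function(x, ...) {
  plot(x$data$x, x$data$y, pch = 19, xlab = "day",
       ylab = "cumulative marked animals", ...)
  xx <- seq(0, max(x$data$x) * 2, length.out = 200)
  lines(xx, predict(x, xx))
  abline(h = x$a, lty = 2)
  invisible(x)
}

#' Bathymetric strata for the stratified abundance extrapolation
#'
#' Each stratum is a depth band with a surface area and a number of traps;
#' each trap is taken as the sampling point for `area / traps` square
#' meters.  `lake_strata()` with no arguments returns the published survey
#' design: depth <= 4 m with 47,500 m2 and 10 traps, 5-10 m with 16,000 m2
#' and 4 traps, > 10 m with 29,000 m2 and 4 traps (area per trap 4,750,
#' 4,000 and 7,250 m2).
#'
#' @param depth_range Character labels of the depth bands.
#' @param area_m2 Stratum surface areas (m2); must sum to the lake area.
#' @param n_traps Traps per stratum (all strata must have traps).
#' @param area_per_trap Assumed sampling area per trap (m2); defaults to
#'   `area_m2 / n_traps`, the canonical design where the traps tile the
#'   stratum.
#' @param area_se_frac Relative SE on each stratum area (default 0.10).
#' @return A data frame of class `lake_strata` with the per-trap area
#'   column `area_per_trap`.
#' @export
lake_strata <- function(depth_range = c("0-4m", "5-10m", ">10m"),
                        area_m2 = c(47500, 16000, 29000),
                        n_traps = c(10L, 4L, 4L),
                        area_per_trap = area_m2 / n_traps,
                        area_se_frac = 0.10) {
  stopifnot(length(depth_range) == length(area_m2),
            length(area_m2) == length(n_traps))
  if (any(n_traps <= 0)) {
    stop("every stratum must contain at least one trap", call. = FALSE)
  }
  out <- data.frame(stratum_id = paste0("S", seq_along(area_m2)),
                    depth_range = depth_range, area_m2 = area_m2,
                    n_traps = as.integer(n_traps),
                    area_per_trap = area_per_trap,
                    stringsAsFactors = FALSE)
  attr(out, "lake_area_m2") <- sum(area_m2)
  attr(out, "area_se_frac") <- area_se_frac
  class(out) <- c("lake_strata", "data.frame")
  out
}

#' Extrapolate the mature trap-based estimate to the whole population
#'
#' Two density paths are computed and reported.  The trap-area path
#' allocates the mature (trappable) abundance estimate to strata by each
#' stratum's share of the trap catch, converts to a density over the
#' stratum's assumed sampled area (`n_traps * area_per_trap`) and
#' re-extrapolates over the stratum's true area; with the canonical design
#' (area-per-trap = area / traps everywhere) this is a no-op and the mature
#' abundance equals the input estimate.  The hand-catch path multiplies the
#' mean hand-catch density by the lake area as an all-sizes cross-check.
#' The total population is the mature abundance divided by the mature
#' fraction `f` of the hand-catch size distribution (share of animals above
#' the 6 cm trap cutoff).
#'
#' @param mature_estimate Mature abundance (animals), e.g. a Schnabel
#'   `N_hat` or a saturation-fit asymptote scaled to the lake.
#' @param strata A [lake_strata()] table.
#' @param hand_catch List with `densities` (data frame with a `density`
#'   column, animals/m2) and `sizes` (numeric, cm), as produced by
#'   [generate_trap_survey()]; or `NULL` to skip the cross-check (then
#'   `mature_fraction` must be given).
#' @param catch_by_stratum Optional named numeric of mature catches per
#'   stratum id; defaults to proportional to trap counts (uniform density).
#' @param mature_fraction Override for `f`; otherwise estimated as
#'   `mean(sizes > size_cutoff_cm)`.
#' @param size_cutoff_cm Trap size cutoff (default 6 cm).
#' @return A list of class `abundance_estimate`: `N_total`, `N_mature`,
#'   `f`, `density_path` (hand-catch cross-check), and `components`.
#' @export
stratified_total <- function(mature_estimate, strata, hand_catch = NULL,
                             catch_by_stratum = NULL, mature_fraction = NULL,
                             size_cutoff_cm = 6) {
  stopifnot(inherits(strata, "lake_strata"), mature_estimate > 0)
  if (is.null(catch_by_stratum)) {
    catch_by_stratum <- setNames(strata$n_traps, strata$stratum_id)
  }
  share <- catch_by_stratum[strata$stratum_id] /
    sum(catch_by_stratum)
  sampled_area <- strata$n_traps * strata$area_per_trap
  dens <- mature_estimate * share / sampled_area
  N_mature <- sum(dens * strata$area_m2)

  f <- if (!is.null(mature_fraction)) {
    check_fraction(mature_fraction, lo = 0, hi = 1)
  } else if (!is.null(hand_catch)) {
    mean(hand_catch$sizes > size_cutoff_cm)
  } else {
    stop("either hand_catch or mature_fraction must be supplied",
         call. = FALSE)
  }
  if (f == 0) stop("mature fraction is zero: cannot extrapolate",
                   call. = FALSE)
  N_total <- N_mature / f

  density_path <- if (!is.null(hand_catch) &&
                      !is.null(hand_catch$densities)) {
    mean(hand_catch$densities$density) * attr(strata, "lake_area_m2")
  } else NA_real_

  structure(list(N_total = N_total, N_mature = N_mature, f = f,
                 density_path = density_path,
                 components = list(stratum_density = dens,
                                   stratum_share = share,
                                   sampled_area = sampled_area,
                                   lake_area_m2 = attr(strata,
                                                       "lake_area_m2"))),
            class = "abundance_estimate")
}

#' @method print abundance_estimate
#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Stratified abundance: mature N = %.0f, mature fraction f = %.3f, total N = %.0f\n",
              x$N_mature, x$f, x$N_total))
  if (!is.null(x$SE)) cat(sprintf("  bootstrap SE = %.0f\n", x$SE))
  if (!is.na(x$density_path)) {
    cat(sprintf("  hand-catch density path (all sizes): %.0f animals\n",
                x$density_path))
  }
  invisible(x)
}

#' Bootstrap combined standard error for the stratified total
#'
#' Each replicate perturbs the uncertainty components and re-runs the
#' extrapolation: the Schnabel mature estimate (normal with its SE), the
#' saturation asymptote `a` when supplied (normal with its fit SE, entering
#' as an alternative mature-abundance input), every stratum area (normal,
#' `area_se_frac` relative SE, default 10%), and the hand-catch size
#' distribution (resampled with replacement, re-estimating the mature
#' fraction).  Replicates producing non-positive draws are rejected and
#' redrawn (count reported).  The combined SE is the standard deviation of
#' the replicate totals.
#'
#' @param schnabel_est A `schnabel_estimate`.
#' @param strata A [lake_strata()] table.
#' @param hand_catch Hand-catch list (`densities`, `sizes`).
#' @param saturation Optional `saturation_fit`; when given, each replicate
#'   draws the mature abundance from the asymptote's sampling distribution
#'   scaled by `schnabel_est$N_hat / fitted a` (so the two inputs agree in
#'   expectation) in half the replicates.
#' @param n_reps Bootstrap replicates (default 10,000).
#' @param seed Integer seed.
#' @param size_cutoff_cm Trap size cutoff (default 6 cm).
#' @return An `abundance_estimate` with `SE`, `components` (per-source SDs)
#'   and `n_rejected`.
#' @export
bootstrap_se <- function(schnabel_est, strata, hand_catch,
                         saturation = NULL, n_reps = 10000L, seed = 1L,
                         size_cutoff_cm = 6) {
  stopifnot(inherits(schnabel_est, "schnabel_estimate"),
            inherits(strata, "lake_strata"))
  n_reps <- check_count(n_reps)
  if (n_reps < 100L) warning("fewer than 100 bootstrap replicates: SE unstable")
  area_se <- attr(strata, "area_se_frac")
  base <- stratified_total(schnabel_est$N_hat, strata, hand_catch,
                           size_cutoff_cm = size_cutoff_cm)
  sizes <- hand_catch$sizes
  with_seed(seed, {
    totals <- numeric(n_reps)
    n_rejected <- 0L
    for (r in seq_len(n_reps)) {
      repeat {
        N_mat <- rnorm(1, schnabel_est$N_hat, schnabel_est$SE)
        if (!is.null(saturation) && r %% 2L == 0L &&
            is.finite(saturation$se["a"])) {
          scale <- schnabel_est$N_hat / saturation$a
          N_mat <- rnorm(1, saturation$a, saturation$se["a"]) * scale
        }
        areas <- rnorm(nrow(strata), strata$area_m2,
                       area_se * strata$area_m2)
        f_star <- mean(sample(sizes, replace = TRUE) > size_cutoff_cm)
        if (N_mat > 0 && all(areas > 0) && f_star > 0) break
        n_rejected <- n_rejected + 1L
      }
      s_star <- strata
      s_star$area_m2 <- areas
      s_star$area_per_trap <- areas / s_star$n_traps
      attr(s_star, "lake_area_m2") <- sum(areas)
      est <- stratified_total(N_mat, s_star, hand_catch = NULL,
                              mature_fraction = f_star)
      totals[r] <- est$N_total
    }
    base$SE <- sd(totals)
    base$replicates_summary <- quantile(totals, c(0.025, 0.5, 0.975))
    base$n_rejected <- n_rejected
    base$n_reps <- n_reps
    base
  })
}
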