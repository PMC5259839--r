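#' Total amount of compound used according to a fit
#'
#' The total amount a species uses is defined from the fitted model as
#' `q = xi(0) - o`, i.e. the modelled concentration at inoculation minus the
#' residual offset the species leaves behind.
#'
#' @inheritParams behrends_value
#' @return Scalar `q` in concentration units.
#' @export
total_used <- function(fit) {
  q <- behrends_value(fit, 0) - fit$o
  if (q <= 0) stop("total used amount q <= 0: degenerate fit")
  q
}

#' Half-depletion time T_h
#'
#' Time at which half of the total amount of compound actually used by the
#' species has been depleted. With `q = xi(0) - o`, `T_h` solves
#' `xi(T_h) = o + q/2`, which has the closed form
#' `T_h = t50 + w * log(2a/q - 1)`. `T_h` coincides with `t50` when the curve
#' starts on its plateau (`t50/w` large) and exceeds it when part of the
#' depletion transition lies before t = 0.
#'
#' @inheritParams behrends_value
#' @return `T_h` in hours.
#' @examples
#' half_depletion_time(behrends_fit(500, 20, 5, 0.5))
#' @export
half_depletion_time <- function(fit) {
  q <- total_used(fit)
  fit$t50 + fit$w * log(2 * fit$a / q - 1)
}

#' Usage window (90% to 10% of the amount used)
#'
#' Times at which the compound has been depleted to 90% and to 10% of the
#' total amount used by the species, i.e. `xi(t90) = o + 0.9 q` and
#' `xi(t10) = o + 0.1 q` with `q = xi(0) - o`. Closed forms:
#' `t_f = t50 + w * log(a/(f*q) - 1)` for `f = 0.9, 0.1`. For a plateau-start
#' fit the window length approaches `2 w log(9)`.
#'
#' @inheritParams behrends_value
#' @return Named numeric vector `c(t90 = , t10 = )`, hours, with
#'   `t90 < T_h < t10`.
#' @export
usage_window <- function(fit) {
  q <- total_used(fit)
  tf <- function(f) fit$t50 + fit$w * log(fit$a / (f * q) - 1)
  c(t90 = tf(0.9), t10 = tf(0.1))
}

#' Maximum absolute depletion rate
#'
#' The depletion rate `-d(xi)/dt` of the logistic is maximal at `t = t50`,
#' where it equals `a / (4 w)`.
#'
#' @inheritParams behrends_value
#' @return Named numeric vector `c(rate = , time = )` (concentration/h, h).
#' @export
max_depletion_rate <- function(fit) {
  c(rate = fit$a / (4 * fit$w), time = fit$t50)
}

#' Biomass trajectory from optical density
#'
#' Converts an OD600 growth curve to grams cell dry weight using a
#' predetermined conversion factor `k` (gCDW/L/OD600) and the declining
#' culture volume: `gcdw(t) = k * od600(t) * volume(t)`. The volume starts at
#' `v0` litres and decreases by `sample_draw_l` litres at each sampling event
#' (default 1.2 mL: 1 mL supernatant + 0.2 mL for the OD measurement); the
#' volume recorded for sampling event i is the volume present when that
#' sample is taken, i.e. after i - 1 previous draws.
#'
#' @param times Sampling times in hours (ascending).
#' @param od600 OD600 readings at `times` (>= 0).
#' @param k Conversion factor, gCDW/L/OD600 (> 0).
#' @param v0 Starting culture volume in litres (default 0.050).
#' @param sample_draw_l Volume removed per sampling event in litres
#'   (default 0.0012).
#' @return Data frame with columns `time_h`, `od600`, `volume_l`, `gcdw`.
#' @examples
#' biomass_trajectory(0:12, rep(0.5, 13), k = 0.9)
#' @export
biomass_trajectory <- function(times, od600, k, v0 = 0.050,
                               sample_draw_l = 0.0012) {
  stopifnot(length(times) == length(od600), k > 0, all(od600 >= 0),
            !is.unsorted(times))
  volume <- v0 - (seq_along(times) - 1) * sample_draw_l
  if (any(volume <= 0)) stop("culture volume exhausted by sampling draws")
  data.frame(time_h = times, od600 = od600, volume_l = volume,
             gcdw = k * od600 * volume)
}

#' Maximum depletion rate per unit biomass
#'
#' Converts the instantaneous depletion rate into a biomass-specific uptake
#' rate in mmol/h/gCDW. At each time on a dense grid the molar depletion rate
#' is `-d(xi)/dt * volume / 1000` (uM/h x L / 1000 = mmol/h) and is divided
#' by the biomass `gcdw(t)`, floored at the inoculum biomass so that rates
#' occurring before measurable growth are not divided by a vanishing
#' denominator; the reported value is the maximum of this ratio over the
#' grid. Very large values arise legitimately when a compound is depleted
#' before appreciable biomass has formed.
#'
#' @inheritParams behrends_value
#' @param biomass A data frame from [biomass_trajectory()] covering the fit's
#'   time range.
#' @param grid_step Evaluation grid step in hours (default 0.01).
#' @param inoculum Biomass floor in gCDW; default is the biomass at the first
#'   time point.
#' @return Named numeric vector `c(max_rate = , t_max_rate = ,
#'   max_rate_per_biomass = , t_max_rate_per_biomass = )` where `max_rate`
#'   is the absolute maximum `a/(4w)` in uM/h and `max_rate_per_biomass` is
#'   in mmol/h/gCDW.
#' @export
max_rate_per_biomass <- function(fit, biomass, grid_step = 0.01,
                                 inoculum = NULL) {
  stopifnot(is.data.frame(biomass), nrow(biomass) >= 2)
  if (all(biomass$gcdw == 0)) stop("biomass trajectory is all zero")
  if (is.null(inoculum)) inoculum <- biomass$gcdw[1]
  tmax <- max(biomass$time_h)
  grid <- seq(0, tmax, by = grid_step)
  vol <- stats::approx(biomass$time_h, biomass$volume_l, grid, rule = 2)$y
  gc <- stats::approx(biomass$time_h, biomass$gcdw, grid, rule = 2)$y
  gc <- pmax(gc, inoculum)
  rate <- .behrends_rate(grid, fit$a, fit$o, fit$t50, fit$w)   # uM/h
  per_bio <- rate * vol / 1000 / gc                            # mmol/h/gCDW
  i <- which.max(per_bio)
  c(max_rate = fit$a / (4 * fit$w), t_max_rate = fit$t50,
    max_rate_per_biomass = per_bio[i], t_max_rate_per_biomass = grid[i])
}

#' Specific growth rate from an OD600 curve
#'
#' Maximum specific growth rate mu (1/h): the largest least-squares slope of
#' `log(OD - blank)` over a sliding window of consecutive points. Windows
#' containing non-positive blank-corrected OD values are skipped. If no
#' window slope exceeds `noise_floor`, the compound is reported as not
#' supporting growth (`mu = 0`).
#'
#' @param times Times in hours.
#' @param od600 OD600 readings.
#' @param window_points Number of consecutive points per window (default 5).
#' @param blank Blank OD to subtract (default 0).
#' @param noise_floor Slope below which growth is called zero (default
#'   0.02/h).
#' @return Scalar `mu` in 1/h (0 for no growth).
#' @examples
#' t <- seq(0, 10, 0.5)
#' specific_growth_rate(t, 0.01 * exp(0.6 * t))   # 0.6
#' @export
specific_growth_rate <- function(times, od600, window_points = 5, blank = 0,
                                 noise_floor = 0.02) {
  stopifnot(length(times) == length(od600))
  y <- od600 - blank
  if (all(y <= 0)) stop("all blank-corrected OD values are non-positive")
  n <- length(y)
  if (n < window_points) stop("fewer points than the window size")
  best <- -Inf
  for (i in seq_len(n - window_points + 1)) {
    idx <- i:(i + window_points - 1)
    if (any(y[idx] <= 0)) next
    sl <- stats::cov(times[idx], log(y[idx])) / stats::var(times[idx])
    if (is.finite(sl) && sl > best) best <- sl
  }
  if (!is.finite(best) || best <= noise_floor) 0 else best
}

#' Substrate-preference metrics for a set of fits
#'
#' Computes, for every converged fit, the half-depletion time `T_h`, the
#' 90-to-10% usage window, and the maximum depletion rate (absolute and, when
#' a biomass trajectory is supplied for the species, per gram cell dry
#' weight).
#'
#' @param fits List of `behrends_fit` objects (see [fit_depletion()]).
#' @param biomass Optional named list mapping species to
#'   [biomass_trajectory()] data frames.
#' @return Data frame with one row per species x compound: `T_h`, `t90`,
#'   `t10`, `max_rate`, `max_rate_per_biomass` (NA without biomass data),
#'   plus `converged` and `flags`. Unconverged fits yield NA metrics.
#' @export
preference_metrics <- function(fits, biomass = NULL) {
  rows <- lapply(fits, function(f) {
    out <- data.frame(species = f$species, compound = f$compound,
                      T_h = NA_real_, t90 = NA_real_, t10 = NA_real_,
                      max_rate = NA_real_, max_rate_per_biomass = NA_real_,
                      converged = f$converged,
                      flags = paste(f$anomaly_flags, collapse = ";"),
                      stringsAsFactors = FALSE)
    if (f$converged && !"indeterminable" %in% f$anomaly_flags) {
      out$T_h <- half_depletion_time(f)
      win <- usage_window(f)
      out$t90 <- win[["t90"]]; out$t10 <- win[["t10"]]
      out$max_rate <- max_depletion_rate(f)[["rate"]]
      if (!is.null(biomass) && !is.null(biomass[[f$species]])) {
        mr <- max_rate_per_biomass(f, biomass[[f$species]])
        out$max_rate_per_biomass <- mr[["max_rate_per_biomass"]]
      }
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Correlate substrate preferences with specific growth rates
#'
#' For one species, Pearson-correlates the specific growth rate on each
#' compound as sole carbon source with (i) the half-depletion time `T_h` and
#' (ii) the maximum depletion rate per biomass, over the compounds whose
#' growth rate is nonzero; compounds with `mu = 0` (no growth as sole carbon
#' source) are excluded from the correlation and reported separately.
#'
#' @param metrics Data frame from [preference_metrics()] for one species
#'   (columns `compound`, `T_h`, `max_rate_per_biomass`).
#' @param growth_rates Named numeric vector of specific growth rates `mu`
#'   (1/h) indexed by compound.
#' @param species Optional species label carried into the output.
#' @return List with `correlations` (data frame: `species`, `metric`, `r`,
#'   `p`, `n`) and `zero_mu` (character vector of non-growth compounds).
#' @export
preference_correlations <- function(metrics, growth_rates,
                                    species = NA_character_) {
  stopifnot(all(c("compound", "T_h") %in% names(metrics)))
  mu <- growth_rates[metrics$compound]
  zero <- metrics$compound[!is.na(mu) & mu == 0]
  use <- !is.na(mu) & mu > 0
  one <- function(metric) {
    x <- mu[use]; y <- metrics[[metric]][use]
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3) {
      stop("fewer than 3 compounds with nonzero growth rate and a finite ",
           metric)
    }
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson",
                          alternative = "two.sided")
    data.frame(species = species, metric = metric,
               r = unname(ct$estimate), p = ct$p.value, n = sum(keep),
               stringsAsFactors = FALSE)
  }
  metrics_used <- c("T_h",
                    if ("max_rate_per_biomass" %in% names(metrics) &&
                        any(is.finite(metrics$max_rate_per_biomass[use])))
                      "max_rate_per_biomass")
  list(correlations = do.call(rbind, lapply(metrics_used, one)),
       zero_mu = as.character(zero))
}
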