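#' R-squared between observed co-culture data and a prediction
#'
#' Both the observed replicate means and the predicted curve are normalised by
#' the observed t = 0 mean, and the coefficient of determination is computed
#' as `1 - SS_res / SS_tot` with `SS_tot` taken about the mean of the
#' normalised observations. Flagged observed points (e.g. `out_of_range` from
#' quantification) are excluded; if fewer than `min_points` usable time
#' points remain the result is "not determined" (`r2 = NA`).
#'
#' @param observed Data frame with columns `time_h`, `value`, optionally
#'   `replicate` and `flags`, for one compound.
#' @param predicted Data frame `time_h`, `value` (a dense prediction grid) or
#'   a function of time. Must cover the observed time range.
#' @param min_points Minimum usable time points (default 4).
#' @param use `"means"` (default) scores replicate means; `"pooled"` scores
#'   every replicate point.
#' @return List with `r2` (NA when not determined), `n` (usable time points),
#'   and `residuals`: data frame `time_h`, `observed`, `predicted`,
#'   `residual` in t0-normalised units (residual = observed - predicted, so
#'   negative means faster-than-predicted depletion).
#' @export
r_squared <- function(observed, predicted, min_points = 4,
                      use = c("means", "pooled")) {
  use <- match.arg(use)
  # the t0 reference level uses every finite t = 0 measurement, flagged or
  # not: a t0 sample at the top of the calibrated range is still the best
  # available estimate of the starting concentration
  t0_all <- observed$value[observed$time_h == 0 & is.finite(observed$value)]
  if (!length(t0_all)) stop("observed series has no t = 0 mean")
  t0_mean <- mean(t0_all)
  if (t0_mean <= 0) stop("observed t = 0 mean is not positive")
  m <- .replicate_means(observed)
  if (!nrow(m)) stop("no usable observed points")
  pred_fn <- if (is.function(predicted)) {
    predicted
  } else {
    function(t) stats::approx(predicted$time_h, predicted$value, t,
                              rule = 2)$y
  }
  pts <- if (use == "means") m else .usable_points(observed)
  obs_n <- pts$value / t0_mean
  pred_n <- pred_fn(pts$time_h) / t0_mean
  res <- data.frame(time_h = pts$time_h, observed = obs_n,
                    predicted = pred_n, residual = obs_n - pred_n)
  if (length(unique(pts$time_h)) < min_points) {
    return(list(r2 = NA_real_, n = length(unique(pts$time_h)),
                residuals = res))
  }
  ss_res <- sum((obs_n - pred_n)^2)
  ss_tot <- sum((obs_n - mean(obs_n))^2)
  list(r2 = 1 - ss_res / ss_tot, n = length(unique(pts$time_h)),
       residuals = res)
}

# usage window of a predicted curve: times at which the curve crosses 90% and
# 10% of its total drop, by linear interpolation on the grid
.curve_window <- function(curve) {
  v0 <- curve$value[1]
  vmin <- min(curve$value)
  drop <- v0 - vmin
  if (drop <= 0) return(c(t90 = NA_real_, t10 = NA_real_))
  cross <- function(level) {
    below <- which(curve$value <= level)
    if (!length(below)) return(NA_real_)
    i <- below[1]
    if (i == 1) return(curve$time_h[1])
    t0 <- curve$time_h[i - 1]; t1 <- curve$time_h[i]
    y0 <- curve$value[i - 1]; y1 <- curve$value[i]
    t0 + (y0 - level) / (y0 - y1) * (t1 - t0)
  }
  c(t90 = cross(vmin + 0.9 * drop), t10 = cross(vmin + 0.1 * drop))
}

#' Classify compounds as consistent with or deviating from blind sharing
#'
#' A compound is `consistent` when its R-squared against the prediction
#' reaches the threshold (default 0.9). Below the threshold the direction of
#' the deviation is read from the mean signed residual (observed minus
#' predicted, t0-normalised) restricted to the predicted usage window, where
#' the curves are informative: negative means the compound was depleted
#' faster than predicted, positive slower. Compounds without a determined
#' R-squared are classed `not_determined`.
#'
#' @param results Data frame with one row per compound, columns `compound`,
#'   `r2`, `mean_signed_residual` (as produced by [evaluate_coculture()]).
#' @param threshold R-squared threshold for consistency (default 0.9).
#' @return The input with a `class` column added, one of `consistent`,
#'   `deviating_faster`, `deviating_slower`, `not_determined`.
#' @export
classify_compounds <- function(results, threshold = 0.9) {
  stopifnot(all(c("r2", "mean_signed_residual") %in% names(results)))
  cls <- ifelse(is.na(results$r2), "not_determined",
         ifelse(results$r2 >= threshold, "consistent",
         ifelse(results$mean_signed_residual < 0, "deviating_faster",
                "deviating_slower")))
  results$class <- cls
  results
}

#' Depletion checkpoints of a curve
#'
#' First time at which a (t0-normalised) depletion curve falls to or below
#' each requested fraction of its starting value; `Inf` when the curve never
#' reaches the fraction.
#'
#' @param curve Data frame `time_h`, `value`, non-increasing.
#' @param fractions Numeric vector of fractions of the starting value
#'   (default 0.10).
#' @return Named numeric vector of times in hours.
#' @export
depletion_checkpoints <- function(curve, fractions = 0.10) {
  stopifnot(nrow(curve) >= 1, all(diff(curve$value) <= 1e-9))
  v0 <- curve$value[1]
  if (v0 <= 0) stop("curve starts at a non-positive value")
  norm <- curve$value / v0
  out <- vapply(fractions, function(f) {
    hit <- which(norm <= f + 1e-12)
    if (!length(hit)) return(Inf)
    i <- hit[1]
    if (i == 1) return(curve$time_h[1])
    # interpolate the crossing between the bracketing grid points
    t0 <- curve$time_h[i - 1]; t1 <- curve$time_h[i]
    y0 <- norm[i - 1]; y1 <- norm[i]
    if (y0 == y1) t1 else t0 + (y0 - f) / (y0 - y1) * (t1 - t0)
  }, numeric(1))
  names(out) <- paste0("f", fractions)
  out
}

#' Score observed co-culture data against predictions, per compound
#'
#' Drives [r_squared()], the signed-residual direction statistic and
#' [classify_compounds()] over all compounds, and reports the time at which
#' each predicted and observed curve falls below 10% of its starting value.
#'
#' @param observed Long-format data frame of co-culture concentrations
#'   (columns `compound`, `time_h`, `value`, optionally `replicate`, `flags`).
#' @param predictions Named list of `coculture_prediction` objects (or plain
#'   curves `time_h`/`value`), indexed by compound.
#' @param threshold R-squared consistency threshold (default 0.9).
#' @param use Passed to [r_squared()].
#' @return Data frame with one row per compound: `r2`, `n`,
#'   `mean_signed_residual`, `class`, `t_below10_pred`, `t_below10_obs`.
#' @export
evaluate_coculture <- function(observed, predictions, threshold = 0.9,
                               use = "means") {
  compounds <- intersect(unique(observed$compound), names(predictions))
  rows <- lapply(compounds, function(cp) {
    obs <- observed[observed$compound == cp, , drop = FALSE]
    pred <- predictions[[cp]]
    curve <- if (inherits(pred, "coculture_prediction")) pred$curve else pred
    nd_row <- function() {
      data.frame(compound = cp, r2 = NA_real_, n = 0L,
                 mean_signed_residual = NA_real_,
                 t_below10_pred = depletion_checkpoints(curve)[[1]],
                 t_below10_obs = NA_real_, stringsAsFactors = FALSE)
    }
    rs <- tryCatch(r_squared(obs, curve, use = use),
                   error = function(e) NULL)
    if (is.null(rs)) return(nd_row())
    win <- .curve_window(curve)
    res <- rs$residuals
    in_win <- is.finite(win["t90"]) &
      res$time_h >= win[["t90"]] & res$time_h <= win[["t10"]]
    if (!any(in_win)) {
      # no observation inside the window: fall back to the point nearest its
      # centre so a direction can still be reported
      ctr <- mean(win)
      in_win <- seq_len(nrow(res)) == which.min(abs(res$time_h - ctr))
    }
    msr <- mean(res$residual[in_win])
    obs_curve <- .replicate_means(obs)
    names(obs_curve) <- c("time_h", "value")
    t10_obs <- tryCatch(
      depletion_checkpoints(data.frame(time_h = obs_curve$time_h,
                                       value = cummin(obs_curve$value)))[[1]],
      error = function(e) NA_real_)
    data.frame(compound = cp, r2 = rs$r2, n = rs$n,
               mean_signed_residual = msr,
               t_below10_pred = depletion_checkpoints(curve)[[1]],
               t_below10_obs = t10_obs,
               stringsAsFactors = FALSE)
  })
  classify_compounds(do.call(rbind, rows), threshold = threshold)
}
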