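#' Decreasing logistic (Behrends) substrate-depletion model
#'
#' Evaluates the four-parameter decreasing logistic used to describe the
#' depletion of a single substrate from the medium during microbial batch
#' culture:
#' \deqn{\xi(t) = \frac{a}{1 + e^{(t - t_{50})/w}} + o}
#' where `a` is the amplitude (total depletable amount, in concentration
#' units), `o` the offset (residual concentration left in the medium),
#' `t50` the inflection-point time and `w` the width of the depletion
#' transition, both in hours.
#'
#' @param fit A `behrends_fit` object (see [fit_behrends()]), or a list with
#'   numeric elements `a`, `o`, `t50`, `w`.
#' @param t Numeric vector of times in hours (any finite value; the model is
#'   defined on the whole real line).
#' @return Numeric vector of modelled concentrations (same units as `a`, `o`).
#' @examples
#' f <- behrends_fit(a = 500, o = 20, t50 = 5, w = 0.8)
#' behrends_value(f, 5)            # midpoint: a/2 + o = 270
#' behrends_value(f, c(0, 26))
#' @export
behrends_value <- function(fit, t) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  .behrends(t, fit$a, fit$o, fit$t50, fit$w)
}

# bare-parameter evaluation; exp() overflow at large (t-t50)/w gives Inf and
# a/Inf -> 0, which is the correct asymptote, so no clamping is needed
.behrends <- function(t, a, o, t50, w) {
  a / (1 + exp((t - t50) / w)) + o
}

# instantaneous depletion rate -d(xi)/dt >= 0, maximal (= a/(4w)) at t = t50
.behrends_rate <- function(t, a, o, t50, w) {
  u <- (t - t50) / w
  # a/w * e^u / (1+e^u)^2, computed stably for |u| large
  a / w * exp(u - 2 * log1p(exp(pmin(u, 700))))
}

#' Construct a fitted-model object for the depletion logistic
#'
#' Normally produced by [fit_behrends()]; the constructor is exported so that
#' known parameter sets (e.g. ground truth in simulations) can be handled with
#' the same downstream machinery.
#'
#' @param a,o,t50,w Model parameters; `a > 0`, `o >= 0`, `t50 > 0`, `w > 0`.
#' @param species,compound Optional labels carried through to outputs.
#' @param converged Logical, whether the optimizer converged.
#' @param rmse Root-mean-square error of the fit on the pooled points.
#' @param anomaly_flags Character vector of anomaly flags (see
#'   [detect_anomalies()]).
#' @param n_points Number of (unflagged) points used in the fit.
#' @return An object of class `behrends_fit`.
#' @export
behrends_fit <- function(a, o, t50, w, species = NA_character_,
                         compound = NA_character_, converged = TRUE,
                         rmse = NA_real_, anomaly_flags = character(),
                         n_points = NA_integer_) {
  stopifnot(is.numeric(a), is.numeric(o), is.numeric(t50), is.numeric(w))
  if (!(a > 0 && o >= 0 && t50 > 0 && w > 0)) {
    stop("invalid Behrends parameters: need a > 0, o >= 0, t50 > 0, w > 0")
  }
  structure(
    list(species = species, compound = compound,
         a = a, o = o, t50 = t50, w = w,
         fixed = c("a", "o"), converged = isTRUE(converged),
         rmse = rmse, anomaly_flags = anomaly_flags,
         n_points = n_points),
    class = "behrends_fit")
}

#' @export
print.behrends_fit <- function(x, ...) {
  cat(sprintf("Behrends depletion fit [%s / %s]\n",
              x$species, x$compound))
  cat(sprintf("  a = %.4g  o = %.4g  t50 = %.4g h  w = %.4g h\n",
              x$a, x$o, x$t50, x$w))
  cat(sprintf("  converged: %s  rmse: %.4g  flags: %s\n",
              x$converged, x$rmse,
              if (length(x$anomaly_flags)) paste(x$anomaly_flags, collapse = ";")
              else "none"))
  invisible(x)
}

# replicate-mean series: data.frame(time_h, value) averaged over replicates,
# flagged values dropped
.replicate_means <- function(series) {
  series <- .usable_points(series)
  agg <- stats::aggregate(value ~ time_h, data = series, FUN = mean)
  agg[order(agg$time_h), , drop = FALSE]
}

# drop rows carrying any flag (e.g. out_of_range from quantification)
.usable_points <- function(series) {
  stopifnot(all(c("time_h", "value") %in% names(series)))
  if (!is.null(series$flags)) {
    keep <- is.na(series$flags) | !nzchar(series$flags)
    series <- series[keep, , drop = FALSE]
  }
  series[is.finite(series$value), , drop = FALSE]
}

#' Fix amplitude and offset from the data
#'
#' Applies the data-defined rule for the two scale parameters of the depletion
#' logistic: replicate values at the same time are averaged, the offset `o` is
#' the minimum of the averaged values, the upper plateau is the average of the
#' t = 0 value and the maximum value, and the amplitude is `plateau - o`.
#' These two parameters are then held fixed while `t50` and `w` are fitted.
#'
#' @param series Data frame with columns `time_h`, `value`, and optionally
#'   `replicate` and `flags` (rows with a non-empty flag are ignored). Must
#'   contain a `time_h == 0` observation and at least 4 usable time points.
#' @return Named numeric vector `c(a = , o = )`.
#' @examples
#' tt <- c(0:12, 26)
#' y <- 500 / (1 + exp((tt - 5) / 0.8)) + 20
#' fix_amplitude_offset(data.frame(time_h = tt, value = y))
#' @export
fix_amplitude_offset <- function(series) {
  m <- .replicate_means(series)
  if (nrow(m) < 4) stop("need at least 4 usable time points")
  if (!any(m$time_h == 0)) stop("series has no t = 0 observation")
  o <- min(m$value)
  plateau <- mean(c(m$value[m$time_h == 0][1], max(m$value)))
  a <- plateau - o
  if (a <= 0) stop("flat or rising series: plateau does not exceed offset")
  c(a = a, o = o)
}

# initial values for (t50, w): t50 at the steepest observed decrease of the
# replicate mean; w from a quarter of the 80%->20% crossing spacing
.fit_init <- function(m, a, o) {
  dt <- diff(m$time_h)
  slope <- diff(m$value) / dt
  k <- which.min(slope)                     # most negative slope
  t50_0 <- mean(m$time_h[k + 0:1])
  lev <- (m$value - o) / a
  t_cross <- function(frac) {
    below <- which(lev <= frac)
    if (!length(below) || below[1] == 1) return(NA_real_)
    i <- below[1]
    # linear interpolation between bracketing points
    t0 <- m$time_h[i - 1]; t1 <- m$time_h[i]
    l0 <- lev[i - 1]; l1 <- lev[i]
    t0 + (l0 - frac) / (l0 - l1) * (t1 - t0)
  }
  t80 <- t_cross(0.8); t20 <- t_cross(0.2)
  w_0 <- if (is.finite(t80) && is.finite(t20) && t20 > t80) (t20 - t80) / 4 else 1.0
  c(t50 = max(t50_0, 1e-3), w = max(w_0, 1e-3))
}

#' Fit the depletion logistic with data-fixed amplitude and offset
#'
#' Fits `t50` and `w` of the depletion logistic by Levenberg-Marquardt least
#' squares over all pooled replicate points, with `a` and `o` fixed from the
#' data (see [fix_amplitude_offset()]). Positivity of `t50` and `w` is
#' enforced by optimizing their logarithms. During optimization the amplitude
#' is anchored to the data-defined plateau through
#' `a(t50, w) = (plateau - o) * (1 + exp(-t50/w))`, so the fitted curve passes
#' through the plateau at t = 0 exactly; this removes the small finite-`t50/w`
#' bias a constant amplitude would impose (the reported `a` is the anchored
#' value at the optimum). Up to `restarts` jittered restarts are attempted
#' before declaring non-convergence.
#'
#' @inheritParams fix_amplitude_offset
#' @param a,o Fixed amplitude and offset; defaults taken from
#'   [fix_amplitude_offset()] applied to `series`.
#' @param restarts Number of jittered restarts after a failed attempt.
#' @param anchor_amplitude Logical; set `FALSE` to hold `a` constant at the
#'   literal `plateau - o` value instead of anchoring.
#' @return A [behrends_fit()] object. On non-convergence after all restarts
#'   the best attempt is returned with `converged = FALSE` and an
#'   `"nonconverged"` anomaly flag.
#' @examples
#' tt <- rep(c(0:12, 26), 3)
#' y <- 500 / (1 + exp((tt - 5) / 0.8)) + 20
#' fit <- fit_behrends(data.frame(time_h = tt, value = y))
#' c(fit$t50, fit$w)
#' @export
fit_behrends <- function(series, a = NULL, o = NULL, restarts = 5,
                         anchor_amplitude = TRUE) {
  pts <- .usable_points(series)
  if (nrow(pts) < 4) stop("need at least 4 usable points")
  if (is.null(a) || is.null(o)) {
    ao <- fix_amplitude_offset(series)
    if (is.null(a)) a <- ao[["a"]]
    if (is.null(o)) o <- ao[["o"]]
  }
  plateau <- a + o
  tt <- pts$time_h
  yy <- pts$value
  m <- .replicate_means(series)
  init <- .fit_init(m, a, o)

  resid_fn <- function(p) {
    t50 <- exp(p[1]); w <- exp(p[2])
    a_eff <- if (anchor_amplitude) (plateau - o) * (1 + exp(-t50 / w)) else a
    yy - .behrends(tt, a_eff, o, t50, w)
  }

  best <- NULL
  set_jitter <- c(1, 0.5, 2, 0.25, 4, 8)   # multiplicative jitter ladder
  for (r in seq_len(restarts + 1)) {
    j <- set_jitter[((r - 1) %% length(set_jitter)) + 1]
    start <- log(c(init[["t50"]] * j, init[["w"]] * ifelse(r > 3, j, 1)))
    ans <- tryCatch(
      suppressWarnings(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, maxfev = 2000,
                           ftol = 1e-14, ptol = 1e-14))),
      error = function(e) NULL)
    if (is.null(ans)) next
    # a numerically perfect fit (step-limit w -> 0 keeps polishing zero
    # residuals past maxiter) counts as converged
    perfect <- sqrt(ans$deviance / length(yy)) < 1e-6 * a
    ok <- (ans$info %in% 1:3 || perfect) && all(is.finite(ans$par))
    dev <- ans$deviance
    if (is.null(best) || (is.finite(dev) && dev < best$deviance)) {
      best <- ans
      best$ok <- ok
    }
    if (ok) break
  }
  if (is.null(best)) {
    # optimizer never produced a result: return an explicitly unconverged fit
    fit <- behrends_fit(a = a, o = o, t50 = init[["t50"]], w = init[["w"]],
                        converged = FALSE, rmse = Inf,
                        anomaly_flags = "nonconverged",
                        n_points = nrow(pts))
    return(fit)
  }
  t50 <- exp(best$par[1]); w <- exp(best$par[2])
  a_eff <- if (anchor_amplitude) (plateau - o) * (1 + exp(-t50 / w)) else a
  rmse <- sqrt(best$deviance / length(yy))
  converged <- isTRUE(best$ok)
  behrends_fit(a = a_eff, o = o, t50 = t50, w = w,
               converged = converged, rmse = rmse,
               anomaly_flags = if (converged) character() else "nonconverged",
               n_points = nrow(pts))
}

#' Flag anomalous depletion series
#'
#' Two anomaly patterns are recognised: `transient_accumulation`, where the
#' compound first rises above its starting level (glycine-like behaviour:
#' the replicate-mean maximum before the series midpoint exceeds the t = 0
#' mean by more than 15% of the t = 0 mean), and `indeterminable`, where the
#' fit failed to converge or its RMSE exceeds 25% of the amplitude
#' (methionine-like high-variance behaviour).
#'
#' @inheritParams fix_amplitude_offset
#' @param fit The attempted [behrends_fit()] for the series.
#' @param rise_frac Fractional rise over the t = 0 mean that triggers the
#'   `transient_accumulation` flag (default 0.15).
#' @param rmse_frac RMSE/amplitude ratio that triggers `indeterminable`
#'   (default 0.25).
#' @return Character vector of flags (possibly empty).
#' @export
detect_anomalies <- function(series, fit, rise_frac = 0.15, rmse_frac = 0.25) {
  flags <- character()
  m <- .replicate_means(series)
  t_mid <- (min(m$time_h) + max(m$time_h)) / 2
  y0 <- m$value[m$time_h == min(m$time_h)][1]
  early <- m$value[m$time_h < t_mid]
  if (length(early) && y0 > 0 && max(early) > y0 * (1 + rise_frac)) {
    flags <- c(flags, "transient_accumulation")
  }
  # the threshold is relative to the data-defined amplitude (plateau - min);
  # the fitted amplitude can be inflated for degenerate mid-transition fits
  a_rule <- tryCatch(fix_amplitude_offset(series)[["a"]],
                     error = function(e) fit$a)
  if (!isTRUE(fit$converged) ||
      (is.finite(fit$rmse) && fit$rmse > rmse_frac * a_rule)) {
    flags <- c(flags, "indeterminable")
  }
  flags
}

#' Fit every species x compound monoculture series in a long table
#'
#' Convenience driver: splits a long-format concentration table by species and
#' compound, applies [fix_amplitude_offset()], [fit_behrends()] and
#' [detect_anomalies()] to each series, and collects the results.
#'
#' @param data Long-format data frame with columns `species`, `compound`,
#'   `replicate`, `condition`, `time_h`, `value` (and optionally `flags`);
#'   only `condition == "mono"` rows are used.
#' @param ... Passed on to [fit_behrends()].
#' @return A list of `behrends_fit` objects named `"species|compound"`, with
#'   anomaly flags filled in. Series that cannot be fitted at all (flat /
#'   rising / too few points) are returned as unconverged placeholder fits
#'   flagged `"unfittable"`.
#' @seealso [fits_to_df()] for a tidy summary table.
#' @export
fit_depletion <- function(data, ...) {
  if (!is.null(data$condition)) {
    data <- data[data$condition == "mono", , drop = FALSE]
  }
  if (!is.null(data$value_type)) {
    data <- data[data$value_type == "concentration_uM", , drop = FALSE]
  }
  keys <- unique(data[c("species", "compound")])
  fits <- vector("list", nrow(keys))
  names(fits) <- paste(keys$species, keys$compound, sep = "|")
  for (i in seq_len(nrow(keys))) {
    ser <- data[data$species == keys$species[i] &
                  data$compound == keys$compound[i], , drop = FALSE]
    fit <- tryCatch(fit_behrends(ser, ...), error = function(e) {
      m <- tryCatch(.replicate_means(ser), error = function(e2) NULL)
      sc <- if (!is.null(m)) max(m$value) else 1
      f <- behrends_fit(a = max(sc, 1e-6), o = 0, t50 = 1, w = 1,
                        converged = FALSE, rmse = Inf,
                        anomaly_flags = "unfittable")
      f
    })
    fit$species <- keys$species[i]
    fit$compound <- keys$compound[i]
    fit$anomaly_flags <- union(fit$anomaly_flags, detect_anomalies(ser, fit))
    fits[[i]] <- fit
  }
  fits
}

#' Summarise a list of fits as a data frame
#'
#' @param fits List of `behrends_fit` objects (as from [fit_depletion()]).
#' @return Data frame with one row per fit: labels, parameters, convergence,
#'   RMSE and semicolon-joined anomaly flags.
#' @export
fits_to_df <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(species = f$species, compound = f$compound,
               a = f$a, o = f$o, t50 = f$t50, w = f$w,
               converged = f$converged, rmse = f$rmse,
               n_points = f$n_points,
               flags = paste(f$anomaly_flags, collapse = ";"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
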