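#' Usage curve of a species for one compound
#'
#' Converts a fitted depletion curve into a cumulative usage curve
#' `U(t) = C0 - xi(t)`: the amount of compound the species has removed from
#' the medium by time t, relative to the starting concentration `C0`. `U` is
#' non-decreasing with `U(Inf) = C0 - o`.
#'
#' @inheritParams behrends_value
#' @param C0 Starting concentration of the compound in uM; must be at least
#'   `xi(0)` (up to a small tolerance for fits whose plateau slightly exceeds
#'   the nominal medium concentration).
#' @return A function of time returning usage in uM.
#' @export
usage_curve <- function(fit, C0) {
  stopifnot(is.numeric(C0), length(C0) == 1, C0 > 0)
  x0 <- behrends_value(fit, 0)
  if (C0 < x0 - 0.05 * C0) {
    stop("C0 is below the fitted starting concentration xi(0)")
  }
  force(fit)
  function(t) C0 - behrends_value(fit, t)
}

#' Amount of compound available to the community
#'
#' The shared pool available to a mixed culture is the starting concentration
#' minus the lowest monoculture offset among the member species: the species
#' that alone depletes the compound furthest will presumably do so in
#' co-culture as well, but no species takes the pool below its own offset.
#'
#' @param C0 Starting concentration, uM.
#' @param fits List of per-species `behrends_fit` objects for the compound.
#' @return `C = C0 - min_i o_i`, uM.
#' @export
available_amount <- function(C0, fits) {
  stopifnot(length(fits) >= 1)
  C0 - min(vapply(fits, function(f) f$o, numeric(1)))
}

# summed usage since inoculation at time t; each species' usage is anchored
# at its own t = 0 value so that nothing is "used" before the experiment
# starts (the logistic tail before t = 0 is not deliverable usage)
.summed_usage <- function(fits, C0) {
  function(t) {
    Reduce(`+`, lapply(fits, function(f) {
      behrends_value(f, 0) - behrends_value(f, t)
    }))
  }
}

#' Shared depletion time of a compound
#'
#' Finds the first time at which the summed monoculture usage curves
#' `S(t) = sum_i U_i(t)` reach the available amount `C` — the predicted time
#' when a co-culture of the species will have used all available compound.
#' The crossing is located by exponential bracketing followed by bisection
#' (to `tol` hours). When the asymptotic total usage `sum_i (C0 - o_i)` never
#' reaches `C`, `Inf` is returned and no capping applies downstream.
#'
#' @inheritParams available_amount
#' @param tol Time tolerance of the root in hours (default 1e-6).
#' @return Depletion time `t_d` in hours, possibly `Inf`.
#' @export
find_depletion_time <- function(fits, C0, tol = 1e-6) {
  C <- available_amount(C0, fits)
  S <- .summed_usage(fits, C0)
  s_max <- sum(vapply(fits, function(f) behrends_value(f, 0) - f$o,
                      numeric(1)))
  # crossing must lie strictly inside the usage asymptote; when the total
  # potential equals C only in the limit the depletion time is infinite
  if (s_max - C < 1e-9 * max(1, C)) return(Inf)
  if (S(0) >= C) return(0)
  hi <- 1
  while (S(hi) < C) {
    hi <- hi * 2
    if (hi > 2^30) return(Inf)   # crossing only in the asymptotic limit
  }
  stats::uniroot(function(t) S(t) - C, lower = hi / 2, upper = hi,
                 tol = tol)$root
}

#' Cap monoculture usage at the shared depletion time and refit
#'
#' Implements the blind-sharing construction: each species' usage curve is
#' capped at the amount it would have used by the shared depletion time,
#' `U'_i(t) = min(U_i(t), U_i(t_d))`, converted back to a depletion curve
#' `xi'_i(t) = C0 - U'_i(t)`, sampled on a dense uniform grid, and refit to
#' the depletion logistic with the same data-fixed amplitude/offset rule used
#' for the monoculture data (offset fixed at the capped floor
#' `C0 - U_i(t_d)`). With `t_d = Inf` the input fits are returned unchanged.
#'
#' @inheritParams available_amount
#' @param t_d Shared depletion time from [find_depletion_time()].
#' @param grid_step Sampling step of the capped curve in hours (default 0.05).
#' @param horizon Sampling horizon; default `max(26, 2 * t_d)` hours.
#' @return A list with elements `fits` (primed `behrends_fit` objects, same
#'   names as the input; species whose refit fails keep `converged = FALSE`
#'   and a `"refit_failed"` flag, with a warning), `capped_usage` (list of
#'   capped usage functions `U'_i(t)`), and `t_d`.
#' @export
cap_and_refit <- function(fits, C0, t_d, grid_step = 0.05, horizon = NULL) {
  if (!is.finite(t_d)) {
    return(list(fits = fits,
                capped_usage = lapply(fits, function(f) {
                  function(t) behrends_value(f, 0) - behrends_value(f, t)
                }),
                t_d = t_d))
  }
  if (is.null(horizon)) horizon <- max(26, 2 * t_d)
  grid <- seq(0, horizon, by = grid_step)
  primed <- fits
  capped <- vector("list", length(fits))
  names(capped) <- names(fits)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    xi_td <- behrends_value(f, t_d)
    u_td <- C0 - xi_td
    # usage since inoculation, capped at the t_d level
    capped[[i]] <- local({
      f_i <- f; cap_level <- xi_td
      function(t) {
        behrends_value(f_i, 0) - pmax(behrends_value(f_i, t), cap_level)
      }
    })
    xi_capped <- pmax(behrends_value(f, grid), xi_td)
    floor_i <- C0 - u_td
    ser <- data.frame(time_h = grid, value = xi_capped)
    pf <- tryCatch({
      plateau <- mean(c(xi_capped[1], max(xi_capped)))
      fit_behrends(ser, a = plateau - floor_i, o = floor_i)
    }, error = function(e) NULL)
    if (is.null(pf) || !pf$converged) {
      warning(sprintf(
        "refit of capped curve failed for %s/%s; keeping capped samples",
        f$species, f$compound))
      if (is.null(pf)) {
        pf <- f
        pf$converged <- FALSE
      }
      pf$anomaly_flags <- union(pf$anomaly_flags, "refit_failed")
    }
    pf$species <- f$species
    pf$compound <- f$compound
    primed[[i]] <- pf
  }
  list(fits = primed, capped_usage = capped, t_d = t_d)
}

#' Predicted co-culture depletion curve
#'
#' Combines the primed (capped-and-refit) per-species models into the
#' community prediction. Each species' usage is anchored at its own refit
#' baseline so that the prediction starts at the full medium concentration:
#' `P(t) = C0 - sum_i (xi'_i(0) - xi'_i(t))`, clipped to `[C0 - C, C0]` and
#' made non-increasing (the refit can introduce sub-tolerance wiggles).
#'
#' @param primed List of primed `behrends_fit` objects (from
#'   [cap_and_refit()]).
#' @param C Available amount from [available_amount()], uM.
#' @param C0 Starting concentration, uM.
#' @param grid Numeric vector of times to evaluate (default 0 to 26 h in
#'   0.05 h steps).
#' @return Data frame `time_h`, `value` (uM), non-increasing.
#' @export
predict_coculture <- function(primed, C, C0, grid = seq(0, 26, by = 0.05)) {
  used <- Reduce(`+`, lapply(primed, function(f) {
    behrends_value(f, 0) - behrends_value(f, grid)
  }))
  p <- pmin(pmax(C0 - used, C0 - C), C0)
  p <- cummin(p)
  data.frame(time_h = grid, value = p)
}

#' Full co-culture prediction for one compound
#'
#' Convenience wrapper chaining [available_amount()],
#' [find_depletion_time()], [cap_and_refit()] and [predict_coculture()].
#'
#' @inheritParams available_amount
#' @inheritParams cap_and_refit
#' @param grid Prediction grid in hours.
#' @return Object of class `coculture_prediction`: list with `compound`,
#'   `C0`, `C`, `t_d`, `fits` (input), `primed`, `capped_usage`, and `curve`
#'   (data frame `time_h`, `value`).
#' @export
predict_compound <- function(fits, C0, grid = seq(0, 26, by = 0.05),
                             grid_step = 0.05) {
  converged <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(converged)) stop("no converged monoculture fit for the compound")
  fits_use <- fits[converged]
  C <- available_amount(C0, fits_use)
  t_d <- find_depletion_time(fits_use, C0)
  cr <- cap_and_refit(fits_use, C0, t_d, grid_step = grid_step)
  curve <- predict_coculture(cr$fits, C, C0, grid)
  structure(
    list(compound = fits_use[[1]]$compound, C0 = C0, C = C, t_d = t_d,
         fits = fits_use, primed = cr$fits, capped_usage = cr$capped_usage,
         curve = curve),
    class = "coculture_prediction")
}

#' Predict co-culture depletion for every compound in a medium
#'
#' Applies [predict_compound()] to each compound, pooling the usable
#' monoculture fits of all species. Fits that did not converge or carry an
#' anomaly flag (transient accumulation, indeterminable) are not valid usage
#' models and are excluded; compounds left with no usable fit are skipped
#' (they will evaluate as not determined downstream), mirroring how
#' anomalous channels are dropped rather than forced in practice.
#'
#' @param fits List of `behrends_fit` objects (as from [fit_depletion()]).
#' @param medium Medium table with `compound` and `conc_uM` columns giving
#'   each compound's starting concentration.
#' @param grid Prediction grid in hours.
#' @param grid_step Refit grid step in hours.
#' @return Named list of `coculture_prediction` objects.
#' @export
predict_depletion <- function(fits, medium, grid = seq(0, 26, by = 0.05),
                              grid_step = 0.05) {
  preds <- lapply(stats::setNames(medium$compound, medium$compound),
                  function(cp) {
    fl <- fits[vapply(fits, function(f) {
      f$compound == cp && isTRUE(f$converged) && !length(f$anomaly_flags)
    }, logical(1))]
    if (!length(fl)) return(NULL)
    C0 <- medium$conc_uM[medium$compound == cp]
    predict_compound(fl, C0, grid = grid, grid_step = grid_step)
  })
  preds[!vapply(preds, is.null, logical(1))]
}

#' @export
print.coculture_prediction <- function(x, ...) {
  cat(sprintf("Co-culture prediction [%s]: C0 = %.4g uM, C = %.4g uM, t_d = %s h\n",
              x$compound, x$C0, x$C,
              if (is.finite(x$t_d)) sprintf("%.3f", x$t_d) else "Inf"))
  invisible(x)
}
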