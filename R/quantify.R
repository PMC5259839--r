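# Peak-area quantification: internal-standard-normalised calibration curves
# built from the medium dilution series, and conversion of sample areas to
# absolute concentrations with dynamic-range flagging.

#' Build per-compound calibration curves
#'
#' For each compound, the internal-standard-normalised response
#' (`area / is_area`) of the calibration dilution series is regressed on the
#' known concentration by ordinary least squares. Points indistinguishable
#' from blank are dropped before fitting: below 3x the standard deviation of
#' blank responses when blanks are available, otherwise below half the
#' smallest nonzero response. The dynamic range is the concentration span of
#' the retained points; sample values implying concentrations outside it are
#' flagged downstream rather than reported.
#'
#' @param calibration Data frame of calibration rows (as produced by
#'   [simulate_peak_areas()], `condition == "calibration"`): columns
#'   `compound`, `known_conc_uM`, `area`, `is_area`.
#' @param blanks Optional data frame of blank rows (`compound`, `area`,
#'   `is_area`) used to estimate the blank response level.
#' @return Data frame of class `calibration_set`: one row per compound with
#'   `slope` (normalised response per uM), `intercept`, `fit_r2`,
#'   `range_lo`, `range_hi` (uM) and `n_points`.
#' @export
build_calibration <- function(calibration, blanks = NULL) {
  calibration <- calibration[calibration$condition %in%
                               c("calibration", NA) |
                               is.null(calibration$condition), , drop = FALSE]
  stopifnot(all(c("compound", "known_conc_uM", "area", "is_area") %in%
                  names(calibration)))
  if (any(!is.finite(calibration$is_area) | calibration$is_area <= 0)) {
    stop("internal-standard areas must be present and > 0")
  }
  rows <- lapply(split(calibration, calibration$compound), function(d) {
    response <- d$area / d$is_area
    lod <- if (!is.null(blanks)) {
      b <- blanks[blanks$compound %in% c(d$compound[1], NA, ""), , drop = FALSE]
      br <- b$area / b$is_area
      3 * stats::sd(br)
    } else {
      nz <- response[response > 0]
      if (!length(nz)) Inf else min(nz) * 0.5
    }
    keep <- response >= lod
    if (sum(keep) < 3) {
      stop("fewer than 3 usable calibration points for ", d$compound[1])
    }
    x <- d$known_conc_uM[keep]
    y <- response[keep]
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      stop("degenerate calibration responses for ", d$compound[1])
    }
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope <= 0) {
      stop("non-positive calibration slope for ", d$compound[1],
           ": unusable channel")
    }
    # computed directly: summary.lm warns on numerically perfect fits
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
    data.frame(compound = d$compound[1], slope = slope,
               intercept = unname(stats::coef(fit)[1]),
               fit_r2 = r2,
               range_lo = min(x), range_hi = max(x),
               n_points = sum(keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("calibration_set", class(out))
  out
}

#' Convert peak areas to absolute concentrations
#'
#' Inverts the calibration: `concentration = (response - intercept) / slope`
#' with `response = area / is_area`, clipped at 0. Values whose implied
#' concentration falls outside the calibration dynamic range carry the
#' `out_of_range` flag and are excluded from downstream fitting by default
#' (never imputed).
#'
#' @param areas Data frame of sample rows (`condition != "calibration"`)
#'   with columns `species`, `compound`, `replicate`, `condition`, `time_h`,
#'   `area`, `is_area`.
#' @param calibration A `calibration_set` from [build_calibration()].
#' @return Long-format concentration data frame (columns `species`,
#'   `compound`, `replicate`, `condition`, `time_h`, `value`, `value_type`,
#'   `flags`).
#' @export
peak_areas_to_concentrations <- function(areas, calibration) {
  if (!is.null(areas$condition)) {
    areas <- areas[areas$condition != "calibration" | is.na(areas$condition), ,
                   drop = FALSE]
  }
  missing_cal <- setdiff(unique(areas$compound), calibration$compound)
  if (length(missing_cal)) {
    stop("no calibration for: ", paste(missing_cal, collapse = ", "))
  }
  if (any(!is.finite(areas$is_area) | areas$is_area <= 0)) {
    stop("missing internal standard for at least one sample")
  }
  i <- match(areas$compound, calibration$compound)
  response <- areas$area / areas$is_area
  conc <- (response - calibration$intercept[i]) / calibration$slope[i]
  conc <- pmax(conc, 0)
  lo <- calibration$range_lo[i]
  hi <- calibration$range_hi[i]
  oor <- conc < lo * (1 - 1e-9) | conc > hi * (1 + 1e-9)
  data.frame(species = areas$species, compound = areas$compound,
             replicate = areas$replicate, condition = areas$condition,
             time_h = areas$time_h, value = conc,
             value_type = "concentration_uM",
             flags = ifelse(oor, "out_of_range", ""),
             stringsAsFactors = FALSE)
}
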