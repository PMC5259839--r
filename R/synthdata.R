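# Synthetic monoculture / co-culture exometabolomics data with known ground
# truth, plus a brute-force shared-pool consumption simulator, so every
# downstream stage of the pipeline can be validated without external data.

# evaluate code under a derived seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# independent sub-streams from one user seed; stays below 2^31
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011 * 1103 + k * 7919) %% 2147483629L)
}

# multiplicative lognormal noise factors with unit mean and the stated CV
.lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Default defined-medium composition
#'
#' The carbon sources of the defined medium: D-glucose and 18 L-amino acids
#' at 0.1 mg/mL each, plus tyrosine at 0.01 mg/mL (its low aqueous
#' solubility), with molecular weights used to convert to molar units
#' (mg/mL = g/L; g/L / (g/mol) x 1e6 = uM).
#'
#' @return Data frame with columns `compound`, `mg_per_ml`, `mw_g_per_mol`,
#'   `conc_uM` (20 rows).
#' @export
default_medium <- function() {
  m <- data.frame(
    compound = c("glucose", "alanine", "arginine", "asparagine", "aspartate",
                 "glutamate", "glutamine", "glycine", "histidine",
                 "isoleucine", "leucine", "lysine", "methionine",
                 "phenylalanine", "proline", "serine", "threonine",
                 "tryptophan", "tyrosine", "valine"),
    mw_g_per_mol = c(180.16, 89.09, 174.20, 132.12, 133.10,
                     147.13, 146.15, 75.07, 155.15,
                     131.17, 131.17, 146.19, 149.21,
                     165.19, 115.13, 105.09, 119.12,
                     204.23, 181.19, 117.15),
    stringsAsFactors = FALSE)
  m$mg_per_ml <- ifelse(m$compound == "tyrosine", 0.01, 0.1)
  m$conc_uM <- m$mg_per_ml / m$mw_g_per_mol * 1e6
  m[c("compound", "mg_per_ml", "mw_g_per_mol", "conc_uM")]
}

#' Build a synthetic study scenario
#'
#' Defines the ground truth for a simulated exometabolomics study: per
#' species x compound true depletion-logistic parameters, the sampling
#' schedule (hourly 0-12 h plus a final 26 h point), replicate count,
#' measurement noise, anomalous compounds and optional co-culture
#' perturbations. All randomness is driven by `seed`; the same seed always
#' yields the same scenario and simulations.
#'
#' True parameters default to: offset `o ~ U(0, 0.04 C0)`, amplitude
#' `a = C0 - o` (the depletable pool is the whole starting concentration),
#' width `w ~ U(0.3, 1.0)` h and midpoint `t50 ~ U(max(2, 5w), 9)` h — the
#' lower bound `t50 >= 5w` keeps the true curve on its plateau at t = 0
#' (less than ~0.7% of the pool nominally used before inoculation), as in a
#' real batch culture where depletion cannot precede it.
#'
#' @param species Character vector of species labels.
#' @param medium Medium table as from [default_medium()].
#' @param sampling_times Hours; strictly increasing, starting at 0.
#' @param replicates Number of replicates (>= 1).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise (>= 0).
#' @param anomalies List of `list(compound =, kind =)` with kind
#'   `"transient_accumulation"` (glycine-like early rise) or
#'   `"high_variance"` (methionine-like 5x noise). Defaults emulate both.
#' @param perturbations List of `list(compound =, kind =, magnitude =,
#'   species = NULL)` with kind `"rate_scale"` (multiplies uptake rate;
#'   `species = NULL` applies to all) or `"midpoint_shift"` (adds hours to
#'   t50), applied only in co-culture simulation.
#' @param seed Integer seed.
#' @param true_params Optional data frame (`species`, `compound`, `a`, `o`,
#'   `t50`, `w`) overriding the random draw.
#' @return Object of class `depletion_scenario`.
#' @export
synthetic_scenario <- function(species = c("Bc", "Pl", "Pb"),
                               medium = default_medium(),
                               sampling_times = c(0:12, 26),
                               replicates = 3,
                               noise_cv = 0.05,
                               anomalies = list(
                                 list(compound = "glycine",
                                      kind = "transient_accumulation"),
                                 list(compound = "methionine",
                                      kind = "high_variance")),
                               perturbations = list(),
                               seed = 1,
                               true_params = NULL) {
  stopifnot(length(species) >= 1, replicates >= 1)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (sampling_times[1] != 0 || is.unsorted(sampling_times, strictly = TRUE)) {
    stop("sampling_times must start at 0 and be strictly increasing")
  }
  anomalies <- lapply(anomalies, function(an) {
    if (!an$compound %in% medium$compound) {
      stop("anomaly references unknown compound: ", an$compound)
    }
    an
  })
  if (is.null(true_params)) {
    true_params <- .with_seed(.derive_seed(seed, 1), {
      grid <- expand.grid(species = species, compound = medium$compound,
                          stringsAsFactors = FALSE)
      C0 <- medium$conc_uM[match(grid$compound, medium$compound)]
      o <- stats::runif(nrow(grid), 0, 0.04) * C0
      w <- stats::runif(nrow(grid), 0.3, 1.0)
      t50 <- stats::runif(nrow(grid), pmax(2, 5 * w), 9)
      data.frame(grid, a = C0 - o, o = o, t50 = t50, w = w)
    })
  }
  C0v <- medium$conc_uM[match(true_params$compound, medium$compound)]
  if (any(true_params$o >= C0v) ||
      any(true_params$a + true_params$o > 1.05 * C0v)) {
    stop("true parameters violate o < C0 and a + o <= 1.05 C0")
  }
  growth <- .with_seed(.derive_seed(seed, 2), {
    data.frame(species = species, od0 = 0.015,
               rate = stats::runif(length(species), 0.4, 0.8),
               K = stats::runif(length(species), 0.8, 1.4))
  })
  assay_mu <- .with_seed(.derive_seed(seed, 3), {
    grid <- expand.grid(species = species, compound = medium$compound,
                        stringsAsFactors = FALSE)
    mu <- ifelse(stats::runif(nrow(grid)) < 0.2, 0,
                 stats::runif(nrow(grid), 0.1, 0.7))
    data.frame(grid, mu = mu)
  })
  structure(
    list(species = species, medium = medium,
         sampling_times = sampling_times, replicates = replicates,
         noise_cv = noise_cv, anomalies = anomalies,
         perturbations = perturbations, seed = seed,
         true_params = true_params, growth = growth, assay_mu = assay_mu),
    class = "depletion_scenario")
}

#' @export
print.depletion_scenario <- function(x, ...) {
  cat(sprintf(paste0("Synthetic depletion scenario: %d species x %d compounds, ",
                     "%d times, %d replicates, noise CV %.3g, seed %d\n"),
              length(x$species), nrow(x$medium), length(x$sampling_times),
              x$replicates, x$noise_cv, x$seed))
  invisible(x)
}

.scenario_params <- function(scenario, species, compound) {
  p <- scenario$true_params
  row <- p[p$species == species & p$compound == compound, , drop = FALSE]
  if (!nrow(row)) stop("no true parameters for ", species, "/", compound)
  row
}

.anomaly_kind <- function(scenario, compound) {
  kinds <- vapply(scenario$anomalies, function(an) {
    if (an$compound == compound) an$kind else NA_character_
  }, character(1))
  kinds[!is.na(kinds)]
}

# glycine-like transient accumulation: additive Gaussian bump early in growth
.accumulation_bump <- function(t, C0, center = 2.5, width = 1.5,
                               amplitude = 0.30) {
  amplitude * C0 * exp(-(t - center)^2 / (2 * width^2))
}

.logistic_od <- function(t, od0, rate, K) {
  K * od0 * exp(rate * t) / (K + od0 * (exp(rate * t) - 1))
}

#' Simulate a monoculture time course
#'
#' Generates, for one species, the concentration time series of every
#' compound (true logistic depletion curve at the sampling times, with
#' multiplicative lognormal noise of the scenario CV, truncated at 0) and an
#' accompanying OD600 logistic growth curve. Anomalies configured in the
#' scenario are applied: `transient_accumulation` adds an early
#' rise-then-fall Gaussian bump (centre 2.5 h, width 1.5 h, amplitude 30% of
#' the starting concentration) and `high_variance` inflates the noise CV
#' 5-fold. Deterministic given the scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param species One of the scenario's species labels.
#' @return List with `concentrations` and `od600`, both long-format data
#'   frames (columns `species`, `compound`, `replicate`, `condition`,
#'   `time_h`, `value`, `value_type`, `flags`).
#' @export
simulate_monoculture <- function(scenario, species) {
  idx <- match(species, scenario$species)
  if (is.na(idx)) stop("unknown species label: ", species)
  tt <- scenario$sampling_times
  reps <- scenario$replicates
  cv <- scenario$noise_cv
  .with_seed(.derive_seed(scenario$seed, 100 + idx), {
    conc <- do.call(rbind, lapply(scenario$medium$compound, function(cp) {
      p <- .scenario_params(scenario, species, cp)
      C0 <- scenario$medium$conc_uM[scenario$medium$compound == cp]
      truth <- .behrends(tt, p$a, p$o, p$t50, p$w)
      kinds <- .anomaly_kind(scenario, cp)
      if ("transient_accumulation" %in% kinds) {
        truth <- truth + .accumulation_bump(tt, C0)
      }
      cv_cp <- if ("high_variance" %in% kinds) cv * 5 else cv
      do.call(rbind, lapply(seq_len(reps), function(r) {
        data.frame(species = species, compound = cp, replicate = r,
                   condition = "mono", time_h = tt,
                   value = pmax(truth * .lognorm_mult(length(tt), cv_cp), 0),
                   value_type = "concentration_uM", flags = "",
                   stringsAsFactors = FALSE)
      }))
    }))
    g <- scenario$growth[idx, ]
    od_truth <- .logistic_od(tt, g$od0, g$rate, g$K)
    od <- do.call(rbind, lapply(seq_len(reps), function(r) {
      data.frame(species = species, compound = "", replicate = r,
                 condition = "mono", time_h = tt,
                 value = pmax(od_truth * .lognorm_mult(length(tt), cv / 2), 0),
                 value_type = "od600", flags = "",
                 stringsAsFactors = FALSE)
    }))
    list(concentrations = conc, od600 = od)
  })
}

#' Simulate sole-carbon-source growth assays
#'
#' Plate-reader style growth curves for each species on each compound as the
#' sole carbon source (0-48 h every 0.5 h), following logistic growth at the
#' scenario's true assay growth rate; compounds with `mu = 0` stay at the
#' inoculation density (no growth).
#'
#' @param scenario A [synthetic_scenario()].
#' @return Data frame `species`, `compound`, `time_h`, `od600`.
#' @export
simulate_growth_assays <- function(scenario) {
  tt <- seq(0, 48, by = 0.5)
  .with_seed(.derive_seed(scenario$seed, 300), {
    do.call(rbind, lapply(seq_len(nrow(scenario$assay_mu)), function(i) {
      row <- scenario$assay_mu[i, ]
      od <- if (row$mu > 0) .logistic_od(tt, 0.05, row$mu, 1.0) else
        rep(0.05, length(tt))
      data.frame(species = row$species, compound = row$compound, time_h = tt,
                 od600 = pmax(od * .lognorm_mult(length(tt), 0.01), 1e-4),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Brute-force shared-pool consumption simulator
#'
#' Explicit time stepping of a finite substrate pool consumed by several
#' species with given instantaneous usage-rate functions of time:
#' `remaining(t + dt) = max(floor, remaining(t) - sum_i rate_i(t + dt/2) dt)`
#' (midpoint rule, which keeps the integration error far below `dt`). The
#' exhaustion time is the first time the pool reaches the floor, which is
#' the smallest residual offset any species leaves behind.
#'
#' @param rate_fns List of vectorised functions of time returning usage rates
#'   in uM/h (>= 0, finite).
#' @param C0 Starting concentration, uM (> 0).
#' @param dt Time step in hours (> 0).
#' @param floor Residual concentration the pool cannot go below (default 0).
#' @param t_max Simulation horizon in hours (default 60).
#' @param tol Exhaustion tolerance above the floor (default `1e-9 * C0`).
#' @return List with `times`, `remaining` (non-increasing trajectory) and
#'   `exhaustion_time` (h; `Inf` if the pool is not exhausted by `t_max`).
#' @export
consumption_oracle <- function(rate_fns, C0, dt, floor = 0, t_max = 60,
                               tol = 1e-9 * C0) {
  stopifnot(dt > 0, C0 > 0, length(rate_fns) >= 1)
  steps <- seq(0, t_max - dt, by = dt)
  mids <- steps + dt / 2
  total <- Reduce(`+`, lapply(rate_fns, function(f) f(mids)))
  if (any(!is.finite(total))) stop("non-finite rate values")
  if (any(total < 0)) stop("negative rate values")
  remaining <- pmax(floor, C0 - cumsum(total * dt))
  times <- c(0, steps + dt)
  remaining <- c(C0, remaining)
  hit <- which(remaining <= floor + tol)
  list(times = times, remaining = remaining,
       exhaustion_time = if (length(hit)) times[hit[1]] else Inf)
}

# Event-based exact solution of the gated shared pool: each species consumes
# following its own monoculture program (its internal clock advances, at
# rate_scale speed, only while the pool remains above its own offset). Between
# freeze events the trajectory has the closed form
#   R(tau) = R_s - sum_{i active} [xi_i(c_i) - xi_i(c_i + k_i tau)]
# so segments are solved exactly with uniroot instead of time stepping.
.shared_pool_trajectory <- function(par, C0, horizon = 60) {
  n <- nrow(par)
  if (is.null(par$rate_scale)) par$rate_scale <- 1
  clocks <- rep(0, n)
  active <- which(par$o < C0)
  floor <- min(par$o)
  t_cur <- 0
  R <- C0
  segments <- list()
  exhaustion <- Inf
  eps <- 1e-12 * C0
  xi_at <- function(i, tc) .behrends(tc, par$a[i], par$o[i], par$t50[i],
                                     par$w[i])
  while (length(active) && t_cur < horizon) {
    theta <- max(par$o[active])
    cl0 <- clocks
    act <- active
    r0 <- R
    ts <- t_cur
    seg_val <- function(tau) {
      used <- 0
      for (i in act) {
        used <- used + (xi_at(i, cl0[i]) -
                          xi_at(i, cl0[i] + par$rate_scale[i] * tau))
      }
      r0 - used
    }
    tau_max <- horizon - t_cur
    end_val <- seg_val(tau_max)
    if (end_val > theta + eps) {
      segments[[length(segments) + 1]] <-
        list(t0 = ts, t1 = horizon, clocks = cl0, active = act, R0 = r0,
             scale = par$rate_scale)
      t_cur <- horizon
      break
    }
    tau_star <- if (seg_val(0) <= theta + eps) 0 else
      stats::uniroot(function(tau) seg_val(tau) - theta,
                     lower = 0, upper = tau_max, tol = 1e-11)$root
    segments[[length(segments) + 1]] <-
      list(t0 = ts, t1 = ts + tau_star, clocks = cl0, active = act, R0 = r0,
           scale = par$rate_scale)
    clocks[act] <- cl0[act] + par$rate_scale[act] * tau_star
    t_cur <- ts + tau_star
    R <- theta
    if (theta <= floor + eps) {
      exhaustion <- t_cur
      active <- integer()
    } else {
      active <- act[par$o[act] < theta - eps]
    }
  }
  seg_df <- segments
  value_fn <- function(t) {
    vapply(t, function(ti) {
      if (!length(seg_df)) return(C0)
      last_R <- R
      for (s in seg_df) {
        if (ti < s$t0) return(C0)          # before first segment (ti < 0)
        if (ti <= s$t1) {
          tau <- ti - s$t0
          used <- 0
          for (i in s$active) {
            used <- used + (xi_at(i, s$clocks[i]) -
                              xi_at(i, s$clocks[i] + s$scale[i] * tau))
          }
          return(s$R0 - used)
        }
      }
      last_R
    }, numeric(1))
  }
  list(value_fn = value_fn, exhaustion_time = exhaustion, floor = floor,
       segments = segments, final = R)
}

#' Simulate observed co-culture depletion
#'
#' Generates the "observed" co-culture concentration series for every
#' compound under the blind-sharing null — all species consume following
#' their monoculture programs from a shared finite pool, each stopping when
#' the pool reaches its own residual offset — or with injected deviations
#' (scenario `perturbations`: `rate_scale` multiplies a species' uptake rate,
#' compressing its progress clock; `midpoint_shift` translates its t50). The
#' shared pool is solved exactly segment-by-segment (see the consumption
#' oracle for the independent time-stepping check), sampled at the scenario
#' sampling times, and measurement noise applied. Deterministic given the
#' scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return Long-format data frame of co-culture concentrations (`species` =
#'   `"coculture"`, `condition` = `"co"`). The true exhaustion time per
#'   compound is attached as attribute `exhaustion_times`.
#' @export
simulate_coculture <- function(scenario) {
  for (pb in scenario$perturbations) {
    if (!pb$compound %in% scenario$medium$compound) {
      stop("perturbation references unknown compound: ", pb$compound)
    }
  }
  tt <- scenario$sampling_times
  reps <- scenario$replicates
  cv <- scenario$noise_cv
  .with_seed(.derive_seed(scenario$seed, 200), {
    exh <- stats::setNames(numeric(nrow(scenario$medium)),
                           scenario$medium$compound)
    out <- do.call(rbind, lapply(scenario$medium$compound, function(cp) {
      C0 <- scenario$medium$conc_uM[scenario$medium$compound == cp]
      par <- scenario$true_params[scenario$true_params$compound == cp, ,
                                  drop = FALSE]
      par$rate_scale <- 1
      for (pb in scenario$perturbations) {
        if (pb$compound != cp) next
        which_sp <- if (is.null(pb$species)) seq_len(nrow(par)) else
          which(par$species %in% pb$species)
        if (pb$kind == "rate_scale") {
          par$rate_scale[which_sp] <- par$rate_scale[which_sp] * pb$magnitude
        } else if (pb$kind == "midpoint_shift") {
          par$t50[which_sp] <- par$t50[which_sp] + pb$magnitude
        } else stop("unknown perturbation kind: ", pb$kind)
      }
      traj <- .shared_pool_trajectory(par, C0, horizon = max(tt) + 1)
      exh[cp] <<- traj$exhaustion_time
      truth <- traj$value_fn(tt)
      do.call(rbind, lapply(seq_len(reps), function(r) {
        data.frame(species = "coculture", compound = cp, replicate = r,
                   condition = "co", time_h = tt,
                   value = pmax(truth * .lognorm_mult(length(tt), cv), 0),
                   value_type = "concentration_uM", flags = "",
                   stringsAsFactors = FALSE)
      }))
    }))
    attr(out, "exhaustion_times") <- exh
    out
  })
}

#' Simulate LC-MS peak areas with a calibration dilution series
#'
#' Converts concentration rows into raw peak areas (`area = response_factor x
#' concentration x noise`), emits an internal-standard area per sample with
#' its own noise, and appends a calibration series built from dilutions of
#' the full medium (default ladder 1x, 1/2x, 1/10x, 1/100x, 1/1000x,
#' 1/10000x), each calibration row labelled with its dilution factor and
#' known concentration.
#'
#' @param concentrations Long-format concentration data frame (columns
#'   `species`, `compound`, `replicate`, `condition`, `time_h`, `value`).
#' @param response_factors Named numeric vector of per-compound response
#'   factors (area per uM, > 0).
#' @param is_response_factor Response factor of the internal standard (> 0);
#'   required.
#' @param is_conc_uM Internal-standard concentration (default 25 uM).
#' @param dilution_factors Calibration dilution ladder, each in (0, 1].
#' @param noise_cv Multiplicative noise CV for areas.
#' @param seed Integer seed.
#' @param medium Medium table giving the 1x calibration concentrations.
#' @return Data frame with columns `species`, `compound`, `replicate`,
#'   `condition` (`"calibration"` for calibration rows), `time_h`,
#'   `dilution`, `known_conc_uM`, `area`, `is_area`.
#' @export
simulate_peak_areas <- function(concentrations, response_factors,
                                is_response_factor, is_conc_uM = 25,
                                dilution_factors = c(1, 1/2, 1/10, 1/100,
                                                     1/1000, 1/10000),
                                noise_cv = 0, seed = 1,
                                medium = default_medium()) {
  if (missing(is_response_factor) || is.null(is_response_factor) ||
      !is.finite(is_response_factor) || is_response_factor <= 0) {
    stop("missing or invalid internal-standard response factor")
  }
  if (any(response_factors <= 0)) stop("response factors must be > 0")
  if (any(dilution_factors <= 0 | dilution_factors > 1)) {
    stop("dilution factors must lie in (0, 1]")
  }
  needed <- unique(concentrations$compound)
  if (!all(needed %in% names(response_factors))) {
    stop("missing response factor for: ",
         paste(setdiff(needed, names(response_factors)), collapse = ", "))
  }
  .with_seed(.derive_seed(seed, 400), {
    rf <- response_factors[concentrations$compound]
    n <- nrow(concentrations)
    samples <- data.frame(
      species = concentrations$species,
      compound = concentrations$compound,
      replicate = concentrations$replicate,
      condition = concentrations$condition,
      time_h = concentrations$time_h,
      dilution = NA_real_, known_conc_uM = NA_real_,
      area = rf * concentrations$value * .lognorm_mult(n, noise_cv),
      is_area = is_response_factor * is_conc_uM * .lognorm_mult(n, noise_cv),
      stringsAsFactors = FALSE)
    cal_grid <- expand.grid(compound = medium$compound,
                            dilution = dilution_factors,
                            stringsAsFactors = FALSE)
    known <- medium$conc_uM[match(cal_grid$compound, medium$compound)] *
      cal_grid$dilution
    m <- nrow(cal_grid)
    cal <- data.frame(
      species = NA_character_, compound = cal_grid$compound,
      replicate = 1L, condition = "calibration", time_h = NA_real_,
      dilution = cal_grid$dilution, known_conc_uM = known,
      area = response_factors[cal_grid$compound] * known *
        .lognorm_mult(m, noise_cv),
      is_area = is_response_factor * is_conc_uM * .lognorm_mult(m, noise_cv),
      stringsAsFactors = FALSE)
    rbind(samples, cal)
  })
}
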