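# shared fixtures: analytic curves, random valid fits, and the
# simulate -> fit -> predict -> evaluate chain used in detection experiments

logistic_curve <- function(t, a, o, t50, w) a / (1 + exp((t - t50) / w)) + o

paper_grid <- c(0:12, 26)

# random valid fit sets mirroring the generator's parameter distribution
random_fits <- function(n_species = 3, C0 = 555, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  o <- runif(n_species, 0, 0.05 * C0)
  w <- runif(n_species, 0.3, 1.2)
  t50 <- runif(n_species, pmax(2, 5 * w), 9)
  lapply(seq_len(n_species), function(i) {
    behrends_fit(a = C0 - o[i], o = o[i], t50 = t50[i], w = w[i],
                 species = paste0("S", i), compound = "x")
  })
}

# rate functions of the monoculture truth, for the consumption oracle
fit_rates <- function(fits) {
  lapply(fits, function(f) {
    function(t) {
      u <- (t - f$t50) / f$w
      f$a / f$w * exp(u - 2 * log1p(exp(pmin(u, 700))))
    }
  })
}

# one noiseless series data frame on the paper grid
noiseless_series <- function(a = 500, o = 20, t50 = 5, w = 0.8,
                             times = paper_grid, replicates = 1) {
  tt <- rep(times, replicates)
  data.frame(time_h = tt, value = logistic_curve(tt, a, o, t50, w),
             replicate = rep(seq_len(replicates), each = length(times)))
}

# full monoculture -> fits -> prediction -> co-culture evaluation chain
run_detection_chain <- function(seed, perturbations = list(),
                                anomalies = list(), medium = default_medium(),
                                threshold = 0.9) {
  sc <- synthetic_scenario(seed = seed, medium = medium,
                           perturbations = perturbations,
                           anomalies = anomalies)
  conc <- do.call(rbind, lapply(sc$species, function(sp) {
    simulate_monoculture(sc, sp)$concentrations
  }))
  fits <- fit_depletion(conc)
  preds <- suppressWarnings(
    predict_depletion(fits, sc$medium, grid = seq(0, 26, 0.05)))
  co <- simulate_coculture(sc)
  suppressWarnings(evaluate_coculture(co, preds, threshold = threshold))
}

rate_perturbations <- function(compounds, magnitude) {
  lapply(compounds, function(cp) {
    list(compound = cp, kind = "rate_scale", magnitude = magnitude)
  })
}
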