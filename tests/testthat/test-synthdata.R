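# Synthetic-data generator and shared-pool consumption simulator

test_that("zero-noise monoculture reproduces the analytic depletion curve", {
  tp <- expand.grid(species = "S1", compound = default_medium()$compound,
                    stringsAsFactors = FALSE)
  C0 <- default_medium()$conc_uM
  tp$a <- C0 * 0.96; tp$o <- C0 * 0.04; tp$t50 <- 5; tp$w <- 0.8
  sc <- synthetic_scenario(species = "S1", noise_cv = 0, anomalies = list(),
                           seed = 3, true_params = tp)
  sim <- simulate_monoculture(sc, "S1")
  glc <- sim$concentrations[sim$concentrations$compound == "glucose" &
                              sim$concentrations$replicate == 1, ]
  C0g <- default_medium()$conc_uM[default_medium()$compound == "glucose"]
  expect_equal(glc$value,
               logistic_curve(glc$time_h, 0.96 * C0g, 0.04 * C0g, 5, 0.8),
               tolerance = 1e-12)
  # midpoint identity: value at t50 is a/2 + o
  expect_equal(glc$value[glc$time_h == 5], 0.96 * C0g / 2 + 0.04 * C0g,
               tolerance = 1e-12)
  # replicates identical at zero noise, and bit-reproducible across runs
  sim2 <- simulate_monoculture(sc, "S1")
  expect_identical(sim$concentrations$value, sim2$concentrations$value)
})

test_that("simulations are deterministic given the seed and differ across seeds", {
  sc1 <- synthetic_scenario(seed = 11)
  sc2 <- synthetic_scenario(seed = 11)
  sc3 <- synthetic_scenario(seed = 12)
  expect_identical(simulate_monoculture(sc1, "Bc"),
                   simulate_monoculture(sc2, "Bc"))
  expect_identical(simulate_coculture(sc1)$value, simulate_coculture(sc2)$value)
  expect_false(identical(simulate_monoculture(sc1, "Bc")$concentrations$value,
                         simulate_monoculture(sc3, "Bc")$concentrations$value))
})

test_that("empirical noise CV matches the configured CV", {
  med <- default_medium()[1, ]
  tp <- data.frame(species = "S1", compound = med$compound,
                   a = med$conc_uM, o = 0, t50 = 8, w = 0.8)
  sc <- synthetic_scenario(species = "S1", medium = med, noise_cv = 0.05,
                           replicates = 200, anomalies = list(), seed = 5,
                           true_params = tp)
  sim <- simulate_monoculture(sc, "S1")$concentrations
  # per-time-point sample CV across 200 replicates, away from depletion
  for (t in c(0, 2, 4)) {
    v <- sim$value[sim$time_h == t]
    expect_gt(sd(v) / mean(v), 0.04)
    expect_lt(sd(v) / mean(v), 0.06)
  }
})

test_that("anomalies shape the series as configured", {
  sc <- synthetic_scenario(noise_cv = 0, seed = 4)
  sim <- simulate_monoculture(sc, "Bc")$concentrations
  gly <- sim[sim$compound == "glycine" & sim$replicate == 1, ]
  p <- sc$true_params[sc$true_params$species == "Bc" &
                        sc$true_params$compound == "glycine", ]
  clean <- logistic_curve(gly$time_h, p$a, p$o, p$t50, p$w)
  # rise-then-fall bump confined to early hours
  expect_gt(max((gly$value - clean)[gly$time_h <= 5]), 0.2 * sum(p$a, p$o))
  expect_lt(max(abs(gly$value - clean)[gly$time_h >= 10]), 0.01 * sum(p$a, p$o))
})

test_that("generator rejects invalid inputs", {
  expect_error(synthetic_scenario(noise_cv = -0.1), "noise_cv")
  expect_error(synthetic_scenario(sampling_times = c(1, 2)), "sampling_times")
  sc <- synthetic_scenario(seed = 1)
  expect_error(simulate_monoculture(sc, "nosuch"), "unknown species")
  sc$perturbations <- list(list(compound = "unobtainium", kind = "rate_scale",
                                magnitude = 2))
  expect_error(simulate_coculture(sc), "unknown compound")
})

test_that("consumption oracle matches constant-rate closed forms", {
  orc1 <- consumption_oracle(list(function(t) rep(50, length(t))),
                             C0 = 500, dt = 0.01)
  expect_lt(abs(orc1$exhaustion_time - 10), 0.01 + 1e-9)
  orc2 <- consumption_oracle(list(function(t) rep(50, length(t)),
                                  function(t) rep(50, length(t))),
                             C0 = 500, dt = 0.01)
  expect_lt(abs(orc2$exhaustion_time - 5), 0.01 + 1e-9)
  expect_error(consumption_oracle(list(function(t) rep(NaN, length(t))),
                                  C0 = 10, dt = 0.1), "non-finite")
})

test_that("oracle trajectory is non-increasing, floored, monotone in consumers", {
  fits <- random_fits(3, seed = 21)
  fl <- min(vapply(fits, `[[`, numeric(1), "o"))
  rates <- fit_rates(fits)
  orc3 <- consumption_oracle(rates, 555, dt = 0.01, floor = fl)
  expect_true(all(diff(orc3$remaining) <= 1e-9))
  expect_true(all(orc3$remaining >= fl - 1e-9))
  for (k in 1:2) {
    sub <- consumption_oracle(rates[seq_len(k)], 555, dt = 0.01, floor = fl)
    expect_gte(sub$exhaustion_time, orc3$exhaustion_time)
  }
})

test_that("single-species co-culture degenerates to the monoculture curve", {
  med <- default_medium()[1:2, ]
  tp <- data.frame(species = "S1", compound = med$compound,
                   a = med$conc_uM * 0.97, o = med$conc_uM * 0.03,
                   t50 = c(4, 6), w = c(0.5, 0.9))
  sc <- synthetic_scenario(species = "S1", medium = med, noise_cv = 0,
                           anomalies = list(), seed = 9, true_params = tp)
  co <- simulate_coculture(sc)
  for (i in 1:2) {
    obs <- co$value[co$compound == med$compound[i] & co$replicate == 1]
    mono <- logistic_curve(sc$sampling_times, tp$a[i], tp$o[i],
                           tp$t50[i], tp$w[i])
    # the shared pool starts at the nominal C0 while the logistic starts at
    # xi(0) = C0 - (pre-t0 tail); the degenerate consortium therefore agrees
    # with the monoculture curve to within that tail (< 1% of C0)
    expect_lt(max(abs(obs - mono)), 0.01 * med$conc_uM[i])
  }
})

test_that("rate_scale perturbation empties the shared pool strictly earlier", {
  med <- default_medium()[1, ]
  sc0 <- synthetic_scenario(medium = med, noise_cv = 0, anomalies = list(),
                            seed = 13)
  sc1 <- sc0
  sc1$perturbations <- rate_perturbations(med$compound, 2)
  e0 <- attr(simulate_coculture(sc0), "exhaustion_times")
  e1 <- attr(simulate_coculture(sc1), "exhaustion_times")
  expect_lt(e1[[med$compound]], e0[[med$compound]])
})

test_that("peak-area simulation follows the response model and calibration design", {
  conc <- data.frame(species = "S1", compound = "glucose", replicate = 1,
                     condition = "mono", time_h = 0, value = 100)
  pa <- simulate_peak_areas(conc, c(glucose = 2), is_response_factor = 1,
                            noise_cv = 0, seed = 1)
  expect_equal(pa$area[pa$condition != "calibration"], 200)
  cal <- pa[pa$condition == "calibration", ]
  # paper ladder: 1x plus five dilutions, per compound
  expect_equal(sum(cal$compound == "glucose"), 6)
  expect_equal(sort(unique(cal$dilution)),
               sort(c(1, 1/2, 1/10, 1/100, 1/1000, 1/10000)))
  C0g <- default_medium()$conc_uM[default_medium()$compound == "glucose"]
  expect_equal(cal$known_conc_uM[cal$dilution == 1/10 &
                                   cal$compound == "glucose"], C0g / 10)
  expect_error(simulate_peak_areas(conc, c(glucose = 2),
                                   is_response_factor = NULL),
               "internal-standard")
  expect_error(simulate_peak_areas(conc, c(glucose = 2), is_response_factor = 1,
                                   dilution_factors = c(1, 2)), "dilution")
})
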