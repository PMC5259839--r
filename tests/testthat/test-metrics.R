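# Substrate-preference metrics and growth-rate correlations

bisect_level <- function(fit, level) {
  uniroot(function(t) behrends_value(fit, t) - level,
          lower = -50, upper = 100, tol = 1e-12)$root
}

test_that("closed-form T_h and window agree with bisection on random fits", {
  set.seed(19)
  for (i in 1:200) {
    C0 <- runif(1, 100, 1000)
    o <- runif(1, 0, 0.05 * C0)
    w <- runif(1, 0.3, 1.2)
    t50 <- runif(1, max(2, 5 * w), 9)
    f <- behrends_fit(a = C0 - o, o = o, t50 = t50, w = w)
    q <- behrends_value(f, 0) - f$o
    expect_equal(half_depletion_time(f), bisect_level(f, f$o + q / 2),
                 tolerance = 1e-9)
    win <- usage_window(f)
    expect_equal(unname(win["t90"]), bisect_level(f, f$o + 0.9 * q),
                 tolerance = 1e-9)
    expect_equal(unname(win["t10"]), bisect_level(f, f$o + 0.1 * q),
                 tolerance = 1e-9)
    expect_true(win["t90"] < half_depletion_time(f) &&
                  half_depletion_time(f) < win["t10"])
  }
})

test_that("plateau-start limits: T_h -> t50 and window length -> 2 w log 9", {
  f <- behrends_fit(a = 500, o = 20, t50 = 5, w = 0.5)   # t50/w = 10
  expect_equal(half_depletion_time(f), 5, tolerance = 1e-4)
  win <- usage_window(f)
  expect_equal(unname(win["t10"] - win["t90"]), 2 * log(9) * 0.5,
               tolerance = 1e-3)
  f2 <- behrends_fit(a = 500, o = 20, t50 = 5, w = 0.25)
  win2 <- usage_window(f2)
  expect_equal(unname(win2["t10"] - win2["t90"]), 1.099, tolerance = 1e-3)
  # pre-t0 usage case: T_h exceeds t50
  f3 <- behrends_fit(a = 500, o = 20, t50 = 1, w = 1)
  expect_gt(half_depletion_time(f3), 1)
  q3 <- behrends_value(f3, 0) - 20
  expect_equal(half_depletion_time(f3), bisect_level(f3, 20 + q3 / 2),
               tolerance = 1e-9)
})

test_that("metrics are equivariant under time translation (plateau regime)", {
  # "total used" is read off the fitted model at t = 0, so exact
  # equivariance holds only once the pre-t0 tail is negligible (t50 >> w)
  f <- behrends_fit(a = 400, o = 10, t50 = 5, w = 0.4)
  fs <- behrends_fit(a = 400, o = 10, t50 = 5 + 2.5, w = 0.4)
  d <- half_depletion_time(fs) - half_depletion_time(f)
  expect_equal(d, 2.5, tolerance = 1e-5)
  expect_equal(unname(usage_window(fs) - usage_window(f)), c(2.5, 2.5),
               tolerance = 1e-5)
})

test_that("biomass trajectory multiplies k, OD and declining volume", {
  b <- biomass_trajectory(0, 1, k = 1, v0 = 1, sample_draw_l = 0)
  expect_equal(b$gcdw, 1)
  b2 <- biomass_trajectory(0, 0.496, k = 0.9, v0 = 0.001, sample_draw_l = 0)
  expect_equal(b2$gcdw, 4.464e-4, tolerance = 1e-6)
  # 13 sampling draws of 1.2 mL leave 34.4 mL of the initial 50 mL
  b3 <- biomass_trajectory(0:13, rep(0.5, 14), k = 0.9)
  expect_equal(b3$volume_l[14], 0.050 - 13 * 0.0012)
  expect_true(all(diff(b3$volume_l) < 0))
  expect_error(biomass_trajectory(0:60, rep(0.5, 61), k = 0.9), "volume")
})

test_that("maximum depletion rate is a/(4w) at t50, scaled by biomass", {
  f <- behrends_fit(a = 500, o = 20, t50 = 5, w = 0.5)
  expect_equal(unname(max_depletion_rate(f)), c(250, 5))
  # constant biomass B and volume V: per-biomass max = a/(4w) V / (1000 B)
  b <- data.frame(time_h = seq(0, 26, 0.5), od600 = 1, volume_l = 0.05,
                  gcdw = 0.02)
  mr <- max_rate_per_biomass(f, b, inoculum = 0.02)
  expect_equal(unname(mr["max_rate_per_biomass"]),
               250 * 0.05 / (1000 * 0.02), tolerance = 1e-6)
  expect_equal(unname(mr["t_max_rate_per_biomass"]), 5, tolerance = 0.02)
  # depletion before growth: flooring at the inoculum inflates the rate by
  # the biomass ratio relative to a full-grown culture
  early <- behrends_fit(a = 500, o = 20, t50 = 2.4, w = 0.3)
  grown <- data.frame(time_h = seq(0, 26, 0.5), od600 = 1, volume_l = 0.05,
                      gcdw = 0.05)
  tiny <- transform(grown, gcdw = 0.0005)
  r_tiny <- max_rate_per_biomass(early, tiny, inoculum = 0.0005)
  r_grown <- max_rate_per_biomass(early, grown, inoculum = 0.05)
  expect_equal(unname(r_tiny["max_rate_per_biomass"] /
                        r_grown["max_rate_per_biomass"]),
               0.05 / 0.0005, tolerance = 1e-6)
  expect_error(max_rate_per_biomass(f, transform(b, gcdw = 0)), "all zero")
})

test_that("specific growth rate recovers exponential slopes", {
  t <- seq(0, 10, 0.5)
  expect_equal(specific_growth_rate(t, 0.01 * exp(0.6 * t)), 0.6,
               tolerance = 1e-6)
  expect_equal(specific_growth_rate(t, rep(0.05, length(t))), 0)
  # logistic growth sampled every 0.25 h: early-phase slope slightly under
  t2 <- seq(0, 12, 0.25)
  od <- 1.0 * 0.01 * exp(0.8 * t2) / (1.0 + 0.01 * (exp(0.8 * t2) - 1))
  mu <- specific_growth_rate(t2, od)
  expect_gte(mu, 0.72)
  expect_lte(mu, 0.80)
  expect_error(specific_growth_rate(t, rep(-1, length(t))), "non-positive")
})

test_that("preference correlations use nonzero-growth compounds only", {
  met <- data.frame(compound = letters[1:6],
                    T_h = c(6, 5, 4, 3, 2, 1),
                    max_rate_per_biomass = c(1, 2, 3, 4, 5, 6))
  mu <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), letters[1:6])
  pc <- preference_correlations(met, mu, species = "S1")
  r_th <- pc$correlations$r[pc$correlations$metric == "T_h"]
  expect_equal(r_th, -1, tolerance = 1e-12)
  expect_lt(pc$correlations$p[pc$correlations$metric == "T_h"], 1e-6)
  # zero-mu compounds are excluded from r and listed separately
  mu2 <- mu
  mu2[c("a", "b")] <- 0
  pc2 <- preference_correlations(met, mu2)
  expect_setequal(pc2$zero_mu, c("a", "b"))
  expect_equal(pc2$correlations$n[1], 4)
  mu3 <- setNames(c(0.3, 0.4, rep(0, 4)), letters[1:6])
  expect_error(preference_correlations(met, mu3), "fewer than 3")
})

test_that("three-point Pearson matches the hand-computed value", {
  met <- data.frame(compound = c("a", "b", "c"), T_h = c(3, 1, 2))
  mu <- setNames(c(1, 2, 3), c("a", "b", "c"))
  pc <- preference_correlations(met, mu)
  # r = cov/(sd sd) = -0.5; p = 2 P(T_1 < r sqrt(n-2)/sqrt(1-r^2))
  expect_equal(pc$correlations$r, -0.5, tolerance = 1e-12)
  tstat <- -0.5 * sqrt(1) / sqrt(1 - 0.25)
  expect_equal(pc$correlations$p, 2 * (0.5 + atan(tstat) / pi),
               tolerance = 1e-9)
})
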