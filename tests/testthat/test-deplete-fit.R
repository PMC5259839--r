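# Depletion-logistic fitting with the data-fixed amplitude/offset rule

test_that("amplitude/offset rule follows the plateau arithmetic", {
  # plateau = mean(t0, max) = 519, offset = min = 20 -> a = 499
  s1 <- data.frame(time_h = 0:4, value = c(519, 519, 400, 100, 20))
  expect_equal(unname(fix_amplitude_offset(s1)), c(499, 20))
  # t0 = 480, max = 520 -> plateau 500; min 0 -> (500, 0)
  s2 <- data.frame(time_h = 0:4, value = c(480, 520, 300, 100, 0))
  expect_equal(unname(fix_amplitude_offset(s2)), c(500, 0))
  # constant series: plateau equals the minimum
  s3 <- data.frame(time_h = 0:5, value = rep(100, 6))
  expect_error(fix_amplitude_offset(s3), "flat or rising")
  # replicate values at the same time are averaged first
  s4 <- rbind(s1, transform(s1, value = value + 2))
  ao <- fix_amplitude_offset(s4)
  expect_equal(unname(ao), c(499, 21))
})

test_that("model evaluation satisfies the logistic identities", {
  f <- behrends_fit(a = 500, o = 20, t50 = 5, w = 0.8)
  expect_equal(behrends_value(f, 5), 270)               # a/2 + o
  expect_equal(behrends_value(f, 1e6), 20)              # t -> Inf: o
  expect_equal(behrends_value(f, -1e6), 520)            # t -> -Inf: a + o
  expect_equal(behrends_value(f, 5 + 0.8 * log(9)), 70) # 10% decile: 0.1 a + o
  # fitted curve strictly decreasing
  g <- seq(-5, 30, 0.1)
  expect_true(all(diff(behrends_value(f, g)) < 0))
  expect_error(behrends_fit(a = -1, o = 0, t50 = 5, w = 1), "invalid")
})

test_that("noiseless series on the sampling grid are recovered exactly", {
  ser <- noiseless_series(a = 500, o = 20, t50 = 5, w = 0.8)
  fit <- fit_behrends(ser)
  expect_true(fit$converged)
  expect_equal(fit$t50, 5, tolerance = 1e-3)
  expect_equal(fit$w, 0.8, tolerance = 1e-3)
  expect_lt(fit$rmse, 1e-6)
})

test_that("a step-like depletion yields a sharp transition at the step", {
  tt <- c(0:12, 26)
  ser <- data.frame(time_h = tt, value = ifelse(tt < 3, 500, 10))
  fit <- fit_behrends(ser)
  expect_true(fit$converged)
  expect_lt(abs(fit$t50 - 3), 0.6)
  expect_lt(fit$w, 0.3)
})

test_that("fit is invariant to uniform concentration rescaling", {
  ser <- noiseless_series(a = 480, o = 35, t50 = 6.2, w = 0.6,
                          replicates = 2)
  f1 <- fit_behrends(ser)
  ser2 <- transform(ser, value = value * 3.7)
  f2 <- fit_behrends(ser2)
  expect_equal(f1$t50, f2$t50, tolerance = 1e-9)
  expect_equal(f1$w, f2$w, tolerance = 1e-9)
})

test_that("parameters are recovered under replicate noise", {
  set.seed(31)
  errs <- t(replicate(40, {
    ser <- noiseless_series(a = 500, o = 20, t50 = 5, w = 0.8,
                            replicates = 3)
    sdl <- sqrt(log1p(0.05^2))
    ser$value <- ser$value * exp(rnorm(nrow(ser), -sdl^2 / 2, sdl))
    fit <- fit_behrends(ser)
    c(abs(fit$t50 - 5), abs(fit$w - 0.8) / 0.8)
  }))
  expect_lt(median(errs[, 1]), 0.2)
  expect_lt(median(errs[, 2]), 0.25)
})

test_that("anomalous series are flagged", {
  # glycine-like transient accumulation: +30% bump early on
  tt <- c(0:12, 26)
  base <- logistic_curve(tt, 450, 30, 7, 0.8)
  bump <- base + 0.3 * 480 * exp(-(tt - 2.5)^2 / (2 * 1.5^2))
  ser <- data.frame(time_h = tt, value = bump)
  fit <- fit_behrends(ser)
  expect_true("transient_accumulation" %in% detect_anomalies(ser, fit))
  # clean sigmoid: no flags
  clean <- data.frame(time_h = tt, value = base)
  expect_length(detect_anomalies(clean, fit_behrends(clean)), 0)
})

test_that("indeterminable flags fire on non-convergence or large residuals", {
  # an unconverged fit is always indeterminable
  tt <- c(0:12, 26)
  ser <- data.frame(time_h = tt,
                    value = logistic_curve(tt, 500, 20, 5, 0.8))
  bad_fit <- behrends_fit(a = 500, o = 20, t50 = 5, w = 0.8,
                          converged = FALSE, rmse = 0)
  expect_true("indeterminable" %in% detect_anomalies(ser, bad_fit))
  # residual scatter worth more than a quarter of the amplitude is flagged
  wild <- ser
  wild$value <- wild$value * rep(c(1.8, 0.2), length.out = nrow(wild))
  fitw <- fit_behrends(wild)
  # threshold is relative to the data-defined (rule) amplitude
  expect_gt(fitw$rmse, 0.25 * fix_amplitude_offset(wild)[["a"]])
  expect_true("indeterminable" %in% detect_anomalies(wild, fitw))
})

test_that("pure noise around a constant is not reported as a usable fit", {
  set.seed(23)
  tt <- c(0:12, 26)
  ser <- data.frame(time_h = tt, value = 100 * exp(rnorm(length(tt), 0, 0.05)))
  fit <- tryCatch(fit_behrends(ser), error = function(e) NULL)
  expect_true(is.null(fit) || !fit$converged || fit$rmse >= 0.5 * fit$a ||
                "indeterminable" %in% detect_anomalies(ser, fit))
})

test_that("fit_depletion drives a long table and fills in labels and flags", {
  sc <- synthetic_scenario(seed = 8, noise_cv = 0.03)
  conc <- simulate_monoculture(sc, "Pl")$concentrations
  fits <- fit_depletion(conc)
  expect_length(fits, nrow(sc$medium))
  df <- fits_to_df(fits)
  expect_setequal(df$compound, sc$medium$compound)
  expect_true(all(df$species == "Pl"))
  expect_true(grepl("transient_accumulation",
                    df$flags[df$compound == "glycine"]))
  # clean compounds recover their generating parameters reasonably
  tp <- sc$true_params[sc$true_params$species == "Pl", ]
  clean <- setdiff(sc$medium$compound, c("glycine", "methionine"))
  err <- vapply(clean, function(cp) {
    abs(fits[[paste0("Pl|", cp)]]$t50 - tp$t50[tp$compound == cp])
  }, numeric(1))
  expect_lt(median(err), 0.1)
})
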