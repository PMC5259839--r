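# exodeplete

Substrate-depletion kinetics and co-culture prediction from exometabolomic
time series.

## What it is for

Exometabolomics (metabolic footprinting) follows the disappearance of
substrates from a growth medium over time. For microbial isolates grown in
batch on a defined mixture — glucose plus 19 amino acids, sampled hourly —
each substrate's depletion traces a sigmoid that can be summarised by four
numbers. `exodeplete` is for researchers who want to turn such time courses
into per-species *resource usage models*, compare substrate preferences
across species, and test whether a mixed culture of those species simply
shares resources "blindly" (each member consuming as it does alone, until
the common pool runs out) or shows interactions.

The core model is the decreasing logistic

ξ(t) = a / (1 + e^((t − t50)/w)) + o

with amplitude `a` (µM), offset `o` (µM, what the species leaves behind),
midpoint `t50` (h) and width `w` (h). Amplitude and offset are fixed from
the data (offset = minimum; plateau = mean of the t = 0 and maximum
values); `t50` and `w` are fitted by Levenberg–Marquardt least squares with
positivity enforced on the log scale. Derived preference metrics: the
half-depletion time `T_h = t50 + w·ln(2a/q − 1)` with `q = ξ(0) − o`, the
90→10% usage window, and the maximum depletion rate `a/(4w)` — absolute and
per gram cell dry weight. The co-culture prediction sums the per-species
usage curves, finds the time `t_d` at which they exhaust the available
amount `C = C0 − min_i o_i`, caps each usage curve at its `t_d` level,
refits, and sums the refit models; observed co-culture data are scored
against the prediction by R² on t0-normalised curves (threshold 0.9), with
deviation direction from the signed residuals.

The package includes a synthetic-data generator (monoculture and shared-pool
co-culture ground truth, LC-MS peak areas with a medium-dilution calibration
ladder) so the entire pipeline is testable without external data, plus an
internal-standard-normalised quantification module with dynamic-range
flagging.

## Worked example

Fit one noisy series (true parameters a = 500, o = 20, t50 = 5, w = 0.8;
3 replicates, 5% CV noise, hourly sampling 0–12 h plus 26 h):

```r
library(exodeplete)
set.seed(1)
tt <- rep(c(0:12, 26), 3)
truth <- 500 / (1 + exp((tt - 5) / 0.8)) + 20
sdl <- sqrt(log1p(0.05^2))
obs <- truth * exp(rnorm(length(tt), -sdl^2 / 2, sdl))
fit <- fit_behrends(data.frame(time_h = tt, value = obs))
fit
#> Behrends depletion fit [NA / NA]
#>   a = 501.8  o = 18.72  t50 = 5.035 h  w = 0.755 h
#>   converged: TRUE  rmse: 11.1  flags: none
half_depletion_time(fit)   # 5.037 h: half of the used amount is gone
usage_window(fit)          # t90 3.386 h, t10 6.695 h
max_depletion_rate(fit)    # 166.2 uM/h at t50
```

`t50` and `w` land within ~0.05 h of the generating values; `T_h ≈ t50`
because the series starts on its plateau.

Run the whole pipeline on the bundled synthetic scenario (3 species ×
20 compounds, including a glycine-like transient-accumulation anomaly and a
methionine-like high-variance channel):

```r
res <- run_pipeline(out_dir = "demo_out")
str(res$summary)
#> $ n_compounds         : int 19
#> $ n_consistent        : int 17
#> $ n_deviating_faster  : int 2
#> $ n_deviating_slower  : int 0
#> $ n_not_determined    : int 0
#> $ n_pred_below10_by_6h: int 11
#> $ n_obs_below10_by_6h : int 14
head(res$evaluation[, c("compound", "r2", "class", "t_below10_pred")])
#>     compound     r2            class t_below10_pred
#> 1    glucose  0.995       consistent           6.37
#> 2    alanine  0.990       consistent           6.37
#> 3   arginine -1.056 deviating_faster          10.63
```

Reading the output: 19 of 20 compounds could be evaluated (glycine's
accumulation anomaly leaves it without a valid usage model, mirroring how
such channels are dropped in practice); 17 agree with the blind-sharing
prediction (R² ≥ 0.9). The two "deviating" compounds are artefacts of
incomplete fit sets — a species whose monoculture fit was discarded still
consumes in the observed co-culture — which is exactly the situation the
classification is meant to surface. `n_pred_below10_by_6h` counts compounds
predicted to fall below 10% of their starting concentration within 6 h.
`run_pipeline()` writes every stage's artefacts (concentration CSVs,
calibration and fit JSONs, metrics, predictions, evaluation, and a run
manifest) under `out_dir`, byte-identically for a fixed seed.

A thin command-line wrapper is available at `inst/cli/exodeplete.R`.

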