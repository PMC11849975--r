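test_that("restitution 0 yields exactly one pulse; geometric cutoff counts", {
  dev <- test_device()
  one <- simulate_drop_trace(impact_sim_config(dev, restitution = 0,
                                               seed = 1))
  expect_equal(attr(one, "n_pulses"), 1)

  # amplitudes 1, .5, .25, .125 of the first; .0625 under the 0.1 cutoff
  four <- simulate_drop_trace(impact_sim_config(dev, restitution = 0.5,
                                                min_pulse_fraction = 0.1,
                                                seed = 1))
  expect_equal(attr(four, "n_pulses"), 4)

  # generic count oracle: #pulses = 1 + floor(log(cutoff)/log(e)) adjusted
  for (e in c(0.2, 0.35, 0.6)) {
    for (cutoff in c(0.3, 0.1, 0.02)) {
      tr <- simulate_drop_trace(impact_sim_config(
        dev, restitution = e, min_pulse_fraction = cutoff, seed = 1))
      expect_equal(attr(tr, "n_pulses"), sum(e^(0:60) >= cutoff))
    }
  }
})

test_that("first-pulse amplitude follows sqrt-height kinematics", {
  a1 <- attr(simulate_drop_trace(impact_sim_config(
    test_device(height_cm = 27), seed = 1)), "pulse_amplitudes_kpa")[1]
  a4 <- attr(simulate_drop_trace(impact_sim_config(
    test_device(height_cm = 108), seed = 1)), "pulse_amplitudes_kpa")[1]
  expect_equal(a4 / a1, 2, tolerance = 1e-12)
})

test_that("bounce flight times shrink geometrically; train length closes", {
  dev <- test_device(height_cm = 108)
  e <- 0.5
  tr <- simulate_drop_trace(impact_sim_config(dev, restitution = e,
                                              min_pulse_fraction = 1e-6,
                                              seed = 1))
  times <- attr(tr, "pulse_times_ms")
  gaps <- diff(times)
  expect_equal(gaps[-1] / gaps[-length(gaps)],
               rep(e, length(gaps) - 1), tolerance = 1e-9)
  # total train duration converges to (2 v0 / g) * e / (1 - e)
  v0 <- sqrt(2 * 9.80665 * 1.08)
  expect_equal(sum(gaps) / 1000, 2 * v0 / 9.80665 * e / (1 - e),
               tolerance = 1e-3)
})

test_that("simulated traces are bit-reproducible given (config, seed)", {
  cfg <- impact_sim_config(test_device(), noise_sd = 2, seed = 99)
  expect_identical(simulate_drop_trace(cfg)$samples,
                   simulate_drop_trace(cfg)$samples)
})

test_that("round trip: simulate -> convert -> segment recovers the pulses", {
  dev <- test_device()
  for (seed in 1:5) {
    cfg <- impact_sim_config(dev, restitution = 0.4,
                             min_pulse_fraction = 0.05, noise_sd = 0,
                             seed = seed)
    tr <- simulate_drop_trace(cfg)
    ds <- summarize_drop(convert_trace(tr), exceedance = 1)
    expect_equal(ds$n_waves, attr(tr, "n_pulses"))
    # peaks within one ADC step (~1.264 kPa) of the generative amplitudes
    expect_equal(ds$waves$peak_kpa, attr(tr, "pulse_amplitudes_kpa"),
                 tolerance = 1.27 / min(attr(tr, "pulse_amplitudes_kpa")))
    expect_true(all(abs(ds$waves$peak_kpa -
                          attr(tr, "pulse_amplitudes_kpa")) <= 1.27))
  }
})

test_that("ADC saturation is flagged and clipped at the rail", {
  # 108 cm at 300 kPa/(m/s) exceeds the 1163.5 kPa rail
  cfg <- impact_sim_config(test_device(), pressure_per_velocity = 300,
                           seed = 1)
  tr <- simulate_drop_trace(cfg)
  expect_gt(attr(tr, "n_saturated"), 0)
  expect_equal(max(tr$samples$adc_output), 1023)
  cfg_nq <- impact_sim_config(test_device(), pressure_per_velocity = 300,
                              adc_quantize = FALSE, seed = 1)
  expect_warning(simulate_drop_trace(cfg_nq), "rail")
})

test_that("activity generator: determinism, baseline mean, forced events", {
  cfg <- behavior_sim_config(n_per_group = 8, seed = 5)
  a1 <- simulate_activity(cfg, 0)
  a2 <- simulate_activity(cfg, 0)
  expect_identical(lapply(a1, function(x) x$bins),
                   lapply(a2, function(x) x$bins))

  # dose 0 with no seizure/inactivity: group mean near truncated baseline
  quiet <- behavior_sim_config(n_per_group = 20, seizure_prob_peak = 0,
                               inactivity_logit = c(-50, 0), seed = 6)
  traces <- simulate_activity(quiet, 0)
  means <- vapply(traces, mean_activity, 0)
  # truncation at 0 barely moves the mean at mean/sd = 4
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 2), 3 * se + 0.01)

  # inactivity probability forced to 1: every larva has >= 60 s inactive
  forced <- behavior_sim_config(n_per_group = 10, seizure_prob_peak = 0,
                                inactivity_logit = c(50, 0), seed = 7)
  for (tr in simulate_activity(forced, 500)) {
    expect_gte(detect_inactivity(tr)$total_inactive_s, 60)
  }
})

test_that("seizure bouts appear inside the detectability band, not outside", {
  cfg <- behavior_sim_config(n_per_group = 40, seizure_prob_peak = 1,
                             inactivity_logit = c(-50, 0), seed = 8)
  # detection threshold 6: far above baseline ~2, far below gain*baseline
  in_band <- simulate_activity(cfg, 195)   # band centre
  n_in <- sum(vapply(in_band, function(tr) {
    nrow(detect_high_activity_bouts(tr, 6)) > 0
  }, TRUE))
  out_band <- simulate_activity(cfg, 800)  # beyond the band
  n_out <- sum(vapply(out_band, function(tr) {
    nrow(detect_high_activity_bouts(tr, 6)) > 0
  }, TRUE))
  expect_gt(n_in, 30)
  expect_equal(n_out, 0)
})

test_that("phenotype generator: prevalence, determinism, round trip", {
  # beta = 0 everywhere -> prevalence 1/2 within a binomial 99% interval
  cfg0 <- phenotype_sim_config(beta0 = 0, beta1_per_kpa = 0,
                               beta2_per_drop = 0, n_per_dose = 334,
                               seed = 9)
  tab0 <- simulate_phenotypes(cfg0)
  n <- nrow(tab0)
  expect_gt(n, 1999)
  expect_lt(abs(mean(tab0$outcome) - 0.5), 2.58 * sqrt(0.25 / n))

  cfg <- phenotype_sim_config(seed = 10)
  expect_identical(simulate_phenotypes(cfg), simulate_phenotypes(cfg))

  # generative OR recovered within the Wald CI
  big <- phenotype_sim_config(n_per_dose = 300, seed = 11)
  fit <- fit_logistic(simulate_phenotypes(big), "max_pressure_kpa")
  ors <- fit$odds_ratios
  expect_true(ors$ci_lower <= 1.005 && 1.005 <= ors$ci_upper)
})
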