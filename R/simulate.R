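#' Configuration for the bouncing-weight impact simulator
#'
#' Physical and signal-chain parameters for [simulate_drop_trace()]. The
#' dropped weight hits the syringe plunger at speed `v0 = sqrt(2 g h)`;
#' each bounce `k` (k = 0 for the first impact) strikes at speed
#' `v0 * restitution^k` and produces a pressure pulse with amplitude
#' `pressure_per_velocity * v0 * restitution^k`, the flight time before
#' bounce `k` being `2 * v0 * restitution^k / g`. Pulse amplitudes thus
#' decay geometrically and bounces crowd together — the impulse-train
#' structure seen in real weight-drop traces. The amplitude law
#' (pressure proportional to impact speed) is a modelling choice that
#' reproduces the qualitative trends (higher drops give larger, more
#' numerous waves); it makes no claim to predict absolute kPa for a
#' physical rig, and holder rigidity or syringe size are represented only
#' through `pressure_per_velocity`.
#'
#' @param device A [device_config()]; `drop_height_cm` sets the impact
#'   speed.
#' @param restitution Coefficient of restitution in \[0, 1): ratio of
#'   rebound to impact speed. 0 means no bounce (single pulse).
#' @param pulse_shape `"half_sine"` or `"exp_decay"`.
#' @param pulse_width_ms Pulse width (half-sine period half / decay
#'   constant), ms.
#' @param pressure_per_velocity Peak kPa per (m/s) of impact speed.
#' @param min_pulse_fraction Bounce train cutoff: pulses smaller than this
#'   fraction of the first pulse are dropped, in (0, 1].
#' @param noise_sd Gaussian sensor noise SD, kPa.
#' @param adc_quantize If `TRUE` (default) the trace is pushed through the
#'   inverse calibration chain and rounded to integer ADC counts,
#'   saturating at the rails.
#' @param sample_dt_ms Sampling interval, ms (default 0.2 ms = 5 kHz).
#' @param duration_ms Recording length, ms. The default `NULL` mimics the
#'   rig: at least the nominal one-second trigger window, extended when
#'   the bounce train (plus a quiescent tail for baseline estimation)
#'   outlasts it — the acquisition setup allows longer recordings.
#' @param impact_delay_ms Time of first impact after the photoresistor
#'   trigger; `NULL` (default) uses the free-fall time
#'   `sqrt(2 h / g)` from the trigger at the top of the guide tube.
#' @param seed Integer RNG seed; mandatory, the generator has no hidden
#'   entropy.
#' @return An `impact_sim_config` list.
#' @export
impact_sim_config <- function(device,
                              restitution = 0.18,
                              pulse_shape = c("half_sine", "exp_decay"),
                              pulse_width_ms = 5,
                              pressure_per_velocity = 50,
                              min_pulse_fraction = 0.05,
                              noise_sd = 0,
                              adc_quantize = TRUE,
                              sample_dt_ms = 0.2,
                              duration_ms = NULL,
                              impact_delay_ms = NULL,
                              seed = 1L) {
  stopifnot(inherits(device, "device_config"))
  pulse_shape <- match.arg(pulse_shape)
  if (restitution < 0 || restitution >= 1) {
    stop("`restitution` must lie in [0, 1)")
  }
  if (pulse_width_ms <= 0) stop("`pulse_width_ms` must be positive")
  if (sample_dt_ms <= 0) stop("`sample_dt_ms` must be positive")
  if (min_pulse_fraction <= 0 || min_pulse_fraction > 1) {
    stop("`min_pulse_fraction` must lie in (0, 1]")
  }
  structure(
    list(device = device, restitution = restitution,
         pulse_shape = pulse_shape, pulse_width_ms = pulse_width_ms,
         pressure_per_velocity = pressure_per_velocity,
         min_pulse_fraction = min_pulse_fraction, noise_sd = noise_sd,
         adc_quantize = adc_quantize, sample_dt_ms = sample_dt_ms,
         duration_ms = duration_ms, impact_delay_ms = impact_delay_ms,
         seed = as.integer(seed)),
    class = "impact_sim_config"
  )
}

# Bounce schedule: per-pulse time offsets (s, from first impact) and
# amplitude fractions restitution^k, truncated at min_pulse_fraction.
bounce_schedule <- function(v0, restitution, min_pulse_fraction) {
  fracs <- 1
  if (restitution > 0) {
    k <- 1
    while (restitution^k >= min_pulse_fraction) {
      fracs <- c(fracs, restitution^k)
      k <- k + 1
    }
  }
  offsets <- cumsum(c(0, 2 * v0 * fracs[-1] / GRAV_G))
  data.frame(k = seq_along(fracs) - 1, amplitude_frac = fracs,
             time_offset_s = offsets)
}

#' Simulate one weight-drop transducer recording
#'
#' Generates the bouncing-weight impulse train described in
#' [impact_sim_config()], adds Gaussian sensor noise, and passes the
#' signal back through the inverse transducer calibration to integer ADC
#' counts (when `adc_quantize`), saturating at the 10-bit rails. The
#' result is a [raw_trace()] that [convert_trace()] and
#' [segment_waves()] can consume like a real recording.
#'
#' @param cfg An [impact_sim_config()].
#' @return A [raw_trace()] with attributes `n_pulses`, `pulse_times_ms`,
#'   `pulse_amplitudes_kpa` (ground truth for round-trip checks) and
#'   `n_saturated` (samples clipped at an ADC rail).
#' @examples
#' dev <- device_config(20, "clamp", 100, 108, barrel_diameter_mm = 19.1)
#' tr <- simulate_drop_trace(impact_sim_config(dev, seed = 7))
#' attr(tr, "n_pulses")
#' @export
simulate_drop_trace <- function(cfg) {
  stopifnot(inherits(cfg, "impact_sim_config"))
  set.seed(cfg$seed)
  h_m <- cfg$device$drop_height_cm / 100
  v0 <- sqrt(2 * GRAV_G * h_m)

  sched <- bounce_schedule(v0, cfg$restitution, cfg$min_pulse_fraction)
  amps <- cfg$pressure_per_velocity * v0 * sched$amplitude_frac
  delay <- if (is.null(cfg$impact_delay_ms)) {
    sqrt(2 * h_m / GRAV_G) * 1000
  } else cfg$impact_delay_ms
  pulse_t <- delay + sched$time_offset_s * 1000

  duration <- if (is.null(cfg$duration_ms)) {
    max(1000, max(pulse_t) + 6 * cfg$pulse_width_ms + 200)
  } else cfg$duration_ms
  t_ms <- seq(0, duration, by = cfg$sample_dt_ms)
  p <- numeric(length(t_ms))
  w <- cfg$pulse_width_ms
  for (i in seq_along(pulse_t)) {
    rel <- t_ms - pulse_t[i]
    if (cfg$pulse_shape == "half_sine") {
      in_pulse <- rel >= 0 & rel <= w
      p[in_pulse] <- p[in_pulse] + amps[i] * sin(pi * rel[in_pulse] / w)
    } else {
      in_pulse <- rel >= 0 & rel <= 6 * w
      p[in_pulse] <- p[in_pulse] + amps[i] * exp(-rel[in_pulse] / w)
    }
  }
  if (cfg$noise_sd > 0) p <- p + stats::rnorm(length(p), 0, cfg$noise_sd)

  adc <- kpa_to_adc(p)
  n_sat <- sum(adc < 0 | adc > ADC_MAX)
  if (n_sat > 0 && !cfg$adc_quantize) {
    warning(n_sat, " sample(s) exceed the ADC rails; clipped")
  }
  if (cfg$adc_quantize) adc <- round(adc)
  adc <- pmin(pmax(adc, 0), ADC_MAX)

  out <- raw_trace(t_ms, adc, device = cfg$device, drop_index = 1L)
  attr(out, "n_pulses") <- nrow(sched)
  attr(out, "pulse_times_ms") <- pulse_t
  attr(out, "pulse_amplitudes_kpa") <- amps
  attr(out, "n_saturated") <- n_sat
  out
}

#' Configuration for the dose-structured activity simulator
#'
#' Parameters for [simulate_activity()], which emulates the biphasic
#' behavioural structure of the assay: seizure-like hyperactivity appears
#' in a moderate-pressure band (detectable roughly between 90 and 300
#' kPa), while higher pressures suppress locomotion and produce long
#' inactivity bouts.
#'
#' @param n_per_group Larvae per simulated group.
#' @param baseline_mean,baseline_sd Per-bin baseline activity draws,
#'   Normal truncated at 0 (distance units per bin).
#' @param seizure_gain Multiplier applied to activity during a seizure
#'   bout.
#' @param seizure_band kPa interval in which seizure bouts occur
#'   (default c(90, 300)).
#' @param seizure_prob_peak Per-larva seizure-bout probability at the
#'   centre of the band; falls linearly to 0 at the band edges.
#' @param inactivity_logit `c(b0, b1)`: per-larva probability of an
#'   inactivity run is `plogis(b0 + b1 * dose_kpa)`.
#' @param recording_s Recording length, s (default 1800 = 30 min).
#' @param bin_s Bin width, s (default 1); must divide `recording_s`.
#' @param seed Integer RNG seed.
#' @return A `behavior_sim_config` list.
#' @export
behavior_sim_config <- function(n_per_group = 24,
                                baseline_mean = 2, baseline_sd = 0.5,
                                seizure_gain = 8,
                                seizure_band = c(90, 300),
                                seizure_prob_peak = 0.6,
                                inactivity_logit = c(-6, 0.008),
                                recording_s = 1800, bin_s = 1,
                                seed = 1L) {
  if (n_per_group < 1) stop("`n_per_group` must be >= 1")
  if (recording_s %% bin_s != 0) {
    stop("`recording_s` must be a multiple of `bin_s`")
  }
  structure(
    list(n_per_group = n_per_group, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, seizure_gain = seizure_gain,
         seizure_band = seizure_band,
         seizure_prob_peak = seizure_prob_peak,
         inactivity_logit = inactivity_logit,
         recording_s = recording_s, bin_s = bin_s, seed = as.integer(seed)),
    class = "behavior_sim_config"
  )
}

# Seizure-bout probability: triangular bump over the detectability band.
seizure_prob <- function(cfg, dose_kpa) {
  lo <- cfg$seizure_band[1]; hi <- cfg$seizure_band[2]
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2
  cfg$seizure_prob_peak * pmax(0, 1 - abs(dose_kpa - mid) / half)
}

#' Simulate per-larva activity traces at a given dose
#'
#' Each larva gets truncated-Normal per-bin baseline activity; with
#' probability rising in the seizure band a contiguous high-activity bout
#' (baseline times `seizure_gain`) is inserted, and with logistic-in-dose
#' probability a contiguous zero-activity run of at least 60 s is
#' inserted. Reproducible given (config, seed).
#'
#' @param cfg A [behavior_sim_config()].
#' @param dose_kpa Group maximal pressure in kPa (0 for uninjured).
#' @param group Group label (default derived from the dose).
#' @return List of [activity_trace()] objects, length `n_per_group`.
#' @export
simulate_activity <- function(cfg, dose_kpa, group = NULL) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  set.seed(cfg$seed + round(dose_kpa))
  if (is.null(group)) {
    group <- if (dose_kpa == 0) "control" else sprintf("%gkPa", dose_kpa)
  }
  n_bins <- cfg$recording_s / cfg$bin_s
  t_start <- (seq_len(n_bins) - 1) * cfg$bin_s
  t_end <- t_start + cfg$bin_s
  p_seiz <- seizure_prob(cfg, dose_kpa)
  p_inact <- stats::plogis(cfg$inactivity_logit[1] +
                             cfg$inactivity_logit[2] * dose_kpa)
  min_inact_bins <- ceiling(60 / cfg$bin_s)

  lapply(seq_len(cfg$n_per_group), function(i) {
    act <- pmax(0, stats::rnorm(n_bins, cfg$baseline_mean, cfg$baseline_sd))
    if (stats::runif(1) < p_seiz) {
      len <- round(stats::runif(1, 10, 30) / cfg$bin_s)
      len <- max(1, min(len, n_bins))
      start <- sample.int(n_bins - len + 1, 1)
      idx <- start:(start + len - 1)
      act[idx] <- act[idx] * cfg$seizure_gain
    }
    if (stats::runif(1) < p_inact) {
      len <- round(stats::runif(1, 60, 180) / cfg$bin_s)
      len <- max(min_inact_bins, min(len, n_bins))
      start <- sample.int(n_bins - len + 1, 1)
      act[start:(start + len - 1)] <- 0
    }
    activity_trace(sprintf("%s_L%02d", group, i), group,
                   sprintf("W%02d", i), t_start, t_end, act)
  })
}

#' Configuration for the Bernoulli phenotype simulator
#'
#' The generative inverse of the logistic dose-response model: each larva's
#' binary outcome is Bernoulli with
#' `logit p = beta0 + beta1 * max_pressure_kpa + beta2 * n_drops`.
#' Defaults place the per-kPa odds ratio at 1.005 and the per-drop odds
#' ratio at 1.099 over the assay's 33-1105 kPa working span.
#'
#' @param beta0 Intercept on the logit scale.
#' @param beta1_per_kpa Log-odds per kPa (default `log(1.005)`).
#' @param beta2_per_drop Log-odds per weight drop (default `log(1.099)`).
#' @param doses Data frame with columns `max_pressure_kpa` and `n_drops`,
#'   one row per dose group.
#' @param n_per_dose Larvae per dose group.
#' @param seed Integer RNG seed.
#' @return A `phenotype_sim_config` list.
#' @export
phenotype_sim_config <- function(beta0 = -2,
                                 beta1_per_kpa = log(1.005),
                                 beta2_per_drop = log(1.099),
                                 doses = data.frame(
                                   max_pressure_kpa = c(33, 150, 300, 500,
                                                        750, 1105),
                                   n_drops = 1L
                                 ),
                                 n_per_dose = 40,
                                 seed = 1L) {
  if (n_per_dose < 1) stop("`n_per_dose` must be >= 1")
  stopifnot(all(c("max_pressure_kpa", "n_drops") %in% names(doses)))
  structure(
    list(beta0 = beta0, beta1_per_kpa = beta1_per_kpa,
         beta2_per_drop = beta2_per_drop, doses = doses,
         n_per_dose = n_per_dose, seed = as.integer(seed)),
    class = "phenotype_sim_config"
  )
}

#' Simulate a per-larva binary phenotype table
#'
#' @param cfg A [phenotype_sim_config()].
#' @return Data frame `larva_id, group, outcome, max_pressure_kpa,
#'   n_drops, p_true` suitable for [fit_logistic()].
#' @examples
#' tab <- simulate_phenotypes(phenotype_sim_config(seed = 3))
#' fit_logistic(tab, c("max_pressure_kpa"))
#' @export
simulate_phenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "phenotype_sim_config"))
  set.seed(cfg$seed)
  d <- cfg$doses[rep(seq_len(nrow(cfg$doses)), each = cfg$n_per_dose), ]
  p <- stats::plogis(cfg$beta0 + cfg$beta1_per_kpa * d$max_pressure_kpa +
                       cfg$beta2_per_drop * d$n_drops)
  out <- data.frame(
    larva_id = sprintf("L%04d", seq_len(nrow(d))),
    group = sprintf("P%g_D%d", d$max_pressure_kpa, d$n_drops),
    outcome = stats::rbinom(nrow(d), 1, p),
    max_pressure_kpa = d$max_pressure_kpa,
    n_drops = as.integer(d$n_drops),
    p_true = p
  )
  rownames(out) <- NULL
  out
}
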