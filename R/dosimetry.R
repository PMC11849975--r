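#' Estimate the baseline pressure of a trace
#'
#' The segmentation rule is "from baseline back to baseline", so a numeric
#' baseline is required. It is estimated from a quiescent window of the
#' trace — by default the trailing `window_ms` (after impact ringing has
#' decayed); a leading pre-impact window can be selected instead. The
#' sensor's zero offset can drift, so baseline is always estimated from
#' data rather than assumed to be 0 kPa.
#'
#' @param trace A [pressure_trace()].
#' @param window_ms Width of the estimation window in ms (default 100).
#' @param mode `"trailing"` (default) or `"leading"` window.
#' @return A list with `baseline` (mean kPa) and `noise_sd` (SD kPa) of the
#'   window samples.
#' @export
estimate_baseline <- function(trace, window_ms = 100,
                              mode = c("trailing", "leading")) {
  stopifnot(inherits(trace, "pressure_trace"))
  mode <- match.arg(mode)
  t <- trace$samples$time_ms
  sel <- if (mode == "trailing") t >= t[length(t)] - window_ms else
    t <= t[1] + window_ms
  if (sum(sel) < 10) {
    stop("baseline window of ", window_ms, " ms covers only ", sum(sel),
         " samples; need at least 10")
  }
  p <- trace$samples$pressure_kpa[sel]
  list(baseline = mean(p), noise_sd = stats::sd(p))
}

#' Segment a pressure trace into waves
#'
#' A pressure wave is the excursion of the trace from baseline back to
#' baseline: a wave opens at the first sample strictly above
#' `baseline + exceedance` and closes at the first subsequent sample at or
#' below that level. Per-wave peak and mean pressure are computed over the
#' open (above-threshold) samples; waves shorter than `min_duration_ms`
#' are discarded as single-sample noise spikes. The exceedance margin
#' exists because the literal from-baseline rule is noise-free only in
#' prose; a practical threshold above the noise floor is required (see
#' [summarize_drop()] for the default choice).
#'
#' A wave still open at the end of the recording is closed at the final
#' sample time.
#'
#' @param trace A [pressure_trace()].
#' @param baseline Baseline pressure in kPa (see [estimate_baseline()]).
#' @param exceedance Threshold margin above baseline in kPa (> 0).
#' @param min_duration_ms Minimum wave duration to keep (default 1 ms;
#'   set 0 to apply the literal rule).
#' @return A data frame of class `wave_table` with one row per wave:
#'   `wave_index`, `start_ms`, `end_ms`, `duration_ms`, `peak_kpa`,
#'   `mean_kpa`.
#' @examples
#' tr <- pressure_trace(0:99, c(rep(0, 10), rep(100, 10), rep(0, 80)))
#' segment_waves(tr, baseline = 0, exceedance = 1)
#' @export
segment_waves <- function(trace, baseline, exceedance, min_duration_ms = 1) {
  stopifnot(inherits(trace, "pressure_trace"))
  if (!is.numeric(exceedance) || exceedance <= 0) {
    stop("`exceedance` must be a positive pressure margin in kPa")
  }
  t <- trace$samples$time_ms
  p <- trace$samples$pressure_kpa
  above <- p > baseline + exceedance

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  open_i <- starts[runs$values]
  close_i <- ends[runs$values]

  if (!length(open_i)) {
    return(empty_wave_table())
  }

  # close at the first sample back at/below threshold; at trace end if none
  end_idx <- ifelse(close_i < length(p), close_i + 1L, length(p))
  start_ms <- t[open_i]
  end_ms <- t[end_idx]
  duration <- end_ms - start_ms

  peak <- vapply(seq_along(open_i),
                 function(k) max(p[open_i[k]:close_i[k]]), 0)
  mean_p <- vapply(seq_along(open_i),
                   function(k) mean(p[open_i[k]:close_i[k]]), 0)

  keep <- duration >= min_duration_ms
  if (!any(keep)) return(empty_wave_table())
  out <- data.frame(
    wave_index = seq_len(sum(keep)),
    start_ms = start_ms[keep],
    end_ms = end_ms[keep],
    duration_ms = duration[keep],
    peak_kpa = peak[keep],
    mean_kpa = mean_p[keep]
  )
  class(out) <- c("wave_table", "data.frame")
  out
}

empty_wave_table <- function() {
  out <- data.frame(wave_index = integer(), start_ms = numeric(),
                    end_ms = numeric(), duration_ms = numeric(),
                    peak_kpa = numeric(), mean_kpa = numeric())
  class(out) <- c("wave_table", "data.frame")
  out
}

#' Summarise one weight drop
#'
#' Computes the dose metrics of a single drop: the maximal pressure (the
#' global maximum of the trace, independent of segmentation), the
#' segmented pressure waves, and the intervals between successive waves.
#' Inter-wave intervals are reported start-to-start (the convention
#' recorded here because "time between waves" is ambiguous); end-to-start
#' gaps are also returned so both conventions are available.
#'
#' The default exceedance threshold is `max(3 * noise_sd, 1)` kPa above
#' the estimated baseline: three noise standard deviations keeps false
#' wave openings rare under Gaussian noise, with a 1 kPa floor (under one
#' ADC step) for essentially noise-free traces.
#'
#' @param trace A [pressure_trace()].
#' @param exceedance Threshold margin in kPa; `NULL` (default) uses
#'   `max(3 * noise_sd, 1)`.
#' @param min_duration_ms Minimum wave duration (default 1 ms).
#' @param baseline_window_ms,baseline_mode Passed to [estimate_baseline()].
#' @return An object of class `drop_summary`: `maximal_pressure_kpa`,
#'   `waves` (a `wave_table`), `n_waves`, `inter_wave_intervals_ms`
#'   (start-to-start), `inter_wave_gaps_ms` (end-to-start), `baseline`,
#'   `noise_sd`, `exceedance`, `device`, `drop_index`.
#' @export
summarize_drop <- function(trace, exceedance = NULL, min_duration_ms = 1,
                           baseline_window_ms = 100,
                           baseline_mode = c("trailing", "leading")) {
  stopifnot(inherits(trace, "pressure_trace"))
  baseline_mode <- match.arg(baseline_mode)
  bl <- estimate_baseline(trace, baseline_window_ms, baseline_mode)
  if (is.null(exceedance)) {
    exceedance <- max(3 * bl$noise_sd, 1)
  }
  waves <- segment_waves(trace, bl$baseline, exceedance, min_duration_ms)
  structure(
    list(
      maximal_pressure_kpa = max(trace$samples$pressure_kpa),
      waves = waves,
      n_waves = nrow(waves),
      inter_wave_intervals_ms = if (nrow(waves) > 1) diff(waves$start_ms)
                                else numeric(),
      inter_wave_gaps_ms = if (nrow(waves) > 1) {
        waves$start_ms[-1] - waves$end_ms[-nrow(waves)]
      } else numeric(),
      baseline = bl$baseline,
      noise_sd = bl$noise_sd,
      exceedance = exceedance,
      device = trace$device,
      drop_index = trace$drop_index
    ),
    class = "drop_summary"
  )
}

#' @export
print.drop_summary <- function(x, ...) {
  cat(sprintf(
    "<drop_summary> drop %d: max %.1f kPa, %d wave(s), baseline %.2f kPa\n",
    x$drop_index, x$maximal_pressure_kpa, x$n_waves, x$baseline
  ))
  if (length(x$inter_wave_intervals_ms)) {
    cat("  inter-wave intervals (start-to-start, ms): ",
        paste(round(x$inter_wave_intervals_ms, 1), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Summarise replicate weight drops
#'
#' Consistency metrics over the per-drop maximal pressures of replicate
#' drops of one configuration: mean, SEM (sample SD / sqrt(n)), and the
#' relative standard deviation RSD = 100 x SD / mean. Sample SD uses the
#' n - 1 denominator.
#'
#' @param drops A list of [summarize_drop()] results, or a numeric vector
#'   of per-drop maximal pressures (kPa). At least 2 drops are required
#'   for the SD to be defined.
#' @return An object of class `replicate_summary`: `n_drops`,
#'   `max_pressures_kpa`, `mean_max_pressure_kpa`, `sem_max_pressure_kpa`,
#'   `rsd_percent`.
#' @examples
#' summarize_replicates(c(90, 100, 110))  # RSD 10%
#' @export
summarize_replicates <- function(drops) {
  maxima <- if (is.numeric(drops)) {
    drops
  } else {
    vapply(drops, function(d) {
      stopifnot(inherits(d, "drop_summary"))
      d$maximal_pressure_kpa
    }, 0)
  }
  if (length(maxima) < 2) {
    stop("need at least 2 drops to summarise replicates, got ",
         length(maxima))
  }
  s <- stats::sd(maxima)
  m <- mean(maxima)
  structure(
    list(
      n_drops = length(maxima),
      max_pressures_kpa = maxima,
      mean_max_pressure_kpa = m,
      sem_max_pressure_kpa = s / sqrt(length(maxima)),
      rsd_percent = 100 * s / m
    ),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "<replicate_summary> n=%d drops: max pressure %.1f +/- %.1f kPa (SEM), RSD %.1f%%\n",
    x$n_drops, x$mean_max_pressure_kpa, x$sem_max_pressure_kpa,
    x$rsd_percent
  ))
  invisible(x)
}

#' Static calibration pressure from Pascal's principle
#'
#' Expected transducer reading when a static weight rests on the syringe
#' plunger: pressure = weight / cross-sectional area of the barrel. Used
#' to validate the transducer against known masses. Note this is a static
#' check only; it says nothing about the transducer's dynamic response.
#'
#' @param mass_g Resting mass in grams (>= 0).
#' @param barrel_diameter_mm Inner barrel diameter in mm (> 0).
#' @return Expected pressure in kPa.
#' @examples
#' expected_static_pressure(1000, 14.5)  # ~59.4 kPa
#' @export
expected_static_pressure <- function(mass_g, barrel_diameter_mm) {
  if (any(mass_g < 0)) stop("`mass_g` must be non-negative")
  if (any(barrel_diameter_mm <= 0)) {
    stop("`barrel_diameter_mm` must be positive")
  }
  force_n <- mass_g / 1000 * GRAV_G
  area_m2 <- pi * (barrel_diameter_mm / 2000)^2
  force_n / area_m2 / 1000
}

#' Percent deviation of a measured pressure from the expected value
#'
#' @param measured_kpa Measured reading (kPa).
#' @param expected_kpa Expected value (kPa), nonzero.
#' @return Signed percent deviation, `100 * (measured - expected) / expected`.
#' @export
calibration_error <- function(measured_kpa, expected_kpa) {
  if (any(expected_kpa == 0)) {
    stop("`expected_kpa` must be nonzero for a percent deviation")
  }
  100 * (measured_kpa - expected_kpa) / expected_kpa
}

#' Gravitational potential energy of a weight drop
#'
#' `E = m g h` with g = 9.80665 m/s^2 exactly; inputs in the assay's
#' units (grams, centimetres), output in joules. Configurations with
#' similar maximal pressure can differ substantially in drop energy, so
#' energy is reported alongside pressure as a second dose axis.
#'
#' @param mass_g Drop mass in grams (>= 0).
#' @param height_cm Drop height in cm (>= 0).
#' @return Energy in joules.
#' @examples
#' potential_energy(100, 108)  # ~1.059 J
#' @export
potential_energy <- function(mass_g, height_cm) {
  if (any(mass_g < 0) || any(height_cm < 0)) {
    stop("mass and height must be non-negative")
  }
  (mass_g / 1000) * GRAV_G * (height_cm / 100)
}

#' Ratio of two drop energies as a percentage
#'
#' `100 * E_a / E_b` for two (mass, height) configurations.
#'
#' @param mass_a_g,height_a_cm Numerator configuration.
#' @param mass_b_g,height_b_cm Denominator configuration (nonzero energy).
#' @return Percent ratio.
#' @examples
#' pe_ratio(200, 27, 100, 108)  # 50: half the drop energy at similar pressure
#' @export
pe_ratio <- function(mass_a_g, height_a_cm, mass_b_g, height_b_cm) {
  e_a <- potential_energy(mass_a_g, height_a_cm)
  e_b <- potential_energy(mass_b_g, height_b_cm)
  if (any(e_b == 0)) stop("denominator configuration has zero energy")
  100 * e_a / e_b
}

#' Flatten drop summaries into a per-wave table
#'
#' @param drops List of [summarize_drop()] results.
#' @return Data frame `drop_index, wave_index, start_ms, end_ms,
#'   duration_ms, peak_kpa, mean_kpa`.
#' @export
wave_table <- function(drops) {
  if (inherits(drops, "drop_summary")) drops <- list(drops)
  rows <- lapply(drops, function(d) {
    if (!nrow(d$waves)) return(NULL)
    cbind(drop_index = d$drop_index, as.data.frame(d$waves))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(drop_index = integer(), as.data.frame(empty_wave_table()))
  }
  rownames(out) <- NULL
  out
}
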