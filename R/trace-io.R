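#' Convert raw ADC counts to pressure in kPa
#'
#' Applies the transducer calibration chain used by the blast-TBI rig: the
#' 10-bit ADC count is mapped to volts on a 5 V reference
#' (`voltage = 5 * output / 1023`), the transducer's 0.5 V zero offset and
#' 37.5 PSI/V sensitivity give PSI (`PSI = (voltage - 0.5) * 37.5`), and
#' PSI converts to kPa (`kPa = PSI * 6.895`). The composition is exact and
#' affine; no rounding is applied.
#'
#' Counts below 102.3 imply a voltage under the 0.5 V sensor offset and map
#' to negative kPa. They are returned as-is (see [convert_trace()], which
#' flags them) so that baseline artifacts remain auditable.
#'
#' @param output Numeric vector of ADC counts in \[0, 1023\].
#' @return Numeric vector of pressures in kPa.
#' @examples
#' adc_to_kpa(102.3)  # sensor zero: exactly 0 kPa
#' adc_to_kpa(1023)   # full scale: 1163.53 kPa
#' @export
adc_to_kpa <- function(output) {
  if (!is.numeric(output)) stop("`output` must be numeric")
  bad <- which(!is.finite(output) | output < 0 | output > ADC_MAX)
  if (length(bad)) {
    stop(sprintf(
      "ADC output outside [0, %d] at position %d: %s",
      ADC_MAX, bad[1], format(output[bad[1]])
    ))
  }
  voltage <- ADC_VREF * output / ADC_MAX
  psi <- (voltage - SENSOR_ZERO_V) * PSI_PER_VOLT
  psi * KPA_PER_PSI
}

# Continuous inverse of adc_to_kpa (no rounding); used by the simulator.
kpa_to_adc <- function(kpa) {
  voltage <- kpa / KPA_PER_PSI / PSI_PER_VOLT + SENSOR_ZERO_V
  voltage * ADC_MAX / ADC_VREF
}

#' Construct a raw transducer trace
#'
#' One weight drop's recording: time-stamped 10-bit ADC samples plus the
#' device configuration that produced them. Recording time is referenced to
#' the photoresistor trigger (t = 0 when the falling weight breaks the
#' light beam) and nominally spans one second; longer recordings are
#' accepted.
#'
#' @param time_ms Sample times in ms, strictly increasing.
#' @param adc_output ADC counts in \[0, 1023\], same length as `time_ms`.
#' @param device A [device_config()].
#' @param drop_index Which drop of a replicate series this is (>= 1).
#' @return An object of class `raw_trace` with a `samples` data frame
#'   (`time_ms`, `adc_output`).
#' @export
raw_trace <- function(time_ms, adc_output, device = NULL, drop_index = 1L) {
  if (length(time_ms) != length(adc_output)) {
    stop("`time_ms` and `adc_output` must have equal length")
  }
  if (length(time_ms) < 2) stop("a trace needs at least 2 samples")
  if (any(diff(time_ms) <= 0)) {
    i <- which(diff(time_ms) <= 0)[1] + 1
    stop("sample times must be strictly increasing; violation at sample ", i)
  }
  bad <- which(!is.finite(adc_output) | adc_output < 0 | adc_output > ADC_MAX)
  if (length(bad)) {
    stop(sprintf("ADC output outside [0, %d] at sample %d: %s",
                 ADC_MAX, bad[1], format(adc_output[bad[1]])))
  }
  if (!is.null(device)) stopifnot(inherits(device, "device_config"))
  structure(
    list(
      samples = data.frame(time_ms = as.numeric(time_ms),
                           adc_output = as.numeric(adc_output)),
      device = device,
      drop_index = as.integer(drop_index)
    ),
    class = "raw_trace"
  )
}

#' @export
print.raw_trace <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<raw_trace> drop %d: %d samples over %.1f ms\n",
              x$drop_index, n,
              x$samples$time_ms[n] - x$samples$time_ms[1]))
  invisible(x)
}

#' Read and write raw trace CSV files
#'
#' The file dialect is plain UTF-8 CSV with columns `time_ms,adc_output`,
#' an optional header row, and optional `# key=value` comment lines
#' carrying device metadata (matching Arduino serial-capture practice).
#' Validation failures (non-numeric rows, non-increasing time, ADC out of
#' range) report the offending data row number.
#'
#' @param path File path.
#' @param device A [device_config()]; if `NULL`, metadata comment lines in
#'   the file are used when present.
#' @param drop_index Drop index to attach (default: `drop_index` metadata
#'   in the file, else 1).
#' @return `read_raw_trace()` returns a [raw_trace()];
#'   `write_raw_trace()` returns `path` invisibly.
#' @export
read_raw_trace <- function(path, device = NULL, drop_index = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(data_lines)) stop("no data rows in ", path)

  meta <- parse_hash_metadata(meta_lines)
  if (is.null(device) && length(meta)) device <- device_from_metadata(meta)
  if (is.null(drop_index)) {
    drop_index <- if (!is.null(meta$drop_index)) {
      as.integer(meta$drop_index)
    } else 1L
  }

  # optional header: first data line whose first field is not a number
  first <- strsplit(data_lines[1], ",", fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(trimws(first[1]))))
  if (has_header) data_lines <- data_lines[-1]
  if (!length(data_lines)) stop("no data rows in ", path)

  fields <- strsplit(data_lines, ",", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 2)) {
    stop("row ", which(n_fields < 2)[1], " of ", path,
         " does not have 2 comma-separated columns")
  }
  t_ms <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  adc <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(t_ms) | is.na(adc))
  if (length(bad)) {
    stop("non-numeric value on row ", bad[1], " of ", path, ": ",
         data_lines[bad[1]])
  }
  if (any(diff(t_ms) <= 0)) {
    stop("time not strictly increasing at row ",
         which(diff(t_ms) <= 0)[1] + 1, " of ", path)
  }
  out_of_range <- which(adc < 0 | adc > ADC_MAX)
  if (length(out_of_range)) {
    stop(sprintf("ADC output %s outside [0, %d] on row %d of %s",
                 format(adc[out_of_range[1]]), ADC_MAX, out_of_range[1], path))
  }
  raw_trace(t_ms, adc, device = device, drop_index = drop_index)
}

#' @rdname read_raw_trace
#' @param trace A [raw_trace()] to serialize.
#' @export
write_raw_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(trace$device)) {
    d <- trace$device
    keep <- !vapply(d, function(v) is.null(v) || (is.numeric(v) && is.na(v)),
                    TRUE)
    writeLines(paste0("# ", names(d)[keep], "=", unlist(d[keep])), con)
  }
  writeLines(paste0("# drop_index=", trace$drop_index), con)
  writeLines("time_ms,adc_output", con)
  writeLines(paste(format(trace$samples$time_ms, trim = TRUE,
                          scientific = FALSE),
                   format(trace$samples$adc_output, trim = TRUE,
                          scientific = FALSE),
                   sep = ","), con)
  invisible(path)
}

parse_hash_metadata <- function(meta_lines) {
  if (!length(meta_lines)) return(list())
  body <- trimws(sub("^\\s*#", "", meta_lines))
  body <- body[grepl("=", body, fixed = TRUE)]
  if (!length(body)) return(list())
  hit <- regexpr("=", body, fixed = TRUE)
  stats::setNames(
    as.list(trimws(substr(body, hit + 1, nchar(body)))),
    trimws(substr(body, 1, hit - 1))
  )
}

device_from_metadata <- function(meta) {
  need <- c("syringe_volume_ml", "holder", "drop_mass_g", "drop_height_cm")
  if (!all(need %in% names(meta))) return(NULL)
  device_config(
    syringe_volume_ml = as.numeric(meta$syringe_volume_ml),
    holder = meta$holder,
    drop_mass_g = as.numeric(meta$drop_mass_g),
    drop_height_cm = as.numeric(meta$drop_height_cm),
    barrel_diameter_mm = if (!is.null(meta$barrel_diameter_mm)) {
      as.numeric(meta$barrel_diameter_mm)
    } else NA_real_,
    media_volume_ml = if (!is.null(meta$media_volume_ml)) {
      as.numeric(meta$media_volume_ml)
    } else 1
  )
}

#' Convert a raw trace to a calibrated pressure trace
#'
#' Applies [adc_to_kpa()] sample-wise. Samples whose implied voltage is
#' below the transducer's 0.5 V zero offset come out negative in kPa; they
#' are retained (never clipped) and flagged in the `below_zero` column so
#' sensor-rail artifacts stay visible to baseline estimation.
#'
#' @param raw A [raw_trace()].
#' @return An object of class `pressure_trace`: `samples` data frame
#'   (`time_ms`, `pressure_kpa`, `below_zero`), the device metadata, and a
#'   `conversion` record of the calibration constants applied.
#' @examples
#' tr <- raw_trace(c(0, 1, 2), c(102.3, 500, 102.3))
#' convert_trace(tr)
#' @export
convert_trace <- function(raw) {
  stopifnot(inherits(raw, "raw_trace"))
  kpa <- adc_to_kpa(raw$samples$adc_output)
  structure(
    list(
      samples = data.frame(
        time_ms = raw$samples$time_ms,
        pressure_kpa = kpa,
        below_zero = raw$samples$adc_output < SENSOR_ZERO_V * ADC_MAX / ADC_VREF
      ),
      device = raw$device,
      drop_index = raw$drop_index,
      conversion = c(adc_max = ADC_MAX, vref = ADC_VREF,
                     zero_v = SENSOR_ZERO_V, psi_per_volt = PSI_PER_VOLT,
                     kpa_per_psi = KPA_PER_PSI)
    ),
    class = "pressure_trace"
  )
}

#' Construct a pressure trace directly from kPa samples
#'
#' Mostly useful for tests and for data already in physical units; regular
#' ingestion goes through [read_raw_trace()] + [convert_trace()].
#'
#' @inheritParams raw_trace
#' @param pressure_kpa Pressures in kPa.
#' @return A `pressure_trace`.
#' @export
pressure_trace <- function(time_ms, pressure_kpa, device = NULL,
                           drop_index = 1L) {
  if (length(time_ms) != length(pressure_kpa)) {
    stop("`time_ms` and `pressure_kpa` must have equal length")
  }
  if (length(time_ms) < 2) stop("a trace needs at least 2 samples")
  if (any(diff(time_ms) <= 0)) stop("sample times must be strictly increasing")
  if (any(!is.finite(pressure_kpa))) stop("pressures must be finite")
  structure(
    list(
      samples = data.frame(time_ms = as.numeric(time_ms),
                           pressure_kpa = as.numeric(pressure_kpa),
                           below_zero = pressure_kpa < 0),
      device = device,
      drop_index = as.integer(drop_index),
      conversion = NULL
    ),
    class = "pressure_trace"
  )
}

#' @export
print.pressure_trace <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf(
    "<pressure_trace> drop %d: %d samples over %.1f ms, peak %.1f kPa\n",
    x$drop_index, n, x$samples$time_ms[n] - x$samples$time_ms[1],
    max(x$samples$pressure_kpa)
  ))
  nflag <- sum(x$samples$below_zero)
  if (nflag) cat(sprintf("  %d sample(s) below sensor zero offset\n", nflag))
  invisible(x)
}

#' Write a converted pressure trace as CSV
#'
#' Columns `time_ms,pressure_kpa,flag`; `flag` is 1 where the sample sat
#' below the sensor zero offset.
#'
#' @param trace A `pressure_trace`.
#' @param path Output file.
#' @export
write_pressure_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  df <- data.frame(
    time_ms = trace$samples$time_ms,
    pressure_kpa = trace$samples$pressure_kpa,
    flag = as.integer(trace$samples$below_zero)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
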