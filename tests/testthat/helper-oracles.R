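# Independent brute-force oracles the fast implementations are tested
# against. These walk the definitions literally, one element at a time.

# Literal open/close scan: a wave opens at the first sample strictly above
# threshold and closes at the first subsequent sample at or below it
# (trace end closes an open wave). Returns the same columns as
# segment_waves().
oracle_segment <- function(time_ms, pressure, baseline, exceedance,
                           min_duration_ms = 1) {
  thr <- baseline + exceedance
  waves <- list()
  open <- FALSE
  start_i <- NA
  for (i in seq_along(pressure)) {
    if (!open && pressure[i] > thr) {
      open <- TRUE
      start_i <- i
    } else if (open && pressure[i] <= thr) {
      waves[[length(waves) + 1]] <- c(start_i, i - 1, i)
      open <- FALSE
    }
  }
  if (open) {
    waves[[length(waves) + 1]] <- c(start_i, length(pressure),
                                    length(pressure))
  }
  rows <- lapply(waves, function(w) {
    seg <- pressure[w[1]:w[2]]
    data.frame(start_ms = time_ms[w[1]], end_ms = time_ms[w[3]],
               duration_ms = time_ms[w[3]] - time_ms[w[1]],
               peak_kpa = max(seg), mean_kpa = mean(seg))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start_ms = numeric(), end_ms = numeric(),
                      duration_ms = numeric(), peak_kpa = numeric(),
                      mean_kpa = numeric())
  }
  out <- out[out$duration_ms >= min_duration_ms, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Literal run-length scan over a logical per-bin flag; returns integer
# start/end bin indices of maximal TRUE runs.
oracle_runs <- function(flag) {
  runs <- list()
  i <- 1
  n <- length(flag)
  while (i <= n) {
    if (flag[i]) {
      j <- i
      while (j < n && flag[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# All-pairs AUC with half credit for ties.
oracle_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Rectangular-pulse pressure trace on a 1-ms grid: pulses is a data frame
# with start_ms, width_ms, height_kpa; baseline added everywhere.
make_pulse_trace <- function(pulses, baseline = 0, duration_ms = 1000,
                             dt_ms = 1) {
  t <- seq(0, duration_ms, by = dt_ms)
  p <- rep(baseline, length(t))
  for (i in seq_len(nrow(pulses))) {
    sel <- t >= pulses$start_ms[i] &
      t < pulses$start_ms[i] + pulses$width_ms[i]
    p[sel] <- p[sel] + pulses$height_kpa[i]
  }
  pressure_trace(t, p)
}

# Activity trace on a 1-s grid from a plain activity vector.
make_activity <- function(activity, larva_id = "L1", group = "control",
                          bin_s = 1) {
  n <- length(activity)
  activity_trace(larva_id, group, "W1",
                 (seq_len(n) - 1) * bin_s, seq_len(n) * bin_s, activity)
}

test_device <- function(height_cm = 108, mass_g = 100) {
  device_config(20, "clamp", drop_mass_g = mass_g,
                drop_height_cm = height_cm, barrel_diameter_mm = 19.1)
}
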