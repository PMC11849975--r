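#' Construct a per-larva activity trace
#'
#' One larva's binned locomotor activity as exported by plate-tracking
#' software (EthoVision-style): contiguous, non-overlapping time bins with
#' a non-negative distance-moved value per bin. "Activity" is per-bin
#' distance moved; the bin width is whatever the export used.
#'
#' @param larva_id,group,well Identifiers (character).
#' @param t_start_s,t_end_s Bin boundaries in seconds; bins must be
#'   contiguous (`t_end_s[i] == t_start_s[i+1]`) and non-overlapping.
#' @param activity Distance moved per bin (>= 0).
#' @return An object of class `activity_trace` with a `bins` data frame.
#' @export
activity_trace <- function(larva_id, group, well, t_start_s, t_end_s,
                           activity) {
  n <- length(activity)
  if (n < 1) stop("a trace needs at least one bin")
  if (length(t_start_s) != n || length(t_end_s) != n) {
    stop("bin boundary vectors must match `activity` length")
  }
  if (any(t_end_s <= t_start_s)) stop("bins must have positive width")
  if (n > 1 && any(abs(t_start_s[-1] - t_end_s[-n]) > 1e-9)) {
    stop("bins must be contiguous and non-overlapping")
  }
  if (any(activity < 0)) stop("activity must be non-negative")
  structure(
    list(
      larva_id = as.character(larva_id),
      group = as.character(group),
      well = as.character(well),
      bins = data.frame(t_start_s = as.numeric(t_start_s),
                        t_end_s = as.numeric(t_end_s),
                        activity = as.numeric(activity))
    ),
    class = "activity_trace"
  )
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf(
    "<activity_trace> %s (%s, well %s): %d bins over %.0f s, mean activity %.2f\n",
    x$larva_id, x$group, x$well, nrow(x$bins),
    x$bins$t_end_s[nrow(x$bins)] - x$bins$t_start_s[1],
    mean(x$bins$activity)
  ))
  invisible(x)
}

#' Read a plate-tracking activity export
#'
#' CSV with columns `larva_id,group,well,t_start_s,t_end_s,activity`, one
#' row per larva x time bin.
#'
#' @param path CSV path.
#' @return A named list of [activity_trace()] objects, one per larva.
#' @export
read_activity_export <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("larva_id", "group", "well", "t_start_s", "t_end_s", "activity")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("activity export ", path, " missing columns: ",
         paste(missing, collapse = ", "))
  }
  split_df <- split(df, df$larva_id)
  traces <- lapply(split_df, function(d) {
    d <- d[order(d$t_start_s), ]
    activity_trace(d$larva_id[1], d$group[1], d$well[1],
                   d$t_start_s, d$t_end_s, d$activity)
  })
  traces[order(names(traces))]
}

#' Write activity traces as a plate-tracking-style export
#'
#' @param traces List of [activity_trace()] objects.
#' @param path Output CSV.
#' @export
write_activity_export <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    cbind(larva_id = tr$larva_id, group = tr$group, well = tr$well,
          tr$bins)
  })
  df <- do.call(rbind, rows)
  names(df)[names(df) == "t_start_s"] <- "t_start_s"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean and total locomotor activity of a trace
#'
#' `mean_activity()` is the arithmetic mean of per-bin activity (the
#' per-bin convention; multiply by the bin count for the total, which
#' `total_activity()` returns directly).
#'
#' @param trace An [activity_trace()].
#' @return A single number (distance units per bin, or total distance).
#' @export
mean_activity <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  if (!nrow(trace$bins)) stop("trace has no bins")
  mean(trace$bins$activity)
}

#' @rdname mean_activity
#' @export
total_activity <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  sum(trace$bins$activity)
}

#' High-activity bout threshold from the uninjured group
#'
#' The seizure-candidate threshold is 64% of the highest per-bin activity
#' observed anywhere in the uninjured (control) group, pooled across all
#' control larvae of the session. Bins above this threshold mark
#' abnormally high activity bouts whose time points are then manually
#' scored for seizure characteristics.
#'
#' @param controls A list of [activity_trace()] objects from the uninjured
#'   group (or a single trace).
#' @param fraction Threshold fraction of the control maximum (default 0.64).
#' @return Threshold in the export's distance units. If every control bin
#'   is zero, the threshold is 0 and a warning is emitted (every positive
#'   bin would then qualify).
#' @export
high_activity_threshold <- function(controls, fraction = 0.64) {
  if (inherits(controls, "activity_trace")) controls <- list(controls)
  if (!length(controls)) stop("need at least one control trace")
  maxima <- vapply(controls, function(tr) {
    stopifnot(inherits(tr, "activity_trace"))
    max(tr$bins$activity)
  }, 0)
  ctrl_max <- max(maxima)
  if (ctrl_max == 0) {
    warning("all control bins are zero; threshold 0 makes every positive ",
            "bin a high-activity bout")
  }
  fraction * ctrl_max
}

#' Detect high-activity (seizure-candidate) bouts
#'
#' Maximal runs of consecutive bins with activity strictly above the
#' threshold, reported with bin-boundary times.
#'
#' @param trace An [activity_trace()].
#' @param threshold Activity threshold (>= 0), usually from
#'   [high_activity_threshold()].
#' @return A data frame of bouts: `kind` (`"high_activity"`), `start_s`,
#'   `end_s`, `duration_s`. Zero rows if nothing exceeds the threshold.
#' @export
detect_high_activity_bouts <- function(trace, threshold) {
  stopifnot(inherits(trace, "activity_trace"))
  if (!is.numeric(threshold) || threshold < 0) {
    stop("`threshold` must be a non-negative number")
  }
  runs_to_bouts(trace, trace$bins$activity > threshold, "high_activity")
}

#' Detect inactivity bouts and total inactive time
#'
#' Maximal runs of consecutive bins with activity at or below `epsilon`
#' that last at least `min_duration_s` (default 60 s — the one-minute
#' rule) count as inactivity bouts; shorter pauses are ignored. The
#' default `epsilon` of 0 requires strictly zero movement.
#'
#' @param trace An [activity_trace()].
#' @param min_duration_s Minimum bout duration in seconds (> 0, default 60).
#' @param epsilon Largest per-bin activity still considered inactive
#'   (default 0).
#' @return A list with `bouts` (data frame as in
#'   [detect_high_activity_bouts()], `kind` `"inactive"`) and
#'   `total_inactive_s`, the summed duration of qualifying bouts.
#' @export
detect_inactivity <- function(trace, min_duration_s = 60, epsilon = 0) {
  stopifnot(inherits(trace, "activity_trace"))
  if (min_duration_s <= 0) stop("`min_duration_s` must be positive")
  bouts <- runs_to_bouts(trace, trace$bins$activity <= epsilon, "inactive")
  bouts <- bouts[bouts$duration_s >= min_duration_s, , drop = FALSE]
  rownames(bouts) <- NULL
  list(bouts = bouts, total_inactive_s = sum(bouts$duration_s))
}

# Shared run-length machinery: maximal runs of TRUE bins -> bout rows.
runs_to_bouts <- function(trace, flag, kind) {
  empty <- data.frame(kind = character(), start_s = numeric(),
                      end_s = numeric(), duration_s = numeric())
  if (!any(flag)) return(empty)
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  start_s <- trace$bins$t_start_s[starts[keep]]
  end_s <- trace$bins$t_end_s[ends[keep]]
  data.frame(kind = kind, start_s = start_s, end_s = end_s,
             duration_s = end_s - start_s)
}

#' Flag candidate-dead larvae
#'
#' Larvae that float and never move are considered dead and removed from
#' quantification, but floating cannot be read from the activity table
#' alone. This flag is therefore advisory: `TRUE` when total activity over
#' the recording is at or below `epsilon`. Exclusion from group statistics
#' happens only once death is confirmed (floating / absent heartbeat);
#' nothing is dropped silently.
#'
#' @param trace An [activity_trace()].
#' @param epsilon Total-activity tolerance (default 0).
#' @return Logical: candidate-dead.
#' @export
classify_dead <- function(trace, epsilon = 0) {
  stopifnot(inherits(trace, "activity_trace"))
  total_activity(trace) <= epsilon
}

#' Per-larva behaviour metrics table
#'
#' Applies the bout detectors to each trace and assembles the per-larva
#' metrics used downstream: mean and total activity, number of
#' high-activity bouts, total inactive time, and the candidate-dead flag.
#'
#' @param traces List of [activity_trace()] objects.
#' @param threshold High-activity threshold; `NULL` computes it from the
#'   traces whose group equals `control_group` via
#'   [high_activity_threshold()].
#' @param control_group Group label of the uninjured larvae (default
#'   `"control"`); only used when `threshold` is `NULL`.
#' @param inactivity_min_s,epsilon Passed to [detect_inactivity()].
#' @return A data frame: `larva_id, group, mean_activity, total_activity,
#'   n_high_bouts, total_inactive_s, candidate_dead`.
#' @export
behavior_metrics <- function(traces, threshold = NULL,
                             control_group = "control",
                             inactivity_min_s = 60, epsilon = 0) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  if (is.null(threshold)) {
    ctrl <- Filter(function(tr) tr$group == control_group, traces)
    if (!length(ctrl)) {
      stop("no traces in control group '", control_group,
           "' to set the high-activity threshold")
    }
    threshold <- high_activity_threshold(ctrl)
  }
  rows <- lapply(traces, function(tr) {
    inact <- detect_inactivity(tr, inactivity_min_s, epsilon)
    data.frame(
      larva_id = tr$larva_id,
      group = tr$group,
      mean_activity = mean_activity(tr),
      total_activity = total_activity(tr),
      n_high_bouts = nrow(detect_high_activity_bouts(tr, threshold)),
      total_inactive_s = inact$total_inactive_s,
      candidate_dead = classify_dead(tr, epsilon)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "high_activity_threshold") <- threshold
  out
}

#' Fin-poke stimulus response rate at a time point
#'
#' The fin-poke assay probes loss of consciousness: a poke to the
#' posterior fin every 5 minutes for 30 minutes; responsive larvae swim
#' away immediately. Dead larvae (no heartbeat on post-assay check) are
#' excluded, so only heartbeat-verified records enter the denominator.
#'
#' @param records Data frame with columns `larva_id`, `group`,
#'   `timepoint_min` (on the 5-minute grid 5..30), `responded` (logical or
#'   0/1), `heartbeat_verified` (logical or 0/1).
#' @param timepoint_min Which time point to evaluate.
#' @return Proportion of heartbeat-verified larvae that responded.
#' @export
response_rate <- function(records, timepoint_min) {
  need <- c("larva_id", "timepoint_min", "responded", "heartbeat_verified")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("fin-poke records missing columns: ",
         paste(missing, collapse = ", "))
  }
  bad_tp <- setdiff(unique(records$timepoint_min), c(5, 10, 15, 20, 25, 30))
  if (length(bad_tp)) {
    stop("timepoints must lie on the 5-minute grid 5..30; found ",
         paste(bad_tp, collapse = ", "))
  }
  sel <- records$timepoint_min == timepoint_min &
    as.logical(records$heartbeat_verified)
  if (!any(sel)) {
    stop("no heartbeat-verified records at timepoint ", timepoint_min,
         " min")
  }
  mean(as.logical(records$responded[sel]))
}

#' Seizure-stage proportions from manual scores
#'
#' Manual (blinded) seizure scores use three categories: no seizure,
#' stage I (distinct hyperactive movements with slight convulsive
#' behaviour and minor loss of posture), and stage II/III (whirlpool
#' movements, clonic events, full loss of posture). Stage labels are
#' ingested as data; they are never inferred from kinematics.
#'
#' @param scores Data frame with columns `larva_id` and `stage` (values
#'   among `"none"`, `"stage_I"`, `"stage_II_III"`). One row per larva.
#' @return Named numeric vector of proportions over the three stages;
#'   sums to 1.
#' @export
seizure_proportions <- function(scores) {
  if (!nrow(scores)) stop("need at least one score")
  if (anyDuplicated(scores$larva_id)) {
    dup <- scores$larva_id[duplicated(scores$larva_id)][1]
    stop("duplicate seizure score for larva '", dup, "'")
  }
  stages <- c("none", "stage_I", "stage_II_III")
  bad <- setdiff(unique(scores$stage), stages)
  if (length(bad)) {
    stop("unknown seizure stage(s): ", paste(bad, collapse = ", "))
  }
  tab <- table(factor(scores$stage, levels = stages))
  stats::setNames(as.numeric(tab) / nrow(scores), stages)
}
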