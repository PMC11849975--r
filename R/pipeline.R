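#' Read a session manifest
#'
#' A manifest describes one analysis session as a flat `key=value` file
#' (`#` comments allowed):
#'
#' ```
#' session_id=demo
#' control_group=control
#' activity_csv=activity.csv
#' phenotype_csv=phenotypes.csv
#' group.clamp100.device=devices/clamp100.cfg
#' group.clamp100.traces=traces/c100_1.csv;traces/c100_2.csv
#' param.exceedance=        # empty = auto (3 x noise SD, 1 kPa floor)
#' param.inactivity_min_s=60
#' seed=1
#' ```
#'
#' `group.<name>.traces` lists the replicate drop recordings for one
#' device configuration, semicolon-separated. Paths are resolved relative
#' to the manifest file.
#'
#' @param path Manifest file path.
#' @return A `session_manifest` list: `session_id`, `control_group`,
#'   file paths, `groups` (named list with `device` and `traces`),
#'   `params`, `seed`.
#' @export
read_manifest <- function(path) {
  kv <- read_key_value(path)
  base <- dirname(normalizePath(path, mustWork = TRUE))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }

  groups <- list()
  gkeys <- grep("^group\\.", names(kv), value = TRUE)
  for (key in gkeys) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("malformed manifest key: ", key)
    gname <- parts[2]; field <- parts[3]
    if (!field %in% c("device", "traces")) {
      stop("unknown group field in manifest key: ", key)
    }
    val <- kv[[key]]
    groups[[gname]][[field]] <- if (field == "traces") {
      resolve(trimws(strsplit(val, ";", fixed = TRUE)[[1]]))
    } else resolve(val)
  }

  params <- list()
  pkeys <- grep("^param\\.", names(kv), value = TRUE)
  for (key in pkeys) {
    val <- kv[[key]]
    params[[sub("^param\\.", "", key)]] <-
      if (nzchar(val)) as.numeric(val) else NULL
  }

  opt_path <- function(key) {
    if (!is.null(kv[[key]]) && nzchar(kv[[key]])) resolve(kv[[key]]) else NULL
  }
  structure(
    list(
      session_id = if (!is.null(kv$session_id)) kv$session_id else "session",
      control_group = if (!is.null(kv$control_group)) kv$control_group
                      else "control",
      activity_csv = opt_path("activity_csv"),
      phenotype_csv = opt_path("phenotype_csv"),
      scores_csv = opt_path("scores_csv"),
      finpoke_csv = opt_path("finpoke_csv"),
      groups = groups,
      params = params,
      seed = if (!is.null(kv$seed)) as.integer(kv$seed) else NULL
    ),
    class = "session_manifest"
  )
}

#' Validate a session manifest
#'
#' Schema and cross-reference checks before a run: every referenced file
#' must exist; every injured group in the phenotype table needs a
#' dosimetry entry (trace files) or must be the designated control;
#' larva IDs must be unique within each table. Advisory findings flag
#' shared-control reuse across panels and candidate-dead larvae.
#'
#' @param manifest A `session_manifest` (or path to one).
#' @return A data frame of findings with columns `level` (`"error"` or
#'   `"note"`) and `message`; zero rows when everything checks out.
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "session_manifest"))
  findings <- list()
  add <- function(level, msg) {
    findings[[length(findings) + 1]] <<- data.frame(level = level,
                                                    message = msg)
  }

  for (gname in names(manifest$groups)) {
    g <- manifest$groups[[gname]]
    if (is.null(g$device)) {
      add("error", sprintf("group '%s' has no device config", gname))
    } else if (!file.exists(g$device)) {
      add("error", sprintf("device config missing for group '%s': %s",
                           gname, g$device))
    }
    if (is.null(g$traces)) {
      add("error", sprintf("group '%s' has no trace files", gname))
    } else {
      for (tf in g$traces) {
        if (!file.exists(tf)) {
          add("error", sprintf("trace file missing for group '%s': %s",
                               gname, tf))
        }
      }
    }
  }

  for (key in c("activity_csv", "phenotype_csv", "scores_csv",
                "finpoke_csv")) {
    p <- manifest[[key]]
    if (!is.null(p) && !file.exists(p)) {
      add("error", sprintf("%s missing: %s", key, p))
    }
  }

  if (!is.null(manifest$phenotype_csv) &&
      file.exists(manifest$phenotype_csv)) {
    ph <- utils::read.csv(manifest$phenotype_csv, stringsAsFactors = FALSE)
    if (anyDuplicated(ph$larva_id)) {
      add("error", sprintf("duplicated larva_id in phenotype table: %s",
                           ph$larva_id[duplicated(ph$larva_id)][1]))
    }
    no_dose <- setdiff(unique(ph$group),
                       c(names(manifest$groups), manifest$control_group))
    for (g in no_dose) {
      add("error", sprintf(
        "phenotype group '%s' has no dosimetry entry and is not the control",
        g))
    }
  }
  if (!is.null(manifest$activity_csv) &&
      file.exists(manifest$activity_csv)) {
    av <- utils::read.csv(manifest$activity_csv, stringsAsFactors = FALSE)
    if (manifest$control_group %in% av$group) {
      add("note", sprintf(
        "control group '%s' is shared across comparisons in this session",
        manifest$control_group))
    } else {
      add("error", sprintf("activity table has no control group '%s'",
                           manifest$control_group))
    }
  }

  out <- if (length(findings)) do.call(rbind, findings) else
    data.frame(level = character(), message = character())
  rownames(out) <- NULL
  out
}

#' Run a full analysis session
#'
#' Executes the stages in dependency order — trace conversion, wave
#' segmentation and dose summaries per group; behaviour metrics with the
#' 64% high-activity threshold from the shared control; dose-response
#' fits (logistic phenotype-vs-pressure\[/-drops\], linear activity-vs-
#' pressure, ANOVA + Dunnett of activity by group) — and writes all
#' tables plus a structured run log under `out_dir`. Each larva inherits
#' its group's mean maximal pressure (individual pressure is not
#' observable inside a shared syringe); the control group's dose is 0
#' kPa.
#'
#' Outputs (CSV unless noted): `converted/<group>_<drop>.csv`,
#' `wave_table.csv`, `dose_summary.csv`, `behavior_metrics.csv`,
#' `logistic_fit.csv`, `linear_fit.csv`, `dunnett.csv`, `run_log.txt`.
#' Any stage failure raises a stage-labelled error; outputs of completed
#' stages are left on disk.
#'
#' @param manifest A `session_manifest` or manifest file path.
#' @param out_dir Output directory (created if needed).
#' @return A `session_report` list with the computed objects and file
#'   paths, invisibly.
#' @export
run_pipeline <- function(manifest, out_dir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "session_manifest"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  log_add("session=%s", manifest$session_id)

  findings <- stage("validate", {
    f <- validate_manifest(manifest)
    for (i in seq_len(nrow(f))) log_add("validate %s: %s",
                                        f$level[i], f$message[i])
    if (any(f$level == "error")) {
      stop(f$message[f$level == "error"][1])
    }
    f
  })

  ## ---- dosimetry: convert traces, segment waves, summarise drops ----
  p <- manifest$params
  dose_rows <- list(); all_drops <- list()
  stage("dose", {
    dir.create(file.path(out_dir, "converted"), showWarnings = FALSE)
    for (gname in names(manifest$groups)) {
      g <- manifest$groups[[gname]]
      device <- read_device_config(g$device)
      drops <- lapply(seq_along(g$traces), function(i) {
        rawt <- read_raw_trace(g$traces[i], device = device, drop_index = i)
        pt <- convert_trace(rawt)
        write_pressure_trace(pt, file.path(out_dir, "converted",
                                           sprintf("%s_%d.csv", gname, i)))
        summarize_drop(
          pt,
          exceedance = p$exceedance,
          min_duration_ms = if (!is.null(p$min_duration_ms))
            p$min_duration_ms else 1,
          baseline_window_ms = if (!is.null(p$baseline_window_ms))
            p$baseline_window_ms else 100
        )
      })
      all_drops[[gname]] <- drops
      rs <- summarize_replicates(drops)
      dose_rows[[gname]] <- data.frame(
        group = gname, n_drops = rs$n_drops,
        mean_max_pressure_kpa = rs$mean_max_pressure_kpa,
        sem_max_pressure_kpa = rs$sem_max_pressure_kpa,
        rsd_percent = rs$rsd_percent,
        mean_n_waves = mean(vapply(drops, function(d) d$n_waves, 0)),
        potential_energy_j = potential_energy(device$drop_mass_g,
                                              device$drop_height_cm)
      )
      log_add("dose group=%s drops=%d mean_max=%.2f kPa rsd=%.2f%%",
              gname, rs$n_drops, rs$mean_max_pressure_kpa, rs$rsd_percent)
    }
  })
  dose_summary <- do.call(rbind, dose_rows)
  rownames(dose_summary) <- NULL
  utils::write.csv(dose_summary, file.path(out_dir, "dose_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  wt <- do.call(rbind, lapply(names(all_drops), function(gname) {
    w <- wave_table(all_drops[[gname]])
    if (nrow(w)) cbind(group = gname, w) else NULL
  }))
  if (!is.null(wt)) {
    utils::write.csv(wt, file.path(out_dir, "wave_table.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  ## ---- behaviour metrics ----
  metrics <- NULL
  if (!is.null(manifest$activity_csv)) {
    metrics <- stage("behavior", {
      traces <- read_activity_export(manifest$activity_csv)
      m <- behavior_metrics(
        traces,
        control_group = manifest$control_group,
        inactivity_min_s = if (!is.null(p$inactivity_min_s))
          p$inactivity_min_s else 60,
        epsilon = if (!is.null(p$epsilon)) p$epsilon else 0
      )
      log_add("behavior larvae=%d threshold=%.3f candidate_dead=%d",
              nrow(m), attr(m, "high_activity_threshold"),
              sum(m$candidate_dead))
      utils::write.csv(m, file.path(out_dir, "behavior_metrics.csv"),
                       row.names = FALSE, quote = FALSE)
      m
    })
  }

  ## ---- dose-response fits ----
  group_dose <- stats::setNames(dose_summary$mean_max_pressure_kpa,
                                dose_summary$group)
  group_dose[manifest$control_group] <- 0

  logistic_fit <- NULL
  if (!is.null(manifest$phenotype_csv)) {
    logistic_fit <- stage("doseresponse", {
      ph <- utils::read.csv(manifest$phenotype_csv, stringsAsFactors = FALSE)
      ph$max_pressure_kpa <- unname(group_dose[ph$group])
      covs <- "max_pressure_kpa"
      if ("n_drops" %in% names(ph) && length(unique(ph$n_drops)) > 1) {
        covs <- c(covs, "n_drops")
      }
      fit <- fit_logistic(ph, covs)
      log_add("doseresponse logistic n=%d covariates=%s auc=%.3f",
              fit$n, paste(covs, collapse = "+"), fit$auc)
      tab <- fit$odds_ratios
      tab$auc <- fit$auc
      tab$n <- fit$n
      utils::write.csv(tab, file.path(out_dir, "logistic_fit.csv"),
                       row.names = FALSE, quote = FALSE)
      fit
    })
  }

  linear_fit <- NULL; dunnett <- NULL
  if (!is.null(metrics)) {
    stage("doseresponse", {
      kept <- metrics[!metrics$candidate_dead, ]
      log_add("doseresponse activity larvae in=%d kept=%d (candidate-dead excluded: %d)",
              nrow(metrics), nrow(kept), nrow(metrics) - nrow(kept))
      kept$dose_kpa <- unname(group_dose[kept$group])
      if (length(unique(kept$dose_kpa[!is.na(kept$dose_kpa)])) >= 3) {
        linear_fit <- fit_linear(kept$dose_kpa, kept$mean_activity)
        utils::write.csv(
          data.frame(slope = linear_fit$slope,
                     intercept = linear_fit$intercept,
                     r_squared = linear_fit$r_squared,
                     p_value = linear_fit$p_value, n = linear_fit$n),
          file.path(out_dir, "linear_fit.csv"),
          row.names = FALSE, quote = FALSE)
        log_add("doseresponse linear slope=%.4g r2=%.3f", linear_fit$slope,
                linear_fit$r_squared)
      }
      by_group <- split(kept$mean_activity, kept$group)
      ok <- vapply(by_group, length, 0L) >= 2
      if (manifest$control_group %in% names(by_group)[ok] &&
          sum(ok) >= 2) {
        dunnett <- anova_dunnett(by_group[ok], manifest$control_group)
        utils::write.csv(dunnett$comparisons,
                         file.path(out_dir, "dunnett.csv"),
                         row.names = FALSE, quote = FALSE)
        log_add("doseresponse dunnett F=%.3g p=%.3g", dunnett$f_statistic,
                dunnett$f_p_value)
      }
    })
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(structure(
    list(
      session_id = manifest$session_id,
      findings = findings,
      dose_summary = dose_summary,
      behavior_metrics = metrics,
      logistic_fit = logistic_fit,
      linear_fit = linear_fit,
      dunnett = dunnett,
      out_dir = out_dir
    ),
    class = "session_report"
  ))
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %s -> %s\n", x$session_id, x$out_dir))
  cat(sprintf("  %d dose group(s)", nrow(x$dose_summary)))
  if (!is.null(x$behavior_metrics)) {
    cat(sprintf(", %d larva(e) with behaviour metrics",
                nrow(x$behavior_metrics)))
  }
  cat("\n")
  if (!is.null(x$logistic_fit)) print(x$logistic_fit)
  invisible(x)
}

#' Generate and analyse a fully synthetic session
#'
#' Builds a complete on-disk session — simulated weight-drop recordings
#' for several device configurations spanning the assay's working
#' pressure range, dose-structured activity traces, and a Bernoulli
#' phenotype table from a stated logistic model — then runs
#' [run_pipeline()] on it. The round trip (known generative odds ratio
#' in, fitted odds ratio out) is the package's main end-to-end check.
#'
#' @param out_dir Directory for inputs and results.
#' @param seed Integer seed controlling every random draw.
#' @param n_per_group Larvae per dose group in the phenotype table.
#' @param or_per_kpa Generative odds ratio per kPa (default 1.005).
#' @param beta0 Logit intercept of the generative model (default -2).
#' @param n_activity_per_group Larvae per group in the activity table
#'   (default 12).
#' @return The `session_report`, with the generative parameters attached
#'   as attribute `truth`.
#' @export
run_synthetic_session <- function(out_dir, seed = 1L, n_per_group = 50,
                                  or_per_kpa = 1.005, beta0 = -2,
                                  n_activity_per_group = 12) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)

  # device configurations spanning the working pressure range: height and
  # holder rigidity (via pressure_per_velocity) vary across groups
  setups <- list(
    clamp_low   = list(height = 27,  ppv = 20,  holder = "clamp",
                       syringe = 20),
    clamp_mid   = list(height = 54,  ppv = 45,  holder = "clamp",
                       syringe = 20),
    clamp_high  = list(height = 108, ppv = 60,  holder = "clamp",
                       syringe = 20),
    foam_mid    = list(height = 54,  ppv = 120, holder = "foam_block",
                       syringe = 10),
    foam_high   = list(height = 108, ppv = 160, holder = "foam_block",
                       syringe = 10),
    foam_top    = list(height = 108, ppv = 235, holder = "foam_block",
                       syringe = 10)
  )

  manifest_lines <- c(
    "session_id=synthetic",
    "control_group=control",
    "activity_csv=inputs/activity.csv",
    "phenotype_csv=inputs/phenotypes.csv",
    sprintf("seed=%d", seed)
  )
  group_mean_kpa <- numeric()
  for (gname in names(setups)) {
    s <- setups[[gname]]
    dev <- device_config(s$syringe, s$holder, drop_mass_g = 100,
                         drop_height_cm = s$height,
                         barrel_diameter_mm = if (s$syringe == 20) 19.1
                                              else 14.5)
    dev_path <- file.path(in_dir, paste0(gname, ".cfg"))
    write_device_config(dev, dev_path)
    trace_paths <- character(3)
    maxima <- numeric(3)
    for (i in 1:3) {
      cfg <- impact_sim_config(dev, pressure_per_velocity = s$ppv,
                               noise_sd = 1,
                               seed = seed * 1000 + match(gname,
                                                          names(setups)) *
                                 10 + i)
      tr <- simulate_drop_trace(cfg)
      trace_paths[i] <- file.path(in_dir,
                                  sprintf("%s_drop%d.csv", gname, i))
      write_raw_trace(tr, trace_paths[i])
      maxima[i] <- max(convert_trace(tr)$samples$pressure_kpa)
    }
    group_mean_kpa[gname] <- mean(maxima)
    manifest_lines <- c(
      manifest_lines,
      sprintf("group.%s.device=inputs/%s.cfg", gname, gname),
      sprintf("group.%s.traces=%s",
              gname, paste(file.path("inputs", basename(trace_paths)),
                           collapse = ";"))
    )
  }

  # activity: control plus each injured group at its simulated mean dose
  bcfg <- behavior_sim_config(n_per_group = n_activity_per_group,
                              seed = seed)
  traces <- simulate_activity(bcfg, 0, group = "control")
  for (gname in names(setups)) {
    traces <- c(traces,
                simulate_activity(bcfg, group_mean_kpa[gname],
                                  group = gname))
  }
  write_activity_export(traces, file.path(in_dir, "activity.csv"))

  # phenotypes from the stated logistic model at the group doses
  pcfg <- phenotype_sim_config(
    beta0 = beta0, beta1_per_kpa = log(or_per_kpa), beta2_per_drop = 0,
    doses = data.frame(max_pressure_kpa = c(0, unname(group_mean_kpa)),
                       n_drops = 1L),
    n_per_dose = n_per_group, seed = seed + 7
  )
  ph <- simulate_phenotypes(pcfg)
  ph$group <- rep(c("control", names(setups)), each = n_per_group)
  ph$larva_id <- sprintf("PH_%s_%03d", ph$group,
                         stats::ave(seq_len(nrow(ph)), ph$group,
                                    FUN = seq_along))
  utils::write.csv(ph[c("larva_id", "group", "outcome", "n_drops")],
                   file.path(in_dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(manifest_lines, manifest_path)
  report <- run_pipeline(manifest_path, file.path(out_dir, "results"))
  attr(report, "truth") <- list(or_per_kpa = or_per_kpa, beta0 = beta0,
                                group_mean_kpa = group_mean_kpa)
  report
}
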