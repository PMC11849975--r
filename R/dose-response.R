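#' Simple linear regression of a response on a dose metric
#'
#' Ordinary least squares of `y` on `x` (e.g. mean locomotor activity on
#' maximal pressure), returning the slope, intercept, R-squared and the
#' two-sided p-value of the slope.
#'
#' @param x Dose metric (numeric, not constant, n >= 3).
#' @param y Response (numeric, same length).
#' @return An object of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("`x` is constant; slope is undefined")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = s$r.squared,
      p_value = unname(s$coefficients[2, 4]),
      n = length(x)
    ),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> slope %.4g, intercept %.4g, R^2 %.3f, p %.3g (n=%d)\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' Logistic regression of a binary phenotype on dose covariates
#'
#' Maximum-likelihood logit fit of a binary outcome (seizure, tau-positive,
#' stimulus response, ...) on one or more dose covariates — typically
#' maximal pressure in kPa and/or the number of weight drops. Covariates
#' enter untransformed, so each odds ratio is per one unit of that
#' covariate (per kPa, per weight drop); use [scale_odds_ratio()] to
#' re-express an OR per k units. Confidence intervals are Wald intervals
#' on the log-odds scale, `exp(beta +/- 1.96 * SE)`. Model discrimination
#' is summarised by the ROC AUC of the fitted probabilities against the
#' outcomes ([roc_auc()]).
#'
#' Complete separation (a covariate that perfectly splits the outcome
#' classes) makes the MLE diverge; it is detected up front by a monotone
#' overlap check and reported as an error naming the covariate — no
#' penalized fallback is fitted silently.
#'
#' @param records Data frame with an `outcome` column in \{0, 1\} and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   `"max_pressure_kpa"`).
#' @return An object of class `dose_response_fit`: `coefficients`,
#'   `odds_ratios` (data frame: covariate, OR, CI bounds, p), `auc`,
#'   `model`, `n`.
#' @examples
#' set.seed(1)
#' kpa <- runif(200, 33, 1105)
#' out <- rbinom(200, 1, plogis(-2 + log(1.005) * kpa))
#' fit_logistic(data.frame(outcome = out, max_pressure_kpa = kpa))
#' @export
fit_logistic <- function(records, covariates = "max_pressure_kpa") {
  missing_cols <- setdiff(c("outcome", covariates), names(records))
  if (length(missing_cols)) {
    stop("records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- records[stats::complete.cases(records[c("outcome", covariates)]), ]
  y <- records$outcome
  if (!all(y %in% c(0, 1))) stop("`outcome` must be coded 0/1")
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; logistic fit undefined")
  }
  if (nrow(records) < 10 * length(covariates)) {
    stop("need at least 10 observations per covariate; have ",
         nrow(records), " for ", length(covariates), " covariate(s)")
  }
  for (cv in covariates) {
    x <- records[[cv]]
    if (length(unique(x)) > 1 &&
        (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0]))) {
      stop("complete separation on covariate '", cv,
           "': outcome classes do not overlap")
    }
  }
  fml <- stats::as.formula(paste("outcome ~", paste(covariates, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = records)
  if (!fit$converged) stop("logistic fit did not converge")
  s <- summary(fit)$coefficients
  beta <- s[-1, 1]
  se <- s[-1, 2]
  or_tab <- data.frame(
    covariate = covariates,
    beta = unname(beta),
    se = unname(se),
    odds_ratio = exp(unname(beta)),
    ci_lower = exp(unname(beta) - 1.96 * unname(se)),
    ci_upper = exp(unname(beta) + 1.96 * unname(se)),
    p_value = unname(s[-1, 4])
  )
  structure(
    list(
      coefficients = stats::coef(fit),
      odds_ratios = or_tab,
      auc = roc_auc(stats::fitted(fit), y),
      model = deparse(fml),
      n = nrow(records),
      glm = fit
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> %s  (n=%d, AUC %.2f)\n",
              x$model, x$n, x$auc))
  tab <- x$odds_ratios
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %s: OR %.4g per unit (95%% CI %.4g-%.4g), p %.3g\n",
                tab$covariate[i], tab$odds_ratio[i], tab$ci_lower[i],
                tab$ci_upper[i], tab$p_value[i]))
  }
  invisible(x)
}

#' Re-express a per-unit odds ratio per k units
#'
#' On the logit scale odds multiply, so an odds ratio per one unit of
#' exposure becomes `or^k` per k units: an OR of 1.005 per kPa is a 64.7%
#' increase in odds per 100 kPa. The percent change is
#' `100 * (or^k - 1)`; reports round it to one decimal, full precision is
#' returned.
#'
#' @param or_per_unit Odds ratio per one unit (> 0).
#' @param k Number of units to scale to.
#' @return List with `or` (`or_per_unit^k`) and `percent_change`.
#' @examples
#' scale_odds_ratio(1.005, 100)  # +64.7% per 100 kPa
#' scale_odds_ratio(1.099, 1)    # +9.9% per weight drop
#' @export
scale_odds_ratio <- function(or_per_unit, k) {
  if (any(or_per_unit <= 0)) stop("odds ratio must be positive")
  or_k <- or_per_unit^k
  list(or = or_k, percent_change = 100 * (or_k - 1))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive case receives a higher
#' score than a randomly chosen negative case, with ties counted one
#' half. Computed from midranks, which is exactly the all-pairs count
#' with the half-tie convention.
#'
#' @param scores Numeric scores (e.g. fitted probabilities).
#' @param outcomes Binary outcomes (0/1 or logical), same length.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))  # 0.75
#' @export
roc_auc <- function(scores, outcomes) {
  outcomes <- as.integer(as.logical(outcomes))
  if (length(scores) != length(outcomes)) {
    stop("`scores` and `outcomes` must have equal length")
  }
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present to compute an AUC")
  }
  r <- rank(scores)  # midranks handle ties at half credit
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-way ANOVA with Dunnett comparisons against a shared control
#'
#' Fits a one-way ordinary ANOVA over the groups and then compares every
#' treatment group to the single (shared) control with Dunnett's
#' multiple-comparison procedure, using the pooled error variance and
#' two-sided adjusted p-values. Unadjusted pooled-t p-values are reported
#' alongside; the Dunnett adjustment can only raise them.
#'
#' When the control group is reused across several phenotype panels of a
#' session, that reuse should be flagged in reports (see
#' [validate_manifest()]).
#'
#' @param groups Named list of numeric vectors, one per group (each
#'   n >= 2), including the control.
#' @param control Name of the control group.
#' @param alpha Significance level for the `significant` flags
#'   (default 0.05).
#' @return An object of class `group_comparison`: `f_statistic`,
#'   `f_p_value`, and a `comparisons` data frame (`group`, `mean`,
#'   `diff_from_control`, `p_unadjusted`, `p_adjusted`, `significant`).
#' @export
anova_dunnett <- function(groups, control, alpha = 0.05) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a fully named list")
  }
  if (!control %in% names(groups)) {
    stop("control group '", control, "' not found among: ",
         paste(names(groups), collapse = ", "))
  }
  if (length(groups) < 2) stop("need the control and at least one treatment group")
  small <- names(groups)[vapply(groups, length, 0L) < 2]
  if (length(small)) {
    stop("each group needs n >= 2; too small: ",
         paste(small, collapse = ", "))
  }

  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 0L)),
               levels = c(control, setdiff(names(groups), control)))
  )
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  f_stat <- an[["F value"]][1]
  f_p <- an[["Pr(>F)"]][1]

  treat <- setdiff(names(groups), control)
  means <- vapply(groups, mean, 0)
  sigma2 <- an[["Mean Sq"]][2]

  # residual variance indistinguishable from roundoff => degenerate
  var_tol <- .Machine$double.eps^0.5 * max(1, mean(df$y)^2)
  if (!is.finite(sigma2) || sigma2 <= var_tol) {
    # degenerate: zero residual variance; identical constants => no difference
    diffs <- means[treat] - means[control]
    p_adj <- p_un <- ifelse(abs(diffs) < .Machine$double.eps^0.5, 1, 0)
  } else {
    dunnett <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    p_adj <- as.numeric(summary(dunnett)$test$pvalues)
    # unadjusted: pooled-variance t against the control, two-sided
    se <- sqrt(sigma2 * (1 / lengths(groups)[treat] +
                           1 / length(groups[[control]])))
    tval <- (means[treat] - means[control]) / se
    p_un <- 2 * stats::pt(abs(tval), df = fit$df.residual, lower.tail = FALSE)
  }

  comparisons <- data.frame(
    group = treat,
    n = unname(lengths(groups)[treat]),
    mean = unname(means[treat]),
    diff_from_control = unname(means[treat] - means[control]),
    p_unadjusted = unname(p_un),
    p_adjusted = unname(p_adj),
    significant = unname(p_adj) < alpha
  )
  rownames(comparisons) <- NULL
  structure(
    list(
      control = control,
      control_mean = unname(means[control]),
      f_statistic = f_stat,
      f_p_value = f_p,
      comparisons = comparisons,
      alpha = alpha
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> one-way ANOVA F = %.3g (p = %.3g); Dunnett vs '%s' (mean %.3g)\n",
    x$f_statistic, x$f_p_value, x$control, x$control_mean
  ))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
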