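test_that("fit_linear matches the normal-equations oracle", {
  # noiseless line
  x <- 0:9
  # an exact line makes lm's p-value machinery complain; values are exact
  f <- suppressWarnings(fit_linear(x, 2 * x + 1))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  # three-point hand algebra: slope 2, intercept -1/3, R^2 = 12/13
  f3 <- fit_linear(c(0, 1, 2), c(0, 1, 4))
  expect_equal(f3$slope, 2)
  expect_equal(f3$intercept, -1 / 3)
  expect_equal(f3$r_squared, 12 / 13)

  # brute-force normal equations on random data
  set.seed(61)
  xr <- runif(50); yr <- runif(50)
  fr <- fit_linear(xr, yr)
  sxx <- sum((xr - mean(xr))^2)
  sxy <- sum((xr - mean(xr)) * (yr - mean(yr)))
  expect_equal(fr$slope, sxy / sxx)
  expect_equal(fr$intercept, mean(yr) - fr$slope * mean(xr))

  expect_error(fit_linear(rep(1, 5), 1:5), "constant")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("fit_linear under the null gives near-zero R^2", {
  set.seed(62)
  x <- runif(1000)
  f <- fit_linear(x, rnorm(1000))
  expect_lt(f$r_squared, 0.01)
  expect_gt(f$p_value, 0.001)
})

test_that("fit_logistic reproduces the 2x2 cross-product odds ratio", {
  # a=20 exposed cases, b=10 exposed non-cases, c=10, d=20 -> OR = ad/bc = 4
  tab <- data.frame(
    outcome = c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20)),
    exposed = c(rep(1, 30), rep(0, 30))
  )
  fit <- fit_logistic(tab, "exposed")
  expect_equal(fit$odds_ratios$odds_ratio, 4, tolerance = 1e-6)
  expect_equal(fit$n, 60)
})

test_that("fit_logistic guards its preconditions", {
  d <- data.frame(outcome = rep(1, 20), max_pressure_kpa = runif(20))
  expect_error(fit_logistic(d), "single class")
  d2 <- data.frame(outcome = rep(0:1, 3), max_pressure_kpa = runif(6))
  expect_error(fit_logistic(d2), "at least 10")
  # complete separation is reported, naming the covariate
  d3 <- data.frame(outcome = rep(c(0, 1), each = 10),
                   max_pressure_kpa = c(1:10, 101:110))
  expect_error(fit_logistic(d3), "separation.*max_pressure_kpa")
})

test_that("null logistic fit: OR CI covers 1 and AUC near 0.5", {
  set.seed(63)
  d <- data.frame(outcome = rbinom(2000, 1, 0.5),
                  max_pressure_kpa = runif(2000, 33, 1105))
  fit <- fit_logistic(d)
  ors <- fit$odds_ratios
  expect_true(ors$ci_lower <= 1 && 1 <= ors$ci_upper)
  expect_equal(fit$auc, 0.5, tolerance = 0.05)
})

test_that("parameter recovery over the assay's dose span", {
  set.seed(64)
  kpa <- runif(2000, 33, 1105)
  p <- plogis(-2 + log(1.005) * kpa)
  d <- data.frame(outcome = rbinom(2000, 1, p), max_pressure_kpa = kpa)
  fit <- fit_logistic(d)
  ors <- fit$odds_ratios
  expect_true(ors$ci_lower <= 1.005 && 1.005 <= ors$ci_upper)
  expect_equal(ors$odds_ratio, 1.005, tolerance = 0.002)
})

test_that("Wald CI coverage is nominal over repeated simulation", {
  set.seed(65)
  true_or <- 1.005
  covered <- logical(200)
  for (i in 1:200) {
    kpa <- runif(500, 33, 1105)
    y <- rbinom(500, 1, plogis(-2 + log(true_or) * kpa))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(data.frame(outcome = y, max_pressure_kpa = kpa))
    covered[i] <- fit$odds_ratios$ci_lower <= true_or &&
      true_or <= fit$odds_ratios$ci_upper
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("odds-ratio scaling is exponential and composes", {
  s <- scale_odds_ratio(1.005, 100)
  expect_equal(s$or, 1.005^100)
  expect_equal(round(s$percent_change, 1), 64.7)
  expect_equal(round(scale_odds_ratio(1.099, 1)$percent_change, 1), 9.9)
  expect_equal(round(scale_odds_ratio(1.004, 100)$percent_change, 1), 49.1)
  expect_equal(scale_odds_ratio(1, 250)$percent_change, 0)

  # or^(k1+k2) = or^k1 * or^k2 to machine precision
  set.seed(66)
  for (rep in 1:20) {
    or <- runif(1, 0.9, 1.2)
    k1 <- runif(1, 0, 200)
    k2 <- runif(1, 0, 200)
    expect_equal(scale_odds_ratio(or, k1 + k2)$or,
                 scale_odds_ratio(or, k1)$or * scale_odds_ratio(or, k2)$or)
  }
  expect_error(scale_odds_ratio(-1, 10), "positive")
})

test_that("roc_auc matches the all-pairs oracle and handles ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 10), rep(0:1, 5)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)

  set.seed(67)
  for (rep in 1:120) {
    n <- sample(4:25, 1)
    scores <- sample(1:8, n, replace = TRUE)  # forces ties
    outcomes <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(scores, outcomes), oracle_auc(scores, outcomes))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("roc_auc is invariant under strictly increasing transforms", {
  set.seed(68)
  scores <- rnorm(100)
  outcomes <- rbinom(100, 1, 0.4)
  a0 <- roc_auc(scores, outcomes)
  expect_equal(roc_auc(exp(scores), outcomes), a0)
  expect_equal(roc_auc(qlogis(plogis(scores)), outcomes), a0)
  expect_equal(roc_auc(rank(scores, ties.method = "average"), outcomes), a0)
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(69)
  scores <- rnorm(200)
  outcomes <- rbinom(200, 1, plogis(scores))
  expect_equal(
    roc_auc(scores, outcomes),
    as.numeric(pROC::auc(pROC::roc(outcomes, scores, quiet = TRUE,
                                   direction = "<")))
  )
})

test_that("Dunnett with one treatment group reduces to the pooled t-test", {
  set.seed(71)
  g <- list(control = rnorm(12, 5), treat = rnorm(10, 6))
  cmp <- anova_dunnett(g, "control")
  tt <- t.test(g$treat, g$control, var.equal = TRUE)
  expect_equal(cmp$comparisons$p_adjusted, tt$p.value, tolerance = 1e-3)
  expect_equal(cmp$comparisons$p_unadjusted, tt$p.value)
})

test_that("Dunnett adjusted p never undercuts the unadjusted pooled-t p", {
  set.seed(72)
  for (rep in 1:15) {
    k <- sample(3:6, 1)
    g <- stats::setNames(
      lapply(seq_len(k), function(i) rnorm(sample(5:15, 1), mean = i / 4)),
      c("control", sprintf("t%d", seq_len(k - 1)))
    )
    cmp <- anova_dunnett(g, "control")
    expect_true(all(cmp$comparisons$p_adjusted >=
                      cmp$comparisons$p_unadjusted - 1e-8))
    expect_true(all(cmp$comparisons$p_adjusted >= 0 &
                      cmp$comparisons$p_adjusted <= 1))
  }
})

test_that("degenerate identical groups report no difference", {
  g <- list(control = rep(3, 5), a = rep(3, 5), b = rep(3, 5))
  cmp <- anova_dunnett(g, "control")
  expect_true(all(cmp$comparisons$p_adjusted == 1))
  expect_false(any(cmp$comparisons$significant))
})

test_that("anova_dunnett validates its inputs", {
  g <- list(control = rnorm(5), a = rnorm(5))
  expect_error(anova_dunnett(g, "missing"), "not found")
  expect_error(anova_dunnett(list(control = rnorm(5), a = 1), "control"),
               "n >= 2")
})
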