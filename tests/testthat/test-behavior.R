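test_that("mean activity is the per-bin arithmetic mean", {
  expect_equal(mean_activity(make_activity(rep(2, 30))), 2)
  expect_equal(mean_activity(make_activity(c(0, 4))), 2)
  set.seed(51)
  a <- runif(100, 0, 10)
  expect_equal(mean_activity(make_activity(a)), sum(a) / length(a))
  expect_equal(total_activity(make_activity(a)), sum(a))
})

test_that("the high-activity threshold is 64% of the pooled control max", {
  expect_equal(high_activity_threshold(make_activity(c(1, 10, 3))), 6.4)
  two <- list(make_activity(c(1, 8)), make_activity(c(2, 10)))
  expect_equal(high_activity_threshold(two), 6.4)
  expect_warning(thr <- high_activity_threshold(make_activity(rep(0, 5))),
                 "zero")
  expect_equal(thr, 0)
  # linear in a uniform rescaling of control activities
  set.seed(52)
  ctrl <- lapply(1:3, function(i) make_activity(runif(50, 0, 5)))
  scaled <- lapply(ctrl, function(tr) make_activity(3 * tr$bins$activity))
  expect_equal(high_activity_threshold(scaled),
               3 * high_activity_threshold(ctrl))
})

test_that("high-activity bout detection matches the run-length oracle", {
  tr <- make_activity(c(1, 9, 9, 1))
  b <- detect_high_activity_bouts(tr, 6.4)
  expect_equal(nrow(b), 1)
  expect_equal(b$start_s, 1)
  expect_equal(b$end_s, 3)

  expect_equal(nrow(detect_high_activity_bouts(make_activity(1:5), 10)), 0)
  all_above <- detect_high_activity_bouts(make_activity(rep(9, 20)), 5)
  expect_equal(nrow(all_above), 1)
  expect_equal(all_above$duration_s, 20)

  set.seed(53)
  for (rep in 1:40) {
    a <- sample(0:10, sample(5:60, 1), replace = TRUE)
    thr <- sample(0:9, 1)
    got <- detect_high_activity_bouts(make_activity(a), thr)
    runs <- oracle_runs(a > thr)
    expect_equal(nrow(got), length(runs))
    for (k in seq_along(runs)) {
      expect_equal(got$start_s[k], runs[[k]][1] - 1)
      expect_equal(got$end_s[k], runs[[k]][2])
    }
  }
})

test_that("inactivity bouts honour the one-minute rule at the boundary", {
  # 90 s of zero in one run qualifies
  a <- c(rep(1, 10), rep(0, 90), rep(1, 10))
  r <- detect_inactivity(make_activity(a))
  expect_equal(nrow(r$bouts), 1)
  expect_equal(r$total_inactive_s, 90)

  # 30 s run is below the rule
  a30 <- c(rep(1, 10), rep(0, 30), rep(1, 10))
  expect_equal(detect_inactivity(make_activity(a30))$total_inactive_s, 0)

  # exactly 60 s qualifies; 59 s does not
  a60 <- c(1, rep(0, 60), 1)
  expect_equal(detect_inactivity(make_activity(a60))$total_inactive_s, 60)
  a59 <- c(1, rep(0, 59), 1)
  expect_equal(detect_inactivity(make_activity(a59))$total_inactive_s, 0)

  # two qualifying runs sum
  a2 <- c(rep(0, 60), rep(1, 5), rep(0, 120), rep(1, 5))
  r2 <- detect_inactivity(make_activity(a2))
  expect_equal(nrow(r2$bouts), 2)
  expect_equal(r2$total_inactive_s, 180)
})

test_that("total inactive time is bounded and monotone in activity", {
  set.seed(54)
  for (rep in 1:20) {
    a <- ifelse(runif(300) < 0.7, 0, runif(300, 0.5, 3))
    r <- detect_inactivity(make_activity(a))
    expect_lte(r$total_inactive_s, 300)
    # adding activity to any bin never increases total inactive time
    i <- sample(300, 1)
    a2 <- a
    a2[i] <- a2[i] + 1
    expect_lte(detect_inactivity(make_activity(a2))$total_inactive_s,
               r$total_inactive_s)
  }
})

test_that("candidate-dead flag requires zero total activity", {
  expect_true(classify_dead(make_activity(rep(0, 100))))
  a <- rep(0, 100); a[37] <- 0.2
  expect_false(classify_dead(make_activity(a)))
})

test_that("fin-poke response rates exclude non-verified larvae", {
  rec <- data.frame(
    larva_id = sprintf("L%02d", 1:13), group = "g",
    timepoint_min = 30,
    responded = c(rep(1, 8), rep(0, 5)),
    heartbeat_verified = TRUE
  )
  expect_equal(response_rate(rec, 30), 8 / 13)

  rec$responded <- 1
  expect_equal(response_rate(rec, 30), 1)
  rec$responded <- 0
  expect_equal(response_rate(rec, 30), 0)

  # dead larvae (no heartbeat) leave the denominator
  rec$responded <- c(rep(1, 8), rep(0, 5))
  rec$heartbeat_verified <- c(rep(TRUE, 10), rep(FALSE, 3))
  expect_equal(response_rate(rec, 30), 8 / 10)

  expect_error(response_rate(rec, 15), "no heartbeat-verified records")
  rec$timepoint_min <- 7
  expect_error(response_rate(rec, 7), "5-minute grid")
})

test_that("seizure-stage proportions count and normalise correctly", {
  all_none <- data.frame(larva_id = sprintf("L%d", 1:10), stage = "none")
  expect_equal(unname(seizure_proportions(all_none)), c(1, 0, 0))

  mixed <- data.frame(
    larva_id = sprintf("L%d", 1:24),
    stage = c(rep("none", 12), rep("stage_I", 6), rep("stage_II_III", 6))
  )
  expect_equal(unname(seizure_proportions(mixed)), c(0.5, 0.25, 0.25))

  # permutation invariance and normalisation
  set.seed(55)
  shuffled <- mixed[sample(nrow(mixed)), ]
  expect_equal(seizure_proportions(shuffled), seizure_proportions(mixed))
  expect_equal(sum(seizure_proportions(shuffled)), 1)

  dup <- rbind(mixed, mixed[1, ])
  expect_error(seizure_proportions(dup), "duplicate")
})

test_that("behavior_metrics assembles per-larva rows with group threshold", {
  traces <- list(
    make_activity(c(rep(2, 100), rep(10, 5), rep(2, 95)),
                  larva_id = "C1", group = "control"),
    make_activity(rep(1, 200), larva_id = "T1", group = "tbi"),
    make_activity(c(rep(20, 10), rep(0, 190)), larva_id = "T2",
                  group = "tbi"),
    make_activity(rep(0, 200), larva_id = "T3", group = "tbi")
  )
  m <- behavior_metrics(traces, control_group = "control")
  expect_equal(attr(m, "high_activity_threshold"), 6.4)
  expect_equal(m$n_high_bouts[m$larva_id == "C1"], 1)  # its own 10s spike
  expect_equal(m$n_high_bouts[m$larva_id == "T1"], 0)
  expect_equal(m$total_inactive_s[m$larva_id == "T2"], 190)
  expect_true(m$candidate_dead[m$larva_id == "T3"])
  expect_equal(sum(m$candidate_dead), 1)
})
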