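test_that("profiles validate their parameters", {
  expect_error(gait_profile(stride_length_mean = -1), "positive")
  expect_error(gait_profile(stance_fraction = 1.2), "stance_fraction")
  expect_error(gait_profile(stride_time_sd = -0.1), "non-negative")
  expect_error(default_profile("sideways"))
})

test_that("wall profile is smaller, slower, more variable, with less sway", {
  nw <- default_profile("no_wall")
  w <- default_profile("wall")
  expect_lt(w$stride_length_mean, nw$stride_length_mean)
  expect_gt(w$stride_time_mean, nw$stride_time_mean)
  expect_lt(w$com_sway_amp, nw$com_sway_amp)
  expect_gt(w$stride_length_sd / w$stride_length_mean,
            nw$stride_length_sd / nw$stride_length_mean)
  expect_gt(w$stride_time_sd / w$stride_time_mean,
            nw$stride_time_sd / nw$stride_time_mean)
})

test_that("the same seed reproduces a bit-identical session", {
  mz <- test_mazes(1)[[1]]
  prof <- default_profile("no_wall", seed = 6)
  a <- simulate_walk(mz, prof)
  b <- simulate_walk(mz, prof)
  for (id in c("left_ankle", "right_ankle", "navel")) {
    expect_identical(as.data.frame(a$session$streams[[id]]),
                     as.data.frame(b$session$streams[[id]]))
  }
  expect_identical(a$truth$events, b$truth$events)
})

test_that("emitted streams run at the 90 Hz protocol rate", {
  mz <- test_mazes(1)[[1]]
  sw <- simulate_walk(mz, default_profile("no_wall"))
  for (id in c("left_ankle", "right_ankle", "navel")) {
    st <- sw$session$streams[[id]]
    expect_equal(stream_rate(st), 90)
    expect_equal(median(diff(st$t)), 1 / 90, tolerance = 1e-9)
  }
})

test_that("over-long strides against the block size are rejected", {
  mz <- test_mazes(1)[[1]]
  prof <- default_profile("no_wall")
  prof$stride_length_mean <- 2 * mz$block_size + 0.1
  expect_error(simulate_walk(mz, prof), "block size")
})

test_that("ground truth is internally consistent", {
  mz <- test_mazes(1)[[1]]
  sw <- simulate_walk(mz, default_profile("no_wall", seed = 3))
  tr <- sw$truth
  expect_equal(tr$strides$velocity, tr$strides$length / tr$strides$time)
  for (sd in c("left", "right")) {
    ev <- tr$events[tr$events$side == sd, ]
    ev <- ev[order(ev$t), ]
    expect_true(all(rle(ev$kind)$lengths == 1))       # HS/TO alternate
    n_hs <- sum(ev$kind == "heel_strike")
    expect_equal(n_hs, sum(tr$strides$side == sd) + 1)
  }
})

test_that("dropouts appear at the configured rate and create gaps", {
  mz <- test_mazes(1)[[1]]
  prof <- default_profile("no_wall", seed = 9)
  prof$dropout_rate <- 8   # per minute; expect a few in a ~20 s walk
  sw <- simulate_walk(mz, prof)
  n_gaps <- sum(vapply(sw$session$streams,
                       function(s) nrow(stream_gaps(s)), numeric(1)))
  expect_gt(n_gaps, 0)
  a <- analyze_session(sw$session, maze = mz)
  # strides across gaps are excluded rather than mis-measured
  expect_true(all(a$summary$n_excluded >= 0))
})

test_that("event-detection F1 degrades monotonically with orientation noise", {
  mz <- test_mazes(1)[[1]]
  grid <- c(0, 5, 15, 30)
  f1 <- vapply(grid, function(na) {
    mean(vapply(1:3, function(s) {
      prof <- default_profile("no_wall", seed = s)
      prof$noise_sd_angle <- na
      sw <- simulate_walk(mz, prof)
      event_detection_f1(detect_session_events(sw$session),
                         sw$truth$events)$f1
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(f1) <= 0.01))
  expect_equal(f1[1], 1.0)
})

test_that("cohorts reproduce the reference score distributions", {
  co <- generate_cohort(10000, seed = 5)
  expect_equal(mean(co$tmt_a), 37.7, tolerance = 0.02)
  expect_equal(sd(co$tmt_a), 13.4, tolerance = 0.05)
  expect_equal(mean(co$dlm), 23.7, tolerance = 0.02)
  tests <- cognitive_tests()
  for (k in seq_len(nrow(tests))) {
    v <- co[[tests$test[k]]]
    expect_true(all(v >= tests$lower[k] & v <= tests$upper[k]))
  }
  expect_identical(generate_cohort(50, seed = 2), generate_cohort(50, seed = 2))
  expect_error(
    generate_cohort(10, planted_effects = data.frame(
      outcome = "stride_velocity", test = "nope", slope = 1)),
    "unknown test"
  )
})

test_that("a small simulated study has the full session bookkeeping", {
  st <- simulate_study(3, seed = 8, kinematics = TRUE)
  expect_equal(nrow(st$outcomes), 12)
  expect_equal(length(st$sessions), 12)
  meta <- do.call(rbind, lapply(st$sessions, function(s) s$meta))
  expect_equal(nrow(unique(meta)), 12)
  expect_setequal(unique(meta$condition), c("no_wall", "wall"))
  expect_setequal(unique(meta$visit), c("immediate", "delayed"))
  # same maze within a condition across visits, different across conditions
  mazes <- vapply(st$sessions, function(s) s$maze$maze_id, character(1))
  for (sub in unique(meta$subject_id)) {
    for (cond in c("no_wall", "wall")) {
      sel <- meta$subject_id == sub & meta$condition == cond
      expect_equal(length(unique(mazes[sel])), 1)
    }
    sel_nw <- meta$subject_id == sub & meta$condition == "no_wall"
    sel_w <- meta$subject_id == sub & meta$condition == "wall"
    expect_false(mazes[which(sel_nw)[1]] == mazes[which(sel_w)[1]])
  }
})

test_that("the delayed visit carries the learning effect", {
  st <- simulate_study(60, seed = 13)
  agg <- tapply(st$outcomes$stride_length_mean, st$outcomes$visit, mean)
  expect_gt(agg[["delayed"]], agg[["immediate"]])
  aggv <- tapply(st$outcomes$stride_velocity_mean, st$outcomes$visit, mean)
  expect_gt(aggv[["delayed"]], aggv[["immediate"]])
})

test_that("planted cognitive effects propagate into cohort outcomes", {
  eff <- data.frame(outcome = "stride_velocity", test = "dlm", slope = -0.01)
  co <- generate_cohort(4000, seed = 21, planted_effects = eff)
  sl <- coef(lm(stride_velocity ~ dlm, data = co))["dlm"]
  expect_equal(as.numeric(sl), -0.01, tolerance = 0.25)
})
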