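test_that("foot heading reproduces hand projections", {
  # identity: local x along global X
  st <- make_regular_stream("left_ankle", 5)
  expect_equal(foot_heading(st, 0), 0, tolerance = 1e-9)

  # 90 deg about Z: local x along global Y
  q <- quat_about(pi / 2, c(0, 0, 1))
  st2 <- tracker_stream(
    data.frame(t = 0:4 / 90, px = 0, py = 0, pz = 0.1,
               qw = q[1], qx = q[2], qy = q[3], qz = q[4]),
    "left_ankle"
  )
  expect_equal(foot_heading(st2, 0), 90, tolerance = 1e-9)

  # vertical x-axis: heading undefined
  qv <- quat_about(-pi / 2, c(0, 1, 0))
  stv <- tracker_stream(
    data.frame(t = 0:4 / 90, px = 0, py = 0, pz = 0.1,
               qw = qv[1], qx = qv[2], qy = qv[3], qz = qv[4]),
    "left_ankle"
  )
  expect_true(is.na(foot_heading(stv, 0)))
})

test_that("rotating the pose about Z adds to the heading", {
  set.seed(21)
  for (k in 1:20) {
    base <- runif(1, -pi, pi)
    qb <- quat_about(base, c(0, 0, 1))
    qr <- quat_about(base + pi / 6, c(0, 0, 1))
    mk <- function(q) tracker_stream(
      data.frame(t = 0:2 / 90, px = 0, py = 0, pz = 0,
                 qw = q[1], qx = q[2], qy = q[3], qz = q[4]),
      "left_ankle"
    )
    h0 <- foot_heading(mk(qb), 0)
    h1 <- foot_heading(mk(qr), 0)
    d <- (h1 - h0) %% 360
    expect_equal(min(d, 360 - d), 30, tolerance = 1e-6)
  }
})

test_that("step classification uses a strict threshold on wrapped deviations", {
  expect_equal(classify_step(0, 0, 25), "straight")
  expect_equal(classify_step(0, 90, 25), "turn")
  expect_equal(classify_step(0, 25, 25), "turn")     # equality is not below
  expect_equal(classify_step(0, 24.999, 25), "straight")
  expect_equal(classify_step(170, -170, 25), "straight")  # wraps to 20
  expect_equal(classify_step(170, -160, 25), "turn")      # wraps to 30
})

hand_stride_fixture <- function() {
  # left HS at (0,0) t=0, left TO t=0.62, left HS at (1.2,0) t=1.0,
  # right HS at (0.6,0.12) t=0.5
  rate <- 90
  t <- seq(0, 1.2, by = 1 / rate)
  nearest <- function(tt) which.min(abs(t - tt))
  lx <- approx(c(0, 0.62, 1.0, 1.2), c(0, 0, 1.2, 1.2), t, rule = 2)$y
  left <- tracker_stream(
    data.frame(t = t, px = lx, py = 0, pz = 0.1,
               qw = 1, qx = 0, qy = 0, qz = 0),
    "left_ankle"
  )
  right <- tracker_stream(
    data.frame(t = t, px = 0.6, py = 0.12, pz = 0.1,
               qw = 1, qx = 0, qy = 0, qz = 0),
    "right_ankle"
  )
  events <- tibble::tibble(
    side = c("left", "right", "left", "left"),
    kind = c("heel_strike", "heel_strike", "toe_off", "heel_strike"),
    t = c(0, 0.5, 0.62, 1.0),
    sample_index = c(nearest(0), nearest(0.5), nearest(0.62), nearest(1.0))
  )
  list(events = events, streams = list(left_ankle = left, right_ankle = right))
}

test_that("stride parameters follow their definitions on a hand example", {
  fx <- hand_stride_fixture()
  st <- assemble_strides(fx$events, fx$streams)
  expect_equal(nrow(st), 1)
  expect_equal(st$length, 1.2, tolerance = 1e-6)
  expect_equal(st$time, 1.0, tolerance = 1e-9)
  expect_equal(st$velocity, st$length / st$time)   # exact identity
  expect_equal(st$stance_pct, 62, tolerance = 1e-9)
  expect_equal(st$width, 0.12, tolerance = 1e-6)
  expect_equal(st$classification, "straight")
})

test_that("strides overlapping a dropout gap are excluded", {
  fx <- hand_stride_fixture()
  attr(fx$streams$left_ankle, "gaps") <-
    tibble::tibble(t_start = 0.3, t_end = 0.4)
  st <- assemble_strides(fx$events, fx$streams)
  expect_equal(st$classification, "excluded")
})

test_that("zero-noise walks classify corner strides as turns, segment strides as straight", {
  for (mz in test_mazes(2)) {
    sw <- simulate_walk(mz, zero_noise_profile())
    a <- analyze_session(sw$session, maze = mz)
    tt <- sw$truth$strides
    mm <- a$strides
    j <- vapply(mm$t_initial,
                function(x) which.min(abs(tt$t_initial - x)), integer(1))
    expect_equal(mm$classification, tt$classification[j])
    # truth straight strides never span corners here
    expect_false(any(tt$crosses_corner[tt$classification == "straight"]))
  }
})

test_that("threshold calibration clamps to 20 on clean straight walking", {
  mz <- corridor_maze(12)
  sw <- simulate_walk(mz, zero_noise_profile())
  # straight-line deviations are ~0, so max + 5 degree margin clamps to 20
  expect_equal(calibrate_threshold(sw$session, mz), 20)
})

test_that("threshold calibration falls back to 25 with too few strides", {
  mz <- test_mazes(1)[[1]]
  sw <- simulate_walk(mz, zero_noise_profile())
  expect_warning(th <- calibrate_threshold(sw$session, mz, min_strides = 1000),
                 "25")
  expect_equal(th, 25)
})

test_that("coefficient of variation follows the sample-SD convention", {
  expect_equal(cov_of(c(1, 1, 1)), 0)
  expect_equal(cov_of(c(1, 2, 3)), 0.5)   # sample SD 1, mean 2
  x <- rlnorm(50)
  expect_equal(cov_of(2 * x), cov_of(x), tolerance = 1e-12)
  expect_true(is.na(cov_of(c(1))))
})

test_that("session summaries cover straight strides only", {
  strides <- tibble::tibble(
    side = "left", t_initial = 1:4, t_toe_off = 1:4 + 0.6,
    t_terminal = 2:5,
    x_initial = 0, y_initial = 0, x_terminal = 1, y_terminal = 0,
    length = c(1, 2, 3, 10), width = 0.1, time = 1,
    velocity = c(1, 2, 3, 10), stance_pct = 60,
    heading_initial = 0, heading_terminal = c(0, 0, 0, 90),
    classification = c("straight", "straight", "straight", "turn")
  )
  s <- summarize_session(strides, completion_time = 30)
  expect_equal(s$length_mean, 2)
  expect_equal(s$length_cov, 0.5)
  expect_equal(s$n_straight, 3)
  expect_equal(s$n_turn, 1)
  expect_equal(s$completion_time, 30)
  expect_false(s$insufficient)

  s2 <- summarize_session(strides[strides$classification == "turn", ])
  expect_true(s2$insufficient)
  expect_true(is.na(s2$length_cov))
})
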