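test_that("extrapolated CoM follows the pendulum formula", {
  p <- pendulum_params(0.98, g = 9.8)
  # zero velocity: XCoM equals the CoM at machine precision
  expect_identical(xcom(c(0.3, -0.1), c(0, 0), p), c(0.3, -0.1))
  # hand-evaluated case: omega0 = sqrt(10), offset = 3.1623/sqrt(10) = 1
  expect_equal(xcom(c(0, 0), c(3.1623, 0), p), c(1.0000, 0),
               tolerance = 1e-4)
  # linearity: doubling the velocity doubles the offset
  x1 <- xcom(c(0.2, 0.1), c(0.5, -0.2), p) - c(0.2, 0.1)
  x2 <- xcom(c(0.2, 0.1), c(1.0, -0.4), p) - c(0.2, 0.1)
  expect_equal(x2, 2 * x1, tolerance = 1e-12)
  expect_error(pendulum_params(-1), "positive")
})

test_that("the offset identity XCoM - u = u_dot * sqrt(l/g) holds", {
  set.seed(33)
  for (k in 1:1000) {
    l <- runif(1, 0.5, 1.3)
    u <- rnorm(2)
    ud <- rnorm(2)
    p <- pendulum_params(l)
    expect_equal(xcom(u, ud, p) - u, ud * sqrt(l / 9.8), tolerance = 1e-9)
  }
})

test_that("CoM velocity estimation matches analytic derivatives", {
  rate <- 90
  t <- seq(0, 3, by = 1 / rate)
  lin <- tracker_stream(
    data.frame(t = t, px = 1.3 * t, py = 0, pz = 1,
               qw = 1, qx = 0, qy = 0, qz = 0), "navel"
  )
  v <- estimate_com_velocity(lin)
  expect_equal(v$vx, rep(1.3, length(t)), tolerance = 1e-6)
  expect_equal(v$vy, rep(0, length(t)), tolerance = 1e-6)

  stat <- tracker_stream(
    data.frame(t = t, px = 0.5, py = -0.2, pz = 1,
               qw = 1, qx = 0, qy = 0, qz = 0), "navel"
  )
  vs <- estimate_com_velocity(stat)
  expect_equal(max(abs(c(vs$vx, vs$vy))), 0, tolerance = 1e-9)

  A <- 0.07
  sine <- tracker_stream(
    data.frame(t = t, px = A * sin(2 * pi * t), py = 0, pz = 1,
               qw = 1, qx = 0, qy = 0, qz = 0), "navel"
  )
  vv <- estimate_com_velocity(sine)
  mid <- t > 0.5 & t < 2.5
  expect_equal(max(abs(vv$vx[mid])), 2 * pi * A, tolerance = 0.02)
})

test_that("leg length is the median vertical tracker separation", {
  rate <- 90
  t <- seq(0, 2, by = 1 / rate)
  mk <- function(z, id) tracker_stream(
    data.frame(t = t, px = 0, py = 0, pz = z,
               qw = 1, qx = 0, qy = 0, qz = 0), id
  )
  expect_equal(leg_length(mk(0.1, "left_ankle"), mk(1.0, "navel")), 0.9)
  expect_error(leg_length(mk(1.2, "left_ankle"), mk(1.0, "navel")), "leg length")

  # swing excursions barely move the median
  zr <- 0.1 + 0.08 * pmax(0, sin(2 * pi * t))^2 * (sin(8 * t) > 0)
  swingy <- tracker_stream(
    data.frame(t = t, px = 0, py = 0, pz = zr,
               qw = 1, qx = 0, qy = 0, qz = 0), "left_ankle"
  )
  expect_equal(leg_length(swingy, mk(1.0, "navel")), 0.9, tolerance = 0.02)
})

test_that("leg length from a simulated walk is near the quiet-stance value", {
  mz <- test_mazes(1)[[1]]
  sw <- simulate_walk(mz, zero_noise_profile())
  l <- leg_length(sw$session$streams$left_ankle, sw$session$streams$navel)
  expect_equal(l, 0.95, tolerance = 0.02)
})

test_that("base of support covers both footprints", {
  bos <- base_of_support(c(0, 0.1), c(0, -0.1), 0, 0)
  expect_equal(bos$half_extents, c(0.125, 0.15), tolerance = 1e-9)
  expect_equal(abs(bos$ap_axis), c(1, 0), tolerance = 1e-9)

  # degenerate: coincident feet collapse to a single footprint
  bos1 <- base_of_support(c(0.3, 0.2), c(0.3, 0.2), 45, 45)
  expect_equal(bos1$half_extents, c(0.125, 0.05), tolerance = 1e-9)

  # containment on random configurations, against corner enumeration
  set.seed(7)
  for (k in 1:1000) {
    lp <- rnorm(2); rp <- lp + rnorm(2, sd = 0.15)
    lh <- runif(1, -180, 180); rh <- runif(1, -180, 180)
    bos <- base_of_support(lp, rp, lh, rh)
    corners <- rbind(
      vrgait:::footprint_corners(lp, lh, 0.25, 0.10),
      vrgait:::footprint_corners(rp, rh, 0.25, 0.10)
    )
    rel <- sweep(corners, 2, bos$center)
    a <- rel %*% bos$ap_axis
    m <- rel %*% bos$ml_axis
    expect_true(all(abs(a) <= bos$half_extents[1] + 1e-9))
    expect_true(all(abs(m) <= bos$half_extents[2] + 1e-9))
  }
})

test_that("signed mediolateral margin matches the border-sampling oracle", {
  bos <- base_of_support(c(0, 0.1), c(0, -0.1), 0, 0)
  # on the lateral border: zero margin
  expect_equal(mos_ml(c(0, 0.15), bos), 0, tolerance = 1e-12)
  # 0.05 inside the nearer border
  expect_equal(mos_ml(c(0, 0.10), bos), 0.05, tolerance = 1e-9)
  # 0.03 outside
  expect_equal(mos_ml(c(0, 0.18), bos), -0.03, tolerance = 1e-9)

  set.seed(8)
  for (k in 1:1000) {
    lp <- rnorm(2); rp <- lp + rnorm(2, sd = 0.2)
    lh <- runif(1, -180, 180); rh <- runif(1, -180, 180)
    bos <- base_of_support(lp, rp, lh, rh)
    xc <- bos$center + rnorm(2, sd = 0.25)
    expect_equal(mos_ml(xc, bos), oracle_mos_ml(xc, bos), tolerance = 1e-6)
  }
})

test_that("direction of progression normalises and flags degenerate cycles", {
  expect_equal(direction_of_progression(c(0, 0), c(1, 0)), c(1, 0))
  expect_equal(direction_of_progression(c(0, 0), c(1, 1)),
               c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)
  expect_warning(d <- direction_of_progression(c(0, 0), c(1e-9, 0)), "flagged")
  expect_true(all(is.na(d)))
})

test_that("mediolateral CoM displacement is a max perpendicular deviation", {
  t <- seq(0, 1, by = 1 / 90)
  # collinear trajectory: zero deviation
  traj <- cbind(t, 0.5 * t)
  dop <- direction_of_progression(traj[1, ], traj[nrow(traj), ])
  expect_equal(com_ml_displacement(traj, dop), 0, tolerance = 1e-12)

  # half-sine lateral bow of amplitude 0.04
  bow <- cbind(t, 0.04 * sin(pi * t))
  expect_equal(com_ml_displacement(bow, c(1, 0)), 0.04, tolerance = 1e-4)

  # invariance under joint rotation + translation
  R <- rot2(0.83)
  bow_r <- sweep(bow %*% t(R), 2, c(3, -2), `+`)
  expect_equal(com_ml_displacement(bow_r, as.numeric(R %*% c(1, 0))),
               com_ml_displacement(bow, c(1, 0)), tolerance = 1e-12)
})

test_that("margin of stability is invariant under rigid motions", {
  set.seed(12)
  for (k in 1:50) {
    lp <- rnorm(2); rp <- lp + rnorm(2, sd = 0.2)
    lh <- runif(1, -180, 180); rh <- runif(1, -180, 180)
    bos <- base_of_support(lp, rp, lh, rh)
    xc <- bos$center + rnorm(2, sd = 0.2)
    m0 <- mos_ml(xc, bos)
    th <- runif(1, -pi, pi); sh <- rnorm(2)
    R <- rot2(th)
    bos2 <- base_of_support(as.numeric(R %*% lp + sh), as.numeric(R %*% rp + sh),
                            lh + th * 180 / pi, rh + th * 180 / pi)
    m1 <- mos_ml(as.numeric(R %*% xc + sh), bos2)
    expect_equal(m1, m0, tolerance = 1e-9)
  }
})

test_that("balance summaries recover the planted sway amplitude", {
  mz <- test_mazes(1)[[1]]
  sw <- simulate_walk(mz, zero_noise_profile())
  a <- analyze_session(sw$session, maze = mz)
  bal <- summarize_balance(a$cycles)
  expect_equal(bal$com_ml_mean, 0.04, tolerance = 0.05)
  expect_false(bal$insufficient)

  # identical cycles have zero CoV
  cyc <- tibble::tibble(side = "left", t_hs = 1:3,
                        classification = "straight",
                        mos_ml = 0.05, com_ml = 0.04)
  expect_equal(summarize_balance(cyc)$com_ml_cov, 0)
})

test_that("wall walks sway less than no-wall walks", {
  mz <- test_mazes(1)[[1]]
  coms <- sapply(1:5, function(s) {
    nw <- simulate_walk(mz, default_profile("no_wall", seed = s))
    w <- simulate_walk(mz, default_profile("wall", seed = s))
    anw <- analyze_session(nw$session, maze = mz)
    aw <- analyze_session(w$session, maze = mz)
    c(summarize_balance(anw$cycles)$com_ml_mean,
      summarize_balance(aw$cycles)$com_ml_mean)
  })
  expect_lt(mean(coms[2, ]), mean(coms[1, ]))
})
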