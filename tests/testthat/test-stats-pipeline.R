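test_that("normality screen passes normal data at the nominal rate", {
  pass <- vapply(1:200, function(s) {
    set.seed(s)
    screen_and_transform(rnorm(500, 10, 2))$transform == "none"
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_gte(mean(pass), 0.95 - 3 * se)
  expect_lte(mean(pass), 1.0)
})

test_that("lognormal data are log-transformed and recoverable", {
  ok <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    v <- rlnorm(500, 1, 0.8)
    sc <- screen_and_transform(v)
    sc$transform == "log" &&
      isTRUE(all.equal(exp(sc$values), v)) &&
      stats::shapiro.test(sc$values)$p.value >= 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("non-positive non-normal data are refused, not shifted", {
  set.seed(2)
  v <- c(-1, rlnorm(200, 0, 1))
  expect_warning(sc <- screen_and_transform(v), "non-positive")
  expect_equal(sc$transform, "untransformable")
  expect_identical(sc$values, v)
  expect_error(screen_and_transform(c(1, 2)), "3")
})

test_that("adjusted regression equals the normal-equations OLS solution", {
  co <- generate_cohort(200, seed = 3)
  r <- adjusted_regression(co, "stride_velocity", "tmt_a", transform = FALSE)
  X <- cbind(1, co$tmt_a, co$age, as.numeric(factor(co$sex)) - 1,
             co$education, co$height, co$weight)
  beta <- solve(t(X) %*% X, t(X) %*% co$stride_velocity)
  expect_equal(tidy(r)$estimate, beta[2], tolerance = 1e-8)
  expect_equal(tidy(r)$n, 200)
  expect_error(adjusted_regression(co[1:10, ], "stride_velocity", "tmt_a"),
               "complete cases")
})

test_that("planted slopes are recovered within their confidence intervals", {
  eff <- data.frame(outcome = "stride_velocity", test = "tmt_a",
                    slope = -0.003)
  cover <- vapply(1:20, function(s) {
    co <- generate_cohort(500, seed = 300 + s, planted_effects = eff)
    r <- tidy(adjusted_regression(co, "stride_velocity", "tmt_a",
                                  transform = FALSE))
    abs(r$estimate - (-0.003)) <= qt(0.975, 500 - 7) * r$std_error
  }, logical(1))
  expect_gte(mean(cover), 0.85)   # 95% nominal coverage, 20 replicates
})

test_that("the regression holds its type-I error under the null", {
  rej <- vapply(1:300, function(s) {
    co <- generate_cohort(100, seed = 5000 + s)
    tidy(adjusted_regression(co, "stride_velocity", "dlm"))$p_value < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 300)
  expect_gte(mean(rej), 0.05 - 3 * se)
  expect_lte(mean(rej), 0.05 + 3 * se)
})

test_that("effects transmitted through age vanish after adjustment", {
  ok <- vapply(1:60, function(s) {
    co <- generate_cohort(
      300, seed = 7000 + s,
      age_effects = c(stride_velocity = -0.01),
      score_age_slopes = c(tmt_a = 0.8)
    )
    r <- tidy(adjusted_regression(co, "stride_velocity", "tmt_a",
                                  transform = FALSE))
    abs(r$estimate) < 2 * r$std_error
  }, logical(1))
  expect_gte(mean(ok), 0.85)
})

test_that("mixed model matches two-way OLS on balanced data without subject variance", {
  set.seed(41)
  grid <- expand.grid(subject_id = sprintf("S%02d", 1:24),
                      condition = c("no_wall", "wall"),
                      visit = c("immediate", "delayed"),
                      stringsAsFactors = FALSE)
  grid$y <- 1 + 0.5 * (grid$condition == "wall") -
    0.2 * (grid$visit == "delayed") + rnorm(nrow(grid), 0, 0.3)
  mm <- suppressMessages(condition_visit_mixed_model(grid, "y"))
  ols <- lm(y ~ factor(condition, c("no_wall", "wall")) *
              factor(visit, c("immediate", "delayed")), data = grid)
  expect_equal(mm$fixed$estimate[mm$fixed$term == "condition"],
               unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(mm$fixed$estimate[mm$fixed$term == "visit"],
               unname(coef(ols)[3]), tolerance = 1e-6)
  expect_error(condition_visit_mixed_model(grid[1:8, ], "y"), "10 subjects")
})

test_that("the planted MoS interaction pattern is detected with Bonferroni follow-up", {
  st <- simulate_study(40, seed = 17)
  mm <- condition_visit_mixed_model(st$outcomes, "mos_ml_mean")
  expect_lt(mm$interaction_p, 0.05)
  pw <- mm$pairwise
  expect_equal(nrow(pw), 4)
  expect_equal(pw$p_adj, pmin(1, 4 * pw$p_raw))   # exact Bonferroni
  nw <- pw[pw$contrast == "delayed - immediate | no_wall", ]
  wl <- pw[pw$contrast == "delayed - immediate | wall", ]
  expect_lt(nw$p_adj, 0.05)
  expect_lt(nw$estimate, 0)          # decrease from immediate to delayed
  expect_gt(wl$p_adj, 0.05)          # no change in the wall condition
  # broom-style accessors
  expect_equal(nrow(tidy(mm)), 3)
  expect_true(is.finite(glance(mm)$ranef_var))
})

test_that("condition main effects on gait are detected in a single study", {
  st <- simulate_study(40, seed = 19)
  mm <- condition_visit_mixed_model(st$outcomes, "stride_length_mean")
  expect_lt(mm$fixed$p_value[mm$fixed$term == "condition"], 0.05)
  expect_lt(mm$fixed$estimate[mm$fixed$term == "condition"], 0)
  mv <- condition_visit_mixed_model(st$outcomes, "stride_velocity_mean")
  expect_lt(mv$fixed$p_value[mv$fixed$term == "visit"], 0.05)
  expect_gt(mv$fixed$estimate[mv$fixed$term == "visit"], 0)
})

test_that("association tables have the report shape and flag planted cells", {
  eff <- data.frame(outcome = "stride_velocity", test = "dlm", slope = -0.012)
  st <- simulate_study(120, seed = 23, planted_effects = eff)
  tbl <- build_association_table(
    st$cohort, st$outcomes,
    outcome_cols = c("stride_velocity_mean", "stride_length_mean"),
    tests = c("tmt_a", "dlm", "pm")
  )
  expect_equal(nrow(tbl), 4 * 2 * 3)   # strata x outcomes x tests
  expect_setequal(
    names(tbl),
    c("condition", "visit", "outcome", "test", "estimate", "std_error",
      "p_value", "n", "transform", "significant")
  )
  planted <- tbl[tbl$outcome == "stride_velocity_mean" & tbl$test == "dlm", ]
  expect_true(all(planted$significant))
})
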