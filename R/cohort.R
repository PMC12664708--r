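#' Synthetic cohorts with cognitive scores and planted gait effects
#'
#' Cohorts are drawn to match the demographic and neuropsychological
#' profile of a community sample of older adults without dementia:
#' age 67.8 +/- 6.3 years, height 167.7 +/- 8.6 cm, weight 77.4 +/- 17.7
#' kg, education 16.9 +/- 3.2 years, and eleven cognitive test scores
#' (means, SDs and instrument ranges in [cognitive_tests()]). Scores are
#' drawn from truncated normals respecting each instrument's bounds.
#'
#' @name cohort
NULL

#' Reference distribution of the eleven cognitive tests
#'
#' @return tibble with columns `test` (short code), `domain`, `mean`,
#'   `sd`, `lower`, `upper`.
#' @export
cognitive_tests <- function() {
  tibble::tribble(
    ~test,    ~domain,                 ~mean, ~sd,  ~lower, ~upper,
    "tmt_a",  "attention",             37.7,  13.4, 0,      Inf,
    "tmt_b",  "executive_function",    83.9,  41.2, 0,      Inf,
    "dsst",   "executive_function",    49.7,  13.5, 0,      93,
    "dc",     "executive_function",    59.7,  12.1, 0,      192,
    "co",     "verbal",                41.6,  12.1, 0,      Inf,
    "wrat4",  "verbal",                49.4,  6.4,  0,      70,
    "ilm",    "auditory_memory",       29.0,  7.0,  0,      50,
    "dlm",    "auditory_memory",       23.7,  7.3,  0,      50,
    "id",     "visual_memory",         61.6,  10.4, 0,      120,
    "dd",     "visual_memory",         50.8,  9.4,  0,      120,
    "pm",     "visuospatial",          15.5,  1.5,  0,      17
  )
}

COHORT_OUTCOMES <- c("stride_length", "stride_time", "stride_velocity",
                     "stride_width", "stance_pct", "com_ml")

#' Generate a synthetic cohort
#'
#' Draws `n` subjects with covariates (age, sex, education, height,
#' weight) and the eleven cognitive scores, plus subject-level gait
#' outcome values built from latent stride length and stride time.
#' Planted effects enter the outcome-generating process linearly in the
#' centred scores, so a downstream covariate-adjusted regression should
#' recover the planted slope.
#'
#' @param n number of subjects.
#' @param seed RNG seed.
#' @param planted_effects `NULL`, or a data frame with columns
#'   `outcome` (one of `r paste(COHORT_OUTCOMES, collapse=", ")`),
#'   `test` (a [cognitive_tests()] code) and `slope` (outcome units per
#'   score unit).
#' @param age_effects optional named numeric: slope of an outcome per
#'   year of (centred) age, e.g. `c(stride_velocity = -0.004)`.
#' @param score_age_slopes optional named numeric: slope of a score per
#'   year of (centred) age, to build confounded scores.
#' @param noise_sd named overrides for the residual SD of latent stride
#'   length (`length`), stride time (`time`), width, stance and sway.
#' @return tibble, one row per subject: `subject_id`, covariates, the
#'   eleven score columns, and the outcome columns.
#' @export
generate_cohort <- function(n, seed = 1, planted_effects = NULL,
                            age_effects = NULL, score_age_slopes = NULL,
                            noise_sd = NULL) {
  stopifnot(n >= 1)
  tests <- cognitive_tests()
  check_effects(planted_effects, tests$test)
  nsd <- list(length = 0.06, time = 0.07, width = 0.015,
              stance = 1.5, sway = 0.006)
  nsd[names(noise_sd)] <- noise_sd

  with_preserved_seed(seed, {
    cohort <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = rnorm_trunc(n, 67.8, 6.3, 60, 95),
      sex = ifelse(stats::runif(n) < 16 / 65, "M", "F"),
      education = rnorm_trunc(n, 16.9, 3.2, 6, 26),
      height = rnorm_trunc(n, 167.7, 8.6, 140, 200),
      weight = rnorm_trunc(n, 77.4, 17.7, 40, 160)
    )
    for (k in seq_len(nrow(tests))) {
      v <- rnorm_trunc(n, tests$mean[k], tests$sd[k],
                       tests$lower[k], tests$upper[k])
      if (!is.null(score_age_slopes) && tests$test[k] %in% names(score_age_slopes)) {
        v <- v + score_age_slopes[[tests$test[k]]] * (cohort$age - 67.8)
      }
      cohort[[tests$test[k]]] <- v
    }

    # latent gait outcomes around the no-wall defaults
    base <- default_profile("no_wall")
    eff <- function(outcome) {
      out <- rep(0, n)
      if (!is.null(planted_effects)) {
        pe <- planted_effects[planted_effects$outcome == outcome, ]
        for (k in seq_len(nrow(pe))) {
          mu <- tests$mean[tests$test == pe$test[k]]
          out <- out + pe$slope[k] * (cohort[[pe$test[k]]] - mu)
        }
      }
      if (!is.null(age_effects) && outcome %in% names(age_effects)) {
        out <- out + age_effects[[outcome]] * (cohort$age - 67.8)
      }
      out
    }
    len <- base$stride_length_mean + stats::rnorm(n, 0, nsd$length) +
      eff("stride_length")
    tm <- rnorm_trunc(n, base$stride_time_mean, nsd$time, lo = 0.5) +
      eff("stride_time")
    # velocity gets its own gaussian residual about the profile-implied
    # mean, so regression errors are homoscedastic and normal
    vel <- base$stride_length_mean / base$stride_time_mean +
      stats::rnorm(n, 0, 0.08) + eff("stride_velocity")
    cohort$stride_length <- len
    cohort$stride_time <- tm
    cohort$stride_velocity <- vel
    cohort$stride_width <- base$stride_width_mean +
      stats::rnorm(n, 0, nsd$width) + eff("stride_width")
    cohort$stance_pct <- 100 * base$stance_fraction +
      stats::rnorm(n, 0, nsd$stance) + eff("stance_pct")
    cohort$com_ml <- rnorm_trunc(n, base$com_sway_amp, nsd$sway, lo = 0.002) +
      eff("com_ml")
    cohort
  })
}

check_effects <- function(planted_effects, test_names) {
  if (is.null(planted_effects)) return(invisible(NULL))
  stopifnot(all(c("outcome", "test", "slope") %in% names(planted_effects)))
  bad_t <- setdiff(planted_effects$test, test_names)
  if (length(bad_t) > 0) stop("unknown test name(s): ", paste(bad_t, collapse = ", "))
  bad_o <- setdiff(planted_effects$outcome, COHORT_OUTCOMES)
  if (length(bad_o) > 0) stop("unknown outcome(s): ", paste(bad_o, collapse = ", "))
  invisible(NULL)
}

#' Simulate a full two-condition, two-visit study
#'
#' Per subject: two conditions (no_wall, wall) times two visits
#' (immediate, delayed), with the same maze reused across visits within
#' a condition and a different maze across conditions. The delayed visit
#' carries a learning effect (longer, faster strides); the wall
#' condition uses the wall gait profile (smaller, slower, more variable
#' strides, less sway). Session-level outcomes include a subject random
#' intercept per outcome, so the long table is suitable for linear
#' mixed modelling.
#'
#' By default the generator plants an interaction on the mediolateral
#' margin of stability: it decreases from the immediate to the delayed
#' visit in the no-wall condition only (`mos_interaction = TRUE`).
#'
#' @param n number of subjects.
#' @param seed RNG seed.
#' @param planted_effects as in [generate_cohort()].
#' @param learning named list: additive delayed-visit shifts for
#'   `stride_length` (m) and `stride_time` (s).
#' @param mos_interaction plant the no-wall-only immediate-to-delayed
#'   decrease in the margin of stability (default `TRUE`).
#' @param kinematics if `TRUE`, additionally simulate full tracker
#'   streams for every session via [simulate_walk()] (slow; intended
#'   for small `n`). If `FALSE`, only the session-level outcome table is
#'   generated from the same profile-level model.
#' @return list with `cohort` (from [generate_cohort()]), `outcomes`
#'   (long tibble: subject x condition x visit rows with completion
#'   time, five gait means, five CoVs, `mos_ml_mean`, `com_ml_mean`,
#'   `com_ml_cov`), and, when `kinematics = TRUE`, `sessions`: a list
#'   of `simulate_walk()` results with `$meta`.
#' @export
simulate_study <- function(n, seed = 1, planted_effects = NULL,
                           learning = list(stride_length = 0.04,
                                           stride_time = -0.04),
                           mos_interaction = TRUE,
                           kinematics = FALSE) {
  stopifnot(n >= 1)
  cohort <- generate_cohort(n, seed = seed, planted_effects = planted_effects)
  tests <- cognitive_tests()

  grid <- tidyr::expand_grid(
    subject_id = cohort$subject_id,
    condition = c("no_wall", "wall"),
    visit = c("immediate", "delayed")
  )

  with_preserved_seed(seed + 1000003L, {
    ns <- nrow(grid)
    idx <- match(grid$subject_id, cohort$subject_id)
    wall <- grid$condition == "wall"
    delayed <- grid$visit == "delayed"

    prof_nw <- default_profile("no_wall")
    prof_w <- default_profile("wall")
    pick <- function(field) {
      ifelse(wall, prof_w[[field]], prof_nw[[field]])
    }

    # subject random intercepts per outcome family
    re <- function(sd) stats::rnorm(n, 0, sd)[idx]
    eps <- function(sd) stats::rnorm(ns, 0, sd)

    # planted cognitive effects, shared across sessions of a subject
    eff <- function(outcome) {
      out <- rep(0, ns)
      if (!is.null(planted_effects)) {
        pe <- planted_effects[planted_effects$outcome == outcome, ]
        for (k in seq_len(nrow(pe))) {
          mu <- tests$mean[tests$test == pe$test[k]]
          out <- out + pe$slope[k] * (cohort[[pe$test[k]]][idx] - mu)
        }
      }
      out
    }

    len <- pick("stride_length_mean") + delayed * learning$stride_length +
      re(0.05) + eps(0.025) + eff("stride_length")
    tm <- pick("stride_time_mean") + delayed * learning$stride_time +
      re(0.05) + eps(0.03) + eff("stride_time")
    vel <- len / tm + eff("stride_velocity")
    width <- pick("stride_width_mean") + re(0.012) + eps(0.006) +
      eff("stride_width")
    stance <- 100 * pick("stance_fraction") + re(1.2) + eps(0.6) +
      eff("stance_pct")

    lncov <- function(base_nw, base_w, delayed_shift = 0) {
      mu <- ifelse(wall, base_w, base_nw) * exp(delayed * delayed_shift)
      mu * exp(stats::rnorm(n, 0, 0.15)[idx] + stats::rnorm(ns, 0, 0.25))
    }
    length_cov <- lncov(0.050, 0.075)
    width_cov <- lncov(0.130, 0.150, delayed_shift = -0.15)
    time_cov <- lncov(0.050, 0.075)
    velocity_cov <- lncov(0.080, 0.060, delayed_shift = 0.10)
    stance_cov <- lncov(0.020, 0.030)

    com_ml <- pmax(0.002, pick("com_sway_amp") + re(0.005) + eps(0.003) +
                     eff("com_ml"))
    com_ml_cov <- lncov(0.15, 0.12)
    mos_base <- ifelse(wall, 0.048,
                       ifelse(delayed & mos_interaction, 0.040, 0.055))
    if (!mos_interaction) mos_base <- ifelse(wall, 0.048, 0.055)
    mos <- mos_base + re(0.010) + eps(0.008)

    ct_mean <- ifelse(wall,
                      ifelse(delayed, 49.7, 64.3),
                      ifelse(delayed, 26.1, 28.4))
    ct_sdlog <- ifelse(wall, 0.60, 0.35)
    ct <- exp(log(ct_mean) - ct_sdlog^2 / 2 +
                stats::rnorm(n, 0, 0.15)[idx] + stats::rnorm(ns, 0, ct_sdlog))

    outcomes <- dplyr::bind_cols(grid, tibble::tibble(
      completion_time = ct,
      stride_length_mean = len, stride_time_mean = tm,
      stride_velocity_mean = vel, stride_width_mean = width,
      stance_pct_mean = stance,
      stride_length_cov = length_cov, stride_time_cov = time_cov,
      stride_velocity_cov = velocity_cov, stride_width_cov = width_cov,
      stance_pct_cov = stance_cov,
      com_ml_mean = com_ml, com_ml_cov = com_ml_cov,
      mos_ml_mean = mos
    ))

    sessions <- NULL
    if (kinematics) {
      sessions <- vector("list", ns)
      maze_for <- function(i, cond) {
        s0 <- seed * 10000L + i * 97L + 31L * (cond == "wall")
        repeat {
          mz <- generate_maze(seed = s0)
          if (nrow(solution_path(mz)) >= 16) return(mz)
          s0 <- s0 + 10000L
        }
      }
      for (r in seq_len(ns)) {
        i <- idx[r]
        mz <- maze_for(i, grid$condition[r])
        prof <- if (wall[r]) prof_w else prof_nw
        prof$stride_length_mean <- max(0.3, min(len[r], 2 * mz$block_size))
        prof$stride_time_mean <- max(0.4, tm[r])
        prof$stride_width_mean <- max(0.02, width[r])
        prof$stance_fraction <- min(0.9, max(0.3, stance[r] / 100))
        prof$com_sway_amp <- com_ml[r]
        prof$seed <- seed * 100000L + r
        sessions[[r]] <- c(
          simulate_walk(mz, prof, condition = grid$condition[r],
                        visit = grid$visit[r],
                        subject_id = grid$subject_id[r]),
          list(meta = grid[r, ], maze = mz)
        )
      }
    }

    out <- list(cohort = cohort, outcomes = outcomes)
    if (!is.null(sessions)) out$sessions <- sessions
    out
  })
}
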