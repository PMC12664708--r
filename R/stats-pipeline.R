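#' Statistical stage: normality screening, adjusted regressions,
#' condition-by-visit mixed models
#'
#' Outcomes are screened with the Shapiro-Wilk test and log-transformed
#' (natural log) when non-normal; associations between maze outcomes and
#' cognitive scores are estimated by ordinary least squares adjusted for
#' age, sex, education, height and weight (one model per outcome-test
#' pair); condition and repetition effects are estimated by linear mixed
#' models with a condition-by-visit interaction and a subject random
#' intercept (REML, Satterthwaite denominator degrees of freedom), with
#' Bonferroni-adjusted pairwise follow-up when the interaction is
#' significant.
#'
#' @name stats-pipeline
NULL

ADJUST_COVARIATES <- c("age", "sex", "education", "height", "weight")

#' Normality screen with log transform
#'
#' Applies the Shapiro-Wilk test; when `p < alpha` and all values are
#' positive, returns natural-log values with `transform = "log"`. When
#' the data are non-normal but contain non-positive values the values
#' are returned unchanged with `transform = "untransformable"` and a
#' warning (no shift is invented).
#'
#' @param values numeric vector, `n >= 3` (NAs dropped for the test).
#' @param alpha screening level (default 0.05).
#' @return list with `values`, `transform` (`"none"`, `"log"`,
#'   `"untransformable"`) and `shapiro_p`.
#' @export
screen_and_transform <- function(values, alpha = 0.05) {
  ok <- values[!is.na(values)]
  if (length(ok) < 3) stop("need at least 3 non-missing values")
  # shapiro.test caps n at 5000; screen on a deterministic thinning
  test_vals <- if (length(ok) > 5000) ok[round(seq(1, length(ok), length.out = 5000))] else ok
  p <- stats::shapiro.test(test_vals)$p.value
  if (p >= alpha) {
    return(list(values = values, transform = "none", shapiro_p = p))
  }
  if (all(ok > 0)) {
    list(values = log(values), transform = "log", shapiro_p = p)
  } else {
    warning("non-normal outcome contains non-positive values; left untransformed")
    list(values = values, transform = "untransformable", shapiro_p = p)
  }
}

#' Covariate-adjusted regression of an outcome on one cognitive score
#'
#' Ordinary least squares of the (possibly log-transformed) outcome on
#' a single cognitive score plus age, sex, education, height and weight,
#' on complete cases.
#'
#' @param cohort data frame with the covariates, the score column and
#'   the outcome column.
#' @param outcome,test column names (strings).
#' @param transform apply [screen_and_transform()] to the outcome
#'   (default `TRUE`).
#' @param min_n minimum complete cases (default 15).
#' @param alpha screening level for the normality test.
#' @return object of class `vrgait_regression`: a one-row result tibble
#'   is available via [generics::tidy()]; the underlying `lm` fit via
#'   `$fit`.
#' @export
adjusted_regression <- function(cohort, outcome, test, transform = TRUE,
                                min_n = 15, alpha = 0.05) {
  need <- c(outcome, test, ADJUST_COVARIATES)
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  df <- cohort[need]
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < min_n) {
    stop("only ", nrow(df), " complete cases; need at least ", min_n)
  }
  tr <- "none"
  if (transform) {
    sc <- screen_and_transform(df[[outcome]], alpha = alpha)
    df[[outcome]] <- sc$values
    tr <- sc$transform
  }
  df$sex <- factor(df$sex)
  fml <- stats::reformulate(c(test, ADJUST_COVARIATES), response = outcome)
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(stats::coef(fit))) {
    stop("rank-deficient design matrix; aliased terms: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  structure(
    list(
      result = tibble::tibble(
        outcome = outcome, test = test,
        estimate = sm[test, "Estimate"],
        std_error = sm[test, "Std. Error"],
        p_value = sm[test, "Pr(>|t|)"],
        n = nrow(df), transform = tr
      ),
      fit = fit
    ),
    class = "vrgait_regression"
  )
}

#' @export
print.vrgait_regression <- function(x, ...) {
  cat("<adjusted regression>\n")
  print(x$result)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.vrgait_regression <- function(x, ...) x$result

#' @export
glance.vrgait_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    sigma = s$sigma, nobs = x$result$n, transform = x$result$transform
  )
}

#' Condition-by-visit linear mixed model
#'
#' Fits `outcome ~ condition * visit + (1 | subject_id)` by REML with
#' Satterthwaite denominator degrees of freedom for the fixed-effect
#' tests. When the interaction is significant at `alpha`, the four
#' simple-effect contrasts (visit within each condition, condition
#' within each visit) are computed with Bonferroni adjustment
#' (`p_adj = min(1, 4 p)`).
#'
#' @param long_table data frame with `subject_id`, `condition`, `visit`
#'   and the outcome column; missing rows are allowed (the random
#'   intercept accommodates unbalanced data).
#' @param outcome outcome column name (string).
#' @param alpha significance level for the interaction gate (default
#'   0.05).
#' @param transform apply [screen_and_transform()] to the outcome.
#' @return object of class `vrgait_mixed` with `fixed` (tibble of
#'   fixed-effect estimates and p-values), `ranef_var`, `pairwise`
#'   (tibble or `NULL`), `singular`, `transform` and the `lmerModLmerTest`
#'   fit in `$fit`.
#' @export
condition_visit_mixed_model <- function(long_table, outcome, alpha = 0.05,
                                        transform = FALSE) {
  need <- c("subject_id", "condition", "visit", outcome)
  miss <- setdiff(need, names(long_table))
  if (length(miss) > 0) stop("long table lacks columns: ", paste(miss, collapse = ", "))
  df <- long_table[need]
  names(df)[4] <- ".y"
  df <- df[stats::complete.cases(df), ]
  n_sub <- table(df$subject_id)
  if (sum(n_sub >= 2) < 10) {
    stop("need at least 10 subjects with at least 2 sessions each")
  }
  tr <- "none"
  if (transform) {
    sc <- screen_and_transform(df$.y, alpha = alpha)
    df$.y <- sc$values
    tr <- sc$transform
  }
  df$condition <- factor(df$condition, levels = c("no_wall", "wall"))
  df$visit <- factor(df$visit, levels = c("immediate", "delayed"))
  fit <- lmerTest::lmer(.y ~ condition * visit + (1 | subject_id),
                        data = df, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    message("random-intercept variance estimated at the zero boundary")
  }
  an <- stats::anova(fit, type = 3)
  coefs <- summary(fit)$coefficients
  fixed <- tibble::tibble(
    term = c("condition", "visit", "condition:visit"),
    estimate = unname(coefs[c("conditionwall", "visitdelayed",
                              "conditionwall:visitdelayed"), "Estimate"]),
    p_value = an[c("condition", "visit", "condition:visit"), "Pr(>F)"]
  )
  interaction_p <- fixed$p_value[fixed$term == "condition:visit"]

  pairwise <- NULL
  if (is.finite(interaction_p) && interaction_p < alpha) {
    emm_v <- emmeans::emmeans(fit, ~ visit | condition, lmer.df = "satterthwaite")
    emm_c <- emmeans::emmeans(fit, ~ condition | visit, lmer.df = "satterthwaite")
    pv <- as.data.frame(emmeans::contrast(emm_v, "revpairwise", adjust = "none"))
    pc <- as.data.frame(emmeans::contrast(emm_c, "revpairwise", adjust = "none"))
    pv$within <- as.character(pv$condition)
    pc$within <- as.character(pc$visit)
    pw <- rbind(pv[c("contrast", "within", "estimate", "p.value")],
                pc[c("contrast", "within", "estimate", "p.value")])
    pairwise <- tibble::tibble(
      contrast = paste(pw$contrast, "|", pw$within),
      estimate = pw$estimate,
      p_raw = pw$p.value,
      p_adj = pmin(1, 4 * pw$p.value)
    )
  }

  structure(
    list(
      outcome = outcome, fixed = fixed,
      ranef_var = as.numeric(lme4::VarCorr(fit)$subject_id[1, 1]),
      interaction_p = interaction_p, pairwise = pairwise,
      singular = singular, transform = tr,
      n_subjects = length(unique(df$subject_id)), n_obs = nrow(df),
      fit = fit
    ),
    class = "vrgait_mixed"
  )
}

#' @export
print.vrgait_mixed <- function(x, ...) {
  cat("<condition x visit mixed model> outcome:", x$outcome,
      "| subjects:", x$n_subjects, "| obs:", x$n_obs, "\n")
  print(x$fixed)
  if (!is.null(x$pairwise)) {
    cat("pairwise (Bonferroni x4):\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' @export
tidy.vrgait_mixed <- function(x, ...) x$fixed

#' @export
glance.vrgait_mixed <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n_subjects = x$n_subjects, n_obs = x$n_obs,
    ranef_var = x$ranef_var, singular = x$singular,
    interaction_p = x$interaction_p, transform = x$transform
  )
}

#' Association table of outcomes by cognitive tests, per stratum
#'
#' Runs [adjusted_regression()] for every (outcome, test) pair within
#' each condition-by-visit stratum of a long outcome table and returns
#' the coefficient grid with unadjusted-significance flags (the familiar
#' report shape: rows outcomes, columns tests, one block per stratum).
#'
#' @param cohort subject-level table with covariates and score columns.
#' @param outcomes long table (subject x condition x visit rows) with
#'   outcome columns.
#' @param outcome_cols outcome columns to regress (default: all outcome
#'   columns present).
#' @param tests cognitive test codes (default: all eleven).
#' @param alpha significance flag level (default 0.05, unadjusted).
#' @param min_n minimum complete cases per regression.
#' @return tibble with columns `condition`, `visit`, `outcome`, `test`,
#'   `estimate`, `p_value`, `n`, `transform`, `significant`.
#' @export
build_association_table <- function(cohort, outcomes,
                                    outcome_cols = NULL,
                                    tests = cognitive_tests()$test,
                                    alpha = 0.05, min_n = 15) {
  if (is.null(outcome_cols)) {
    outcome_cols <- setdiff(names(outcomes),
                            c("subject_id", "condition", "visit"))
  }
  strata <- unique(outcomes[c("condition", "visit")])
  res <- list()
  for (s in seq_len(nrow(strata))) {
    sub <- dplyr::inner_join(
      outcomes[outcomes$condition == strata$condition[s] &
                 outcomes$visit == strata$visit[s], ],
      cohort, by = "subject_id"
    )
    for (oc in outcome_cols) {
      for (te in tests) {
        row <- suppressWarnings(tryCatch(
          tidy(adjusted_regression(sub, oc, te, min_n = min_n)),
          error = function(e) tibble::tibble(
            outcome = oc, test = te, estimate = NA_real_,
            std_error = NA_real_, p_value = NA_real_,
            n = NA_integer_, transform = NA_character_
          )
        ))
        res[[length(res) + 1]] <- dplyr::bind_cols(
          strata[s, ], row
        )
      }
    }
  }
  out <- dplyr::bind_rows(res)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
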