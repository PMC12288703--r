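#' Descriptive mean and sample SD
#'
#' @param x Numeric vector (NAs dropped).
#' @return One-row tibble with `n`, `mean`, `sd` (n - 1 denominator; `NA`
#'   when fewer than two values).
#' @examples
#' describe(c(52, 43, 22, 23, 23, 52, 39, 47)) # mean 37.6, sd 13.1
#' @export
describe <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1) abort("Need at least one value.")
  tibble(n = length(x), mean = mean(x),
         sd = if (length(x) >= 2) sd(x) else NA_real_)
}

#' Paired pre/post effect with Cohen's dz
#'
#' Differences are oriented `pre - post`, so a positive effect means
#' improvement on symptom scales. `dz = mean(d) / sd(d)` (the standard paired
#' convention), `t = dz * sqrt(n)` with `n - 1` degrees of freedom, two-sided
#' p-value.
#'
#' @param pre,post Equal-length numeric vectors of paired scores.
#' @return One-row tibble: `n`, `mean_pre`, `mean_post`, `mean_diff`,
#'   `sd_diff`, `dz`, `statistic`, `df`, `p_value`.
#' @examples
#' paired_prepost(c(12, 17, 14, 17), c(9, 10, 11, 12))
#' @export
paired_prepost <- function(pre, post) {
  if (length(pre) != length(post)) abort("`pre` and `post` lengths differ.")
  ok <- !is.na(pre) & !is.na(post)
  pre <- pre[ok]
  post <- post[ok]
  n <- length(pre)
  if (n < 2) abort("Need at least 2 complete pairs.")
  d <- pre - post
  s <- sd(d)
  if (s == 0) {
    # exact invariance (pre == post everywhere) is a well-defined null result;
    # a constant nonzero shift has no finite dz and is signalled instead
    if (all(d == 0)) {
      return(tibble(n = n, mean_pre = mean(pre), mean_post = mean(post),
                    mean_diff = 0, sd_diff = 0, dz = 0, statistic = 0,
                    df = n - 1, p_value = 1))
    }
    abort("Zero-variance nonzero differences: dz is undefined.")
  }
  dz <- mean(d) / s
  t <- dz * sqrt(n)
  tibble(
    n = n, mean_pre = mean(pre), mean_post = mean(post),
    mean_diff = mean(d), sd_diff = s, dz = dz,
    statistic = t, df = n - 1, p_value = 2 * pt(-abs(t), n - 1)
  )
}

#' Paired pre/post effects for every scored instrument
#'
#' Convenience wrapper applying [paired_prepost()] per instrument to a scored
#' questionnaire table (participants with both occasions only).
#'
#' @param scored Tibble from [score_questionnaires()].
#' @return Tibble with one row per instrument.
#' @export
prepost_questionnaires <- function(scored) {
  stopifnot(all(c("participant_id", "instrument", "occasion", "total") %in%
                  names(scored)))
  wide <- scored %>%
    select("participant_id", "instrument", "occasion", "total") %>%
    tidyr::pivot_wider(names_from = "occasion", values_from = "total") %>%
    filter(!is.na(.data$pre), !is.na(.data$post))
  wide %>%
    group_by(.data$instrument) %>%
    summarise(res = list(paired_prepost(.data$pre, .data$post)),
              .groups = "drop") %>%
    tidyr::unnest("res")
}

fit_two_level <- function(data, predictor, levels, outcome_cols = NULL) {
  # data: participant_id, <predictor> (factor with 2 levels), stress
  data[[predictor]] <- factor(data[[predictor]], levels = levels)
  fml <- stats::as.formula(paste("stress ~", predictor, "+ (1 | participant_id)"))
  fit <- lmerTest::lmer(fml, data = data, REML = FALSE)
  co <- summary(fit)$coefficients
  row <- co[2, , drop = TRUE]
  vc <- as.data.frame(lme4::VarCorr(fit))
  between <- vc$vcov[vc$grp == "participant_id"][1]
  resid <- vc$vcov[vc$grp == "Residual"][1]
  list(fit = fit, estimate = unname(row["Estimate"]),
       std_error = unname(row["Std. Error"]), df = unname(row["df"]),
       statistic = unname(row["t value"]), p_value = unname(row["Pr(>|t|)"]),
       var_between = between, var_residual = resid)
}

new_mixed_fit <- function(fitted, dz, contrast, n_participants, n_obs) {
  structure(
    list(fit = fitted$fit, estimate = fitted$estimate,
         std_error = fitted$std_error, df = fitted$df,
         statistic = fitted$statistic, p_value = fitted$p_value,
         var_between = fitted$var_between, var_residual = fitted$var_residual,
         cohens_dz = dz, contrast = contrast,
         n_participants = n_participants, n_obs = n_obs,
         estimation = "maximum likelihood",
         df_method = "Satterthwaite"),
    class = "mixed_fit"
  )
}

#' Acute pre/post exercise effect (random-intercept model)
#'
#' Fits a two-level linear model of momentary stress on time (pre- vs
#' post-exercise) with a random intercept per participant, by maximum
#' likelihood; degrees of freedom use the Satterthwaite approximation. The
#' fixed effect is the post-minus-pre change, so a negative estimate is an
#' acute stress reduction. On balanced complete data it equals the grand mean
#' of the within-observation differences.
#'
#' Cohen's dz is computed at the participant level: each participant's mean
#' pre-minus-post difference, averaged and divided by the between-participant
#' SD of those means — a clustering-respecting paired convention.
#'
#' @param pairs Tibble with columns `participant_id`, `stress_pre`,
#'   `stress_post`; rows lacking either member are dropped.
#' @return A `mixed_fit` object; see [tidy.mixed_fit()].
#' @export
acute_effect_model <- function(pairs) {
  stopifnot(all(c("participant_id", "stress_pre", "stress_post") %in%
                  names(pairs)))
  pairs <- pairs %>% filter(!is.na(.data$stress_pre), !is.na(.data$stress_post))
  ids <- unique(pairs$participant_id)
  if (length(ids) < 2) abort("Need paired observations from >= 2 participants.")
  long <- pairs %>%
    mutate(.obs = row_number()) %>%
    tidyr::pivot_longer(c("stress_pre", "stress_post"), names_to = "time",
                        values_to = "stress") %>%
    mutate(time = ifelse(.data$time == "stress_pre", "pre", "post"))
  fitted <- fit_two_level(long, "time", c("pre", "post"))
  pd <- pairs %>%
    group_by(.data$participant_id) %>%
    summarise(diff = mean(.data$stress_pre - .data$stress_post),
              .groups = "drop")
  dz <- if (nrow(pd) >= 2 && sd(pd$diff) > 0) {
    mean(pd$diff) / sd(pd$diff)
  } else {
    NA_real_
  }
  new_mixed_fit(fitted, dz, contrast = "post - pre (acute exercise effect)",
                n_participants = length(ids), n_obs = nrow(pairs))
}

#' Baseline vs pre-exercise stress (random-intercept model)
#'
#' Companion contrast to [acute_effect_model()]: do pre-exercise momentary
#' stress levels in the intervention phase differ from baseline-phase levels?
#' Same two-level ML model with phase as the fixed predictor (baseline as
#' reference, so the fixed effect is pre-exercise minus baseline).
#'
#' @param data Tibble with columns `participant_id`, `phase` (values
#'   `"baseline"` and `"pre_exercise"`, or `"A"`/`"B"`), `stress`.
#' @return A `mixed_fit` object.
#' @export
baseline_vs_preexercise_model <- function(data) {
  stopifnot(all(c("participant_id", "phase", "stress") %in% names(data)))
  data <- data %>% filter(!is.na(.data$stress))
  data$phase <- dplyr::recode(as.character(data$phase),
                              A = "baseline", B = "pre_exercise")
  lv <- c("baseline", "pre_exercise")
  if (!all(data$phase %in% lv) || length(unique(data$phase)) < 2) {
    abort("`phase` must contain both baseline and pre_exercise values.")
  }
  ids <- unique(data$participant_id)
  if (length(ids) < 2) abort("Need >= 2 participants.")
  fitted <- fit_two_level(data, "phase", lv)
  pd <- data %>%
    group_by(.data$participant_id, .data$phase) %>%
    summarise(m = mean(.data$stress), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "phase", values_from = "m") %>%
    filter(!is.na(.data$baseline), !is.na(.data$pre_exercise)) %>%
    mutate(diff = .data$baseline - .data$pre_exercise)
  dz <- if (nrow(pd) >= 2 && sd(pd$diff) > 0) {
    mean(pd$diff) / sd(pd$diff)
  } else {
    NA_real_
  }
  new_mixed_fit(fitted, dz, contrast = "pre_exercise - baseline",
                n_participants = length(ids), n_obs = nrow(data))
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Two-level linear model (ML,", x$df_method, "df)\n")
  cat("  contrast:    ", x$contrast, "\n")
  cat(sprintf("  fixed effect: %.3f (SE %.3f), t(%.2f) = %.3f, p = %.3g\n",
              x$estimate, x$std_error, x$df, x$statistic, x$p_value))
  cat(sprintf("  Cohen's dz:   %.3f\n", x$cohens_dz))
  invisible(x)
}

#' Tidy a two-level model fit
#'
#' @param x A `mixed_fit` object.
#' @param ... Unused.
#' @return One-row tibble with the fixed effect, Satterthwaite df, p-value,
#'   variance components and participant-level Cohen's dz.
#' @method tidy mixed_fit
#' @export
tidy.mixed_fit <- function(x, ...) {
  tibble(
    contrast = x$contrast, estimate = x$estimate, std_error = x$std_error,
    df = x$df, statistic = x$statistic, p_value = x$p_value,
    cohens_dz = x$cohens_dz
  )
}

#' @rdname tidy.mixed_fit
#' @method glance mixed_fit
#' @export
glance.mixed_fit <- function(x, ...) {
  tibble(
    n_participants = x$n_participants, n_obs = x$n_obs,
    var_between = x$var_between, var_residual = x$var_residual,
    estimation = x$estimation, df_method = x$df_method
  )
}

#' Extract paired pre/post exercise observations from EMA records
#'
#' Intervention-phase momentary slots with both a pre- and a post-exercise
#' stress report — the rows [acute_effect_model()] consumes.
#'
#' @param records EMA record tibble or a `sim_trial`.
#' @return Tibble `participant_id`, `day`, `stress_pre`, `stress_post`.
#' @export
extract_exercise_pairs <- function(records) {
  if (inherits(records, "sim_trial")) records <- records$ema
  records %>%
    filter(.data$prompt_type == "momentary",
           !is.na(.data$stress_pre), !is.na(.data$stress_post)) %>%
    select("participant_id", "day", "stress_pre", "stress_post")
}
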