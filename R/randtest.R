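#' Phase mean difference for a hypothetical start day
#'
#' The test statistic of the multiple-baseline randomization test:
#' `D = mean(days >= start_day) - mean(days < start_day)` over non-missing
#' day-level values (intervention minus baseline, so a stress reduction is
#' negative).
#'
#' @param series Day-level tibble for one participant with columns `day` and
#'   `value` (missing days `NA`).
#' @param start_day Hypothetical first intervention day.
#' @return The mean difference `D`, a single number.
#' @examples
#' s <- tibble::tibble(day = 1:6, value = c(9, 8, 1, 2, 1, 2))
#' phase_mean_difference(s, 3) # -7
#' @export
phase_mean_difference <- function(series, start_day) {
  stopifnot(all(c("day", "value") %in% names(series)))
  a <- series$value[series$day < start_day]
  b <- series$value[series$day >= start_day]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    abort(sprintf("Start day %d leaves a phase with no observed days.",
                  as.integer(start_day)))
  }
  mean(b) - mean(a)
}

# D at every admissible start; infeasible starts (an empty side) are NA
stat_by_start <- function(day, value, starts) {
  ok <- !is.na(value)
  day <- day[ok]
  value <- value[ok]
  vapply(starts, function(s) {
    a <- value[day < s]
    b <- value[day >= s]
    if (length(a) == 0 || length(b) == 0) NA_real_ else mean(b) - mean(a)
  }, numeric(1))
}

rank_p <- function(dist, observed, alternative) {
  switch(alternative,
    less = mean(dist <= observed),
    greater = mean(dist >= observed),
    two_sided = mean(abs(dist) >= abs(observed))
  )
}

new_rand_test <- function(observed_stat, distribution, p_value, method,
                          n_permutations, alternative, seed, starts,
                          observed_start, participant_id = NA_character_,
                          scope = "individual") {
  structure(
    list(observed_stat = observed_stat, distribution = distribution,
         p_value = p_value, method = method, n_permutations = n_permutations,
         alternative = alternative, seed = seed, starts = starts,
         observed_start = observed_start, participant_id = participant_id,
         scope = scope),
    class = "rand_test"
  )
}

#' Individual multiple-baseline randomization test
#'
#' Tests, for a single participant, the null hypothesis of no phase effect by
#' locating the observed phase mean difference in the distribution of the
#' same statistic recomputed under every admissible intervention start day
#' (`method = "exhaustive"`) or under `R` starts sampled uniformly with
#' replacement from the admissible set (`method = "monte_carlo"`).
#'
#' The exhaustive p-value for `alternative = "less"` is the proportion of
#' admissible starts whose statistic is at or below the observed one; since
#' the observed assignment is a member of the set, `p >= 1/K` for `K`
#' admissible starts — with the default 8-start design no individual test can
#' reach `p < 0.125`. The Monte Carlo p-value uses the add-one estimator
#' `(1 + count) / (R + 1)`, which is strictly positive and valid. Permuted
#' starts that would leave a phase with no observed days are dropped from the
#' exhaustive set (resampled in Monte Carlo) with a warning.
#'
#' @param series Day-level tibble for one participant (`day`, `value`, and
#'   either a `start_day` column or the `start_day` argument).
#' @param design A [study_design()]; its baseline range defines the
#'   admissible start set. Alternatively pass `starts` directly.
#' @param start_day Observed first intervention day; defaults to the
#'   `start_day` column of `series`.
#' @param starts Optional explicit admissible start set (overrides `design`).
#' @param alternative `"less"` (default; intervention reduces the outcome),
#'   `"greater"`, or `"two_sided"` (ranks by `|D|`).
#' @param method `"exhaustive"` (default) or `"monte_carlo"`.
#' @param R Number of Monte Carlo permutations (default 5000).
#' @param seed Optional seed for Monte Carlo sampling.
#'
#' @return A `rand_test` object; see [tidy.rand_test()] and
#'   [glance.rand_test()].
#' @examples
#' s <- tibble::tibble(day = 1:6, value = c(9, 8, 1, 2, 1, 2))
#' out <- individual_randomization_test(s, start_day = 3, starts = 3:5)
#' out$p_value # 1/3
#' @export
individual_randomization_test <- function(series, design = study_design(),
                                          start_day = NULL, starts = NULL,
                                          alternative = c("less", "greater",
                                                          "two_sided"),
                                          method = c("exhaustive",
                                                     "monte_carlo"),
                                          R = 5000, seed = NULL) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(all(c("day", "value") %in% names(series)))
  if (is.null(start_day)) {
    if (!"start_day" %in% names(series)) {
      abort("Supply `start_day` or a start_day column in `series`.")
    }
    start_day <- series$start_day[1]
  }
  if (is.null(starts)) starts <- enumerate_start_days(design)
  if (length(starts) == 0) abort("Admissible start set is empty.")
  if (!start_day %in% starts) {
    abort("Observed start day is not in the admissible set.")
  }
  d_all <- stat_by_start(series$day, series$value, starts)
  names(d_all) <- starts
  if (is.na(d_all[as.character(start_day)])) {
    abort("Observed assignment leaves a phase with no observed days.")
  }
  observed <- unname(d_all[as.character(start_day)])
  feasible <- !is.na(d_all)
  if (!all(feasible)) {
    warn(sprintf("%d of %d admissible starts are infeasible (empty phase) %s",
                 sum(!feasible), length(starts),
                 "and were dropped from the randomization set."))
  }
  d_feas <- d_all[feasible]
  pid <- if ("participant_id" %in% names(series)) {
    as.character(series$participant_id[1])
  } else {
    NA_character_
  }
  if (method == "exhaustive") {
    p <- rank_p(d_feas, observed, alternative)
    new_rand_test(observed, unname(d_feas), p, "exhaustive", length(d_feas),
                  alternative, seed = NULL, starts = starts[feasible],
                  observed_start = start_day, participant_id = pid)
  } else {
    dist <- with_seed(seed,
      unname(d_feas)[sample.int(length(d_feas), R, replace = TRUE)])
    cnt <- switch(alternative,
      less = sum(dist <= observed),
      greater = sum(dist >= observed),
      two_sided = sum(abs(dist) >= abs(observed))
    )
    p <- (1 + cnt) / (R + 1)
    new_rand_test(observed, dist, p, "monte_carlo", R, alternative, seed,
                  starts = starts[feasible], observed_start = start_day,
                  participant_id = pid)
  }
}

#' Combined (across-case) multiple-baseline randomization test
#'
#' The cohort-level test: the statistic is the mean of the per-participant
#' phase mean differences at the observed start days, and the null
#' distribution reassigns each participant's start independently and
#' uniformly over their admissible set. The full product space is enumerated
#' when its size is at most `exhaustive_cap` (default 10^6); larger spaces
#' fall back to Monte Carlo with the add-one estimator `(1 + count)/(R + 1)`.
#'
#' @param day_series Day-level tibble covering >= 2 participants
#'   (`participant_id`, `day`, `value`, `start_day`), e.g. from
#'   [aggregate_daily()].
#' @inheritParams individual_randomization_test
#' @param method `"auto"` (exhaustive when the joint space fits under the
#'   cap), `"exhaustive"`, or `"monte_carlo"`.
#' @param exhaustive_cap Largest joint-space size enumerated exhaustively.
#'
#' @return A `rand_test` object with `scope = "combined"`; `observed_stat` is
#'   the mean of the individual differences and `per_participant` holds each
#'   participant's statistic-by-start table.
#' @export
combined_randomization_test <- function(day_series, design = study_design(),
                                        starts = NULL,
                                        alternative = c("less", "greater",
                                                        "two_sided"),
                                        method = c("auto", "exhaustive",
                                                   "monte_carlo"),
                                        R = 5000, exhaustive_cap = 1e6,
                                        seed = NULL) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(all(c("participant_id", "day", "value", "start_day") %in%
                  names(day_series)))
  if (is.null(starts)) starts <- enumerate_start_days(design)
  ids <- unique(day_series$participant_id)
  if (length(ids) < 2) {
    abort("The combined test needs at least 2 participants.")
  }
  per <- purrr::map(ids, function(id) {
    s <- day_series[day_series$participant_id == id, ]
    d_all <- stat_by_start(s$day, s$value, starts)
    obs_start <- s$start_day[1]
    if (!obs_start %in% starts) {
      abort(sprintf("Observed start of %s not in the admissible set.", id))
    }
    obs <- d_all[match(obs_start, starts)]
    if (is.na(obs)) {
      abort(sprintf("Observed assignment of %s leaves an empty phase.", id))
    }
    feas <- d_all[!is.na(d_all)]
    if (length(feas) < length(d_all)) {
      warn(sprintf("%s: %d infeasible start(s) dropped.", id,
                   length(d_all) - length(feas)))
    }
    list(id = id, d = feas, observed = obs, observed_start = obs_start)
  })
  observed <- mean(purrr::map_dbl(per, "observed"))
  sizes <- purrr::map_int(per, ~ length(.x$d))
  space <- prod(as.numeric(sizes))
  P <- length(per)
  use_exhaustive <- method == "exhaustive" ||
    (method == "auto" && space <= exhaustive_cap)
  if (use_exhaustive && space > exhaustive_cap) {
    abort(sprintf("Joint space (%.0f) exceeds exhaustive_cap (%.0f).",
                  space, exhaustive_cap))
  }
  per_tbl <- purrr::map_dfr(per, function(x) {
    tibble(participant_id = x$id, observed_start = x$observed_start,
           observed_stat = x$observed, n_starts = length(x$d))
  })
  if (use_exhaustive) {
    sums <- 0
    for (x in per) sums <- as.vector(outer(sums, x$d, "+"))
    dist <- sums / P
    p <- rank_p(dist, observed, alternative)
    out <- new_rand_test(observed, dist, p, "exhaustive", length(dist),
                         alternative, seed = NULL, starts = starts,
                         observed_start = per_tbl$observed_start,
                         scope = "combined")
  } else {
    dist <- with_seed(seed, {
      sums <- numeric(R)
      for (x in per) {
        sums <- sums + x$d[sample.int(length(x$d), R, replace = TRUE)]
      }
      sums / P
    })
    cnt <- switch(alternative,
      less = sum(dist <= observed),
      greater = sum(dist >= observed),
      two_sided = sum(abs(dist) >= abs(observed))
    )
    p <- (1 + cnt) / (R + 1)
    out <- new_rand_test(observed, dist, p, "monte_carlo", R, alternative,
                         seed, starts = starts,
                         observed_start = per_tbl$observed_start,
                         scope = "combined")
  }
  out$per_participant <- per_tbl
  out
}

#' @export
print.rand_test <- function(x, ...) {
  cat(sprintf("%s multiple-baseline randomization test (%s)\n",
              if (x$scope == "combined") "Combined" else "Individual",
              x$method))
  if (x$scope == "individual" && !is.na(x$participant_id)) {
    cat("  participant:   ", x$participant_id, "\n")
  }
  cat(sprintf("  observed D:     %.3f (intervention - baseline)\n",
              x$observed_stat))
  cat(sprintf("  permutations:   %d, alternative: %s\n",
              x$n_permutations, x$alternative))
  cat(sprintf("  p-value:        %.4g\n", x$p_value))
  invisible(x)
}

#' Tidy a randomization test result
#'
#' @param x A `rand_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the observed statistic, p-value and method
#'   metadata.
#' @method tidy rand_test
#' @export
tidy.rand_test <- function(x, ...) {
  tibble(
    scope = x$scope,
    participant_id = x$participant_id,
    statistic = x$observed_stat,
    p_value = x$p_value,
    alternative = x$alternative,
    method = x$method,
    n_permutations = x$n_permutations
  )
}

#' @rdname tidy.rand_test
#' @method glance rand_test
#' @export
glance.rand_test <- function(x, ...) tidy(x, ...)

#' Serialize a randomization test result to JSON
#'
#' @param x A `rand_test` object.
#' @param path Optional file to write; when `NULL`, the JSON string is
#'   returned.
#' @param include_distribution Include the full null distribution? Default
#'   `FALSE`.
#' @return The JSON string, invisibly when written to `path`.
#' @export
rand_test_json <- function(x, path = NULL, include_distribution = FALSE) {
  stopifnot(inherits(x, "rand_test"))
  obj <- list(
    scope = x$scope, statistic = x$observed_stat, p_value = x$p_value,
    method = x$method, n_permutations = x$n_permutations,
    alternative = x$alternative, seed = x$seed,
    observed_start = x$observed_start
  )
  if (!is.null(x$per_participant)) obj$per_participant <- x$per_participant
  if (include_distribution) obj$distribution <- x$distribution
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
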