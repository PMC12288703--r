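#' Define the temporal skeleton of an AB multiple-baseline trial
#'
#' A study design describes the fixed scaffolding of a single-case AB trial
#' with randomized baseline lengths: the total study length, the daily prompt
#' schedule (three momentary cues, a morning busyness cue, and an evening
#' delivery slot for the morning-triggered exercise), and the admissible range
#' of baseline-phase lengths.
#'
#' Clock times are carried as metadata only; all inference downstream is at
#' day resolution, and phase boundaries fall between days.
#'
#' @param total_days Total study length in days. Default 28.
#' @param momentary_times Character vector of `"HH:MM"` clock times for the
#'   momentary stress prompts, strictly increasing. Default
#'   `c("11:00", "16:00", "21:00")`.
#' @param morning_time Clock time of the morning busyness prompt; must be
#'   earlier than the first momentary prompt. Default `"07:00"`.
#' @param evening_delivery_time Clock time at which the morning-triggered
#'   exercise is delivered. Default `"19:00"`.
#' @param baseline_min,baseline_max Shortest and longest admissible baseline
#'   length in days. Defaults 7 and 14.
#'
#' @return An object of class `study_design` (a list with the fields above).
#' @examples
#' design <- study_design()
#' enumerate_start_days(design)
#' @export
study_design <- function(total_days = 28,
                         momentary_times = c("11:00", "16:00", "21:00"),
                         morning_time = "07:00",
                         evening_delivery_time = "19:00",
                         baseline_min = 7,
                         baseline_max = 14) {
  total_days <- as.integer(total_days)
  baseline_min <- as.integer(baseline_min)
  baseline_max <- as.integer(baseline_max)
  if (total_days < 2) abort("`total_days` must be at least 2.")
  if (!(1 <= baseline_min && baseline_min <= baseline_max &&
        baseline_max < total_days)) {
    abort("Need 1 <= baseline_min <= baseline_max < total_days.")
  }
  mins <- clock_minutes(momentary_times)
  if (length(mins) < 1 || any(diff(mins) <= 0)) {
    abort("`momentary_times` must be strictly increasing clock times.")
  }
  if (clock_minutes(morning_time) >= mins[1]) {
    abort("`morning_time` must be earlier than the first momentary time.")
  }
  structure(
    list(
      total_days = total_days,
      momentary_times = momentary_times,
      morning_time = morning_time,
      evening_delivery_time = evening_delivery_time,
      baseline_min = baseline_min,
      baseline_max = baseline_max
    ),
    class = "study_design"
  )
}

clock_minutes <- function(x) {
  ok <- grepl("^\\d{1,2}:\\d{2}$", x)
  if (!all(ok)) abort("Clock times must be 'HH:MM' strings.")
  p <- strsplit(x, ":", fixed = TRUE)
  vapply(p, function(h) as.numeric(h[1]) * 60 + as.numeric(h[2]), numeric(1))
}

#' @export
print.study_design <- function(x, ...) {
  cat("AB multiple-baseline study design\n")
  cat("  total days:      ", x$total_days, "\n")
  cat("  momentary cues:  ", paste(x$momentary_times, collapse = ", "), "\n")
  cat("  morning cue:     ", x$morning_time, "\n")
  cat("  evening delivery:", x$evening_delivery_time, "\n")
  cat("  baseline range:  ", x$baseline_min, "-", x$baseline_max, "days\n")
  invisible(x)
}

#' Draw randomized baseline lengths for a cohort
#'
#' Two assignment modes are supported. `"balanced_permutation"` assigns each
#' admissible length exactly once per block of `baseline_max - baseline_min +
#' 1` participants (cycling through freshly shuffled blocks when `n` exceeds
#' the block size), so a cohort of 8 under the default 7--14 range receives
#' each length once. `"iid_uniform"` draws each participant's length
#' independently and uniformly from the admissible range, the scheme assumed
#' by the power simulations.
#'
#' @param design A [study_design()].
#' @param n Number of participants (>= 1).
#' @param mode `"balanced_permutation"` or `"iid_uniform"`.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#'
#' @return Integer vector of length `n` of baseline lengths (days).
#' @examples
#' sort(draw_baseline_lengths(study_design(), 8, seed = 1))
#' @export
draw_baseline_lengths <- function(design, n,
                                  mode = c("balanced_permutation", "iid_uniform"),
                                  seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1) abort("`n` must be a positive integer.")
  lengths <- seq.int(design$baseline_min, design$baseline_max)
  with_seed(seed, {
    # index-based sampling: sample(x) misbehaves when x has length 1
    if (mode == "iid_uniform") {
      as.integer(lengths[sample.int(length(lengths), n, replace = TRUE)])
    } else {
      blocks <- ceiling(n / length(lengths))
      out <- unlist(lapply(seq_len(blocks),
                           function(b) lengths[sample.int(length(lengths))]))
      as.integer(out[seq_len(n)])
    }
  })
}

#' Assign baseline and intervention phases for one participant
#'
#' @param design A [study_design()].
#' @param baseline_length Baseline length in days, within the design's range.
#' @param participant_id Optional identifier carried through to outputs.
#'
#' @return A one-row tibble with `participant_id`, `baseline_length`,
#'   `start_day` (the first intervention day, `baseline_length + 1`),
#'   `intervention_length` and `total_days`.
#' @examples
#' assign_phases(study_design(), 7) # 21 intervention days
#' @export
assign_phases <- function(design, baseline_length, participant_id = NA_character_) {
  stopifnot(inherits(design, "study_design"))
  L <- as.integer(baseline_length)
  if (is.na(L) || L < design$baseline_min || L > design$baseline_max) {
    abort(sprintf(
      "`baseline_length` must lie in [%d, %d], got %s.",
      design$baseline_min, design$baseline_max, as.character(baseline_length)
    ))
  }
  tibble(
    participant_id = as.character(participant_id),
    baseline_length = L,
    start_day = L + 1L,
    intervention_length = design$total_days - L,
    total_days = design$total_days
  )
}

#' Phase label for each study day
#'
#' @param day Integer day (1-based).
#' @param start_day First intervention day.
#' @return `"A"` for baseline days, `"B"` for intervention days.
#' @export
phase_of <- function(day, start_day) {
  ifelse(day < start_day, "A", "B")
}

#' Enumerate the admissible intervention start days
#'
#' The randomization space of the multiple-baseline test: every day on which
#' the intervention could have started under the design's baseline range.
#'
#' @param design A [study_design()].
#' @return Increasing integer vector `{baseline_min + 1, ..., baseline_max + 1}`.
#' @examples
#' enumerate_start_days(study_design()) # 8..15
#' @export
enumerate_start_days <- function(design) {
  stopifnot(inherits(design, "study_design"))
  seq.int(design$baseline_min + 1L, design$baseline_max + 1L)
}

#' Expand the full prompt schedule for one participant
#'
#' @param design A [study_design()].
#' @param assignment A one-row assignment tibble from [assign_phases()].
#'
#' @return A tibble with one row per scheduled slot: `participant_id`, `day`,
#'   `slot_time`, `prompt_type` (`momentary`, `morning`, `evening_delivery`)
#'   and `phase`. Momentary slots number `3 * total_days`; morning and evening
#'   slots one per day.
#' @examples
#' sched <- schedule_prompts(study_design(), assign_phases(study_design(), 10))
#' sum(sched$prompt_type == "momentary" & sched$phase == "A") # 30
#' @export
schedule_prompts <- function(design, assignment) {
  stopifnot(inherits(design, "study_design"), is.data.frame(assignment),
            nrow(assignment) == 1)
  days <- seq_len(design$total_days)
  momentary <- tidyr::expand_grid(day = days, slot_time = design$momentary_times) %>%
    mutate(prompt_type = "momentary")
  morning <- tibble(day = days, slot_time = design$morning_time,
                    prompt_type = "morning")
  evening <- tibble(day = days, slot_time = design$evening_delivery_time,
                    prompt_type = "evening_delivery")
  bind_rows(morning, momentary, evening) %>%
    mutate(
      participant_id = assignment$participant_id,
      phase = phase_of(.data$day, assignment$start_day)
    ) %>%
    arrange(.data$day, clock_minutes(.data$slot_time)) %>%
    select("participant_id", "day", "slot_time", "prompt_type", "phase")
}
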