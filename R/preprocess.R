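# instrument metadata: item counts, per-item range, severity cutoffs, and the
# marginals/change targets the synthetic generator draws from
instrument_info <- function() {
  tibble(
    instrument = c("PSS", "PHQ9", "GAD7", "RSQ_brooding",
                   "HEMA_eud", "HEMA_pleasure", "HEMA_relax"),
    n_items = c(10L, 9L, 7L, 5L, 4L, 3L, 2L),
    item_lo = c(0L, 0L, 0L, 1L, 1L, 1L, 1L),
    item_hi = c(4L, 3L, 3L, 4L, 7L, 7L, 7L),
    pre_mean = c(33, 6.4, 6.1, 13.0, 21.1, 17.9, 11.0),
    pre_sd = c(4, 3.4, 3.7, 3.21, 3.3, 1.1, 2.5)
  )
}

severity_cutoffs <- function(instrument) {
  switch(instrument,
    PHQ9 = c("none/minimal" = 0, mild = 5, moderate = 10,
             "moderately severe" = 15, severe = 20),
    GAD7 = c("none/minimal" = 0, mild = 5, moderate = 10, severe = 15),
    NULL
  )
}

#' Score a questionnaire from item responses
#'
#' Computes the instrument sum score and, for the symptom scales that define
#' them, a severity band. Bands are left-closed: a total equal to a cutoff
#' enters that band (PHQ-9 cutoffs 5/10/15/20: mild, moderate, moderately
#' severe, severe; GAD-7 cutoffs 5/10/15: mild, moderate, severe). The PSS,
#' brooding (RSQ) and HEMA subscales have no banding.
#'
#' @param instrument One of `"PSS"` (10 items, 0--4), `"PHQ9"` (9 items,
#'   0--3), `"GAD7"` (7 items, 0--3), `"RSQ_brooding"` (5 items, 1--4),
#'   `"HEMA_eud"` (4), `"HEMA_pleasure"` (3), `"HEMA_relax"` (2 items, 1--7).
#' @param items Integer vector of item responses; count and range must match
#'   the instrument.
#'
#' @return A one-row tibble with `instrument`, `total` and `band` (`NA` where
#'   no banding is defined).
#' @examples
#' score_questionnaire("PHQ9", c(1, 1, 1, 1, 1, 1, 1, 0, 0)) # total 7, mild
#' @export
score_questionnaire <- function(instrument, items) {
  info <- instrument_info()
  if (!instrument %in% info$instrument) {
    abort(sprintf("Unknown instrument '%s'.", instrument))
  }
  row <- info[info$instrument == instrument, ]
  items <- as.numeric(items)
  if (length(items) != row$n_items) {
    abort(sprintf("%s expects %d items, got %d.", instrument, row$n_items,
                  length(items)))
  }
  if (anyNA(items) || any(items < row$item_lo | items > row$item_hi) ||
      any(items != round(items))) {
    abort(sprintf("%s items must be integers in [%d, %d].", instrument,
                  row$item_lo, row$item_hi))
  }
  total <- sum(items)
  cuts <- severity_cutoffs(instrument)
  band <- if (is.null(cuts)) {
    NA_character_
  } else {
    names(cuts)[findInterval(total, cuts)]
  }
  tibble(instrument = instrument, total = total, band = band)
}

#' Score a long questionnaire table
#'
#' Applies [score_questionnaire()] to every participant x instrument x
#' occasion cell of a long item table (the questionnaire CSV schema).
#'
#' @param items Tibble with columns `participant_id`, `instrument`,
#'   `item_index`, `response`, `occasion`.
#' @return Tibble with one row per cell: `participant_id`, `instrument`,
#'   `occasion`, `total`, `band`.
#' @export
score_questionnaires <- function(items) {
  stopifnot(all(c("participant_id", "instrument", "item_index", "response",
                  "occasion") %in% names(items)))
  items %>%
    group_by(.data$participant_id, .data$instrument, .data$occasion) %>%
    arrange(.data$item_index, .by_group = TRUE) %>%
    summarise(
      scored = list(score_questionnaire(.data$instrument[1], .data$response)),
      .groups = "drop"
    ) %>%
    mutate(
      total = purrr::map_dbl(.data$scored, "total"),
      band = purrr::map_chr(.data$scored, "band")
    ) %>%
    select("participant_id", "instrument", "occasion", "total", "band")
}

#' Compliance accounting for scheduled prompts
#'
#' Counts responded versus scheduled prompts per participant, optionally
#' restricted to a prompt type and/or phase. Percentages are rounded half-up
#' to one decimal for reporting.
#'
#' @param records EMA record tibble (schema of [read_ema_table()]).
#' @param assignments Assignment tibble (`participant_id`, `start_day`)
#'   needed when filtering by phase; taken from a `sim_trial` if one is
#'   passed as `records`.
#' @param prompt_types Prompt types to count; default `"momentary"`.
#' @param phases Optional subset of `c("A", "B")`.
#'
#' @return Tibble per participant: `responded`, `scheduled`, `percentage`,
#'   plus an overall row with `participant_id = "(all)"`.
#' @examples
#' trial <- generate_cohort(n = 2, seed = 7)
#' compute_compliance(trial$ema, trial$assignments, phases = "A")
#' @export
compute_compliance <- function(records, assignments = NULL,
                               prompt_types = "momentary", phases = NULL) {
  if (inherits(records, "sim_trial")) {
    assignments <- records$assignments
    records <- records$ema
  }
  stopifnot(is.data.frame(records))
  rec <- records %>% filter(.data$prompt_type %in% prompt_types)
  if (!is.null(phases)) {
    if (is.null(assignments)) {
      abort("Phase filtering needs `assignments` with start_day.")
    }
    rec <- rec %>%
      left_join(assignments %>% select("participant_id", "start_day"),
                by = "participant_id") %>%
      filter(phase_of(.data$day, .data$start_day) %in% phases)
  }
  if (nrow(rec) == 0) abort("No scheduled prompts after filtering.")
  per <- rec %>%
    group_by(.data$participant_id) %>%
    summarise(responded = sum(.data$responded), scheduled = n(),
              .groups = "drop")
  all_row <- tibble(participant_id = "(all)",
                    responded = sum(per$responded),
                    scheduled = sum(per$scheduled))
  bind_rows(per, all_row) %>%
    mutate(percentage = round_half_up(100 * .data$responded / .data$scheduled, 1))
}

#' Aggregate momentary stress to day level
#'
#' Momentary reports are averaged within each day, one value per study day
#' per participant. During the intervention phase each responded slot
#' contributes the post-exercise report when one exists; when the exercise
#' opportunity was skipped the pre-exercise report is used
#' (`b_phase_value = "post_else_pre"`, the default) or the slot is dropped
#' (`"post_only"`). Baseline slots always contribute the momentary report.
#' Days with no usable response are `NA`.
#'
#' @param records EMA record tibble, or a `sim_trial`.
#' @param assignments Assignment tibble (`participant_id`, `start_day`,
#'   `total_days`); taken from a `sim_trial` automatically.
#' @param b_phase_value Intervention-phase substitution rule, see above.
#'
#' @return A day-level tibble (`participant_id`, `day`, `phase`, `value`,
#'   `start_day`) with `total_days` rows per participant — the series the
#'   randomization tests consume.
#' @export
aggregate_daily <- function(records, assignments = NULL,
                            b_phase_value = c("post_else_pre", "post_only")) {
  b_phase_value <- match.arg(b_phase_value)
  if (inherits(records, "sim_trial")) {
    assignments <- records$assignments
    records <- records$ema
  }
  stopifnot(is.data.frame(records), is.data.frame(assignments))
  total_days <- assignments$total_days[1]
  day_vals <- records %>%
    filter(.data$prompt_type == "momentary", .data$responded == 1) %>%
    left_join(assignments %>% select("participant_id", "start_day"),
              by = "participant_id") %>%
    mutate(
      phase = phase_of(.data$day, .data$start_day),
      used = dplyr::case_when(
        phase == "A" ~ .data$stress_pre,
        b_phase_value == "post_else_pre" ~
          dplyr::coalesce(.data$stress_post, .data$stress_pre),
        TRUE ~ .data$stress_post
      )
    ) %>%
    filter(!is.na(.data$used)) %>%
    group_by(.data$participant_id, .data$day) %>%
    summarise(value = mean(.data$used), .groups = "drop")
  grid <- tidyr::expand_grid(
    participant_id = assignments$participant_id,
    day = seq_len(total_days)
  )
  grid %>%
    left_join(day_vals, by = c("participant_id", "day")) %>%
    left_join(assignments %>% select("participant_id", "start_day"),
              by = "participant_id") %>%
    mutate(phase = phase_of(.data$day, .data$start_day)) %>%
    select("participant_id", "day", "phase", "value", "start_day") %>%
    arrange(.data$participant_id, .data$day)
}

#' Per-protocol exclusion of sparsely observed participants
#'
#' A participant is analyzable only when both phases retain at least
#' `min_obs_per_phase` non-missing day-level observations; otherwise they are
#' excluded with a recorded reason. The default minimum of 3 follows the
#' practical floor for randomization tests on short series.
#'
#' @param day_series Day-level tibble from [aggregate_daily()].
#' @param min_obs_per_phase Minimum non-missing days required per phase.
#'
#' @return A list with `kept` (the filtered day series) and `excluded`
#'   (tibble `participant_id`, `n_A`, `n_B`, `reason`).
#' @export
per_protocol_filter <- function(day_series, min_obs_per_phase = 3) {
  stopifnot(all(c("participant_id", "phase", "value") %in% names(day_series)))
  counts <- day_series %>%
    group_by(.data$participant_id) %>%
    summarise(
      n_A = sum(!is.na(.data$value) & .data$phase == "A"),
      n_B = sum(!is.na(.data$value) & .data$phase == "B"),
      .groups = "drop"
    )
  excluded <- counts %>%
    filter(.data$n_A < min_obs_per_phase | .data$n_B < min_obs_per_phase) %>%
    mutate(reason = dplyr::case_when(
      .data$n_A + .data$n_B == 0 ~ "no observations",
      .data$n_A < min_obs_per_phase & .data$n_B < min_obs_per_phase ~
        sprintf("fewer than %d observed days in both phases", min_obs_per_phase),
      .data$n_A < min_obs_per_phase ~
        sprintf("fewer than %d observed days in baseline phase", min_obs_per_phase),
      TRUE ~
        sprintf("fewer than %d observed days in intervention phase", min_obs_per_phase)
    ))
  list(
    kept = day_series %>%
      filter(!.data$participant_id %in% excluded$participant_id),
    excluded = excluded
  )
}

#' Count feasibility endorsements
#'
#' On a 1--7 agreement scale, a rating at or above the threshold (default 4)
#' counts as endorsement.
#'
#' @param ratings Numeric vector of 1--7 ratings.
#' @param threshold Endorsement threshold; default 4.
#' @return One-row tibble with `count`, `n` and `percentage` (half-up, one
#'   decimal).
#' @examples
#' count_endorsements(c(4, 5, 6, 4, 3, 2, 7, 4)) # 6 of 8, 75%
#' @export
count_endorsements <- function(ratings, threshold = 4) {
  if (length(ratings) == 0) abort("`ratings` must be non-empty.")
  if (any(is.na(ratings)) || any(ratings < 1 | ratings > 7)) {
    abort("Ratings must lie in [1, 7].")
  }
  cnt <- sum(ratings >= threshold)
  tibble(count = cnt, n = length(ratings),
         percentage = round_half_up(100 * cnt / length(ratings), 1))
}
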