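#' The CBT exercise catalog
#'
#' Six stand-alone exercises, three delivered after momentary stress cues
#' (quick, body-focused) and three triggered by the morning busyness forecast
#' and delivered in the evening (imaginative/cognitive). Tutorial durations
#' for the momentary exercises are the published video lengths; the morning
#' exercises carry synthetic durations within the published 3.5--9.0 minute
#' range, as their individual lengths are not reported.
#'
#' @return A tibble with `exercise_id`, `cue_type` and `tutorial_minutes`.
#' @examples
#' exercise_catalog()
#' @export
exercise_catalog <- function() {
  tibble(
    exercise_id = c("breath_control", "mindfulness", "muscle_relaxation",
                    "self_talk", "cognitive_defusion", "cognitive_restructuring"),
    cue_type = rep(c("momentary", "morning"), each = 3),
    tutorial_minutes = c(3.8, 9.0, 5.5, 4.0, 6.0, 8.0)
  )
}

#' Threshold-band decision rules for exercise recommendation
#'
#' The tailoring variable (momentary stress for momentary cues, forecast
#' busyness for morning cues) is a 0--100 slider split into four bands with
#' thresholds at 40, 60 and 80. The lowest band prompts no exercise. The
#' printed integer bands (0--39, 40--59, 60--79, 80--100) are implemented as
#' half-open real intervals `[0,40)`, `[40,60)`, `[60,80)`, `[80,100]` so any
#' real-valued response maps to exactly one band while integer inputs keep
#' their printed meaning.
#'
#' @param momentary_thresholds,morning_thresholds Increasing numeric vectors
#'   of interior band thresholds (defaults `c(40, 60, 80)`); one threshold per
#'   exercise in the cue's catalog, lowest band mapping to no exercise.
#' @param catalog Exercise catalog tibble, see [exercise_catalog()].
#'
#' @return A tibble of bands with `cue_type`, `lower`, `upper` and
#'   `exercise_id` (`"none"` for the lowest band).
#' @examples
#' decision_rules()
#' @export
decision_rules <- function(momentary_thresholds = c(40, 60, 80),
                           morning_thresholds = c(40, 60, 80),
                           catalog = exercise_catalog()) {
  build <- function(cue, thresholds) {
    ex <- catalog$exercise_id[catalog$cue_type == cue]
    if (length(thresholds) != length(ex)) {
      abort(sprintf("Need one %s threshold per exercise (%d).", cue, length(ex)))
    }
    if (any(diff(thresholds) <= 0) || thresholds[1] <= 0 ||
        thresholds[length(thresholds)] >= 100) {
      abort("Thresholds must be strictly increasing and inside (0, 100).")
    }
    lower <- c(0, thresholds)
    upper <- c(thresholds, 100)
    tibble(cue_type = cue, lower = lower, upper = upper,
           exercise_id = c("none", ex))
  }
  bind_rows(build("momentary", momentary_thresholds),
            build("morning", morning_thresholds))
}

band_lookup <- function(value, rules, cue) {
  bands <- rules[rules$cue_type == cue, , drop = FALSE]
  if (nrow(bands) == 0) abort(sprintf("No decision bands for cue type '%s'.", cue))
  bad <- !is.na(value) & (value < 0 | value > 100)
  if (any(bad)) {
    abort(sprintf("Tailoring values must lie in [0, 100]; got %s.",
                  paste(utils::head(value[bad], 3), collapse = ", ")))
  }
  # half-open bands [lower, upper) with the top band closed at 100
  idx <- findInterval(value, bands$lower)
  out <- bands$exercise_id[idx]
  out[is.na(value)] <- NA_character_
  out
}

#' Recommend an exercise from a momentary stress report
#'
#' Deterministic band lookup against the momentary decision rules: stress
#' below 40 prompts nothing, 40--59 breath control, 60--79 mindfulness and
#' 80--100 progressive muscle relaxation (under the default rules).
#'
#' @param stress Numeric vector of 0--100 slider values (NA allowed,
#'   propagated).
#' @param rules Decision-rule tibble from [decision_rules()].
#' @return Character vector of `exercise_id`s, `"none"` for the lowest band.
#' @examples
#' recommend_momentary(c(39, 40, 80, 100))
#' @export
recommend_momentary <- function(stress, rules = decision_rules()) {
  band_lookup(stress, rules, "momentary")
}

#' Recommend an evening exercise from the morning busyness forecast
#'
#' As [recommend_momentary()] but against the morning rules (compassionate
#' self-talk, cognitive defusion, cognitive restructuring under the
#' defaults); the recommended exercise is delivered at the design's evening
#' delivery time.
#'
#' @inheritParams recommend_momentary
#' @param busyness Numeric vector of 0--100 slider values.
#' @return Character vector of `exercise_id`s.
#' @examples
#' recommend_morning(c(0, 60, 80))
#' @export
recommend_morning <- function(busyness, rules = decision_rules()) {
  band_lookup(busyness, rules, "morning")
}

#' Tabulate recommendation and engagement dose
#'
#' Counts, per exercise, how often it was recommended and how often it was
#' actually performed, plus spontaneous engagements (performed without having
#' been the recommendation of that prompt). The `engaged` field is a
#' semicolon-separated set per prompt; each distinct engaged exercise counts
#' once per record.
#'
#' @param records EMA record tibble with `recommended` and `engaged` columns
#'   (see [read_ema_table()] for the schema).
#'
#' @return A tibble with one row per engageable category (the six exercises
#'   plus `other` and `skipped`) and columns `recommended`, `engaged`,
#'   `spontaneous`.
#' @examples
#' recs <- tibble::tibble(
#'   recommended = c("none", "breath_control", "breath_control"),
#'   engaged = c("breath_control", "breath_control", "skipped")
#' )
#' tabulate_dose(recs)
#' @export
tabulate_dose <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("recommended", "engaged") %in% names(records)))
  cats <- c(exercise_catalog()$exercise_id, "other", "skipped")
  rec <- as.character(records$recommended)
  eng <- as.character(records$engaged)
  if (nrow(records) == 0) {
    return(tibble(exercise_id = cats, recommended = 0L, engaged = 0L,
                  spontaneous = 0L))
  }
  eng_sets <- lapply(strsplit(ifelse(is.na(eng) | eng == "", "", eng), ";",
                              fixed = TRUE), unique)
  rec_counts <- table(factor(rec[!is.na(rec) & rec != "none" & rec != ""],
                             levels = cats))
  eng_flat <- unlist(eng_sets)
  eng_counts <- table(factor(eng_flat[eng_flat != ""], levels = cats))
  spont <- integer(length(cats))
  names(spont) <- cats
  for (i in seq_along(eng_sets)) {
    s <- setdiff(eng_sets[[i]], c("", "skipped", if (!is.na(rec[i])) rec[i]))
    s <- intersect(s, c(exercise_catalog()$exercise_id, "other"))
    spont[s] <- spont[s] + 1L
  }
  tibble(
    exercise_id = cats,
    recommended = as.integer(rec_counts),
    engaged = as.integer(eng_counts),
    spontaneous = as.integer(spont)
  )
}
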