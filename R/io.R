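ema_col_types <- function() {
  readr::cols(
    participant_id = readr::col_character(),
    day = readr::col_integer(),
    slot_time = readr::col_character(),
    prompt_type = readr::col_character(),
    responded = readr::col_integer(),
    stress_pre = readr::col_double(),
    stress_post = readr::col_double(),
    busyness = readr::col_double(),
    recommended = readr::col_character(),
    engaged = readr::col_character()
  )
}

ema_columns <- c("participant_id", "day", "slot_time", "prompt_type",
                 "responded", "stress_pre", "stress_post", "busyness",
                 "recommended", "engaged")

validate_ema <- function(records) {
  missing_cols <- setdiff(ema_columns, names(records))
  if (length(missing_cols)) {
    abort(paste("Missing EMA columns:", paste(missing_cols, collapse = ", ")))
  }
  problems <- character()
  note <- function(rows, col, msg) {
    if (length(rows)) {
      sprintf("rows %s, column '%s': %s",
              paste(utils::head(rows, 5), collapse = ","), col, msg)
    } else {
      character()
    }
  }
  problems <- c(
    problems,
    note(which(is.na(records$day) | records$day < 1), "day",
         "must be an integer >= 1"),
    note(which(!records$prompt_type %in%
                 c("momentary", "morning", "evening_delivery")),
         "prompt_type", "must be momentary/morning/evening_delivery"),
    note(which(!records$responded %in% c(0L, 1L)), "responded",
         "must be 0 or 1")
  )
  for (col in c("stress_pre", "stress_post", "busyness")) {
    v <- records[[col]]
    problems <- c(problems, note(which(!is.na(v) & (v < 0 | v > 100)), col,
                                 "must lie in [0, 100]"))
  }
  valid_rec <- c(exercise_catalog()$exercise_id, "none")
  problems <- c(problems, note(
    which(!is.na(records$recommended) & records$recommended != "" &
            !records$recommended %in% valid_rec),
    "recommended", "unknown exercise id"))
  valid_eng <- c(exercise_catalog()$exercise_id, "other", "skipped")
  eng <- records$engaged
  bad_eng <- vapply(seq_along(eng), function(i) {
    if (is.na(eng[i]) || eng[i] == "") return(FALSE)
    parts <- strsplit(eng[i], ";", fixed = TRUE)[[1]]
    !all(parts %in% valid_eng) ||
      ("skipped" %in% parts && length(parts) > 1)
  }, logical(1))
  problems <- c(problems, note(which(bad_eng), "engaged",
                               "invalid or contradictory engagement set"))
  dup <- records %>%
    count(.data$participant_id, .data$day, .data$slot_time,
          .data$prompt_type) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    problems <- c(problems, sprintf(
      "duplicate slot keys: %s",
      paste(sprintf("(%s, day %d, %s, %s)", dup$participant_id, dup$day,
                    dup$slot_time, dup$prompt_type)[seq_len(min(3, nrow(dup)))],
            collapse = "; ")))
  }
  if (length(problems)) {
    abort(paste0("Invalid EMA table:\n  ", paste(problems, collapse = "\n  ")))
  }
  invisible(records)
}

#' Read and validate a long-format EMA prompt table
#'
#' The schema has one row per scheduled prompt slot: `participant_id`, `day`
#' (integer >= 1), `slot_time` (`HH:MM`), `prompt_type`
#' (`momentary`/`morning`/`evening_delivery`), `responded` (0/1),
#' `stress_pre`, `stress_post`, `busyness` (0--100 sliders), `recommended`
#' (exercise id or `none`), `engaged` (semicolon-separated exercise ids,
#' `other`, or `skipped`). Empty fields are missing values. Schema violations
#' raise an error naming the offending rows and column; duplicate slot keys
#' are rejected.
#'
#' @param path CSV file path.
#' @return A validated EMA record tibble.
#' @export
read_ema_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  records <- readr::read_csv(path, col_types = ema_col_types(), na = "")
  records <- records[, ema_columns]
  validate_ema(records)
  records
}

#' @rdname read_ema_table
#' @param records EMA record tibble to write.
#' @export
write_ema_table <- function(records, path) {
  records <- as_tibble(records)
  validate_ema(records)
  readr::write_csv(records[, ema_columns], path, na = "")
  invisible(path)
}

#' Read or write a long-format questionnaire item table
#'
#' Schema: `participant_id`, `instrument`, `item_index`, `response`,
#' `occasion` (`pre`/`post`).
#'
#' @param path CSV file path.
#' @return A questionnaire item tibble.
#' @export
read_questionnaire_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  q <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    instrument = readr::col_character(),
    item_index = readr::col_integer(),
    response = readr::col_integer(),
    occasion = readr::col_character()
  ), na = "")
  bad <- which(!q$occasion %in% c("pre", "post"))
  if (length(bad)) {
    abort(sprintf("rows %s: occasion must be 'pre' or 'post'",
                  paste(utils::head(bad, 5), collapse = ",")))
  }
  unknown <- setdiff(unique(q$instrument), instrument_info()$instrument)
  if (length(unknown)) {
    abort(paste("Unknown instruments:", paste(unknown, collapse = ", ")))
  }
  q
}

#' @rdname read_questionnaire_table
#' @param items Questionnaire item tibble to write.
#' @export
write_questionnaire_table <- function(items, path) {
  readr::write_csv(items, path, na = "")
  invisible(path)
}

default_config <- function() {
  list(
    design = list(total_days = 28, baseline_min = 7, baseline_max = 14,
                  momentary_times = c("11:00", "16:00", "21:00"),
                  morning_time = "07:00", evening_delivery_time = "19:00"),
    rules = list(momentary_thresholds = c(40, 60, 80),
                 morning_thresholds = c(40, 60, 80)),
    cohort = list(n = 8, mode = "balanced_permutation", seed = 1,
                  model = list()),
    preprocessing = list(min_obs_per_phase = 3,
                         b_phase_value = "post_else_pre"),
    inference = list(alternative = "less", method = "auto", R = 5000,
                     exhaustive_cap = 1e6, seed = 1),
    inputs = list(ema_csv = NULL, questionnaire_csv = NULL,
                  assignments_csv = NULL),
    output = list(dir = "jitai-analysis")
  )
}

merge_config <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults)) {
      abort(sprintf("Unknown config key: %s", full))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(as.list(user[[key]]), defaults[[key]],
                                      full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full trial analysis pipeline from a config file
#'
#' Executes simulate (or load) -> day-level aggregation -> per-protocol
#' filter -> individual randomization tests -> combined test -> mixed-model
#' effects -> questionnaire effects, logging one line per stage, and writes
#' the analysis bundle (day-level CSV, compliance CSV, per-participant report
#' table, randomization JSON, model JSON) to the configured output
#' directory.
#'
#' The YAML config mirrors the module structure with sections `design`,
#' `rules`, `cohort` (simulation mode), `inputs` (analysis of existing CSVs:
#' `ema_csv`, `assignments_csv`, optional `questionnaire_csv`),
#' `preprocessing`, `inference` and `output`; unknown keys are errors.
#' Omitted keys take the documented defaults. When `inputs$ema_csv` is set
#' the cohort section is ignored and no simulation happens.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Optional override of the configured output directory;
#'   `NULL` disables writing.
#' @return The analysis bundle (named list), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config not found: %s", config))
    merge_config(yaml::read_yaml(config), default_config())
  } else {
    merge_config(config, default_config())
  }
  if (!missing(out_dir)) cfg$output$dir <- out_dir
  design <- study_design(
    total_days = cfg$design$total_days,
    momentary_times = cfg$design$momentary_times,
    morning_time = cfg$design$morning_time,
    evening_delivery_time = cfg$design$evening_delivery_time,
    baseline_min = cfg$design$baseline_min,
    baseline_max = cfg$design$baseline_max
  )
  rules <- decision_rules(
    momentary_thresholds = unlist(cfg$rules$momentary_thresholds),
    morning_thresholds = unlist(cfg$rules$morning_thresholds)
  )
  stage_log("config", "effective config resolved (%d sections)", length(cfg))

  if (!is.null(cfg$inputs$ema_csv)) {
    ema <- read_ema_table(cfg$inputs$ema_csv)
    if (is.null(cfg$inputs$assignments_csv)) {
      abort("Analyzing an EMA CSV requires inputs$assignments_csv.")
    }
    asg <- readr::read_csv(cfg$inputs$assignments_csv, col_types = readr::cols(
      participant_id = readr::col_character(),
      baseline_length = readr::col_integer()
    ), na = "")
    assignments <- purrr::map_dfr(seq_len(nrow(asg)), function(i) {
      assign_phases(design, asg$baseline_length[i], asg$participant_id[i])
    })
    quest <- if (!is.null(cfg$inputs$questionnaire_csv)) {
      read_questionnaire_table(cfg$inputs$questionnaire_csv)
    } else {
      NULL
    }
    stage_log("load", "read %d EMA records, %d participants", nrow(ema),
              nrow(assignments))
  } else {
    model <- do.call(participant_model, cfg$cohort$model)
    trial <- generate_cohort(cfg$cohort$n, design, rules, model,
                             mode = cfg$cohort$mode, seed = cfg$cohort$seed)
    ema <- trial$ema
    assignments <- trial$assignments
    quest <- trial$questionnaires
    stage_log("simulate", "generated %d records for %d participants (seed %s)",
              nrow(ema), cfg$cohort$n, cfg$cohort$seed)
  }

  compliance <- compute_compliance(ema, assignments)
  day <- aggregate_daily(ema, assignments,
                         b_phase_value = cfg$preprocessing$b_phase_value)
  pp <- per_protocol_filter(day, cfg$preprocessing$min_obs_per_phase)
  stage_log("preprocess", "%d day-level rows; kept %d, excluded %d participants",
            nrow(day), length(unique(pp$kept$participant_id)),
            nrow(pp$excluded))
  for (i in seq_len(nrow(pp$excluded))) {
    stage_log("per-protocol", "excluded %s: %s",
              pp$excluded$participant_id[i], pp$excluded$reason[i])
  }

  kept_ids <- unique(pp$kept$participant_id)
  inf <- cfg$inference
  individual <- purrr::map(kept_ids, function(id) {
    s <- pp$kept[pp$kept$participant_id == id, ]
    individual_randomization_test(
      s, design, alternative = inf$alternative,
      method = if (inf$method == "auto") "exhaustive" else inf$method,
      R = inf$R, seed = inf$seed
    )
  })
  names(individual) <- kept_ids
  combined <- if (length(kept_ids) >= 2) {
    combined_randomization_test(pp$kept, design,
                                alternative = inf$alternative,
                                method = inf$method, R = inf$R,
                                exhaustive_cap = inf$exhaustive_cap,
                                seed = inf$seed)
  } else {
    NULL
  }
  stage_log("randomization", "%d individual tests; combined p = %s",
            length(individual),
            if (is.null(combined)) "NA" else format(combined$p_value))

  report <- purrr::map_dfr(kept_ids, function(id) {
    s <- pp$kept[pp$kept$participant_id == id, ]
    a <- s$value[s$phase == "A"]
    b <- s$value[s$phase == "B"]
    tibble(
      participant_id = id,
      baseline_mean = mean(a, na.rm = TRUE),
      baseline_sd = sd(a[!is.na(a)]),
      intervention_mean = mean(b, na.rm = TRUE),
      intervention_sd = sd(b[!is.na(b)]),
      p_value = individual[[id]]$p_value
    )
  })
  if (!is.null(combined)) {
    all_a <- report$baseline_mean
    all_b <- report$intervention_mean
    report <- bind_rows(report, tibble(
      participant_id = "(all)",
      baseline_mean = mean(all_a), baseline_sd = sd(all_a),
      intervention_mean = mean(all_b), intervention_sd = sd(all_b),
      p_value = combined$p_value
    ))
  }

  pairs <- extract_exercise_pairs(ema) %>%
    filter(.data$participant_id %in% kept_ids)
  acute <- if (length(unique(pairs$participant_id)) >= 2 && nrow(pairs) >= 4) {
    acute_effect_model(pairs)
  } else {
    NULL
  }
  base_pre <- ema %>%
    filter(.data$prompt_type == "momentary", .data$responded == 1,
           !is.na(.data$stress_pre), .data$participant_id %in% kept_ids) %>%
    left_join(assignments %>% select("participant_id", "start_day"),
              by = "participant_id") %>%
    mutate(phase = phase_of(.data$day, .data$start_day)) %>%
    select("participant_id", "phase", stress = "stress_pre")
  phase_model <- if (length(unique(base_pre$participant_id)) >= 2 &&
                     all(c("A", "B") %in% base_pre$phase)) {
    baseline_vs_preexercise_model(base_pre)
  } else {
    NULL
  }
  stage_log("effects", "acute model %s; phase model %s",
            if (is.null(acute)) "skipped" else "fitted",
            if (is.null(phase_model)) "skipped" else "fitted")

  quest_effects <- if (!is.null(quest)) {
    prepost_questionnaires(score_questionnaires(quest))
  } else {
    NULL
  }

  bundle <- list(
    config = cfg, design = design, rules = rules, ema = ema,
    assignments = assignments, compliance = compliance, day_series = day,
    per_protocol = pp, individual_tests = individual, combined_test = combined,
    report = report, acute_model = acute, phase_model = phase_model,
    questionnaire_effects = quest_effects
  )

  dir <- cfg$output$dir
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(day, file.path(dir, "day_level.csv"), na = "")
    readr::write_csv(compliance, file.path(dir, "compliance.csv"), na = "")
    readr::write_csv(report, file.path(dir, "report.csv"), na = "")
    if (!is.null(combined)) {
      rand_test_json(combined, file.path(dir, "combined_test.json"))
    }
    models <- list(
      acute = if (!is.null(acute)) c(as.list(tidy(acute)),
                                     as.list(glance(acute))),
      baseline_vs_preexercise = if (!is.null(phase_model)) {
        c(as.list(tidy(phase_model)), as.list(glance(phase_model)))
      }
    )
    writeLines(jsonlite::toJSON(models, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               file.path(dir, "models.json"))
    if (!is.null(quest_effects)) {
      readr::write_csv(quest_effects, file.path(dir, "questionnaires.csv"),
                       na = "")
    }
    stage_log("write", "bundle written to %s", dir)
  }
  invisible(bundle)
}
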