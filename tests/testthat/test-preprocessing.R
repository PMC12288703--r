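make_records <- function(rows) {
  defaults <- tibble::tibble(
    participant_id = "P01", day = 1L, slot_time = "11:00",
    prompt_type = "momentary", responded = 1L, stress_pre = NA_real_,
    stress_post = NA_real_, busyness = NA_real_,
    recommended = NA_character_, engaged = NA_character_
  )
  dplyr::bind_rows(lapply(rows, function(r) {
    out <- defaults
    for (nm in names(r)) out[[nm]] <- r[[nm]]
    out
  }))
}

test_that("compliance percentages use the schedule denominator", {
  d <- study_design()
  # 30 scheduled baseline momentary prompts, 9 responded
  sched <- schedule_prompts(d, assign_phases(d, 10, "P01"))
  mom <- sched[sched$prompt_type == "momentary", ]
  rec <- make_records(lapply(seq_len(nrow(mom)), function(i) {
    list(day = mom$day[i], slot_time = mom$slot_time[i],
         responded = as.integer(mom$phase[i] == "A" && i <= 27))
  }))
  # exactly 9 responded baseline slots (first 9 baseline rows)
  rec$responded <- 0L
  base_rows <- which(rec$day <= 10)
  rec$responded[base_rows[1:9]] <- 1L
  asg <- assign_phases(d, 10, "P01")
  cc <- compute_compliance(rec, asg, phases = "A")
  expect_equal(cc$scheduled[cc$participant_id == "P01"], 30L)
  expect_equal(cc$responded[cc$participant_id == "P01"], 9L)
  expect_equal(cc$percentage[cc$participant_id == "P01"], 30)

  rec$responded <- 0L
  expect_equal(compute_compliance(rec, asg)$percentage, c(0, 0))
  rec$responded <- 1L
  expect_equal(compute_compliance(rec, asg)$percentage, c(100, 100))
})

test_that("day-level aggregation averages available reports", {
  d <- study_design()
  asg <- assign_phases(d, 10, "P01")
  rec <- make_records(list(
    list(day = 1L, slot_time = "11:00", stress_pre = 50),
    list(day = 1L, slot_time = "16:00", stress_pre = 60),
    list(day = 1L, slot_time = "21:00", responded = 0L),
    # intervention-phase day: one engaged (post), one skipped (pre fallback)
    list(day = 12L, slot_time = "11:00", stress_pre = 50, stress_post = 40,
         recommended = "breath_control", engaged = "breath_control"),
    list(day = 12L, slot_time = "16:00", stress_pre = 60,
         recommended = "breath_control", engaged = "skipped")
  ))
  day <- aggregate_daily(rec, asg)
  expect_equal(day$value[day$day == 1], 55)
  expect_true(is.na(day$value[day$day == 2]))
  expect_equal(day$value[day$day == 12], 50) # mean(40, 60)
  expect_equal(nrow(day), 28)

  strict <- aggregate_daily(rec, asg, b_phase_value = "post_only")
  expect_equal(strict$value[strict$day == 12], 40)
})

test_that("aggregation is invariant to within-day slot order", {
  d <- study_design()
  asg <- assign_phases(d, 10, "P01")
  rec <- make_records(list(
    list(day = 3L, slot_time = "11:00", stress_pre = 20),
    list(day = 3L, slot_time = "16:00", stress_pre = 80),
    list(day = 3L, slot_time = "21:00", stress_pre = 35)
  ))
  shuffled <- rec[c(3, 1, 2), ]
  expect_equal(aggregate_daily(rec, asg)$value,
               aggregate_daily(shuffled, asg)$value)
  # single-report day passes through unchanged
  one <- make_records(list(list(day = 5L, stress_pre = 42.5)))
  expect_equal(aggregate_daily(one, asg)$value[5], 42.5)
})

test_that("per-protocol filter excludes sparse phases with reasons", {
  mk_day <- function(id, nA, nB) {
    tibble::tibble(
      participant_id = id, day = 1:28,
      phase = c(rep("A", 10), rep("B", 18)),
      value = c(ifelse(seq_len(10) <= nA, 50, NA),
                ifelse(seq_len(18) <= nB, 40, NA)),
      start_day = 11L
    )
  }
  ds <- dplyr::bind_rows(mk_day("ok", 3, 3), mk_day("sparse", 9, 2),
                         mk_day("void", 0, 0))
  pp <- per_protocol_filter(ds)
  expect_setequal(unique(pp$kept$participant_id), "ok")
  expect_setequal(pp$excluded$participant_id, c("sparse", "void"))
  expect_match(pp$excluded$reason[pp$excluded$participant_id == "sparse"],
               "intervention phase")
  expect_equal(pp$excluded$reason[pp$excluded$participant_id == "void"],
               "no observations")
  # kept + excluded partition the input
  expect_setequal(c(unique(pp$kept$participant_id),
                    pp$excluded$participant_id),
                  unique(ds$participant_id))
})

test_that("questionnaire scoring applies sums and severity bands", {
  expect_equal(score_questionnaire("PHQ9", c(1, 1, 1, 1, 1, 1, 1, 0, 0))$band,
               "mild")
  z <- score_questionnaire("PHQ9", rep(0, 9))
  expect_equal(z$total, 0)
  expect_equal(z$band, "none/minimal")
  expect_equal(score_questionnaire("PHQ9", c(3, 3, 3, 3, 3, 0, 0, 0, 0))$band,
               "moderately severe")
  expect_equal(score_questionnaire("GAD7", c(3, 3, 3, 3, 3, 0, 0))$band,
               "severe") # total 15, at the cutoff
  rsq <- score_questionnaire("RSQ_brooding", rep(1, 5))
  expect_equal(rsq$total, 5)
  expect_true(is.na(rsq$band))
  expect_error(score_questionnaire("PHQ9", rep(1, 8)), "expects 9 items")
  expect_error(score_questionnaire("PSS", c(rep(1, 9), 5)), "\\[0, 4\\]")
  expect_error(score_questionnaire("XYZ", 1), "Unknown instrument")
})

test_that("endorsement counting uses the >= 4 threshold", {
  e <- count_endorsements(c(4, 5, 6, 4, 3, 2, 7, 4))
  expect_equal(e$count, 6L)
  expect_equal(e$percentage, 75)
  expect_equal(count_endorsements(rep(3, 5))$percentage, 0)
  expect_equal(count_endorsements(rep(7, 4))$percentage, 100)
  expect_error(count_endorsements(numeric(0)), "non-empty")
  expect_error(count_endorsements(c(3, 8)), "\\[1, 7\\]")
})
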