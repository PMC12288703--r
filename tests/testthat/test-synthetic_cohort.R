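test_that("simulation is seed-deterministic at every level", {
  m <- participant_model()
  d <- study_design()
  a <- assign_phases(d, 10, "P01")
  expect_identical(simulate_prompt_stream(m, a, d, seed = 7),
                   simulate_prompt_stream(m, a, d, seed = 7))
  expect_false(identical(simulate_prompt_stream(m, a, d, seed = 7),
                         simulate_prompt_stream(m, a, d, seed = 8)))
  expect_identical(generate_cohort(3, seed = 21), generate_cohort(3, seed = 21))
  expect_identical(simulate_questionnaires(m, "P01", seed = 3),
                   simulate_questionnaires(m, "P01", seed = 3))
})

test_that("noise-free limit gives a constant two-level series", {
  m <- participant_model(mu = 50, sigma = 1e-9, phi = 0, delta = 10)
  d <- study_design()
  s <- simulate_stress_series(m, assign_phases(d, 10), d, seed = 1)
  expect_equal(unique(round(s$stress[s$phase == "A"], 6)), 50)
  expect_equal(unique(round(s$stress[s$phase == "B"], 6)), 40)
})

test_that("the AR(1) phase shift hits its long-run mean", {
  m <- participant_model(mu = 45, sigma = 8, phi = 0.3, delta = 10)
  d <- study_design()
  b_vals <- unlist(lapply(1:25, function(i) {
    s <- simulate_stress_series(m, assign_phases(d, 7), d, seed = 100 + i)
    s$stress[s$phase == "B"]
  }))
  # >= 10^4 intervention-phase slots; stationary mean is mu - delta = 35
  expect_gt(length(b_vals), 1000)
  se <- sd(b_vals) / sqrt(length(b_vals) / 10) # conservative for autocorrelation
  expect_lt(abs(mean(b_vals) - 35), 3 * se + 0.2)
})

test_that("response probability drives observed compliance", {
  m <- participant_model(p_resp = 0.3)
  d <- study_design()
  n_resp <- 0L
  n_slots <- 0L
  for (i in 1:40) {
    st <- simulate_prompt_stream(m, assign_phases(d, 10, "X"), d, seed = i)
    mom <- st[st$prompt_type == "momentary", ]
    n_resp <- n_resp + sum(mom$responded)
    n_slots <- n_slots + nrow(mom)
  }
  phat <- n_resp / n_slots
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / n_slots))
})

test_that("full response with no acute effect reproduces pre at post", {
  m <- participant_model(p_resp = 1, gamma = 0, post_noise_sd = 0,
                         p_engage = 1)
  d <- study_design()
  st <- simulate_prompt_stream(m, assign_phases(d, 8, "X"), d, seed = 4)
  mom <- st[st$prompt_type == "momentary" & !is.na(st$stress_post), ]
  expect_gt(nrow(mom), 0)
  expect_equal(mom$stress_post, mom$stress_pre)
})

test_that("baseline slots are single-blind and skipped slots carry no post", {
  m <- participant_model(p_resp = 1)
  d <- study_design()
  st <- simulate_prompt_stream(m, assign_phases(d, 10, "X"), d, seed = 5)
  mom <- st[st$prompt_type == "momentary", ]
  a <- mom[mom$day <= 10, ]
  expect_true(all(is.na(a$recommended)))
  expect_true(all(is.na(a$stress_post)))
  skipped <- mom[!is.na(mom$engaged) & mom$engaged == "skipped", ]
  expect_true(all(is.na(skipped$stress_post)))
  unanswered <- mom[mom$responded == 0, ]
  expect_true(all(is.na(unanswered$stress_pre)))
})

test_that("questionnaire totals stay in range and track the change effect", {
  m <- participant_model(questionnaire_change = c(RSQ_brooding = 3.75))
  rsq_post <- numeric(400)
  for (i in seq_len(400)) {
    q <- simulate_questionnaires(m, "P", seed = 1000 + i)
    sc <- score_questionnaires(q)
    info <- jitaisim:::instrument_info()
    rng <- merge(sc, info, by = "instrument")
    expect_true(all(rng$total >= rng$n_items * rng$item_lo &
                      rng$total <= rng$n_items * rng$item_hi))
    rsq_post[i] <- sc$total[sc$instrument == "RSQ_brooding" &
                              sc$occasion == "post"]
  }
  # pre mean 13.00 minus change 3.75; the scale floor at 5 sits within one
  # SD of the target, so truncation shifts the realized mean slightly upward
  expect_lt(abs(mean(rsq_post) - 9.25), 0.75)
})

test_that("a zero change effect leaves questionnaires unchanged on average", {
  m <- participant_model(questionnaire_change = c(PHQ9 = 0),
                         change_noise_sd = 2)
  diffs <- sapply(1:300, function(i) {
    sc <- score_questionnaires(simulate_questionnaires(m, "P", seed = 5000 + i))
    sc$total[sc$instrument == "PHQ9" & sc$occasion == "pre"] -
      sc$total[sc$instrument == "PHQ9" & sc$occasion == "post"]
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.05)
})

test_that("cohorts carry ground truth and support single-participant use", {
  tr <- generate_cohort(8, seed = 31)
  expect_equal(sort(tr$assignments$baseline_length), 7:14)
  expect_equal(tr$truth$start_day, tr$assignments$start_day)

  one <- generate_cohort(1, model = participant_model(d = 0, p_resp = 1),
                         seed = 9)
  day <- aggregate_daily(one)
  res <- individual_randomization_test(day, one$design)
  expect_true(res$p_value >= 1 / 8 && res$p_value <= 1)
})

test_that("the phase effect is recoverable from a large cohort", {
  m <- participant_model(mu = 45, sigma = 12, phi = 0.3, delta = 10,
                         gamma = 0, p_resp = 1)
  tr <- generate_cohort(150, model = m, mode = "iid_uniform", seed = 77,
                        questionnaires = FALSE)
  day <- aggregate_daily(tr)
  est <- day %>%
    dplyr::group_by(participant_id, phase) %>%
    dplyr::summarise(m = mean(value, na.rm = TRUE), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = phase, values_from = m) %>%
    dplyr::summarise(d = mean(A - B)) %>%
    dplyr::pull(d)
  expect_lt(abs(est - 10), 0.5) # within 5% of the true effect
})

test_that("sliders are always clamped to the 0-100 range", {
  m <- participant_model(mu = 95, sigma = 30, phi = 0.5, delta = -20)
  d <- study_design()
  st <- simulate_prompt_stream(m, assign_phases(d, 10, "X"), d, seed = 13)
  vals <- c(st$stress_pre, st$stress_post, st$busyness)
  vals <- vals[!is.na(vals)]
  expect_true(all(vals >= 0 & vals <= 100))
})
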