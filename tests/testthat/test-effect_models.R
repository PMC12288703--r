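test_that("descriptives use the sample SD and handle edge cases", {
  d <- describe(c(52, 43, 22, 23, 23, 52, 39, 47))
  expect_equal(round(d$mean, 1), 37.6)
  expect_equal(round(d$sd, 1), 13.1)
  one <- describe(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
  expect_error(describe(numeric(0)), "at least one")
})

test_that("paired effects match the closed form and the t-test", {
  res <- paired_prepost(c(12, 17, 14, 17), c(9, 10, 11, 12))
  tt <- stats::t.test(c(12, 17, 14, 17), c(9, 10, 11, 12), paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
  expect_equal(res$dz, res$mean_diff / res$sd_diff)

  # identical pre and post is an exact null
  same <- paired_prepost(c(3, 5, 9), c(3, 5, 9))
  expect_equal(same$dz, 0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(paired_prepost(c(5, 6, 7, 8), c(4, 5, 6, 7)), "undefined")
  expect_error(paired_prepost(1:3, 1:2), "lengths differ")

  # dz is invariant to rescaling
  a <- c(20, 25, 18, 30, 24)
  b <- c(15, 21, 17, 22, 20)
  expect_equal(paired_prepost(a, b)$dz, paired_prepost(3 * a, 3 * b)$dz)
})

test_that("paired dz recovers a known standardized change", {
  set.seed(61)
  pre <- rnorm(200, 30, 5)
  post <- pre - rnorm(200, 3, 3) # mean(d) = sd(d) = 3 => dz = 1
  expect_lt(abs(paired_prepost(pre, post)$dz - 1), 0.15)
})

test_that("acute mixed model equals the grand mean difference when balanced", {
  set.seed(9)
  pairs <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:6),
                              obs = 1:5) %>%
    dplyr::mutate(stress_pre = rnorm(dplyr::n(), 50, 10),
                  stress_post = stress_pre - 5 + rnorm(dplyr::n(), 0, 2))
  fit <- suppressMessages(acute_effect_model(pairs))
  grand <- mean(pairs$stress_post - pairs$stress_pre)
  expect_equal(fit$estimate, grand, tolerance = 1e-6)
  expect_equal(fit$df_method, "Satterthwaite")
  expect_true(fit$var_between >= 0 && fit$var_residual >= 0)

  # swapping the pre/post roles flips the sign of the fixed effect
  swapped <- pairs %>%
    dplyr::rename(stress_pre = stress_post, stress_post = stress_pre)
  fit2 <- suppressMessages(acute_effect_model(swapped))
  expect_equal(fit2$estimate, -fit$estimate, tolerance = 1e-6)

  expect_error(acute_effect_model(pairs[pairs$participant_id == "P01", ]),
               ">= 2 participants")
})

test_that("the acute model recovers the generating exercise effect", {
  m <- participant_model(mu = 45, sigma = 12, phi = 0.3, delta = 0,
                         gamma = 6, p_resp = 1, p_engage = 1)
  tr <- generate_cohort(30, model = m, mode = "iid_uniform", seed = 303,
                        questionnaires = FALSE)
  pairs <- extract_exercise_pairs(tr)
  expect_gt(nrow(pairs), 200)
  fit <- suppressMessages(acute_effect_model(pairs))
  expect_lt(abs(fit$estimate - (-6)), 0.3) # bias under 5% of gamma
  expect_lt(fit$p_value, 0.001)
})

test_that("phase contrast is null in a gamma-only world", {
  m <- participant_model(mu = 45, sigma = 12, phi = 0.3, delta = 0,
                         gamma = 6, p_resp = 1, p_engage = 1)
  tr <- generate_cohort(20, model = m, mode = "iid_uniform", seed = 404,
                        questionnaires = FALSE)
  dat <- tr$ema %>%
    dplyr::filter(prompt_type == "momentary", responded == 1,
                  !is.na(stress_pre)) %>%
    dplyr::left_join(tr$assignments[, c("participant_id", "start_day")],
                     by = "participant_id") %>%
    dplyr::mutate(phase = phase_of(day, start_day)) %>%
    dplyr::select(participant_id, phase, stress = stress_pre)
  fit <- suppressMessages(baseline_vs_preexercise_model(dat))
  expect_lt(abs(fit$estimate), 3 * fit$std_error + 0.5)

  single <- dat[dat$phase == "A", ]
  expect_error(baseline_vs_preexercise_model(single), "both baseline")
})

test_that("mixed-fit tidiers expose estimates and variance components", {
  set.seed(14)
  pairs <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:5),
                              obs = 1:4) %>%
    dplyr::mutate(stress_pre = rnorm(dplyr::n(), 50, 8),
                  stress_post = stress_pre - 4 + rnorm(dplyr::n(), 0, 2))
  fit <- suppressMessages(acute_effect_model(pairs))
  td <- tidy(fit)
  expect_named(td, c("contrast", "estimate", "std_error", "df", "statistic",
                     "p_value", "cohens_dz"))
  gl <- glance(fit)
  expect_equal(gl$n_participants, 5L)
  expect_equal(gl$estimation, "maximum likelihood")
})
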