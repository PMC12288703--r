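test_that("phase mean difference matches hand arithmetic", {
  s1 <- tibble::tibble(day = 1:6, value = c(10, 10, 4, 4, 4, 4))
  expect_equal(phase_mean_difference(s1, 3), -6)
  s2 <- tibble::tibble(day = 1:6, value = c(9, 8, 1, 2, 1, 2))
  expect_equal(phase_mean_difference(s2, 3), -7)
  const <- tibble::tibble(day = 1:10, value = rep(5, 10))
  for (s in 2:10) expect_equal(phase_mean_difference(const, s), 0)
  expect_error(phase_mean_difference(s2, 1), "no observed days")
})

test_that("exhaustive individual test reproduces the worked enumeration", {
  s <- tibble::tibble(day = 1:6, value = c(9, 8, 1, 2, 1, 2))
  res <- individual_randomization_test(s, start_day = 3, starts = 3:5)
  expect_equal(sort(res$distribution),
               sort(c(-7, -13 / 3, -3.5)), tolerance = 1e-12)
  expect_equal(res$p_value, 1 / 3)
  # the maximum statistic ranks last: p = 1
  res5 <- individual_randomization_test(s, start_day = 5, starts = 3:5)
  expect_equal(res5$p_value, 1)
})

test_that("exhaustive test agrees with a brute-force oracle on random series", {
  set.seed(402)
  for (rep in 1:20) {
    n_days <- sample(10:28, 1)
    starts <- seq(4, n_days - 3)
    value <- rnorm(n_days, 50, 15)
    value[sample(n_days, sample(0:3, 1))] <- NA
    day <- seq_len(n_days)
    obs <- sample(starts, 1)
    ok <- !is.na(oracle_D(day, value, obs))
    if (!ok) next
    s <- tibble::tibble(day = day, value = value)
    got <- suppressWarnings(
      individual_randomization_test(s, start_day = obs, starts = starts))
    want <- oracle_individual(day, value, starts, obs)
    expect_equal(sort(unname(got$distribution)), sort(want$dist))
    expect_equal(got$observed_stat, want$observed)
    expect_equal(got$p_value, want$p)
  }
})

test_that("the default design floors the individual p-value at 1/8", {
  d <- study_design()
  set.seed(7)
  # strong decreasing series: the observed start should rank first
  val <- c(rnorm(10, 80, 1), rnorm(18, 10, 1))
  s <- tibble::tibble(day = 1:28, value = val)
  res <- individual_randomization_test(s, d, start_day = 11)
  expect_equal(res$p_value, 1 / 8)
  expect_equal(res$n_permutations, 8L)
})

test_that("Monte Carlo p converges to the exhaustive p", {
  s <- tibble::tibble(day = 1:6, value = c(9, 8, 1, 2, 1, 2))
  ex <- individual_randomization_test(s, start_day = 3, starts = 3:5)
  mc <- individual_randomization_test(s, start_day = 3, starts = 3:5,
                                      method = "monte_carlo", R = 4000,
                                      seed = 12)
  tol <- 3 * sqrt(ex$p_value * (1 - ex$p_value) / 4000) + 1 / 4001
  expect_lt(abs(mc$p_value - ex$p_value), tol)
  expect_gte(mc$p_value, 1 / 4001)
  # seed determinism of the sampled distribution
  mc2 <- individual_randomization_test(s, start_day = 3, starts = 3:5,
                                       method = "monte_carlo", R = 4000,
                                       seed = 12)
  expect_identical(mc$distribution, mc2$distribution)
})

test_that("combined exhaustive test enumerates the joint space", {
  s1 <- tibble::tibble(participant_id = "a", day = 1:6,
                       value = c(9, 8, 1, 2, 1, 2), start_day = 3L)
  s2 <- tibble::tibble(participant_id = "b", day = 1:6,
                       value = c(7, 9, 8, 2, 1, 3), start_day = 4L)
  res <- combined_randomization_test(dplyr::bind_rows(s1, s2), starts = 3:5)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_permutations, 9L)
  want <- oracle_combined(list(s1, s2), 3:5, c(3, 4))
  expect_equal(sort(res$distribution), sort(want$dist))
  expect_equal(res$observed_stat, want$observed)
  expect_equal(res$p_value, want$p)
  expect_error(combined_randomization_test(s1), "at least 2")
})

test_that("large joint spaces fall back to Monte Carlo under the cap", {
  d <- study_design()
  m <- participant_model(d = 0, p_resp = 1)
  tr <- generate_cohort(7, model = m, seed = 55, questionnaires = FALSE)
  day <- aggregate_daily(tr)
  res <- combined_randomization_test(day, d, R = 500, seed = 2)
  # 8^7 joint assignments exceed the default exhaustive cap
  expect_equal(res$method, "monte_carlo")
  expect_equal(res$n_permutations, 500L)
  expect_gte(res$p_value, 1 / 501)
})

test_that("the statistic and p are invariant to location shifts", {
  set.seed(118)
  s <- tibble::tibble(participant_id = "a", day = 1:12,
                      value = rnorm(12, 40, 5), start_day = 6L)
  s$value[4] <- NA
  base <- individual_randomization_test(s, starts = 4:8)
  shift <- s
  shift$value <- shift$value + 25
  moved <- individual_randomization_test(shift, starts = 4:8)
  expect_equal(moved$observed_stat, base$observed_stat)
  expect_equal(moved$p_value, base$p_value)
})

test_that("infeasible permuted starts are dropped with a warning", {
  s <- tibble::tibble(day = 1:8, value = c(10, 9, NA, NA, NA, NA, 3, 2))
  # start 7 leaves days {1,2} vs {7,8}; start 3 leaves an empty A side? no:
  # start 3 -> A = {1,2}, B = {7,8}. Start 8 -> B = {8} fine. Use missing tail:
  s2 <- tibble::tibble(day = 1:8, value = c(10, 9, 8, 7, 6, NA, NA, NA))
  expect_warning(
    res <- individual_randomization_test(s2, start_day = 3, starts = 3:8),
    "infeasible"
  )
  expect_equal(res$n_permutations, 3L) # starts 6,7,8 leave an empty B side
})

test_that("tidy and glance expose the test metadata", {
  s <- tibble::tibble(participant_id = "a", day = 1:6,
                      value = c(9, 8, 1, 2, 1, 2), start_day = 3L)
  res <- individual_randomization_test(s, starts = 3:5)
  td <- tidy(res)
  expect_equal(td$statistic, -7)
  expect_equal(td$p_value, 1 / 3)
  expect_equal(td$method, "exhaustive")
  expect_equal(glance(res), td)
  js <- jsonlite::fromJSON(rand_test_json(res))
  expect_equal(js$p_value, 1 / 3)
})
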