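#' Parameterize one simulated participant
#'
#' The data-generating process for momentary stress is an AR(1) process
#' around a person-specific mean with a level shift in the intervention
#' phase: latent stress follows
#' `X_t = mu + phi * (X_{t-1} - mu) + e_t`, `e_t ~ N(0, sigma^2)`, with
#' `delta` slider units subtracted throughout phase B, and observed sliders
#' clamped to `[0, 100]`. The phase effect can equivalently be given as a
#' standardized `d`, converted via the stationary marginal SD
#' `sigma / sqrt(1 - phi^2)` so `d` is comparable across `phi` settings.
#' Engaged exercises additionally drop stress acutely by `gamma` units from
#' the pre- to the post-exercise report.
#'
#' Non-response is Bernoulli per scheduled prompt
#' (missing-completely-at-random); `p_resp` may be a single probability or a
#' named pair `c(A = , B = )` for phase-specific compliance. Defaults emulate
#' a moderately stressed community cohort prompted three times daily for 28
#' days: person mean 45, marginal spread near 19 slider units, lag-1
#' autocorrelation 0.3, momentary compliance 76% (baseline) / 60%
#' (intervention), morning compliance 44%, and a phase effect of d = 0.8.
#'
#' @param mu Person mean of the latent stress process (slider units).
#' @param sigma Innovation SD of the AR(1) process (> 0).
#' @param phi Lag-1 autocorrelation across consecutive momentary slots,
#'   `|phi| < 1`.
#' @param delta Phase-level intervention effect in slider units (subtracted
#'   throughout phase B). Ignored when `d` is given.
#' @param d Standardized phase effect; when non-`NULL`,
#'   `delta = d * sigma / sqrt(1 - phi^2)`.
#' @param gamma Acute pre-to-post exercise drop in slider units.
#' @param p_resp Momentary response probability; scalar or `c(A = , B = )`.
#' @param p_resp_morning Morning-cue response probability.
#' @param p_engage Probability of performing a recommended exercise (else the
#'   opportunity is skipped).
#' @param p_spont Probability of spontaneously performing an exercise when
#'   none was recommended.
#' @param post_noise_sd SD of the noise added to the post-exercise report.
#' @param busyness_mean,busyness_sd Mean and SD of the daily busyness
#'   forecast slider.
#' @param questionnaire_change Named numeric vector of pre-to-post changes in
#'   instrument totals (positive = improvement); names must be instruments
#'   known to [score_questionnaire()]. Default: a brooding (RSQ) reduction of
#'   3.75 points, no change elsewhere.
#' @param change_noise_sd SD of the individual deviation around the
#'   questionnaire change effect.
#'
#' @return An object of class `participant_model` (a validated list; also
#'   stores the implied `delta` and `d`).
#' @examples
#' participant_model(d = 1, phi = 0)
#' @export
participant_model <- function(mu = 45, sigma = 18, phi = 0.3,
                              delta = NULL, d = NULL, gamma = 5,
                              p_resp = c(A = 0.76, B = 0.60),
                              p_resp_morning = 0.44,
                              p_engage = 0.8, p_spont = 0.05,
                              post_noise_sd = 3,
                              busyness_mean = 40, busyness_sd = 20,
                              questionnaire_change = c(RSQ_brooding = 3.75),
                              change_noise_sd = 3.2) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (abs(phi) >= 1) abort("`phi` must satisfy |phi| < 1.")
  stationary_sd <- sigma / sqrt(1 - phi^2)
  if (!is.null(d)) {
    delta <- d * stationary_sd
  } else {
    if (is.null(delta)) d <- 0.8 else d <- delta / stationary_sd
    if (is.null(delta)) delta <- d * stationary_sd
  }
  if (length(p_resp) == 1) p_resp <- c(A = unname(p_resp), B = unname(p_resp))
  if (!all(c("A", "B") %in% names(p_resp))) {
    abort("`p_resp` must be a scalar or a named c(A=, B=) pair.")
  }
  probs <- c(p_resp, p_resp_morning, p_engage, p_spont)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  known <- instrument_info()$instrument
  if (length(questionnaire_change) &&
      !all(names(questionnaire_change) %in% known)) {
    abort("Unknown instrument in `questionnaire_change`.")
  }
  structure(
    list(mu = mu, sigma = sigma, phi = phi, delta = delta, d = d,
         stationary_sd = stationary_sd, gamma = gamma,
         p_resp = p_resp[c("A", "B")], p_resp_morning = p_resp_morning,
         p_engage = p_engage, p_spont = p_spont,
         post_noise_sd = post_noise_sd,
         busyness_mean = busyness_mean, busyness_sd = busyness_sd,
         questionnaire_change = questionnaire_change,
         change_noise_sd = change_noise_sd),
    class = "participant_model"
  )
}

#' Simulate the latent momentary stress series for one participant
#'
#' Generates the AR(1)-around-mean latent process at every momentary slot
#' (three per day), starting from its stationary distribution, subtracts the
#' phase effect `delta` throughout phase B, and clamps to the 0--100 slider.
#'
#' @param model A [participant_model()].
#' @param assignment One-row assignment tibble from [assign_phases()].
#' @param design A [study_design()].
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per momentary slot: `day`, `slot_time`,
#'   `phase`, `latent` (pre-clamp) and `stress` (clamped).
#' @export
simulate_stress_series <- function(model, assignment, design = study_design(),
                                   seed = NULL) {
  stopifnot(inherits(model, "participant_model"))
  slots <- tidyr::expand_grid(day = seq_len(design$total_days),
                              slot_time = design$momentary_times)
  n <- nrow(slots)
  phase <- phase_of(slots$day, assignment$start_day)
  with_seed(seed, {
    dev1 <- rnorm(1, 0, model$stationary_sd)
    eps <- rnorm(n, 0, model$sigma)
    dev <- as.numeric(stats::filter(c(dev1, eps[-1]), model$phi,
                                    method = "recursive"))
    latent <- model$mu + dev - model$delta * (phase == "B")
    tibble(day = slots$day, slot_time = slots$slot_time, phase = phase,
           latent = latent, stress = clamp01(latent))
  })
}

#' Simulate the full prompt stream for one participant
#'
#' Expands the participant's prompt schedule and fills it with simulated
#' behaviour: Bernoulli response per scheduled prompt, decision-rule
#' recommendations on responded intervention-phase slots (baseline slots are
#' single-blind and carry no recommendation), engagement with probability
#' `p_engage`, and a post-exercise stress report
#' `clamp(stress_pre - gamma + noise)` whenever an exercise was performed.
#' Morning busyness forecasts drive the evening recommendation, which is
#' engaged with the intervention-phase response probability.
#'
#' @inheritParams simulate_stress_series
#' @param rules Decision-rule tibble from [decision_rules()].
#'
#' @return An EMA record tibble (one row per scheduled slot) in the schema of
#'   [read_ema_table()].
#' @export
simulate_prompt_stream <- function(model, assignment, design = study_design(),
                                   rules = decision_rules(), seed = NULL) {
  stopifnot(inherits(model, "participant_model"))
  with_seed(seed, {
    series <- simulate_stress_series(model, assignment, design, seed = NULL)
    n <- nrow(series)
    is_b <- series$phase == "B"
    p <- unname(model$p_resp[ifelse(is_b, "B", "A")])
    responded <- runif(n) < p

    stress_pre <- ifelse(responded, series$stress, NA_real_)
    recommended <- rep(NA_character_, n)
    recommended[responded & is_b] <-
      recommend_momentary(stress_pre[responded & is_b], rules)

    eng_u <- runif(n)
    spont_pool <- exercise_catalog()$exercise_id[
      exercise_catalog()$cue_type == "momentary"]
    spont_pick <- sample(spont_pool, n, replace = TRUE)
    engaged <- rep(NA_character_, n)
    has_rec <- !is.na(recommended) & recommended != "none"
    no_rec <- !is.na(recommended) & recommended == "none"
    engaged[has_rec] <- ifelse(eng_u[has_rec] < model$p_engage,
                               recommended[has_rec], "skipped")
    engaged[no_rec] <- ifelse(eng_u[no_rec] < model$p_spont,
                              spont_pick[no_rec], "skipped")

    did_ex <- !is.na(engaged) & engaged != "skipped"
    post_eps <- rnorm(n, 0, model$post_noise_sd)
    stress_post <- rep(NA_real_, n)
    stress_post[did_ex] <-
      clamp01(stress_pre[did_ex] - model$gamma + post_eps[did_ex])

    momentary <- tibble(
      participant_id = assignment$participant_id,
      day = series$day, slot_time = series$slot_time,
      prompt_type = "momentary",
      responded = as.integer(responded),
      stress_pre = stress_pre, stress_post = stress_post,
      busyness = NA_real_, recommended = recommended, engaged = engaged
    )

    days <- seq_len(design$total_days)
    day_b <- phase_of(days, assignment$start_day) == "B"
    busy <- clamp01(rnorm(design$total_days, model$busyness_mean,
                          model$busyness_sd))
    resp_m <- runif(design$total_days) < model$p_resp_morning
    busy_obs <- ifelse(resp_m, busy, NA_real_)
    rec_eve <- rep(NA_character_, design$total_days)
    rec_eve[resp_m & day_b] <- recommend_morning(busy_obs[resp_m & day_b], rules)

    morning <- tibble(
      participant_id = assignment$participant_id,
      day = days, slot_time = design$morning_time, prompt_type = "morning",
      responded = as.integer(resp_m),
      stress_pre = NA_real_, stress_post = NA_real_,
      busyness = busy_obs, recommended = rec_eve, engaged = NA_character_
    )

    eve_u <- runif(design$total_days)
    eve_has_rec <- !is.na(rec_eve) & rec_eve != "none"
    eve_engaged <- rep(NA_character_, design$total_days)
    eve_engaged[eve_has_rec] <-
      ifelse(eve_u[eve_has_rec] < model$p_resp[["B"]],
             rec_eve[eve_has_rec], "skipped")
    evening <- tibble(
      participant_id = assignment$participant_id,
      day = days, slot_time = design$evening_delivery_time,
      prompt_type = "evening_delivery",
      responded = as.integer(eve_has_rec & eve_engaged != "skipped"),
      stress_pre = NA_real_, stress_post = NA_real_,
      busyness = NA_real_,
      recommended = ifelse(eve_has_rec, rec_eve, NA_character_),
      engaged = eve_engaged
    )

    bind_rows(morning, momentary, evening) %>%
      arrange(.data$day, clock_minutes(.data$slot_time))
  })
}

#' Simulate pre/post questionnaire item responses for one participant
#'
#' Pre-intervention totals are drawn near published cohort marginals for each
#' instrument, post totals subtract the instrument's change effect plus
#' individual noise, and both are truncated to the instrument's valid range
#' before being distributed over items.
#'
#' @inheritParams simulate_stress_series
#' @param participant_id Identifier carried into the output.
#'
#' @return A long tibble `participant_id, instrument, item_index, response,
#'   occasion` with `occasion` in `pre`/`post`.
#' @export
simulate_questionnaires <- function(model, participant_id = "P01", seed = NULL) {
  stopifnot(inherits(model, "participant_model"))
  info <- instrument_info()
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(info)), function(i) {
      inst <- info$instrument[i]
      k <- info$n_items[i]
      lo <- k * info$item_lo[i]
      hi <- k * info$item_hi[i]
      pre_total <- round(clamp01(rnorm(1, info$pre_mean[i], info$pre_sd[i]),
                                 lo, hi))
      change <- model$questionnaire_change[inst]
      change <- if (is.na(change) || is.null(change)) 0 else unname(change)
      post_total <- round(clamp01(pre_total - change +
                                    rnorm(1, 0, model$change_noise_sd),
                                  lo, hi))
      bind_rows(
        tibble(occasion = "pre", item_index = seq_len(k),
               response = distribute_total(pre_total, k, info$item_lo[i],
                                           info$item_hi[i])),
        tibble(occasion = "post", item_index = seq_len(k),
               response = distribute_total(post_total, k, info$item_lo[i],
                                           info$item_hi[i]))
      ) %>%
        mutate(participant_id = participant_id, instrument = inst) %>%
        select("participant_id", "instrument", "item_index", "response",
               "occasion")
    })
  })
}

# split an in-range total over k items, each within [lo, hi]
distribute_total <- function(total, k, lo, hi) {
  stopifnot(total >= k * lo, total <= k * hi)
  base <- total %/% k
  rem <- total %% k
  items <- rep(base, k)
  if (rem > 0) items[seq_len(rem)] <- items[seq_len(rem)] + 1L
  # a valid redistribution always exists because total is in range
  while (any(items > hi)) {
    i <- which.max(items); j <- which.min(items)
    items[i] <- items[i] - 1L; items[j] <- items[j] + 1L
  }
  while (any(items < lo)) {
    i <- which.min(items); j <- which.max(items)
    items[i] <- items[i] + 1L; items[j] <- items[j] - 1L
  }
  as.integer(sample(items))
}

#' Generate a complete synthetic JITAI trial
#'
#' Draws randomized baseline lengths for `n` participants, simulates each
#' participant's full prompt stream and questionnaires, and returns the
#' bundle together with the ground-truth parameters that produced it, so
#' downstream estimators can be checked for recovery.
#'
#' @param n Number of participants.
#' @param design A [study_design()].
#' @param rules Decision-rule tibble from [decision_rules()].
#' @param model A single [participant_model()] applied to everyone, or a list
#'   of `n` models.
#' @param mode Baseline assignment mode, see [draw_baseline_lengths()].
#' @param seed Optional integer seed; participant-level seeds are derived
#'   from it.
#' @param questionnaires Simulate pre/post questionnaires too? Default `TRUE`.
#'
#' @return An object of class `sim_trial`: a list with tibbles `ema`,
#'   `questionnaires`, `assignments`, `truth`, plus the `design`, `rules` and
#'   `seed` used.
#' @examples
#' trial <- generate_cohort(n = 2, seed = 42)
#' dplyr::count(trial$ema, prompt_type)
#' @export
generate_cohort <- function(n = 8, design = study_design(),
                            rules = decision_rules(),
                            model = participant_model(),
                            mode = c("balanced_permutation", "iid_uniform"),
                            seed = NULL, questionnaires = TRUE) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1) abort("`n` must be a positive integer.")
  models <- if (inherits(model, "participant_model")) {
    rep(list(model), n)
  } else {
    stopifnot(is.list(model), length(model) == n)
    model
  }
  ids <- sprintf("P%02d", seq_len(n))
  seeds <- derive_seeds(seed, 2L * n + 1L)
  lengths <- draw_baseline_lengths(design, n, mode, seed = seeds[[1]])
  assignments <- purrr::map2_dfr(ids, lengths,
                                 ~ assign_phases(design, .y, .x))
  ema <- purrr::map_dfr(seq_len(n), function(i) {
    simulate_prompt_stream(models[[i]], assignments[i, ], design, rules,
                           seed = seeds[[1L + i]])
  })
  quest <- if (questionnaires) {
    purrr::map_dfr(seq_len(n), function(i) {
      simulate_questionnaires(models[[i]], ids[i], seed = seeds[[1L + n + i]])
    })
  } else {
    NULL
  }
  truth <- purrr::map_dfr(seq_len(n), function(i) {
    m <- models[[i]]
    tibble(participant_id = ids[i], baseline_length = lengths[i],
           start_day = lengths[i] + 1L, mu = m$mu, sigma = m$sigma,
           phi = m$phi, delta = m$delta, d = m$d, gamma = m$gamma,
           p_resp_A = m$p_resp[["A"]], p_resp_B = m$p_resp[["B"]])
  })
  structure(
    list(ema = ema, questionnaires = quest, assignments = assignments,
         truth = truth, design = design, rules = rules, seed = seed),
    class = "sim_trial"
  )
}

#' @export
print.sim_trial <- function(x, ...) {
  cat("Synthetic JITAI trial:", nrow(x$assignments), "participants,",
      x$design$total_days, "days\n")
  cat("  EMA records:", nrow(x$ema), "\n")
  cat("  baseline lengths:",
      paste(x$assignments$baseline_length, collapse = ", "), "\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}
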