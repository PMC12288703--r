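#' Specify a Monte Carlo operating-characteristics run
#'
#' Bundles the design, the data-generating conditions and the Monte Carlo
#' budgets for [estimate_rejection_rate()]. The standardized effect `d` maps
#' to a slider-unit phase effect via the stationary marginal SD of the AR(1)
#' process, so `d` is comparable across `phi` settings. Baseline lengths are
#' drawn iid-uniform over the design's admissible range, the randomization
#' scheme the combined test assumes.
#'
#' `R = 500` permutations per test keeps replicate loops tractable; a single
#' confirmatory analysis would typically use 5000.
#'
#' @param n_participants Cohort size per replicate.
#' @param d Standardized phase effect (0 = null).
#' @param design A [study_design()].
#' @param phi Lag-1 autocorrelation of the latent stress process.
#' @param p_resp Momentary response probability (scalar or `c(A=,B=)`).
#' @param n_replicates Number of simulated trials.
#' @param R Monte Carlo permutations per combined test.
#' @param alpha Significance level.
#' @param sigma Innovation SD of the latent process.
#' @param mu Person mean of the latent process.
#' @param gamma Acute exercise effect passed to the generator.
#' @param rules Decision-rule tibble used by the generator.
#' @param seed Base seed; replicate seeds are derived from it.
#'
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_participants = 10, d = 1.0,
                            design = study_design(), phi = 0,
                            p_resp = 1, n_replicates = 200, R = 500,
                            alpha = 0.05, sigma = 18, mu = 45, gamma = 0,
                            rules = decision_rules(), seed = NULL) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (n_participants < 2) abort("The combined test needs >= 2 participants.")
  structure(
    list(n_participants = as.integer(n_participants), d = d, design = design,
         phi = phi, p_resp = p_resp, n_replicates = as.integer(n_replicates),
         R = as.integer(R), alpha = alpha, sigma = sigma, mu = mu,
         gamma = gamma, rules = rules, seed = seed),
    class = "simulation_spec"
  )
}

#' Estimate the rejection rate of the combined randomization test
#'
#' Each replicate generates a synthetic cohort under the spec's conditions,
#' aggregates to day level, applies the per-protocol filter, and runs the
#' combined multiple-baseline randomization test (alternative `"less"`,
#' Monte Carlo with `R` permutations). The rejection rate is the fraction of
#' replicates with `p <= alpha`: the type-I error rate when `d = 0`, the
#' power otherwise.
#'
#' @param spec A [simulation_spec()].
#' @return A one-row tibble with `rate`, normal-approximation 95% interval
#'   (`ci_lower`, `ci_upper`), and the run conditions; the per-replicate
#'   p-value log is attached as attribute `"replicates"`.
#' @examples
#' \donttest{
#' spec <- simulation_spec(n_participants = 6, d = 1, n_replicates = 20,
#'                         R = 200, seed = 1)
#' estimate_rejection_rate(spec)
#' }
#' @export
estimate_rejection_rate <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  model <- participant_model(mu = spec$mu, sigma = spec$sigma, phi = spec$phi,
                             d = spec$d, gamma = spec$gamma,
                             p_resp = spec$p_resp)
  seeds <- derive_seeds(spec$seed, spec$n_replicates)
  pvals <- purrr::map_dbl(seq_len(spec$n_replicates), function(i) {
    rep_seeds <- derive_seeds(seeds[[i]], 2L)
    trial <- generate_cohort(spec$n_participants, spec$design, spec$rules,
                             model = model, mode = "iid_uniform",
                             seed = rep_seeds[[1]], questionnaires = FALSE)
    day <- aggregate_daily(trial)
    keep <- per_protocol_filter(day)$kept
    if (length(unique(keep$participant_id)) < 2) return(NA_real_)
    combined_randomization_test(keep, spec$design, method = "monte_carlo",
                                R = spec$R, seed = rep_seeds[[2]])$p_value
  })
  log <- tibble(replicate = seq_along(pvals), p_value = pvals)
  done <- pvals[!is.na(pvals)]
  if (length(done) == 0) abort("All replicates were infeasible.")
  rate <- mean(done <= spec$alpha)
  se <- sqrt(rate * (1 - rate) / length(done))
  out <- tibble(
    n_participants = spec$n_participants, d = spec$d, phi = spec$phi,
    alpha = spec$alpha, n_replicates = length(done), R = spec$R,
    rate = rate,
    ci_lower = max(0, rate - 1.96 * se),
    ci_upper = min(1, rate + 1.96 * se)
  )
  attr(out, "replicates") <- log
  class(out) <- c("rejection_rate", class(out))
  out
}

#' Power curve over a grid of effect sizes and cohort sizes
#'
#' Runs [estimate_rejection_rate()] for every combination of `d` and
#' `n_participants`, deriving a distinct cell seed from the base seed so
#' cells are independent yet reproducible.
#'
#' @param d Numeric vector of standardized effects.
#' @param n_participants Integer vector of cohort sizes.
#' @param ... Further arguments to [simulation_spec()] shared by all cells.
#' @param seed Base seed.
#' @return A tibble of class `power_curve`, one row per grid cell.
#' @export
power_curve <- function(d = c(0, 0.6, 1.0), n_participants = c(6, 10),
                        ..., seed = NULL) {
  grid <- tidyr::expand_grid(d = d, n_participants = n_participants)
  if (nrow(grid) == 0) abort("Empty grid.")
  seeds <- derive_seeds(seed, nrow(grid))
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    spec <- simulation_spec(n_participants = grid$n_participants[i],
                            d = grid$d[i], ..., seed = seeds[[i]])
    estimate_rejection_rate(spec)
  })
  class(out) <- c("power_curve", class(out))
  out
}
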