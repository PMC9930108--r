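#' Landscape for the strategy-comparison experiment
#'
#' Draws seeded 2-D three-well landscapes until one is found whose global
#' minimum lies outside the given d1 restriction window by at least `margin`
#' degrees while at least one other well sits comfortably inside the window
#' — the configuration in which a restricted-domain search must settle for
#' the best in-window minimum while the full-domain strategies can reach the
#' true one. The landscape also carries one failure box and one clash box so
#' that both clash-handling pathways are exercised during the runs.
#'
#' @param seed replicate seed; sub-draws are derived deterministically.
#' @param window d1 restriction window in degrees.
#' @param margin minimum distance of the global-minimum d1 outside the
#'   window (degrees).
#' @return A `synthetic_landscape`.
#' @export
make_strategy_comparison_landscape <- function(seed, window = c(70, 210),
                                               margin = 80) {
  for (k in 0:500) {
    ls <- make_synthetic_landscape(2, 3, n_failure_regions = 1,
                                   failure_fraction = 0.1,
                                   n_clash_regions = 1, clash_fraction = 0.1,
                                   seed = seed * 1000 + k)
    gm <- ls$global_min[1]
    outside <- !(gm >= window[1] - margin && gm <= window[2] + margin)
    inside <- any(ls$centers[, 1] >= window[1] + 10 &
                  ls$centers[, 1] <= window[2] - 10)
    if (outside && inside) return(ls)
  }
  stop("could not draw a landscape with the required well placement")
}

# max per-dimension periodic angular difference (degrees)
max_periodic_diff <- function(a, b) max(abs(wrap180(a - b)))

#' Strategy-comparison experiment (one replicate)
#'
#' On a [make_strategy_comparison_landscape()] landscape, runs the three
#' clash strategies at the same budget through the full workflow — active
#' learning, surrogate-minima extraction, backend refinement, duplicate
#' purging — and reports, for each strategy, the distance (max per-dimension
#' periodic difference, degrees) from its lowest-energy refined conformer to
#' the planted global minimum. Ranking refined energies rather than raw
#' surrogate predictions is what the method prescribes: surrogate artifacts
#' (e.g. undershoot next to constant-substitution cliffs) refine away on the
#' true surface.
#'
#' @param seed replicate seed.
#' @param iterations acquisition budget per run.
#' @param window d1 restriction window for the restricted-domain strategy.
#' @return One-row data frame with columns `err_i`, `err_ii`, `err_iii`
#'   (degrees) and `true_d1` (the global minimum's d1).
#' @export
run_strategy_comparison <- function(seed, iterations = 150,
                                    window = c(70, 210)) {
  ls <- make_strategy_comparison_landscape(seed, window)
  err <- function(mode, rb = NULL) {
    pol <- clash_policy(mode, restricted_bounds = rb)
    run <- suppressWarnings(run_active_learning(
      ls, pol, bo_config(iterations = iterations, seed = seed,
                         track_predicted_min = FALSE)))
    recs <- suppressWarnings(conformer_pipeline(run, ls, policy = pol,
                                                n_starts = 40, seed = seed))
    if (nrow(recs) == 0) return(Inf)
    best <- as.numeric(recs[1, paste0("d", seq_len(ls$dimension))])
    max_periodic_diff(best, ls$global_min)
  }
  data.frame(
    err_i = err("restricted_domain", rbind(window, c(NA, NA))),
    err_ii = err("safe_distance"),
    err_iii = err("energy_transform"),
    true_d1 = ls$global_min[1]
  )
}

#' Clash-avoidance experiment (one replicate)
#'
#' On a seeded 2-D landscape with a failure region covering 20% of the
#' domain, compares the energy-transform strategy against the no-strategy
#' baseline (failed evaluations simply yield no training point) and reports
#' each arm's proposal rate inside the failure region after the burn-in
#' iteration.
#'
#' @param seed replicate seed.
#' @param iterations acquisition budget.
#' @param after burn-in: proposals at iterations strictly greater than this
#'   count toward the rate.
#' @return One-row data frame with `rate_iii` and `rate_none`.
#' @export
run_clash_avoidance <- function(seed, iterations = 100, after = 50) {
  ls <- make_synthetic_landscape(2, 3, n_failure_regions = 1,
                                 failure_fraction = 0.2, seed = seed * 1000)
  rate <- function(mode) {
    pol <- clash_policy(mode)
    run <- suppressWarnings(run_active_learning(
      ls, pol, bo_config(iterations = iterations, seed = seed,
                         track_predicted_min = FALSE)))
    tr <- run$trace[run$trace$iter > after, ]
    dcols <- paste0("d", seq_len(ls$dimension))
    inside <- apply(as.matrix(tr[, dcols]), 1, in_any_box,
                    boxes = ls$failure_regions)
    mean(inside)
  }
  data.frame(rate_iii = rate("energy_transform"), rate_none = rate("none"))
}

#' Lengthscale-recovery experiment (one replicate)
#'
#' Simulates `n` observations from a 1-D periodic GP with known
#' hyperparameters, refits the surrogate, and reports the recovered
#' lengthscale.
#'
#' @param seed replicate seed.
#' @param n number of training points.
#' @param ell_true true lengthscale in degrees.
#' @param sf2_true true signal variance in eV^2.
#' @param noise observation-noise variance used both to simulate and to fit.
#' @return One-row data frame with `ell_true`, `ell_hat` and `ratio`.
#' @export
run_lengthscale_recovery <- function(seed, n = 60, ell_true = 40,
                                     sf2_true = 1.0, noise = 1e-4) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  X <- matrix(stats::runif(n, 0, 360), ncol = 1)
  feats <- kernel_features(X, X, periodic = TRUE)
  K <- kernel_from_features(feats, sf2_true, ell_true) + diag(noise, n)
  y <- drop(crossprod(chol(K), stats::rnorm(n)))
  fit <- fit_gp(X, y, periodic = TRUE, noise = noise, n_starts = 3)
  data.frame(ell_true = ell_true, ell_hat = fit$hyp$ell[1],
             ratio = fit$hyp$ell[1] / ell_true)
}

#' End-to-end minima-recovery experiment
#'
#' Runs the full search pipeline on a seeded 2-D landscape with `k` planted
#' wells and reports the recovered unique conformers next to the planted
#' centers.
#'
#' @param seed replicate seed.
#' @param k number of planted wells (<= 5).
#' @param iterations acquisition budget.
#' @param energy_window conformers within this window above the lowest
#'   refined energy are kept (eV); the default comfortably covers every
#'   planted well depth while excluding baseline plateau artifacts.
#' @return List with `landscape`, `records` (ranked conformer table) and
#'   `match` (for each planted center, the distance in degrees to the
#'   closest record).
#' @export
run_minima_recovery <- function(seed, k = 4, iterations = 200,
                                energy_window = 0.6) {
  ls <- make_synthetic_landscape(2, k, seed = seed)
  pol <- clash_policy("energy_transform")
  run <- run_active_learning(ls, pol,
                             bo_config(iterations = iterations, seed = seed,
                                       track_predicted_min = FALSE))
  recs <- conformer_pipeline(run, ls, policy = pol,
                             energy_window = energy_window,
                             n_starts = 60, seed = seed)
  match <- vapply(seq_len(k), function(i) {
    if (nrow(recs) == 0) return(Inf)
    min(vapply(seq_len(nrow(recs)), function(r) {
      max_periodic_diff(as.numeric(recs[r, c("d1", "d2")]), ls$centers[i, ])
    }, numeric(1)))
  }, numeric(1))
  list(landscape = ls, records = recs, match = match)
}
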