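#' Active-learning run configuration
#'
#' @param iterations acquisition budget after the initial design.
#' @param seed integer seed governing every stochastic step of the run.
#' @param init_design size of the uniform-random initial design; default
#'   `5 + d`, resolved at run time.
#' @param kappa_delta confidence parameter of the eLCB schedule.
#' @param n_candidates,n_polish acquisition-optimizer effort per iteration.
#' @param refit_full_until refit hyperparameters every iteration while the
#'   training set is at most this large ...
#' @param refit_every ... then every this many iterations.
#' @param track_predicted_min record the surrogate's predicted global minimum
#'   each iteration (needed for convergence diagnostics; adds cost).
#' @return A `bo_config` object.
#' @export
bo_config <- function(iterations = 1000, seed = 1, init_design = NULL,
                      kappa_delta = 0.1, n_candidates = 300, n_polish = 3,
                      refit_full_until = 50, refit_every = 5,
                      track_predicted_min = TRUE) {
  stopifnot(iterations >= 0)
  structure(list(iterations = iterations, seed = as.integer(seed),
                 init_design = init_design, kappa_delta = kappa_delta,
                 n_candidates = n_candidates, n_polish = n_polish,
                 refit_full_until = refit_full_until,
                 refit_every = refit_every,
                 track_predicted_min = track_predicted_min),
            class = "bo_config")
}

#' Search domain of a run
#'
#' Bounds and periodicity per torsion, derived from a `torsion_spec` or a
#' `synthetic_landscape` (full 360-degree periodic box).
#'
#' @param x a `torsion_spec` or `synthetic_landscape`.
#' @return List with `bounds` (d x 2 matrix, degrees) and `periodic`.
#' @export
search_domain <- function(x) {
  if (inherits(x, "torsion_spec")) {
    list(bounds = cbind(x$lower, x$upper), periodic = x$periodic)
  } else if (inherits(x, "synthetic_landscape")) {
    d <- x$dimension
    list(bounds = cbind(rep(0, d), rep(360, d)), periodic = rep(TRUE, d))
  } else stop("cannot derive a search domain from this object")
}

#' Run the active-learning conformer search loop
#'
#' Executes the iterative surrogate refinement: a uniform-random initial
#' design, then repeated cycles of GP (re)fitting, eLCB minimization,
#' evaluation through the active clash policy, and training-set update.
#' Backend failures are absorbed by the policy and never abort the loop. The
#' whole run is reproducible from `config$seed`.
#'
#' @param backend energy backend (`synthetic_landscape` or `energy_backend`).
#' @param policy a [clash_policy()].
#' @param config a [bo_config()].
#' @param domain optional domain override (see [search_domain()]); defaults
#'   to the backend's own domain. Under a `restricted_domain` policy the
#'   restriction in `policy$restricted_bounds` is applied here.
#' @return List of class `bo_run` with elements `model` (final `gp_model`),
#'   `trace` (per-iteration data frame: proposal, raw energy, training
#'   target, provenance, best observed raw energy, hyperparameters and the
#'   predicted global minimum), `X`, `targets`, `raw`, `provenance`,
#'   `domain`.
#' @export
run_active_learning <- function(backend, policy, config, domain = NULL) {
  if (is.null(domain)) domain <- search_domain(backend)
  if (policy$mode == "restricted_domain" && !is.null(policy$restricted_bounds)) {
    rb <- matrix(policy$restricted_bounds, ncol = 2)
    for (i in seq_len(nrow(rb))) {
      if (!is.na(rb[i, 1])) {
        domain$bounds[i, ] <- rb[i, ]
        domain$periodic[i] <- (rb[i, 2] - rb[i, 1]) >= 360
      }
    }
  }
  d <- nrow(domain$bounds)
  n_init <- if (is.null(config$init_design)) 5 + d else config$init_design

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  span <- domain$bounds[, 2] - domain$bounds[, 1]
  draw <- function() domain$bounds[, 1] + stats::runif(d) * span

  X <- matrix(numeric(0), ncol = d)
  targets <- numeric(0); raw <- numeric(0); prov <- character(0)
  add_point <- function(x, rec) {
    X <<- rbind(X, x)
    targets <<- c(targets, rec$e_new)
    raw <<- c(raw, rec$raw_energy)
    prov <<- c(prov, rec$provenance)
  }

  # initial design: redraw on policy-absorbed NULLs (mode "none" failures)
  attempts <- 0
  while (nrow(X) < n_init && attempts < 50 * n_init) {
    x <- draw()
    rec <- apply_policy(x, backend, policy)
    if (!is.null(rec)) add_point(x, rec)
    attempts <- attempts + 1
  }
  if (nrow(X) < 2) stop("initial design could not collect two valid evaluations")

  trace <- vector("list", config$iterations)
  model <- fit_gp(X, targets, domain$periodic)
  for (n in seq_len(config$iterations)) {
    kap <- kappa_schedule(n, d, config$kappa_delta)
    x <- propose_next(model, domain$bounds, kap,
                      n_candidates = config$n_candidates,
                      n_polish = config$n_polish)
    rec <- apply_policy(x, backend, policy)
    if (!is.null(rec)) add_point(x, rec)
    refit <- nrow(X) <= config$refit_full_until ||
      n %% config$refit_every == 0 || n == config$iterations
    model <- if (refit) {
      fit_gp(X, targets, domain$periodic, init = model$hyp, n_starts = 1)
    } else {
      build_gp(X, targets, domain$periodic, model$hyp, model$noise)
    }
    pm <- if (config$track_predicted_min) {
      predicted_minimum(model, domain$bounds)
    } else list(x = rep(NA_real_, d), energy = NA_real_)
    best_raw <- if (any(is.finite(raw))) min(raw, na.rm = TRUE) else NA_real_
    trace[[n]] <- data.frame(
      iter = n, t(stats::setNames(x, paste0("d", seq_len(d)))),
      raw_energy = if (is.null(rec)) NA_real_ else rec$raw_energy,
      e_new = if (is.null(rec)) NA_real_ else rec$e_new,
      provenance = if (is.null(rec)) "skipped" else rec$provenance,
      best_raw = best_raw, kappa = kap,
      sf2 = model$hyp$sf2,
      t(stats::setNames(model$hyp$ell, paste0("ell", seq_len(d)))),
      t(stats::setNames(pm$x, paste0("pmin_d", seq_len(d)))),
      pmin_energy = pm$energy
    )
  }
  trace <- if (config$iterations > 0) do.call(rbind, trace) else
    data.frame()
  structure(list(model = model, trace = trace, X = X, targets = targets,
                 raw = raw, provenance = prov, domain = domain,
                 config = config, policy = policy),
            class = "bo_run")
}

#' @export
print.bo_run <- function(x, ...) {
  cat(sprintf("bo_run: %d training points (%d iterations), policy = %s\n",
              nrow(x$X), nrow(x$trace), x$policy$mode))
  if (nrow(x$trace) > 0) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  best observed raw energy: %.4f eV | predicted minimum energy: %.4f eV\n",
                last$best_raw, last$pmin_energy))
  }
  invisible(x)
}
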