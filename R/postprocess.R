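#' Extract local minima of the surrogate PES
#'
#' Multi-start bounded local minimization of the posterior mean over the
#' torsion box; converged endpoints (numerical gradient below `grad_tol`)
#' are clustered by periodic distance and reduced to unique candidates
#' sorted by surrogate energy.
#'
#' @param model a fitted `gp_model`.
#' @param bounds d x 2 matrix of per-dimension bounds (degrees).
#' @param periodic logical per dimension (controls distance wrapping when
#'   clustering).
#' @param n_starts number of random starts.
#' @param seed RNG seed for the starts.
#' @param cluster_tol endpoints closer than this (degrees, per-dimension
#'   periodic max difference) are merged.
#' @param grad_tol stationarity threshold on the numerical gradient of the
#'   posterior mean (eV/degree).
#' @return Data frame of candidates: one row per minimum with columns
#'   `d1..dk` and `surrogate_energy`, sorted by energy. Empty (with a
#'   warning) if no start converged.
#' @export
extract_minima <- function(model, bounds, periodic = NULL, n_starts = 50,
                           seed = 1, cluster_tol = 2, grad_tol = 1e-3) {
  d <- nrow(bounds)
  if (is.null(periodic)) periodic <- model$periodic
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  span <- bounds[, 2] - bounds[, 1]
  starts <- sweep(sweep(matrix(stats::runif(n_starts * d), ncol = d),
                        2, span, "*"), 2, bounds[, 1], "+")
  # seed with the lowest observed training points too
  nbest <- min(5, nrow(model$X))
  starts <- rbind(starts, model$X[order(model$y)[seq_len(nbest)], , drop = FALSE])
  # a flat posterior mean makes every point stationary: return one
  # representative instead of echoing every start back
  mvals <- gp_mean(model, starts)
  if (diff(range(mvals)) < 1e-9 * max(1, max(abs(mvals)))) {
    out <- data.frame(starts[1, , drop = FALSE], surrogate_energy = mvals[1])
    names(out) <- c(paste0("d", seq_len(d)), "surrogate_energy")
    rownames(out) <- NULL
    return(out)
  }
  ends <- list()
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn = function(x) gp_mean(model, x),
                   method = "L-BFGS-B", lower = bounds[, 1],
                   upper = bounds[, 2],
                   control = list(maxit = 120, factr = 1e6)),
      error = function(e) NULL)
    if (is.null(res)) next
    g <- num_grad(function(x) gp_mean(model, x), res$par)
    # interior stationary points only: on-boundary endpoints of restricted
    # dimensions may carry gradient, keep those as boundary minima
    interior <- res$par > bounds[, 1] + 1e-6 & res$par < bounds[, 2] - 1e-6
    if (max(abs(g[interior]), 0) > grad_tol) next
    ends[[length(ends) + 1]] <- c(res$par, res$value)
  }
  if (length(ends) == 0) {
    warning("no minimization start converged to a stationary point")
    return(empty_candidates(d))
  }
  M <- do.call(rbind, ends)
  pts <- M[, seq_len(d), drop = FALSE]
  vals <- M[, d + 1]
  ord <- order(vals)
  keep <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in keep) {
      if (max(dihedral_diff(pts[i, ], pts[j, ], periodic)) < cluster_tol) {
        dup <- TRUE; break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  out <- data.frame(pts[keep, , drop = FALSE], surrogate_energy = vals[keep])
  names(out) <- c(paste0("d", seq_len(d)), "surrogate_energy")
  rownames(out) <- NULL
  out
}

empty_candidates <- function(d) {
  out <- as.data.frame(matrix(numeric(0), ncol = d + 1))
  names(out) <- c(paste0("d", seq_len(d)), "surrogate_energy")
  out
}

# Is the (canonicalized) point inside the searched domain? Full-period
# dimensions always are; restricted dimensions use the wrapped interval.
point_in_domain <- function(x, domain) {
  for (j in seq_along(x)) {
    lo <- domain$bounds[j, 1]; hi <- domain$bounds[j, 2]
    if (hi - lo >= 360 - 1e-9) next
    if (!angle_in_wrapped_interval(x[j], lo, hi)) return(FALSE)
  }
  TRUE
}

# Per-dimension absolute angular difference, wrapped for periodic dims.
dihedral_diff <- function(a, b, periodic) {
  raw <- abs(a - b)
  ifelse(periodic, abs(wrap180(a - b)), raw)
}

num_grad <- function(f, x, h = 1e-4) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Refine minimum candidates on the backend
#'
#' Each candidate is relaxed with [local_refine()] on the true energy surface
#' and reported on the backend's reference energy scale. Candidates whose
#' evaluation fails (e.g., inside a failure region) are flagged and excluded
#' from the ranked output; a clash flag is set when the refined
#' configuration's D_min falls below the policy's safe distance.
#'
#' @param candidates data frame from [extract_minima()] (columns `d1..dk`).
#' @param backend energy backend.
#' @param policy a [clash_policy()] supplying `D0` for the clash flag.
#' @param fmax refinement convergence threshold.
#' @param domain optional search domain (list with `bounds` and `periodic`,
#'   see [search_domain()]): a refined record whose dihedrals leave the
#'   searched phase space is flagged `out_of_domain` and excluded — a
#'   restricted-domain search only reports conformers inside its own window.
#' @return Data frame of conformer records: dihedrals, `energy` (eV),
#'   `converged`, `clash` flags; rows sorted by energy; candidates whose
#'   evaluation fails and refinements that exit the domain are removed.
#' @export
refine_minima <- function(candidates, backend, policy = clash_policy(),
                          fmax = 1e-4, domain = NULL) {
  dcols <- grep("^d[0-9]+$", names(candidates))
  d <- length(dcols)
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    x0 <- as.numeric(candidates[i, dcols])
    ev <- evaluate_config(backend, x0)
    if (ev$status == "failure") {
      rows[[i]] <- NULL
      next
    }
    ref <- local_refine(backend, x0, fmax = fmax)
    if (!is.null(domain) && !point_in_domain(ref$x, domain)) next
    dmin <- backend_dmin(backend, ref$x)
    rows[[i]] <- data.frame(
      t(stats::setNames(canon_angle(ref$x), paste0("d", seq_len(d)))),
      energy = ref$energy, converged = ref$converged,
      clash = dmin < policy$D0)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- as.data.frame(matrix(numeric(0), ncol = d + 1))
    names(out) <- c(paste0("d", seq_len(d)), "energy")
    out$converged <- logical(0); out$clash <- logical(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$energy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Duplicate-purging configuration
#'
#' Two conformers are the same structure when *both* their maximum periodic
#' dihedral difference and their energy difference fall within the
#' thresholds. Defaults are the study values: 10 degrees and 0.0057 eV.
#'
#' @param delta_d_max angular threshold in degrees.
#' @param delta_e energy threshold in eV.
#' @return A `dedup_config` object.
#' @export
dedup_config <- function(delta_d_max = 10, delta_e = 0.0057) {
  stopifnot(delta_d_max > 0, delta_e > 0)
  structure(list(delta_d_max = delta_d_max, delta_e = delta_e),
            class = "dedup_config")
}

#' Purge duplicate conformer records
#'
#' Greedy scan from the lowest energy: a record is dropped iff its maximum
#' per-torsion periodic angular difference to an already-kept record is at
#' most `delta_d_max` *and* its energy difference is at most `delta_e`.
#' Idempotent; output sorted by energy.
#'
#' @param records data frame with dihedral columns `d1..dk` and `energy`.
#' @param config a [dedup_config()].
#' @param periodic logical per torsion (default all periodic).
#' @return The unique records, sorted by energy.
#' @export
purge_duplicates <- function(records, config = dedup_config(),
                             periodic = NULL) {
  if (nrow(records) == 0) return(records)
  dcols <- grep("^d[0-9]+$", names(records))
  if (is.null(periodic)) periodic <- rep(TRUE, length(dcols))
  ord <- order(records$energy)
  pts <- as.matrix(records[ord, dcols, drop = FALSE])
  en <- records$energy[ord]
  keep <- integer(0)
  for (i in seq_along(ord)) {
    dup <- FALSE
    for (j in keep) {
      if (max(dihedral_diff(pts[i, ], pts[j, ], periodic)) <= config$delta_d_max &&
          abs(en[i] - en[j]) <= config$delta_e) {
        dup <- TRUE; break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  out <- records[ord[keep], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full surrogate-to-conformers pipeline
#'
#' Convenience wrapper: extract surrogate minima, refine on the backend,
#' purge duplicates, and optionally keep only records within an energy
#' window above the best one.
#'
#' @param run a `bo_run` from [run_active_learning()].
#' @param backend energy backend (defaults to none; required).
#' @param policy clash policy for flags.
#' @param dedup a [dedup_config()].
#' @param energy_window keep records within this many eV of the lowest
#'   refined energy (`Inf` keeps all).
#' @param n_starts,seed passed to [extract_minima()].
#' @return Ranked conformer data frame (see [refine_minima()]).
#' @export
conformer_pipeline <- function(run, backend, policy = clash_policy(),
                               dedup = dedup_config(), energy_window = Inf,
                               n_starts = 50, seed = 1) {
  cand <- extract_minima(run$model, run$domain$bounds,
                         periodic = run$domain$periodic,
                         n_starts = n_starts, seed = seed)
  recs <- refine_minima(cand, backend, policy = policy, domain = run$domain)
  recs <- purge_duplicates(recs, dedup, periodic = run$domain$periodic)
  if (nrow(recs) > 0 && is.finite(energy_window)) {
    recs <- recs[recs$energy <= min(recs$energy) + energy_window, ,
                 drop = FALSE]
  }
  recs
}
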