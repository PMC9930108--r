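#' Energy evaluation result
#'
#' Outcome of a single backend call: either a success carrying an energy in
#' eV relative to the backend's reference configuration, or a failure (the
#' analogue of a crashed electronic-structure calculation). Both carry the
#' shortest molecule--environment distance of the evaluated configuration.
#'
#' @param status `"success"` or `"failure"`.
#' @param energy energy in eV (required iff success).
#' @param d_min shortest mobile--environment distance in Angstrom.
#' @return An `energy_evaluation` object.
#' @export
energy_evaluation <- function(status, energy = NULL, d_min = NA_real_) {
  status <- match.arg(status, c("success", "failure"))
  if (status == "success" && (is.null(energy) || !is.finite(energy))) {
    stop("successful evaluation must carry a finite energy")
  }
  if (status == "failure") energy <- NULL
  if (!is.na(d_min) && d_min < 0) stop("d_min must be nonnegative")
  structure(list(status = status, energy = energy, d_min = d_min),
            class = "energy_evaluation")
}

#' Synthetic periodic multi-well landscape
#'
#' Generates a test energy surface over dihedral space: a flat baseline minus
#' a sum of Gaussian wells on the wrapped (360-degree periodic) angular
#' metric, optionally decorated with axis-aligned *failure boxes* (where
#' evaluation returns a failure, emulating a crashed calculation) and *clash
#' boxes* (where the reported d_min drops below typical bonding distance,
#' emulating steric overlap). The true global minimum is located by local
#' refinement from the deepest planted center and stored for test oracles.
#'
#' @param dimension number of dihedral dimensions (>= 1).
#' @param n_wells number of Gaussian wells (>= 1).
#' @param n_failure_regions number of failure boxes.
#' @param seed integer RNG seed.
#' @param depth_range depths drawn uniformly from this range (eV).
#' @param width_range isotropic well widths drawn uniformly (degrees).
#' @param baseline baseline energy far from all wells (eV).
#' @param failure_fraction approximate total domain fraction covered by
#'   failure boxes (split evenly across boxes).
#' @param n_clash_regions number of clash boxes (same sizing rule).
#' @param clash_fraction approximate domain fraction covered by clash boxes.
#' @param d_safe,d_clash d_min reported outside / inside clash boxes (Angstrom).
#' @return A `synthetic_landscape` object; fields include `centers`, `depths`,
#'   `widths`, `global_min` (location) and `global_min_energy`.
#' @export
make_synthetic_landscape <- function(dimension, n_wells, n_failure_regions = 0,
                                     seed = 1,
                                     depth_range = c(0.5, 1.0),
                                     width_range = c(25, 40),
                                     baseline = 0,
                                     failure_fraction = 0.2,
                                     n_clash_regions = 0,
                                     clash_fraction = 0.1,
                                     d_safe = 3.0, d_clash = 1.0) {
  stopifnot(dimension >= 1, n_wells >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  widths <- stats::runif(n_wells, width_range[1], width_range[2])
  min_sep <- 3 * max(widths)
  centers <- matrix(NA_real_, n_wells, dimension)
  tries <- 0
  i <- 1
  while (i <= n_wells) {
    cand <- stats::runif(dimension, 0, 360)
    ok <- TRUE
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        if (periodic_dist(cand, centers[j, ]) < min_sep) { ok <- FALSE; break }
      }
    }
    if (ok) { centers[i, ] <- cand; i <- i + 1 } else {
      tries <- tries + 1
      if (tries > 5000) {
        stop("cannot place wells with the requested separation; reduce n_wells or widths")
      }
    }
  }
  depths <- stats::runif(n_wells, depth_range[1], depth_range[2])
  place_boxes <- function(n_boxes, fraction) {
    if (n_boxes == 0) return(list())
    per_box <- fraction / n_boxes
    side <- 360 * per_box^(1 / dimension)
    boxes <- list()
    t2 <- 0
    while (length(boxes) < n_boxes) {
      lo <- stats::runif(dimension, 0, 360)
      box <- cbind(lo, lo + side)
      # keep boxes away from every well center (margin: one width)
      clear <- TRUE
      for (w in seq_len(n_wells)) {
        cen <- centers[w, ]
        inside <- all(vapply(seq_len(dimension), function(j) {
          angle_in_wrapped_interval(cen[j], box[j, 1] - widths[w],
                                    box[j, 2] + widths[w])
        }, logical(1)))
        if (inside) { clear <- FALSE; break }
      }
      if (clear) boxes[[length(boxes) + 1]] <- box else {
        t2 <- t2 + 1
        if (t2 > 5000) stop("cannot place failure/clash boxes clear of wells")
      }
    }
    boxes
  }
  failure_regions <- place_boxes(n_failure_regions, failure_fraction)
  clash_regions <- place_boxes(n_clash_regions, clash_fraction)
  ls <- structure(
    list(dimension = dimension, centers = centers, depths = depths,
         widths = widths, baseline = baseline,
         failure_regions = failure_regions, clash_regions = clash_regions,
         d_safe = d_safe, d_clash = d_clash, period = 360),
    class = "synthetic_landscape"
  )
  gm <- landscape_refine_point(ls, centers[which.max(depths), ])
  ls$global_min <- gm$x
  ls$global_min_energy <- gm$energy
  ls
}

periodic_dist <- function(x, y) sqrt(sum(wrap180(x - y)^2))

# Is angle `a` inside the (possibly wrapping) interval [lo, hi] on the circle?
angle_in_wrapped_interval <- function(a, lo, hi) {
  a <- canon_angle(a)
  width <- hi - lo
  if (width >= 360) return(TRUE)
  rel <- canon_angle(a - lo)
  rel <= width
}

in_any_box <- function(x, boxes) {
  for (box in boxes) {
    if (all(vapply(seq_along(x), function(j) {
      angle_in_wrapped_interval(x[j], box[j, 1], box[j, 2])
    }, logical(1)))) return(TRUE)
  }
  FALSE
}

#' Landscape energy (closed form)
#'
#' `baseline - sum_k depth_k * exp(-Delta_k^2 / (2 width_k^2))` with
#' `Delta_k` the wrapped angular distance to well center k. Vectorized over
#' rows of `x`.
#'
#' @param landscape a `synthetic_landscape`.
#' @param x numeric vector (one point) or matrix (one point per row), degrees.
#' @return Energy in eV (vector if `x` is a matrix).
#' @export
landscape_energy <- function(landscape, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  e <- rep(landscape$baseline, nrow(x))
  for (k in seq_len(nrow(landscape$centers))) {
    d2 <- rowSums(wrap180(sweep(x, 2, landscape$centers[k, ]))^2)
    e <- e - landscape$depths[k] * exp(-d2 / (2 * landscape$widths[k]^2))
  }
  e
}

landscape_gradient <- function(landscape, x) {
  g <- numeric(length(x))
  for (k in seq_len(nrow(landscape$centers))) {
    delta <- wrap180(x - landscape$centers[k, ])
    w2 <- landscape$widths[k]^2
    g <- g + landscape$depths[k] * exp(-sum(delta^2) / (2 * w2)) * delta / w2
  }
  g
}

#' Evaluate a configuration on a backend
#'
#' Single-point evaluation honoring the backend contract: a backend never
#' throws on a bad configuration; it reports `status = "failure"` instead.
#'
#' @param backend a `synthetic_landscape` or any object with class
#'   `energy_backend` (list with `eval_fn(x)` returning an
#'   `energy_evaluation`, and optional `dmin_fn(x)`).
#' @param x dihedral vector in degrees.
#' @return An `energy_evaluation`.
#' @export
evaluate_config <- function(backend, x) {
  if (inherits(backend, "synthetic_landscape")) {
    dmin <- if (in_any_box(x, backend$clash_regions)) backend$d_clash else backend$d_safe
    if (in_any_box(x, backend$failure_regions)) {
      return(energy_evaluation("failure", d_min = dmin))
    }
    return(energy_evaluation("success", energy = landscape_energy(backend, x),
                             d_min = dmin))
  }
  if (inherits(backend, "energy_backend")) {
    return(tryCatch(backend$eval_fn(x),
                    error = function(e) energy_evaluation("failure")))
  }
  stop("unknown backend type")
}

#' Shortest-distance query for a configuration
#'
#' Geometric D_min of configuration `x` under a backend, available without an
#' energy evaluation (used by the safe-distance strategy to pre-screen).
#'
#' @inheritParams evaluate_config
#' @return Distance in Angstrom.
#' @export
backend_dmin <- function(backend, x) {
  if (inherits(backend, "synthetic_landscape")) {
    return(if (in_any_box(x, backend$clash_regions)) backend$d_clash else backend$d_safe)
  }
  if (inherits(backend, "energy_backend") && !is.null(backend$dmin_fn)) {
    return(backend$dmin_fn(x))
  }
  stop("backend does not provide a distance query")
}

#' Build an energy backend from a structure and an energy function
#'
#' Adapter realizing the backend contract for real atomic structures: each
#' dihedral vector is applied to the structure with [set_dihedrals()] and the
#' supplied Cartesian energy function is called; the geometric D_min is
#' computed from the posed structure.
#'
#' @param structure an `atomic_structure`.
#' @param spec a `torsion_spec`.
#' @param energy_fn function(atomic_structure) -> energy in eV (may stop() to
#'   signal failure).
#' @return An `energy_backend`.
#' @export
structure_backend <- function(structure, spec, energy_fn) {
  force(structure); force(spec); force(energy_fn)
  structure(list(
    eval_fn = function(x) {
      posed <- set_dihedrals(structure, spec, x)
      dmin <- min_pair_distance(posed)
      e <- tryCatch(energy_fn(posed), error = function(err) NULL)
      if (is.null(e)) energy_evaluation("failure", d_min = dmin)
      else energy_evaluation("success", energy = e, d_min = dmin)
    },
    dmin_fn = function(x) min_pair_distance(set_dihedrals(structure, spec, x)),
    structure = structure, spec = spec
  ), class = "energy_backend")
}

# Refinement on the landscape's closed-form surface. Gaussian tails have
# vanishing curvature, where raw BFGS crawls; a normalized-gradient descent
# stage first walks into the attracting basin, then BFGS polishes with
# analytic gradients. Coordinates are wrapped back into [0, 360) at the end.
landscape_refine_point <- function(landscape, x0, fmax = 1e-4, maxit = 300) {
  x <- x0
  step <- 4
  for (i in seq_len(500)) {
    g <- landscape_gradient(landscape, x)
    gn <- sqrt(sum(g^2))
    if (gn <= fmax || step < 1e-6) break
    prop <- x - step * g / gn
    if (landscape_energy(landscape, prop) < landscape_energy(landscape, x)) {
      x <- prop
      step <- min(step * 1.5, 8)
    } else {
      step <- step / 2
    }
  }
  res <- stats::optim(x, fn = function(z) landscape_energy(landscape, z),
                      gr = function(z) landscape_gradient(landscape, z),
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  if (res$value > landscape_energy(landscape, x)) {
    res <- list(par = x, value = landscape_energy(landscape, x))
  }
  g <- landscape_gradient(landscape, res$par)
  list(x = canon_angle(res$par), energy = res$value,
       converged = max(abs(g)) <= max(fmax, 1e-8))
}

#' Local refinement of a configuration
#'
#' Relaxes a configuration on the backend's energy surface. Synthetic
#' landscapes refine in dihedral space using analytic gradients; other
#' backends must expose a `refine_fn`. Never increases the energy; a
#' non-converged refinement is flagged, not an error.
#'
#' @param backend backend object.
#' @param x starting dihedral vector (degrees).
#' @param fmax gradient-norm convergence threshold (eV/degree for dihedral
#'   refinement).
#' @return List with `x` (refined point, canonicalized), `energy` (eV) and
#'   `converged` flag.
#' @export
local_refine <- function(backend, x, fmax = 1e-4) {
  if (inherits(backend, "synthetic_landscape")) {
    start_e <- landscape_energy(backend, x)
    out <- landscape_refine_point(backend, x, fmax = fmax)
    if (out$energy > start_e + 1e-12) {  # descent guarantee
      out <- list(x = canon_angle(x), energy = start_e, converged = FALSE)
    }
    return(out)
  }
  if (inherits(backend, "energy_backend") && !is.null(backend$refine_fn)) {
    return(backend$refine_fn(x, fmax))
  }
  stop("backend does not support refinement")
}
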