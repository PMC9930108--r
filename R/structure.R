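#' Atomic structure with a mobile molecule and a fixed environment
#'
#' Container for an atomic system split into a *mobile* molecule, whose
#' conformation is searched over dihedral angles, and a *fixed environment*
#' whose atoms never move (the "building block" convention: bond lengths and
#' angles inside each rigid fragment stay at their input values, only the
#' declared torsions vary).
#'
#' @param elements character vector of chemical symbols, one per atom.
#' @param coords numeric n x 3 matrix of Cartesian coordinates in Angstrom.
#' @param mobile_mask logical vector, `TRUE` for atoms of the mobile molecule.
#' @param bonds integer m x 2 matrix of 0-based atom-index pairs giving the
#'   covalent topology (undirected).
#' @return An object of class `atomic_structure`.
#' @export
atomic_structure <- function(elements, coords, mobile_mask, bonds) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- length(elements)
  stopifnot(nrow(coords) == n, ncol(coords) == 3, length(mobile_mask) == n)
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (!any(mobile_mask)) stop("at least one atom must be mobile")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && (min(bonds) < 0 || max(bonds) >= n)) {
    stop("bond indices out of range (0-based)")
  }
  structure(
    list(elements = as.character(elements), coords = coords,
         mobile_mask = as.logical(mobile_mask), bonds = bonds),
    class = "atomic_structure"
  )
}

#' @export
print.atomic_structure <- function(x, ...) {
  cat(sprintf("atomic_structure: %d atoms (%d mobile, %d environment), %d bonds\n",
              length(x$elements), sum(x$mobile_mask), sum(!x$mobile_mask),
              nrow(x$bonds)))
  invisible(x)
}

#' Torsion specification
#'
#' Defines the search coordinates: an ordered list of dihedral angles, each
#' given by four 0-based atom indices (a, b, c, d) about the rotatable bond
#' b--c, with per-torsion bounds in degrees and a periodicity flag. The set of
#' atoms that rotates with each torsion is derived by cutting the bond graph
#' at b--c and taking the connected component containing d; a user-supplied
#' `rotating` override is honored.
#'
#' @param quads integer k x 4 matrix of 0-based atom indices (a, b, c, d).
#' @param lower,upper numeric bounds in degrees (defaults 0 and 360).
#' @param periodic logical per torsion; `TRUE` means the full 360-degree circle.
#' @param structure optional `atomic_structure` used to derive rotating sets.
#' @param rotating optional list of 0-based index vectors overriding the
#'   derived rotating sets.
#' @return An object of class `torsion_spec`.
#' @export
torsion_spec <- function(quads, lower = NULL, upper = NULL, periodic = NULL,
                         structure = NULL, rotating = NULL) {
  quads <- matrix(as.integer(quads), ncol = 4)
  k <- nrow(quads)
  if (is.null(lower)) lower <- rep(0, k)
  if (is.null(upper)) upper <- rep(360, k)
  if (is.null(periodic)) periodic <- (upper - lower) >= 360
  stopifnot(length(lower) == k, length(upper) == k, length(periodic) == k)
  if (any(upper - lower > 360 + 1e-9)) stop("bounds must lie within one period")
  if (any(upper <= lower)) stop("upper bound must exceed lower bound")
  if (is.null(rotating) && !is.null(structure)) {
    rotating <- lapply(seq_len(k), function(i) {
      derive_rotating_set(structure$bonds, quads[i, 2], quads[i, 3], quads[i, 4])
    })
  }
  if (!is.null(rotating)) {
    for (i in seq_len(k)) {
      r <- rotating[[i]]
      if (quads[i, 4] %in% r == FALSE) stop("rotating set must contain atom d")
      if (quads[i, 1] %in% r) stop("rotating set must not contain atom a")
    }
  }
  structure(
    list(quads = quads, lower = as.numeric(lower), upper = as.numeric(upper),
         periodic = as.logical(periodic), rotating = rotating),
    class = "torsion_spec"
  )
}

n_torsions <- function(spec) nrow(spec$quads)

#' @export
print.torsion_spec <- function(x, ...) {
  cat(sprintf("torsion_spec: %d torsions\n", n_torsions(x)))
  for (i in seq_len(n_torsions(x))) {
    cat(sprintf("  d%d: atoms (%d,%d,%d,%d)  bounds [%g, %g]%s\n", i,
                x$quads[i, 1], x$quads[i, 2], x$quads[i, 3], x$quads[i, 4],
                x$lower[i], x$upper[i], if (x$periodic[i]) " periodic" else ""))
  }
  invisible(x)
}

# Connected component of the bond graph containing `d` after deleting the
# edge b--c. 0-based in and out.
derive_rotating_set <- function(bonds, b, c, d) {
  adj <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
  drop_edge <- function(from, to) {
    key <- as.character(from)
    adj[[key]] <<- setdiff(adj[[key]], to)
  }
  drop_edge(b, c); drop_edge(c, b)
  seen <- d
  frontier <- d
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (b %in% seen) {
    stop(sprintf("bond %d--%d is not a graph cut; torsion rotating set undefined", b, c))
  }
  sort(seen)
}

canon_angle <- function(x) ((x %% 360) + 360) %% 360

# Signed angular difference wrapped into (-180, 180].
wrap180 <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y <= -180] <- y[y <= -180] + 360
  y
}

#' Measure a dihedral angle
#'
#' Signed IUPAC dihedral about the bond b--c defined by atoms (a, b, c, d),
#' reported in degrees canonicalized to `[0, 360)`.
#'
#' @param structure an `atomic_structure`.
#' @param quad integer vector of four distinct 0-based atom indices.
#' @return Angle in degrees in `[0, 360)`.
#' @export
measure_dihedral <- function(structure, quad) {
  stopifnot(length(quad) == 4, !anyDuplicated(quad))
  p <- structure$coords[quad + 1L, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop(sprintf("degenerate geometry: atoms (%s) contain a collinear triple",
                 paste(quad, collapse = ",")))
  }
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  canon_angle(ang)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Rodrigues rotation of points (rows of `pts`) about the axis through `origin`
# with unit direction `axis`, by `theta` degrees.
rotate_about_axis <- function(pts, origin, axis, theta) {
  th <- theta * pi / 180
  k <- axis / sqrt(sum(axis^2))
  p <- sweep(pts, 2, origin)
  cth <- cos(th); sth <- sin(th)
  kx <- p[, 2] * k[3] - p[, 3] * k[2]
  ky <- p[, 3] * k[1] - p[, 1] * k[3]
  kz <- p[, 1] * k[2] - p[, 2] * k[1]
  kdp <- p %*% k
  rot <- p * cth + cbind(kx, ky, kz) * sth + (kdp %*% t(k)) * (1 - cth)
  sweep(rot, 2, origin, "+")
}

#' Set dihedral angles
#'
#' Rotates the rigid fragments of the mobile molecule so that every torsion in
#' `spec` measures the corresponding `target` angle. Torsions are applied in
#' the listed order; environment atoms never move; all distances inside each
#' rigid fragment are preserved.
#'
#' @param structure an `atomic_structure`.
#' @param spec a `torsion_spec` with rotating sets available (pass `structure`
#'   to [torsion_spec()] or supply `rotating`).
#' @param target numeric vector of target angles in degrees, one per torsion.
#' @return A new `atomic_structure` with the requested dihedrals.
#' @export
set_dihedrals <- function(structure, spec, target) {
  k <- n_torsions(spec)
  stopifnot(length(target) == k)
  target <- canon_angle(target)
  in_torsion_bounds_or_stop(spec, target)
  if (is.null(spec$rotating)) {
    spec$rotating <- lapply(seq_len(k), function(i) {
      derive_rotating_set(structure$bonds, spec$quads[i, 2], spec$quads[i, 3],
                          spec$quads[i, 4])
    })
  }
  coords <- structure$coords
  for (i in seq_len(k)) {
    q <- spec$quads[i, ]
    cur <- measure_dihedral_coords(coords, q)
    delta <- wrap180(target[i] - cur)
    if (abs(delta) < 1e-13) next
    idx <- spec$rotating[[i]] + 1L
    bpt <- coords[q[2] + 1L, ]
    cpt <- coords[q[3] + 1L, ]
    # right-handed rotation about b->c decreases the signed dihedral
    coords[idx, ] <- rotate_about_axis(coords[idx, , drop = FALSE],
                                       bpt, cpt - bpt, -delta)
  }
  out <- structure
  out$coords <- coords
  out
}

measure_dihedral_coords <- function(coords, quad) {
  s <- list(coords = coords)
  class(s) <- "atomic_structure"
  measure_dihedral(s, quad)
}

# Checks a canonical angle vector against the spec's bounds, honoring wrap:
# a bound pair like [300, 420] is stored as lower=300, upper=420 and an angle
# of 30 (== 390) is inside it.
in_torsion_bounds <- function(spec, values) {
  values <- canon_angle(values)
  ok <- logical(length(values))
  for (i in seq_along(values)) {
    if (spec$periodic[i] && (spec$upper[i] - spec$lower[i]) >= 360 - 1e-9) {
      ok[i] <- TRUE
    } else {
      v <- values[i]
      lo <- spec$lower[i]; hi <- spec$upper[i]
      ok[i] <- (v >= lo - 1e-9 && v <= hi + 1e-9) ||
        (v + 360 >= lo - 1e-9 && v + 360 <= hi + 1e-9)
    }
  }
  ok
}

in_torsion_bounds_or_stop <- function(spec, values) {
  ok <- in_torsion_bounds(spec, values)
  if (!all(ok)) {
    stop(sprintf("dihedral target outside bounds for torsion(s): %s",
                 paste(which(!ok), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Shortest molecule--environment distance
#'
#' Minimum Euclidean distance over all (mobile atom, environment atom) pairs;
#' the geometric steric-clash diagnostic D_min.
#'
#' @param structure an `atomic_structure`.
#' @return Distance in Angstrom.
#' @export
min_pair_distance <- function(structure) {
  if (!any(!structure$mobile_mask)) stop("structure has no environment atoms")
  if (!any(structure$mobile_mask)) stop("structure has no mobile atoms")
  a <- structure$coords[structure$mobile_mask, , drop = FALSE]
  b <- structure$coords[!structure$mobile_mask, , drop = FALSE]
  # squared cross-distance matrix via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Uniform random dihedral configurations
#'
#' Draws `n` dihedral vectors independently and uniformly within each
#' torsion's bounds. Reproducible under `seed`.
#'
#' @param spec a `torsion_spec`.
#' @param n number of configurations.
#' @param seed integer RNG seed.
#' @return n x k numeric matrix of angles in degrees, canonicalized to
#'   `[0, 360)`.
#' @export
random_configurations <- function(spec, n, seed) {
  stopifnot(n >= 1)
  k <- n_torsions(spec)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  m <- matrix(stats::runif(n * k), nrow = n)
  out <- sweep(sweep(m, 2, spec$upper - spec$lower, "*"), 2, spec$lower, "+")
  out <- canon_angle(out)
  colnames(out) <- paste0("d", seq_len(k))
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
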