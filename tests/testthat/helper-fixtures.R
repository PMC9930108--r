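# Shared builders and independent oracles used across the suite.

# Butane-like four-atom chain whose terminal atom is rotated to a requested
# dihedral by explicit axis-angle construction: the oracle IS the
# construction, independent of the package's geometry code.
chain_with_dihedral <- function(phi_deg) {
  a <- c(0, 1, 0)
  b <- c(0, 0, 0)
  c_ <- c(1.5, 0, 0)
  # start with d trans (phi = 180): in the abc plane, opposite side from a
  d0 <- c(1.5, -1, 0) + c(0.5, 0, 0)
  # rotate d about the b->c axis by (phi - 180)
  rot <- function(p, theta) {
    th <- theta * pi / 180
    k <- c(1, 0, 0)
    p * cos(th) + pracma_cross(k, p) * sin(th) + k * sum(k * p) * (1 - cos(th))
  }
  d <- c_ + rot(d0 - c_, phi_deg - 180)
  rbind(a, b, c_, d)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# 10-atom flexible chain molecule with two torsions, no environment; used
# for rigid-fragment conservation checks.
toy_chain_molecule <- function() {
  coords <- rbind(
    c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0), c(3.7, 1.3, 0),
    c(4.4, 2.6, 0.1), c(-0.5, -0.9, 0.2), c(1.9, -0.8, 0.6),
    c(1.8, 2.2, -0.4), c(4.1, 0.4, -0.5), c(5.4, 2.5, 0.4)
  )
  elements <- c("C", "C", "C", "C", "C", "H", "H", "H", "H", "H")
  bonds <- rbind(
    c(0, 1), c(1, 2), c(2, 3), c(3, 4),
    c(0, 5), c(1, 6), c(2, 7), c(3, 8), c(4, 9)
  )
  env <- rbind(c(20, 20, 20), c(21, 20, 20))
  st <- atomic_structure(c(elements, "Au", "Au"),
                         rbind(coords, env),
                         c(rep(TRUE, 10), FALSE, FALSE),
                         bonds)
  spec <- torsion_spec(rbind(c(0L, 1L, 2L, 3L), c(1L, 2L, 3L, 4L)),
                       structure = st)
  list(structure = st, spec = spec)
}

all_bond_lengths <- function(st) {
  apply(st$bonds, 1, function(b) {
    sqrt(sum((st$coords[b[1] + 1, ] - st$coords[b[2] + 1, ])^2))
  })
}

# Independent dense linear-algebra GP oracle: plain solve() on the full
# covariance, no Cholesky reuse, kernels recomputed from scratch.
oracle_gp_posterior <- function(X, y, Xstar, periodic, sf2, ell, noise) {
  kfun <- function(x1, x2) {
    v <- 1
    for (j in seq_along(x1)) {
      if (periodic[j]) {
        s <- (360 / pi) * sin(pi * (x1[j] - x2[j]) / 360)
        v <- v * exp(-s^2 / (2 * ell[j]^2))
      } else {
        v <- v * exp(-(x1[j] - x2[j])^2 / (2 * ell[j]^2))
      }
    }
    sf2 * v
  }
  n <- nrow(X); m <- nrow(Xstar)
  K <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n) K[i, k] <- kfun(X[i, ], X[k, ])
  Ks <- matrix(0, n, m)
  for (i in 1:n) for (k in 1:m) Ks[i, k] <- kfun(X[i, ], Xstar[k, ])
  Kinv <- solve(K + diag(noise, n))
  mu <- mean(y) + drop(t(Ks) %*% Kinv %*% (y - mean(y)))
  var <- vapply(1:m, function(k) {
    kfun(Xstar[k, ], Xstar[k, ]) - drop(t(Ks[, k]) %*% Kinv %*% Ks[, k])
  }, numeric(1))
  list(mean = mu, sd = sqrt(pmax(var, 0)))
}

max_wrap_diff <- function(a, b) {
  d <- abs(((a - b + 180) %% 360) - 180)
  max(d)
}
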