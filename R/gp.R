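#' Gaussian-process surrogate over dihedral space
#'
#' The surrogate potential-energy surface is a zero-mean (after centering) GP
#' with a product kernel over torsion dimensions: squared-exponential for
#' nonperiodic dimensions and the standard-periodic kernel
#' `exp(-2 sin^2(pi (x - x') / 360) / l^2)` (period 360 degrees) for periodic
#' ones, scaled by a common signal variance. Observation noise is a fixed
#' small nugget because backend evaluations are deterministic.
#'
#' @name surrogate-gp
NULL

# Per-dimension squared half-distances used inside the kernel exponent, so
# that k = sf2 * exp(-sum_j F_j / l_j^2) with every lengthscale in degrees:
# nonperiodic dims use delta^2 / 2 (squared exponential); periodic dims use
# the chordal distance s = (360/pi) * sin(pi*delta/360), giving the
# standard-periodic kernel reparameterized so that for delta << 360 it
# matches the squared exponential with the same lengthscale.
# `A` is n x d, `B` is m x d; returns a list of n x m matrices.
kernel_features <- function(A, B, periodic) {
  d <- ncol(A)
  lapply(seq_len(d), function(j) {
    delta <- outer(A[, j], B[, j], "-")
    if (periodic[j]) {
      (180 / pi)^2 * 2 * sin(pi * delta / 360)^2
    } else {
      delta^2 / 2
    }
  })
}

# Kernel matrix from cached features: sf2 * exp(-sum_j F_j / l_j^2).
kernel_from_features <- function(feats, sf2, ell) {
  S <- feats[[1]] / ell[1]^2
  if (length(feats) > 1) {
    for (j in 2:length(feats)) S <- S + feats[[j]] / ell[j]^2
  }
  sf2 * exp(-S)
}

chol_with_jitter <- function(K, base_jitter = 0) {
  jitter <- base_jitter
  for (attempt in 1:6) {
    U <- tryCatch(chol(K + diag(jitter, nrow(K))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = jitter))
    jitter <- if (jitter == 0) 1e-8 * mean(diag(K)) else jitter * 10
  }
  stop("covariance matrix not positive definite even after jitter escalation")
}

#' Fit a GP surrogate to training data
#'
#' Maximizes the log marginal likelihood over log signal variance and log
#' per-dimension lengthscales with multi-start bounded quasi-Newton
#' optimization (analytic gradients). The noise variance is a fixed nugget.
#' Degenerate data (all targets identical) fall back to prior lengthscales
#' with a warning flag.
#'
#' @param X n x d matrix of dihedral vectors (degrees).
#' @param y numeric training targets (eV).
#' @param periodic logical per dimension.
#' @param noise fixed noise variance in eV^2.
#' @param init optional warm-start hyperparameters `list(sf2, ell)`.
#' @param n_starts number of additional random starts.
#' @param ell_bounds lengthscale search bounds in degrees.
#' @return A `gp_model` (kernel description, hyperparameters, Cholesky
#'   factor, and training data).
#' @export
fit_gp <- function(X, y, periodic, noise = 1e-4, init = NULL, n_starts = 2,
                   ell_bounds = c(5, 720)) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(n >= 2, length(y) == n, length(periodic) == d)
  ymean <- mean(y)
  yc <- y - ymean
  degenerate <- stats::sd(y) < 1e-12
  feats <- kernel_features(X, X, periodic)

  if (degenerate) {
    warning("all training targets identical; noise-dominated fit with prior lengthscales")
    hyp <- list(sf2 = noise, ell = rep(60, d))
    model <- build_gp(X, y, periodic, hyp, noise, degenerate = TRUE)
    return(model)
  }

  nll_grad <- function(theta) {
    sf2 <- exp(theta[1]); ell <- exp(theta[-1])
    Kc <- kernel_from_features(feats, sf2, ell)
    K <- Kc + diag(noise, n)
    cj <- chol_with_jitter(K)
    U <- cj$U
    alpha <- backsolve(U, backsolve(U, yc, transpose = TRUE))
    nll <- 0.5 * sum(yc * alpha) + sum(log(diag(U))) + 0.5 * n * log(2 * pi)
    Kinv <- chol2inv(U)
    W <- tcrossprod(alpha) - Kinv      # d(logLik)/dK = 0.5 * W
    g <- numeric(length(theta))
    g[1] <- -0.5 * sum(W * Kc)         # dK/dlog sf2 = Kc
    for (j in seq_len(d)) {
      Dj <- Kc * (2 * feats[[j]] / ell[j]^2)  # dK/dlog ell_j
      g[j + 1] <- -0.5 * sum(W * Dj)
    }
    list(value = nll, gradient = g)
  }
  fn <- function(theta) nll_grad(theta)$value
  gr <- function(theta) nll_grad(theta)$gradient

  lower <- c(log(1e-6), rep(log(ell_bounds[1]), d))
  upper <- c(log(1e4), rep(log(ell_bounds[2]), d))
  starts <- list(c(log(stats::var(y)), rep(log(60), d)))
  if (!is.null(init)) {
    starts <- c(list(c(log(init$sf2), log(init$ell))), starts)
  }
  if (n_starts > 0) {
    for (s in seq_len(n_starts)) {
      starts[[length(starts) + 1]] <-
        c(log(stats::var(y)) + stats::rnorm(1, 0, 1),
          log(stats::runif(d, 15, 200)))
    }
  }
  best <- NULL
  for (th0 in starts) {
    th0 <- pmin(pmax(th0, lower), upper)
    res <- tryCatch(
      stats::optim(th0, fn = fn, gr = gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 60, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("hyperparameter optimization failed from every start")
  # optimizer contract: never worse than the first (heuristic) start
  theta0 <- pmin(pmax(starts[[1]], lower), upper)
  if (best$value > fn(theta0) + 1e-9) best <- list(par = theta0, value = fn(theta0))
  hyp <- list(sf2 = exp(best$par[1]), ell = exp(best$par[-1]))
  build_gp(X, y, periodic, hyp, noise, degenerate = FALSE)
}

# Assemble the fitted-model object: Cholesky factor and weight vector for
# fast posterior queries.
build_gp <- function(X, y, periodic, hyp, noise, degenerate = FALSE) {
  n <- nrow(X)
  feats <- kernel_features(X, X, periodic)
  Kc <- kernel_from_features(feats, hyp$sf2, hyp$ell)
  cj <- chol_with_jitter(Kc + diag(noise, n))
  ymean <- mean(y)
  alpha <- backsolve(cj$U, backsolve(cj$U, y - ymean, transpose = TRUE))
  structure(list(X = X, y = y, ymean = ymean, periodic = periodic,
                 hyp = hyp, noise = noise, U = cj$U, alpha = alpha,
                 jitter = cj$jitter, degenerate = degenerate),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("gp_model: %d points, %d dims | sf2 = %.4g eV^2, ell = [%s] deg, noise = %.1g\n",
              nrow(x$X), ncol(x$X), x$hyp$sf2,
              paste(sprintf("%.1f", x$hyp$ell), collapse = ", "), x$noise))
  invisible(x)
}

#' GP posterior mean and standard deviation
#'
#' @param model a fitted `gp_model`.
#' @param Xstar query point (vector) or matrix of query points (rows), degrees.
#' @return List with numeric vectors `mean` (eV) and `sd` (eV; latent
#'   predictive standard deviation, excluding observation noise).
#' @export
gp_posterior <- function(model, Xstar) {
  if (is.null(dim(Xstar))) Xstar <- matrix(Xstar, nrow = 1)
  feats <- kernel_features(model$X, Xstar, model$periodic)
  Ks <- kernel_from_features(feats, model$hyp$sf2, model$hyp$ell)  # n x m
  mu <- model$ymean + drop(crossprod(Ks, model$alpha))
  W <- backsolve(model$U, Ks, transpose = TRUE)
  v <- model$hyp$sf2 - colSums(W^2)
  list(mean = mu, sd = sqrt(pmax(v, 0)))
}

gp_mean <- function(model, Xstar) {
  if (is.null(dim(Xstar))) Xstar <- matrix(Xstar, nrow = 1)
  feats <- kernel_features(model$X, Xstar, model$periodic)
  Ks <- kernel_from_features(feats, model$hyp$sf2, model$hyp$ell)
  model$ymean + drop(crossprod(Ks, model$alpha))
}

#' Exploratory lower-confidence-bound acquisition
#'
#' `mean(x) - kappa * sd(x)`, minimized to pick the next sample: low values
#' flag either a promising predicted energy or an unexplored region.
#'
#' @param model a fitted `gp_model`.
#' @param x query point or matrix of points.
#' @param kappa nonnegative exploration weight.
#' @return Acquisition values (eV scale).
#' @export
elcb <- function(model, x, kappa) {
  stopifnot(kappa >= 0)
  p <- gp_posterior(model, x)
  p$mean - kappa * p$sd
}

#' Exploration-weight schedule
#'
#' The usual LCB/GP-UCB schedule `kappa_n = sqrt(2 log(n^(d/2+2) pi^2 /
#' (3 delta)))` with confidence parameter `delta`; nondecreasing in the
#' iteration index `n`.
#'
#' @param n iteration index (>= 1).
#' @param d search-space dimension.
#' @param delta confidence parameter.
#' @return kappa value.
#' @export
kappa_schedule <- function(n, d, delta = 0.1) {
  sqrt(2 * log(n^(d / 2 + 2) * pi^2 / (3 * delta)))
}

# Minimize `objective(x)` over a box by batch screening of uniform random
# candidates followed by bounded local polishing of the best few. `objective`
# must accept a matrix of rows. Deterministic given the RNG state.
optimize_in_box <- function(objective, bounds, n_candidates = 300,
                            n_polish = 3, extra_starts = NULL, maxit = 40) {
  d <- nrow(bounds)
  span <- bounds[, 2] - bounds[, 1]
  cand <- sweep(sweep(matrix(stats::runif(n_candidates * d), ncol = d),
                      2, span, "*"), 2, bounds[, 1], "+")
  if (!is.null(extra_starts)) cand <- rbind(cand, extra_starts)
  vals <- objective(cand)
  ord <- order(vals)
  starts <- cand[ord[seq_len(min(n_polish, length(ord)))], , drop = FALSE]
  best_x <- cand[ord[1], ]
  best_v <- vals[ord[1]]
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ],
                   fn = function(x) objective(matrix(x, nrow = 1)),
                   method = "L-BFGS-B",
                   lower = bounds[, 1], upper = bounds[, 2],
                   control = list(maxit = maxit, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(res) && res$value < best_v) {
      best_v <- res$value
      best_x <- res$par
    }
  }
  list(x = best_x, value = best_v)
}

#' Propose the next configuration to evaluate
#'
#' Minimizes the eLCB acquisition over the (possibly restricted) torsion box
#' by random-candidate screening plus bounded local polishing. Deterministic
#' under a fixed RNG state.
#'
#' @param model a fitted `gp_model`.
#' @param bounds d x 2 matrix of per-dimension bounds (degrees).
#' @param kappa exploration weight.
#' @param n_candidates,n_polish screening and polishing effort.
#' @return Dihedral vector (degrees, within bounds).
#' @export
propose_next <- function(model, bounds, kappa, n_candidates = 300,
                         n_polish = 3) {
  out <- optimize_in_box(function(M) elcb(model, M, kappa), bounds,
                         n_candidates = n_candidates, n_polish = n_polish)
  out$x
}

#' Predicted global minimum of the surrogate PES
#'
#' Minimizes the posterior mean (a kappa = 0 acquisition search seeded with
#' the best observed training point).
#'
#' @param model a fitted `gp_model`.
#' @param bounds d x 2 matrix of per-dimension bounds (degrees).
#' @param n_candidates,n_polish search effort.
#' @return List with `x` (location, degrees) and `energy` (eV).
#' @export
predicted_minimum <- function(model, bounds, n_candidates = 150, n_polish = 2) {
  best_obs <- model$X[which.min(model$y), , drop = FALSE]
  out <- optimize_in_box(function(M) gp_mean(model, M), bounds,
                         n_candidates = n_candidates, n_polish = n_polish,
                         extra_starts = best_obs)
  list(x = out$x, energy = out$value)
}
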