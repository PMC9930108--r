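test_that("extract_minima recovers the analytic minima of a cosine surface", {
  # fit the surrogate to a dense design of cos(d1) + cos(2 d2): minima at
  # (180, 90) and (180, 270)
  set.seed(31)
  X <- as.matrix(expand.grid(seq(0, 330, by = 30), seq(0, 330, by = 30)))
  colnames(X) <- NULL
  y <- cos(X[, 1] * pi / 180) + cos(2 * X[, 2] * pi / 180)
  model <- fit_gp(X, y, periodic = c(TRUE, TRUE), n_starts = 1)
  bounds <- cbind(c(0, 0), c(360, 360))
  cand <- extract_minima(model, bounds, n_starts = 60, seed = 2)
  expect_gte(nrow(cand), 2)
  best2 <- as.matrix(cand[1:2, c("d1", "d2")])
  hits <- vapply(list(c(180, 90), c(180, 270)), function(m) {
    min(apply(best2, 1, function(r) max_wrap_diff(r, m)))
  }, numeric(1))
  expect_lt(max(hits), 2)
  # stationarity of every candidate
  for (i in seq_len(nrow(cand))) {
    g <- boconf:::num_grad(function(x) boconf:::gp_mean(model, x),
                           as.numeric(cand[i, c("d1", "d2")]))
    expect_lt(max(abs(g)), 1e-3)
  }
})

test_that("a constant surrogate yields a single representative candidate", {
  X <- matrix(runif(10, 0, 360), ncol = 2)
  suppressWarnings(model <- fit_gp(X, rep(2, 5), periodic = c(TRUE, TRUE)))
  cand <- extract_minima(model, cbind(c(0, 0), c(360, 360)), n_starts = 20,
                         seed = 3)
  expect_equal(nrow(cand), 1)
})

test_that("two-well surrogates give both wells across seeds", {
  ls <- make_synthetic_landscape(1, 2, seed = 33)
  X <- matrix(seq(0, 355, by = 5), ncol = 1)
  y <- landscape_energy(ls, X)
  model <- fit_gp(X, y, periodic = TRUE, n_starts = 1)
  found <- 0
  for (s in 1:10) {
    cand <- extract_minima(model, matrix(c(0, 360), ncol = 2),
                           n_starts = 50, seed = s)
    hit <- all(vapply(1:2, function(k) {
      any(vapply(cand$d1, function(v) {
        max_wrap_diff(v, ls$centers[k, 1]) < 3
      }, logical(1)))
    }, logical(1)))
    found <- found + hit
  }
  expect_gte(found, 9.5)  # >= 95% of seeded runs
})

test_that("refine_minima pulls candidates onto centers and flags failures", {
  ls <- make_synthetic_landscape(2, 2, n_failure_regions = 1, seed = 35,
                                 failure_fraction = 0.15)
  ctr <- ls$centers[1, ]
  cand <- data.frame(d1 = c(ctr[1], ctr[1] + 5,
                            boconf:::canon_angle(rowMeans(ls$failure_regions[[1]]))[1]),
                     d2 = c(ctr[2], ctr[2] - 5,
                            boconf:::canon_angle(rowMeans(ls$failure_regions[[1]]))[2]),
                     surrogate_energy = NA)
  recs <- refine_minima(cand, ls)
  # the failure-region candidate is excluded
  expect_equal(nrow(recs), 2)
  for (i in 1:2) {
    expect_lt(max_wrap_diff(as.numeric(recs[i, c("d1", "d2")]), ctr), 0.1)
  }
  expect_lte(recs$energy[1], landscape_energy(ls, ctr))
})

test_that("purge_duplicates applies the study thresholds with AND semantics", {
  recs <- data.frame(d1 = c(100, 105, 100), d2 = c(50, 53, 50),
                     energy = c(-1.0, -0.999, -0.90))
  out <- purge_duplicates(recs)
  # rows 1 and 2 merge (5 deg, 0.001 eV); row 3 is kept: same geometry but
  # energy differs by 0.1 eV > 0.0057
  expect_equal(nrow(out), 2)
  expect_equal(out$energy, c(-1.0, -0.90))
  expect_equal(nrow(purge_duplicates(recs[0, ])), 0)
})

test_that("purge_duplicates follows greedy-by-energy chain semantics and is idempotent", {
  # A ~ B, B ~ C, A !~ C: A kept, B dropped (dup of A), C kept (not dup of A)
  recs <- data.frame(d1 = c(0, 8, 16), d2 = c(0, 0, 0),
                     energy = c(-1.000, -0.998, -0.996))
  out <- purge_duplicates(recs)
  expect_equal(out$d1, c(0, 16))
  expect_identical(purge_duplicates(out), out)
  # matches exhaustive enumeration of the greedy rule on random inputs
  set.seed(36)
  for (rep in 1:20) {
    n <- 12
    r <- data.frame(d1 = runif(n, 0, 360), d2 = runif(n, 0, 360),
                    energy = runif(n, -1, -0.9))
    cfg <- dedup_config(delta_d_max = 40, delta_e = 0.03)
    got <- purge_duplicates(r, cfg)
    # independent brute-force of the greedy rule
    ord <- order(r$energy)
    kept <- integer(0)
    for (i in ord) {
      dup <- FALSE
      for (j in kept) {
        dmax <- max(abs(((r$d1[i] - r$d1[j] + 180) %% 360) - 180),
                    abs(((r$d2[i] - r$d2[j] + 180) %% 360) - 180))
        if (dmax <= 40 && abs(r$energy[i] - r$energy[j]) <= 0.03) {
          dup <- TRUE; break
        }
      }
      if (!dup) kept <- c(kept, i)
    }
    expect_equal(got$energy, r$energy[kept])
    expect_identical(purge_duplicates(got, cfg), got)
  }
})

test_that("no kept pair remains mutually duplicate (greedy soundness)", {
  set.seed(37)
  r <- data.frame(d1 = runif(30, 0, 360), d2 = runif(30, 0, 360),
                  energy = runif(30, -1, 0))
  cfg <- dedup_config(30, 0.2)
  out <- purge_duplicates(r, cfg)
  if (nrow(out) > 1) {
    for (i in 1:(nrow(out) - 1)) for (j in (i + 1):nrow(out)) {
      dmax <- max(abs(((out$d1[i] - out$d1[j] + 180) %% 360) - 180),
                  abs(((out$d2[i] - out$d2[j] + 180) %% 360) - 180))
      expect_false(dmax <= cfg$delta_d_max &&
                   abs(out$energy[i] - out$energy[j]) <= cfg$delta_e)
    }
  }
})

test_that("the end-to-end pipeline returns one record per planted well", {
  m <- run_minima_recovery(3, k = 3, iterations = 150)
  expect_equal(nrow(m$records), 3)
  expect_lt(max(m$match), 2)
})
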