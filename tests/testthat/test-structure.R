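test_that("measure_dihedral reproduces planar and constructed angles", {
  mk <- function(coords) {
    atomic_structure(rep("C", 4), coords, rep(TRUE, 4),
                     rbind(c(0, 1), c(1, 2), c(2, 3)))
  }
  # planar cis: a and d on the same side of the b-c bond
  cis <- mk(rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1, 0)))
  expect_equal(measure_dihedral(cis, 0:3), 0)
  trans <- mk(rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, -1, 0)))
  expect_equal(measure_dihedral(trans, 0:3), 180)
  # axis-angle construction oracle across the circle
  for (phi in c(10, 60, 123.4, 249, 355)) {
    st <- mk(chain_with_dihedral(phi))
    expect_equal(measure_dihedral(st, 0:3), phi, tolerance = 1e-9)
  }
})

test_that("measure_dihedral rejects collinear triples", {
  st <- atomic_structure(rep("C", 4),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
                         rep(TRUE, 4), rbind(c(0, 1), c(1, 2), c(2, 3)))
  expect_error(measure_dihedral(st, 0:3), "collinear")
})

test_that("measure_dihedral agrees with an external torsion implementation", {
  skip_if_not_installed("bio3d")
  set.seed(42)
  for (rep in 1:10) {
    coords <- matrix(rnorm(12, sd = 2), 4, 3)
    ok <- tryCatch({
      st <- atomic_structure(rep("C", 4), coords, rep(TRUE, 4),
                             rbind(c(0, 1), c(1, 2), c(2, 3)))
      ours <- measure_dihedral(st, 0:3)
      ref <- bio3d::torsion.xyz(as.vector(t(coords)), atm.inc = 4)
      expect_equal(ours, (ref[1] + 360) %% 360, tolerance = 1e-6)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
  }
})

test_that("set_dihedrals round-trips, preserves rigid fragments, leaves environment fixed", {
  toy <- toy_chain_molecule()
  st <- toy$structure; spec <- toy$spec
  bl0 <- all_bond_lengths(st)
  set.seed(7)
  for (rep in 1:15) {
    target <- runif(2, 0, 360)
    posed <- set_dihedrals(st, spec, target)
    got <- vapply(1:2, function(i) measure_dihedral(posed, spec$quads[i, ]),
                  numeric(1))
    expect_lt(max_wrap_diff(got, target), 1e-6)
    expect_lt(max(abs(all_bond_lengths(posed) - bl0)), 1e-9)
    expect_identical(posed$coords[!posed$mobile_mask, ],
                     st$coords[!st$mobile_mask, ])
  }
})

test_that("set_dihedrals identity and 360-degree shifts leave coordinates unchanged", {
  toy <- toy_chain_molecule()
  cur <- vapply(1:2, function(i) measure_dihedral(toy$structure, toy$spec$quads[i, ]),
                numeric(1))
  same <- set_dihedrals(toy$structure, toy$spec, cur)
  expect_lt(max(abs(same$coords - toy$structure$coords)), 1e-10)
  shifted <- set_dihedrals(toy$structure, toy$spec, cur + 360)
  expect_lt(max(abs(shifted$coords - toy$structure$coords)), 1e-9)
})

test_that("set_dihedrals is idempotent and enforces bounds", {
  toy <- toy_chain_molecule()
  spec <- torsion_spec(toy$spec$quads, lower = c(0, 90), upper = c(360, 270),
                       structure = toy$structure)
  once <- set_dihedrals(toy$structure, spec, c(200, 120))
  twice <- set_dihedrals(once, spec, c(200, 120))
  expect_identical(once$coords, twice$coords)
  expect_error(set_dihedrals(toy$structure, spec, c(200, 80)), "outside bounds")
})

test_that("min_pair_distance matches brute force and handles trivial cases", {
  st <- atomic_structure(c("C", "Au"), rbind(c(0, 0, 0), c(3, 4, 0)),
                         c(TRUE, FALSE), matrix(integer(0), ncol = 2))
  expect_equal(min_pair_distance(st), 5)
  st0 <- atomic_structure(c("C", "Au"), rbind(c(1, 1, 1), c(1, 1, 1)),
                          c(TRUE, FALSE), matrix(integer(0), ncol = 2))
  expect_equal(min_pair_distance(st0), 0)
  set.seed(11)
  A <- matrix(runif(150, 0, 10), 50)
  B <- matrix(runif(150, 0, 10), 50)
  st2 <- atomic_structure(rep(c("C", "Au"), each = 50), rbind(A, B),
                          rep(c(TRUE, FALSE), each = 50),
                          matrix(integer(0), ncol = 2))
  brute <- min(vapply(1:50, function(i) {
    min(sqrt(colSums((t(B) - A[i, ])^2)))
  }, numeric(1)))
  expect_equal(min_pair_distance(st2), brute, tolerance = 1e-9)
  st3 <- atomic_structure("C", matrix(0, 1, 3), TRUE, matrix(integer(0), ncol = 2))
  expect_error(min_pair_distance(st3), "environment")
})

test_that("random_configurations respects bounds, moments, and determinism", {
  quads <- rbind(c(0L, 1L, 2L, 3L))
  degenerate <- torsion_spec(quads, lower = 0, upper = 1e-12, periodic = FALSE,
                             rotating = list(3L))
  # degenerate bounds collapse to (essentially) a single value
  expect_true(all(random_configurations(degenerate, 5, 1) < 1e-11))
  full <- torsion_spec(quads, rotating = list(3L))
  x <- random_configurations(full, 10000, 3)
  se <- sqrt(360^2 / 12 / 10000)
  expect_lt(abs(mean(x) - 180), 3 * se)
  expect_true(all(x >= 0 & x < 360))
  expect_identical(random_configurations(full, 100, 5),
                   random_configurations(full, 100, 5))
})

test_that("rotating sets are derived by graph cut and honor overrides", {
  toy <- toy_chain_molecule()
  # torsion about bond 1-2: rotating side contains atoms 2..4 side minus b
  rot <- toy$spec$rotating[[1]]
  expect_true(3 %in% rot)
  expect_false(0 %in% rot)
  expect_false(1 %in% rot)
  # a ring edge is not a cut: expect an error
  ringb <- rbind(c(0, 1), c(1, 2), c(2, 0))
  st <- atomic_structure(rep("C", 3), diag(3), rep(TRUE, 3), ringb)
  expect_error(torsion_spec(rbind(c(0L, 1L, 2L, 0L))), NA) # no structure: no derivation
  expect_error(boconf:::derive_rotating_set(ringb, 0, 1, 2), "cut")
})
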