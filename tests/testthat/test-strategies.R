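# Counting backend: a 1-D landscape-like backend that records every energy
# evaluation, with a clash box on d1 in [300, 340].
counting_backend <- function(fail_box = NULL) {
  env <- new.env()
  env$calls <- 0
  be <- structure(list(
    eval_fn = function(x) {
      env$calls <- env$calls + 1
      if (!is.null(fail_box) && x[1] >= fail_box[1] && x[1] <= fail_box[2]) {
        return(energy_evaluation("failure", d_min = 2.0))
      }
      energy_evaluation("success", energy = cos(x[1] * pi / 180), d_min = 2.0)
    },
    dmin_fn = function(x) if (x[1] >= 300 && x[1] <= 340) 1.2 else 2.0
  ), class = "energy_backend")
  list(backend = be, counter = env)
}

test_that("safe-distance strategy substitutes E0 without calling the backend", {
  cb <- counting_backend()
  pol <- clash_policy("safe_distance")
  out <- strategy_ii_target(c(320), cb$backend, pol)
  expect_equal(out$e_new, 6.0)
  expect_identical(out$provenance, "substituted_constant")
  expect_identical(cb$counter$calls, 0)
  # pass-through branch
  out2 <- strategy_ii_target(c(10), cb$backend, pol)
  expect_equal(out2$e_new, cos(10 * pi / 180))
  expect_identical(out2$provenance, "evaluated")
  expect_identical(cb$counter$calls, 1)
})

test_that("safe-distance boundary D_min == D0 goes to the evaluated branch", {
  be <- structure(list(
    eval_fn = function(x) energy_evaluation("success", energy = 0.3,
                                            d_min = 1.4),
    dmin_fn = function(x) 1.4
  ), class = "energy_backend")
  out <- strategy_ii_target(c(0), be, clash_policy("safe_distance"))
  expect_identical(out$provenance, "evaluated")
  expect_equal(out$e_new, 0.3)
})

test_that("backend failure on a safe structure falls back to E0 with a warning", {
  cb <- counting_backend(fail_box = c(0, 50))
  expect_warning(
    out <- strategy_ii_target(c(20), cb$backend, clash_policy("safe_distance")),
    "substituting E0")
  expect_equal(out$e_new, 6.0)
  expect_identical(out$provenance, "penalty")
})

test_that("energy transform: identity below Ecut, closed form above, penalty on failure", {
  pol <- clash_policy("energy_transform")
  be_ok <- structure(list(eval_fn = function(x) {
    energy_evaluation("success", energy = x[1], d_min = 3)
  }), class = "energy_backend")
  low <- strategy_iii_target(c(1.5), be_ok, pol)
  expect_identical(low$e_new, 1.5)        # bit-identical pass-through
  expect_identical(low$provenance, "evaluated")
  # E = 2e => e_new = 2 * (1 + ln e) = 4 exactly
  hi <- strategy_iii_target(c(2 * exp(1)), be_ok, pol)
  expect_equal(hi$e_new, 4.0, tolerance = 1e-12)
  expect_identical(hi$provenance, "transformed")
  be_fail <- structure(list(eval_fn = function(x) {
    energy_evaluation("failure", d_min = 1)
  }), class = "energy_backend")
  pen <- strategy_iii_target(c(0), be_fail, pol)
  expect_identical(pen$e_new, 4.5)
  expect_identical(pen$provenance, "penalty")
})

test_that("the attenuation transform is continuous, slope-1 at Ecut, and order-preserving", {
  Ecut <- 2.0
  eps <- 1e-7
  expect_equal(attenuate_energy(Ecut - eps, Ecut),
               attenuate_energy(Ecut + eps, Ecut), tolerance = 1e-5)
  slope <- (attenuate_energy(Ecut + eps, Ecut) -
            attenuate_energy(Ecut - eps, Ecut)) / (2 * eps)
  expect_equal(slope, 1.0, tolerance = 1e-5)
  set.seed(14)
  E <- sort(runif(500, 0.01, 20))
  tr <- attenuate_energy(E, Ecut)
  expect_true(all(diff(tr) > 0))
  expect_identical(tr[E < Ecut], E[E < Ecut])
})

test_that("domain restriction narrows bounds, drops periodicity, confines sampling", {
  toy <- toy_chain_molecule()
  spec <- toy$spec
  rspec <- strategy_i_domain(spec, rbind(c(70, 210), c(NA, NA)))
  expect_equal(rspec$lower[1], 70)
  expect_equal(rspec$upper[1], 210)
  expect_false(rspec$periodic[1])
  expect_true(rspec$periodic[2])
  draws <- random_configurations(rspec, 1000, 9)
  expect_true(all(draws[, 1] >= 70 & draws[, 1] <= 210))
  # full-period restriction only flips nothing
  full <- strategy_i_domain(spec, rbind(c(0, 360), c(NA, NA)))
  expect_true(full$periodic[1])
  expect_error(strategy_i_domain(spec, rbind(c(210, 70), c(NA, NA))), "empty")
})

test_that("all strategies leave sub-Ecut non-clashing evaluations bit-identical", {
  raw <- 0.73125
  be <- structure(list(
    eval_fn = function(x) energy_evaluation("success", energy = raw, d_min = 3),
    dmin_fn = function(x) 3.0
  ), class = "energy_backend")
  for (mode in c("safe_distance", "energy_transform", "restricted_domain", "none")) {
    out <- boconf:::apply_policy(c(0), be, clash_policy(mode))
    expect_identical(out$e_new, raw)
  }
})
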