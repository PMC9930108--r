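test_that("similarity index: self-similarity, antipodal case, symmetry, range", {
  a <- similarity_vector(c(10, 60, 120, 180, 240), subset = 2:5)
  expect_equal(similarity_index(a, a), 1.0)
  v0 <- similarity_vector(c(0, 0, 0, 0, 0), subset = 2:5)
  v180 <- similarity_vector(c(0, 180, 180, 180, 180), subset = 2:5)
  expect_equal(similarity_index(v0, v180), -1.0)
  # arithmetic oracle on a fixed pair
  da <- c(60, 120, 180, 240); db <- c(0, 90, 180, 270)
  va <- cos(da * pi / 180); vb <- cos(db * pi / 180)
  want <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  expect_equal(similarity_index(va, vb), want, tolerance = 1e-12)
  set.seed(41)
  for (rep in 1:2000) {
    x <- runif(4, -1, 1); y <- runif(4, -1, 1)
    s <- similarity_index(x, y)
    expect_true(s >= -1 && s <= 1)
    expect_equal(s, similarity_index(y, x))
  }
  expect_error(similarity_index(c(0, 0), c(1, 0)), "zero-norm")
})

test_that("hydrogen bonds obey the distance cutoff and exclusion rules", {
  # constructed geometry: amino N-H ... carbonyl O at N..O = 2.9 A
  el <- c("N", "H", "H", "C", "C", "O", "O", "H")
  coords <- rbind(
    c(0, 0, 0),       # N (donor)
    c(-0.5, 0.8, 0),  # H on N
    c(0.5, -0.2, 0.9),# H on N, points toward O
    c(1.2, 0.9, 0),   # C alpha-ish
    c(2.2, -0.5, 0.5),# carboxyl C
    c(2.0, -1.2, 1.5),# carbonyl O at ~2.9 A from N
    c(3.4, -0.2, 0.1),# hydroxyl O
    c(3.9, -0.9, 0.5) # H on hydroxyl O
  )
  bonds <- rbind(c(0, 1), c(0, 2), c(0, 3), c(3, 4), c(4, 5), c(4, 6), c(6, 7))
  st <- atomic_structure(el, coords, rep(TRUE, 8), bonds)
  hb <- detect_hbonds(st)
  expect_true(nrow(hb) >= 1)
  top <- hb[hb$donor == 0 & hb$acceptor == 5, ]
  expect_equal(nrow(top), 1)
  expect_equal(top$distance, sqrt(sum((coords[1, ] - coords[6, ])^2)))
  expect_true(all(hb$distance <= 3.5))
  # directly bonded pairs are never reported
  expect_false(any(hb$donor == 4 & hb$acceptor == 5))
  # tighter cutoff removes the bond
  expect_equal(nrow(detect_hbonds(st, hbond_config(r_hb = 2.0))), 0)
  # invariance under rigid motion
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  st2 <- atomic_structure(el, coords %*% R + 5, rep(TRUE, 8), bonds)
  hb2 <- detect_hbonds(st2)
  expect_equal(hb2$distance, hb$distance, tolerance = 1e-9)
  expect_identical(hb2$donor, hb$donor)
})

test_that("hydrogen bonds are typed I-IV from groups and carboxyl isomer", {
  fx <- make_fixture_system()
  # amino N-H to carbonyl O depends on the carboxyl isomer
  hb <- list(donor = 6, acceptor = 10)
  expect_identical(classify_hbond_type(fx$structure, hb, "trans"), "IV")
  expect_identical(classify_hbond_type(fx$structure, hb, "cis"), "I")
  # carboxyl O-H to amino N
  expect_identical(classify_hbond_type(fx$structure,
                                       list(donor = 11, acceptor = 6), "cis"),
                   "II")
  # amino N-H to hydroxyl O
  expect_identical(classify_hbond_type(fx$structure,
                                       list(donor = 6, acceptor = 11), "trans"),
                   "III")
  # outside the table: anything involving S
  expect_identical(classify_hbond_type(fx$structure,
                                       list(donor = 6, acceptor = 0), "cis"),
                   "other")
  # the table is data: a relabeled copy changes the output predictably
  tab <- default_hbond_types()
  tab$type[tab$type == "II"] <- "Z"
  expect_identical(classify_hbond_type(fx$structure,
                                       list(donor = 11, acceptor = 6), "cis",
                                       table = tab), "Z")
})

test_that("a constructed trans-COOH NH...O=C geometry is typed IV end-to-end", {
  fx <- make_fixture_system()
  # rotate the carboxyl H to trans and swing the backbone so N-H approaches O
  posed <- set_dihedrals(fx$structure, fx$spec, c(180, 60, 180))
  expect_identical(cooh_cis_trans(posed), "trans")
  # measure the N..O distance directly; classification must follow the table
  hb <- list(donor = 6, acceptor = 10)
  expect_identical(classify_hbond_type(posed, hb), "IV")
})

test_that("carboxyl cis/trans follows the H-O-C=O dihedral threshold rule", {
  fx <- make_fixture_system()
  for (case in list(list(d3 = 0, want = "cis"), list(d3 = 180, want = "trans"),
                    list(d3 = 100, want = "trans"), list(d3 = 80, want = "cis"))) {
    posed <- set_dihedrals(fx$structure, fx$spec, c(180, 180, case$d3))
    expect_identical(cooh_cis_trans(posed), case$want)
  }
})

test_that("phase-space scan fractions are conserved, bounded and reproducible", {
  fx <- make_fixture_system()
  scan <- phase_space_scan(fx$structure, fx$spec, n = 400, seed = 5,
                           distance_threshold = 1.4)
  expect_true(scan$safe_fraction >= 0 && scan$safe_fraction <= 1)
  scan2 <- phase_space_scan(fx$structure, fx$spec, n = 400, seed = 5,
                            distance_threshold = 1.4)
  expect_identical(scan$samples, scan2$samples)
  w <- window_fraction(scan, 1, c(300, 340))
  out <- window_fraction(scan, 1, c(340, 660))   # complement, wrapping
  # conservation: in-window + out-window weighted fractions = overall
  tot <- w$safe_fraction * w$n_in_window + out$safe_fraction * out$n_in_window
  expect_equal(tot / scan$n, scan$safe_fraction, tolerance = 1e-12)
  expect_equal(w$n_in_window + out$n_in_window, scan$n)
})

test_that("the planted d1 clash window concentrates low D_min samples", {
  fx <- make_fixture_system()
  scan <- phase_space_scan(fx$structure, fx$spec, n = 800, seed = 7,
                           distance_threshold = 1.4)
  inw <- window_fraction(scan, 1, c(300, 340))
  outw <- window_fraction(scan, 1, c(340, 660))
  # clashes are much more frequent inside the planted window
  expect_lt(inw$safe_fraction, outw$safe_fraction)
  # far-away environment: everything is safe
  far <- fx$structure
  far$coords[!far$mobile_mask, ] <- far$coords[!far$mobile_mask, ] + 500
  sc2 <- phase_space_scan(far, fx$spec, n = 100, seed = 3,
                          distance_threshold = 10)
  expect_equal(sc2$safe_fraction, 1.0)
})
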