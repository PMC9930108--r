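#' Construct the packaged test system
#'
#' Builds, from idealized internal coordinates, a cysteine-like molecule
#' (thiolate anchor S, CH2, CH backbone, NH2 amino group, COOH carboxyl
#' group; 13 atoms) attached through its sulfur to a rigid 10-atom metal
#' cluster. Three torsions are declared: the anchor torsion d1 about the
#' S-CB bond, the backbone torsion d2 about CB-CA, and the carboxyl torsion
#' d3 (O=C-O-H). One cluster atom is deliberately placed so that a
#' documented d1 window (around 300-340 degrees) drives the amino group into
#' steric overlap, giving the phase-space scan a planted clash region.
#'
#' This is a synthetic stand-in system constructed for testing; it is not a
#' structure taken from any experimental or deposited dataset.
#'
#' @return List with `structure` (an `atomic_structure`) and `spec`
#'   (a `torsion_spec` with rotating sets attached).
#' @export
make_fixture_system <- function() {
  # --- mobile molecule, NeRF chain with idealized bond lengths/angles ---
  # indices (0-based): 0 S, 1 CB, 2 HB1, 3 HB2, 4 CA, 5 HA, 6 N, 7 HN1,
  # 8 HN2, 9 C, 10 O (carbonyl), 11 OH, 12 HO
  au0 <- c(0, 0, 0)                      # anchor cluster atom
  s   <- c(2.30, 0, 0)                   # S-Au 2.30 A
  cb  <- place_atom_internal(c(-1, 0.8, 0), au0, s, 1.82, 103, 75)
  ca  <- place_atom_internal(au0, s, cb, 1.53, 112, 180)
  hb1 <- place_atom_internal(au0, s, cb, 1.09, 109, 60)
  hb2 <- place_atom_internal(au0, s, cb, 1.09, 109, 300)
  n   <- place_atom_internal(s, cb, ca, 1.47, 110, 60)
  c9  <- place_atom_internal(s, cb, ca, 1.52, 110, 180)
  ha  <- place_atom_internal(s, cb, ca, 1.09, 108, 300)
  hn1 <- place_atom_internal(cb, ca, n, 1.01, 109, 60)
  hn2 <- place_atom_internal(cb, ca, n, 1.01, 109, 180)
  o   <- place_atom_internal(cb, ca, c9, 1.21, 121, 0)
  oh  <- place_atom_internal(cb, ca, c9, 1.34, 113, 180)
  ho  <- place_atom_internal(o, c9, oh, 0.97, 106, 0)   # cis COOH start

  mol_coords <- rbind(s, cb, hb1, hb2, ca, ha, n, hn1, hn2, c9, o, oh, ho)
  mol_el <- c("S", "C", "H", "H", "C", "H", "N", "H", "H", "C", "O", "O", "H")
  # molecule-internal bonds, still 0-based *within the molecule*
  mol_bonds <- rbind(
    c(0, 1), c(1, 2), c(1, 3), c(1, 4), c(4, 5), c(4, 6), c(6, 7), c(6, 8),
    c(4, 9), c(9, 10), c(9, 11), c(11, 12)
  )

  # --- rigid environment: compact 10-atom cluster behind the anchor ---
  env <- rbind(
    au0,
    c(-2.7, 0.9, 0.4), c(-2.4, -1.3, -0.8), c(-1.5, 2.4, -1.1),
    c(-1.7, -0.4, 2.2), c(-3.9, -0.5, 1.0), c(-0.9, 1.2, -2.8),
    c(-1.2, -2.6, 1.2), c(-3.3, 1.8, -1.4)
  )
  env_el <- rep("Au", nrow(env))

  n_mol <- nrow(mol_coords)
  elements <- c(mol_el, env_el)
  coords <- rbind(mol_coords, env)
  mobile <- c(rep(TRUE, n_mol), rep(FALSE, nrow(env)))
  env_anchor <- n_mol               # 0-based index of the anchor cluster atom
  bonds <- rbind(mol_bonds, c(0L, env_anchor))

  st <- atomic_structure(elements, coords, mobile, bonds)
  spec <- torsion_spec(
    rbind(c(env_anchor, 0L, 1L, 4L),   # d1: Au-S-CB-CA, about S-CB
          c(0L, 1L, 4L, 9L),           # d2: S-CB-CA-C, about CB-CA
          c(10L, 9L, 11L, 12L)),       # d3: O=C-O-H, about C-OH
    structure = st
  )

  # plant a clash: pose d1 = 320 and drop one more cluster atom 0.8 A from
  # the amino nitrogen so that d1 near 320 always collides
  posed <- set_dihedrals(st, spec, c(320, measure_dihedral(st, spec$quads[2, ]),
                                     measure_dihedral(st, spec$quads[3, ])))
  npos <- posed$coords[7, ]                   # atom 6 (N), 1-based row 7
  blocker <- npos + c(0, 0, 0.8)
  elements <- c(elements, "Au")
  coords <- rbind(st$coords, blocker)
  mobile <- c(mobile, FALSE)
  st <- atomic_structure(elements, coords, mobile, bonds)
  spec <- torsion_spec(spec$quads, lower = spec$lower, upper = spec$upper,
                       periodic = spec$periodic, structure = st)
  list(structure = st, spec = spec)
}

#' Serialize a synthetic landscape to a plain config list
#'
#' @param landscape a `synthetic_landscape`.
#' @return A nested list suitable for `yaml::write_yaml()`.
#' @export
landscape_to_config <- function(landscape) {
  list(
    dimension = landscape$dimension,
    baseline = landscape$baseline,
    centers = apply(landscape$centers, 1, as.numeric, simplify = FALSE),
    depths = as.numeric(landscape$depths),
    widths = as.numeric(landscape$widths),
    failure_regions = lapply(landscape$failure_regions, function(b) {
      list(lower = as.numeric(b[, 1]), upper = as.numeric(b[, 2]))
    }),
    clash_regions = lapply(landscape$clash_regions, function(b) {
      list(lower = as.numeric(b[, 1]), upper = as.numeric(b[, 2]))
    }),
    d_safe = landscape$d_safe, d_clash = landscape$d_clash,
    global_min = as.numeric(landscape$global_min),
    global_min_energy = landscape$global_min_energy
  )
}

#' Rebuild a synthetic landscape from a config list
#'
#' @param cfg list as produced by [landscape_to_config()] (e.g., read back
#'   from YAML).
#' @return A `synthetic_landscape`.
#' @export
landscape_from_config <- function(cfg) {
  centers <- do.call(rbind, lapply(cfg$centers, as.numeric))
  boxes <- function(lst) {
    lapply(lst, function(b) cbind(as.numeric(b$lower), as.numeric(b$upper)))
  }
  structure(
    list(dimension = cfg$dimension, centers = centers,
         depths = as.numeric(cfg$depths), widths = as.numeric(cfg$widths),
         baseline = cfg$baseline,
         failure_regions = boxes(cfg$failure_regions),
         clash_regions = boxes(cfg$clash_regions),
         d_safe = cfg$d_safe, d_clash = cfg$d_clash, period = 360,
         global_min = as.numeric(cfg$global_min),
         global_min_energy = cfg$global_min_energy),
    class = "synthetic_landscape"
  )
}

#' Generate packaged test assets
#'
#' Writes the fixture system (XYZ + torsion table), two synthetic-landscape
#' configs (with and without failure regions) and ready-to-run scan/search
#' config files into `dir`.
#'
#' @param dir output directory (created if missing).
#' @param seed seed for the landscape generation.
#' @return Named character vector of written file paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_fixture_system()
  paths <- c(
    structure = file.path(dir, "fixture.xyz"),
    torsions = file.path(dir, "fixture.tors"),
    landscape_basic = file.path(dir, "landscape_basic.yaml"),
    landscape_failures = file.path(dir, "landscape_failures.yaml"),
    scan_config = file.path(dir, "scan_config.yaml"),
    search_config = file.path(dir, "search_config.yaml")
  )
  write_xyz(fx$structure, paths["structure"], comment = "synthetic test system")
  write_torsion_spec(fx$spec, paths["torsions"])
  ls1 <- make_synthetic_landscape(2, 3, n_failure_regions = 0, seed = seed)
  ls2 <- make_synthetic_landscape(2, 3, n_failure_regions = 2, seed = seed,
                                  failure_fraction = 0.2)
  yaml::write_yaml(landscape_to_config(ls1), paths["landscape_basic"])
  yaml::write_yaml(landscape_to_config(ls2), paths["landscape_failures"])
  yaml::write_yaml(list(
    seed = 1, output_dir = file.path(dir, "scan_out"),
    structure = paths[["structure"]], torsions = paths[["torsions"]],
    scan = list(n = 1000, threshold = 1.4,
                windows = list(list(torsion = 1, window = c(70, 210))))
  ), paths["scan_config"])
  yaml::write_yaml(list(
    seed = 1, output_dir = file.path(dir, "search_out"),
    backend = list(type = "landscape", config = paths[["landscape_basic"]]),
    policy = list(mode = "energy_transform", Ecut = 2.0, Ep = 4.5),
    bo = list(iterations = 40, track_predicted_min = TRUE),
    postprocess = list(n_starts = 40, energy_window = 0.5)
  ), paths["search_config"])
  invisible(paths)
}
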