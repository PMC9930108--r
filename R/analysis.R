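#' Dihedral-cosine similarity vector
#'
#' Fingerprint of a conformer: the cosines of a declared subset of its
#' torsions. By default the first torsion is excluded — the anchor torsion
#' closest to the environment has no counterpart in isolated-molecule
#' references, so comparing it is not meaningful.
#'
#' @param dihedrals numeric vector of dihedral angles in degrees.
#' @param subset integer indices of the torsions to include (default: all
#'   but the first).
#' @return Numeric vector of cosines in `[-1, 1]`.
#' @export
similarity_vector <- function(dihedrals, subset = NULL) {
  if (is.null(subset)) subset <- setdiff(seq_along(dihedrals), 1L)
  cos(dihedrals[subset] * pi / 180)
}

#' Similarity index between two conformers
#'
#' Cosine of the angle between two dihedral-cosine vectors,
#' `dot(a, b) / (|a| |b|)`; symmetric and confined to `[-1, 1]`. Higher
#' values mean more similar torsional patterns.
#'
#' @param a,b numeric vectors of equal length (e.g., from
#'   [similarity_vector()]); neither may be all-zero.
#' @return The similarity index S_cos.
#' @export
similarity_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("similarity undefined for a zero-norm vector")
  s <- sum(a * b) / (na * nb)
  min(1, max(-1, s))
}

#' Pairwise similarity matrix
#'
#' @param A,B matrices of dihedral vectors (degrees, one conformer per row).
#' @param subset torsion subset passed to [similarity_vector()].
#' @return `nrow(A)` x `nrow(B)` matrix of S_cos values.
#' @export
similarity_matrix <- function(A, B, subset = NULL) {
  out <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    va <- similarity_vector(A[i, ], subset)
    for (j in seq_len(nrow(B))) {
      out[i, j] <- similarity_index(va, similarity_vector(B[j, ], subset))
    }
  }
  out
}

#' Hydrogen-bond detection configuration
#'
#' @param r_hb donor-heavy-atom to acceptor cutoff in Angstrom (default the
#'   study value 3.5).
#' @param angle_min optional minimum donor-H...acceptor angle in degrees;
#'   `NULL` (default) disables the angle filter — the criterion is then
#'   heavy-atom distance only.
#' @return An `hbond_config` object.
#' @export
hbond_config <- function(r_hb = 3.5, angle_min = NULL) {
  stopifnot(r_hb > 0)
  structure(list(r_hb = r_hb, angle_min = angle_min), class = "hbond_config")
}

neighbors_of <- function(bonds, i) {
  c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
}

are_bonded <- function(bonds, i, j) {
  any((bonds[, 1] == i & bonds[, 2] == j) | (bonds[, 1] == j & bonds[, 2] == i))
}

#' Detect intramolecular hydrogen bonds
#'
#' Finds donor--acceptor pairs within the mobile molecule: a donor is an N or
#' O carrying at least one H, an acceptor is any N or O; the pair is reported
#' when the heavy-atom distance is at most `r_hb` and donor and acceptor are
#' not covalently bonded to each other. Results are sorted by distance.
#'
#' @param structure an `atomic_structure` with bond topology.
#' @param config an [hbond_config()].
#' @return Data frame with 0-based columns `donor`, `hydrogen`, `acceptor`
#'   and `distance` (Angstrom).
#' @export
detect_hbonds <- function(structure, config = hbond_config()) {
  if (nrow(structure$bonds) == 0) stop("bond topology required for hydrogen-bond detection")
  el <- structure$elements
  mob <- which(structure$mobile_mask) - 1L
  heavy <- mob[el[mob + 1L] %in% c("N", "O")]
  rows <- list()
  for (don in heavy) {
    hyds <- neighbors_of(structure$bonds, don)
    hyds <- hyds[el[hyds + 1L] == "H" & hyds %in% mob]
    if (length(hyds) == 0) next
    for (acc in setdiff(heavy, don)) {
      if (are_bonded(structure$bonds, don, acc)) next
      dist <- sqrt(sum((structure$coords[don + 1L, ] -
                        structure$coords[acc + 1L, ])^2))
      if (dist > config$r_hb) next
      # attribute the bond to the donor H closest to the acceptor
      hd <- vapply(hyds, function(h) {
        sqrt(sum((structure$coords[h + 1L, ] - structure$coords[acc + 1L, ])^2))
      }, numeric(1))
      h <- hyds[which.min(hd)]
      if (!is.null(config$angle_min)) {
        v1 <- structure$coords[don + 1L, ] - structure$coords[h + 1L, ]
        v2 <- structure$coords[acc + 1L, ] - structure$coords[h + 1L, ]
        ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
        if (ang < config$angle_min) next
      }
      rows[[length(rows) + 1]] <- data.frame(donor = don, hydrogen = h,
                                             acceptor = acc, distance = dist)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$distance), , drop = FALSE]
}

# Functional-group role of atom `i` (0-based) from topology: one of
# "amino_N", "carbonyl_O", "hydroxyl_O" (the carboxyl O-H oxygen), or NA.
atom_group <- function(structure, i) {
  el <- structure$elements[i + 1L]
  nb <- neighbors_of(structure$bonds, i)
  nbel <- structure$elements[nb + 1L]
  if (el == "N" && sum(nbel == "H") >= 1 && any(nbel == "C")) return("amino_N")
  if (el == "O") {
    if (any(nbel == "H")) return("hydroxyl_O")
    carbons <- nb[nbel == "C"]
    for (cc in carbons) {
      cnb <- neighbors_of(structure$bonds, cc)
      oth <- cnb[structure$elements[cnb + 1L] == "O" & cnb != i]
      if (length(oth) > 0) return("carbonyl_O")  # O on a carboxyl carbon
    }
    return("carbonyl_O")  # lone =O
  }
  NA_character_
}

#' Default hydrogen-bond typing table
#'
#' The standard amino-acid conformer nomenclature for bonds between the
#' amino group and the carboxyl group: type I is amino N-H donating to the
#' carbonyl O with a cis carboxyl; type II is the carboxyl O-H donating to
#' the amino N; type III is amino N-H donating to the hydroxyl O; type IV is
#' amino N-H donating to the carbonyl O with a trans carboxyl. The table is
#' data, not code: supply a modified copy to [classify_hbond_type()] to
#' change the nomenclature.
#'
#' @return Data frame with columns `donor_group`, `acceptor_group`,
#'   `cooh_isomer` (`"cis"`, `"trans"` or `"any"`), `type`.
#' @export
default_hbond_types <- function() {
  data.frame(
    donor_group    = c("amino_N", "hydroxyl_O", "amino_N", "amino_N"),
    acceptor_group = c("carbonyl_O", "amino_N", "hydroxyl_O", "carbonyl_O"),
    cooh_isomer    = c("cis", "any", "any", "trans"),
    type           = c("I", "II", "III", "IV"),
    stringsAsFactors = FALSE
  )
}

#' Classify a hydrogen bond
#'
#' Table lookup on (donor group, acceptor group, carboxyl isomer); pairs
#' outside the table are labelled `"other"`.
#'
#' @param structure an `atomic_structure`.
#' @param hbond one row of the [detect_hbonds()] output (or a list with
#'   `donor` and `acceptor`, 0-based).
#' @param cooh_isomer `"cis"` or `"trans"`; defaults to
#'   [cooh_cis_trans()] on the structure.
#' @param table typing table (see [default_hbond_types()]).
#' @return Type label: `"I"`, `"II"`, `"III"`, `"IV"` or `"other"`.
#' @export
classify_hbond_type <- function(structure, hbond, cooh_isomer = NULL,
                                table = default_hbond_types()) {
  if (is.null(cooh_isomer)) cooh_isomer <- cooh_cis_trans(structure)
  dg <- atom_group(structure, hbond$donor)
  ag <- atom_group(structure, hbond$acceptor)
  if (is.na(dg) || is.na(ag)) return("other")
  hit <- table$donor_group == dg & table$acceptor_group == ag &
    (table$cooh_isomer == "any" | table$cooh_isomer == cooh_isomer)
  if (any(hit)) table$type[which(hit)[1]] else "other"
}

#' Carboxyl cis/trans classification
#'
#' Locates the COOH group (a carbon bonded to a hydroxyl O and a carbonyl O)
#' and classifies the H-O-C=O dihedral: values in `(-90, 90]` degrees are
#' cis, the rest trans.
#'
#' @param structure an `atomic_structure`.
#' @return `"cis"`, `"trans"`, or `NA` when no carboxyl group is present.
#' @export
cooh_cis_trans <- function(structure) {
  el <- structure$elements
  mob <- which(structure$mobile_mask) - 1L
  for (cc in mob[el[mob + 1L] == "C"]) {
    nb <- neighbors_of(structure$bonds, cc)
    ox <- nb[el[nb + 1L] == "O"]
    if (length(ox) != 2) next
    groups <- vapply(ox, function(o) atom_group(structure, o), "")
    if (!("hydroxyl_O" %in% groups) || !("carbonyl_O" %in% groups)) next
    oh <- ox[groups == "hydroxyl_O"][1]
    oc <- ox[groups == "carbonyl_O"][1]
    h <- neighbors_of(structure$bonds, oh)
    h <- h[el[h + 1L] == "H"][1]
    ang <- measure_dihedral(structure, c(h, oh, cc, oc))
    return(if (wrap180(ang) > -90 && wrap180(ang) <= 90) "cis" else "trans")
  }
  NA_character_
}

#' Phase-space clash scan
#'
#' Draws `n` uniform random dihedral configurations, poses the structure and
#' tabulates the shortest molecule--environment distance D_min against each
#' torsion — the scan used to locate a clash-free restriction window for the
#' restricted-domain strategy.
#'
#' @param structure an `atomic_structure`.
#' @param spec a `torsion_spec`.
#' @param n number of random configurations.
#' @param seed RNG seed.
#' @param distance_threshold D_min threshold in Angstrom defining "safe".
#' @return List of class `phase_space_scan`: `samples` (data frame of
#'   dihedrals and `d_min`), `safe_fraction` (overall fraction with
#'   `d_min > distance_threshold`), `threshold`, and the helper
#'   [window_fraction()] applies to it.
#' @export
phase_space_scan <- function(structure, spec, n, seed = 1,
                             distance_threshold = 1.0) {
  stopifnot(n >= 1)
  configs <- random_configurations(spec, n, seed)
  dmin <- numeric(n)
  for (i in seq_len(n)) {
    dmin[i] <- min_pair_distance(set_dihedrals(structure, spec, configs[i, ]))
  }
  samples <- data.frame(configs, d_min = dmin)
  structure(list(samples = samples, threshold = distance_threshold,
                 safe_fraction = mean(dmin > distance_threshold),
                 n = n, seed = seed),
            class = "phase_space_scan")
}

#' Safe fraction inside a candidate restriction window
#'
#' Fraction of scan samples whose torsion `torsion` lies inside
#' `[window[1], window[2]]` (wrapping allowed) and whose D_min exceeds the
#' scan threshold, computed over the in-window samples.
#'
#' @param scan a `phase_space_scan`.
#' @param torsion torsion index (1-based column of the scan).
#' @param window numeric `c(lower, upper)` in degrees.
#' @return List with `in_window_fraction` (share of samples in the window),
#'   `safe_fraction` (share of in-window samples above the threshold) and
#'   `n_in_window`.
#' @export
window_fraction <- function(scan, torsion, window) {
  v <- scan$samples[[paste0("d", torsion)]]
  inw <- vapply(v, angle_in_wrapped_interval, logical(1),
                lo = window[1], hi = window[2])
  nin <- sum(inw)
  list(in_window_fraction = mean(inw),
       safe_fraction = if (nin > 0) {
         mean(scan$samples$d_min[inw] > scan$threshold)
       } else NA_real_,
       n_in_window = nin)
}

#' @export
print.phase_space_scan <- function(x, ...) {
  cat(sprintf("phase_space_scan: %d samples, %.1f%% with D_min > %.2f A\n",
              x$n, 100 * x$safe_fraction, x$threshold))
  invisible(x)
}
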