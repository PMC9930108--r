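#' Read an extended XYZ file
#'
#' Standard XYZ layout (atom count, comment, then one line per atom). Two
#' optional extra per-atom columns are recognized: column 5 is the mobile flag
#' (1 = mobile molecule, 0 = fixed environment). Bond topology is carried in
#' the comment line as `bonds=i-j,k-l,...` with 0-based indices.
#'
#' @param path file path.
#' @return An `atomic_structure`. If no mobile column is present all atoms are
#'   marked mobile.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  comment <- lines[2]
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  elements <- vapply(rows, `[`, "", 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  mobile <- if (all(lengths(rows) >= 5)) {
    vapply(rows, function(r) as.numeric(r[5]), 0) > 0.5
  } else rep(TRUE, n)
  bonds <- parse_bonds_comment(comment)
  atomic_structure(elements, coords, mobile, bonds)
}

parse_bonds_comment <- function(comment) {
  m <- regmatches(comment, regexpr("bonds=[-0-9,]+", comment))
  if (length(m) == 0) return(matrix(integer(0), ncol = 2))
  pairs <- strsplit(strsplit(sub("bonds=", "", m), ",")[[1]], "-")
  t(vapply(pairs, function(p) as.integer(p), integer(2)))
}

#' Write an extended XYZ file
#'
#' @param structure an `atomic_structure`.
#' @param path file path.
#' @param comment optional extra comment text (bond topology is appended).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, comment = "") {
  n <- length(structure$elements)
  bstr <- if (nrow(structure$bonds) > 0) {
    paste0(" bonds=", paste(structure$bonds[, 1], structure$bonds[, 2],
                            sep = "-", collapse = ","))
  } else ""
  lines <- c(
    as.character(n),
    paste0(comment, bstr),
    sprintf("%-2s %18.12f %18.12f %18.12f %d",
            structure$elements,
            structure$coords[, 1], structure$coords[, 2], structure$coords[, 3],
            as.integer(structure$mobile_mask))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a multi-frame XYZ trajectory
#'
#' @param structures list of `atomic_structure` objects sharing one topology.
#' @param path file path.
#' @param comments character vector of per-frame comments.
#' @return `path`, invisibly.
#' @export
write_multi_xyz <- function(structures, path, comments = NULL) {
  if (is.null(comments)) comments <- rep("", length(structures))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    writeLines(as.character(length(s$elements)), con)
    writeLines(comments[i], con)
    writeLines(sprintf("%-2s %18.12f %18.12f %18.12f %d",
                       s$elements, s$coords[, 1], s$coords[, 2], s$coords[, 3],
                       as.integer(s$mobile_mask)), con)
  }
  invisible(path)
}

#' Read a torsion specification table
#'
#' Plain-text whitespace table, one torsion per row:
#' `a b c d lower upper periodic` with 0-based atom indices, bounds in
#' degrees, and periodic as 0/1. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param structure optional `atomic_structure` for deriving rotating sets.
#' @return A `torsion_spec`.
#' @export
read_torsion_spec <- function(path, structure = NULL) {
  tab <- utils::read.table(path, comment.char = "#")
  torsion_spec(as.matrix(tab[, 1:4]), lower = tab[, 5], upper = tab[, 6],
               periodic = tab[, 7] > 0.5, structure = structure)
}

#' Write a torsion specification table
#'
#' @param spec a `torsion_spec`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_torsion_spec <- function(spec, path) {
  lines <- c("# a b c d lower upper periodic (0-based atom indices, degrees)",
             sprintf("%d %d %d %d %g %g %d",
                     spec$quads[, 1], spec$quads[, 2], spec$quads[, 3],
                     spec$quads[, 4], spec$lower, spec$upper,
                     as.integer(spec$periodic)))
  writeLines(lines, path)
  invisible(path)
}

# Place a new atom by internal coordinates (NeRF construction): at distance
# `r` from atom C, with angle A-B-C...new = `theta` degrees at C, and dihedral
# A-B-C-new = `phi` degrees. a, b, c are Cartesian positions.
place_atom_internal <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
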