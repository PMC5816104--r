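#' Build an atomic structure table
#'
#' A structure is a tibble of atoms with one row per atom: integer `serial`,
#' chemical `element`, Cartesian `x`, `y`, `z` in Angstrom, `charge` in
#' elementary-charge units (may be `NA` until a charge model is assigned) and
#' a free-text `residue_tag` (e.g. `"SF4"`, `"CYS"`, `"HOH"`).  Atom order is
#' preserved exactly as given; nothing in the package ever re-sorts atoms.
#'
#' @param serial Integer atom identifiers, unique.
#' @param element Chemical symbols (`"Fe"`, `"S"`, `"C"`, ...).
#' @param x,y,z Cartesian coordinates in Angstrom; must be finite.
#' @param charge Partial charges in elementary-charge units, or `NA`.
#' @param residue_tag Residue/group label per atom.
#' @param title Free-text title stored as an attribute.
#' @return A tibble of class `fes_structure`.
#' @examples
#' fes_structure(
#'   serial = 1:2, element = c("Fe", "S"),
#'   x = c(0, 2.3), y = 0, z = 0
#' )
#' @export
fes_structure <- function(serial, element, x, y, z,
                          charge = NA_real_, residue_tag = "UNK",
                          title = "") {
  atoms <- tibble::tibble(
    serial = as.integer(serial),
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    charge = as.numeric(charge),
    residue_tag = as.character(residue_tag)
  )
  validate_structure(atoms)
  structure(atoms,
    class = c("fes_structure", class(tibble::tibble())),
    title = title
  )
}

#' @rdname fes_structure
#' @param atoms A data frame with the columns of [fes_structure()].
#' @export
as_fes_structure <- function(atoms, title = "") {
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"residue_tag" %in% names(atoms)) atoms$residue_tag <- "UNK"
  fes_structure(atoms$serial, atoms$element, atoms$x, atoms$y, atoms$z,
    charge = atoms$charge, residue_tag = atoms$residue_tag,
    title = title
  )
}

validate_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("serial", "element", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing)) {
    rlang::abort(paste0(
      "structure is missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(atoms$serial)) {
    rlang::abort("atom serials must be unique")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    rlang::abort("atom coordinates must be finite")
  }
  bad <- setdiff(unique(atoms$element), names(covalent_radii()))
  if (length(bad)) {
    rlang::abort(paste0(
      "unrecognised element symbol(s): ", paste(bad, collapse = ", ")
    ))
  }
  invisible(atoms)
}

coords_matrix <- function(structure, serials = NULL) {
  if (!is.null(serials)) {
    structure <- structure[match(serials, structure$serial), , drop = FALSE]
  }
  m <- as.matrix(structure[, c("x", "y", "z")])
  rownames(m) <- structure$serial
  m
}

atom_position <- function(structure, serial) {
  i <- match(serial, structure$serial)
  if (is.na(i)) rlang::abort(paste0("serial ", serial, " not in structure"))
  c(structure$x[i], structure$y[i], structure$z[i])
}

# Covalent radii (Angstrom), Cordero-style consensus values; enough of the
# periodic table for metalloprotein active sites and water/solvent.
covalent_radii <- function() {
  c(
    H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
    Na = 1.66, Mg = 1.41, P = 1.07, S = 1.05, Cl = 1.02,
    K = 2.03, Ca = 1.76, Mn = 1.39, Fe = 1.32, Co = 1.26,
    Ni = 1.24, Cu = 1.32, Zn = 1.22, Se = 1.20, Mo = 1.54
  )
}

#' Detect covalent bonds by a distance cutoff
#'
#' Two atoms are bonded when their separation is below 1.2 times the sum of
#' their covalent radii.  Used to discover QM/MM junctions automatically when
#' no explicit bond list is supplied.
#'
#' @param structure An [fes_structure()].
#' @return A tibble with columns `serial_i`, `serial_j` (`serial_i <
#'   serial_j`) and `distance_A`.
#' @export
detect_bonds <- function(structure) {
  validate_structure(structure)
  xyz <- coords_matrix(structure)
  d <- as.matrix(stats::dist(xyz))
  r <- covalent_radii()[structure$element]
  cutoff <- outer(r, r, `+`) * 1.2
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  tibble::tibble(
    serial_i = structure$serial[hit[, 1]],
    serial_j = structure$serial[hit[, 2]],
    distance_A = d[hit]
  ) |>
    dplyr::arrange(.data$serial_i, .data$serial_j)
}

#' Apply a rigid motion to a structure
#'
#' @param structure An [fes_structure()].
#' @param rotation 3x3 orthogonal matrix.
#' @param translation Length-3 shift in Angstrom.
#' @return The transformed structure (atom order, serials and charges
#'   untouched).
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  validate_structure(structure)
  xyz <- coords_matrix(structure) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

#' Read a structure from a PDB file
#'
#' Accepts both `ATOM` (protein) and `HETATM` (e.g. `SF4` cluster) records.
#' Alternate locations are resolved by keeping the highest-occupancy copy,
#' first record on a tie.  Partial charges are not stored in PDB files and
#' are set to `NA`.
#'
#' @param path Path to a PDB file.
#' @return An [fes_structure()].
#' @export
read_pdb_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at$o[is.na(at$o)] <- 1
  # altloc resolution: per (chain, resno, atom name) keep max occupancy,
  # first on tie
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- !logical(nrow(at))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(at$o[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- gsub("[^A-Za-z].*", "", at$elety[bad])
  elem <- paste0(
    toupper(substr(elem, 1, 1)),
    tolower(substr(elem, 2, nchar(elem)))
  )
  fes_structure(
    serial = at$eleno, element = elem,
    x = at$x, y = at$y, z = at$z,
    charge = NA_real_, residue_tag = at$resid,
    title = basename(path)
  )
}

#' Write a structure as an XYZ file
#'
#' @param structure An [fes_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  validate_structure(structure)
  lines <- c(
    as.character(nrow(structure)),
    attr(structure, "title") %||% "",
    sprintf(
      "%-2s %14.8f %14.8f %14.8f",
      structure$element, structure$x, structure$y, structure$z
    )
  )
  writeLines(lines, path)
  invisible(path)
}
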