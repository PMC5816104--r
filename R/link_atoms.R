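#' Default link-atom placement factors
#'
#' The hydrogen link atom sits on the severed bond at
#' `qm + scale * (cl - qm)`, i.e. the scale is the ratio of the equilibrium
#' X-H bond length to the X-CL bond length.  A small per-element-pair table
#' supplies defaults; the C-C -> C-H ratio 1.09/1.51 ~ 0.722 is the common
#' case (thiolate/serinate side chains cut at CA).
#'
#' @param qm_element Element of the QM-side bonded atom.
#' @param cl_element Element of the replaced environment atom.
#' @return A dimensionless scale in (0, 1].
#' @export
link_scale_default <- function(qm_element = "C", cl_element = "C") {
  xh <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)
  xc <- c(C = 1.51, N = 1.47, O = 1.43, S = 1.82)
  num <- xh[[qm_element]] %||% 1.09
  den <- xc[[cl_element]] %||% 1.51
  num / den
}

#' Place a hydrogen link atom on a severed bond
#'
#' The cap position is linearly related to the carbon link atom:
#' `qm_pos + scale * (cl_pos - qm_pos)`, exactly collinear with the two
#' input positions.
#'
#' @param qm_pos,cl_pos Length-3 Cartesian positions (Angstrom) of the
#'   QM-side atom and the environment (CL) atom; must differ.
#' @param scale Dimensionless factor in `[0, 1]`; 0 returns `qm_pos`, 1
#'   returns `cl_pos`.
#' @return Length-3 position of the hydrogen cap.
#' @examples
#' place_link_atom(c(0, 0, 0), c(1.51, 0, 0), 1.09 / 1.51)
#' @export
place_link_atom <- function(qm_pos, cl_pos, scale) {
  stopifnot(length(qm_pos) == 3, length(cl_pos) == 3)
  if (scale < 0 || scale > 1) rlang::abort("scale must lie in [0, 1]")
  if (all(qm_pos == cl_pos)) {
    rlang::abort("QM and CL positions coincide; cannot orient the link atom")
  }
  qm_pos + scale * (cl_pos - qm_pos)
}

#' Build the point-charge model of the environment
#'
#' Electrostatic embedding represents system 2 as an array of fixed partial
#' point charges, one per atom.  Every system-2 atom contributes except the
#' carbon link atoms, which are replaced by hydrogen caps on the QM side and
#' therefore excluded.  Charges are copied unmodified; the excluded CL
#' charge is not redistributed, so the model total may be non-integral.
#'
#' @param structure An [fes_structure()] whose system-2 atoms carry partial
#'   charges.
#' @param partition A [partition_structure()] result.
#' @return A tibble `x`, `y`, `z`, `q`, `serial` of class
#'   `point_charge_model`; zero rows when system 2 is empty.
#' @export
point_charge_model <- function(structure, partition) {
  validate_partition(structure, partition)
  keep <- setdiff(partition$system2, partition$junctions$cl_serial)
  rows <- structure[match(keep, structure$serial), , drop = FALSE]
  if (nrow(rows) && anyNA(rows$charge)) {
    rlang::abort("system-2 atoms are missing partial charges")
  }
  out <- tibble::tibble(
    x = rows$x, y = rows$y, z = rows$z,
    q = rows$charge, serial = rows$serial
  )
  class(out) <- c("point_charge_model", class(out))
  out
}

#' Write a point-charge model as whitespace-delimited text
#'
#' Five columns: `x y z q serial`.
#' @param model A [point_charge_model()].
#' @param path Output path.
#' @export
write_point_charges <- function(model, path) {
  lines <- sprintf(
    "%14.8f %14.8f %14.8f %12.6f %8d",
    model$x, model$y, model$z, model$q, model$serial
  )
  writeLines(lines, path)
  invisible(path)
}

#' Truncate the QM region with hydrogen caps
#'
#' Returns the system-1 atoms plus one hydrogen link atom per junction,
#' placed by [place_link_atom()].  Cap atoms get fresh serials above the
#' structure maximum, element `"H"`, zero charge and residue tag `"HL"`.
#'
#' @param structure An [fes_structure()].
#' @param partition A [partition_structure()] result.
#' @return An [fes_structure()] with `|system1| + n_junctions` atoms.
#' @export
truncate_qm_region <- function(structure, partition) {
  validate_partition(structure, partition)
  qm <- structure[structure$serial %in% partition$system1, , drop = FALSE]
  jn <- partition$junctions
  if (nrow(jn) == 0) {
    return(as_fes_structure(qm, title = attr(structure, "title") %||% ""))
  }
  hl <- purrr::pmap_dfr(jn, function(qm_serial, cl_serial, scale) {
    pos <- place_link_atom(
      atom_position(structure, qm_serial),
      atom_position(structure, cl_serial),
      scale
    )
    tibble::tibble(
      serial = NA_integer_, element = "H",
      x = pos[1], y = pos[2], z = pos[3],
      charge = 0, residue_tag = "HL"
    )
  })
  hl$serial <- max(structure$serial) + seq_len(nrow(hl))
  as_fes_structure(
    dplyr::bind_rows(qm, hl),
    title = attr(structure, "title") %||% ""
  )
}
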