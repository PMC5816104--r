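#' Split a structure into a QM region and a fixed MM environment
#'
#' The structure is divided into system 1 (the QM region, relaxed by the
#' quantum engine) and system 2 (everything else, kept fixed and represented
#' by point charges).  Every covalent bond crossing the boundary becomes a
#' junction: the system-2 atom of the severed bond is the carbon link atom
#' (CL) whose position anchors a hydrogen cap (HL) on the QM side.
#'
#' @param structure An [fes_structure()].
#' @param qm_serials Serials of the system-1 (QM) atoms; non-empty.
#' @param junctions Either `NULL` (junctions are discovered with
#'   [detect_bonds()]), or a data frame with columns `qm_serial`,
#'   `cl_serial` and optionally `scale` declaring each severed bond.
#' @param scale Default link-atom placement factor used when `junctions`
#'   does not carry its own (see [place_link_atom()]).
#' @return A list of class `qmmm_partition` with elements `system1`,
#'   `system2` (integer serial vectors) and `junctions` (tibble with
#'   `qm_serial`, `cl_serial`, `scale`).
#' @export
partition_structure <- function(structure, qm_serials, junctions = NULL,
                                scale = link_scale_default("C", "C")) {
  validate_structure(structure)
  qm_serials <- unique(as.integer(qm_serials))
  if (length(qm_serials) == 0) rlang::abort("qm_serials must be non-empty")
  absent <- setdiff(qm_serials, structure$serial)
  if (length(absent)) {
    rlang::abort(paste0(
      "qm serial(s) not in structure: ", paste(absent, collapse = ", ")
    ))
  }
  system2 <- setdiff(structure$serial, qm_serials)
  if (is.null(junctions)) {
    bonds <- detect_bonds(structure)
    cross <- xor(
      bonds$serial_i %in% qm_serials,
      bonds$serial_j %in% qm_serials
    )
    bonds <- bonds[cross, , drop = FALSE]
    junctions <- tibble::tibble(
      qm_serial = ifelse(bonds$serial_i %in% qm_serials,
        bonds$serial_i, bonds$serial_j
      ),
      cl_serial = ifelse(bonds$serial_i %in% qm_serials,
        bonds$serial_j, bonds$serial_i
      ),
      scale = scale
    )
  } else {
    junctions <- tibble::as_tibble(junctions)
    if (!"scale" %in% names(junctions)) junctions$scale <- scale
    junctions <- junctions[, c("qm_serial", "cl_serial", "scale")]
    for (i in seq_len(nrow(junctions))) {
      q <- junctions$qm_serial[i]
      cl <- junctions$cl_serial[i]
      if (!q %in% qm_serials || !cl %in% system2) {
        rlang::abort(paste0(
          "junction ", q, "-", cl,
          " does not bridge system 1 and system 2"
        ))
      }
    }
  }
  if (nrow(junctions) &&
    (any(junctions$scale <= 0) || any(junctions$scale > 1))) {
    rlang::abort("junction scale factors must lie in (0, 1]")
  }
  junctions <- dplyr::arrange(junctions, .data$qm_serial, .data$cl_serial)
  structure(
    list(
      system1 = sort(qm_serials),
      system2 = sort(system2),
      junctions = junctions
    ),
    class = "qmmm_partition"
  )
}

#' @export
print.qmmm_partition <- function(x, ...) {
  cat(
    "QM/MM partition: |system 1| =", length(x$system1),
    " |system 2| =", length(x$system2),
    " junctions:", nrow(x$junctions), "\n"
  )
  invisible(x)
}

validate_partition <- function(structure, partition) {
  stopifnot(inherits(partition, "qmmm_partition"))
  all_serials <- sort(c(partition$system1, partition$system2))
  if (!identical(all_serials, sort(structure$serial))) {
    rlang::abort("partition does not cover the structure exactly")
  }
  if (length(intersect(partition$system1, partition$system2))) {
    rlang::abort("system 1 and system 2 overlap")
  }
  invisible(partition)
}

#' Describe a [4Fe4S]-type cluster within a structure
#'
#' Site labels (Fe1..Fe4 or Fe5..Fe8) follow the order of `fe_serials`, not
#' any spatial sorting, so a renumbering of input atoms only permutes labels.
#'
#' @param fe_serials Exactly 4 Fe serials in site order.
#' @param sulfide_serials Exactly 4 inorganic sulfide serials.
#' @param oxidation_assignment Formal Fe charges, e.g. `c(2, 2, 3, 3)`.
#' @param site_offset 0 for the first cluster (Fe1-Fe4), 4 for the second
#'   (Fe5-Fe8).
#' @return A list of class `cluster_spec`; `total_charge` is derived from the
#'   oxidation assignment and four sulfide dianions.
#' @export
cluster_spec <- function(fe_serials, sulfide_serials,
                         oxidation_assignment = c(2, 2, 3, 3),
                         site_offset = 0) {
  if (length(fe_serials) != 4 || length(sulfide_serials) != 4) {
    rlang::abort("a cubane cluster has exactly 4 Fe and 4 sulfide serials")
  }
  if (!all(oxidation_assignment %in% c(2, 3))) {
    rlang::abort("oxidation assignment must be +2 or +3 per Fe")
  }
  structure(
    list(
      fe_serials = as.integer(fe_serials),
      sulfide_serials = as.integer(sulfide_serials),
      oxidation_assignment = as.integer(oxidation_assignment),
      total_charge = sum(oxidation_assignment) - 8L,
      site_labels = paste0("Fe", site_offset + 1:4)
    ),
    class = "cluster_spec"
  )
}

#' Fe-ligand distance table
#'
#' Euclidean Fe-ligand distances, one row per Fe site and ligand atom within
#' the cutoff, in the style metalloprotein structure papers tabulate
#' first-sphere coordination.  Coincident atom pairs are treated as corrupt
#' geometry and raise an error.
#'
#' @param structure An [fes_structure()].
#' @param cluster A [cluster_spec()].
#' @param ligand_serials Serials of candidate ligand atoms (typically the
#'   sulfides plus first-sphere ligand donor atoms); non-empty.
#' @param cutoff_A Only pairs closer than this are reported (default 3.0
#'   Angstrom, generous for Fe-S/Fe-O/Fe-N first-sphere bonds).  `Inf`
#'   reports every pair.
#' @return A tibble `fe_site`, `ligand`, `distance_A` of class
#'   `fes_distance_table`.
#' @export
fe_ligand_distances <- function(structure, cluster, ligand_serials,
                                cutoff_A = 3.0) {
  validate_structure(structure)
  ligand_serials <- as.integer(ligand_serials)
  if (length(ligand_serials) == 0) rlang::abort("ligand set is empty")
  absent <- setdiff(c(cluster$fe_serials, ligand_serials), structure$serial)
  if (length(absent)) {
    rlang::abort(paste0(
      "serial(s) not in structure: ", paste(absent, collapse = ", ")
    ))
  }
  fe_xyz <- coords_matrix(structure, cluster$fe_serials)
  lig_xyz <- coords_matrix(structure, ligand_serials)
  lig_elem <- structure$element[match(ligand_serials, structure$serial)]
  out <- tidyr::expand_grid(fe = 1:4, lig = seq_along(ligand_serials))
  out$distance_A <- unname(sqrt(rowSums(
    (fe_xyz[out$fe, , drop = FALSE] - lig_xyz[out$lig, , drop = FALSE])^2
  )))
  out <- out[cluster$fe_serials[out$fe] != ligand_serials[out$lig], ,
    drop = FALSE
  ]
  if (any(out$distance_A == 0)) {
    rlang::abort("coincident atoms found; geometry is corrupt")
  }
  out <- out[out$distance_A < cutoff_A, , drop = FALSE]
  tbl <- tibble::tibble(
    fe_site = cluster$site_labels[out$fe],
    ligand = paste0(lig_elem[out$lig], ligand_serials[out$lig]),
    distance_A = out$distance_A
  )
  class(tbl) <- c("fes_distance_table", class(tbl))
  tbl
}

#' Write a distance table as TSV
#'
#' Columns `fe_site`, `ligand`, `distance_A`, tab separated.
#' @param table Output of [fe_ligand_distances()].
#' @param path Output path.
#' @export
write_distance_table <- function(table, path) {
  readr::write_tsv(as.data.frame(table), path)
  invisible(path)
}
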