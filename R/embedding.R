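hartree_kjmol <- 2625.4996

#' Convert energies between hartree, kJ/mol and J/mol
#'
#' The convention 1 hartree (a.u.) = 2625.4996 kJ/mol fixes all
#' conversions, so a 1e-6 a.u. convergence threshold is about 2.6 J/mol.
#'
#' @param value Numeric energy value(s).
#' @param from,to One of `"au"`, `"kJ/mol"`, `"J/mol"` (`"a.u."` and
#'   `"hartree"` are accepted aliases for `"au"`).
#' @return `value` expressed in `to`.
#' @examples
#' convert_energy(1e-6, "au", "J/mol") # ~ 2.6
#' @export
convert_energy <- function(value, from, to) {
  per_au <- function(u) {
    switch(u,
      "au" = ,
      "a.u." = ,
      "hartree" = 1,
      "kJ/mol" = hartree_kjmol,
      "J/mol" = hartree_kjmol * 1000,
      rlang::abort(paste0("unknown energy unit: ", u))
    )
  }
  value * per_au(to) / per_au(from)
}

#' Subtractive QM/MM energy components
#'
#' The three terms of the subtractive electrostatic-embedding assembly:
#' `e_qm1_ptch2_hl`, the QM energy of the hydrogen-capped QM region in the
#' environment point-charge field (charge-charge self-energy excluded);
#' `e_mm12_q1_0_cl`, the MM energy of all atoms with the QM charges zeroed;
#' `e_mm1_q1_0_hl`, the MM energy of the capped QM region with no
#' electrostatics.  All in hartree.
#'
#' @param e_qm1_ptch2_hl,e_mm12_q1_0_cl,e_mm1_q1_0_hl Finite energies (a.u.).
#' @return A list of class `energy_components`.
#' @export
energy_components <- function(e_qm1_ptch2_hl, e_mm12_q1_0_cl, e_mm1_q1_0_hl) {
  vals <- c(e_qm1_ptch2_hl, e_mm12_q1_0_cl, e_mm1_q1_0_hl)
  if (!all(is.finite(vals))) rlang::abort("energy components must be finite")
  structure(
    list(
      e_qm1_ptch2_hl = e_qm1_ptch2_hl,
      e_mm12_q1_0_cl = e_mm12_q1_0_cl,
      e_mm1_q1_0_hl = e_mm1_q1_0_hl
    ),
    class = "energy_components"
  )
}

#' Assemble the total subtractive QM/MM energy
#'
#' `E = E(QM1+ptch2, HL) + E(MM12, q1 = 0, CL) - E(MM1, q1 = 0, HL)`.
#' The double subtraction makes truncation artefacts of the capped QM
#' region cancel between the two MM evaluations.
#'
#' @param components An [energy_components()] object.
#' @return Total energy in hartree.
#' @export
assemble_qmmm_energy <- function(components) {
  stopifnot(inherits(components, "energy_components"))
  components$e_qm1_ptch2_hl + components$e_mm12_q1_0_cl -
    components$e_mm1_q1_0_hl
}

#' Multi-level energy extrapolation
#'
#' Combines a QM/MM energy at a small-basis GGA level with single-point
#' energies to approximate a hybrid-functional, large-basis total:
#' `E_tot = E_qmmm_svp + E_tpss_tzvp + E_b3lyp_svp - 2 * E_tpss_svp`,
#' i.e. additive basis-set and functional corrections on top of the
#' geometry-level energy.  Level names are labels only; no electronic
#' structure is computed here.
#'
#' @param e_qmmm_svp QM/MM energy at the geometry level (a.u.).
#' @param e_tpss_tzvp,e_b3lyp_svp,e_tpss_svp Single-point energies (a.u.).
#' @return Extrapolated total energy in hartree.
#' @export
extrapolate_total_energy <- function(e_qmmm_svp, e_tpss_tzvp,
                                     e_b3lyp_svp, e_tpss_svp) {
  vals <- c(e_qmmm_svp, e_tpss_tzvp, e_b3lyp_svp, e_tpss_svp)
  if (!all(is.finite(vals))) rlang::abort("level energies must be finite")
  e_qmmm_svp + e_tpss_tzvp + e_b3lyp_svp - 2 * e_tpss_svp
}

#' The engine contract
#'
#' An engine is any function `f(structure, charges = NULL, state = NULL,
#' level = "toy")` returning a list with `energy` (hartree), and optionally
#' `gradient` (n x 3 matrix, hartree/Angstrom, rows in structure atom
#' order) and `spin_populations`.  Engines must be deterministic for fixed
#' inputs, and must exclude the charge-charge self-energy of the point
#' charges (`charges` enters only through its interaction with the atoms).
#' The built-in toy engines ([toy_mm_engine()], [toy_spin_engine()],
#' [double_well_engine()]) satisfy the contract.
#'
#' @param result A candidate engine return value.
#' @param n_atoms Expected atom count for the gradient check.
#' @return `result`, invisibly, or an error.
#' @export
check_engine_result <- function(result, n_atoms = NULL) {
  if (!is.list(result) || is.null(result$energy) ||
    !is.finite(result$energy)) {
    rlang::abort("engine must return a list with a finite $energy")
  }
  if (!is.null(result$gradient) && !is.null(n_atoms) &&
    nrow(result$gradient) != n_atoms) {
    rlang::abort("engine gradient rows must match the atom count")
  }
  invisible(result)
}

#' Run a subtractive QM/MM single point
#'
#' Orchestrates the full subtractive assembly: caps the QM region with
#' hydrogen link atoms, builds the environment point-charge model, makes
#' three engine calls (QM on the capped region in the charge field; MM on
#' all atoms with QM charges zeroed; MM on the capped region with all
#' charges zeroed, i.e. no electrostatics) and combines them.  Engine calls
#' are memoised on (structure, charges, state, level) within the cache
#' environment, so repeated profile assembly never re-evaluates a term.
#'
#' @param structure An [fes_structure()] with charges on all atoms.
#' @param partition A [partition_structure()] result.
#' @param qm_engine,mm_engine Engine functions (see
#'   [check_engine_result()]).  The MM engine is called without `state`.
#' @param state Optional [bs_state()] forwarded to the QM engine.
#' @param qm_level,mm_level Opaque level labels forwarded to the engines.
#' @param cache Optional environment used to memoise engine calls; pass the
#'   same environment across calls to share the cache.
#' @return A list with `total` (hartree), `components`
#'   ([energy_components()]) and `total_kjmol`.
#' @export
run_qmmm <- function(structure, partition, qm_engine, mm_engine,
                     state = NULL, qm_level = "QM/toy", mm_level = "MM/toy",
                     cache = NULL) {
  validate_partition(structure, partition)
  truncated <- truncate_qm_region(structure, partition)
  charges <- point_charge_model(structure, partition)

  call_engine <- function(engine, tag, structure, charges, state, level) {
    run <- function() {
      res <- tryCatch(
        engine(structure, charges = charges, state = state, level = level),
        error = function(e) {
          rlang::abort(paste0("engine failed on term ", tag, ": ",
            conditionMessage(e)))
        }
      )
      check_engine_result(res, n_atoms = nrow(structure))
      res
    }
    if (is.null(cache)) return(run())
    key <- rlang::hash(list(
      tag,
      structure[, c("serial", "element", "x", "y", "z", "charge")],
      if (nrow(charges)) charges else NULL,
      if (is.null(state)) NULL else unclass(state),
      level
    ))
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- run()
    cache[[key]]
  }

  # term 1: QM of capped region, embedded, own charges live
  t1 <- call_engine(
    qm_engine, "e_qm1_ptch2_hl",
    truncated, charges, state, qm_level
  )
  # term 2: MM of everything, QM charges zeroed
  full_q1_0 <- structure
  full_q1_0$charge[full_q1_0$serial %in% partition$system1] <- 0
  if (anyNA(full_q1_0$charge)) {
    rlang::abort("system-2 atoms are missing partial charges")
  }
  empty <- charges[0, , drop = FALSE]
  t2 <- call_engine(mm_engine, "e_mm12_q1_0_cl", full_q1_0, empty, NULL,
    mm_level)
  # term 3: MM of capped region, no electrostatics at all
  trunc_q0 <- truncated
  trunc_q0$charge[] <- 0
  t3 <- call_engine(mm_engine, "e_mm1_q1_0_hl", trunc_q0, empty, NULL,
    mm_level)

  comp <- energy_components(t1$energy, t2$energy, t3$energy)
  total <- assemble_qmmm_energy(comp)
  list(
    total = total,
    components = comp,
    total_kjmol = convert_energy(total, "au", "kJ/mol")
  )
}

#' Round-trip energy components through a key-value text record
#'
#' @param components An [energy_components()].
#' @param path File path.
#' @return `read_energy_components`: an [energy_components()].
#' @export
write_energy_components <- function(components, path) {
  stopifnot(inherits(components, "energy_components"))
  writeLines(
    sprintf("%s %.15g", names(components), unlist(components)),
    path
  )
  invisible(path)
}

#' @rdname write_energy_components
#' @export
read_energy_components <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  vals <- stats::setNames(
    vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
    vapply(parts, `[[`, character(1), 1)
  )
  energy_components(
    vals[["e_qm1_ptch2_hl"]], vals[["e_mm12_q1_0_cl"]],
    vals[["e_mm1_q1_0_hl"]]
  )
}
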