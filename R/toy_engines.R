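bohr_A <- 0.529177210903

#' Harmonic bond terms for the toy engines
#'
#' @param serial_i,serial_j Atom serials of each bond.
#' @param k_au Force constants in hartree/Angstrom^2.
#' @param d0_A Equilibrium lengths in Angstrom.
#' @return A tibble of bond terms.
#' @export
bond_terms <- function(serial_i, serial_j, k_au = 0.3, d0_A = 1.5) {
  tibble::tibble(
    serial_i = as.integer(serial_i),
    serial_j = as.integer(serial_j),
    k_au = as.numeric(rep_len(k_au, length(serial_i))),
    d0_A = as.numeric(rep_len(d0_A, length(serial_i)))
  )
}

# Harmonic-bond + Coulomb force field shared by the toy engines.  Bonds are
# matched by serial; bonds whose atoms are absent from the structure (e.g.
# severed at a junction) are skipped, so the same term set serves the full
# and the truncated system.  Coulomb covers atom-atom pairs (using the
# structure's partial charges, NA treated as 0) and atom-point-charge
# interactions; the charge-charge self-energy of the point-charge array is
# never computed, as the engine contract requires.
force_field_eval <- function(structure, charges, bonds, want_gradient) {
  xyz <- coords_matrix(structure)
  n <- nrow(xyz)
  q <- structure$charge
  q[is.na(q)] <- 0
  energy <- 0
  grad <- matrix(0, n, 3)

  if (!is.null(bonds) && nrow(bonds)) {
    ii <- match(bonds$serial_i, structure$serial)
    jj <- match(bonds$serial_j, structure$serial)
    ok <- !is.na(ii) & !is.na(jj)
    for (b in which(ok)) {
      d_vec <- xyz[ii[b], ] - xyz[jj[b], ]
      d <- sqrt(sum(d_vec^2))
      energy <- energy + bonds$k_au[b] * (d - bonds$d0_A[b])^2
      if (want_gradient && d > 0) {
        g <- 2 * bonds$k_au[b] * (d - bonds$d0_A[b]) * d_vec / d
        grad[ii[b], ] <- grad[ii[b], ] + g
        grad[jj[b], ] <- grad[jj[b], ] - g
      }
    }
  }

  if (any(q != 0) && n > 1) {
    for (i in seq_len(n - 1)) {
      if (q[i] == 0) next
      for (j in seq(i + 1, n)) {
        if (q[j] == 0) next
        d_vec <- xyz[i, ] - xyz[j, ]
        r <- sqrt(sum(d_vec^2))
        if (r == 0) rlang::abort("coincident charged atoms")
        energy <- energy + bohr_A * q[i] * q[j] / r
        if (want_gradient) {
          g <- -bohr_A * q[i] * q[j] * d_vec / r^3
          grad[i, ] <- grad[i, ] + g
          grad[j, ] <- grad[j, ] - g
        }
      }
    }
  }

  if (!is.null(charges) && nrow(charges)) {
    cxyz <- as.matrix(charges[, c("x", "y", "z")])
    for (i in seq_len(n)) {
      if (q[i] == 0) next
      d_vec <- sweep(cxyz, 2, xyz[i, ], `-`)
      r <- sqrt(rowSums(d_vec^2))
      if (any(r == 0)) rlang::abort("atom coincides with a point charge")
      energy <- energy + bohr_A * q[i] * sum(charges$q / r)
      if (want_gradient) {
        grad[i, ] <- grad[i, ] +
          colSums(bohr_A * q[i] * charges$q * d_vec / r^3)
      }
    }
  }

  list(energy = energy, gradient = grad)
}

#' Toy molecular-mechanics engine
#'
#' A deterministic, gradient-capable stand-in for the MM side of the QM/MM
#' assembly: harmonic bonds plus Coulomb electrostatics (internal and with
#' an optional point-charge array).  Spin-blind: any `state` argument is
#' ignored.
#'
#' @param bonds A [bond_terms()] tibble, or `NULL` for a non-bonded system.
#' @return An engine function `f(structure, charges, state, level)`
#'   returning `list(energy, gradient)` (hartree; hartree/Angstrom).
#' @export
toy_mm_engine <- function(bonds = NULL) {
  force(bonds)
  function(structure, charges = NULL, state = NULL, level = "MM/toy") {
    force_field_eval(structure, charges, bonds, want_gradient = TRUE)
  }
}

#' Toy spin-polarised engine
#'
#' The DFT stand-in: the same force field as [toy_mm_engine()] plus the
#' Ising exchange energy of the supplied BS state (converted from kJ/mol to
#' hartree).  The exchange term is geometry-independent, so the energy
#' difference between two BS states on identical structures is exactly the
#' Ising energy difference.  It also reports idealised per-site spin
#' populations `sign * magnitude`.
#'
#' @param params A [heisenberg_params()].
#' @param spins Site spin magnitudes (see [ising_energy()]).
#' @param bonds A [bond_terms()] tibble, or `NULL`.
#' @return An engine function; `state` may be `NULL` (no exchange term) or
#'   a [bs_state()] whose length matches `params`.
#' @export
toy_spin_engine <- function(params, spins = 2.25, bonds = NULL) {
  force(params)
  force(spins)
  force(bonds)
  function(structure, charges = NULL, state = NULL, level = "QM/toy") {
    res <- force_field_eval(structure, charges, bonds, want_gradient = TRUE)
    pops <- NULL
    if (!is.null(state)) {
      e_spin <- ising_energy(state, params, spins)
      res$energy <- res$energy + convert_energy(e_spin, "kJ/mol", "au")
      pops <- as.integer(unclass(state)) *
        rep_len(spins, length(unclass(state))) * 2
    }
    c(res, list(spin_populations = pops))
  }
}

#' Analytic double-well engine for scan validation
#'
#' A toy energy surface that is quartic in one interatomic distance and
#' harmonic in every other (spectator) term:
#' `E = A * ((d - center)^2 - width^2)^2 + bonds`.  The two wells sit at
#' `center +/- width` with `E = 0` and the saddle between them at
#' `d = center` with the closed-form energy `A * width^4` (see
#' [double_well_saddle_energy()]), so a relaxed scan over `d` can be
#' checked against an exact barrier.
#'
#' @param pair Length-2 serials of the scanned atom pair.
#' @param barrier_a Quartic prefactor `A` (hartree/Angstrom^4).
#' @param center_A,width_A Well geometry (Angstrom).
#' @param bonds Spectator [bond_terms()], or `NULL`.
#' @return An engine function with analytic gradients.
#' @export
double_well_engine <- function(pair, barrier_a = 0.05,
                               center_A = 2.0, width_A = 0.4,
                               bonds = NULL) {
  force(pair)
  function(structure, charges = NULL, state = NULL, level = "toy/dw") {
    res <- force_field_eval(structure, charges, bonds, want_gradient = TRUE)
    i <- match(pair[1], structure$serial)
    j <- match(pair[2], structure$serial)
    if (is.na(i) || is.na(j)) {
      rlang::abort("scanned pair not present in structure")
    }
    xyz <- coords_matrix(structure)
    d_vec <- xyz[i, ] - xyz[j, ]
    d <- sqrt(sum(d_vec^2))
    u <- (d - center_A)^2 - width_A^2
    res$energy <- res$energy + barrier_a * u^2
    dEdd <- 4 * barrier_a * u * (d - center_A)
    g <- dEdd * d_vec / d
    res$gradient[i, ] <- res$gradient[i, ] + g
    res$gradient[j, ] <- res$gradient[j, ] - g
    res
  }
}

#' @rdname double_well_engine
#' @return `double_well_saddle_energy`: the exact saddle height
#'   `A * width^4` in hartree, relative to the wells.
#' @export
double_well_saddle_energy <- function(barrier_a, width_A) {
  barrier_a * width_A^4
}
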