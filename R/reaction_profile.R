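# Compact BFGS with backtracking line search and the two-criterion stop
# rule: both the energy change between iterations and the maximum component
# of the free-space gradient must fall below their tolerances.
bfgs_minimize <- function(x0, fn, gr, max_steps = 200,
                          tol_e = 1e-6, tol_g = 1e-3) {
  x <- x0
  n <- length(x)
  H <- diag(n)
  f <- fn(x)
  g <- gr(x)
  converged <- FALSE
  steps <- 0
  repeat {
    if (max(abs(g)) < tol_g && steps == 0) {
      # already at a stationary point to tolerance; energy change is 0
      converged <- TRUE
      break
    }
    if (steps >= max_steps) break
    p <- -drop(H %*% g)
    if (sum(p * g) >= 0) p <- -g # reset on loss of descent direction
    alpha <- 1
    f_new <- fn(x + alpha * p)
    tries <- 0
    while (!is.finite(f_new) || f_new > f + 1e-4 * alpha * sum(g * p)) {
      alpha <- alpha / 2
      tries <- tries + 1
      if (tries > 40) break
      f_new <- fn(x + alpha * p)
    }
    s <- alpha * p
    x_new <- x + s
    g_new <- gr(x_new)
    y <- g_new - g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      V <- diag(n) - rho * outer(s, y)
      H <- V %*% H %*% t(V) + rho * outer(s, s)
    }
    de <- abs(f_new - f)
    x <- x_new
    f <- f_new
    g <- g_new
    steps <- steps + 1
    if (de < tol_e && max(abs(g)) < tol_g) {
      converged <- TRUE
      break
    }
  }
  list(
    x = x, value = f, gradient = g, converged = converged,
    steps = steps, max_grad = max(abs(g))
  )
}

#' Relaxed scan along a constrained interatomic distance
#'
#' For each target value of the scanned distance, all movable degrees of
#' freedom are relaxed while the distance is held exactly at the target —
#' the constrained-optimisation device used to walk a reaction coordinate
#' through a barrier.  The constraint is eliminated analytically: the
#' second atom of the pair is re-expressed as `r_a + d * u(theta, phi)`, so
#' the optimiser works in an unconstrained space whose gradient is the
#' engine gradient projected onto the constraint manifold.  System-2 atoms
#' and any extra `frozen_serials` are never moved.  Optimisation stops when
#' the energy change between iterations is below `tol_e_au` and the maximum
#' free-gradient component is below `tol_g_au` (both must hold); each grid
#' point restarts from the previous relaxed geometry.
#'
#' @param structure An [fes_structure()].
#' @param partition A [partition_structure()] result; only system-1 atoms
#'   may move.
#' @param engine A gradient-capable engine (see [check_engine_result()]).
#' @param pair Length-2 serials of the constrained atom pair (must be in
#'   system 1; at least one movable).
#' @param targets_A Vector of target distances (Angstrom).
#' @param frozen_serials Additional serials to hold fixed.
#' @param max_steps Maximum optimiser iterations per grid point.
#' @param tol_e_au Energy-change tolerance (hartree), default 1e-6.
#' @param tol_g_au Max gradient-component tolerance (hartree/Angstrom),
#'   default 1e-3.
#' @param state Optional [bs_state()] forwarded to the engine.
#' @return A tibble `coordinate_A`, `energy_au`, `energy_kjmol`,
#'   `converged`, `n_steps`, `max_grad_au`, plus a `structure` list-column
#'   with the relaxed geometry at each point.
#' @export
constrained_scan <- function(structure, partition, engine, pair, targets_A,
                             frozen_serials = integer(0),
                             max_steps = 200, tol_e_au = 1e-6,
                             tol_g_au = 1e-3, state = NULL) {
  validate_partition(structure, partition)
  pair <- as.integer(pair)
  if (!all(pair %in% partition$system1)) {
    rlang::abort("scanned atoms must belong to system 1")
  }
  fixed <- union(partition$system2, as.integer(frozen_serials))
  movable <- setdiff(partition$system1, fixed)
  if (!any(pair %in% movable)) {
    rlang::abort("at least one scanned atom must be movable")
  }
  # atom "b" is re-parameterised on the constraint sphere around "a"
  b <- if (pair[2] %in% movable) pair[2] else pair[1]
  a <- setdiff(pair, b)
  free_atoms <- setdiff(movable, b)

  current <- structure
  out <- purrr::map_dfr(targets_A, function(d_target) {
    xyz_a <- atom_position(current, a)
    xyz_b <- atom_position(current, b)
    sep <- xyz_b - xyz_a
    if (all(sep == 0)) rlang::abort("scanned atoms coincide")
    theta0 <- acos(min(1, max(-1, sep[3] / sqrt(sum(sep^2)))))
    phi0 <- atan2(sep[2], sep[1])

    free_idx <- match(free_atoms, current$serial)
    pack <- function(str) {
      xyz <- coords_matrix(str)
      c(t(xyz[free_idx, , drop = FALSE]))
    }
    unpack <- function(x) {
      str <- current
      n_free <- length(free_atoms)
      if (n_free) {
        m <- matrix(x[seq_len(3 * n_free)], ncol = 3, byrow = TRUE)
        str$x[free_idx] <- m[, 1]
        str$y[free_idx] <- m[, 2]
        str$z[free_idx] <- m[, 3]
      }
      ang <- x[3 * n_free + 1:2]
      u <- c(
        sin(ang[1]) * cos(ang[2]),
        sin(ang[1]) * sin(ang[2]),
        cos(ang[1])
      )
      ra <- atom_position(str, a)
      rb <- ra + d_target * u
      ib <- match(b, str$serial)
      str$x[ib] <- rb[1]
      str$y[ib] <- rb[2]
      str$z[ib] <- rb[3]
      str
    }
    eval_engine <- function(x) {
      str <- unpack(x)
      res <- engine(str, charges = NULL, state = state)
      check_engine_result(res, n_atoms = nrow(str))
      list(str = str, res = res)
    }
    fn <- function(x) eval_engine(x)$res$energy
    gr <- function(x) {
      ev <- eval_engine(x)
      g <- ev$res$gradient
      str <- ev$str
      ia <- match(a, str$serial)
      ib <- match(b, str$serial)
      g_free <- c(t(g[match(free_atoms, str$serial), , drop = FALSE]))
      if (a %in% free_atoms) {
        # b rides on a: dE/dra picks up gb
        pos <- which(free_atoms == a)
        g_free[3 * (pos - 1) + 1:3] <-
          g_free[3 * (pos - 1) + 1:3] + g[ib, ]
      }
      ang <- x[3 * length(free_atoms) + 1:2]
      du_dtheta <- c(
        cos(ang[1]) * cos(ang[2]),
        cos(ang[1]) * sin(ang[2]),
        -sin(ang[1])
      )
      du_dphi <- c(
        -sin(ang[1]) * sin(ang[2]),
        sin(ang[1]) * cos(ang[2]),
        0
      )
      c(
        g_free,
        d_target * sum(g[ib, ] * du_dtheta),
        d_target * sum(g[ib, ] * du_dphi)
      )
    }

    x0 <- c(pack(current), theta0, phi0)
    opt <- bfgs_minimize(x0, fn, gr,
      max_steps = max_steps,
      tol_e = tol_e_au, tol_g = tol_g_au
    )
    relaxed <- unpack(opt$x)
    current <<- relaxed
    if (!opt$converged) {
      rlang::warn(paste0(
        "scan point ", format(d_target),
        " A did not converge in ", opt$steps,
        " steps (max gradient ", format(opt$max_grad, digits = 3), " a.u.)"
      ))
    }
    tibble::tibble(
      coordinate_A = d_target,
      energy_au = opt$value,
      energy_kjmol = convert_energy(opt$value, "au", "kJ/mol"),
      converged = opt$converged,
      n_steps = opt$steps,
      max_grad_au = opt$max_grad,
      structure = list(relaxed)
    )
  })
  class(out) <- c("fes_scan", class(out))
  out
}

#' Write a scan result as TSV
#'
#' Columns `coordinate_A`, `energy_au`, `energy_kjmol`, `converged`.
#' @param scan Output of [constrained_scan()].
#' @param path Output path.
#' @export
write_scan <- function(scan, path) {
  readr::write_tsv(
    as.data.frame(scan[, c(
      "coordinate_A", "energy_au", "energy_kjmol", "converged"
    )]),
    path
  )
  invisible(path)
}

#' Assemble a reaction profile from stationary points
#'
#' Shifts all energies so the reference stationary point sits at zero,
#' preserving the declared mechanism order.  Gauge invariant: adding a
#' constant to every absolute energy leaves the profile unchanged.
#'
#' @param points A data frame with `label` and `energy_kjmol` (absolute or
#'   already-relative energies) and optionally `note`.
#' @param reference Label of the zero-energy reference (default: first
#'   row).
#' @return A tibble of class `reaction_profile` with relative
#'   `energy_kjmol`.
#' @export
assemble_profile <- function(points, reference = NULL) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("label", "energy_kjmol") %in% names(points)))
  if (anyDuplicated(points$label)) {
    rlang::abort("stationary-point labels must be unique")
  }
  if (is.null(reference)) reference <- points$label[1]
  i <- match(reference, points$label)
  if (is.na(i)) rlang::abort("reference label not present")
  points$energy_kjmol <- points$energy_kjmol - points$energy_kjmol[i]
  attr(points, "reference") <- reference
  class(points) <- c("reaction_profile", class(points))
  points
}

profile_index <- function(profile, label) {
  i <- match(label, profile$label)
  if (is.na(i)) {
    rlang::abort(paste0("label not in profile: ", label))
  }
  i
}

#' Barrier and exothermicity along a profile
#'
#' `barrier` is the highest energy on the segment from `from` to `to`
#' (endpoints included) minus the energy of `from`, hence never negative.
#' `exothermicity` is `E(from) - E(to)`: positive for a downhill
#' (exothermic) step and antisymmetric under exchanging the two labels.
#'
#' @param profile A [assemble_profile()] result.
#' @param from,to Stationary-point labels; `to` must follow `from`.
#' @return Energy in kJ/mol.
#' @export
barrier <- function(profile, from, to) {
  i <- profile_index(profile, from)
  j <- profile_index(profile, to)
  if (j <= i) rlang::abort("`to` must follow `from` in the profile order")
  max(profile$energy_kjmol[i:j]) - profile$energy_kjmol[i]
}

#' @rdname barrier
#' @export
exothermicity <- function(profile, from, to) {
  i <- profile_index(profile, from)
  j <- profile_index(profile, to)
  profile$energy_kjmol[i] - profile$energy_kjmol[j]
}

#' Compare two reaction mechanisms
#'
#' Both barriers are measured from a common precursor label; products are
#' compared on each profile's own reference scale.  Sign convention:
#' positive `delta_barrier_kjmol` means mechanism A has the higher
#' barrier; positive `delta_product_kjmol` means mechanism A's product is
#' the less stable (higher in energy).
#'
#' @param profile_a,profile_b Two [assemble_profile()] results.
#' @param from Common precursor label (present in both profiles).
#' @param ts_a,ts_b Transition-state labels in each profile.
#' @param product_a,product_b Product labels in each profile.
#' @return A one-row tibble with both barriers, both product energies and
#'   the two differences.
#' @export
compare_mechanisms <- function(profile_a, profile_b, from,
                               ts_a, ts_b, product_a, product_b) {
  b_a <- barrier(profile_a, from, ts_a)
  b_b <- barrier(profile_b, from, ts_b)
  p_a <- profile_a$energy_kjmol[profile_index(profile_a, product_a)]
  p_b <- profile_b$energy_kjmol[profile_index(profile_b, product_b)]
  tibble::tibble(
    barrier_a_kjmol = b_a, barrier_b_kjmol = b_b,
    product_a_kjmol = p_a, product_b_kjmol = p_b,
    delta_barrier_kjmol = b_a - b_b,
    delta_product_kjmol = p_a - p_b
  )
}

#' Read / write reaction profiles
#'
#' Tab-separated columns `label`, `energy_kjmol` and optional `note`.
#' @param path File path.
#' @return `read_profile`: a `reaction_profile` tibble (energies taken as
#'   already relative to the first row's reference).
#' @export
read_profile <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      label = readr::col_character(),
      energy_kjmol = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  ref <- tbl$label[which(tbl$energy_kjmol == 0)[1]]
  if (is.na(ref)) ref <- tbl$label[1]
  assemble_profile(tbl, reference = ref)
}

#' @rdname read_profile
#' @param profile A `reaction_profile`.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(as.data.frame(profile), path)
  invisible(path)
}
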