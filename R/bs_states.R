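arrow_up <- "↑"
arrow_down <- "↓"

#' Broken-symmetry state constructor
#'
#' A BS state is a signed spin-orientation assignment over Fe sites, the
#' collinear determinant picture in which each high-spin Fe carries a
#' surplus of spin up (+1) or down (-1).  States of length 4 describe one
#' cubane; length 8 describes two cubanes (sites Fe1-Fe4, then Fe5-Fe8).
#'
#' @param orientations Vector of +1/-1 of length 4 or 8.
#' @return An integer vector of class `bs_state`.
#' @export
bs_state <- function(orientations) {
  o <- as.integer(orientations)
  if (!length(o) %in% c(4L, 8L)) {
    rlang::abort("a BS state has 4 sites (one cluster) or 8 (two clusters)")
  }
  if (!all(o %in% c(-1L, 1L))) {
    rlang::abort("orientations must be +1 or -1")
  }
  structure(o, class = "bs_state")
}

#' @export
print.bs_state <- function(x, ...) {
  cat(format_bs_label(x), "\n")
  invisible(x)
}

#' @export
format.bs_state <- function(x, ...) format_bs_label(x)

#' Parse and format arrow-string spin-state labels
#'
#' Labels follow the convention of spin-state tables for two-cluster
#' systems: one up/down arrow per Fe site in site order, an optional single
#' space between clusters of four, optional enclosing square brackets, e.g.
#' `"[↑↑↓↓ ↓↑↑↓]"`.  ASCII `u`/`d`
#' are accepted as aliases on input.  `format_bs_label(parse_bs_label(x))`
#' is the identity on well-formed labels.
#'
#' @param text An arrow-string label.
#' @return `parse_bs_label`: a [bs_state()]; `format_bs_label`: a label
#'   string with brackets, arrows and the inter-cluster space.
#' @export
parse_bs_label <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("[][ ]", "", text)
  chars <- strsplit(s, "")[[1]]
  o <- dplyr::case_when(
    chars == arrow_up | chars == "u" ~ 1L,
    chars == arrow_down | chars == "d" ~ -1L,
    TRUE ~ NA_integer_
  )
  if (anyNA(o)) {
    rlang::abort(paste0("malformed spin-state label: ", text))
  }
  bs_state(o)
}

#' @rdname parse_bs_label
#' @param state A [bs_state()].
#' @export
format_bs_label <- function(state) {
  o <- unclass(state)
  arrows <- ifelse(o > 0, arrow_up, arrow_down)
  if (length(o) == 8) {
    body <- paste0(
      paste(arrows[1:4], collapse = ""), " ",
      paste(arrows[5:8], collapse = "")
    )
  } else {
    body <- paste(arrows, collapse = "")
  }
  paste0("[", body, "]")
}

states_tibble <- function(mat) {
  tibble::tibble(
    label = apply(mat, 1, function(o) format_bs_label(bs_state(o))),
    state = lapply(seq_len(nrow(mat)), function(i) bs_state(mat[i, ]))
  )
}

#' Enumerate broken-symmetry determinants
#'
#' All distinct assignments of `n_up` spin-up sites among `n_sites`, in
#' deterministic lexicographic order of the up-site positions.  For a
#' [4Fe4S](2+) cubane with two Fe(2+) and two Fe(3+), the singlet-like
#' manifold is `enumerate_bs_states(4, 2)`: six states.
#'
#' @param n_sites Number of Fe sites (4 or 8 for labelled output).
#' @param n_up Number of spin-up sites, `0 <= n_up <= n_sites`.
#' @return A tibble with `label` and a `state` list-column of [bs_state()]
#'   objects; `choose(n_sites, n_up)` rows.
#' @export
enumerate_bs_states <- function(n_sites, n_up) {
  if (n_sites < 0 || n_up < 0) rlang::abort("counts must be non-negative")
  if (n_up > n_sites) rlang::abort("n_up cannot exceed n_sites")
  if (!n_sites %in% c(4, 8)) {
    rlang::abort("labelled enumeration supports 4 or 8 sites")
  }
  combos <- utils::combn(n_sites, n_up, simplify = FALSE)
  if (n_up == 0) combos <- list(integer(0))
  mat <- do.call(rbind, lapply(combos, function(up) {
    o <- rep(-1L, n_sites)
    o[up] <- 1L
    o
  }))
  states_tibble(mat)
}

# Orientation matrix for arbitrary n_sites with n_up up-spins; used by the
# enumeration-equivalence property tests (no labelling constraint).
spin_assignment_matrix <- function(n_sites, n_up) {
  combos <- utils::combn(n_sites, n_up, simplify = FALSE)
  if (n_up == 0) combos <- list(integer(0))
  do.call(rbind, lapply(combos, function(up) {
    o <- rep(-1L, n_sites)
    o[up] <- 1L
    o
  }))
}

#' Enumerate combined singlet states of two cubanes
#'
#' The Cartesian product of the per-cluster 2-up/2-down assignments: 6 x 6 =
#' 36 combined states, each with zero net orientation in both clusters (the
#' antiferromagnetically coupled singlet picture).
#'
#' @return A 36-row tibble with `label` and `state` list-column.
#' @export
enumerate_two_cluster_singlets <- function() {
  per <- spin_assignment_matrix(4, 2)
  grid <- tidyr::expand_grid(a = seq_len(6), b = seq_len(6))
  mat <- cbind(per[grid$a, , drop = FALSE], per[grid$b, , drop = FALSE])
  states_tibble(mat)
}

#' Count unpaired spins of high-spin Fe sites
#'
#' High-spin Fe(2+) carries 4 unpaired electrons and Fe(3+) carries 5; a
#' [4Fe4S](2+) cluster with two of each has 18, and two such clusters 36.
#'
#' @param oxidation_assignments A list of per-cluster formal Fe charges,
#'   each charge +2 or +3 (a single vector is taken as one cluster).
#' @return Total unpaired-electron count.
#' @examples
#' count_unpaired_spins(list(c(2, 2, 3, 3), c(2, 2, 3, 3))) # 36
#' @export
count_unpaired_spins <- function(oxidation_assignments) {
  if (!is.list(oxidation_assignments)) {
    oxidation_assignments <- list(oxidation_assignments)
  }
  charges <- unlist(oxidation_assignments)
  if (!all(charges %in% c(2, 3))) {
    rlang::abort("only high-spin Fe(2+) and Fe(3+) are supported")
  }
  sum(ifelse(charges == 2, 4L, 5L))
}

#' Build a BS state from a fragment assignment
#'
#' The fragment route to BS determinants assigns each Fe site to a fragment
#' and gives every fragment a spin orientation; sites inherit their
#' fragment's sign.  Splitting a cubane into two ferromagnetic pairs with
#' opposite signs yields the pair-aligned singlet states.
#'
#' @param fragment_assignment Named vector or list mapping each site index
#'   `1..n` to a fragment id (any atomic value), e.g. `c(1, 1, 2, 2)`.
#' @param fragment_spins Named vector mapping fragment id to +1/-1.
#' @return A [bs_state()].
#' @export
bs_from_fragments <- function(fragment_assignment, fragment_spins) {
  frag <- as.character(unlist(fragment_assignment))
  if (anyNA(frag)) rlang::abort("every site must be assigned a fragment")
  spins <- fragment_spins
  names(spins) <- as.character(names(fragment_spins))
  missing <- setdiff(unique(frag), names(spins))
  if (length(missing)) {
    rlang::abort(paste0(
      "no spin given for fragment(s): ", paste(missing, collapse = ", ")
    ))
  }
  bs_state(unname(spins[frag]))
}

#' All fragment pair-bipartitions of one cubane
#'
#' The three ways of splitting four sites into two ferromagnetic pairs,
#' each signed two ways, generate the six 2-up/2-down states.
#'
#' @return A tibble `pair_a`, `pair_b` (list-columns of site indices),
#'   `sign_a`, and the resulting `label`/`state`.
#' @export
fragment_pairings <- function() {
  pairings <- list(
    list(a = c(1L, 2L), b = c(3L, 4L)),
    list(a = c(1L, 3L), b = c(2L, 4L)),
    list(a = c(1L, 4L), b = c(2L, 3L))
  )
  rows <- purrr::map_dfr(pairings, function(p) {
    purrr::map_dfr(c(1L, -1L), function(s) {
      assignment <- integer(4)
      assignment[p$a] <- 1L
      assignment[p$b] <- 2L
      st <- bs_from_fragments(assignment, c("1" = s, "2" = -s))
      tibble::tibble(
        pair_a = list(p$a), pair_b = list(p$b), sign_a = s,
        label = format_bs_label(st), state = list(st)
      )
    })
  })
  rows
}

#' Generate a BS state by swapping Fe sites
#'
#' The coordinate-swap route: permuting Fe sites within a cluster permutes
#' the orientations, staying inside the enumerated set.  Permutations mixing
#' the two clusters of an 8-site state are rejected.
#'
#' @param state A [bs_state()].
#' @param permutation Integer vector, a permutation of `1..length(state)`.
#' @return The permuted [bs_state()] (`new[i] = old[permutation[i]]`).
#' @export
bs_site_swap <- function(state, permutation) {
  o <- unclass(state)
  n <- length(o)
  if (!identical(sort(as.integer(permutation)), seq_len(n))) {
    rlang::abort("permutation must rearrange all site indices exactly once")
  }
  if (n == 8) {
    moved <- which(permutation != seq_len(n))
    if (any(moved <= 4 & permutation[moved] > 4) ||
      any(moved > 4 & permutation[moved] <= 4)) {
      rlang::abort("site swaps must stay within one cluster")
    }
  }
  bs_state(o[permutation])
}

#' Family statistics of a BS energy table
#'
#' Reproduces the derived statements spin-state surveys make about their
#' energy tables.  A "family" is the set of states sharing a fixed pattern
#' in one cluster while the other cluster is varied: `main_fixed` fixes the
#' first four sites, `aux_fixed` the last four.  The fixed pattern is read
#' from the rows tagged with that family, and membership is then decided by
#' matching the label pattern, so a state whose main half matches the fixed
#' main pattern AND whose aux half matches the fixed aux pattern belongs to
#' both families.  Missing energies (`NA`, unconverged states) are excluded
#' from every statistic.
#'
#' @param table A BS energy table: tibble with `label`, `family`
#'   (`main_fixed`/`aux_fixed` block tag), `column`
#'   (`resting`/`reactive`), `energy_kjmol`.
#' @param family `"main_fixed"` or `"aux_fixed"`; `"all"` pools every row
#'   of the column.
#' @param column Which energy column to analyse.
#' @param tol_kjmol Width of the near-degeneracy window: `n_within` counts
#'   states at most this far above the minimum (inclusive).
#' @return A one-row tibble of class `bs_family_stats`: `family`, `column`,
#'   `n`, `spread_kjmol`, `min_state`, `min_energy_kjmol`,
#'   `gap_to_second_kjmol`, `n_within`, `tol_kjmol`, `tied_minimum`.
#' @export
analyze_family <- function(table, family = c("main_fixed", "aux_fixed", "all"),
                           column = c("resting", "reactive"),
                           tol_kjmol = 2) {
  family <- match.arg(family)
  column <- match.arg(column)
  rows <- dplyr::filter(table, .data$column == !!column)
  if (family != "all") {
    block <- dplyr::filter(rows, .data$family == !!family)
    if (nrow(block) == 0) rlang::abort("family has no rows in the table")
    half <- if (family == "main_fixed") 1:4 else 5:8
    patterns <- vapply(
      block$label,
      function(l) paste(unclass(parse_bs_label(l))[half], collapse = ","),
      character(1)
    )
    fixed <- unique(patterns)
    if (length(fixed) != 1) {
      rlang::abort("family block does not share a single fixed pattern")
    }
    match_half <- vapply(
      rows$label,
      function(l) paste(unclass(parse_bs_label(l))[half], collapse = ","),
      character(1)
    )
    rows <- rows[match_half == fixed, , drop = FALSE]
  }
  rows <- dplyr::filter(rows, !is.na(.data$energy_kjmol))
  if (nrow(rows) == 0) rlang::abort("no non-missing energies in the family")
  e <- rows$energy_kjmol
  ord <- order(e, rows$label)
  min_i <- ord[1]
  ties <- sum(e == e[min_i]) > 1
  gap <- if (nrow(rows) >= 2) e[ord[2]] - e[min_i] else 0
  out <- tibble::tibble(
    family = family, column = column, n = nrow(rows),
    spread_kjmol = max(e) - min(e),
    min_state = rows$label[min_i],
    min_energy_kjmol = e[min_i],
    gap_to_second_kjmol = gap,
    n_within = sum(e <= e[min_i] + tol_kjmol),
    tol_kjmol = tol_kjmol,
    tied_minimum = ties
  )
  class(out) <- c("bs_family_stats", class(out))
  out
}

#' Additive transfer estimate for an unconverged state
#'
#' When one BS determinant cannot be converged, its energy can be estimated
#' by assuming main-cluster and auxiliary-cluster spin energies add: the
#' energy of a reference state computed with a substitute auxiliary pattern,
#' minus the known auxiliary-cluster penalty of that substitution.
#'
#' @param e_reference Energy (kJ/mol) of the reference calculation.
#' @param delta_aux Energy cost (kJ/mol) of the substituted auxiliary
#'   pattern relative to the one of interest.
#' @return `e_reference - delta_aux`, in kJ/mol.
#' @export
estimate_missing_state <- function(e_reference, delta_aux) {
  stopifnot(is.finite(e_reference), is.finite(delta_aux))
  e_reference - delta_aux
}

#' Classify per-site spin populations
#'
#' Mulliken-style per-Fe spin populations identify the BS orientation of
#' each site by their sign.  A site is flagged "low" when its magnitude
#' falls below the family median magnitude minus a tolerance — the
#' signature of, e.g., a three-coordinate Fe with depleted spin density.
#' Zero populations get sign 0 (unassigned) and are always flagged.
#'
#' @param populations Numeric vector, one value per Fe site.
#' @param low_magnitude_tol Tolerance (spin units) subtracted from the
#'   median magnitude to form the low-spin-density threshold.
#' @return A tibble `site`, `population`, `sign`, `magnitude`, `low_flag`.
#' @export
summarize_spin_populations <- function(populations, low_magnitude_tol = 0.1) {
  if (length(populations) == 0) rlang::abort("no spin populations supplied")
  mag <- abs(populations)
  threshold <- stats::median(mag) - low_magnitude_tol
  tibble::tibble(
    site = seq_along(populations),
    population = populations,
    sign = sign(populations),
    magnitude = mag,
    low_flag = mag < threshold | populations == 0
  )
}

#' Half-up integer rounding
#'
#' Prose reporting of energy spreads rounds halves away from zero (39.5 ->
#' 40), unlike R's banker's rounding.
#'
#' @param x Numeric.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Read / write BS energy tables
#'
#' Tab-separated columns `label`, `family`, `column`, `energy_kjmol`
#' (missing energies as `NA`) plus an optional `provenance` column of
#' per-row source notes.
#'
#' @param path File path.
#' @return `read_bs_table`: a tibble of class `bs_energy_table`.
#' @export
read_bs_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      label = readr::col_character(),
      family = readr::col_character(),
      column = readr::col_character(),
      energy_kjmol = readr::col_double(),
      .default = readr::col_character()
    ),
    locale = readr::locale(encoding = "UTF-8"),
    progress = FALSE
  )
  for (l in tbl$label) parse_bs_label(l)
  if (anyDuplicated(tbl[, c("label", "column")])) {
    rlang::abort("at most one row per (label, column)")
  }
  class(tbl) <- c("bs_energy_table", class(tbl))
  tbl
}

#' @rdname read_bs_table
#' @param table A BS energy table.
#' @export
write_bs_table <- function(table, path) {
  readr::write_tsv(as.data.frame(table), path, na = "NA")
  invisible(path)
}
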