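#' Exchange-coupling parameter sets
#'
#' The collinear (Ising) reading of a Heisenberg exchange Hamiltonian over
#' Fe sites: `E = offset + sum_{i<j} J_ij * m_i * m_j * s_i * s_j`, with
#' `s_i = +/-1` the BS orientation and `m_i` the site spin magnitude.  Two
#' parameterisations are supported: `full_6J` (one coupling per within-
#' cluster pair; 6 per cubane) and `two_J` (a ferromagnetic `J_intra`
#' within the two delocalised pairs of a cubane and a single `J_inter`
#' across them — the [2Fe2S]+ subcluster picture).  Couplings between
#' sites of different cubanes (8-site states) are zero, mirroring the weak
#' interaction of two clusters ~12 Angstrom apart.
#'
#' @param model `"two_J"` or `"full_6J"`.
#' @param n_sites 4 or 8.
#' @param J_intra,J_inter Couplings (kJ/mol) for the `two_J` model; the
#'   ferromagnetic-pair picture has `J_intra < 0 < J_inter`.
#' @param intra_pairs List of site-index pairs forming the ferromagnetic
#'   pairs (default `(1,2)/(3,4)` per cluster).
#' @param couplings For `full_6J`, either a single numeric recycled over
#'   all within-cluster pairs or a tibble `i`, `j`, `J_kjmol`.
#' @param offset Constant energy offset (kJ/mol).
#' @return A list of class `heisenberg_params` with a `couplings` tibble
#'   (`i < j`), `offset`, `model` and `intra_pairs`.
#' @export
heisenberg_params <- function(model = c("two_J", "full_6J"),
                              n_sites = 4,
                              J_intra = -12, J_inter = 8,
                              intra_pairs = NULL,
                              couplings = NULL,
                              offset = 0) {
  model <- match.arg(model)
  stopifnot(n_sites %in% c(4L, 8L))
  cluster_of <- function(i) (i - 1) %/% 4
  all_pairs <- t(utils::combn(n_sites, 2))
  within <- cluster_of(all_pairs[, 1]) == cluster_of(all_pairs[, 2])
  pairs <- all_pairs[within, , drop = FALSE]
  if (is.null(intra_pairs)) {
    intra_pairs <- list(c(1L, 2L), c(3L, 4L))
    if (n_sites == 8L) {
      intra_pairs <- c(intra_pairs, list(c(5L, 6L), c(7L, 8L)))
    }
  }
  pair_key <- paste(pairs[, 1], pairs[, 2])
  intra_key <- vapply(
    intra_pairs,
    function(p) paste(min(p), max(p)),
    character(1)
  )
  if (model == "two_J") {
    J <- ifelse(pair_key %in% intra_key, J_intra, J_inter)
    tbl <- tibble::tibble(i = pairs[, 1], j = pairs[, 2], J_kjmol = J)
  } else {
    if (is.null(couplings)) couplings <- 0
    if (is.data.frame(couplings)) {
      tbl <- tibble::as_tibble(couplings)
      stopifnot(all(c("i", "j", "J_kjmol") %in% names(tbl)))
      ij <- cbind(pmin(tbl$i, tbl$j), pmax(tbl$i, tbl$j))
      tbl$i <- ij[, 1]
      tbl$j <- ij[, 2]
      if (!all(paste(tbl$i, tbl$j) %in% pair_key)) {
        rlang::abort("couplings must be within-cluster site pairs")
      }
    } else {
      tbl <- tibble::tibble(
        i = pairs[, 1], j = pairs[, 2],
        J_kjmol = rep_len(couplings, nrow(pairs))
      )
    }
  }
  if (!all(is.finite(tbl$J_kjmol))) rlang::abort("couplings must be finite")
  structure(
    list(
      model = model, couplings = tbl, offset = offset,
      n_sites = as.integer(n_sites), intra_pairs = intra_pairs
    ),
    class = "heisenberg_params"
  )
}

#' Ising energy of a BS determinant
#'
#' Evaluates `offset + sum_{i<j} J_ij m_i m_j s_i s_j` (kJ/mol) for a
#' collinear spin assignment.  The default site magnitude 2.25 is the
#' spin-quantum-number equivalent of a delocalised mixed-valence Fe(2.5+)
#' pair (4.5 unpaired electrons shared over two sites).
#'
#' @param state A [bs_state()] (or +/-1 vector).
#' @param params A [heisenberg_params()].
#' @param spins Per-site spin magnitudes `m_i`; scalar values are recycled.
#' @return Energy in kJ/mol.
#' @export
ising_energy <- function(state, params, spins = 2.25) {
  stopifnot(inherits(params, "heisenberg_params"))
  o <- as.integer(unclass(state))
  if (length(o) != params$n_sites) {
    rlang::abort("state length does not match the parameter set")
  }
  m <- rep_len(spins, length(o))
  if (any(m <= 0)) rlang::abort("site spin magnitudes must be positive")
  cp <- params$couplings
  params$offset +
    sum(cp$J_kjmol * m[cp$i] * m[cp$j] * o[cp$i] * o[cp$j])
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic BS energy table
#'
#' Evaluates the Ising energy of each state and adds independent Gaussian
#' noise, emulating the statistical shape of a BS spin-state survey table
#' with known ground truth.  Reproducible for a fixed seed; the global RNG
#' state is left untouched.
#'
#' @param states A tibble with `label`/`state` columns (from
#'   [enumerate_bs_states()] and friends) or a list of [bs_state()]s.
#' @param params A [heisenberg_params()].
#' @param spins Per-site magnitudes (see [ising_energy()]).
#' @param noise_sd Gaussian noise standard deviation (kJ/mol), `>= 0`.
#' @param seed Integer seed for the noise stream, or `NULL`.
#' @param family,column Tags written into the table rows.
#' @return A `bs_energy_table` tibble: `label`, `family`, `column`,
#'   `energy_kjmol`.
#' @export
generate_bs_table <- function(states, params, spins = 2.25,
                              noise_sd = 0, seed = NULL,
                              family = "main_fixed", column = "resting") {
  stopifnot(noise_sd >= 0)
  if (is.data.frame(states)) states <- states$state
  e0 <- vapply(
    states,
    function(s) ising_energy(s, params, spins),
    numeric(1)
  )
  noise <- if (noise_sd > 0) {
    with_local_seed(seed, stats::rnorm(length(e0), 0, noise_sd))
  } else {
    0
  }
  tbl <- tibble::tibble(
    label = vapply(states, format_bs_label, character(1)),
    family = family, column = column,
    energy_kjmol = e0 + noise
  )
  class(tbl) <- c("bs_energy_table", class(tbl))
  tbl
}

ising_design <- function(labels, spins, model, n_sites, intra_pairs) {
  template <- heisenberg_params(
    model = model, n_sites = n_sites,
    J_intra = 0, J_inter = 0, intra_pairs = intra_pairs, couplings = 0
  )
  cp <- template$couplings
  rows <- lapply(labels, function(l) {
    o <- as.integer(unclass(parse_bs_label(l)))
    if (length(o) != n_sites) {
      rlang::abort("table states do not match n_sites")
    }
    m <- rep_len(spins, n_sites)
    prods <- m[cp$i] * m[cp$j] * o[cp$i] * o[cp$j]
    if (model == "two_J") {
      key <- paste(cp$i, cp$j)
      intra_key <- vapply(
        template$intra_pairs,
        function(p) paste(min(p), max(p)), character(1)
      )
      c(
        J_intra = sum(prods[key %in% intra_key]),
        J_inter = sum(prods[!key %in% intra_key])
      )
    } else {
      stats::setNames(prods, paste0("J_", cp$i, "_", cp$j))
    }
  })
  X <- do.call(rbind, rows)
  cbind(X, offset = 1)
}

#' Recover exchange couplings from a BS energy table
#'
#' Linear least squares of the table energies on the pair-product design
#' `m_i m_j s_i s_j`.  The design over a restricted state set is often
#' rank-deficient — famously, the 2-up/2-down singlet manifold of one
#' cubane constrains only two independent combinations because the total
#' pair-sum is the same for every singlet state — so the fit reports the
#' design rank, returns the minimum-norm solution (via the singular value
#' decomposition) and names the identifiable parameter combinations.
#' Adding states outside the restricted manifold (e.g. the all-up
#' determinant) raises the rank.
#'
#' @param table A `bs_energy_table` (missing energies are dropped).
#' @param spins Per-site magnitudes used to generate the table.
#' @param model `"two_J"` or `"full_6J"`.
#' @param n_sites 4 or 8 (inferred from the first label by default).
#' @param intra_pairs Ferromagnetic-pair partition for `two_J`; default
#'   `(1,2)/(3,4)` per cluster, matching the fragment assignment used to
#'   build pair-aligned states.
#' @return An object of class `heisenberg_fit`: fitted
#'   [heisenberg_params()], coefficient table, design rank and singular
#'   values, residual norm, and the identifiable combinations (right
#'   singular vectors with non-negligible singular values).
#' @export
fit_couplings <- function(table, spins = 2.25,
                          model = c("two_J", "full_6J"),
                          n_sites = NULL, intra_pairs = NULL) {
  model <- match.arg(model)
  rows <- dplyr::filter(table, !is.na(.data$energy_kjmol))
  if (nrow(rows) < 2) {
    rlang::abort("need at least two non-missing table rows to fit")
  }
  if (is.null(n_sites)) {
    n_sites <- length(unclass(parse_bs_label(rows$label[1])))
  }
  X <- ising_design(rows$label, spins, model, n_sites, intra_pairs)
  y <- rows$energy_kjmol
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  rank <- sum(pos)
  if (nrow(rows) < rank) {
    rlang::abort("fewer table rows than identifiable parameters")
  }
  dinv <- ifelse(pos, 1 / sv$d, 0)
  beta <- sv$v %*% (dinv * (t(sv$u) %*% y))
  beta <- stats::setNames(drop(beta), colnames(X))
  fitted <- drop(X %*% beta)
  identifiable <- sv$v[, pos, drop = FALSE]
  rownames(identifiable) <- colnames(X)
  nullspace <- sv$v[, !pos, drop = FALSE]
  rownames(nullspace) <- colnames(X)

  if (model == "two_J") {
    params <- heisenberg_params(
      model = "two_J", n_sites = n_sites,
      J_intra = beta[["J_intra"]], J_inter = beta[["J_inter"]],
      intra_pairs = intra_pairs, offset = beta[["offset"]]
    )
  } else {
    cp <- heisenberg_params(
      model = "full_6J", n_sites = n_sites,
      couplings = 0
    )$couplings
    cp$J_kjmol <- unname(beta[paste0("J_", cp$i, "_", cp$j)])
    params <- heisenberg_params(
      model = "full_6J", n_sites = n_sites,
      couplings = cp, offset = beta[["offset"]]
    )
  }
  structure(
    list(
      params = params,
      coefficients = tibble::tibble(
        term = names(beta), estimate = unname(beta)
      ),
      rank = rank,
      n_parameters = ncol(X),
      n_states = nrow(rows),
      singular_values = sv$d,
      identifiable = identifiable,
      nullspace = nullspace,
      residual_norm = sqrt(sum((y - fitted)^2)),
      fitted = fitted,
      labels = rows$label
    ),
    class = "heisenberg_fit"
  )
}

#' @export
print.heisenberg_fit <- function(x, ...) {
  cat(
    "Ising coupling fit (", x$params$model, "): rank ", x$rank, "/",
    x$n_parameters, " on ", x$n_states, " states; residual norm ",
    format(x$residual_norm, digits = 4), " kJ/mol\n",
    sep = ""
  )
  if (x$rank < x$n_parameters) {
    cat("design is rank-deficient; estimates are the minimum-norm solution\n")
  }
  print(x$coefficients)
  invisible(x)
}

#' Tidy an exchange-coupling fit
#'
#' @param x A `heisenberg_fit`.
#' @param ... Unused.
#' @return One row per model term with the (minimum-norm) estimate.
#' @export
tidy.heisenberg_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.heisenberg_fit
#' @return `glance`: a one-row model summary (rank, parameter and state
#'   counts, residual norm, deficiency flag).
#' @export
glance.heisenberg_fit <- function(x, ...) {
  tibble::tibble(
    model = x$params$model,
    rank = x$rank,
    n_parameters = x$n_parameters,
    n_states = x$n_states,
    residual_norm = x$residual_norm,
    rank_deficient = x$rank < x$n_parameters
  )
}

#' Serialise fitted couplings as a key-value text record
#'
#' @param fit A `heisenberg_fit`.
#' @param path Output path.
#' @export
write_couplings <- function(fit, path) {
  writeLines(
    c(
      paste("model", fit$params$model),
      paste("rank", fit$rank),
      sprintf("%s %.12g", fit$coefficients$term, fit$coefficients$estimate)
    ),
    path
  )
  invisible(path)
}
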