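#' Idealised cubane cluster with ligand stubs
#'
#' Builds a [4Fe4S] core as two interpenetrating tetrahedra — the
#' alternating corners of a cube scaled so that all twelve Fe-S contacts
#' equal `fe_s_distance` — plus a truncated first-sphere ligand stub per Fe
#' site along its outward body diagonal.  Stub types: `"thiolate"` (Cys
#' model: SG-CB-CA chain), `"serinate"` (Ser model: OG-CB-CA), `"water"`
#' (O with two H, no junction) or `"none"` (the three-coordinate site left
#' after Fe dissociation).  Real crystallographic cubanes are distorted
#' (Fe-S spans of ~0.2 Angstrom); optional Gaussian jitter emulates that
#' spread reproducibly.
#'
#' @param fe_s_distance Target Fe-S bond length (Angstrom), default 2.30.
#' @param stubs Character vector of 4 stub types, one per Fe site.
#' @param centroid Cluster centre (Angstrom).
#' @param orientation 3x3 rotation applied to the ideal geometry.
#' @param jitter_sd Gaussian coordinate jitter (Angstrom), default 0.
#' @param seed Seed for the jitter stream.
#' @param serial_start First atom serial.
#' @return A list of class `cubane_fixture`: `structure`
#'   ([fes_structure()]), `fe_serials`, `sulfide_serials`, `qm_serials`
#'   (everything except the CA link carbons), and a `stub_info` tibble
#'   with per-site `type`, `qm_edge_serial` (CB) and `ca_serial` (CL) for
#'   junction bookkeeping (`NA` for water/none).
#' @export
make_cubane <- function(fe_s_distance = 2.30,
                        stubs = rep("thiolate", 4),
                        centroid = c(0, 0, 0),
                        orientation = diag(3),
                        jitter_sd = 0, seed = NULL,
                        serial_start = 1L) {
  stopifnot(fe_s_distance > 0, length(stubs) == 4)
  stubs <- match.arg(stubs,
    c("thiolate", "serinate", "water", "none"),
    several.ok = TRUE
  )
  a <- fe_s_distance / 2
  fe_dirs <- rbind(
    c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)
  )
  s_dirs <- -fe_dirs
  rows <- list()
  add <- function(element, pos, charge, tag) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      element = element, x = pos[1], y = pos[2], z = pos[3],
      charge = charge, residue_tag = tag
    )
    length(rows)
  }
  fe_idx <- integer(4)
  s_idx <- integer(4)
  for (i in 1:4) fe_idx[i] <- add("Fe", a * fe_dirs[i, ], 0.5, "SF4")
  for (i in 1:4) s_idx[i] <- add("S", a * s_dirs[i, ], -0.5, "SF4")
  stub_info <- tibble::tibble(
    site = 1:4, type = stubs,
    qm_edge_serial = NA_integer_, ca_serial = NA_integer_
  )
  for (i in 1:4) {
    u <- fe_dirs[i, ] / sqrt(3)
    fe_pos <- a * fe_dirs[i, ]
    if (stubs[i] == "thiolate") {
      sg <- add("S", fe_pos + 2.30 * u, -0.6, "CYS")
      cb <- add("C", fe_pos + (2.30 + 1.80) * u, 0.2, "CYS")
      ca <- add("C", fe_pos + (2.30 + 1.80 + 1.53) * u, 0.1, "CYS")
      stub_info$qm_edge_serial[i] <- cb
      stub_info$ca_serial[i] <- ca
    } else if (stubs[i] == "serinate") {
      og <- add("O", fe_pos + 1.86 * u, -0.6, "SER")
      cb <- add("C", fe_pos + (1.86 + 1.43) * u, 0.2, "SER")
      ca <- add("C", fe_pos + (1.86 + 1.43 + 1.53) * u, 0.1, "SER")
      stub_info$qm_edge_serial[i] <- cb
      stub_info$ca_serial[i] <- ca
    } else if (stubs[i] == "water") {
      o_pos <- fe_pos + 2.12 * u
      # perpendicular frame for the two protons
      perp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v <- perp - sum(perp * u) * u
      v <- v / sqrt(sum(v^2))
      h1 <- o_pos + 0.96 * (0.6 * u + 0.8 * v)
      h2 <- o_pos + 0.96 * (0.6 * u - 0.8 * v)
      add("O", o_pos, -0.834, "HOH")
      add("H", h1, 0.417, "HOH")
      add("H", h2, 0.417, "HOH")
    }
  }
  atoms <- dplyr::bind_rows(rows)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(orientation)
  if (jitter_sd > 0) {
    xyz <- xyz + with_local_seed(
      seed,
      matrix(stats::rnorm(length(xyz), 0, jitter_sd), ncol = 3)
    )
  }
  xyz <- sweep(xyz, 2, centroid, `+`)
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms$serial <- serial_start - 1L + seq_len(nrow(atoms))
  offset <- function(i) atoms$serial[i]
  st <- as_fes_structure(atoms, title = "ideal [4Fe4S] cubane fixture")
  stub_info$qm_edge_serial <- ifelse(
    is.na(stub_info$qm_edge_serial), NA_integer_,
    serial_start - 1L + stub_info$qm_edge_serial
  )
  stub_info$ca_serial <- ifelse(
    is.na(stub_info$ca_serial), NA_integer_,
    serial_start - 1L + stub_info$ca_serial
  )
  structure(
    list(
      structure = st,
      fe_serials = offset(fe_idx),
      sulfide_serials = offset(s_idx),
      qm_serials = setdiff(st$serial, stats::na.omit(stub_info$ca_serial)),
      stub_info = stub_info
    ),
    class = "cubane_fixture"
  )
}

#' Two-cluster active-site fixture with a charged environment
#'
#' Emulates the layout of a radical SAM active site at desk scale: a main
#' cubane (three thiolate stubs plus a water ligand on Fe1) and an
#' auxiliary cubane (three thiolate stubs plus a serinate on Fe5) with
#' centroids 12 Angstrom apart, surrounded by ~100 environment atoms
#' arranged as neutral water-like charge groups in system 2.  Junctions sit
#' at every stub CA atom.  Bit-reproducible for a fixed seed.
#'
#' @param seed Integer seed for environment placement.
#' @param n_env_groups Number of 3-atom neutral charge groups (default 33,
#'   ~100 atoms).
#' @param jitter_sd Coordinate jitter applied to both cubanes (Angstrom).
#' @return A list of class `lipa_fixture`: `structure`, `partition`,
#'   `clusters` (list of two [cluster_spec()]), `main`/`aux` cubane
#'   fixtures and `env_serials`.
#' @export
make_lipa_fixture <- function(seed = 1, n_env_groups = 33, jitter_sd = 0) {
  main <- make_cubane(
    stubs = c("water", "thiolate", "thiolate", "thiolate"),
    centroid = c(0, 0, 0), jitter_sd = jitter_sd, seed = seed,
    serial_start = 1L
  )
  aux <- make_cubane(
    stubs = c("serinate", "thiolate", "thiolate", "thiolate"),
    centroid = c(12, 0, 0), jitter_sd = jitter_sd,
    seed = if (is.null(seed)) NULL else seed + 1L,
    serial_start = max(main$structure$serial) + 1L
  )
  env <- with_local_seed(seed, {
    centre <- c(6, 0, 0)
    purrr::map_dfr(seq_len(n_env_groups), function(g) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      r <- stats::runif(1, 10, 14)
      o_pos <- centre + r * u
      v <- stats::rnorm(3)
      v <- v - sum(v * u) * u
      v <- v / sqrt(sum(v^2))
      w <- c(
        u[2] * v[3] - u[3] * v[2],
        u[3] * v[1] - u[1] * v[3],
        u[1] * v[2] - u[2] * v[1]
      )
      pos <- rbind(o_pos, o_pos + 0.96 * v, o_pos + 0.96 * (0.5 * v + 0.86 * w))
      tibble::tibble(
        element = c("O", "H", "H"),
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        charge = c(-0.834, 0.417, 0.417),
        residue_tag = "HOH"
      )
    })
  })
  env$serial <- max(aux$structure$serial) + seq_len(nrow(env))
  full <- as_fes_structure(
    dplyr::bind_rows(main$structure, aux$structure, env),
    title = "two-cluster active-site fixture"
  )
  stub_all <- dplyr::bind_rows(main$stub_info, aux$stub_info)
  stub_all <- stub_all[!is.na(stub_all$ca_serial), , drop = FALSE]
  qm <- c(main$qm_serials, aux$qm_serials)
  partition <- partition_structure(
    full, qm,
    junctions = tibble::tibble(
      qm_serial = stub_all$qm_edge_serial,
      cl_serial = stub_all$ca_serial,
      scale = link_scale_default("C", "C")
    )
  )
  clusters <- list(
    main = cluster_spec(main$fe_serials, main$sulfide_serials,
      site_offset = 0
    ),
    aux = cluster_spec(aux$fe_serials, aux$sulfide_serials,
      site_offset = 4
    )
  )
  structure(
    list(
      structure = full, partition = partition, clusters = clusters,
      main = main, aux = aux, env_serials = env$serial
    ),
    class = "lipa_fixture"
  )
}

fixture_checksums <- c(
  table1.tsv = "654b7d78a25b8b85b622522c4c4e9d0d",
  profile_s1.tsv = "555c3cda6b8afe7a370f97062c660785",
  profile_s2_mech1.tsv = "db0447b24ef45f13c5af4e1c4d3bc507",
  profile_s2_mech2.tsv = "7b9d901ede611ed81ff741298491e97f",
  profile_s2_oxidised.tsv = "a30f09f3e77bd2a5a6694b2f5fde457c"
)

packaged_path <- function(file) {
  path <- system.file("extdata", file, package = "fescubane")
  if (path == "") rlang::abort(paste0("packaged fixture missing: ", file))
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, unname(fixture_checksums[file]))) {
    rlang::abort(paste0("checksum mismatch for packaged fixture ", file))
  }
  path
}

#' Packaged spin-state survey table
#'
#' The shipped transcription of the published two-cluster BS energy table
#' (resting and reactive columns, kJ/mol; the unconverged determinant as
#' `NA`).  Every row carries a provenance note; loading fails on a missing
#' note or a checksum mismatch against the shipped file.
#'
#' @return A `bs_energy_table` tibble with a `provenance` column.
#' @export
packaged_bs_table <- function() {
  tbl <- read_bs_table(packaged_path("table1.tsv"))
  if (!"provenance" %in% names(tbl) || anyNA(tbl$provenance) ||
    any(tbl$provenance == "")) {
    rlang::abort("packaged table rows must carry provenance notes")
  }
  tbl
}

#' Packaged reaction-profile transcriptions
#'
#' The stationary-point energies of the two S-insertion half-reactions as
#' printed in the source text (nothing read off figures): the first
#' insertion (`s1`), the second insertion up to the two competing
#' sulfur-attack mechanisms (`s2_mech1`, `s2_mech2`), and the
#' no-prior-reduction cleavage branch (`s2_oxidised`).  Transition-state
#' energies are stored as explicit points derived from the printed barrier
#' heights; each row's `note` records which printed quantity it encodes.
#'
#' @return A named list of `reaction_profile` tibbles.
#' @export
packaged_profiles <- function() {
  files <- c(
    s1 = "profile_s1.tsv",
    s2_mech1 = "profile_s2_mech1.tsv",
    s2_mech2 = "profile_s2_mech2.tsv",
    s2_oxidised = "profile_s2_oxidised.tsv"
  )
  profiles <- lapply(files, function(f) {
    p <- read_profile(packaged_path(f))
    if (!"note" %in% names(p) || anyNA(p$note) || any(p$note == "")) {
      rlang::abort("packaged profile rows must carry provenance notes")
    }
    p
  })
  profiles
}

#' Write a complete fixture bundle to disk
#'
#' Materialises [make_lipa_fixture()] as plain-text files: the structure as
#' PDB-style XYZ, the partition, the point-charge table and copies of the
#' packaged TSV fixtures.
#'
#' @param dir Output directory (created if needed).
#' @param seed Fixture seed.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(dir, seed = 7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- make_lipa_fixture(seed = seed)
  write_xyz(fx$structure, file.path(dir, "structure.xyz"))
  writeLines(
    c(
      paste("system1", paste(fx$partition$system1, collapse = " ")),
      paste("system2", paste(fx$partition$system2, collapse = " ")),
      sprintf(
        "junction %d %d %.6f",
        fx$partition$junctions$qm_serial,
        fx$partition$junctions$cl_serial,
        fx$partition$junctions$scale
      )
    ),
    file.path(dir, "partition.txt")
  )
  write_point_charges(
    point_charge_model(fx$structure, fx$partition),
    file.path(dir, "point_charges.txt")
  )
  write_bs_table(packaged_bs_table(), file.path(dir, "table1.tsv"))
  for (nm in names(packaged_profiles())) {
    write_profile(
      packaged_profiles()[[nm]],
      file.path(dir, paste0("profile_", nm, ".tsv"))
    )
  }
  invisible(dir)
}
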