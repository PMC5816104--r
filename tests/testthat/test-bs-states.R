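up <- "↑"
dn <- "↓"
lab <- function(main, aux = NULL) {
  body <- if (is.null(aux)) main else paste(main, aux)
  paste0("[", body, "]")
}

test_that("label parsing and formatting round-trip", {
  s <- parse_bs_label(lab(
    paste0(up, up, dn, dn), paste0(dn, up, up, dn)
  ))
  expect_equal(unclass(s), c(1, 1, -1, -1, -1, 1, 1, -1))
  tbl <- packaged_bs_table()
  for (l in unique(tbl$label)) {
    expect_identical(format_bs_label(parse_bs_label(l)), l)
  }
  expect_equal(length(unique(tbl$label)), 11)
  # ascii aliases accepted on input
  expect_equal(
    unclass(parse_bs_label("uudd")),
    c(1, 1, -1, -1)
  )
  expect_error(parse_bs_label(paste0(up, up, up)), "4 sites")
  expect_error(parse_bs_label("uuxd"), "malformed")
})

test_that("enumeration counts match the binomial coefficient", {
  expect_equal(nrow(enumerate_bs_states(4, 2)), 6)
  expect_equal(nrow(enumerate_bs_states(4, 4)), 1)
  expect_equal(
    enumerate_bs_states(4, 4)$label[1],
    lab(paste0(up, up, up, up))
  )
  expect_equal(nrow(enumerate_bs_states(8, 4)), choose(8, 4))
  expect_error(enumerate_bs_states(4, -1), "non-negative")
  expect_error(enumerate_bs_states(4, 5), "exceed")
})

test_that("enumeration is equivalent to brute-force bitmask generation", {
  for (n in c(4, 8)) {
    for (k in 0:n) {
      mine <- enumerate_bs_states(n, k)$state
      oracle <- bitmask_assignments(n, k)
      key <- function(o) paste(unlist(o), collapse = ",")
      expect_setequal(
        vapply(mine, key, character(1)),
        vapply(oracle, key, character(1))
      )
    }
  }
  # unlabelled generator covers larger site counts
  for (n in c(6, 10)) {
    k <- n %/% 2
    expect_equal(
      nrow(spin_assignment_matrix(n, k)),
      length(bitmask_assignments(n, k))
    )
  }
})

test_that("two-cluster singlet product has 36 members, all net-zero", {
  combined <- enumerate_two_cluster_singlets()
  expect_equal(nrow(combined), 36)
  expect_equal(nrow(dplyr::distinct(combined, label)), 36)
  expect_true(
    lab(paste0(up, up, dn, dn), paste0(dn, up, up, dn)) %in% combined$label
  )
  for (s in combined$state) {
    o <- unclass(s)
    expect_equal(sum(o[1:4]), 0)
    expect_equal(sum(o[5:8]), 0)
  }
})

test_that("unpaired-spin counting follows the high-spin rule", {
  expect_equal(
    count_unpaired_spins(list(c(2, 2, 3, 3), c(2, 2, 3, 3))), 36
  )
  expect_equal(count_unpaired_spins(c(2, 2, 3, 3)), 18)
  expect_equal(count_unpaired_spins(c(3, 3, 3, 3)), 20)
  expect_error(count_unpaired_spins(c(2, 4)), "high-spin")
})

test_that("fragment generation produces pair-aligned states", {
  s <- bs_from_fragments(c(1, 1, 2, 2), c("1" = 1, "2" = -1))
  expect_equal(format_bs_label(s), lab(paste0(up, up, dn, dn)))
  expect_error(
    bs_from_fragments(c(1, 1, 2, NA), c("1" = 1, "2" = -1)),
    "assigned"
  )
  expect_error(
    bs_from_fragments(c(1, 1, 2, 3), c("1" = 1, "2" = -1)),
    "fragment"
  )
  # 3 bipartitions x 2 signs = all six 2-up states (enumeration oracle)
  pr <- fragment_pairings()
  expect_equal(nrow(pr), 6)
  expect_setequal(pr$label, enumerate_bs_states(4, 2)$label)
  # single all-site fragment is ferromagnetic, not a singlet
  all_up <- bs_from_fragments(c(1, 1, 1, 1), c("1" = 1))
  expect_equal(sum(unclass(all_up)), 4)
})

test_that("site swaps stay inside the enumerated set and span the orbit", {
  s <- parse_bs_label(paste0(up, dn, up, dn))
  expect_identical(bs_site_swap(s, 1:4), s)
  expect_equal(
    format_bs_label(bs_site_swap(s, c(2, 1, 3, 4))),
    lab(paste0(dn, up, up, dn))
  )
  # orbit under all 24 permutations = the full 6-state set (group oracle)
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  orbit <- unique(apply(perms, 1, function(p) {
    format_bs_label(bs_site_swap(s, p))
  }))
  expect_setequal(orbit, enumerate_bs_states(4, 2)$label)
  # cross-cluster swap rejected
  s8 <- parse_bs_label(lab(
    paste0(up, dn, up, dn), paste0(dn, up, up, dn)
  ))
  expect_error(bs_site_swap(s8, c(5, 2, 3, 4, 1, 6, 7, 8)), "cluster")
  closure <- bs_site_swap(s8, c(1, 2, 3, 4, 8, 7, 6, 5))
  expect_true(
    format_bs_label(closure) %in% enumerate_two_cluster_singlets()$label
  )
})

test_that("family analysis reproduces the packaged survey statements", {
  tbl <- packaged_bs_table()
  main_rest <- analyze_family(tbl, "main_fixed", "resting", tol_kjmol = 2)
  expect_equal(main_rest$n, 6)
  expect_equal(main_rest$spread_kjmol, 8.6)
  expect_equal(round_half_up(main_rest$spread_kjmol), 9)
  aux_rest <- analyze_family(tbl, "aux_fixed", "resting", tol_kjmol = 2)
  # shared row joins the family by pattern matching: 6 members
  expect_equal(aux_rest$n, 6)
  expect_equal(aux_rest$spread_kjmol, 13.4)
  expect_equal(round_half_up(aux_rest$spread_kjmol), 13)
  expect_equal(
    aux_rest$min_state,
    lab(paste0(dn, up, up, dn), paste0(dn, up, up, dn))
  )
  expect_equal(aux_rest$n_within, 3) # three states within 2 kJ/mol
  main_react <- analyze_family(tbl, "main_fixed", "reactive")
  expect_equal(round_half_up(main_react$spread_kjmol), 40)
  aux_react <- analyze_family(tbl, "aux_fixed", "reactive")
  expect_equal(aux_react$n, 5) # the unconverged row is excluded
  expect_equal(round_half_up(aux_react$spread_kjmol), 14)
  pooled <- analyze_family(tbl, "all", "reactive")
  expect_equal(
    pooled$min_state,
    lab(paste0(up, up, dn, dn), paste0(dn, up, up, dn))
  )
  expect_equal(pooled$min_energy_kjmol, -9.1)
  expect_equal(pooled$gap_to_second_kjmol, 7.0)
})

test_that("family analysis is invariant to row order and uniform shifts", {
  tbl <- packaged_bs_table()
  ref <- analyze_family(tbl, "aux_fixed", "resting")
  set.seed(3)
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(
    analyze_family(shuffled, "aux_fixed", "resting")[
      , c("spread_kjmol", "min_state", "gap_to_second_kjmol", "n_within")
    ],
    ref[, c("spread_kjmol", "min_state", "gap_to_second_kjmol", "n_within")]
  )
  shifted <- dplyr::mutate(tbl, energy_kjmol = energy_kjmol + 123.4)
  got <- analyze_family(shifted, "aux_fixed", "resting")
  expect_equal(got$spread_kjmol, ref$spread_kjmol)
  expect_equal(got$gap_to_second_kjmol, ref$gap_to_second_kjmol)
  expect_equal(got$n_within, ref$n_within)
  expect_equal(got$min_energy_kjmol, ref$min_energy_kjmol + 123.4)
})

test_that("single-entry families and degenerate tolerances behave", {
  tbl <- tibble::tibble(
    label = lab(paste0(up, dn, up, dn)),
    family = "main_fixed", column = "resting", energy_kjmol = -3
  )
  got <- analyze_family(tbl, "all", "resting", tol_kjmol = 0)
  expect_equal(got$spread_kjmol, 0)
  expect_equal(got$n_within, 1)
  all_na <- dplyr::mutate(tbl, energy_kjmol = NA_real_)
  expect_error(analyze_family(all_na, "all", "resting"), "non-missing")
})

test_that("additive transfer estimate for an unconverged state", {
  expect_equal(estimate_missing_state(11, 2), 9)
  expect_equal(estimate_missing_state(5, 0), 5)
  expect_equal(estimate_missing_state(0, 0), 0)
})

test_that("spin-population summary flags depleted sites", {
  got <- summarize_spin_populations(c(-3.4, 3.6, 3.7, 3.8),
    low_magnitude_tol = 0.1)
  expect_equal(got$sign, c(-1, 1, 1, 1))
  expect_equal(got$low_flag, c(TRUE, FALSE, FALSE, FALSE))
  all4 <- summarize_spin_populations(rep(4, 4))
  expect_true(all(all4$sign == 1) && !any(all4$low_flag))
  zero <- summarize_spin_populations(c(0, 3.6, 3.7, 3.8))
  expect_equal(zero$sign[1], 0)
  expect_true(zero$low_flag[1])
  expect_error(summarize_spin_populations(numeric(0)), "no spin")
})

test_that("BS tables round-trip through TSV with missing values", {
  tbl <- packaged_bs_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bs_table(tbl, path)
  back <- read_bs_table(path)
  expect_equal(back$label, tbl$label)
  expect_equal(back$energy_kjmol, tbl$energy_kjmol)
  expect_equal(sum(is.na(back$energy_kjmol)), 1)
})
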