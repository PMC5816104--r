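test_that("Ising energy matches the direct pair-sum oracle", {
  set.seed(12)
  for (rep in 1:20) {
    params <- heisenberg_params(
      "full_6J",
      couplings = round(stats::rnorm(6, 0, 10), 2),
      offset = round(stats::rnorm(1, 0, 5), 2)
    )
    m <- stats::runif(4, 1.5, 2.5)
    s <- bs_state(sample(c(-1L, 1L), 4, replace = TRUE))
    expect_equal(
      ising_energy(s, params, m),
      ising_oracle(unclass(s), params, m)
    )
  }
})

test_that("zero couplings give the offset; uniform J gives offset - 2Jm^2", {
  params0 <- heisenberg_params("full_6J", couplings = 0, offset = 3.5)
  expect_equal(
    ising_energy(parse_bs_label("udud"), params0), 3.5
  )
  J <- 4.2
  m <- 2
  params <- heisenberg_params("full_6J", couplings = J, offset = 1)
  # every 2-up/2-down state has 2 aligned and 4 anti-aligned pairs
  for (s in enumerate_bs_states(4, 2)$state) {
    expect_equal(ising_energy(s, params, m), 1 + J * m^2 * (2 - 4))
  }
})

test_that("ferromagnetic pairs with antiferromagnetic inter coupling put
           the pair-aligned states lowest", {
  params <- heisenberg_params("two_J", J_intra = -10, J_inter = 6)
  singlets <- enumerate_bs_states(4, 2)
  e <- vapply(singlets$state, ising_energy, numeric(1), params = params)
  paired <- singlets$label %in% c(
    format_bs_label(bs_state(c(1, 1, -1, -1))),
    format_bs_label(bs_state(c(-1, -1, 1, 1)))
  )
  expect_lt(max(e[paired]), min(e[!paired]))
})

test_that("global spin flip leaves the Ising energy unchanged", {
  set.seed(9)
  params <- heisenberg_params(
    "full_6J",
    couplings = round(stats::rnorm(6, 0, 8), 2), offset = 2
  )
  for (k in 0:4) {
    for (s in enumerate_bs_states(4, k)$state) {
      flipped <- bs_state(-unclass(s))
      expect_equal(
        ising_energy(s, params),
        ising_energy(flipped, params)
      )
    }
  }
})

test_that("table generation is exact without noise and seed-reproducible", {
  params <- heisenberg_params("two_J", J_intra = -12, J_inter = 8)
  singlets <- enumerate_bs_states(4, 2)
  t0 <- generate_bs_table(singlets, params, noise_sd = 0)
  expect_equal(
    t0$energy_kjmol,
    vapply(singlets$state, ising_energy, numeric(1), params = params)
  )
  t1 <- generate_bs_table(singlets, params, noise_sd = 1, seed = 42)
  t2 <- generate_bs_table(singlets, params, noise_sd = 1, seed = 42)
  expect_identical(t1$energy_kjmol, t2$energy_kjmol)
  t3 <- generate_bs_table(singlets, params, noise_sd = 1, seed = 43)
  expect_false(identical(t1$energy_kjmol, t3$energy_kjmol))
  # noise scale sane: sample sd of the residuals within chi-square bounds
  resid <- t1$energy_kjmol - t0$energy_kjmol
  expect_gt(stats::sd(resid), 0.2)
  expect_lt(stats::sd(resid), 2.5)
})

test_that("the ground state of a pair-coupled synthetic table is
           pair-aligned in every cluster", {
  set.seed(31)
  for (rep in 1:20) {
    params <- heisenberg_params(
      "two_J",
      J_intra = -stats::runif(1, 5, 20),
      J_inter = stats::runif(1, 2, 10)
    )
    tbl <- generate_bs_table(
      enumerate_bs_states(4, 2), params,
      noise_sd = 0
    )
    best <- tbl$label[which.min(tbl$energy_kjmol)]
    expect_true(best %in% c(
      format_bs_label(bs_state(c(1, 1, -1, -1))),
      format_bs_label(bs_state(c(-1, -1, 1, 1)))
    ))
  }
})

test_that("coupling recovery over the singlet manifold is rank limited and
           reproduces the table exactly", {
  params <- heisenberg_params("two_J", J_intra = -12, J_inter = 8,
    offset = 4)
  singlets <- enumerate_bs_states(4, 2)
  tbl <- generate_bs_table(singlets, params, noise_sd = 0)
  fit <- fit_couplings(tbl, model = "two_J")
  # only two combinations are identifiable on the singlet manifold: the
  # pair-sum over all couplings is the same for every 2-up/2-down state
  expect_equal(fit$rank, 2)
  expect_true(glance(fit)$rank_deficient)
  expect_equal(fit$fitted, tbl$energy_kjmol, tolerance = 1e-10)
  expect_equal(fit$residual_norm, 0, tolerance = 1e-9)
})

test_that("adding states outside the singlet manifold raises the rank and
           makes two_J recovery exact", {
  params <- heisenberg_params("two_J", J_intra = -12, J_inter = 8,
    offset = 4)
  states <- dplyr::bind_rows(
    enumerate_bs_states(4, 2),
    enumerate_bs_states(4, 3),
    enumerate_bs_states(4, 4)
  )
  tbl <- generate_bs_table(states, params, noise_sd = 0)
  fit <- fit_couplings(tbl, model = "two_J")
  expect_equal(fit$rank, 3)
  est <- tidy(fit)
  expect_equal(
    est$estimate[match(
      c("J_intra", "J_inter", "offset"), est$term
    )],
    c(-12, 8, 4),
    tolerance = 1e-10
  )
  # singlet-only fit has strictly lower rank
  fit_singlet <- fit_couplings(
    generate_bs_table(enumerate_bs_states(4, 2), params, noise_sd = 0),
    model = "two_J"
  )
  expect_lt(fit_singlet$rank, fit$rank)
})

test_that("full 6-coupling design over the 6 singlet states is singular but
           interpolates; the full state set recovers every coupling", {
  set.seed(77)
  true_j <- round(stats::rnorm(6, 0, 10), 3)
  params <- heisenberg_params("full_6J", couplings = true_j, offset = 2)
  singlets <- enumerate_bs_states(4, 2)
  tbl6 <- generate_bs_table(singlets, params, noise_sd = 0)
  fit6 <- fit_couplings(tbl6, model = "full_6J")
  expect_lt(fit6$rank, 7) # singular-value rank oracle
  expect_equal(fit6$fitted, tbl6$energy_kjmol, tolerance = 1e-9)
  all_states <- dplyr::bind_rows(
    lapply(0:4, function(k) enumerate_bs_states(4, k))
  )
  tbl_all <- generate_bs_table(all_states, params, noise_sd = 0)
  fit_all <- fit_couplings(tbl_all, model = "full_6J")
  expect_gt(fit_all$rank, fit6$rank)
  expect_equal(fit_all$rank, 7)
  expect_equal(
    fit_all$params$couplings$J_kjmol,
    params$couplings$J_kjmol,
    tolerance = 1e-10
  )
})

test_that("recovery error shrinks in expectation as states are added", {
  params <- heisenberg_params("two_J", J_intra = -12, J_inter = 8)
  small_set <- dplyr::bind_rows(
    enumerate_bs_states(4, 2)[1:4, ],
    enumerate_bs_states(4, 4)
  )
  big_set <- dplyr::bind_rows(
    lapply(0:4, function(k) enumerate_bs_states(4, k))
  )
  err <- function(states, seed) {
    tbl <- generate_bs_table(states, params, noise_sd = 2, seed = seed)
    est <- tidy(fit_couplings(tbl, model = "two_J"))
    sqrt(sum((est$estimate[match(c("J_intra", "J_inter"), est$term)] -
      c(-12, 8))^2))
  }
  seeds <- 1:50
  err_small <- vapply(seeds, function(s) err(small_set, s), numeric(1))
  err_big <- vapply(seeds, function(s) err(big_set, s + 1000), numeric(1))
  expect_lt(mean(err_big), mean(err_small))
})

test_that("fit rejects unusable tables", {
  params <- heisenberg_params("two_J")
  tbl <- generate_bs_table(enumerate_bs_states(4, 2)[1, ], params)
  expect_error(fit_couplings(tbl, model = "two_J"), "at least two")
})

test_that("couplings serialise to a key-value record", {
  params <- heisenberg_params("two_J", J_intra = -12, J_inter = 8)
  tbl <- generate_bs_table(
    dplyr::bind_rows(
      enumerate_bs_states(4, 2), enumerate_bs_states(4, 4)
    ),
    params
  )
  fit <- fit_couplings(tbl, model = "two_J")
  path <- withr::local_tempfile(fileext = ".txt")
  write_couplings(fit, path)
  lines <- readLines(path)
  expect_true(any(grepl("^model two_J", lines)))
  expect_true(any(grepl("^J_intra ", lines)))
})

test_that("spin engine with zero couplings equals the MM engine", {
  set.seed(8)
  st <- random_structure(5)
  bonds <- chain_bonds(5)
  params0 <- heisenberg_params("full_6J", n_sites = 4, couplings = 0)
  spin <- toy_spin_engine(params0, bonds = bonds)
  mm <- toy_mm_engine(bonds)
  s <- bs_state(c(1, -1, 1, -1))
  expect_equal(
    spin(st, state = s)$energy,
    mm(st)$energy,
    tolerance = 1e-14
  )
  # with couplings, the energy difference between states is geometry-free
  params <- heisenberg_params("two_J", J_intra = -9, J_inter = 5)
  spin2 <- toy_spin_engine(params, bonds = bonds)
  s2 <- bs_state(c(1, 1, -1, -1))
  d_geom1 <- spin2(st, state = s2)$energy - spin2(st, state = s)$energy
  st_moved <- transform_structure(st, translation = c(5, 5, 5))
  st_moved$x[2] <- st_moved$x[2] + 0.3
  d_geom2 <- spin2(st_moved, state = s2)$energy -
    spin2(st_moved, state = s)$energy
  expect_equal(d_geom1, d_geom2, tolerance = 1e-12)
  expect_equal(
    convert_energy(d_geom1, "au", "kJ/mol"),
    ising_energy(s2, params) - ising_energy(s, params),
    tolerance = 1e-9
  )
  # wrong state length rejected
  expect_error(
    spin2(st, state = bs_state(rep(1, 8))),
    "length"
  )
})

test_that("toy engine gradients agree with finite differences", {
  set.seed(21)
  st <- random_structure(4)
  charges <- tibble::tibble(
    x = c(4, -3), y = c(1, 2), z = c(0, -1),
    q = c(0.3, -0.2), serial = c(90L, 91L)
  )
  eng <- toy_mm_engine(chain_bonds(4))
  g <- eng(st, charges = charges)$gradient
  h <- 1e-6
  for (i in 1:4) {
    for (dim in c("x", "y", "z")) {
      stp <- st
      stp[[dim]][i] <- stp[[dim]][i] + h
      stm <- st
      stm[[dim]][i] <- stm[[dim]][i] - h
      fd <- (eng(stp, charges = charges)$energy -
        eng(stm, charges = charges)$energy) / (2 * h)
      expect_equal(
        g[i, match(dim, c("x", "y", "z"))], fd,
        tolerance = 1e-6
      )
    }
  }
})
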