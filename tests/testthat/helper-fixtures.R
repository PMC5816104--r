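# Shared test helpers: tiny structures, random fixtures, independent oracles.

# chain of n atoms along x, 1.5 A apart
chain_structure <- function(n, charge = 0) {
  fes_structure(
    serial = seq_len(n), element = "C",
    x = 1.5 * (seq_len(n) - 1), y = 0, z = 0,
    charge = charge
  )
}

trivial_partition <- function(structure, qm_serials = structure$serial) {
  partition_structure(
    structure, qm_serials,
    junctions = data.frame(
      qm_serial = integer(0), cl_serial = integer(0)
    )
  )
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

# random bonded structure with charges: a loose chain with perturbed
# geometry, used for cancellation and invariance properties
random_structure <- function(n = 6, charged = TRUE) {
  st <- chain_structure(n)
  st$x <- st$x + stats::rnorm(n, 0, 0.1)
  st$y <- stats::rnorm(n, 0, 0.3)
  st$z <- stats::rnorm(n, 0, 0.3)
  if (charged) st$charge <- round(stats::runif(n, -0.5, 0.5), 3)
  st
}

chain_bonds <- function(n, k_au = 0.25, d0_A = 1.5) {
  bond_terms(seq_len(n - 1), 2:n, k_au = k_au, d0_A = d0_A)
}

# independent bitmask enumeration oracle for spin assignments
bitmask_assignments <- function(n_sites, n_up) {
  out <- list()
  for (mask in 0:(2^n_sites - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n_sites)]
    if (sum(bits) == n_up) {
      out[[length(out) + 1]] <- ifelse(bits == 1, 1L, -1L)
    }
  }
  out
}

# independent Ising oracle: direct loop over pairs
ising_oracle <- function(o, params, m) {
  m <- rep_len(m, length(o))
  e <- params$offset
  cp <- params$couplings
  for (r in seq_len(nrow(cp))) {
    i <- cp$i[r]; j <- cp$j[r]
    e <- e + cp$J_kjmol[r] * m[i] * m[j] * o[i] * o[j]
  }
  e
}

label_set <- function(states_tbl) sort(states_tbl$label)
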