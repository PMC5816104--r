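---
title: "Methods: broken-symmetry spin states and subtractive QM/MM at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: broken-symmetry spin states and subtractive QM/MM at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fescubane)
```

## The problem

[4Fe4S] cubane clusters are the working parts of many metalloenzymes —
electron carriers, iron sensors, and, in radical SAM enzymes such as lipoyl
synthase, the sulfur donor itself. In the common [4Fe4S]²⁺ oxidation state
the cluster formally holds two Fe²⁺ (four unpaired electrons each) and two
Fe³⁺ (five each). Single-determinant electronic-structure methods cannot
represent the true antiferromagnetically coupled singlet; the standard
workaround is the *broken-symmetry* (BS) approach: each high-spin Fe site
is assigned a collinear surplus of spin up or down, and the low-spin
physics is approximated by determinants in which two sites point up and two
down. Choosing two up-sites among four gives `choose(4, 2) = 6`
determinants per cluster, and `6 × 6 = 36` combined assignments for an
active site holding two clusters. Which of these determinants is lowest —
and by how much — is an empirical question answered by tabulating their
energies.

This package implements the *machinery* of such a study at desk scale:
state enumeration, table analysis, the subtractive QM/MM energy assembly
with hydrogen link atoms and electrostatic embedding, the multi-level
energy extrapolation, constrained reaction-coordinate scans, and
reaction-profile statistics. The quantum-chemistry engine itself is
replaced by a pluggable contract and analytic toy engines, so every stage
is exercised end to end with exactly known expectations.

## BS state generation and analysis

Three generation routes are provided, and they must agree:

* `enumerate_bs_states(n, k)` — direct combinatorics, lexicographic order;
* `bs_from_fragments()` — the fragment route: sites inherit the sign of
  their fragment, so splitting a cubane into two ferromagnetic pairs with
  opposite signs generates the pair-aligned singlet states (all six arise
  from the 3 pair-bipartitions × 2 signs, see `fragment_pairings()`);
* `bs_site_swap()` — the coordinate-swap route: permuting sites within a
  cluster permutes orientations and stays inside the enumerated set.

`analyze_family()` reproduces the derived statements a spin-state survey
makes about its energy table: the spread (max − min), the minimum state and
its gap to the second-lowest, and the count of states within a tolerance of
the minimum. One convention matters: a "family" is defined by the *fixed
pattern* of one cluster, matched on the label, not by which block of the
table a row was printed in. A state whose main half matches the fixed main
pattern *and* whose auxiliary half matches the fixed auxiliary pattern
belongs to both families; this is required to reproduce the published
spreads (13.4 and 14.2 kJ/mol) of the packaged table. Missing
(unconverged) determinants are first-class `NA`s and excluded from every
statistic. Prose-style integer reporting uses half-up rounding
(`round_half_up(39.5)` is 40), matching how such surveys round.

```{r}
tbl <- packaged_bs_table()
analyze_family(tbl, "aux_fixed", "resting", tol_kjmol = 2)
```

## The Ising stand-in for the DFT engine

BS determinants are collinear, so the natural energy model over them is
the Ising evaluation of a Heisenberg exchange Hamiltonian:

E(σ) = offset + Σ_{i<j} J_ij · m_i · m_j · σ_i · σ_j,

with σ_i = ±1 the site orientation and m_i the site spin magnitude. No
spin projection is applied — the model mimics raw BS energies. The default
magnitude m = 2.25 is the spin-quantum-number equivalent of a delocalised
mixed-valence Fe²·⁵⁺ pair (9/2 shared over two sites); it is configurable
per site. The `two_J` parameterisation (ferromagnetic `J_intra < 0` inside
the two delocalised pairs, antiferromagnetic `J_inter > 0` across them)
encodes the accepted physical picture of [4Fe4S]²⁺: two high-spin
ferromagnetic [2Fe2S]⁺ halves coupling antiferromagnetically to a singlet.
With such parameters the pair-aligned singlet states are always the ground
states of a generated table, which the test suite asserts over randomised
parameter draws.

`generate_bs_table()` adds independent Gaussian noise (default sd 0) under
a local seed that never touches the global RNG stream. `fit_couplings()`
inverts the construction by linear least squares on the pair-product
design. A point worth documenting because it is easy to get wrong: over
the 2-up/2-down singlet manifold the total pair sum Σσ_iσ_j is the same
(−2) for every state, so with equal magnitudes the intra-pair column, the
inter-pair column and the intercept are exactly collinear — the design has
rank 2 and individual couplings are *not identifiable* from singlet
states alone, no matter how precise the energies. The fit therefore
reports the SVD rank, returns the minimum-norm solution (which still
reproduces all table energies exactly in the noiseless case) and names the
identifiable combinations. Adding any state outside the manifold (the
all-up determinant, a 3-up state) restores full rank and makes noiseless
recovery exact to 1e-10 kJ/mol.

## Subtractive QM/MM with electrostatic embedding

`run_qmmm()` assembles

E = E(QM1+ptch2, HL) + E(MM12, q₁=0, CL) − E(MM1, q₁=0, HL):

the QM energy of the hydrogen-capped QM region embedded in the
environment's point charges, plus the MM energy of everything (QM charges
zeroed to avoid double counting), minus the MM energy of the capped region
without electrostatics. Truncation artefacts of the cap cancel between the
two MM terms. Conventions adopted where the method description leaves
freedom:

* Link atoms are always hydrogen, placed at `qm + g·(cl − qm)`; the default
  `g` is the ratio of equilibrium X–H to X–CL bond lengths (C–C → C–H:
  1.09/1.51 ≈ 0.722), configurable per junction.
* Every system-2 atom enters the point-charge model except the CL atoms;
  the excluded CL charge is *not* redistributed, so the model total may be
  non-integral. This is deliberate bare exclusion; tests assert the exact
  bookkeeping.
* "q₁ = 0" is realised by zeroing QM-atom charges in the structure handed
  to the MM engine, not by deleting atoms, so bonded MM terms spanning the
  junction are kept once, in the full-system MM term.
* Junction discovery, when no bond list is declared, uses a covalent-radius
  sum × 1.2 distance cutoff.
* Internal unit is hartree; reporting is kJ/mol via 1 a.u. = 2625.4996
  kJ/mol (so the 1e-6 a.u. optimiser threshold is ≈ 2.6 J/mol).
* Engine calls are memoised on (structure, charge model, state, level)
  when a cache environment is supplied.

The load-bearing identity — and the sharpest test the assembly admits —
is exact cancellation: with the *same* engine on both sides and no
environment charges, the total must equal the full-system MM energy to
1e-12 a.u. on arbitrary structures and partitions. The engine contract
also obliges engines to exclude the charge-charge self-energy of the
point-charge array; the toy engines comply by construction and the
embedding term is linear in the charges, which is tested.

The level extrapolation
`E_tot = E_qmmm_svp + E_tpss_tzvp + E_b3lyp_svp − 2·E_tpss_svp`
is implemented as pure arithmetic over labelled energies — the labels
(TPSS, B3LYP, def2-SV(P), def2-TZVP) are opaque text on the engine
contract; no functional or basis set is ever evaluated here. Its affine
coefficients (+1, +1, +1, −2) are verified by finite differencing, and the
two consistency limits (all levels equal; hybrid = GGA at the small basis)
collapse to the expected forms.

## Constrained scans

`constrained_scan()` walks a distance constraint across a grid, relaxing
all other movable degrees of freedom at each point. The single distance
constraint is eliminated analytically: the second atom of the pair is
re-expressed as `r_a + d·u(θ, φ)`, so the optimiser works in an
unconstrained space and the gradient seen by the optimiser is the engine
gradient projected onto the constraint manifold via the chain rule. The
optimiser is a compact BFGS with backtracking line search and the
two-criterion stop rule: the energy change between iterations must fall
below 1e-6 a.u. *and* the maximum gradient component below 1e-3 a.u.,
simultaneously. Non-convergence is reported per grid point with the last
gradient norm, and each point restarts from the previous relaxed geometry.

Validation uses an engine whose relaxed profile is known in closed form:
`double_well_engine()` is quartic in the scanned distance — wells at
`center ± width` with E = 0, saddle at `center` with E = A·width⁴ — and
harmonic in all spectator terms. On a 0.02 Å grid the scan maximum
reproduces the analytic saddle within 2% (the residual error is the grid
offset from the exact saddle position; refining the grid only increases
the maximum toward the bound). Frozen (system-2) atoms are bitwise
untouched, which is asserted exactly.

## Reaction-profile statistics

`assemble_profile()` anchors labelled stationary points (RS/TS/IM/PS) to a
zero reference and is gauge-invariant under constant shifts. `barrier()`
is the highest energy on the inclusive segment minus the starting energy
(hence never negative; a downhill step has barrier 0, the convention that
makes "cleavage was barrierless" a computable statement).
`exothermicity()` is E(from) − E(to), antisymmetric under exchange.
`compare_mechanisms()` measures both barriers from a shared precursor
label and reports signed differences (positive = mechanism A higher
barrier / less stable product).

The packaged profiles transcribe only numbers printed in the source text
of the study they accompany — barrier heights, exothermicities and product
stabilities; nothing was read off a figure. Transition states are stored
as explicit points at `E(precursor) + printed barrier`, and every row's
`note` says which printed quantity it encodes. For the competing
sulfur-attack step, both barriers are measured from the rotated-conformer
intermediate IM2_2′, which reproduces the printed 34 vs 42 kJ/mol
comparison; a concluding summary elsewhere quotes 30 kJ/mol for the same
step with an unstated reference, and that number is kept as a note rather
than forced into the profile.

## What the synthetic data emulate — and what they do not

`make_cubane()` realises the cubane as alternating corners of a cube
(two interpenetrating regular tetrahedra), scaled so all twelve Fe–S
contacts equal 2.30 Å, with truncated first-sphere stubs (thiolate,
serinate, water, or none for the three-coordinate post-dissociation site).
Real clusters are distorted — crystallographic Fe–S bonds span roughly
2.24–2.43 Å — and the optional Gaussian jitter (`jitter_sd`) emulates that
spread reproducibly. `make_lipa_fixture()` arranges two such cubanes 12 Å
apart (the main cluster with three thiolates and a water on Fe1, the
auxiliary with three thiolates and a serinate on Fe5), with ~100
environment atoms as neutral water-like charge groups and a junction at
every stub CA.

These fixtures validate *bookkeeping and algebra* — partition coverage,
cap collinearity, charge totals, cancellation identities, state
generation closure, parameter recovery, scan convergence. They do not
emulate a solvated ~15,000-atom protein, real charge distributions,
anisotropic cluster distortion, or any electronic structure; passing
tests therefore says nothing about DFT-level energetics, which are out of
scope by design. Equally, the coupling fit is a synthetic validation
device: no exchange constants are claimed for the packaged survey table,
and none are pretended.

## Numerical choices and problem sizes

Tolerances: scan stop rule 1e-6 a.u. energy / 1e-3 a.u. gradient;
cancellation asserted at 1e-12 a.u.; collinearity at 1e-9 Å; noiseless
coupling recovery at 1e-10 kJ/mol. Ties for a family minimum are broken
lexicographically on the arrow label and flagged explicitly. Coincident
atoms are treated as corrupt geometry and rejected rather than returned as
zero distances. The randomised suites use fixed seeds and modest sizes
chosen to probe the identities thoroughly: 100 random fixtures for the
cancellation property, 50 seeds for the noisy-recovery comparison, a
51-point grid for the scan; the whole suite completes in well under a
minute on one core.
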