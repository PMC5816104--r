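# fescubane

Broken-symmetry spin states and subtractive QM/MM energetics for
iron–sulfur cubane clusters, at desk scale.

## What this is for

[4Fe4S] clusters — cubanes of four Fe and four inorganic sulfide ions —
sit at the heart of radical SAM enzymes such as lipoyl synthase, where the
"main" cluster cleaves S-adenosylmethionine into the 5′-deoxyadenosyl
radical and the "auxiliary" cluster donates the inserted sulfur atoms.
Their low-spin physics is modelled with *broken-symmetry* (BS)
determinants: each high-spin Fe site carries a surplus of spin up or down
(`σᵢ = ±1`), and the antiferromagnetic singlet of a [4Fe4S]²⁺ cluster is
approximated by the six 2-up/2-down assignments per cluster (36 combined
assignments for two clusters; 4 × (4+5) = 36 unpaired spins in total).

The package implements, for users who analyse such studies or build
method prototypes:

* **BS state machinery** — enumeration, the fragment route and the
  site-swap route to determinants (`enumerate_bs_states()`,
  `bs_from_fragments()`, `bs_site_swap()`), arrow-label parsing, and
  survey-table statistics (`analyze_family()`: spread, ground state, gap
  to second, near-degenerate count).
* **Subtractive electrostatic-embedding QM/MM** —
  `run_qmmm()` assembles
  `E = E(QM1+ptch2, HL) + E(MM12, q₁=0, CL) − E(MM1, q₁=0, HL)`
  with hydrogen link atoms on severed bonds (`place_link_atom()`,
  `truncate_qm_region()`) and a point-charge environment model that
  excludes the replaced CL atoms (`point_charge_model()`), behind a
  pluggable engine contract; plus the multi-level extrapolation
  `E_tot = E_qmmm_svp + E_tpss_tzvp + E_b3lyp_svp − 2·E_tpss_svp`.
* **An Ising exchange Hamiltonian as the DFT stand-in** —
  `E(σ) = offset + Σ_{i<j} J_ij mᵢ mⱼ σᵢ σⱼ` (`ising_energy()`), synthetic
  survey tables with known couplings (`generate_bs_table()`), and coupling
  recovery by least squares with honest rank diagnostics
  (`fit_couplings()`, with `tidy()`/`glance()` methods).
* **Constrained scans and reaction profiles** — a relaxed scan driver with
  an exactly enforced distance constraint (`constrained_scan()`), and
  profile statistics (`assemble_profile()`, `barrier()`,
  `exothermicity()`, `compare_mechanisms()`) over labelled stationary
  points (RS/TS/IM/PS).
* **Fixtures** — ideal cubane geometries with ligand stubs
  (`make_cubane()`), a two-cluster active-site bundle
  (`make_lipa_fixture()`), and packaged transcriptions of a published
  two-cluster spin-state survey and its S-insertion reaction profiles
  (`packaged_bs_table()`, `packaged_profiles()`).

No electronic structure is ever computed: method/basis names are opaque
labels on the engine contract, and the toy engines (harmonic bonds +
Coulomb + the Ising term; an analytic double well for scan validation)
make every identity testable with exactly known answers.

## Worked example

```r
library(fescubane)

# which BS determinant is the ground state of the packaged survey?
tbl <- packaged_bs_table()
analyze_family(tbl, "all", "reactive")
#> # A tibble: 1 × 10
#>   family column       n spread_kjmol min_state   min_energy_kjmol
#> 1 all    reactive    10         46.5 [↑↑↓↓ ↓↑↑↓]             -9.1
#>   gap_to_second_kjmol n_within tol_kjmol tied_minimum
#> 1                   7        1         2 FALSE
```

The reactive-state ground determinant is `[↑↑↓↓ ↓↑↑↓]` at −9.1 kJ/mol,
7 kJ/mol below every other converged state — the survey's "reactive spin
state".

```r
pr <- packaged_profiles()
barrier(pr$s1, "IM_1", "PS_1")
#> [1] 37        # H6 abstraction is rate limiting in the first insertion

compare_mechanisms(pr$s2_mech1, pr$s2_mech2, from = "IM2_2p",
                   ts_a = "TS3_2", ts_b = "TS3_2p",
                   product_a = "PS2_2", product_b = "PS2_2p")
#>   barrier_a_kjmol barrier_b_kjmol product_a_kjmol product_b_kjmol
#> 1              42              34             -69             -95
#>   delta_barrier_kjmol delta_product_kjmol
#> 1                   8                  26
```

Sulfur attack by S3 (mechanism 2) beats attack by S1 by 8 kJ/mol in
barrier and 26 kJ/mol in product stability.

```r
# synthetic validation: recover known couplings from a generated table
params <- heisenberg_params("two_J", J_intra = -12, J_inter = 8, offset = 3)
states <- dplyr::bind_rows(enumerate_bs_states(4, 2),
                           enumerate_bs_states(4, 4))
fit <- fit_couplings(generate_bs_table(states, params), model = "two_J")
fit
#> Ising coupling fit (two_J): rank 3/3 on 7 states; residual norm 2.471e-13 kJ/mol
#> # A tibble: 3 × 2
#>   term    estimate
#> 1 J_intra   -12.0
#> 2 J_inter     8
#> 3 offset      3.00
```

Note the all-up state in the fit set: on the six singlet states alone the
design is rank 2 and individual couplings are not identifiable (the fit
then says so and returns the minimum-norm solution).

Each result type has an `autoplot()` method (survey tables, profiles,
scans) and `plot_mechanism_comparison()` overlays two profiles.

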