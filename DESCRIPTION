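Package: fescubane
Title: Broken-Symmetry Spin States and Subtractive QM/MM Energetics for
    Iron-Sulfur Cubane Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the magnetic and energetic structure of
    [4Fe4S] cubane clusters in metalloenzymes at desk scale.  Enumerates
    broken-symmetry (BS) collinear spin determinants by direct combinatorics,
    by the fragment method and by site swapping; summarises BS energy tables
    (spread, ground state, gap to the second state) the way spin-state
    surveys of radical SAM enzymes report them; assembles subtractive
    electrostatically embedded QM/MM energies with hydrogen link atoms and a
    point-charge environment model behind a pluggable engine contract; and
    extrapolates energies across method/basis levels.  An Ising-approximation
    exchange Hamiltonian with least-squares coupling recovery and analytic
    toy force-field engines stand in for the quantum-chemistry package, so
    constrained reaction-coordinate scans and reaction-profile statistics
    (barriers, exothermicities, mechanism comparison) are testable end to end
    without any electronic-structure code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
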