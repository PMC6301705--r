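Package: kynox
Title: Thermochemistry of Aminophenol and Hydroxykynurenine Oxidative
    Dimerization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for quantum-thermochemistry summaries of
    the oxidative dimerization of 2-aminophenol and the hydroxykynurenines
    (L-3-hydroxykynurenine, 3-hydroxyanthranilic acid). Composes Gibbs free
    energies from total energies and thermal corrections, encodes the 26-stage
    enzymatic and non-enzymatic dimerization network with pathway sums and
    Hess path-independence checks, computes homolytic bond-dissociation
    free-energy summaries, adiabatic ionization potentials, electron
    affinities and Mulliken electronegativities, classifies thermodynamically
    feasible couplings of the oxidation steps with molecular-oxygen reduction
    to reactive oxygen species, and evaluates transition-state-theory rate
    constants with Wigner tunneling for H-atom abstraction by O2. Ships
    curated reference energy tables for the full network in gas phase,
    heptane and water, a constructive synthetic-data generator with exact
    Hess consistency, and supporting statistics (permutation tests,
    regression across theory levels, assay batch normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
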