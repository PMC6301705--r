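# Shared fixtures: reference tables and registries are loaded once per run.
ref <- load_reference_data()
rxn <- reaction_registry()

# tiny hand-built species table: one fake abstraction A -> B + H*
tiny_registry <- function(G_A = -10, G_B = -5, G_H = -3, phase = "gas") {
  species_table(data.frame(
    species_id = c("A", "B", "H"),
    compound = c("2AP", "2AP", "shared"),
    form = c("D7", "D8", "Hstar"),
    phase = phase,
    E_T = c(G_A, G_B, G_H),
    G_CORR = 0,
    stringsAsFactors = FALSE))
}

expect_rel_equal <- function(actual, expected, rel) {
  expect_lt(abs(actual / expected - 1), rel)
}
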