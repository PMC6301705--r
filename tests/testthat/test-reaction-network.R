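test_that("stage free energy is the product/reactant G difference", {
  reg <- tiny_registry(G_A = -10, G_B = -5, G_H = -3)
  # N11 in the registry is D7 -> D8 + H*
  se <- stage_free_energy("N11", "2AP", "gas", "species", registry = reg,
                          reactions = rxn)
  expect_equal(se$dG, (-5) + (-3) - (-10))
  expect_equal(se$rclass, "H_ABSTRACTION")
  expect_named(se$components)
})

test_that("missing species are reported by name", {
  reg <- tiny_registry()
  expect_error(stage_free_energy("N12", "2AP", "gas", "species",
                                 registry = reg, reactions = rxn), "'D9'")
})

test_that("a registry pinned to a printed value reproduces it", {
  pin <- data.frame(stage = "N1", compound = "2AP", phase = "gas",
                    dG = 58.230)
  reg <- generate_registry(synth_config(seed = 5), pins = pin)
  se <- stage_free_energy("N1", "2AP", "gas", "species", registry = reg,
                          reactions = rxn)
  expect_equal(se$dG, 58.230, tolerance = 1e-9)
})

test_that("enzymatic pathway sums reproduce the printed totals", {
  for (row in seq_len(nrow(ref$pathway_sums))) {
    cp <- ref$pathway_sums$compound[row]
    phz <- ref$pathway_sums$phase[row]
    p <- pathway_sum(enzymatic_route(phz), cp, phz, ref = ref)
    expect_equal(p$total, ref$pathway_sums$total[row], tolerance = 5e-4)
    expect_identical(p$pair_summaries_used, phz == "heptane")
  }
})

test_that("heptane protonation requires the pair summaries", {
  expect_error(pathway_sum(paste0("N", 1:14), "2AP", "heptane", ref = ref),
               "pair summary")
  p <- pathway_sum(enzymatic_route("heptane"), "2AP", "heptane", ref = ref)
  expect_equal(p$total, 313.132, tolerance = 5e-4)
})

test_that("pair summaries match individual protonation sums in gas/water", {
  for (phz in c("gas", "water")) for (cp in compounds()) {
    p78 <- fixture_stage_dG(ref, "N7+8", cp, phz)
    s78 <- fixture_stage_dG(ref, "N7", cp, phz) +
      fixture_stage_dG(ref, "N8", cp, phz)
    expect_lt(abs(p78 - s78), 0.0075)  # printed rounding; gas 2AP is 0.007
    p14 <- fixture_stage_dG(ref, "N13+14", cp, phz)
    s14 <- fixture_stage_dG(ref, "N13", cp, phz) +
      fixture_stage_dG(ref, "N14", cp, phz)
    expect_lt(abs(p14 - s14), 0.0075)
  }
})

test_that("hess_check rejects routes with different net stoichiometry", {
  expect_error(hess_check("N16", "N18", "2AP", "gas", ref = ref),
               "net stoichiometry")
  expect_error(hess_check("N17", c("N20", "N21", "N21"), "2AP", "gas",
                          ref = ref), "net stoichiometry")
})

test_that("printed route identities hold for 2AP and fail only where the
           source tables are conformer-inconsistent (L-3HOK)", {
  h <- hess_check(enzymatic_route("gas"), nonenzymatic_route("gas"),
                  "2AP", "gas", ref = ref)
  expect_true(h$pass)
  expect_lt(h$delta, 5e-4)
  h16 <- hess_check("N16", c("N18", "N19"), "2AP", "gas", ref = ref)
  expect_true(h16$pass)
  # L-3HOK: the printed gas values disagree between routes by ~1.71
  hL <- hess_check("N16", c("N18", "N19"), "L3HOK", "gas", ref = ref)
  expect_false(hL$pass)
  expect_equal(hL$delta, 1.706, tolerance = 1e-3)
  hLh <- hess_check("N16", c("N18", "N19"), "L3HOK", "heptane", ref = ref)
  expect_equal(hLh$delta, 3.050, tolerance = 1e-3)
  # but L-3HOK water is internally consistent
  hLw <- hess_check("N16", c("N18", "N19"), "L3HOK", "water", ref = ref)
  expect_true(hLw$pass)
})

test_that("six H atoms are released along any complete route, eight with
           the xanthommatin stage", {
  enz <- enzymatic_route("gas")
  expect_equal(h_atoms_released(enz$stage, enz$mult, rxn), 6)
  non <- nonenzymatic_route("gas")
  expect_equal(h_atoms_released(non$stage, non$mult, rxn), 6)
  hept <- enzymatic_route("heptane")
  expect_equal(h_atoms_released(hept$stage, hept$mult, rxn), 6)
  expect_equal(h_atoms_released(c(enz$stage, "N26_NH4"),
                                c(enz$mult, 1), rxn), 8)
  expect_equal(h_atoms_released("N26_NH3", 1, rxn), 2)
})

test_that("H-abstraction stages produce exactly one H atom", {
  for (s in bdg_stages()) expect_equal(h_atoms_released(s, 1, rxn), 1)
  expect_equal(h_atoms_released("N24", 1, rxn), 0)  # H migration, no release
})

test_that("charge is conserved across every stage except the printed
           ammonium variant of N26", {
  chg <- c(M = 0, Mstar = 0, Mq = 0, D1 = 0, D2 = 0, D3 = 0, D4 = 0,
           D4H = 1, D5 = 0, D6 = 0, D7 = 0, D8 = 0, D9 = 0, D9H = 1,
           D10 = 0, D1p = 0, D2p = 0, D3p = 0, D4p = 0, D5p = 0, D6p = 0,
           XAN = 0, Hstar = 0, Hplus = 1, NH3 = 0, NH4p = 1)
  for (s in unique(rxn$stage)) {
    r <- rxn[rxn$stage == s, ]
    net <- sum(ifelse(r$role == "product", 1, -1) * r$count * chg[r$species])
    if (s == "N26_NH4") expect_equal(net, 1) else expect_equal(net, 0)
  }
})

test_that("BDG summaries reproduce the published gas and water statistics", {
  g <- bdg_summary("gas", ref = ref)
  expect_equal(g$n, 44)
  expect_equal(g$mean, 50.056, tolerance = 1e-4)
  expect_equal(g$ci95, 5.136, tolerance = 0.01)
  w <- bdg_summary("water", ref = ref)
  expect_equal(w$mean, 52.335, tolerance = 1e-4)
  expect_equal(w$ci95, 5.229, tolerance = 0.01)
})

test_that("bdg_summary lists the missing cells of an incomplete registry", {
  reg <- tiny_registry()
  expect_error(bdg_summary("gas", "species", registry = reg),
               "incomplete.*N1/2AP")
})

test_that("BSSE application follows the stated sign convention, once", {
  se <- stage_free_energy("N3", "2AP", "gas", ref = ref)  # dimerization 5.799
  cor <- apply_bsse(se, -5.373)
  expect_equal(cor$dG, 5.799 + 5.373)  # less favorable binding
  expect_equal(attr(cor, "bsse")$original, 5.799)
  expect_error(apply_bsse(cor, -5.373), "already applied")

  ha <- stage_free_energy("N1", "2AP", "gas", ref = ref)
  ha_cor <- apply_bsse(ha, -1.543)
  expect_equal(ha_cor$dG, 58.230 - 1.543)  # BDG less positive
  unchanged <- apply_bsse(stage_free_energy("N3", "2AP", "gas", ref = ref), 0)
  expect_equal(unchanged$dG, 5.799)
})
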