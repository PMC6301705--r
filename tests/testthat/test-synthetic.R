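test_that("generation is deterministic in the seed", {
  a <- generate_registry(synth_config(seed = 17))
  b <- generate_registry(synth_config(seed = 17))
  expect_identical(a, b)
  c_ <- generate_registry(synth_config(seed = 18))
  expect_false(identical(a, c_))
  expect_error(synth_config(), "seed is mandatory")
})

test_that("every Hess identity holds to machine precision on generated
           registries", {
  for (seed in c(2, 23)) {
    reg <- generate_registry(synth_config(seed = seed))
    for (cp in compounds()) for (phz in phases()) {
      pairs <- list(
        list(enzymatic_route(phz), nonenzymatic_route(phz)),
        list("N16", c("N18", "N19")),
        list("N17", c("N20", "N21")),
        list("N17", c("N22", "N23", "N24")),
        list("N17", c("N20", "N25", "N12", "N13+14")))
      for (pr in pairs) {
        h <- hess_check(pr[[1]], pr[[2]], cp, phz, "species",
                        registry = reg, reactions = rxn, tolerance = 1e-9)
        expect_true(h$pass)
      }
    }
  }
})

test_that("sampled stage energies respect their class ranges", {
  cfg <- synth_config(seed = 41)
  reg <- generate_registry(cfg)
  for (cp in compounds()) for (phz in phases()) {
    for (s in bdg_stages()[bdg_stages() %in%
                           c("N1", "N2", "N5", "N6", "N11", "N12",
                             "N16", "N22")]) {
      dg <- stage_free_energy(s, cp, phz, "species", registry = reg,
                              reactions = rxn)$dG
      expect_gte(dg, cfg$ranges$h_abstraction[1])
      expect_lte(dg, cfg$ranges$h_abstraction[2])
    }
    p78 <- stage_free_energy("N7+8", cp, phz, "species", registry = reg,
                             reactions = rxn)$dG
    expect_gte(p78, cfg$ranges$pair[1])
    expect_lte(p78, cfg$ranges$pair[2])
  }
})

test_that("pinning fixes sampled stages and refuses determined ones", {
  pins <- data.frame(stage = c("N1", "N16"),
                     compound = "3HAA", phase = "water",
                     dG = c(58.320, 38.734))
  reg <- generate_registry(synth_config(seed = 6), pins = pins)
  for (i in seq_len(nrow(pins))) {
    got <- stage_free_energy(pins$stage[i], "3HAA", "water", "species",
                             registry = reg, reactions = rxn)$dG
    expect_equal(got, pins$dG[i], tolerance = 1e-9)
  }
  expect_error(
    generate_registry(synth_config(seed = 6),
                      pins = data.frame(stage = "N17", compound = "2AP",
                                        phase = "gas", dG = 1)),
    "Hess-determined")
})

test_that("the heptane registry has no proton and relies on pair stages", {
  reg <- generate_registry(synth_config(seed = 8))
  expect_false(any(reg$form == "Hplus" & reg$phase == "heptane"))
  expect_error(stage_free_energy("N7", "2AP", "heptane", "species",
                                 registry = reg, reactions = rxn),
               "unavailable in heptane")
  ok <- stage_free_energy("N7+8", "2AP", "heptane", "species",
                          registry = reg, reactions = rxn)
  expect_true(is.finite(ok$dG))
})

test_that("synthetic TS records carry their own rates as ground truth", {
  cfg <- synth_config(seed = 12)
  ts <- generate_ts_records(cfg)
  expect_equal(nrow(ts), cfg$ts$n)
  expect_true(all(ts$dG_TS_R >= cfg$ts$barrier[1] &
                    ts$dG_TS_R <= cfg$ts$barrier[2]))
  rt <- rate_table(ts)
  expect_equal(rt$k_forward, ts$k_forward_truth, tolerance = 1e-12)
  expect_equal(rt$k_reverse, ts$k_reverse_truth, tolerance = 1e-12)
  cst <- thermo_constants()
  expect_equal(rt$k_forward / rt$k_reverse,
               exp(-rt$dG_P_R * 1000 / (cst$R_cal * cst$T)),
               tolerance = 1e-12)
})

test_that("two-level energies follow the configured linear relation", {
  exact <- generate_two_level(synth_config(seed = 13,
                                           two_level = list(sigma = 0)))
  f <- linear_regression(exact$level_II, exact$level_III)
  expect_equal(f$slope, 0.977, tolerance = 1e-9)
  expect_equal(f$intercept, -0.916, tolerance = 1e-9)
  expect_equal(f$r2, 1)
  tiny <- generate_two_level(synth_config(seed = 13,
                                          two_level = list(sigma = 1e-4)))
  expect_gt(linear_regression(tiny$level_II, tiny$level_III)$r2, 0.999999)
})
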