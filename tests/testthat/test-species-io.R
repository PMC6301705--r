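test_that("species tables read from delimited text and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,compound,form,phase,E_T,G_CORR",
               "a,2AP,M,gas,-100.5,0.25",
               "b,2AP,Mstar,gas,-90.25,0.5"), path)
  tab <- read_species_table(path)
  expect_s3_class(tab, "species_table")
  expect_equal(nrow(tab), 2)
  expect_equal(free_energy(tab), c(-100.25, -89.75))
})

test_that("duplicate keys, unknown phases and bad numbers are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,compound,form,phase,E_T,G_CORR",
               "a,2AP,M,gas,-1,0", "a,2AP,M,gas,-2,0"), path)
  expect_error(read_species_table(path), "duplicate")
  writeLines(c("species_id,compound,form,phase,E_T,G_CORR",
               "a,2AP,M,plasma,-1,0"), path)
  expect_error(read_species_table(path), "unknown phase")
  writeLines(c("species_id,compound,form,phase,E_T,G_CORR",
               "a,2AP,M,gas,oops,0"), path)
  expect_error(read_species_table(path), "non-numeric")
})

test_that("decimal commas are normalized with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,compound,form,phase,E_T,G_CORR",
               "a,2AP,M,water,\"-431,358\",0"), path)
  expect_warning(tab <- read_species_table(path), "decimal comma")
  expect_equal(tab$E_T, -431.358)
})

test_that("writer/reader round trip is lossless", {
  reg <- generate_registry(synth_config(seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(as.data.frame(reg), path)
  back <- read_species_table(path)
  expect_equal(nrow(back), nrow(reg))
  expect_true(all(abs(back$E_T - reg$E_T) < 1e-9 * pmax(1, abs(reg$E_T))))
  expect_true(all(abs(back$G_CORR - reg$G_CORR) < 1e-9))

  jp <- withr::local_tempfile(fileext = ".json")
  df <- data.frame(stage = c("N1", "N2"), dG = c(58.230, 64.400))
  write_report(df, jp, format = "json")
  expect_equal(read_report(jp, format = "json"), df)
})

test_that("pathway results serialize as a stage table with a SUM row", {
  p <- pathway_sum(enzymatic_route("gas"), "2AP", "gas", ref = ref)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(p, path)
  out <- read_report(path)
  expect_equal(nrow(out), 15)  # 14 stages + SUM
  expect_equal(out$dG[out$stage == "SUM"], p$total)
  # empty route -> header-only stage list with a zero SUM
  p0 <- pathway_sum(character(), "2AP", "gas", ref = ref)
  expect_equal(p0$total, 0)
})

test_that("reference tables load, log their normalizations, and spot-check", {
  expect_s3_class(ref, "kynox_ref")
  nrm <- attr(ref, "normalizations")
  expect_true(any(grepl("decimal comma", nrm)))
  expect_true(any(grepl("1.5 O2", nrm)))
  # transcribed printed values are the test vectors
  expect_equal(fixture_stage_dG(ref, "N1", "2AP", "gas"), 58.230)
  expect_equal(fixture_stage_dG(ref, "N7+8", "2AP", "heptane"), -8.341)
  expect_equal(ref$ip$IP[ref$ip$form == "D7" & ref$ip$compound == "3HAAi" &
                           ref$ip$phase == "water"], 94.892)
  expect_equal(unique(ref$ts$nu_i[ref$ts$form == "D1p" &
                                    ref$ts$compound == "2AP"]), 1702.2)
  expect_equal(o2_reduction("water", ref)[["full"]], -431.358)
  # shape: all three phases present wherever the tables print them
  expect_setequal(unique(ref$stage_dG$phase), phases())
  expect_equal(sum(ref$stage_dG$stage == "N16"), 12)
})

test_that("individual heptane protonation stages point to the pair summary", {
  expect_error(fixture_stage_dG(ref, "N7", "2AP", "heptane"), "N7\\+8")
  expect_error(fixture_stage_dG(ref, "N14", "2AP", "heptane"), "N13\\+14")
})
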