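test_that("species tables round-trip through write/load at input precision", {
  sp <- toy_species()
  f <- withr::local_tempfile(fileext = ".csv")
  write_species_table(sp, f)
  back <- load_species_table(f)
  for (col in c("E_total", "G_free", "dipole", "E_H", "E_L")) {
    expect_equal(back[[col]], sp[[col]], tolerance = 1e-12)
  }
  expect_identical(back$label, sp$label)
  expect_identical(back$charges, sp$charges)
})

test_that("energies declared in hartree are converted to eV", {
  sp <- toy_species()[3, ]
  sp$E_total <- -10
  f <- withr::local_tempfile(fileext = ".csv")
  write_species_table(sp, f)
  back <- load_species_table(f, unit = "hartree")
  expect_equal(back$E_total, -272.114, tolerance = 1e-9)
  # sidecar JSON config declares the unit when not given explicitly
  jsonlite::write_json(list(unit = "hartree"), paste0(f, ".json"),
                       auto_unbox = TRUE)
  expect_equal(load_species_table(f)$E_total, -272.114, tolerance = 1e-9)
})

test_that("an empty species file with a valid header loads as an empty table", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_species_table(toy_species()[0, ], f)
  expect_identical(nrow(load_species_table(f)), 0L)
})

test_that("schema and validation errors name the offending column or row", {
  sp <- toy_species()
  f <- withr::local_tempfile(fileext = ".csv")
  write_species_table(sp[, setdiff(names(sp), "E_H")], f)
  expect_error(load_species_table(f), "E_H", class = "cagesense_schema_error")

  bad <- sp
  bad$E_L[1] <- bad$E_H[1] - 1
  write_species_table(bad, f)
  expect_error(load_species_table(f), "hostA",
               class = "cagesense_validation_error")

  dup <- rbind(sp, sp[1, ])
  write_species_table(dup, f)
  expect_error(load_species_table(f), "duplicated",
               class = "cagesense_validation_error")

  singlet_two <- sp
  singlet_two$multiplicity[c(1, 2)] <- 1L
  write_species_table(singlet_two, f)
  expect_error(load_species_table(f), "exactly one channel",
               class = "cagesense_validation_error")
})

test_that("formulas and charge strings parse; malformed input is rejected", {
  expect_identical(parse_formula("C5H14N2")[[1]],
                   c(C = 5L, H = 14L, N = 2L))
  # repeated elements accumulate (complex formulas concatenate host+guest)
  expect_identical(parse_formula("B12N11CuC5H14N2")[[1]][["N"]], 13L)
  expect_identical(count_atoms(c("H2O", "B12N12")), c(3L, 24L))
  expect_error(parse_formula("12B"), class = "cagesense_validation_error")

  q <- parse_charges("Cu=0.257;guest=0.2")[[1]]
  expect_equal(q[["Cu"]], 0.257)
  expect_equal(q[["guest"]], 0.2)
  expect_length(parse_charges(NA_character_)[[1]], 0)
  expect_error(parse_charges("Cu0.25"), class = "cagesense_validation_error")
})

test_that("pairs and transitions loaders validate their inputs", {
  sp <- toy_species()
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(toy_pairs(), f)
  pr <- load_pairs_table(f, species = sp)
  expect_equal(pr$E_BSSE, 0.1)
  readr::write_csv(tibble::tibble(host = "nope", guest = "guestX",
                                  complex = "cplxAX"), f)
  expect_error(load_pairs_table(f, species = sp), "nope",
               class = "cagesense_lookup_error")

  readr::write_csv(tibble::tibble(label = "x", wavelength_nm = -5, f = 0.1), f)
  expect_error(load_transitions_table(f), class = "cagesense_validation_error")
  readr::write_csv(tibble::tibble(label = "x", wavelength_nm = 250, f = -0.1), f)
  expect_error(load_transitions_table(f), class = "cagesense_validation_error")
})

test_that("packaged reference dataset has the documented structure", {
  expect_identical(sum(fx$species$role == "host"), 12L)
  expect_identical(sum(fx$species$role == "guest"), 9L)
  expect_identical(nrow(fx$pairs), 20L)
  # every pair label resolves with matching roles
  expect_silent(validate_pairs(fx$pairs, fx$species))
  # known-inconsistent rows are flagged, not dropped
  expect_identical(
    fx$selectivity$flag[fx$selectivity$guest == "COCl2"],
    "baseline_unprinted"
  )
  expect_identical(
    fx$descriptors$flag[fx$descriptors$label == "CuAl11N12"],
    "omega_inconsistent"
  )
  expect_identical(
    fx$adsorption$flag[fx$adsorption$complex == "CuAl11N12-Cad"],
    "dphi_inconsistent"
  )
})

test_that("packaged records reproduce key published values", {
  ads <- adsorption_energy(fx$pairs, fx$species)
  expect_equal(ads$E_ads[ads$complex == "Cu(b64)B12N12-Cad"], -1.39,
               tolerance = 1e-9)
  co <- fx$selectivity[fx$selectivity$guest == "CO", ]
  expect_identical(co$dphi_pct, 0)
  expect_identical(co$S_j, 0)
  expect_true(is.na(co$kappa_j))
})

test_that("the parsed-log adapter emits valid per-channel records", {
  sp <- species_from_qc("cage", "host", "B12N12",
                        mo_energies = list(c(-9.1, -7.63, -0.76, 0.4)),
                        homo_index = 1, scf_energy = -26037.6)
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$channel, "restricted")
  expect_equal(sp$E_H, -7.63)
  expect_equal(sp$E_L, -0.76)

  os <- species_from_qc("radical", "host", "B12N12Cu",
                        mo_energies = list(c(-0.3, -0.2, -0.05),
                                           c(-0.31, -0.19, -0.04)),
                        homo_index = c(1, 0), scf_energy = -2500,
                        unit = "hartree")
  expect_identical(os$channel, c("alpha", "beta"))
  expect_equal(os$E_H[1], -0.2 * 27.2114, tolerance = 1e-12)
  expect_equal(os$E_total[1], -2500 * 27.2114, tolerance = 1e-9)
  expect_identical(os$multiplicity, c(2L, 2L))

  expect_error(
    species_from_qc("bad", "host", "B12N12",
                    mo_energies = list(c(-1, -0.5)), homo_index = 1,
                    scf_energy = -10),
    class = "cagesense_validation_error"
  )
})
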