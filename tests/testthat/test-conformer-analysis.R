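t1 <- tautomer_table()
t2 <- conformer_table_fixture()

test_that("packaged fixtures load with the expected shapes and checksums", {
  expect_equal(nrow(t2), 78L)
  expect_setequal(t1$name, c("N1", "N3", "N7", "OHC", "OHT"))
  mp2 <- conformer_table_fixture("MP2/6-31G(d)")
  expect_equal(nrow(mp2), 9L)
  expect_equal(mp2$phi1[mp2$name == "B2"], 95.6)
  # checksum-pinned transcriptions
  expect_equal(unname(tools::md5sum(acv_fixture("table1_tautomers.tsv"))),
               "c7b3fe2452fa8a70b6e75a7211545a8f")
  expect_equal(unname(tools::md5sum(acv_fixture("table2_conformers.tsv"))),
               "d714ca11f3dc1ffcc0eb14788ad7830e")
  expect_equal(unname(tools::md5sum(acv_fixture("table4_solid.tsv"))),
               "83b393ae41f140fc4a12cfd9d1501e6f")
})

test_that("reader handles schema errors, row errors and level filtering", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("", path)
  expect_error(read_conformer_table(path), "schema error")
  writeLines(c("name,R,beta", "x,1,2"), path)
  expect_error(read_conformer_table(path), "schema error")
  writeLines(c("name\tR\tbeta\tPhi\tphi1\tphi2\tphi3\tphi4\tphi5\tmu\tdE\tdG",
               "x\t1\t2\t3\toops\t5\t6\t7\t8\t9\t10\t11"), path)
  expect_error(read_conformer_table(path), "line 2")
  # unicode minus is normalized
  writeLines(c("name,R,beta,Phi,phi1,phi2,phi3,phi4,phi5,mu,dE,dG",
               "x,1,2,3,−74.1,5,6,7,8,9,10,11"), path)
  expect_equal(read_conformer_table(path)$phi1, -74.1)
  expect_warning(read_conformer_table(acv_fixture("table2_conformers.tsv"),
                                      level = "MP2/6-31G(d)"), "skipping")
})

test_that("classification splits by the sign of phi1 and refuses zero", {
  expect_equal(classify_conformer(-74.1),
               data.frame(class = "A", orientation = "anti"))
  expect_equal(classify_conformer(73.5),
               data.frame(class = "B", orientation = "syn"))
  expect_error(classify_conformer(0), "unclassifiable")
  cc <- classify_conformer(t2)
  expect_equal(sum(cc$class == "A") + sum(cc$class == "B"), nrow(t2))
})

test_that("Boltzmann populations behave as a proper distribution", {
  # symmetry
  two <- data.frame(name = c("a", "b"), dE = c(1.7, 1.7))
  p <- boltzmann_populations(two)
  expect_equal(p$population, c(50, 50))
  # normalization and reference-shift invariance
  p1 <- boltzmann_populations(t2)
  expect_equal(sum(p1$population), 100, tolerance = 1e-9)
  shifted <- t2
  shifted$dE <- shifted$dE + 123.4
  p2 <- boltzmann_populations(shifted)
  expect_equal(p2$population, p1$population, tolerance = 1e-9)
  # temperature limits
  cold <- boltzmann_populations(t2, population_config(temperature = 1e-3))
  expect_equal(max(cold$population), 100, tolerance = 1e-6)
  expect_equal(cold$name[which.max(cold$population)], "A1")
  hot <- boltzmann_populations(t2, population_config(temperature = 1e9))
  expect_equal(hot$population, rep(100 / nrow(t2), nrow(t2)),
               tolerance = 1e-6)
  # configuration and record errors
  expect_error(population_config(temperature = -5), "temperature")
  expect_error(boltzmann_populations(data.frame(name = "x", dE = NA_real_)),
               "record error")
})

test_that("tautomer populations reproduce the reference values", {
  p298 <- boltzmann_populations(t1, population_config(298.15, "dE"))
  pop <- stats::setNames(p298$population, p298$name)
  expect_lt(abs(pop[["N1"]] - 48.1), 0.05)
  expect_lt(abs(pop[["OHC"]] - 37.65), 0.05)
  expect_lt(abs(pop[["OHT"]] - 14.3), 0.05)
  expect_lt(pop[["N3"]], 0.05)
  expect_lt(pop[["N7"]], 0.05)
  p273 <- boltzmann_populations(t1, population_config(273.15, "dE"))
  pop <- stats::setNames(p273$population, p273$name)
  expect_lt(abs(pop[["N1"]] - 49.2), 0.05)
  expect_lt(abs(pop[["OHT"]] - 13.1), 0.05)
})

test_that("torsion bins partition the table for any bin set", {
  bins <- default_torsion_bins()
  for (t in names(bins)) {
    b <- bin_torsions(t2, t, bins[[t]], round_to = 0)
    expect_equal(sum(b$total), nrow(t2))
    expect_equal(b$A + b$B, b$total)
  }
  # empty table gives all-zero counts
  empty <- t2[0, ]
  b <- bin_torsions(empty, "phi2", bins$phi2)
  expect_true(all(b$total == 0))
  # overlap is a configuration error
  expect_error(bin_torsions(t2, "phi2", list(c(0, 90), c(45, 120))),
               "overlapping")
  # wrapped bins work: the phi4 trans mode crosses +-180
  b4 <- bin_torsions(t2, "phi4", bins$phi4, round_to = 0)
  expect_equal(b4$total[1], 28)
})

test_that("energy bands count half-open and report anti/syn ratios", {
  expect_equal(energy_band_stats(t2, c(0, 1.0))$count, 4L)
  b3 <- energy_band_stats(t2, c(0, 3.0))
  expect_equal(b3$ratio_rounded, 0.8)
  b85 <- energy_band_stats(t2, c(3.0, 8.5), include_upper = TRUE)
  expect_equal(b85$ratio_rounded, 1.7)
  expect_equal(b3$count + b85$count, nrow(t2))
  # empty band: ratio undefined, not an exception
  eb <- energy_band_stats(t2, c(100, 200))
  expect_equal(eb$count, 0L)
  expect_true(is.na(eb$ratio_anti_syn))
})

test_that("solid-state fixture stores the printed Phi transcription artifact", {
  s <- solid_state_table()
  expect_equal(nrow(s), 9L)
  calc <- s[s$form %in% c("dimer", "tetramer"), ]
  expect_true(all(calc$Phi_equals_phi1))
  expect_equal(calc$Phi, calc$phi1)
  expect_true(all(is.na(s$R[s$form == "xray"])))
})
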