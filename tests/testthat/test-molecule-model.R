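test_that("XYZ round trip is the identity on positions and atom order", {
  tmpl <- build_template("N1")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tmpl, path)
  back <- read_xyz(path)
  expect_equal(nrow(back$atoms), nrow(tmpl$atoms))
  expect_equal(back$atoms$element, tmpl$atoms$element)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(tmpl$atoms[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # descriptor values survive the round trip (labels via map from template)
  map <- stats::setNames(tmpl$atoms$label, auto <- {
    el <- tmpl$atoms$element
    paste0(el, stats::ave(seq_along(el), el, FUN = seq_along))
  })
  relabeled <- read_xyz(path, label_map = map)
  d0 <- descriptor_set(tmpl, name = "x")
  d1 <- descriptor_set(relabeled, name = "x")
  expect_equal(d1, d0, tolerance = 1e-8)
})

test_that("multimer files split into molecules like the component oracle", {
  a <- build_template("N1")
  b <- transform_conformation(a, translate = c(30, 0, 0))
  # single frame holding both molecules: split must come from connectivity
  combined <- rbind(a$atoms, b$atoms)
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(nrow(combined), "two monomer blocks",
               sprintf("%s %.6f %.6f %.6f", combined$element,
                       combined$x, combined$y, combined$z)), path)
  conf <- read_xyz(path)
  oc <- oracle_components(as.matrix(combined[, c("x", "y", "z")]),
                          combined$element)
  expect_equal(length(unique(conf$atoms$molecule_id)), 2L)
  expect_equal(as.integer(factor(conf$atoms$molecule_id)), oc)
  expect_equal(as.vector(table(conf$atoms$molecule_id)),
               c(nrow(a$atoms), nrow(b$atoms)))
  # multi-frame convention takes precedence and round-trips
  path2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(assemble_molecules(a, b), path2)
  conf2 <- read_xyz(path2)
  expect_equal(sort(unique(conf2$atoms$molecule_id)), c(0L, 1L))
})

test_that("XYZ parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "truncated", "C 0 0 0", "C 1 0 0"), path)
  expect_error(read_xyz(path), "ends early")
  writeLines(c("2", "bad element", "C 0 0 0", "Xx 1 0 0"), path)
  expect_error(read_xyz(path), "unknown element")
  writeLines(c("1", "ok", "C 0 0 0"), path)
  expect_error(read_xyz(path, label_map = c(Zz1 = "C9")), "labeling error")
})

test_that("validate_topology reports missing atoms and torsion axes", {
  tmpl <- build_template("N1")
  expect_length(validate_topology(tmpl), 0L)

  no_o5 <- tmpl
  keep <- no_o5$atoms$label != "O5'"
  no_o5$atoms <- no_o5$atoms[keep, ]
  no_o5$bonds <- no_o5$bonds[no_o5$bonds$a1 != "O5'" &
                               no_o5$bonds$a2 != "O5'", ]
  viol <- validate_topology(no_o5)
  expect_true(any(grepl("missing atom O5'", viol)))

  cut <- tmpl
  cut$bonds <- cut$bonds[!(cut$bonds$a1 == "N9" & cut$bonds$a2 == "C1'"), ]
  viol <- validate_topology(cut)
  expect_true(any(grepl("missing bond N9-C1'.*phi1 axis undefined", viol)))
})

test_that("Z-matrix construction reproduces its internal coordinates", {
  zm <- data.frame(label = c("C1", "C2", "C3", "C4"),
                   ref1 = c(NA, "C1", "C2", "C3"),
                   ref2 = c(NA, NA, "C1", "C2"),
                   ref3 = c(NA, NA, NA, "C1"),
                   bond = c(NA, 1.54, 1.54, 1.54),
                   angle = c(NA, NA, 111, 111),
                   dihedral = c(NA, NA, NA, 0))
  expect_equal(measure_torsion(zmatrix_to_cartesian(zm),
                               c("C4", "C3", "C2", "C1")), 0)
  zm$dihedral[4] <- 60
  conf <- zmatrix_to_cartesian(zm)
  expect_equal(measure_torsion(conf, c("C4", "C3", "C2", "C1")), 60,
               tolerance = 1e-6)
  # oracle: explicit rotation of the cis-placed atom about the 2-3 axis
  zm$dihedral[4] <- 0
  cis <- zmatrix_to_cartesian(zm)
  p <- oracle_rotate(atom_xyz(cis, "C4"), atom_xyz(cis, "C3"),
                     atom_xyz(cis, "C3") - atom_xyz(cis, "C2"), 60)
  expect_equal(p, atom_xyz(conf, "C4"), tolerance = 1e-6)

  # property: random valid Z-matrices round-trip every internal coordinate
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:9, 1)
    lab <- paste0("C", seq_len(n))
    zm <- data.frame(label = lab,
                     ref1 = c(NA, lab[pmax(1, seq_len(n - 1))])[seq_len(n)],
                     ref2 = NA, ref3 = NA,
                     bond = c(NA, runif(n - 1, 1.2, 1.8)),
                     angle = NA, dihedral = NA)
    zm$ref1 <- c(NA, lab[seq_len(n - 1)])
    zm$ref2 <- c(NA, NA, lab[seq_len(max(0, n - 2))])
    zm$ref3 <- c(NA, NA, NA, lab[seq_len(max(0, n - 3))])
    zm$angle <- c(NA, NA, runif(n - 2, 60, 150))
    zm$dihedral <- c(NA, NA, NA, runif(n - 3, -179, 180))
    conf <- zmatrix_to_cartesian(zm)
    for (i in seq_len(n)) {
      if (i >= 2) {
        expect_equal(atom_distance(conf, zm$label[i], zm$ref1[i]),
                     zm$bond[i], tolerance = 1e-6)
      }
      if (i >= 3) {
        expect_equal(bond_angle(atom_xyz(conf, zm$label[i]),
                                atom_xyz(conf, zm$ref1[i]),
                                atom_xyz(conf, zm$ref2[i])),
                     zm$angle[i], tolerance = 1e-4)
      }
      if (i >= 4) {
        expect_equal(measure_torsion(conf, c(zm$label[i], zm$ref1[i],
                                             zm$ref2[i], zm$ref3[i])),
                     zm$dihedral[i], tolerance = 1e-4)
      }
    }
  }
})

test_that("Z-matrix refuses colinear reference frames", {
  zm <- data.frame(label = c("C1", "C2", "C3", "C4"),
                   ref1 = c(NA, "C1", "C2", "C3"),
                   ref2 = c(NA, NA, "C1", "C2"),
                   ref3 = c(NA, NA, NA, "C1"),
                   bond = c(NA, 1.5, 1.5, 1.5),
                   angle = c(NA, NA, 180, 109),
                   dihedral = c(NA, NA, NA, 10))
  expect_error(zmatrix_to_cartesian(zm), "degenerate")
})

test_that("rigid motion leaves topology reports and distances unchanged", {
  set.seed(7)
  tmpl <- build_template("N1")
  d0 <- as.matrix(stats::dist(tmpl$atoms[, c("x", "y", "z")]))
  for (rep in 1:5) {
    moved <- random_rigid_motion(tmpl)
    expect_identical(validate_topology(moved), validate_topology(tmpl))
    d1 <- as.matrix(stats::dist(moved$atoms[, c("x", "y", "z")]))
    expect_equal(d1, d0, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("PDB subset reader normalizes primes and reads coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "HETATM", 1L, "N9", "", "ACV", "A", 1L, 0, 0, 0, 1, 0, "N"),
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "HETATM", 2L, "O5*", "", "ACV", "A", 1L, 1.42, 0, 0, 1, 0, "O")),
    path)
  conf <- read_pdb(path)
  expect_setequal(conf$atoms$label, c("N9", "O5'"))
  expect_equal(atom_distance(conf, "N9", "O5'"), 1.42, tolerance = 1e-6)
})
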