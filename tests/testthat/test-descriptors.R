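test_that("dihedral_angle follows the IUPAC sign convention", {
  a <- c(1, 0, 0); b <- c(0, 0, 0); cc <- c(0, 1, 0)
  expect_equal(dihedral_angle(a, b, cc, c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(a, b, cc, c(-1, 1, 0)), 180)
  # oracle: rotating the cis position by +x about the b->c axis gives +x
  set.seed(11)
  for (ang in c(60, -60, 135.5, 179.9, -90, runif(20, -179, 180))) {
    d <- oracle_rotate(c(1, 1, 0), b, cc - b, ang)
    expect_equal(dihedral_angle(a, b, cc, d), ang, tolerance = 1e-9)
  }
})

test_that("dihedral identity and mirror antisymmetry hold", {
  set.seed(23)
  for (rep in 1:200) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    val <- try(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
               silent = TRUE)
    if (inherits(val, "try-error")) next
    # dihedral(a,b,c,d) == dihedral(d,c,b,a)
    expect_equal(dihedral_angle(pts[4, ], pts[3, ], pts[2, ], pts[1, ]),
                 val, tolerance = 1e-9)
    # mirror reflection (z -> -z) flips the sign
    m <- pts; m[, 3] <- -m[, 3]
    mirrored <- dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ])
    if (abs(abs(val) - 180) > 1e-6) {
      expect_equal(mirrored, -val, tolerance = 1e-9)
    }
  }
})

test_that("dihedral_angle rejects degenerate geometry", {
  expect_error(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)),
               "coincide")
  expect_error(dihedral_angle(c(0, 2, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               "colinear")
})

test_that("descriptor_set measures what the builder realizes", {
  # reference conformer torsions (syn global minimum at the correlated level)
  tor <- c(phi1 = 95.6, phi2 = -66.8, phi3 = -75.8, phi4 = 65.5, phi5 = 44.0)
  conf <- build_template("N1", tor)
  d <- descriptor_set(conf, name = "B2")
  expect_equal(unlist(d[paste0("phi", 1:5)]), tor, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_gt(d$R, 0)
  expect_true(d$beta > 0 && d$beta < 180)
  expect_true(d$Phi > 0 && d$Phi < 180)

  # rigid-motion invariance
  set.seed(5)
  moved <- random_rigid_motion(conf)
  expect_equal(descriptor_set(moved, name = "B2"), d, tolerance = 1e-6)

  # random torsion assignments round-trip through the geometry
  for (rep in 1:10) {
    tr <- stats::setNames(runif(5, -179, 180), paste0("phi", 1:5))
    dd <- descriptor_set(build_template("N1", tr), name = "r")
    expect_equal(unlist(dd[paste0("phi", 1:5)]), tr, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("descriptor errors name the missing atom", {
  tmpl <- build_template("N1")
  broken <- tmpl
  broken$atoms <- broken$atoms[broken$atoms$label != "O5'", ]
  broken$bonds <- broken$bonds[broken$bonds$a1 != "O5'" &
                                 broken$bonds$a2 != "O5'", ]
  expect_error(descriptor_set(broken), "O5'")
})

test_that("set_torsion drives exactly, preserves geometry, and composes", {
  tmpl <- build_template("N1")
  # identity
  cur <- measure_torsion(tmpl, "phi1")
  same <- set_torsion(tmpl, "phi1", cur)
  expect_equal(as.matrix(same$atoms[, c("x", "y", "z")]),
               as.matrix(tmpl$atoms[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # reference target value
  t2 <- set_torsion(tmpl, "phi1", -75.3)
  expect_equal(measure_torsion(t2, "phi1"), -75.3, tolerance = 1e-6)
  # non-rotating side unmoved; all pairwise distances within the rotating
  # fragment preserved (oracle: distance-matrix comparison)
  base_side <- c("N1", "C2", "N3", "C4", "C5", "C6", "N9")
  for (at in base_side) {
    expect_equal(atom_xyz(t2, at), atom_xyz(tmpl, at), tolerance = 1e-9)
  }
  chain <- c("O2'", "C3'", "C4'", "O5'", "H5'")
  d_before <- sapply(chain, function(p) sapply(chain, function(q)
    atom_distance(tmpl, p, q)))
  d_after <- sapply(chain, function(p) sapply(chain, function(q)
    atom_distance(t2, p, q)))
  expect_equal(d_after, d_before, tolerance = 1e-9)
  # composability: setting phi2 then phi4 leaves phi2 unchanged
  t3 <- set_torsion(set_torsion(tmpl, "phi2", 100), "phi4", -50)
  expect_equal(measure_torsion(t3, "phi2"), 100, tolerance = 1e-6)
  expect_equal(measure_torsion(t3, "phi4"), -50, tolerance = 1e-6)
})

test_that("set_torsion refuses ring axes", {
  tmpl <- build_template("N1")
  expect_error(set_torsion(tmpl, c("N1", "C2", "N3", "C4"), 10),
               "ring")
})

test_that("base_nonplanarity flags deviations above the threshold", {
  tmpl <- build_template("N1")
  bp <- base_nonplanarity(tmpl)
  expect_lt(bp$max_abs, 0.01)
  expect_length(bp$flagged, 0L)

  # flag logic on the reference deviation pattern (largest nonplanarity
  # among the six best conformers)
  nu <- c(nu0 = -1.3, nu1 = 2.8, nu2 = -2.3, nu3 = 0.2, nu4 = 0.5)
  fl <- planarity_flags(nu, 1.0)
  expect_equal(fl$max_abs, 2.8)
  expect_setequal(fl$flagged, c("nu0", "nu1", "nu2"))
  expect_length(planarity_flags(nu, 5)$flagged, 0L)

  # a genuinely puckered ring is detected on real coordinates
  bent <- tmpl
  i <- which(bent$atoms$label == "N3")
  bent$atoms$z[i] <- bent$atoms$z[i] + 0.08
  bp2 <- base_nonplanarity(bent)
  expect_gt(bp2$max_abs, 1)
  expect_true(length(bp2$flagged) >= 1L)
  expect_equal(bp2$max_abs, max(abs(bp2$nu)))
})
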