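tmpl <- build_template("N1")

# a separable cosine landscape over the driven torsions, minimum at phi_star
cosine_model <- function(phi_star) {
  function(conf) {
    s <- 0
    for (t in names(phi_star)) {
      s <- s + 1 - cos((measure_torsion(conf, t) - phi_star[[t]]) * pi / 180)
    }
    s
  }
}

test_that("default grid enumerates 6^5 starts; phases normalized", {
  g <- grid_starts(search_config())
  expect_equal(nrow(g), 7776L)
  expect_equal(ncol(g), 5L)
  expect_true(all(unlist(g) > -180 & unlist(g) <= 180))
  expect_equal(sort(unique(g$phi1)), sort(wrap_angle(seq(0, 300, by = 60))))
  expect_error(search_config(step = 50), "divisible")
})

test_that("a convex-per-torsion landscape is found from every start", {
  phi_star <- c(phi4 = 71.1, phi5 = -73.3)
  cfg <- search_config(step = 120, torsions = c("phi4", "phi5"))
  gs <- grid_search(tmpl, cosine_model(phi_star), cfg)
  expect_equal(nrow(gs$minima), 9L)
  expect_equal(gs$minima$phi4, rep(71.1, 9), tolerance = 1e-3)
  expect_equal(gs$minima$phi5, rep(-73.3, 9), tolerance = 1e-3)
  expect_true(all(gs$minima$energy < 1e-6))
  # dedup collapses everything to one named survivor
  tab <- deduplicate_and_rank(gs, cfg)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$name, "A1")  # template phi1 < 0 -> class A
  expect_equal(tab$dE, 0)
})

test_that("energy of every reported minimum <= energy at its start point", {
  model <- toy_energy_model(tmpl, wells = FALSE)
  cfg <- search_config(step = 120, torsions = c("phi1", "phi2"))
  gs <- grid_search(tmpl, model, cfg)
  drv_start <- function(i) {
    conf <- set_chain_torsions(tmpl, c(phi1 = gs$minima$start_phi1[i],
                                       phi2 = gs$minima$start_phi2[i]))
    model(conf)
  }
  for (i in seq_len(nrow(gs$minima))) {
    expect_lte(gs$minima$energy_abs[i], drv_start(i) + 1e-9)
  }
})

test_that("two-well landscapes match the brute-force basin oracle", {
  # double well in each of two torsions: minima near +-70 (phi4), +-60 (phi5)
  well2 <- function(a, b) {
    (1 - cos(2 * (a - 70) * pi / 180)) + (1 - cos(2 * (b - 60) * pi / 180))
  }
  model <- function(conf) {
    well2(measure_torsion(conf, "phi4"), measure_torsion(conf, "phi5"))
  }
  cfg <- search_config(step = 60, torsions = c("phi4", "phi5"),
                       dedup_tol = 20)
  gs <- grid_search(tmpl, model, cfg)
  tab <- deduplicate_and_rank(gs, cfg)
  found <- tab[, c("phi4", "phi5")]
  oracle <- oracle_grid_minima(well2, step = 2)
  expect_equal(nrow(found), nrow(oracle))  # 2 x 2 basins
  for (k in seq_len(nrow(oracle))) {
    dmin <- min(pmax(circular_diff(found$phi4, oracle[k, 1]),
                     circular_diff(found$phi5, oracle[k, 2])))
    expect_lt(dmin, 2.5)
  }
})

test_that("dedup is idempotent, order-independent and keeps the lowest energy", {
  minima <- data.frame(
    phi1 = c(-74.1, -74.0, -73.9, 80, 80.4, -100),
    phi2 = c(140, 141, 140.5, -60, -60.2, 30),
    energy_abs = c(0.2, 0.1, 0.3, 1.0, 0.9, 2.0))
  minima$energy <- minima$energy_abs - min(minima$energy_abs)
  cfg <- search_config(torsions = c("phi1", "phi2"), dedup_tol = 20)
  tab <- deduplicate_and_rank(minima, cfg)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$name, c("A1", "A2", "B1"))
  expect_equal(tab$dE, c(0, 1.9, 0.8), tolerance = 1e-9)
  # idempotent: survivors run through dedup again unchanged
  tab2 <- deduplicate_and_rank(
    data.frame(phi1 = tab$phi1, phi2 = tab$phi2, energy_abs = tab$dE), cfg)
  expect_equal(nrow(tab2), nrow(tab))
  # permutation invariance
  set.seed(99)
  for (rep in 1:5) {
    perm <- sample(nrow(minima))
    tabp <- deduplicate_and_rank(minima[perm, ], cfg)
    expect_equal(tabp$phi1, tab$phi1)
    expect_equal(tabp$dE, tab$dE)
  }
})

test_that("phi1 = 0 is routed to the unclassified bucket with a warning", {
  minima <- data.frame(phi1 = c(0, -50), phi2 = c(10, 20),
                       energy_abs = c(1, 0))
  cfg <- search_config(torsions = c("phi1", "phi2"), dedup_tol = 5)
  expect_warning(tab <- deduplicate_and_rank(minima, cfg), "unclassified")
  expect_setequal(tab$name, c("A1", "U1"))
})

test_that("search results feed conformer_analysis end to end", {
  cfg <- search_config(step = 120, torsions = c("phi1", "phi5"))
  gs <- grid_search(tmpl, toy_energy_model(tmpl, wells = FALSE), cfg)
  tab <- deduplicate_and_rank(gs, cfg)
  expect_s3_class(tab, "conformer_table")
  expect_true(all(tab$dE >= 0))
  p <- boltzmann_populations(tab)
  expect_equal(sum(p$population), 100, tolerance = 1e-9)
  expect_silent(bin_torsions(tab, "phi1", default_torsion_bins()$phi1))
  expect_silent(energy_band_stats(tab, c(0, 3)))
  # determinism: identical inputs give identical tables
  gs2 <- grid_search(tmpl, toy_energy_model(tmpl, wells = FALSE), cfg)
  expect_equal(deduplicate_and_rank(gs2, cfg), tab)
})
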