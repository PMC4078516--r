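# Surrogate energy model. The reference energies are quantum-chemical and
# are consumed as tabulated inputs everywhere in this package; the toy model
# below exists so the grid-search protocol and the downstream analytics can
# be exercised end to end. It is labeled as a surrogate in all outputs and
# no claim is made that its minima match any published conformer set.
#
# E(conf) [kcal/mol] =
#   sum_k w_k (1 - cos(phi_k - phi*_k))          torsional preference
# + soft-sphere repulsion over nonbonded pairs    steric guard
# - bounded attractive wells H5'...N3, H5'...O2'  favors the two
#                                                 intramolecular H-bond
#                                                 motifs, mimicking the
#                                                 stabilizing H5'...N3
#                                                 contact
# All terms depend on interatomic distances and torsions only, so the model
# is invariant under rigid motion. Overlapping atoms (< 0.3 A) return +Inf
# as a sentinel, not an error.

TOY_WEIGHTS <- c(phi1 = 2.0, phi2 = 1.5, phi3 = 1.5, phi4 = 1.0, phi5 = 1.0)
TOY_CENTERS <- DEFAULT_TORSIONS  # the global-minimum conformer torsions

VDW_RADII <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

# topological (bond-graph) distance matrix, capped at `cap`
graph_distances <- function(conf, cap = 3L) {
  n <- nrow(conf$atoms)
  adj <- bond_adjacency(conf)
  D <- matrix(cap, n, n)
  diag(D) <- 0L
  for (s in seq_len(n)) {
    dist <- rep(cap, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      if (dist[cur] >= cap - 1L) next
      for (nb in adj[[cur]]) {
        if (dist[nb] > dist[cur] + 1L) {
          dist[nb] <- dist[cur] + 1L
          queue <- c(queue, nb)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

#' Torsion-preference part of the toy energy (closed form)
#'
#' `sum_k w_k (1 - cos(phi_k - phi*_k))`, the analytically differentiable
#' part of [toy_energy()].
#'
#' @param phi named numeric vector (names among `phi1`..`phi5`), degrees.
#' @return energy, kcal/mol.
#' @export
toy_torsion_energy <- function(phi) {
  k <- intersect(names(TOY_WEIGHTS), names(phi))
  sum(TOY_WEIGHTS[k] * (1 - cos((phi[k] - TOY_CENTERS[k]) * pi / 180)))
}

#' Analytic gradient of [toy_torsion_energy()]
#'
#' @param phi named numeric vector, degrees.
#' @return named vector of derivatives, kcal/mol per degree.
#' @export
toy_torsion_gradient <- function(phi) {
  k <- intersect(names(TOY_WEIGHTS), names(phi))
  g <- TOY_WEIGHTS[k] * sin((phi[k] - TOY_CENTERS[k]) * pi / 180) * pi / 180
  stats::setNames(g, k)
}

#' Surrogate conformational energy of a conformation
#'
#' See the file-level description: torsion preference plus soft-sphere
#' repulsion plus bounded attractive wells between H5' and {N3, O2'} so the
#' two intramolecular H-bond motifs are energetically favored. Invariant
#' under rigid motion; returns `Inf` (sentinel) when any two atoms are
#' closer than 0.3 Angstrom.
#'
#' @param conf a [conformation] with the acyclovir chain atoms.
#' @param wells include the H-bond well terms (default `TRUE`).
#' @return energy in kcal/mol.
#' @export
toy_energy <- function(conf, wells = TRUE) {
  toy_energy_model(conf, wells = wells)(conf)
}

#' Build a toy energy model closure for a fixed topology
#'
#' Precomputes the nonbonded pair mask from the template's bond graph so
#' repeated evaluations during a grid search only touch coordinates. The
#' returned function satisfies the `EnergyModel` contract: a pure mapping
#' from a conformation to a scalar energy in kcal/mol.
#'
#' @param template a [conformation] defining the topology.
#' @param wells include the H-bond well terms.
#' @return a function `conformation -> energy`; attributes `label` and
#'   `torsion_only = FALSE` describe the model.
#' @export
toy_energy_model <- function(template, wells = TRUE) {
  gd <- graph_distances(template, cap = 3L)
  nonbonded <- gd >= 3L & upper.tri(gd)
  sigma <- outer(VDW_RADII[template$atoms$element],
                 VDW_RADII[template$atoms$element], "+") * 0.75
  # precomputed atom indices keep repeated evaluations off the label lookups
  lab <- template$atoms$label
  tor_idx <- lapply(TORSION_DEFS, function(d) match(d, lab))
  tor_ok <- !vapply(tor_idx, anyNA, logical(1L))
  i_h5 <- match("H5'", lab); i_n3 <- match("N3", lab); i_o2 <- match("O2'", lab)
  has_sites <- !anyNA(c(i_h5, i_n3, i_o2))
  n_atoms <- nrow(template$atoms)

  f <- function(conf) {
    stopifnot(nrow(conf$atoms) == n_atoms)
    xyz <- cbind(conf$atoms$x, conf$atoms$y, conf$atoms$z)
    d <- as.matrix(stats::dist(xyz))
    if (any(d[upper.tri(d)] < 0.3)) return(Inf)
    phi <- vapply(names(TORSION_DEFS)[tor_ok], function(t) {
      i <- tor_idx[[t]]
      dihedral_angle(xyz[i[1L], ], xyz[i[2L], ], xyz[i[3L], ], xyz[i[4L], ])
    }, numeric(1L))
    e <- toy_torsion_energy(phi)
    viol <- nonbonded & d < sigma
    if (any(viol)) e <- e + sum(5 * (sigma[viol] - d[viol])^2)
    if (wells && has_sites) {
      dn3 <- d[i_h5, i_n3]
      do2 <- d[i_h5, i_o2]
      e <- e - 2.5 * exp(-((dn3 - 1.90)^2) / (2 * 0.25^2)) -
        1.2 * exp(-((do2 - 2.35)^2) / (2 * 0.25^2))
    }
    e
  }
  attr(f, "label") <- sprintf("toy surrogate (wells %s)",
                              if (wells) "on" else "off")
  attr(f, "torsion_only") <- FALSE
  f
}
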