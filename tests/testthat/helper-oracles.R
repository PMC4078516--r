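# Independent oracles used by the tests. These deliberately do not reuse the
# package's internals for the quantity they check.

# Rodrigues rotation, written out long-hand (oracle for dihedral sign and
# for set_torsion)
oracle_rotate <- function(p, origin, axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  v <- p - origin
  vr <- v * cos(th) + c(k[2] * v[3] - k[3] * v[2],
                        k[3] * v[1] - k[1] * v[3],
                        k[1] * v[2] - k[2] * v[1]) * sin(th) +
    k * sum(k * v) * (1 - cos(th))
  vr + origin
}

# connected components of a distance-threshold bond graph (oracle for
# multimer splitting); returns an integer component id per atom
oracle_components <- function(xyz, elements, factor = 1.6) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)
  n <- nrow(xyz)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      thr <- factor * (radii[[elements[i]]] + radii[[elements[j]]])
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < thr) {
        old <- comp[j]; new <- comp[i]
        comp[comp == old] <- new
      }
    }
  }
  match(comp, unique(comp))
}

# brute-force basin enumeration on a fine grid of a 2-torsion landscape
# (oracle for grid_search minima): returns the set of local minima of f
# evaluated on a 1-degree wrapped grid
oracle_grid_minima <- function(f, step = 1) {
  g <- seq(-180 + step, 180, by = step)
  E <- outer(g, g, Vectorize(function(a, b) f(a, b)))
  n <- length(g)
  idx <- function(i) ((i - 1) %% n) + 1
  mins <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      nb <- c(E[idx(i - 1), j], E[idx(i + 1), j],
              E[i, idx(j - 1)], E[i, idx(j + 1)],
              E[idx(i - 1), idx(j - 1)], E[idx(i - 1), idx(j + 1)],
              E[idx(i + 1), idx(j - 1)], E[idx(i + 1), idx(j + 1)])
      if (all(E[i, j] < nb)) {
        mins[[length(mins) + 1]] <- c(g[i], g[j], E[i, j])
      }
    }
  }
  do.call(rbind, mins)
}

random_rigid_motion <- function(conf) {
  ang <- stats::runif(1, -180, 180)
  ax <- stats::rnorm(3)
  tr <- stats::rnorm(3, sd = 5)
  transform_conformation(conf, angle = ang, axis = ax,
                         origin = stats::rnorm(3), translate = tr)
}
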