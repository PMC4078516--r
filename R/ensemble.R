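# Synthetic conformer ensembles: a statistical stand-in for a quantum-
# chemistry conformer table, with the reference modal structure of the five
# chain torsions (phi1-phi3 bimodal, phi4/phi5 trimodal) and an energy
# spread over [0, 8.5] kcal/mol. Used to exercise binning, classification
# and population analytics with a known generating truth.

#' Default torsion mixture modes
#'
#' Per torsion, a list of `(center, spread, weight)` wrapped-normal
#' components. Centers sit near the middles of the observed modal ranges,
#' weights are the observed modal fractions of the 78-conformer reference
#' set (e.g. 47/78 anti vs 31/78 syn for phi1), and spreads are chosen so
#' roughly 3 standard deviations span each printed modal range.
#'
#' @return named list of component lists.
#' @export
default_ensemble_modes <- function() {
  list(
    phi1 = list(c(center = -95, spread = 15, weight = 47 / 78),
                c(center = 90, spread = 13, weight = 31 / 78)),
    phi2 = list(c(center = 110, spread = 33, weight = 49 / 78),
                c(center = -120, spread = 32, weight = 29 / 78)),
    phi3 = list(c(center = 115, spread = 34, weight = 32 / 78),
                c(center = -115, spread = 35, weight = 46 / 78)),
    phi4 = list(c(center = 180, spread = 25, weight = 28 / 78),
                c(center = 75, spread = 21, weight = 28 / 78),
                c(center = -60, spread = 9, weight = 22 / 78)),
    phi5 = list(c(center = 180, spread = 24, weight = 29 / 78),
                c(center = 75, spread = 23, weight = 29 / 78),
                c(center = -80, spread = 20, weight = 20 / 78)))
}

#' Ensemble specification
#'
#' @param n ensemble size (default 78, the reference conformer count).
#' @param seed integer seed; sampling is deterministic per seed and never
#'   touches the global RNG stream of the caller.
#' @param modes torsion mixture components, see [default_ensemble_modes()];
#'   weights must sum to 1 per torsion.
#' @param energy_mean mean of the (truncated) exponential energy spread,
#'   kcal/mol.
#' @param energy_max truncation of the energy spread, kcal/mol (default 8.5,
#'   the reference electronic-energy window).
#' @return an `ensemble_spec` list.
#' @export
ensemble_spec <- function(n = 78L, seed = 1L,
                          modes = default_ensemble_modes(),
                          energy_mean = 2.5, energy_max = 8.5) {
  stopifnot(n >= 0)
  for (t in names(modes)) {
    w <- vapply(modes[[t]], function(m) m[["weight"]], numeric(1L))
    if (abs(sum(w) - 1) > 1e-8) {
      stop("configuration error: mixture weights for ", t,
           " do not sum to 1", call. = FALSE)
    }
    if (any(vapply(modes[[t]], function(m) m[["spread"]], numeric(1L)) <= 0)) {
      stop("configuration error: nonpositive spread for ", t, call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), seed = as.integer(seed), modes = modes,
                 energy_mean = energy_mean, energy_max = energy_max),
            class = "ensemble_spec")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic conformer ensemble table
#'
#' Draws each torsion from its wrapped-normal mixture, energies from a
#' truncated exponential shifted so the minimum is 0, and assigns names by
#' the ranking convention of [deduplicate_and_rank()] (class by the sign of
#' phi1, numbered by ascending dE). `dG` is dE plus small thermal noise,
#' re-anchored at 0. The generating truth (per-torsion component
#' assignments and weights) is attached as attribute `truth`.
#'
#' @param spec an [ensemble_spec()].
#' @return a `conformer_table` with `R`, `beta`, `Phi` and `mu` set to `NA`
#'   (not modelled); deterministic per seed.
#' @export
generate_ensemble_table <- function(spec = ensemble_spec()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$n
  empty <- data.frame(name = character(), R = numeric(), beta = numeric(),
                      Phi = numeric(), phi1 = numeric(), phi2 = numeric(),
                      phi3 = numeric(), phi4 = numeric(), phi5 = numeric(),
                      mu = numeric(), dE = numeric(), dG = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    return(new_conformer_table(empty, level = "synthetic ensemble",
                               provenance = sprintf("seed %d", spec$seed)))
  }
  with_local_seed(spec$seed, {
    tor <- list()
    comp <- list()
    for (t in names(spec$modes)) {
      modes <- spec$modes[[t]]
      w <- vapply(modes, function(m) m[["weight"]], numeric(1L))
      z <- sample.int(length(modes), n, replace = TRUE, prob = w)
      x <- vapply(seq_len(n), function(i) {
        m <- modes[[z[i]]]
        stats::rnorm(1L, m[["center"]], m[["spread"]])
      }, numeric(1L))
      tor[[t]] <- wrap_angle(x)
      comp[[t]] <- z
    }
    dE <- stats::qexp(stats::runif(n) *
                        stats::pexp(spec$energy_max, 1 / spec$energy_mean),
                      1 / spec$energy_mean)
    dE <- dE - min(dE)
    dG <- pmax(dE + stats::rnorm(n, 0, 0.3), 0)
    dG <- dG - min(dG)

    df <- data.frame(name = NA_character_, R = NA_real_, beta = NA_real_,
                     Phi = NA_real_, phi1 = tor$phi1, phi2 = tor$phi2,
                     phi3 = tor$phi3, phi4 = tor$phi4, phi5 = tor$phi5,
                     mu = NA_real_, dE = dE, dG = dG,
                     stringsAsFactors = FALSE)
    # phi1 = 0 has probability zero but guard the naming convention anyway
    cls <- ifelse(df$phi1 < 0, "A", ifelse(df$phi1 > 0, "B", "U"))
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      df$name[idx[order(df$dE[idx])]] <- paste0(cl, seq_along(idx))
    }
    ord <- order(cls, df$dE)
    df <- df[ord, , drop = FALSE]
    comp <- lapply(comp, function(z) z[ord])
    rownames(df) <- NULL
    out <- new_conformer_table(df, level = "synthetic ensemble",
                               provenance = sprintf("seed %d", spec$seed))
    attr(out, "truth") <- list(components = comp, spec = spec)
    out
  })
}
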