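# Table-level analytics: Boltzmann populations, circular torsion binning and
# energy-band statistics over conformer tables.

#' Configuration for Boltzmann population analysis
#'
#' @param temperature kelvin; 298.15 by default, 273.15 is the usual
#'   alternate.
#' @param energy_column `"dE"` (relative electronic energy + ZPE, the column
#'   that reproduces the reference populations) or `"dG"` (relative Gibbs
#'   energy, the column named by the textbook Boltzmann formula
#'   exp(-dG/kT)). Both are selectable; the default is `"dE"`.
#' @param gas_constant kcal/(mol K); kT is interpreted per mole (RT).
#' @return a `population_config` list.
#' @export
population_config <- function(temperature = 298.15, energy_column = "dE",
                              gas_constant = 1.98720425e-3) {
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("configuration error: temperature must be positive", call. = FALSE)
  }
  energy_column <- match.arg(energy_column, c("dE", "dG"))
  structure(list(temperature = temperature, energy_column = energy_column,
                 gas_constant = gas_constant),
            class = "population_config")
}

#' Boltzmann populations of a conformer or tautomer table
#'
#' p_i = exp(-E_i / RT) / sum_j exp(-E_j / RT), reported in percent. The
#' result is invariant to adding a constant to every energy, tends to 100%
#' for the minimum-energy record as T -> 0 and to the uniform distribution
#' as T -> Inf.
#'
#' @param table a `conformer_table` (any data.frame with the energy column).
#' @param config a [population_config()].
#' @return the table with a `population` column (percent, summing to 100);
#'   the configuration used is attached as attribute `population_config`.
#' @export
boltzmann_populations <- function(table, config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  e <- table[[config$energy_column]]
  if (is.null(e)) {
    stop("record error: energy column '", config$energy_column,
         "' is absent", call. = FALSE)
  }
  if (anyNA(e)) {
    stop("record error: missing ", config$energy_column, " for record(s) ",
         paste(table$name[is.na(e)], collapse = ", "), call. = FALSE)
  }
  rt <- config$gas_constant * config$temperature
  w <- exp(-(e - min(e)) / rt)
  table$population <- 100 * w / sum(w)
  attr(table, "population_config") <- config
  table
}

as_circular_bin <- function(b) {
  stopifnot(is.numeric(b), length(b) == 2L)
  # -180 stays -180: on (-180, 180] the closed bound [-180, hi] is the same
  # set as (-180, hi], while wrapping it to +180 would wrongly make the
  # interval cross the branch point
  w <- ifelse(b == -180, -180, wrap_angle(b))
  c(lo = w[1L], hi = w[2L])
}

in_circular_bin <- function(x, bin) {
  # x is expected in [-180, 180]; -180 is kept distinct from +180 so that
  # printed bounds like [-180, -66] behave as written
  if (bin["lo"] <= bin["hi"]) {
    x >= bin["lo"] & x <= bin["hi"]
  } else {
    x >= bin["lo"] | x <= bin["hi"]  # interval wrapping through +-180
  }
}

#' Bin torsion values of a conformer table, split by class
#'
#' Bins are closed circular intervals on `(-180, 180]`; an interval given as
#' `c(lo, hi)` with `lo > hi` wraps through 180 (e.g. `c(175, -173)` is the
#' trans mode). Overlapping bins are a configuration error. Because
#' published interval endpoints are typically the rounded observed extremes
#' of each mode, `round_to` lets membership be evaluated on values rounded
#' to that many decimals (use 0 to match whole-degree printed bounds).
#'
#' @param table a `conformer_table` with `phi1` available for classification.
#' @param torsion one of `"phi1"`..`"phi5"`.
#' @param bins list of length-2 numeric vectors.
#' @param round_to optional decimals to round values to before membership.
#' @return data.frame with one row per bin plus an `unbinned` bucket:
#'   columns `bin`, `lo`, `hi`, `total`, `A`, `B`.
#' @export
bin_torsions <- function(table, torsion, bins, round_to = NULL) {
  torsion <- match.arg(torsion, names(TORSION_DEFS))
  bins <- lapply(bins, as_circular_bin)
  # configuration check: no grid point may fall in two bins
  grid <- seq(-179.95, 180, by = 0.05)
  member <- vapply(bins, function(b) in_circular_bin(grid, b),
                   logical(length(grid)))
  if (length(bins) > 1L && any(rowSums(member) > 1L)) {
    stop("configuration error: overlapping bins", call. = FALSE)
  }
  vals <- wrap_angle(table[[torsion]])
  # rounding may land exactly on -180; keep it there (not re-wrapped) so it
  # matches printed interval bounds written as -180
  if (!is.null(round_to)) vals <- round(vals, round_to)
  cls <- if (nrow(table)) classify_conformer(table$phi1)$class else character()
  assigned <- rep(FALSE, length(vals))
  rows <- lapply(seq_along(bins), function(k) {
    inb <- in_circular_bin(vals, bins[[k]])
    assigned <<- assigned | inb
    data.frame(bin = sprintf("bin%d", k),
               lo = bins[[k]]["lo"], hi = bins[[k]]["hi"],
               total = sum(inb),
               A = sum(inb & cls == "A"), B = sum(inb & cls == "B"))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(bin = "unbinned", lo = NA_real_, hi = NA_real_,
                               total = sum(!assigned),
                               A = sum(!assigned & cls == "A"),
                               B = sum(!assigned & cls == "B")))
  rownames(out) <- NULL
  out
}

#' Default torsion bins
#'
#' The modal structure of the five chain torsions: phi1-phi3 bimodal,
#' phi4/phi5 trimodal with a trans mode wrapping through +-180. Endpoints
#' are the rounded observed extremes of each mode in the reference conformer
#' set, so they are meant to be used with `round_to = 0`.
#'
#' @return named list of bin lists, one entry per torsion.
#' @export
default_torsion_bins <- function() {
  list(
    phi1 = list(c(-137, -74), c(57, 113)),
    phi2 = list(c(65, 180), c(-180, -66)),
    phi3 = list(c(58, 180), c(-180, -58)),
    phi4 = list(c(175, -173), c(41, 118), c(-75, -45)),
    phi5 = list(c(165, -166), c(39, 123), c(-120, -46)))
}

#' Energy-band statistics of a conformer table
#'
#' Counts records with energies in `[lo, hi)` (half-open, lower-inclusive;
#' set `include_upper = TRUE` for a final closed band), split by class, and
#' reports the anti/syn ratio count(A)/count(B).
#'
#' @param table a `conformer_table`.
#' @param band numeric `c(lo, hi)`, kcal/mol, `lo <= hi`.
#' @param energy_column `"dE"` or `"dG"`.
#' @param include_upper close the upper bound (default `FALSE`).
#' @return list with `count`, `A`, `B`, `ratio_anti_syn` (raw; `NA` when no
#'   B records fall in the band) and `ratio_rounded` (one decimal, the
#'   printed reporting precision).
#' @export
energy_band_stats <- function(table, band, energy_column = c("dE", "dG"),
                              include_upper = FALSE) {
  energy_column <- match.arg(energy_column)
  stopifnot(length(band) == 2L, band[1L] <= band[2L])
  e <- table[[energy_column]]
  inb <- e >= band[1L] & (if (include_upper) e <= band[2L] else e < band[2L])
  inb[is.na(inb)] <- FALSE
  cls <- if (nrow(table)) classify_conformer(table$phi1)$class else character()
  nA <- sum(inb & cls == "A")
  nB <- sum(inb & cls == "B")
  ratio <- if (nB > 0) nA / nB else NA_real_
  list(count = sum(inb), A = nA, B = nB,
       ratio_anti_syn = ratio,
       ratio_rounded = if (is.na(ratio)) NA_real_ else round(ratio, 1L))
}
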