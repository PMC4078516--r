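# Hydrogen-bond detection and typing. The site inventory of the acyclovir
# monomer has four donors -- H1(N1), H2(N2), H2'(N2) and H5'(O5') -- and
# five acceptors: O6, N3, N7, O2' and O5'. Distances are measured
# H...acceptor (matching reported magnitudes of 1.7-2.4 A); the angular
# criterion on donor-H...acceptor is an added geometric guard.

#' Hydrogen-bond detection criteria and site inventory
#'
#' @param donors data.frame with columns `heavy` and `hydrogen` (atom
#'   labels); defaults to the four donor sites of the acyclovir monomer.
#' @param acceptors character vector of heavy-atom acceptor labels.
#' @param max_HA_distance maximum H...acceptor distance, Angstrom. The 2.6
#'   default covers the weakest reference contact (2.350 A) with margin.
#' @param min_DHA_angle minimum donor-H...acceptor angle, degrees.
#' @return an `hbond_spec` list.
#' @export
hbond_spec <- function(donors = data.frame(
                         heavy = c("N1", "N2", "N2", "O5'"),
                         hydrogen = c("H1", "H2", "H2'", "H5'"),
                         stringsAsFactors = FALSE),
                       acceptors = c("O6", "N3", "N7", "O2'", "O5'"),
                       max_HA_distance = 2.6, min_DHA_angle = 110) {
  stopifnot(is.data.frame(donors),
            all(c("heavy", "hydrogen") %in% names(donors)),
            max_HA_distance > 0,
            min_DHA_angle >= 0, min_DHA_angle <= 180)
  structure(list(donors = donors, acceptors = acceptors,
                 max_HA_distance = max_HA_distance,
                 min_DHA_angle = min_DHA_angle),
            class = "hbond_spec")
}

#' Detect hydrogen bonds in a conformation or assembly
#'
#' Reports every donor/acceptor pair satisfying both geometric criteria,
#' within one molecule (`scope = "intra"`) and across molecules (`"inter"`),
#' sorted by H...acceptor distance. A donor's own heavy atom is never its
#' acceptor. Spec labels missing from the structure raise a configuration
#' error listing them.
#'
#' @param conf a [conformation] (monomer or multimer).
#' @param spec an [hbond_spec()].
#' @return data.frame with columns `donor_mol, donor, hydrogen,
#'   acceptor_mol, acceptor, distance_A, angle_deg, scope`.
#' @export
detect_hbonds <- function(conf, spec = hbond_spec()) {
  mols <- sort(unique(conf$atoms$molecule_id))
  referenced <- unique(c(spec$donors$heavy, spec$donors$hydrogen,
                         spec$acceptors))
  missing <- character()
  for (m in mols) {
    present <- conf$atoms$label[conf$atoms$molecule_id == m]
    miss <- setdiff(referenced, present)
    if (length(miss)) {
      missing <- c(missing, sprintf("%s (molecule %d)", miss, m))
    }
  }
  if (length(missing)) {
    stop("configuration error: hbond_spec references missing label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (dm in mols) {
    for (k in seq_len(nrow(spec$donors))) {
      dheavy <- spec$donors$heavy[k]
      dhyd <- spec$donors$hydrogen[k]
      pd <- atom_xyz(conf, dheavy, dm)
      ph <- atom_xyz(conf, dhyd, dm)
      for (am in mols) {
        for (acc in spec$acceptors) {
          if (am == dm && acc == dheavy) next
          pa <- atom_xyz(conf, acc, am)
          dist <- v_norm(pa - ph)
          if (dist > spec$max_HA_distance) next
          ang <- bond_angle(pd, ph, pa)
          if (ang < spec$min_DHA_angle) next
          out[[length(out) + 1L]] <- data.frame(
            donor_mol = dm, donor = dheavy, hydrogen = dhyd,
            acceptor_mol = am, acceptor = acc,
            distance_A = dist, angle_deg = ang,
            scope = if (am == dm) "intra" else "inter",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor_mol = integer(), donor = character(),
                      hydrogen = character(), acceptor_mol = integer(),
                      acceptor = character(), distance_A = numeric(),
                      angle_deg = numeric(), scope = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  # deduplicate by (donor hydrogen, acceptor) identity
  key <- paste(out$donor_mol, out$hydrogen, out$acceptor_mol, out$acceptor)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$distance_A), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Type the intramolecular hydrogen-bond motif
#'
#' Only two intramolecular H-bonds occur in the main conformers of the
#' acyclovir monomer, both from the hydroxyl hydrogen H5': type (i)
#' H5'...N3 (the strong, stabilizing contact) and type (ii) H5'...O2'.
#' Bonds from other donors are ignored with a warning.
#'
#' @param bonds data.frame as returned by [detect_hbonds()] (intra scope).
#' @return one of `"i"`, `"ii"`, `"both"`, `"none"`.
#' @export
classify_intramolecular_type <- function(bonds) {
  if (nrow(bonds)) {
    if (any(bonds$scope != "intra")) {
      stop("classify_intramolecular_type expects intramolecular bonds only",
           call. = FALSE)
    }
    other <- bonds$hydrogen != "H5'"
    if (any(other)) {
      warning("ignoring ", sum(other),
              " intramolecular bond(s) from donors other than H5'",
              call. = FALSE)
      bonds <- bonds[!other, , drop = FALSE]
    }
  }
  has_i <- any(bonds$acceptor == "N3")
  has_ii <- any(bonds$acceptor == "O2'")
  if (has_i && has_ii) "both" else if (has_i) "i" else if (has_ii) "ii" else "none"
}
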