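# Idealized acyclovir template geometry. The reference work prints no usable
# coordinate set, so the template is built from standard small-molecule
# internal coordinates: the purine bicycle as two fused regular polygons
# (exactly planar), in-plane substituents along external bisectors, and the
# exocyclic chain grown by NeRF so the five chain torsions are realized
# exactly. No coordinate-level agreement with any published geometry is
# claimed; torsion-level observables are exact by construction.

TEMPLATE_BONDS <- list(
  ring_len   = 1.39,  # aromatic ring bonds (uniform, regular-polygon bicycle)
  c6_o6_keto = 1.23,  # C6=O6 carbonyl
  c6_o6_enol = 1.36,  # C6-O6 in the enol tautomers
  c2_n2      = 1.36,  # C2-NH2
  n_h        = 1.01,
  c_h_ring   = 1.08,
  o_h        = 0.96,
  n9_c1p     = 1.46,  # glycosidic-like N9-C1'
  c1p_o2p    = 1.41,
  o2p_c3p    = 1.42,
  c3p_c4p    = 1.52,
  c4p_o5p    = 1.42,
  c_h_chain  = 1.09)

TEMPLATE_ANGLES <- list(
  n9_c1p_o2p  = 108.0,
  c1p_o2p_c3p = 113.0,
  o2p_c3p_c4p = 109.47,
  c3p_c4p_o5p = 109.47,
  c4p_o5p_h5p = 108.5,
  amino_h     = 120.0,
  tet_h       = 109.47,
  enol_h      = 109.0)

# Default chain torsions: the global-minimum conformer (A1) values at the
# reference level of theory.
DEFAULT_TORSIONS <- c(phi1 = -74.1, phi2 = 144.7, phi3 = -93.4,
                      phi4 = 71.1, phi5 = -73.3)

TAUTOMER_IDS <- c("N1", "N3", "N7", "OHC", "OHT")

# regular pentagon fused on edge p1-p2, on the side away from `away_from`;
# returns the three new vertex positions continuing p1 -> p2 around the ring
fuse_pentagon <- function(p1, p2, away_from) {
  s <- v_norm(p2 - p1)
  mid <- (p1 + p2) / 2
  apothem <- s / (2 * tan(pi / 5))
  nrm <- v_unit(c(-(p2 - p1)[2L], (p2 - p1)[1L], 0))
  if (sum((mid + nrm - away_from)^2) > sum((mid - nrm - away_from)^2)) {
    ctr <- mid + apothem * nrm
  } else {
    ctr <- mid - apothem * nrm
  }
  th1 <- atan2(p1[2L] - ctr[2L], p1[1L] - ctr[1L])
  th2 <- atan2(p2[2L] - ctr[2L], p2[1L] - ctr[1L])
  step <- if (sin(th2 - th1) > 0) 2 * pi / 5 else -2 * pi / 5
  rad <- s / (2 * sin(pi / 5))
  vapply(1:3, function(k) {
    ctr + rad * c(cos(th2 + k * step), sin(th2 + k * step), 0)
  }, numeric(3L))
}

# in-plane substituent along the external bisector at ring atom v with ring
# neighbours pa, pb
external_bisector <- function(v, pa, pb, len) {
  v + len * v_unit(v_unit(v - pa) + v_unit(v - pb))
}

#' Build an idealized acyclovir template conformation
#'
#' Constructs the full-atom template of the requested tautomer: an exactly
#' planar purine bicycle, in-plane substituents, and the acyclic chain grown
#' so the five exocyclic torsions take the requested values exactly.
#' Tautomers differ only in proton placement: the keto forms carry the
#' labile proton on N1, N3 or N7; the enol forms OHC/OHT carry it on O6 with
#' the N1-C6-O6-H6 torsion at 0 (cis) or 180 (trans).
#'
#' @param tautomer one of `"N1"`, `"N3"`, `"N7"`, `"OHC"`, `"OHT"`.
#' @param torsions named numeric vector of chain torsions (degrees, names
#'   among `phi1`..`phi5`); defaults to the global-minimum conformer values.
#' @param provenance provenance string.
#' @return a [conformation] that passes [validate_topology()], with the ring
#'   planar to below 0.01 degrees.
#' @export
#' @examples
#' tmpl <- build_template("N1", c(phi1 = -75.3, phi2 = 146.4, phi3 = -88.5,
#'                                phi4 = 69.8, phi5 = -69.3))
#' descriptor_set(tmpl)
build_template <- function(tautomer = "N1", torsions = NULL,
                           provenance = NULL) {
  tautomer <- as.character(tautomer)
  if (!tautomer %in% TAUTOMER_IDS) {
    stop("not implemented: unsupported tautomer '", tautomer, "'",
         call. = FALSE)
  }
  tor <- DEFAULT_TORSIONS
  if (!is.null(torsions)) {
    stopifnot(!is.null(names(torsions)),
              all(names(torsions) %in% names(TORSION_DEFS)))
    tor[names(torsions)] <- torsions
  }
  bl <- TEMPLATE_BONDS; an <- TEMPLATE_ANGLES

  # six-membered ring: regular hexagon in the z = 0 plane
  hex_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  hex_angle <- c(90, 150, 210, 270, 330, 30) * pi / 180
  pos <- list()
  for (k in seq_along(hex_names)) {
    pos[[hex_names[k]]] <- bl$ring_len * c(cos(hex_angle[k]),
                                           sin(hex_angle[k]), 0)
  }
  # five-membered ring fused on C4-C5, away from the hexagon centre
  pent <- fuse_pentagon(pos[["C4"]], pos[["C5"]], c(0, 0, 0))
  pos[["N7"]] <- pent[, 1L]
  pos[["C8"]] <- pent[, 2L]
  pos[["N9"]] <- pent[, 3L]

  # in-plane substituents
  keto <- tautomer %in% c("N1", "N3", "N7")
  pos[["O6"]] <- external_bisector(pos[["C6"]], pos[["C5"]], pos[["N1"]],
                                   if (keto) bl$c6_o6_keto else bl$c6_o6_enol)
  pos[["N2"]] <- external_bisector(pos[["C2"]], pos[["N1"]], pos[["N3"]],
                                   bl$c2_n2)
  pos[["H8"]] <- external_bisector(pos[["C8"]], pos[["N7"]], pos[["N9"]],
                                   bl$c_h_ring)
  pos[["C1'"]] <- external_bisector(pos[["N9"]], pos[["C4"]], pos[["C8"]],
                                    bl$n9_c1p)
  # planar amino group
  pos[["H2"]] <- nerf_place(pos[["N2"]], pos[["C2"]], pos[["N1"]],
                            bl$n_h, an$amino_h, 0)
  pos[["H2'"]] <- nerf_place(pos[["N2"]], pos[["C2"]], pos[["N1"]],
                             bl$n_h, an$amino_h, 180)
  # labile proton
  bonds_extra <- NULL
  if (tautomer == "N1") {
    pos[["H1"]] <- external_bisector(pos[["N1"]], pos[["C2"]], pos[["C6"]],
                                     bl$n_h)
    bonds_extra <- c("N1", "H1")
  } else if (tautomer == "N3") {
    pos[["H3"]] <- external_bisector(pos[["N3"]], pos[["C2"]], pos[["C4"]],
                                     bl$n_h)
    bonds_extra <- c("N3", "H3")
  } else if (tautomer == "N7") {
    pos[["H7"]] <- external_bisector(pos[["N7"]], pos[["C5"]], pos[["C8"]],
                                     bl$n_h)
    bonds_extra <- c("N7", "H7")
  } else {
    tau_h6 <- if (tautomer == "OHC") 0 else 180
    pos[["H6"]] <- nerf_place(pos[["O6"]], pos[["C6"]], pos[["N1"]],
                              bl$o_h, an$enol_h, tau_h6)
    bonds_extra <- c("O6", "H6")
  }

  # chain grown by NeRF; each placement realizes one phi torsion exactly
  pos[["O2'"]] <- nerf_place(pos[["C1'"]], pos[["N9"]], pos[["C4"]],
                             bl$c1p_o2p, an$n9_c1p_o2p, tor[["phi1"]])
  pos[["C3'"]] <- nerf_place(pos[["O2'"]], pos[["C1'"]], pos[["N9"]],
                             bl$o2p_c3p, an$c1p_o2p_c3p, tor[["phi2"]])
  pos[["C4'"]] <- nerf_place(pos[["C3'"]], pos[["O2'"]], pos[["C1'"]],
                             bl$c3p_c4p, an$o2p_c3p_c4p, tor[["phi3"]])
  pos[["O5'"]] <- nerf_place(pos[["C4'"]], pos[["C3'"]], pos[["O2'"]],
                             bl$c4p_o5p, an$c3p_c4p_o5p, tor[["phi4"]])
  pos[["H5'"]] <- nerf_place(pos[["O5'"]], pos[["C4'"]], pos[["C3'"]],
                             bl$o_h, an$c4p_o5p_h5p, tor[["phi5"]])
  # chain hydrogens, staggered +-120 deg from the heavy-atom torsion
  pos[["H1'a"]] <- nerf_place(pos[["C1'"]], pos[["N9"]], pos[["C4"]],
                              bl$c_h_chain, an$tet_h, tor[["phi1"]] + 120)
  pos[["H1'b"]] <- nerf_place(pos[["C1'"]], pos[["N9"]], pos[["C4"]],
                              bl$c_h_chain, an$tet_h, tor[["phi1"]] - 120)
  pos[["H3'a"]] <- nerf_place(pos[["C3'"]], pos[["O2'"]], pos[["C1'"]],
                              bl$c_h_chain, an$tet_h, tor[["phi2"]] + 120)
  pos[["H3'b"]] <- nerf_place(pos[["C3'"]], pos[["O2'"]], pos[["C1'"]],
                              bl$c_h_chain, an$tet_h, tor[["phi2"]] - 120)
  pos[["H4'a"]] <- nerf_place(pos[["C4'"]], pos[["C3'"]], pos[["O2'"]],
                              bl$c_h_chain, an$tet_h, tor[["phi3"]] + 120)
  pos[["H4'b"]] <- nerf_place(pos[["C4'"]], pos[["C3'"]], pos[["O2'"]],
                              bl$c_h_chain, an$tet_h, tor[["phi3"]] - 120)

  labels <- names(pos)
  xyz <- do.call(rbind, pos)
  atoms <- data.frame(label = labels, element = element_from_label(labels),
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      stringsAsFactors = FALSE)
  bonds <- rbind(
    data.frame(a1 = c("N1", "C2", "N3", "C4", "C5", "C6", "C5", "N7", "C8",
                      "N9", "C6", "C2", "N2", "N2", "C8",
                      "N9", "C1'", "O2'", "C3'", "C4'", "O5'",
                      "C1'", "C1'", "C3'", "C3'", "C4'", "C4'"),
               a2 = c("C2", "N3", "C4", "C5", "C6", "N1", "N7", "C8", "N9",
                      "C4", "O6", "N2", "H2", "H2'", "H8",
                      "C1'", "O2'", "C3'", "C4'", "O5'", "H5'",
                      "H1'a", "H1'b", "H3'a", "H3'b", "H4'a", "H4'b"),
               stringsAsFactors = FALSE),
    data.frame(a1 = bonds_extra[1L], a2 = bonds_extra[2L],
               stringsAsFactors = FALSE))
  bonds$molecule_id <- 0L
  if (is.null(provenance)) {
    provenance <- sprintf("template %s (phi = %s)", tautomer,
                          paste(sprintf("%.1f", tor), collapse = ", "))
  }
  conformation(atoms, bonds, tautomer_id = tautomer,
               provenance = provenance)
}
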