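# Topology validation against the acyclovir template: the purine bicycle,
# the exocyclic chain N9-C1'-O2'-C3'-C4'-O5'-H5', and the substituents that
# the descriptor set and the hydrogen-bond site inventory rely on.

REQUIRED_ATOMS <- c(PURINE_RING_ATOMS, "N2", "O6",
                    "C1'", "O2'", "C3'", "C4'", "O5'", "H5'")

required_bond_table <- function() {
  data.frame(
    a1 = c("N1", "C2", "N3", "C4", "C5", "C6", "C5", "N7", "C8", "N9",
           "C6", "C2", "N9", "C1'", "O2'", "C3'", "C4'", "O5'"),
    a2 = c("C2", "N3", "C4", "C5", "C6", "N1", "N7", "C8", "N9", "C4",
           "O6", "N2", "C1'", "O2'", "C3'", "C4'", "O5'", "H5'"),
    torsion = c(rep(NA_character_, 12L),
                "phi1", "phi2", "phi3", "phi4", "phi5", NA_character_),
    stringsAsFactors = FALSE)
}

#' Validate a molecular graph against the acyclovir topology
#'
#' Checks, per molecule, that every atom required by the chain-placement
#' descriptors and by the hydrogen-bond site inventory is present with the
#' expected bonding (e.g. N9 bonded to C4, C8 and C1'). Violations are
#' returned as data, not raised as conditions.
#'
#' @param conf a [conformation] (the graph plus coordinates).
#' @return character vector of violations; empty when the topology is valid.
#' @export
#' @examples
#' tmpl <- build_template("N1")
#' validate_topology(tmpl)  # character(0)
validate_topology <- function(conf) {
  out <- character()
  req <- required_bond_table()
  for (m in unique(conf$atoms$molecule_id)) {
    a <- conf$atoms[conf$atoms$molecule_id == m, , drop = FALSE]
    b <- conf$bonds[conf$bonds$molecule_id == m, , drop = FALSE]
    tag <- if (length(unique(conf$atoms$molecule_id)) > 1L)
      sprintf(" (molecule %d)", m) else ""
    missing <- setdiff(REQUIRED_ATOMS, a$label)
    out <- c(out, sprintf("missing atom %s%s", missing, tag))
    # element/label consistency
    expected <- element_from_label(a$label)
    bad <- a$label[expected %in% names(COVALENT_RADII) &
                     expected != a$element]
    out <- c(out, sprintf("element of atom %s inconsistent with its label%s",
                          bad, tag))
    # bonding
    have <- c(paste(b$a1, b$a2, sep = "~"), paste(b$a2, b$a1, sep = "~"))
    for (k in seq_len(nrow(req))) {
      if (!all(c(req$a1[k], req$a2[k]) %in% a$label)) next
      if (!(paste(req$a1[k], req$a2[k], sep = "~") %in% have)) {
        msg <- sprintf("missing bond %s-%s%s", req$a1[k], req$a2[k], tag)
        if (!is.na(req$torsion[k])) {
          msg <- sprintf("%s: torsion %s axis undefined", msg, req$torsion[k])
        }
        out <- c(out, msg)
      }
    }
    # steric sanity: no two atoms closer than 0.3 A
    if (nrow(a) > 1L) {
      d <- as.matrix(stats::dist(a[, c("x", "y", "z")]))
      clash <- which(d < 0.3 & upper.tri(d), arr.ind = TRUE)
      out <- c(out, sprintf("atoms %s and %s closer than 0.3 A%s",
                            a$label[clash[, 1L]], a$label[clash[, 2L]], tag))
    }
  }
  out
}

#' Build Cartesian coordinates from internal coordinates (Z-matrix)
#'
#' Sequential natural-extension placement: atom 1 sits at the origin, atom 2
#' on the x axis, atom 3 in the xy plane; every later atom is placed from
#' three previously defined reference atoms by its bond length, bond angle
#' and torsion. Measured internal coordinates reproduce the inputs to 1e-6
#' Angstrom / 1e-4 degrees.
#'
#' @param zmat data.frame with columns `label`, `ref1`, `ref2`, `ref3`
#'   (labels of earlier atoms; `NA` where not applicable), `bond` (Angstrom,
#'   to `ref1`), `angle` (degrees, atom-ref1-ref2) and `dihedral` (degrees,
#'   atom-ref1-ref2-ref3).
#' @param tautomer_id,provenance passed to [conformation()].
#' @return a [conformation]; bonds connect each atom to its `ref1`.
#' @export
zmatrix_to_cartesian <- function(zmat, tautomer_id = "other",
                                 provenance = "zmatrix") {
  stopifnot(is.data.frame(zmat), nrow(zmat) >= 1L,
            all(c("label", "ref1", "ref2", "ref3",
                  "bond", "angle", "dihedral") %in% names(zmat)))
  n <- nrow(zmat)
  pos <- matrix(NA_real_, n, 3L)
  lookup <- function(lab, row) {
    i <- match(lab, zmat$label[seq_len(row - 1L)])
    if (is.na(i)) {
      stop(sprintf("Z-matrix row %d references '%s' before it is defined",
                   row, lab), call. = FALSE)
    }
    pos[i, ]
  }
  for (i in seq_len(n)) {
    if (i == 1L) {
      pos[i, ] <- c(0, 0, 0)
    } else if (i == 2L) {
      r1 <- lookup(zmat$ref1[i], i)
      pos[i, ] <- r1 + c(zmat$bond[i], 0, 0)
    } else if (i == 3L) {
      r1 <- lookup(zmat$ref1[i], i)
      r2 <- lookup(zmat$ref2[i], i)
      th <- zmat$angle[i]
      if (min(abs(th), abs(180 - th)) < 1e-8) {
        stop("degenerate reference frame: bond angle at row 3 is 0 or 180 degrees",
             call. = FALSE)
      }
      u <- v_unit(r2 - r1)
      w <- v_unit(v_cross(v_cross(u, c(0, 0, 1)), u))
      pos[i, ] <- r1 + zmat$bond[i] *
        (cos(th * pi / 180) * u + sin(th * pi / 180) * w)
    } else {
      r1 <- lookup(zmat$ref1[i], i)
      r2 <- lookup(zmat$ref2[i], i)
      r3 <- lookup(zmat$ref3[i], i)
      th <- zmat$angle[i]
      if (min(abs(th), abs(180 - th)) < 1e-8) {
        stop(sprintf("degenerate reference frame at row %d: bond angle is 0 or 180 degrees", i),
             call. = FALSE)
      }
      ang_ref <- bond_angle(r3, r2, r1)
      if (min(ang_ref, 180 - ang_ref) < 1e-8 * 180 / pi) {
        stop(sprintf("degenerate reference frame at row %d: colinear reference triple", i),
             call. = FALSE)
      }
      pos[i, ] <- nerf_place(r1, r2, r3, zmat$bond[i], th, zmat$dihedral[i])
    }
  }
  atoms <- data.frame(label = zmat$label,
                      element = element_from_label(zmat$label),
                      x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                      stringsAsFactors = FALSE)
  keep <- !is.na(zmat$ref1)
  bonds <- data.frame(a1 = zmat$label[keep], a2 = zmat$ref1[keep],
                      molecule_id = 0L, stringsAsFactors = FALSE)
  conformation(atoms, bonds, tautomer_id = tautomer_id,
               provenance = provenance)
}
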