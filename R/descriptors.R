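# Chain-placement descriptors of an acyclovir-like conformation:
#   phi1 (C4-N9-C1'-O2')   base orientation about the glycosidic-like bond
#   phi2 (N9-C1'-O2'-C3')  \
#   phi3 (C1'-O2'-C3'-C4')  > folds of the acyclic chain
#   phi4 (O2'-C3'-C4'-O5') /
#   phi5 (C3'-C4'-O5'-H5') hydroxyl hydrogen orientation
# plus the pseudo-bond placement of the hydroxyl end relative to the base:
#   R (N9...O5'), beta (C4-N9...O5'), Phi (C1'-N9...O5') with vertex at N9.

TORSION_DEFS <- list(
  phi1 = c("C4", "N9", "C1'", "O2'"),
  phi2 = c("N9", "C1'", "O2'", "C3'"),
  phi3 = c("C1'", "O2'", "C3'", "C4'"),
  phi4 = c("O2'", "C3'", "C4'", "O5'"),
  phi5 = c("C3'", "C4'", "O5'", "H5'"))

NU_DEFS <- list(
  nu0 = c("N1", "C2", "N3", "C4"),
  nu1 = c("C2", "N3", "C4", "C5"),
  nu2 = c("N3", "C4", "C5", "C6"),
  nu3 = c("N7", "C8", "N9", "C4"),
  nu4 = c("C6", "N1", "C2", "N3"))

torsion_labels <- function(torsion) {
  if (is.character(torsion) && length(torsion) == 4L) return(torsion)
  if (is.character(torsion) && length(torsion) == 1L &&
      torsion %in% names(TORSION_DEFS)) {
    return(TORSION_DEFS[[torsion]])
  }
  stop("torsion must be one of ", paste(names(TORSION_DEFS), collapse = ", "),
       " or a vector of four atom labels", call. = FALSE)
}

#' Measure a named torsion of a conformation
#'
#' @param conf a [conformation].
#' @param torsion one of `"phi1"`..`"phi5"`, or four atom labels.
#' @param molecule_id molecule within an assembly.
#' @return torsion in degrees, `(-180, 180]`.
#' @export
measure_torsion <- function(conf, torsion, molecule_id = 0L) {
  lab <- torsion_labels(torsion)
  p <- lapply(lab, atom_xyz, conf = conf, molecule_id = molecule_id)
  dihedral_angle(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
}

#' Compute the eight chain-placement descriptors
#'
#' A pure function of the coordinates: the five exocyclic torsions phi1-phi5,
#' the pseudo-bond distance R = N9...O5' and the angles beta (C4-N9...O5')
#' and Phi (C1'-N9...O5'), both with vertex at N9.
#'
#' @param conf a [conformation].
#' @param molecule_id molecule within an assembly (default 0).
#' @param name row label for the output (defaults to the provenance).
#' @return one-row data.frame with columns
#'   `name, R, beta, Phi, phi1, phi2, phi3, phi4, phi5` (Angstrom / degrees).
#' @export
descriptor_set <- function(conf, molecule_id = 0L, name = NULL) {
  needed <- unique(c(unlist(TORSION_DEFS), "C4", "N9", "C1'", "O5'"))
  present <- conf$atoms$label[conf$atoms$molecule_id == molecule_id]
  missing <- setdiff(needed, present)
  if (length(missing)) {
    stop("descriptor error: missing atom(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g <- function(lab) atom_xyz(conf, lab, molecule_id)
  phis <- vapply(names(TORSION_DEFS), function(t)
    measure_torsion(conf, t, molecule_id), numeric(1L))
  out <- data.frame(
    name = if (is.null(name)) conf$provenance else name,
    R = v_norm(g("N9") - g("O5'")),
    beta = bond_angle(g("C4"), g("N9"), g("O5'")),
    Phi = bond_angle(g("C1'"), g("N9"), g("O5'")),
    stringsAsFactors = FALSE)
  out[names(TORSION_DEFS)] <- as.list(phis)
  out
}

#' Flag ring-planarity deviations
#'
#' Helper shared by [base_nonplanarity()]: given the five nu dihedrals,
#' returns the maximum absolute deviation and which dihedrals exceed the
#' threshold.
#'
#' @param nu named numeric vector of the five nu dihedrals (degrees).
#' @param threshold flagging threshold, degrees (default 1).
#' @return list with `max_abs` and `flagged` (character vector of names).
#' @export
#' @examples
#' planarity_flags(c(nu0 = -1.3, nu1 = 2.8, nu2 = -2.3, nu3 = 0.2, nu4 = 0.5))
planarity_flags <- function(nu, threshold = 1.0) {
  list(max_abs = max(abs(nu)), flagged = names(nu)[abs(nu) > threshold])
}

#' Purine-ring nonplanarity dihedrals
#'
#' Computes the five dihedrals quantifying nonplanarity of the purine
#' heterocycle: nu0 (N1-C2-N3-C4), nu1 (C2-N3-C4-C5), nu2 (N3-C4-C5-C6),
#' nu3 (N7-C8-N9-C4) and nu4 (C6-N1-C2-N3).
#'
#' @param conf a [conformation] containing the nine purine atoms.
#' @param threshold deviations above this many degrees are flagged
#'   (default 1, the conventional "essentially planar" cutoff).
#' @param molecule_id molecule within an assembly.
#' @return an object of class `ring_planarity`: list with `nu` (named
#'   vector), `max_abs`, `flagged` and `threshold`.
#' @export
base_nonplanarity <- function(conf, threshold = 1.0, molecule_id = 0L) {
  present <- conf$atoms$label[conf$atoms$molecule_id == molecule_id]
  missing <- setdiff(PURINE_RING_ATOMS, present)
  if (length(missing)) {
    stop("descriptor error: missing ring atom(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nu <- vapply(NU_DEFS, function(lab) measure_torsion(conf, lab, molecule_id),
               numeric(1L))
  fl <- planarity_flags(nu, threshold)
  structure(list(nu = nu, max_abs = fl$max_abs, flagged = fl$flagged,
                 threshold = threshold),
            class = "ring_planarity")
}

#' @export
print.ring_planarity <- function(x, ...) {
  cat("purine ring nonplanarity (degrees):\n")
  print(round(x$nu, 3))
  cat(sprintf("max |nu| = %.3f; flagged (>%g deg): %s\n", x$max_abs,
              x$threshold,
              if (length(x$flagged)) paste(x$flagged, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Drive a torsion to a target value
#'
#' Rigidly rotates the distal fragment about the torsion's bond axis so the
#' torsion takes `value`; atoms on the non-rotating side are unmoved and all
#' bond lengths and angles are preserved. The axis must partition the
#' molecule in two (rotations about ring bonds are refused).
#'
#' @param conf a [conformation].
#' @param torsion one of `"phi1"`..`"phi5"`, or four atom labels a,b,c,d
#'   (axis b-c, the c-side fragment rotates).
#' @param value target torsion, degrees.
#' @param molecule_id molecule within an assembly.
#' @return the modified conformation.
#' @export
set_torsion <- function(conf, torsion, value, molecule_id = 0L) {
  lab <- torsion_labels(torsion)
  ib <- atom_index(conf, lab[2L], molecule_id)
  ic <- atom_index(conf, lab[3L], molecule_id)
  adj <- bond_adjacency(conf)
  if (!(ic %in% adj[[ib]])) {
    stop(sprintf("torsion axis %s-%s is not a bond", lab[2L], lab[3L]),
         call. = FALSE)
  }
  side_c <- reachable_atoms(adj, ic, drop_edge = c(ib, ic))
  if (ib %in% side_c) {
    stop(sprintf("topology error: axis %s-%s lies on a ring and does not bipartition the molecule",
                 lab[2L], lab[3L]), call. = FALSE)
  }
  current <- measure_torsion(conf, lab, molecule_id)
  delta <- wrap_angle(value - current)
  if (abs(delta) < 1e-12) return(conf)
  b <- atom_xyz(conf, lab[2L], molecule_id)
  cc <- atom_xyz(conf, lab[3L], molecule_id)
  move <- setdiff(side_c, ic)
  if (length(move)) {
    xyz <- as.matrix(conf$atoms[move, c("x", "y", "z"), drop = FALSE])
    conf$atoms[move, c("x", "y", "z")] <-
      rotate_points(xyz, cc, cc - b, delta)
  }
  conf
}

#' Set several chain torsions at once
#'
#' @param conf a [conformation].
#' @param values named numeric vector, names among `phi1`..`phi5`.
#' @param molecule_id molecule within an assembly.
#' @return the modified conformation.
#' @export
set_chain_torsions <- function(conf, values, molecule_id = 0L) {
  stopifnot(!is.null(names(values)),
            all(names(values) %in% names(TORSION_DEFS)))
  for (nm in names(values)) {
    conf <- set_torsion(conf, nm, values[[nm]], molecule_id)
  }
  conf
}
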