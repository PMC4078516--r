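# Posed assemblies for hydrogen-bond analysis. The reference multimer
# coordinates are not published, so these are synthetic poses constructed to
# realize stated contact distances exactly; they are labeled as such in
# their provenance.

#' Pose a symmetric, doubly hydrogen-bonded dimer
#'
#' Builds two copies of the monomer template related by point inversion, so
#' that the pairing contacts H1(A)...O6(B) and H1(B)...O6(A) both measure
#' exactly `distance` with a linear N1-H1...O6 arrangement -- the reciprocal
#' N1-H...O6 motif of the base-paired dimer.
#'
#' @param distance target H1...O6 distance, Angstrom (default 1.733, a
#'   reported dimer contact).
#' @param tautomer template tautomer (default `"N1"`; the donor H1 must
#'   exist).
#' @param torsions optional chain torsions passed to [build_template()].
#' @return a two-molecule [conformation] with molecule ids 0 and 1.
#' @export
build_hbond_dimer <- function(distance = 1.733, tautomer = "N1",
                              torsions = NULL) {
  a <- build_template(tautomer, torsions)
  if (!"H1" %in% a$atoms$label) {
    stop("dimer pose requires the H1 donor (tautomer N1)", call. = FALSE)
  }
  h1 <- atom_xyz(a, "H1")
  n1 <- atom_xyz(a, "N1")
  o6 <- atom_xyz(a, "O6")
  u <- v_unit(h1 - n1)
  centre <- (h1 + distance * u + o6) / 2
  b <- a
  b$atoms[, c("x", "y", "z")] <-
    sweep(-as.matrix(a$atoms[, c("x", "y", "z")]), 2L, 2 * centre, "+")
  assemble_molecules(a, b,
                     provenance = sprintf(
                       "synthetic inversion dimer, H1...O6 = %.3f A", distance))
}

#' Pose the monomer so an H5' contact takes a target distance
#'
#' Scans one chain torsion (phi5 by default, then refines continuously) so
#' the distance from H5' to the requested acceptor matches `distance` as
#' closely as the torsion allows. Used to construct the intramolecular
#' H-bond motifs -- type (i) H5'...N3, type (ii) H5'...O2' -- at stated
#' distances.
#'
#' @param acceptor acceptor atom label (`"N3"` or `"O2'"`).
#' @param distance target H5'...acceptor distance, Angstrom.
#' @param base a starting [conformation] (default the N1 template at its
#'   default torsions).
#' @param torsion which torsion to drive (default `"phi5"`).
#' @return the posed conformation; attribute `achieved` records the final
#'   distance.
#' @export
pose_h5p_contact <- function(acceptor = "N3", distance = 1.9,
                             base = build_template("N1"),
                             torsion = "phi5") {
  objective <- function(v) {
    conf <- set_torsion(base, torsion, v)
    abs(v_norm(atom_xyz(conf, "H5'") - atom_xyz(conf, acceptor)) - distance)
  }
  coarse <- seq(-179, 180, by = 1)
  best <- coarse[which.min(vapply(coarse, objective, numeric(1L)))]
  opt <- stats::optimize(objective, lower = best - 1.5, upper = best + 1.5,
                         tol = 1e-8)
  conf <- set_torsion(base, torsion, opt$minimum)
  conf$provenance <- sprintf("synthetic pose, H5'...%s target %.3f A",
                             acceptor, distance)
  attr(conf, "achieved") <-
    v_norm(atom_xyz(conf, "H5'") - atom_xyz(conf, acceptor))
  conf
}
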