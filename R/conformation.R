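# The geometric substrate: labeled atoms + bonds + Cartesian coordinates.
# A "conformation" bundles the molecular graph with one coordinate snapshot;
# multimer assemblies carry per-atom molecule_id (0-based, 0 for monomers).

COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39)

# canonical atom names of the acyclovir template (Figure-1 style numbering)
PURINE_RING_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
CHAIN_ATOMS <- c("C1'", "O2'", "C3'", "C4'", "O5'", "H5'")

# label aliases seen in crystallographic files (prime chars normalized first)
LABEL_ALIASES <- c("H(N1)" = "H1", "H(N2)" = "H2", "H(N2')" = "H2'",
                   "H(O5')" = "H5'", "O5*" = "O5'", "O2*" = "O2'",
                   "C1*" = "C1'", "C3*" = "C3'", "C4*" = "C4'")

element_from_label <- function(label) {
  el <- sub("^([A-Za-z]+).*$", "\\1", label)
  el <- paste0(toupper(substr(el, 1L, 1L)), tolower(substr(el, 2L, 2L)))
  # single-letter organic elements dominate here; "Cl"/"Br" pass through
  ifelse(el %in% c("Cl", "Br"), el, substr(el, 1L, 1L))
}

#' Construct a conformation
#'
#' @param atoms data.frame with columns `label`, `element`, `x`, `y`, `z`,
#'   and optionally `molecule_id` (default 0) and `charge` (partial charges,
#'   electron units; input-only, never computed here).
#' @param bonds data.frame with columns `a1`, `a2` (atom labels) and
#'   optionally `molecule_id`; bonds join atoms within one molecule.
#' @param tautomer_id one of `"N1"`, `"N3"`, `"N7"`, `"OHC"`, `"OHT"` or
#'   `"other"`.
#' @param provenance free-text origin (source file, generator seed, search
#'   label).
#' @return an object of class `conformation`.
#' @export
conformation <- function(atoms, bonds, tautomer_id = "other",
                         provenance = "") {
  stopifnot(is.data.frame(atoms),
            all(c("label", "element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$molecule_id)) atoms$molecule_id <- 0L
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atomic coordinates", call. = FALSE)
  }
  key <- paste(atoms$molecule_id, atoms$label)
  if (anyDuplicated(key)) {
    stop("duplicated atom label within a molecule: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(a1 = character(), a2 = character(),
                        molecule_id = integer())
  }
  if (is.null(bonds$molecule_id)) bonds$molecule_id <- 0L
  bonds$molecule_id <- as.integer(bonds$molecule_id)
  bkey1 <- paste(bonds$molecule_id, bonds$a1)
  bkey2 <- paste(bonds$molecule_id, bonds$a2)
  if (!all(c(bkey1, bkey2) %in% key)) {
    bad <- setdiff(c(bkey1, bkey2), key)
    stop("bond endpoint not present among atoms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(atoms = atoms, bonds = bonds,
                 tautomer_id = tautomer_id, provenance = provenance),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  nm <- length(unique(x$atoms$molecule_id))
  cat(sprintf("<conformation> %d atoms, %d bonds, %d molecule(s), tautomer %s\n",
              nrow(x$atoms), nrow(x$bonds), nm, x$tautomer_id))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

coords_matrix <- function(conf) {
  m <- as.matrix(conf$atoms[, c("x", "y", "z")])
  rownames(m) <- paste(conf$atoms$molecule_id, conf$atoms$label)
  m
}

atom_index <- function(conf, label, molecule_id = 0L) {
  i <- which(conf$atoms$label == label & conf$atoms$molecule_id == molecule_id)
  if (length(i) != 1L) {
    stop(sprintf("atom '%s' (molecule %d) not found", label, molecule_id),
         call. = FALSE)
  }
  i
}

#' Position of a named atom
#'
#' @param conf a [conformation].
#' @param label canonical atom name, e.g. `"N9"`, `"O5'"`.
#' @param molecule_id molecule within a multimer assembly (default 0).
#' @return numeric length-3 coordinate vector (Angstrom).
#' @export
atom_xyz <- function(conf, label, molecule_id = 0L) {
  i <- atom_index(conf, label, molecule_id)
  as.numeric(conf$atoms[i, c("x", "y", "z")])
}

#' Distance between two named atoms
#' @inheritParams atom_xyz
#' @param label1,label2 atom names.
#' @param mol1,mol2 their molecule ids.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(conf, label1, label2, mol1 = 0L, mol2 = mol1) {
  v_norm(atom_xyz(conf, label1, mol1) - atom_xyz(conf, label2, mol2))
}

# adjacency list (indices into conf$atoms) of the covalent bond graph
bond_adjacency <- function(conf) {
  n <- nrow(conf$atoms)
  adj <- vector("list", n)
  if (nrow(conf$bonds)) {
    i1 <- mapply(atom_index, label = conf$bonds$a1,
                 molecule_id = conf$bonds$molecule_id,
                 MoreArgs = list(conf = conf))
    i2 <- mapply(atom_index, label = conf$bonds$a2,
                 molecule_id = conf$bonds$molecule_id,
                 MoreArgs = list(conf = conf))
    for (k in seq_along(i1)) {
      adj[[i1[k]]] <- c(adj[[i1[k]]], i2[k])
      adj[[i2[k]]] <- c(adj[[i2[k]]], i1[k])
    }
  }
  adj
}

# connected component (atom indices) reachable from `start`, optionally with
# one edge removed (used for torsion bipartition)
reachable_atoms <- function(adj, start, drop_edge = NULL) {
  n <- length(adj)
  seen <- logical(n)
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (!is.null(drop_edge) &&
          ((cur == drop_edge[1L] && nb == drop_edge[2L]) ||
           (cur == drop_edge[2L] && nb == drop_edge[1L]))) next
      if (!seen[nb]) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  which(seen)
}

# infer covalent bonds: distance < factor * (sum of covalent radii)
infer_bonds <- function(atoms, factor = 1.6) {
  n <- nrow(atoms)
  if (n < 2L) {
    return(data.frame(a1 = character(), a2 = character(),
                      molecule_id = integer()))
  }
  radii <- COVALENT_RADII[atoms$element]
  if (anyNA(radii)) {
    stop("unknown element symbol: ",
         paste(unique(atoms$element[is.na(radii)]), collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(radii, radii, "+") * factor
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  data.frame(i = hit[, 1L], j = hit[, 2L])
}

#' Apply a rigid motion to a conformation
#'
#' Rotates all atoms about an axis through `origin` and then translates them.
#' Used mainly to pose molecules in assemblies and to test rigid-motion
#' invariance of descriptors and energies.
#'
#' @param conf a [conformation].
#' @param angle rotation angle, degrees (right-hand rule about `axis`).
#' @param axis rotation axis direction (length-3).
#' @param origin point on the axis.
#' @param translate translation vector applied after the rotation.
#' @param molecule_id if given, only that molecule is moved.
#' @return the transformed conformation.
#' @export
transform_conformation <- function(conf, angle = 0, axis = c(0, 0, 1),
                                   origin = c(0, 0, 0),
                                   translate = c(0, 0, 0),
                                   molecule_id = NULL) {
  sel <- if (is.null(molecule_id)) seq_len(nrow(conf$atoms)) else
    which(conf$atoms$molecule_id == molecule_id)
  xyz <- as.matrix(conf$atoms[sel, c("x", "y", "z")])
  if (angle != 0) xyz <- rotate_points(xyz, origin, axis, angle)
  xyz <- sweep(xyz, 2L, translate, "+")
  conf$atoms[sel, c("x", "y", "z")] <- xyz
  conf
}

#' Combine monomer conformations into a multimer assembly
#'
#' @param ... conformations; each becomes one molecule, renumbered 0, 1, ...
#' @param provenance provenance string of the assembly.
#' @return a multi-molecule [conformation].
#' @export
assemble_molecules <- function(..., provenance = "assembly") {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  atoms <- list(); bonds <- list()
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    a <- p$atoms; a$molecule_id <- k - 1L
    b <- p$bonds; if (nrow(b)) b$molecule_id <- k - 1L
    atoms[[k]] <- a; bonds[[k]] <- b
  }
  conformation(do.call(rbind, atoms), do.call(rbind, bonds),
               tautomer_id = parts[[1L]]$tautomer_id,
               provenance = provenance)
}
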