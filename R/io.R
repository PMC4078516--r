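# Coordinate file I/O. XYZ is the primary format (count / comment / records);
# a file holding several XYZ frames is read as one molecule per frame, which
# is the package's multimer convention since plain XYZ has no chain field.
# A minimal read-only PDB v3 subset (ATOM/HETATM) is provided for crystal
# files; prime characters are normalized (O5* -> O5').

parse_xyz_frames <- function(lines, path) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0L) {
      stop(sprintf("XYZ parse error in '%s' at line %d: expected an atom count, got '%s'",
                   path, i, lines[i]), call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop(sprintf("XYZ parse error in '%s': frame starting at line %d declares %d atoms but the file ends early",
                   path, i, n), call. = FALSE)
    }
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    rec <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(rec), "[[:space:]]+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad)) {
      stop(sprintf("XYZ parse error in '%s' at line %d: expected 'element x y z'",
                   path, i + 1L + bad[1L]), call. = FALSE)
    }
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3L)))
    if (anyNA(xyz)) {
      stop(sprintf("XYZ parse error in '%s': non-numeric coordinate in frame starting at line %d",
                   path, i), call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- list(element = el, xyz = xyz,
                                          comment = comment)
    i <- i + 2L + n
  }
  if (!length(frames)) {
    stop(sprintf("XYZ parse error: '%s' contains no frames", path),
         call. = FALSE)
  }
  frames
}

auto_labels <- function(elements) {
  idx <- stats::ave(seq_along(elements), elements, FUN = seq_along)
  paste0(elements, idx)
}

resolve_label_map <- function(label_map) {
  if (is.null(label_map)) return(NULL)
  if (is.character(label_map) && length(label_map) == 1L &&
      file.exists(label_map)) {
    tab <- utils::read.table(label_map, header = FALSE, quote = "",
                             stringsAsFactors = FALSE,
                             col.names = c("from", "to"))
    label_map <- stats::setNames(tab$to, tab$from)
  }
  if (is.null(names(label_map))) {
    stop("label_map must be a named character vector (auto label -> canonical label) or a two-column file",
         call. = FALSE)
  }
  label_map
}

#' Read an XYZ coordinate file
#'
#' Reads the count/comment/records XYZ dialect. A file containing several
#' frames is interpreted as a multimer assembly, one molecule per frame
#' (explicit block markers take precedence over inference); a single-frame
#' file is split into molecules by connected components of the covalent bond
#' graph (bond when the distance is below `bond_factor` times the sum of
#' covalent radii).
#'
#' @param path file path.
#' @param label_map optional named character vector (or two-column text file)
#'   mapping auto-generated labels (element + ordinal per molecule, e.g.
#'   `"N5"`) to canonical names (e.g. `"N9"`). Must cover all atoms; when
#'   omitted, auto-generated labels are kept.
#' @param bond_factor multiplier on the covalent-radius sum used for bond
#'   inference (default 1.6).
#' @return a [conformation]; atoms appear in file order.
#' @export
read_xyz <- function(path, label_map = NULL, bond_factor = 1.6) {
  lines <- readLines(path, warn = FALSE)
  frames <- parse_xyz_frames(lines, path)
  label_map <- resolve_label_map(label_map)

  atoms <- list()
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    el <- element_from_label(fr$element)
    if (!all(el %in% names(COVALENT_RADII))) {
      stop(sprintf("XYZ parse error in '%s': unknown element symbol '%s'",
                   path, setdiff(el, names(COVALENT_RADII))[1L]),
           call. = FALSE)
    }
    lab <- auto_labels(el)
    if (!is.null(label_map)) {
      missing <- setdiff(lab, names(label_map))
      if (length(missing)) {
        stop("labeling error: label_map does not cover atom(s) ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      lab <- unname(label_map[lab])
    }
    atoms[[k]] <- data.frame(label = lab, element = el,
                             x = fr$xyz[, 1L], y = fr$xyz[, 2L],
                             z = fr$xyz[, 3L],
                             molecule_id = k - 1L,
                             stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms)

  if (length(frames) == 1L) {
    # split one frame into molecules by covalent connectivity
    eb <- infer_bonds(atoms, bond_factor)
    n <- nrow(atoms)
    adj <- vector("list", n)
    for (k in seq_len(nrow(eb))) {
      adj[[eb$i[k]]] <- c(adj[[eb$i[k]]], eb$j[k])
      adj[[eb$j[k]]] <- c(adj[[eb$j[k]]], eb$i[k])
    }
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (s in seq_len(n)) {
      if (is.na(comp[s])) {
        comp[reachable_atoms(adj, s)] <- cid
        cid <- cid + 1L
      }
    }
    atoms$molecule_id <- comp
    if (cid > 1L) {
      # relabel per molecule so labels stay unique within molecules
      if (is.null(label_map)) {
        for (m in unique(comp)) {
          sel <- atoms$molecule_id == m
          atoms$label[sel] <- auto_labels(atoms$element[sel])
        }
      }
    }
  }

  bonds <- list()
  for (m in unique(atoms$molecule_id)) {
    sel <- which(atoms$molecule_id == m)
    eb <- infer_bonds(atoms[sel, , drop = FALSE], bond_factor)
    if (nrow(eb)) {
      bonds[[length(bonds) + 1L]] <-
        data.frame(a1 = atoms$label[sel[eb$i]], a2 = atoms$label[sel[eb$j]],
                   molecule_id = m, stringsAsFactors = FALSE)
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else NULL
  conformation(atoms, bonds, provenance = path)
}

#' Write a conformation to an XYZ file
#'
#' Multimer assemblies are written as one XYZ frame per molecule so that
#' [read_xyz()] recovers the molecule ids. Coordinates are printed with 12
#' decimals; the round trip preserves positions to well below 1e-6 Angstrom.
#'
#' @param conf a [conformation].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_xyz <- function(conf, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot open '", path, "' for writing", call. = FALSE)
  }
  on.exit(close(con))
  for (m in unique(conf$atoms$molecule_id)) {
    a <- conf$atoms[conf$atoms$molecule_id == m, , drop = FALSE]
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("molecule %d | %s", m, conf$provenance), con)
    writeLines(sprintf("%-2s %20.12f %20.12f %20.12f",
                       a$element, a$x, a$y, a$z), con)
  }
  invisible(path)
}

#' Read a PDB file (minimal v3 subset, read-only)
#'
#' Parses ATOM/HETATM records only. Atom names are taken verbatim from the
#' atom-name column after prime normalization (`*` becomes `'`) and alias
#' resolution (`H(N1)` style names become `H1`). Chains map to molecule ids
#' in order of appearance.
#'
#' @param path file path.
#' @param bond_factor covalent bond inference threshold factor.
#' @return a [conformation].
#' @export
read_pdb <- function(path, bond_factor = 1.6) {
  lines <- readLines(path, warn = FALSE)
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("no ATOM/HETATM records in '", path, "'", call. = FALSE)
  name <- trimws(substr(rec, 13L, 16L))
  chain <- substr(rec, 22L, 22L)
  x <- as.numeric(substr(rec, 31L, 38L))
  y <- as.numeric(substr(rec, 39L, 46L))
  z <- as.numeric(substr(rec, 47L, 54L))
  if (anyNA(c(x, y, z))) stop("unparseable coordinates in '", path, "'", call. = FALSE)
  el <- trimws(substr(rec, 77L, 78L))
  name <- gsub("\\*", "'", name)
  name <- ifelse(name %in% names(LABEL_ALIASES), LABEL_ALIASES[name], name)
  el <- ifelse(nzchar(el), paste0(toupper(substr(el, 1L, 1L)),
                                  tolower(substr(el, 2L, 2L))),
               element_from_label(name))
  mol <- as.integer(factor(chain, levels = unique(chain))) - 1L
  atoms <- data.frame(label = name, element = el, x = x, y = y, z = z,
                      molecule_id = mol, stringsAsFactors = FALSE)
  bonds <- list()
  for (m in unique(mol)) {
    sel <- which(mol == m)
    eb <- infer_bonds(atoms[sel, , drop = FALSE], bond_factor)
    if (nrow(eb)) {
      bonds[[length(bonds) + 1L]] <-
        data.frame(a1 = atoms$label[sel[eb$i]], a2 = atoms$label[sel[eb$j]],
                   molecule_id = m, stringsAsFactors = FALSE)
    }
  }
  conformation(atoms, if (length(bonds)) do.call(rbind, bonds) else NULL,
               provenance = path)
}
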