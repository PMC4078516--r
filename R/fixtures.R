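# Packaged fixtures: transcriptions of the reference tautomer table
# (table1_tautomers.tsv), the 78-conformer table (table2_conformers.tsv, at
# three levels of theory) and the dimer/tetramer/crystal descriptor rows
# (table4_solid.tsv). All ship inside the package; loading them needs no
# network access.

#' Path to a packaged fixture
#'
#' @param name fixture file name, e.g. `"table2_conformers.tsv"`; with no
#'   argument, lists the available fixtures.
#' @return file path (or a character vector of names).
#' @export
acv_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "acvconf")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    stop("no packaged fixture named '", name, "'", call. = FALSE)
  }
  path
}

#' Load the tautomer table fixture
#'
#' Five tautomers (N1, N3, N7 keto; OHC, OHT enol) with descriptors, dipole
#' moments and relative energies at the requested level of theory.
#'
#' @param level level-of-theory tag (default the B3LYP/6-31G(d,p) column,
#'   the only one carrying both dE and dG for all five tautomers).
#' @return a `conformer_table` with 5 records.
#' @export
tautomer_table <- function(level = "B3LYP/6-31G(d,p)") {
  suppressWarnings(
    read_conformer_table(acv_fixture("table1_tautomers.tsv"), level = level))
}

#' Load the 78-conformer table fixture
#'
#' @param level level-of-theory tag; `"B3LYP/6-31G(d,p)"` (default) carries
#'   all 78 conformers, `"MP2/6-31G(d)"` and `"B3LYP/6-311++G(3df,pd)"` the
#'   nine main ones (A1-A4, B1-B5).
#' @return a `conformer_table`.
#' @export
conformer_table_fixture <- function(level = "B3LYP/6-31G(d,p)") {
  suppressWarnings(
    read_conformer_table(acv_fixture("table2_conformers.tsv"), level = level))
}

#' Load the solid-state descriptor fixture
#'
#' Descriptor rows of the simulated dimer/tetramer molecules and the crystal
#' molecules. The printed `Phi` column repeats the `phi1` value for the
#' calculated rows (an apparent transcription artifact in the source, stored
#' as printed); the `Phi_equals_phi1` flag column marks those rows.
#'
#' @return a data.frame.
#' @export
solid_state_table <- function() {
  path <- acv_fixture("table4_solid.tsv")
  lines <- normalize_numeric_text(readLines(path, warn = FALSE,
                                            encoding = "UTF-8"))
  utils::read.table(text = lines, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
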