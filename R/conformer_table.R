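# Conformer/tautomer tables: one record per optimized species with its
# descriptors, dipole moment (input-only), relative electronic energy
# including ZPE (dE, kcal/mol) and relative Gibbs energy (dG, kcal/mol).

CONFORMER_COLUMNS <- c("name", "R", "beta", "Phi",
                       "phi1", "phi2", "phi3", "phi4", "phi5",
                       "mu", "dE", "dG")

# normalize transcription artifacts: Unicode minus / dashes, thin spaces
normalize_numeric_text <- function(x) {
  x <- gsub("−|–|—", "-", x)
  gsub(" | ", "", x)
}

new_conformer_table <- function(df, level = NA_character_, provenance = "") {
  attr(df, "level") <- level
  attr(df, "provenance") <- provenance
  class(df) <- c("conformer_table", "data.frame")
  df
}

#' Read a conformer or tautomer table from delimited text
#'
#' Expects a UTF-8 comma- or tab-delimited file with a header containing the
#' canonical column names `name,R,beta,Phi,phi1,phi2,phi3,phi4,phi5,mu,dE,dG`
#' (extra columns, e.g. `level`, are kept). Unicode minus signs and thin
#' spaces are normalized at parse time. When `level` is given and the table
#' carries a `level` column, rows of other levels are skipped with a warning.
#'
#' @param path file path.
#' @param level optional level-of-theory tag, e.g. `"B3LYP/6-31G(d,p)"`.
#' @return a `conformer_table` (data.frame subclass) with attributes `level`
#'   and `provenance`.
#' @export
read_conformer_table <- function(path, level = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("schema error: '", path, "' has no header or no data rows",
         call. = FALSE)
  }
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  lines <- normalize_numeric_text(lines)
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          quote = "\"", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  missing <- setdiff(CONFORMER_COLUMNS, names(df))
  if (length(missing)) {
    stop("schema error: '", path, "' lacks mandatory column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(CONFORMER_COLUMNS, "name")
  for (cn in num_cols) {
    raw <- df[[cn]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(trimws(as.character(raw))) & is.na(val))
    if (length(bad)) {
      stop(sprintf("row error in '%s' line %d: unparseable numeric '%s' in column %s",
                   path, bad[1L] + 1L, raw[bad[1L]], cn), call. = FALSE)
    }
    df[[cn]] <- val
  }
  if (!is.null(level)) {
    if ("level" %in% names(df)) {
      keep <- df$level == level
      if (sum(!keep)) {
        warning(sprintf("skipping %d row(s) not at level '%s'",
                        sum(!keep), level), call. = FALSE)
      }
      df <- df[keep, , drop = FALSE]
      rownames(df) <- NULL
    }
  } else if ("level" %in% names(df)) {
    level <- NA_character_
  }
  if (!nrow(df)) {
    stop("schema error: no rows at level '", level, "' in '", path, "'",
         call. = FALSE)
  }
  dup <- df$name[duplicated(paste(df$name, df$level %||% ""))]
  if (length(dup)) {
    stop("record names not unique per level: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  new_conformer_table(df, level = level %||% NA_character_,
                      provenance = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify conformers as A/anti or B/syn
#'
#' The sign of the glycosidic-like torsion phi1 splits the conformational
#' space: class A (orientation anti) when phi1 < 0, class B (syn) when
#' phi1 > 0. phi1 exactly 0 is refused rather than guessed.
#'
#' @param x a `conformer_table` (or any data.frame with a `phi1` column), or
#'   a numeric vector of phi1 values.
#' @return for a table: the table with `class` and `orientation` columns
#'   appended; for a numeric vector: a data.frame with those two columns.
#' @export
#' @examples
#' classify_conformer(c(-74.1, 73.5))
classify_conformer <- function(x) {
  phi1 <- if (is.data.frame(x)) x$phi1 else x
  if (is.null(phi1)) stop("phi1 is not defined", call. = FALSE)
  if (any(!is.na(phi1) & phi1 == 0)) {
    stop("unclassifiable: phi1 is exactly 0 for record(s) ",
         paste(which(phi1 == 0), collapse = ", "), call. = FALSE)
  }
  cls <- ifelse(phi1 < 0, "A", "B")
  ori <- ifelse(phi1 < 0, "anti", "syn")
  if (is.data.frame(x)) {
    x$class <- cls
    x$orientation <- ori
    x
  } else {
    data.frame(class = cls, orientation = ori, stringsAsFactors = FALSE)
  }
}
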