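#' Table schemas used across the pipeline
#'
#' Every table the pipeline reads or writes is long-format TSV with a one-line
#' header. Missing values are serialized as empty fields; zeros are treated as
#' measured intensities. Wide profile matrices (one column per fraction,
#' `F1..Fn`) are accepted for the `profile` schema and converted to long form
#' on read.
#'
#' @format A named list; each entry gives `required` column names and the
#'   names of columns holding non-negative intensities.
#' @keywords internal
table_schemas <- list(
  peptide  = list(required = c("protein", "peptide", "condition", "replicate", "intensity"),
                  intensity = "intensity"),
  protein  = list(required = c("protein", "condition", "replicate", "intensity"),
                  intensity = "intensity"),
  profile  = list(required = c("entity_id", "entity_kind", "fraction", "intensity"),
                  intensity = "intensity"),
  fragment = list(required = c("peptide", "channel", "fragment", "rt", "area", "sn"),
                  intensity = c("area", "sn")),
  ppi      = list(required = c("protein_a", "protein_b", "evidence"),
                  intensity = character()),
  scores   = list(required = c("protein", "score"),
                  intensity = character())
)

#' Read a pipeline table
#'
#' Reads a TSV (or CSV) file against one of the declared schemas, with typed
#' columns and explicit missing values: empty fields become `NA`, never zero.
#' For the `profile` schema a wide entity-by-fraction matrix with columns
#' `F1..Fn` is accepted and pivoted to long form.
#'
#' @param path Path to a TSV/CSV file with a one-line header.
#' @param schema One of `"peptide"`, `"protein"`, `"profile"`, `"fragment"`,
#'   `"ppi"`, `"scores"`.
#' @return A tibble with the schema's columns; intensity columns are numeric
#'   with `NA` for missing.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("protein\tcondition\treplicate\tintensity",
#'              "A\tctrl\t1\t100", "A\tctrl\t2\t"), f)
#' read_table(f, "protein")
#' @export
read_table <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  abort_if(!file.exists(path), paste0("file not found: ", path))
  sc <- table_schemas[[schema]]
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, na = "", trim_ws = TRUE,
                          show_col_types = FALSE, progress = FALSE)
  if (schema == "profile" && !"fraction" %in% names(df) &&
      any(grepl("^F[0-9]+$", names(df)))) {
    df <- wide_to_long_profiles(df)
  }
  missing_cols <- setdiff(sc$required, names(df))
  abort_if(length(missing_cols) > 0,
           paste0("schema '", schema, "' is missing required column(s): ",
                  paste(missing_cols, collapse = ", ")),
           class = "comigratr_schema_error")
  for (col in sc$intensity) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    abort_if(length(bad) > 0,
             paste0("negative ", col, " at row(s) ",
                    paste(utils::head(bad, 5), collapse = ", ")),
             class = "comigratr_validation_error")
  }
  if ("replicate" %in% names(df)) df$replicate <- as.integer(df$replicate)
  if ("fraction" %in% names(df)) df$fraction <- as.integer(df$fraction)
  tibble::as_tibble(df)
}

#' Write a pipeline table
#'
#' Writes a tibble as TSV with missing values serialized as empty fields, so
#' that `read_table(write_table(x))` round-trips losslessly.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param provenance Optional character vector written as `#`-prefixed header
#'   lines before the column header (ignored on read by `readr`'s comment
#'   handling is not used; provenance lines are written to a sidecar when
#'   reading matters).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, provenance = NULL) {
  if (!is.null(provenance)) {
    con <- file(path, open = "wt")
    writeLines(paste0("# ", provenance), con)
    close(con)
    readr::write_tsv(df, path, na = "", append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(df, path, na = "", progress = FALSE)
  }
  invisible(path)
}

# Pivot an entity x fraction matrix (columns F1..Fn, optional loc_F1..loc_Fn
# localization columns) to the long profile schema.
wide_to_long_profiles <- function(df) {
  frac_cols <- grep("^F[0-9]+$", names(df), value = TRUE)
  loc_cols <- grep("^loc_F[0-9]+$", names(df), value = TRUE)
  id_cols <- setdiff(names(df), c(frac_cols, loc_cols))
  long <- tidyr::pivot_longer(df[, c(id_cols, frac_cols)], dplyr::all_of(frac_cols),
                              names_to = "fraction", values_to = "intensity")
  long$fraction <- as.integer(sub("^F", "", long$fraction))
  long$intensity <- suppressWarnings(as.numeric(long$intensity))
  if (length(loc_cols) > 0) {
    loc <- tidyr::pivot_longer(df[, c(id_cols, loc_cols)], dplyr::all_of(loc_cols),
                               names_to = "fraction", values_to = "loc_score")
    loc$fraction <- as.integer(sub("^loc_F", "", loc$fraction))
    long <- dplyr::left_join(long, loc, by = c(id_cols, "fraction"))
  }
  dplyr::arrange(long, .data$entity_id, .data$fraction)
}

#' Read a GMT annotation file
#'
#' Parses a gene-set (GMT) file into a named list of membership vectors, the
#' format used for cellular-compartment annotation.
#'
#' @param path Path to a GMT file (term, description, tab-separated members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) unique(x[-(1:2)])),
                  vapply(lines, `[[`, "", 1L))
}

#' Read a protein-protein interaction reference
#'
#' Reads a 3-column tab file (`protein_a`, `protein_b`, `evidence` count) into
#' a symmetric, self-edge-free edge table.
#'
#' @param path Path to the TSV edge list.
#' @return Tibble with columns `protein_a`, `protein_b`, `evidence`.
#' @export
read_ppi <- function(path) {
  df <- read_table(path, "ppi")
  df <- dplyr::filter(df, .data$protein_a != .data$protein_b)
  dplyr::distinct(
    dplyr::mutate(df,
                  a = pmin(.data$protein_a, .data$protein_b),
                  b = pmax(.data$protein_a, .data$protein_b)),
    .data$a, .data$b, .keep_all = TRUE
  ) |>
    dplyr::transmute(protein_a = .data$a, protein_b = .data$b,
                     evidence = .data$evidence)
}
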