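# column schemas for the delimited-text inputs; units in the header names
table_schemas <- list(
  restraints = list(
    cols = c(residue_index = "integer", shift_ppm = "numeric",
             error_ppm = "numeric"),
    key = "residue_index"),
  shifts = list(
    cols = c(residue = "integer", residue_type = "character",
             atom = "character", shift_ppm = "numeric"),
    key = c("residue", "atom")),
  pre = list(
    cols = c(residue = "integer", intensity_ref = "numeric",
             intensity_para = "numeric", noise_ref = "numeric",
             noise_para = "numeric"),
    key = "residue"),
  splittings = list(
    cols = c(carbon = "integer", group = "character",
             splitting_khz = "numeric", condition = "character"),
    key = c("carbon", "condition"))
)

#' Read and validate a delimited-text table
#'
#' Reads a tab-separated file with a mandatory header row and validates
#' it against one of the package's table schemas (restraints, shifts,
#' pre, splittings): required columns must be present, cells must parse
#' to the schema type, and key columns must not contain duplicates.
#' Errors name the file, the offending column and the (1-based data) row.
#'
#' @param path path to a TSV file.
#' @param schema one of \code{"restraints"}, \code{"shifts"},
#'   \code{"pre"}, \code{"splittings"}.
#' @return Validated data frame.
#' @export
read_table <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("input file not found: ", path)
  sc <- table_schemas[[schema]]
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = TRUE)
  miss <- setdiff(names(sc$cols), names(df))
  if (length(miss) > 0)
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in names(sc$cols)) {
    type <- sc$cols[[col]]
    if (type %in% c("numeric", "integer")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
      if (length(bad) > 0 || anyNA(df[[col]]))
        stop("file ", path, ", column ", col, ": non-numeric value at row ",
             paste(head(c(bad, which(is.na(df[[col]]))), 3), collapse = ", "))
      df[[col]] <- if (type == "integer") as.integer(round(v)) else v
    }
  }
  if (anyDuplicated(df[, sc$key, drop = FALSE])) {
    dup <- which(duplicated(df[, sc$key, drop = FALSE]))
    stop("file ", path, ": duplicate key (",
         paste(sc$key, collapse = ", "), ") at row ",
         paste(head(dup, 3), collapse = ", "))
  }
  df
}

#' Write a table as tab-separated text
#'
#' Locale-independent TSV writer (period decimal separator, header row,
#' no quoting, no row names) — the inverse of \code{\link{read_table}}.
#'
#' @param x data frame.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_table <- function(x, path) {
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a restraints file into shift_restraint objects
#'
#' @param path TSV file with columns \code{residue_index},
#'   \code{shift_ppm}, \code{error_ppm}.
#' @return List of \code{\link{shift_restraint}} objects.
#' @export
read_restraints <- function(path) {
  df <- read_table(path, "restraints")
  lapply(seq_len(nrow(df)), function(k)
    shift_restraint(df$residue_index[k], df$shift_ppm[k], df$error_ppm[k]))
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
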