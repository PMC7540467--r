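# Delimited-text readers for phenotypes and population metadata.
# Delimiter is auto-detected among comma / semicolon / tab because field
# exports differ between locales.

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  counts <- c(`,` = lengths(regmatches(first, gregexpr(",", first, fixed = TRUE))),
              `;` = lengths(regmatches(first, gregexpr(";", first, fixed = TRUE))),
              `\t` = lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE))))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

#' Read a phenotype table
#'
#' Expects a header with the factor columns `individual`, `subspecies`,
#' `population`, `family`, `block`; every remaining numeric column is taken
#' as a trait.  Empty trait cells become `NA` (missing); factor columns are
#' kept as character.  The delimiter (comma, semicolon or tab) is
#' auto-detected.
#'
#' @param path delimited text file.
#' @return a `data.frame` of class `"phenotype_table"` with an attribute
#'   `traits` naming the trait columns.
#' @export
read_phenotype_csv <- function(path) {
  sep <- detect_delimiter(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"), check.names = FALSE,
                   colClasses = "character", quote = "\"")
  required <- c("individual", "subspecies", "population", "family", "block")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("phenotype schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  traits <- setdiff(names(df), required)
  if (!length(traits))
    stop("phenotype schema error: no trait columns found", call. = FALSE)
  for (tr in traits) {
    raw <- df[[tr]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("phenotype value error: non-numeric value for trait '", tr,
           "' at data row ", bad[1], call. = FALSE)
    if (any(!is.finite(num) & !is.na(num)))
      stop("phenotype value error: non-finite value in trait '", tr, "'",
           call. = FALSE)
    df[[tr]] <- num
  }
  phenotype_table(df, traits = traits)
}

#' Construct a phenotype table from a data frame
#'
#' @param df data frame with the factor columns `individual`, `subspecies`,
#'   `population`, `family`, `block` plus numeric trait columns.
#' @param traits character names of the trait columns; defaults to all
#'   non-factor columns.
#' @return `df` with class `"phenotype_table"` and a `traits` attribute.
#' @export
phenotype_table <- function(df, traits = NULL) {
  required <- c("individual", "subspecies", "population", "family", "block")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("phenotype schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(traits)) traits <- setdiff(names(df), required)
  for (f in required) df[[f]] <- as.character(df[[f]])
  df <- df[c(required, traits)]
  rownames(df) <- NULL
  structure(df, traits = traits,
            class = c("phenotype_table", "data.frame"))
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("Phenotype table: ", nrow(x), " individuals, ",
      length(unique(x$population)), " populations, ",
      length(attr(x, "traits")), " trait(s)\n", sep = "")
  cat("Traits:", paste(attr(x, "traits"), collapse = ", "), "\n")
  NextMethod()
}

#' Write a phenotype table as UTF-8 CSV
#' @param p a [phenotype_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(p, path) {
  write.table(as.data.frame(p), path, sep = ",", row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read population metadata
#'
#' One row per population with columns `population`, `subspecies`,
#' `latitude`, `longitude` (decimal degrees) and `altitude` (metres).
#' Coordinates are range-checked and duplicate populations rejected.
#'
#' @param path delimited text file (delimiter auto-detected).
#' @return a `data.frame` of class `"population_metadata"`.
#' @export
read_population_metadata <- function(path) {
  sep <- detect_delimiter(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "\"")
  population_metadata(df)
}

#' Construct population metadata from a data frame
#' @param df data frame with columns `population`, `subspecies`, `latitude`,
#'   `longitude`, `altitude`.
#' @return `df` with class `"population_metadata"`.
#' @export
population_metadata <- function(df) {
  required <- c("population", "subspecies", "latitude", "longitude", "altitude")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("metadata schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$population))
    stop("metadata error: duplicate population label '",
         df$population[duplicated(df$population)][1], "'", call. = FALSE)
  for (col in c("latitude", "longitude", "altitude"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(abs(df$latitude) > 90, na.rm = TRUE))
    stop("metadata error: latitude outside [-90, 90]", call. = FALSE)
  if (any(abs(df$longitude) > 180, na.rm = TRUE))
    stop("metadata error: longitude outside [-180, 180]", call. = FALSE)
  if (any(df$altitude < 0, na.rm = TRUE))
    stop("metadata error: negative altitude", call. = FALSE)
  df$population <- as.character(df$population)
  df$subspecies <- as.character(df$subspecies)
  df <- df[c(required, setdiff(names(df), required))]
  rownames(df) <- NULL
  structure(df, class = c("population_metadata", "data.frame"))
}

#' Write population metadata as UTF-8 CSV
#' @param m a [population_metadata()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_population_metadata <- function(m, path) {
  write.table(as.data.frame(m), path, sep = ",", row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
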