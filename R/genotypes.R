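#' Genotype tables
#'
#' A `genotype_table` holds diploid multi-allelic genotypes for a set of
#' individuals at a set of loci, with one population label per individual.
#' Alleles are stored as positive integers (the numeric codes of a GenePop
#' file); the pair is unordered and `NA` marks a missing call.
#'
#' @param allele1,allele2 integer matrices (individuals x loci) holding the
#'   two alleles of each call; `NA` in either slot makes the call missing.
#' @param population character or factor of population labels, one per
#'   individual.
#' @param individuals character ids, one per row.
#' @param loci character locus names, one per column.
#' @return an object of class `"genotype_table"`.
#' @export
genotype_table <- function(allele1, allele2, population,
                           individuals = NULL, loci = NULL) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  if (!all(dim(allele1) == dim(allele2)))
    stop("allele matrices must have identical dimensions", call. = FALSE)
  n <- nrow(allele1)
  if (length(population) != n)
    stop("one population label per individual is required", call. = FALSE)
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(n))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(allele1)))
  if (anyDuplicated(individuals))
    stop("individual ids must be unique", call. = FALSE)
  miss <- is.na(allele1) | is.na(allele2)
  allele1[miss] <- NA_integer_; allele2[miss] <- NA_integer_
  dimnames(allele1) <- dimnames(allele2) <- list(individuals, loci)
  structure(
    list(allele1 = allele1, allele2 = allele2,
         population = factor(as.character(population)),
         individuals = individuals, loci = loci),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table: ", length(x$individuals), " individuals, ",
      length(x$loci), " loci, ", nlevels(x$population), " populations\n",
      sep = "")
  cat("Populations:", paste(levels(x$population), collapse = ", "), "\n")
  miss <- mean(is.na(x$allele1))
  cat(sprintf("Missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype table to a set of populations
#'
#' @param g a [genotype_table()].
#' @param populations character vector of population labels to keep.
#' @return a [genotype_table()] restricted to those populations, with
#'   factor levels dropped.
#' @export
subset_populations <- function(g, populations) {
  keep <- as.character(g$population) %in% populations
  if (!any(keep)) stop("no individuals in the requested populations",
                       call. = FALSE)
  genotype_table(g$allele1[keep, , drop = FALSE],
                 g$allele2[keep, , drop = FALSE],
                 droplevels(g$population[keep]),
                 g$individuals[keep], g$loci)
}

#' Read a GenePop genotype file
#'
#' Parses the GenePop dialect: a title line, one block of locus names (one
#' per line or a single comma-separated line), then populations separated by
#' `POP` lines, each individual on a line `id , a1a2 a1a2 ...` with 2- or
#' 3-digit allele codes.  An all-zero code is a missing call.  The allele
#' code width (4 or 6 characters per diploid call) is inferred from the file
#' and must be consistent throughout.
#'
#' @param path path to a `.gen` file.
#' @param pop_names optional character vector naming the populations in file
#'   order; defaults to `pop1..popN`.
#' @return a [genotype_table()].
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("﻿", "", lines)
  if (length(lines) < 3) stop("GenePop file too short: ", path, call. = FALSE)
  is_pop <- toupper(trimws(lines)) == "POP"
  if (!any(is_pop)) stop("GenePop format error: no POP separator in ", path,
                         call. = FALSE)
  first_pop <- which(is_pop)[1]
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("GenePop format error: no locus names in ", path,
                          call. = FALSE)

  pop_starts <- which(is_pop)
  n_pops <- length(pop_starts)
  if (is.null(pop_names)) pop_names <- sprintf("pop%02d", seq_len(n_pops))
  if (length(pop_names) != n_pops)
    stop("pop_names must have one entry per POP section", call. = FALSE)

  ids <- character(); pops <- character()
  a1 <- list(); a2 <- list()
  width <- NA_integer_
  bounds <- c(pop_starts, length(lines) + 1L)
  for (s in seq_len(n_pops)) {
    rng <- seq.int(bounds[s] + 1L, bounds[s + 1L] - 1L)
    rng <- rng[rng <= length(lines)]
    for (i in rng) {
      line <- trimws(lines[i])
      if (!nzchar(line)) next
      parts <- strsplit(line, ",")[[1]]
      if (length(parts) < 2)
        stop("GenePop parse error at line ", i, ": missing ',' separator",
             call. = FALSE)
      id <- trimws(parts[1])
      calls <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                        "[[:space:]]+")[[1]]
      if (length(calls) != length(loci))
        stop("GenePop parse error at line ", i, ": expected ", length(loci),
             " calls, found ", length(calls), call. = FALSE)
      w <- unique(nchar(calls))
      if (length(w) != 1 || !w %in% c(4L, 6L))
        stop("GenePop parse error at line ", i,
             ": allele codes must be uniformly 4 or 6 characters",
             call. = FALSE)
      if (is.na(width)) width <- w
      if (w != width)
        stop("GenePop parse error at line ", i,
             ": mixed 2- and 3-digit allele codes in one file", call. = FALSE)
      if (grepl("[^0-9]", paste(calls, collapse = "")))
        stop("GenePop parse error at line ", i, ": non-numeric allele code",
             call. = FALSE)
      half <- width %/% 2L
      x1 <- as.integer(substr(calls, 1L, half))
      x2 <- as.integer(substr(calls, half + 1L, width))
      x1[x1 == 0L] <- NA_integer_
      x2[x2 == 0L] <- NA_integer_
      ids <- c(ids, id); pops <- c(pops, pop_names[s])
      a1[[length(a1) + 1L]] <- x1; a2[[length(a2) + 1L]] <- x2
    }
  }
  if (!length(ids)) stop("GenePop format error: no individuals in ", path,
                         call. = FALSE)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_table(do.call(rbind, a1), do.call(rbind, a2), pops, ids, loci)
}

#' Write a genotype table as a GenePop file
#'
#' Emits 3-digit allele codes and `000000` for missing calls; one locus name
#' per line; populations in level order of the table.
#'
#' @param g a [genotype_table()].
#' @param path output file.
#' @param title first (comment) line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, title = "qstfst export") {
  stopifnot(inherits(g, "genotype_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  for (p in levels(g$population)) {
    writeLines("POP", con)
    idx <- which(g$population == p)
    for (i in idx) {
      a1 <- g$allele1[i, ]; a2 <- g$allele2[i, ]
      code <- sprintf("%03d%03d", ifelse(is.na(a1), 0L, a1),
                      ifelse(is.na(a2), 0L, a2))
      writeLines(paste0(g$individuals[i], " , ", paste(code, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
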