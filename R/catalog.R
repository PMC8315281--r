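#' Read a microbe-disease association catalog
#'
#' Reads a delimited edge list (TSV or CSV, sniffed from the first line) with
#' header columns `microbe` and `disease` and an optional `source` column.
#' Identifiers are treated as opaque pre-normalized strings: they are
#' whitespace-trimmed, optionally passed through a synonym table, and compared
#' case-sensitively. Duplicate (microbe, disease) pairs are collapsed, keeping
#' the union of their source labels.
#'
#' @param path Path to a UTF-8 delimited file with a header row.
#' @param source_label Label recorded as the provenance of rows whose `source`
#'   column is absent or empty. Defaults to the file name.
#' @param synonym_map Optional two-column data frame (`from`, `to`) mapping
#'   alternate identifiers to their canonical form; applied to both microbe
#'   and disease ids.
#' @return An association catalog: a tibble with columns `microbe`, `disease`,
#'   `sources` (semicolon-joined provenance), one row per distinct pair,
#'   classed `mdrank_catalog`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("microbe\tdisease", "Roseburia\tIBD", "Dorea\tIBD"), tf)
#' read_catalog(tf, source_label = "demo")
#' @export
read_catalog <- function(path, source_label = basename(path),
                         synonym_map = NULL) {
  if (!file.exists(path)) {
    stop("catalog file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    stop("empty catalog file: ", path, call. = FALSE)
  }
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(c("microbe", "disease"), names(raw))
  if (length(missing) > 0L) {
    stop("catalog is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    stop("catalog file has a header but no associations: ", path,
         call. = FALSE)
  }
  src_col <- intersect(c("source", "sources"), names(raw))[1]
  src <- if (!is.na(src_col)) raw[[src_col]] else rep(NA_character_, nrow(raw))
  src <- dplyr::if_else(is.na(src) | stringr::str_trim(src) == "",
                        source_label, stringr::str_trim(src))
  assoc <- tibble::tibble(
    microbe = stringr::str_trim(raw$microbe),
    disease = stringr::str_trim(raw$disease),
    sources = src
  )
  if (any(assoc$microbe == "" | assoc$disease == "")) {
    stop("catalog contains empty microbe or disease ids after trimming",
         call. = FALSE)
  }
  if (!is.null(synonym_map)) {
    assoc$microbe <- apply_synonyms(assoc$microbe, synonym_map)
    assoc$disease <- apply_synonyms(assoc$disease, synonym_map)
  }
  cat <- collapse_catalog(assoc)
  message(sprintf("read %d rows from %s: %d distinct associations",
                  nrow(raw), path, nrow(cat)))
  cat
}

apply_synonyms <- function(ids, synonym_map) {
  synonym_map <- as.data.frame(synonym_map)
  if (!all(c("from", "to") %in% names(synonym_map))) {
    stop("synonym_map must have columns `from` and `to`", call. = FALSE)
  }
  hit <- match(ids, synonym_map$from)
  dplyr::if_else(is.na(hit), ids, synonym_map$to[hit])
}

# Collapse to one row per (microbe, disease); merge provenance, sort ids.
collapse_catalog <- function(assoc) {
  out <- assoc |>
    tidyr::separate_longer_delim("sources", delim = ";") |>
    dplyr::distinct() |>
    dplyr::group_by(.data$microbe, .data$disease) |>
    dplyr::summarise(
      sources = paste(sort(unique(.data$sources)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$microbe, .data$disease)
  class(out) <- c("mdrank_catalog", class(out))
  out
}

#' Construct a catalog from an in-memory association table
#'
#' @param associations Data frame with columns `microbe` and `disease` and an
#'   optional `sources` column (defaulting to `"user"`).
#' @return An `mdrank_catalog` tibble (see [read_catalog()]).
#' @export
as_catalog <- function(associations) {
  associations <- tibble::as_tibble(associations)
  stopifnot(all(c("microbe", "disease") %in% names(associations)))
  if (!"sources" %in% names(associations)) {
    associations$sources <- "user"
  }
  associations <- dplyr::mutate(
    associations,
    microbe = stringr::str_trim(as.character(.data$microbe)),
    disease = stringr::str_trim(as.character(.data$disease))
  )
  if (any(associations$microbe == "" | associations$disease == "")) {
    stop("associations contain empty ids after trimming", call. = FALSE)
  }
  collapse_catalog(associations[, c("microbe", "disease", "sources")])
}

#' Merge association catalogs from multiple sources
#'
#' Takes the set union of associations across catalogs, unique on the
#' (microbe, disease) pair; provenance labels of duplicated pairs are merged.
#' Entity indices are rebuilt lexicographically, so the result is independent
#' of the order in which catalogs are supplied.
#'
#' @param ... Catalogs (from [read_catalog()] or [as_catalog()]), or a single
#'   list of catalogs.
#' @return A merged `mdrank_catalog` tibble.
#' @export
merge_catalogs <- function(...) {
  cats <- list(...)
  if (length(cats) == 1L && is.list(cats[[1]]) && !is.data.frame(cats[[1]])) {
    cats <- cats[[1]]
  }
  if (length(cats) == 0L) {
    stop("at least one catalog is required", call. = FALSE)
  }
  cats <- cats[vapply(cats, nrow, 1L) > 0L]
  if (length(cats) == 0L) {
    return(as_catalog(tibble::tibble(microbe = character(),
                                     disease = character(),
                                     sources = character())))
  }
  collapse_catalog(dplyr::bind_rows(cats))
}

#' Write a catalog as TSV
#'
#' @param catalog An `mdrank_catalog`.
#' @param path Output path; columns `microbe`, `disease`, `sources`.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(tibble::as_tibble(catalog)[, c("microbe", "disease", "sources")],
                   path, progress = FALSE)
  invisible(path)
}

#' Lexicographic entity indices of a catalog
#'
#' @param catalog An `mdrank_catalog`.
#' @return List with character vectors `microbes` and `diseases`, each sorted
#'   by the C locale so downstream matrices are deterministic.
#' @export
catalog_index <- function(catalog) {
  list(
    microbes = stringr::str_sort(unique(catalog$microbe), locale = "en"),
    diseases = stringr::str_sort(unique(catalog$disease), locale = "en")
  )
}

#' Binary interaction profile matrix of a catalog
#'
#' Row i is the interaction profile IP(m_i) of microbe i (which diseases it is
#' associated with); column j is IP(d_j). Row and column order follow the
#' catalog's lexicographic entity indices.
#'
#' @param catalog A non-empty `mdrank_catalog`.
#' @return A binary matrix with microbe row names and disease column names;
#'   its number of ones equals the number of associations.
#' @export
to_profile_matrix <- function(catalog) {
  if (nrow(catalog) == 0L) {
    stop("cannot build a profile matrix from an empty catalog", call. = FALSE)
  }
  idx <- catalog_index(catalog)
  B <- matrix(0, length(idx$microbes), length(idx$diseases),
              dimnames = list(idx$microbes, idx$diseases))
  B[cbind(match(catalog$microbe, idx$microbes),
          match(catalog$disease, idx$diseases))] <- 1
  B
}

#' @export
print.mdrank_catalog <- function(x, ...) {
  idx <- catalog_index(x)
  cat(sprintf("# microbe-disease catalog: %d associations, %d microbes, %d diseases\n",
              nrow(x), length(idx$microbes), length(idx$diseases)))
  NextMethod()
}
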