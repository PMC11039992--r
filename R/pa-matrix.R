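#' Presence/absence matrix of orthologous groups across species
#'
#' A `pa_matrix` is a binary integer matrix with one row per orthologous
#' group (OG) and one column per species. It is the central object of the
#' phylogenetic-profiling co-evolution screen: row `i` is the phylogenetic
#' profile of OG `i`.
#'
#' @param values integer or numeric matrix; any value > 0 is treated as
#'   presence and binarized to 1, values must be non-negative.
#' @param og_ids character vector of unique OG identifiers (rows).
#' @param species_ids character vector of unique species identifiers
#'   (columns).
#' @return an integer matrix of 0/1 with class `pa_matrix`, dimnames set to
#'   `(og_ids, species_ids)`.
#' @export
pa_matrix <- function(values, og_ids = rownames(values),
                      species_ids = colnames(values)) {
  if (!is.matrix(values)) {
    stop("`values` must be a matrix", call. = FALSE)
  }
  if (is.null(og_ids) || is.null(species_ids)) {
    stop("OG and species identifiers are required", call. = FALSE)
  }
  og_ids <- as.character(og_ids)
  species_ids <- as.character(species_ids)
  if (anyDuplicated(og_ids)) {
    stop("duplicate OG ids: ",
         paste(unique(og_ids[duplicated(og_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(species_ids)) {
    stop("duplicate species ids: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(og_ids) != nrow(values) || length(species_ids) != ncol(values)) {
    stop("dimnames do not match matrix dimensions", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(values < 0)) {
    stop("occupancy values must be non-negative and non-missing",
         call. = FALSE)
  }
  m <- matrix(as.integer(values > 0), nrow = nrow(values),
              dimnames = list(og_ids, species_ids))
  class(m) <- c("pa_matrix", class(m))
  m
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("<pa_matrix> %d orthologous groups x %d species\n",
              nrow(x), ncol(x)))
  cat(sprintf("  presence fraction: %.3f\n", mean(x)))
  invisible(x)
}

#' Read an orthology membership table into a presence/absence matrix
#'
#' Parses a TSV membership table: first column OG id, header row species
#' ids, cells non-negative occupancy counts. Counts greater than zero are
#' binarized to presence (1).
#'
#' @param path path to a tab-separated file.
#' @param transpose if `TRUE`, the file is oriented species-by-OG (first
#'   column species id, header OGs) and is transposed after reading.
#'   Orientation is never guessed.
#' @return a [pa_matrix].
#' @export
build_profiles <- function(path, transpose = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    stop("membership table is empty or has no species columns: ", path,
         call. = FALSE)
  }
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    stop("occupancy values are not numeric in ", path, call. = FALSE)
  }
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)
  pa_matrix(vals)
}

#' Write a presence/absence matrix as TSV
#'
#' Layout matches [build_profiles()] without `transpose`: first column
#' `og_id`, one column per species, cells 0/1.
#'
#' @param x a [pa_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path) {
  stopifnot(inherits(x, "pa_matrix"))
  df <- data.frame(og_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
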