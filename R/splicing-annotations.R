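#' Read a BED file of intervals
#'
#' Minimal strict BED reader (0-based half-open, BED3-BED6). Bespoke
#' rather than delegated so that malformed records can be reported with
#' their file and line number, which the merging step relies on.
#'
#' @param path file path.
#' @return data.frame with columns chrom, start, end, name, score, strand
#'   (name/score/strand filled with ".", 0, "*" when absent).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    stop("no records in BED file: ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_field <- lengths(parts)
  bad <- which(n_field < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: fewer than 3 BED fields", path, bad[1L]),
         call. = FALSE)
  }
  get <- function(i, default) {
    vapply(parts, function(p) if (length(p) >= i) p[i] else default, "")
  }
  start <- suppressWarnings(as.numeric(get(2L, NA)))
  end <- suppressWarnings(as.numeric(get(3L, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: non-numeric coordinates", path, bad[1L]),
         call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: start >= end (%d >= %d)", path, bad[1L],
                 start[bad[1L]], end[bad[1L]]), call. = FALSE)
  }
  strand <- get(6L, "*")
  bad <- which(!strand %in% c("+", "-", "*", "."))
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: invalid strand '%s'", path, bad[1L],
                 strand[bad[1L]]), call. = FALSE)
  }
  data.frame(chrom = get(1L, "."), start = as.integer(start),
             end = as.integer(end), name = get(4L, "."),
             score = suppressWarnings(as.numeric(get(5L, "0"))),
             strand = strand, stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param x data.frame with chrom, start, end, strand and optionally
#'   name/score (subtype is used as the name for intron annotations).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name
          else if ("subtype" %in% names(x)) x$subtype else "."
  score <- if ("score" %in% names(x)) x$score else 0
  df <- data.frame(x$chrom, x$start, x$end, name, score, x$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge U12-type intron annotation lists
#'
#' Combines intron lists from several databases into one high-confidence
#' set. Records identical on (chrom, start, end, strand) collapse into a
#' single intron carrying the union of source labels; coordinates are
#' matched exactly — no fuzzy window — so databases that disagree by even
#' one base remain visibly distinct records. Output is sorted by
#' (chrom, start, end). Merging is idempotent.
#'
#' @param ... BED file paths or intron data.frames (chrom, start, end,
#'   strand, optional subtype). For BED input the name column is read as
#'   the subtype when it is `GT-AG`/`AT-AC`.
#' @param sources character vector of source labels, one per input;
#'   defaults to input names or file basenames.
#' @return data.frame with columns chrom, start, end, strand, subtype,
#'   sources (comma-joined sorted labels).
#' @export
merge_u12_annotations <- function(..., sources = NULL) {
  inputs <- list(...)
  if (length(inputs) == 1L && is.list(inputs[[1L]]) &&
      !is.data.frame(inputs[[1L]])) {
    inputs <- inputs[[1L]]
  }
  if (length(inputs) == 0L) stop("no input lists", call. = FALSE)
  if (is.null(sources)) {
    sources <- names(inputs)
    if (is.null(sources)) sources <- rep("", length(inputs))
    fallback <- vapply(inputs, function(x) {
      if (is.character(x)) basename(x) else "table"
    }, "")
    sources[!nzchar(sources)] <- fallback[!nzchar(sources)]
  }
  stopifnot(length(sources) == length(inputs))

  recs <- lapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    if (is.character(x)) {
      b <- read_bed(x)
      subtype <- ifelse(b$name %in% c("GT-AG", "AT-AC"), b$name, "other")
      x <- data.frame(chrom = b$chrom, start = b$start, end = b$end,
                      strand = b$strand, subtype = subtype,
                      stringsAsFactors = FALSE)
    }
    if (!all(c("chrom", "start", "end", "strand") %in% names(x))) {
      stop("intron table needs chrom, start, end, strand", call. = FALSE)
    }
    if (any(x$start >= x$end)) {
      stop("malformed interval (start >= end) in input ", sources[i],
           call. = FALSE)
    }
    if (!"subtype" %in% names(x)) x$subtype <- "other"
    src <- if ("sources" %in% names(x)) x$sources else sources[i]
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               strand = x$strand, subtype = x$subtype, sources = src,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, recs)
  key <- paste(all$chrom, all$start, all$end, all$strand, sep = "\r")
  merged <- do.call(rbind, lapply(split(all, key), function(g) {
    subtype <- unique(g$subtype)
    src <- sort(unique(unlist(strsplit(g$sources, ",", fixed = TRUE))))
    data.frame(chrom = g$chrom[1L], start = g$start[1L], end = g$end[1L],
               strand = g$strand[1L],
               subtype = if (length(subtype) == 1L) subtype else "other",
               sources = paste(src, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$chrom, merged$start, merged$end), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}
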