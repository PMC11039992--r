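#' Read and validate a species tree in Newick format
#'
#' Wraps [ape::read.tree()] and enforces the invariants the simulators and
#' the loss model rely on: unique leaf labels, non-negative branch
#' lengths, a single rooted tree.
#'
#' @param path Newick file path.
#' @return an [ape::phylo].
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("cannot parse Newick file: ", path, call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    stop("expected exactly one tree in ", path, call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in ", path, call. = FALSE)
  }
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have non-negative branch lengths: ", path,
         call. = FALSE)
  }
  tree
}

#' @rdname read_newick
#' @param tree an [ape::phylo].
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# expand one BED12 row into per-exon rows (0-based half-open preserved)
bed12_exons <- function(row, line_no, path) {
  sizes <- suppressWarnings(as.integer(strsplit(row[[11L]], ",")[[1L]]))
  offsets <- suppressWarnings(as.integer(strsplit(row[[12L]], ",")[[1L]]))
  n <- as.integer(row[[10L]])
  if (length(sizes) != n || length(offsets) != n || anyNA(sizes) ||
      anyNA(offsets)) {
    stop(sprintf("%s line %d: blockCount disagrees with blockSizes/blockStarts",
                 path, line_no), call. = FALSE)
  }
  start <- as.integer(row[[2L]]) + offsets
  data.frame(gene_id = row[[4L]], chrom = row[[1L]], start = start,
             end = start + sizes, strand = row[[6L]],
             exon_rank = seq_len(n), stringsAsFactors = FALSE)
}

#' Read gene models as exon intervals
#'
#' Accepts BED12 (one transcript per line, blocks = exons, already 0-based
#' half-open) or exon-level GTF (1-based closed; converted to 0-based
#' half-open on read, so a GTF exon of length 100 yields an internal
#' interval of length 100). GTF parsing is delegated to
#' \pkg{rtracklayer} when available, with a minimal fallback parser.
#'
#' @param path file path; format inferred from the extension (`.bed` vs
#'   `.gtf`/`.gff`) unless `format` is given.
#' @param format `"bed12"` or `"gtf"`.
#' @return exon data.frame: gene_id, chrom, start, end, strand, exon_rank.
#' @export
read_gene_models <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12"
              else "gtf"
  }
  format <- match.arg(format, c("bed12", "gtf"))
  if (format == "bed12") {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    rows <- strsplit(lines[keep], "\t", fixed = TRUE)
    line_no <- which(keep)
    bad <- which(lengths(rows) < 12L)
    if (length(bad) > 0L) {
      stop(sprintf("%s line %d: BED12 requires 12 fields", path,
                   line_no[bad[1L]]), call. = FALSE)
    }
    out <- do.call(rbind, lapply(seq_along(rows), function(i) {
      bed12_exons(rows[[i]], line_no[i], path)
    }))
  } else {
    out <- read_gtf_exons(path)
  }
  rownames(out) <- NULL
  out
}

read_gtf_exons <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "exon"]
    df <- data.frame(gene_id = as.character(gr$gene_id),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 9L) stop("not a 9-column GTF: ", path, call. = FALSE)
    tab <- tab[tab[[3L]] == "exon", , drop = FALSE]
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", tab[[9L]])
    df <- data.frame(gene_id = gid, chrom = tab[[1L]],
                     start = as.integer(tab[[4L]]) - 1L,
                     end = as.integer(tab[[5L]]),
                     strand = tab[[7L]], stringsAsFactors = FALSE)
  }
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  df$exon_rank <- stats::ave(df$start, df$gene_id,
                             FUN = seq_along)
  df
}

#' Write gene models as BED12 (one line per gene)
#'
#' @param exons exon data.frame (gene_id, chrom, start, end, strand).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(exons, path) {
  lines <- vapply(split(exons, exons$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    g0 <- min(e$start); g1 <- max(e$end)
    paste(e$chrom[1L], g0, g1, e$gene_id[1L], 0, e$strand[1L], g0, g1,
          "0,0,0", nrow(e),
          paste0(paste(e$end - e$start, collapse = ","), ","),
          paste0(paste(e$start - g0, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
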