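#' Read / write Whippet-style alternative-splicing event tables
#'
#' TSV with columns gene_id, event_type (CE/AA/AD/RI/other), chrom, start,
#' end (0-based half-open), strand, psi_a, psi_b, delta_psi, probability.
#'
#' @param path file path.
#' @return data.frame of events.
#' @export
read_as_events <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "event_type", "chrom", "start", "end", "strand",
            "delta_psi", "probability")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("event table missing columns: ", paste(miss, collapse = ", "),
         ": ", path, call. = FALSE)
  }
  bad <- which(tab$probability < 0 | tab$probability > 1)
  if (length(bad) > 0L) {
    stop(sprintf("%s row %d: probability outside [0, 1]", path, bad[1L]),
         call. = FALSE)
  }
  bad <- which(abs(tab$delta_psi) > 1)
  if (length(bad) > 0L) {
    stop(sprintf("%s row %d: |delta_psi| > 1", path, bad[1L]),
         call. = FALSE)
  }
  tab
}

#' @rdname read_as_events
#' @param events event data.frame.
#' @export
write_as_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter events by significance thresholds
#'
#' Retains events with `probability > pr_min` AND `|delta_psi| > dpsi_min`
#' — both strict inequalities, so events sitting exactly on a threshold are
#' excluded. Input order is preserved. Raising either threshold can only
#' shrink the retained set.
#'
#' @param events event data.frame (see [read_as_events()]).
#' @param pr_min probability cutoff (default 0.9).
#' @param dpsi_min |delta PSI| cutoff (default 0.05).
#' @return the retained subset, original order and columns.
#' @export
filter_significant_events <- function(events, pr_min = 0.9,
                                      dpsi_min = 0.05) {
  if (pr_min < 0 || pr_min > 1 || dpsi_min < 0 || dpsi_min > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  keep <- events$probability > pr_min & abs(events$delta_psi) > dpsi_min
  events[keep, , drop = FALSE]
}

# classification categories, in precedence order
event_classes <- c("WITHIN_U12", "PROXIMAL_U12", "U12_GENE_DISTAL",
                   "U2_ONLY_BACKGROUND")

events_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}

# for each U12 intron inside a gene model, the immediately flanking
# features: nearest exon and nearest intron on each side
flanking_features <- function(u12_row, exons_one_gene) {
  e <- exons_one_gene[order(exons_one_gene$start), , drop = FALSE]
  feats <- rbind(data.frame(start = e$start, end = e$end),
                 gene_introns(e))
  feats <- feats[order(feats$start), , drop = FALSE]
  up <- feats[feats$end <= u12_row$start, , drop = FALSE]
  up <- utils::tail(up[order(up$end), , drop = FALSE], 2L)
  down <- feats[feats$start >= u12_row$end, , drop = FALSE]
  down <- utils::head(down[order(down$start), , drop = FALSE], 2L)
  out <- rbind(up, down)
  if (nrow(out) == 0L) return(NULL)
  data.frame(chrom = u12_row$chrom, start = out$start, end = out$end,
             strand = u12_row$strand, stringsAsFactors = FALSE)
}

#' Classify alternative-splicing events relative to U12-type introns
#'
#' Each event is placed in exactly one class, tested in this precedence
#' order:
#' \describe{
#'   \item{WITHIN_U12}{the event interval overlaps a U12-type intron on
#'     the same strand;}
#'   \item{PROXIMAL_U12}{it overlaps an immediately flanking feature of a
#'     U12 intron — the nearest exon and nearest intron on either side of
#'     the intron in its host gene model (no base-pair window);}
#'   \item{U12_GENE_DISTAL}{it lies elsewhere in a gene that hosts a U12
#'     intron;}
#'   \item{U2_ONLY_BACKGROUND}{it lies in a gene containing only
#'     major-type introns.}
#' }
#' Events whose `gene_id` is absent from the gene models cannot be
#' classified; they are returned on a skip list, not silently dropped.
#'
#' @param events event data.frame (see [read_as_events()]).
#' @param u12_introns intron annotation data.frame
#'   ([merge_u12_annotations()]).
#' @param gene_models exon-level data.frame (gene_id, chrom, start, end,
#'   strand), e.g. [simulate_gene_models()]`$exons` or [read_gene_models()].
#' @return list with `events` (input rows + `class` column, classified
#'   rows only) and `skipped` (rows with unknown genes, + `reason`).
#' @export
classify_events <- function(events, u12_introns, gene_models) {
  known <- events$gene_id %in% gene_models$gene_id
  skipped <- events[!known, , drop = FALSE]
  if (nrow(skipped) > 0L) skipped$reason <- "gene not in gene models"
  ev <- events[known, , drop = FALSE]
  if (nrow(ev) == 0L) {
    ev$class <- character(0)
    return(list(events = ev, skipped = skipped))
  }

  genes <- split(gene_models, gene_models$gene_id)
  spans <- do.call(rbind, lapply(genes, function(e) {
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               start = min(e$start), end = max(e$end),
               strand = e$strand[1L], stringsAsFactors = FALSE)
  }))

  n_u12 <- if (is.null(u12_introns)) 0L else nrow(u12_introns)
  u12_host <- character(0)
  flanks <- NULL
  if (n_u12 > 0) {
    gr_u12 <- events_granges(u12_introns)
    gr_span <- events_granges(spans)
    hit <- GenomicRanges::findOverlaps(gr_u12, gr_span, type = "within")
    u12_host <- rep(NA_character_, n_u12)
    u12_host[S4Vectors::queryHits(hit)] <-
      spans$gene_id[S4Vectors::subjectHits(hit)]
    if (anyNA(u12_host)) {
      i <- which(is.na(u12_host))[1L]
      stop(sprintf("U12 intron %s:%d-%d not covered by any gene model",
                   u12_introns$chrom[i], u12_introns$start[i],
                   u12_introns$end[i]), call. = FALSE)
    }
    flanks <- do.call(rbind, lapply(seq_len(n_u12), function(i) {
      flanking_features(u12_introns[i, ], genes[[u12_host[i]]])
    }))
  }

  gr_ev <- events_granges(ev)
  cls <- rep("U2_ONLY_BACKGROUND", nrow(ev))
  u12_genes <- unique(u12_host)
  cls[ev$gene_id %in% u12_genes] <- "U12_GENE_DISTAL"
  if (!is.null(flanks) && nrow(flanks) > 0L) {
    hit <- GenomicRanges::findOverlaps(gr_ev, events_granges(flanks))
    cls[unique(S4Vectors::queryHits(hit))] <- "PROXIMAL_U12"
  }
  if (n_u12 > 0) {
    hit <- GenomicRanges::findOverlaps(gr_ev, events_granges(u12_introns))
    cls[unique(S4Vectors::queryHits(hit))] <- "WITHIN_U12"
  }
  ev$class <- cls
  list(events = ev, skipped = skipped)
}

#' @rdname classify_events
#' @param event a single-row event data.frame.
#' @return `classify_event()` returns the class label of one event.
#' @export
classify_event <- function(event, u12_introns, gene_models) {
  res <- classify_events(event, u12_introns, gene_models)
  if (nrow(res$events) == 0L) {
    stop("event gene '", event$gene_id[1L], "' absent from gene models",
         call. = FALSE)
  }
  res$events$class[1L]
}
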