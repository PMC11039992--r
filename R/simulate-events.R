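#' Configuration for synthetic alternative-splicing event tables
#'
#' Describes the synthetic world from which [simulate_gene_models()] and
#' [simulate_as_events()] draw: a panel of genes, a fraction of which host
#' one U12-type (minor) intron, and a stream of alternative-splicing events
#' whose type composition is tilted toward alternative-acceptor (AA) events
#' in the neighbourhood of U12 introns by a planted fold.
#'
#' `aa_enrichment_fold` multiplies the AA event probability within and
#' immediately flanking U12 introns, so the AA fraction in that stratum is
#' `fold * event_type_weights["AA"]` (the remaining types share the
#' leftover mass proportionally). The downstream enrichment test therefore
#' estimates this fold directly.
#'
#' @param n_genes number of genes in the panel.
#' @param frac_u12_genes fraction of genes hosting a U12-type intron,
#'   in `[0, 1]`.
#' @param n_events number of AS events to emit.
#' @param event_type_weights named probability vector over
#'   `c("CE", "AA", "AD", "RI")`; must sum to 1.
#' @param aa_enrichment_fold planted AA fold at U12 introns, >= 1;
#'   `fold * weight["AA"]` must not exceed 1.
#' @param seed RNG seed.
#' @return an `as_event_config` list.
#' @export
as_event_config <- function(n_genes = 200,
                            frac_u12_genes = 0.3,
                            n_events = 2000,
                            event_type_weights = c(CE = 0.4, AA = 0.2,
                                                   AD = 0.2, RI = 0.2),
                            aa_enrichment_fold = 1,
                            seed = 1) {
  if (abs(sum(event_type_weights) - 1) > 1e-9) {
    stop("`event_type_weights` must sum to 1", call. = FALSE)
  }
  if (!setequal(names(event_type_weights), c("CE", "AA", "AD", "RI"))) {
    stop("`event_type_weights` must be named CE, AA, AD, RI", call. = FALSE)
  }
  if (frac_u12_genes < 0 || frac_u12_genes > 1) {
    stop("`frac_u12_genes` must lie in [0, 1]", call. = FALSE)
  }
  if (aa_enrichment_fold < 1) {
    stop("`aa_enrichment_fold` must be >= 1", call. = FALSE)
  }
  if (aa_enrichment_fold * event_type_weights[["AA"]] > 1) {
    stop("fold * AA weight exceeds 1; no valid type distribution",
         call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 frac_u12_genes = frac_u12_genes,
                 n_events = as.integer(n_events),
                 event_type_weights = event_type_weights[c("CE", "AA",
                                                           "AD", "RI")],
                 aa_enrichment_fold = aa_enrichment_fold,
                 seed = seed),
            class = "as_event_config")
}

#' Simulate gene models and U12-type intron annotations
#'
#' Lays out `n_genes` non-overlapping multi-exon genes on one synthetic
#' chromosome (`chrS`), each with `n_exons` exons; a `frac_u12_genes`
#' fraction of genes carries exactly one U12-type intron at an internal
#' position (so that an immediately flanking exon and intron exist on both
#' sides, plus more distal features). Coordinates are 0-based half-open.
#'
#' @param config an [as_event_config()].
#' @param n_exons exons per gene (>= 7, to leave room for proximal and
#'   distal features around the U12 intron).
#' @param exon_len,intron_len feature lengths in bp.
#' @return a list with `exons` (data.frame: gene_id, chrom, start, end,
#'   strand, exon_rank) and `u12_introns` (intron annotation data.frame as
#'   from [merge_u12_annotations()], subtype GT-AG or AT-AC, source
#'   "synthetic").
#' @export
simulate_gene_models <- function(config, n_exons = 9, exon_len = 150,
                                 intron_len = 1000) {
  stopifnot(inherits(config, "as_event_config"), n_exons >= 7)
  n <- config$n_genes
  with_seed(config$seed, {
    gene_span <- n_exons * exon_len + (n_exons - 1) * intron_len
    gap <- 10000L
    gene_ids <- sprintf("gene%04d", seq_len(n))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    n_u12 <- round(config$frac_u12_genes * n)
    u12_genes <- if (n_u12 > 0) sort(sample.int(n, n_u12)) else integer()

    exon_rows <- vector("list", n)
    u12_rows <- vector("list", length(u12_genes))
    ui <- 0L
    for (g in seq_len(n)) {
      g0 <- (g - 1L) * (gene_span + gap)
      starts <- g0 + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
      exon_rows[[g]] <- data.frame(
        gene_id = gene_ids[g], chrom = "chrS",
        start = starts, end = starts + exon_len,
        strand = strands[g], exon_rank = seq_len(n_exons),
        stringsAsFactors = FALSE)
      if (g %in% u12_genes) {
        ui <- ui + 1L
        # internal intron, >= 2 features from either gene end
        idx <- sample(3:(n_exons - 3), 1L)
        u12_rows[[ui]] <- data.frame(
          chrom = "chrS",
          start = starts[idx] + exon_len,
          end = starts[idx + 1L],
          strand = strands[g],
          subtype = sample(c("GT-AG", "AT-AC"), 1L, prob = c(0.7, 0.3)),
          sources = "synthetic",
          stringsAsFactors = FALSE)
      }
    }
    list(exons = do.call(rbind, exon_rows),
         u12_introns = do.call(rbind, u12_rows))
  })
}

# introns of one gene (0-based half-open), from its ordered exons
gene_introns <- function(exons_one_gene) {
  e <- exons_one_gene[order(exons_one_gene$start), , drop = FALSE]
  k <- nrow(e)
  if (k < 2L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = e$end[-k], end = e$start[-1L])
}

#' Simulate an alternative-splicing event table with planted AA enrichment
#'
#' Emits `n_events` Whippet-style events placed within, immediately
#' flanking, or distal to U12-type introns (for U12-host genes), or
#' anywhere in background genes hosting only major-type introns. In the
#' U12-proximal strata the alternative-acceptor probability is multiplied
#' by `aa_enrichment_fold`. Significance annotations (`probability`,
#' `delta_psi`) are drawn independently of event type and stratum, so
#' filtering does not distort the planted fold: `probability ~ Beta(6, 1)`
#' and `|delta_psi| ~ 0.8 * Beta(2, 5)` with random sign; `psi_a` is drawn
#' uniformly from the interval keeping `psi_b = psi_a + delta_psi` in
#' `[0, 1]`.
#'
#' @param config an [as_event_config()].
#' @param u12_introns intron annotation data.frame (chrom, start, end,
#'   strand, ...); every interval must fall inside a gene model.
#' @param gene_models exon data.frame as produced by
#'   [simulate_gene_models()]`$exons`.
#' @return a data.frame with columns gene_id, event_type, chrom, start,
#'   end, strand, psi_a, psi_b, delta_psi, probability.
#' @export
simulate_as_events <- function(config, u12_introns, gene_models) {
  stopifnot(inherits(config, "as_event_config"))
  genes <- split(gene_models, gene_models$gene_id)
  spans <- do.call(rbind, lapply(genes, function(e) {
    data.frame(gene_id = e$gene_id[1L], start = min(e$start),
               end = max(e$end), strand = e$strand[1L],
               stringsAsFactors = FALSE)
  }))
  # map each U12 intron to its host gene; orphan introns are a consistency
  # error, not silently dropped
  host_of <- function(i) {
    hit <- which(spans$start <= u12_introns$start[i] &
                   spans$end >= u12_introns$end[i] &
                   spans$strand == u12_introns$strand[i])
    if (length(hit) == 0L) {
      stop(sprintf("U12 intron %s:%d-%d lies outside all gene models",
                   u12_introns$chrom[i], u12_introns$start[i],
                   u12_introns$end[i]), call. = FALSE)
    }
    spans$gene_id[hit[1L]]
  }
  n_u12 <- if (is.null(u12_introns)) 0L else nrow(u12_introns)
  u12_host <- if (n_u12 > 0) vapply(seq_len(n_u12), host_of, "") else character()

  w <- config$event_type_weights
  types <- names(w)
  # planted stratum type distribution: AA mass scaled by the fold, the
  # other types share the remainder proportionally
  w_u12 <- w
  w_u12[["AA"]] <- config$aa_enrichment_fold * w[["AA"]]
  rest <- setdiff(types, "AA")
  w_u12[rest] <- w[rest] * (1 - w_u12[["AA"]]) / sum(w[rest])

  sub_interval <- function(start, end) {
    len <- max(1L, min(end - start, sample(20:80, 1L)))
    s <- start + sample.int(end - start - len + 1L, 1L) - 1L
    c(s, s + len)
  }

  with_seed(config$seed, {
    n <- config$n_events
    gene_ids <- names(genes)
    is_u12_gene <- stats::setNames(gene_ids %in% u12_host, gene_ids)
    ev_gene <- character(n); ev_type <- character(n)
    ev_chrom <- character(n); ev_strand <- character(n)
    ev_start <- integer(n); ev_end <- integer(n)
    sorted_exons <- lapply(genes, function(e) {
      e[order(e$start), , drop = FALSE]
    })
    sorted_introns <- lapply(sorted_exons, gene_introns)
    for (i in seq_len(n)) {
      g <- sample(gene_ids, 1L)
      exons <- sorted_exons[[g]]
      introns <- sorted_introns[[g]]
      if (is_u12_gene[g]) {
        u12 <- u12_introns[u12_host == g, , drop = FALSE][1L, ]
        u12_idx <- which(introns$start == u12$start & introns$end == u12$end)
        loc <- sample(c("within", "proximal", "distal"), 1L,
                      prob = c(0.4, 0.3, 0.3))
        tw <- if (loc %in% c("within", "proximal")) w_u12 else w
        if (loc == "within") {
          iv <- sub_interval(u12$start, u12$end)
        } else if (loc == "proximal") {
          # immediate flanking features: exons u12_idx / u12_idx+1,
          # introns u12_idx -/+ 1
          feats <- rbind(
            data.frame(start = exons$start[u12_idx],
                       end = exons$end[u12_idx]),
            data.frame(start = exons$start[u12_idx + 1L],
                       end = exons$end[u12_idx + 1L]),
            introns[c(u12_idx - 1L, u12_idx + 1L), c("start", "end")])
          f <- feats[sample.int(nrow(feats), 1L), ]
          iv <- sub_interval(f$start, f$end)
        } else {
          # >= 2 features away from the U12 intron: terminal exons
          f <- exons[sample(c(1L, nrow(exons)), 1L), ]
          iv <- sub_interval(f$start, f$end)
        }
      } else {
        tw <- w
        f <- exons[sample.int(nrow(exons), 1L), ]
        iv <- sub_interval(f$start, f$end)
      }
      ev_gene[i] <- g
      ev_type[i] <- sample(types, 1L, prob = tw)
      ev_chrom[i] <- exons$chrom[1L]
      ev_strand[i] <- exons$strand[1L]
      ev_start[i] <- iv[1L]
      ev_end[i] <- iv[2L]
    }
    # significance annotations are independent of type and stratum, so the
    # Pr/|dPSI| filter leaves the planted type composition untouched
    prob <- stats::rbeta(n, 6, 1)
    dpsi <- sample(c(-1, 1), n, replace = TRUE) * 0.8 * stats::rbeta(n, 2, 5)
    psi_a <- stats::runif(n, pmax(0, -dpsi), pmin(1, 1 - dpsi))
    data.frame(gene_id = ev_gene, event_type = ev_type, chrom = ev_chrom,
               start = ev_start, end = ev_end, strand = ev_strand,
               psi_a = psi_a, psi_b = psi_a + dpsi, delta_psi = dpsi,
               probability = prob, stringsAsFactors = FALSE)
  })
}
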