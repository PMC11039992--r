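config_error <- function(...) {
  stop(structure(class = c("u12kit_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Load and validate a run configuration
#'
#' A run is described by one declarative YAML file with a mandatory global
#' `seed`, an `out_dir`, and a `stages` block whose keys select what runs:
#' `profiles`, `events`, `emsa` (simulation), `coevolve`, `splice`, `fit`
#' (analysis). Unknown keys — at the top level or inside a stage — are
#' rejected outright rather than ignored, so typos cannot silently disable
#' options. Flag overrides (CLI) take precedence over the file.
#'
#' @param path YAML file path, or a list with the same structure.
#' @param overrides named list merged over the file contents (flags win).
#' @return validated config list.
#' @export
load_run_config <- function(path, overrides = list()) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  allowed <- c("seed", "out_dir", "stages", "log_level")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    config_error("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$seed)) {
    config_error("`seed` is mandatory for stochastic stages")
  }
  if (is.null(cfg$out_dir)) config_error("`out_dir` is required")
  if (is.null(cfg$stages) || length(cfg$stages) == 0L) {
    config_error("`stages` must name at least one stage")
  }
  known_stages <- c("profiles", "events", "emsa", "coevolve", "splice",
                    "fit")
  unknown <- setdiff(names(cfg$stages), known_stages)
  if (length(unknown) > 0L) {
    config_error("unknown stages: ", paste(unknown, collapse = ", "))
  }
  cfg
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Execute a configured workflow end to end
#'
#' Runs the requested stages in dependency order (simulation before
#' analysis), writes each stage's primary outputs under `out_dir`, and
#' finishes by atomically writing `manifest.json` recording the package
#' version, a hash of the resolved configuration, md5 checksums of every
#' written file, and per-stage runtimes. Identical config + seed yields
#' byte-identical primary outputs.
#'
#' @param config a path or list accepted by [load_run_config()].
#' @param overrides named list of flag overrides (see [load_run_config()]).
#' @return the manifest, invisibly.
#' @export
run_workflow <- function(config, overrides = list()) {
  cfg <- load_run_config(config, overrides)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  stages <- cfg$stages
  outputs <- list()
  runtimes <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    files <- fun(stages[[name]])
    runtimes[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    outputs[[name]] <<- files
  }

  order_of <- c("profiles", "events", "emsa", "coevolve", "splice", "fit")
  for (name in intersect(order_of, names(stages))) {
    run_stage(name, switch(
      name,
      profiles = function(s) stage_profiles(s, seed, out_dir, state),
      events = function(s) stage_events(s, seed, out_dir, state),
      emsa = function(s) stage_emsa(s, seed, out_dir, state),
      coevolve = function(s) stage_coevolve(s, out_dir, state),
      splice = function(s) stage_splice(s, out_dir, state),
      fit = function(s) stage_fit(s, out_dir, state)))
  }

  files <- unlist(outputs, use.names = FALSE)
  manifest <- list(
    artifact = "u12kit",
    version = as.character(utils::packageVersion("u12kit")),
    config_hash = digest::digest(cfg, algo = "md5"),
    seed = seed,
    outputs = outputs,
    checksums = as.list(tools::md5sum(files)),
    runtimes_s = runtimes)
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  write_json_out(manifest, tmp)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

stage_profiles <- function(s, seed, out_dir, state) {
  s <- s %||% list()
  tree <- simulate_tree(s$n_species %||% 120, seed)
  model <- loss_model(lambda = s$lambda %||% 1,
                      module_members = sprintf("MOD%02d",
                                               seq_len(s$module_size %||% 10)),
                      rho = s$rho %||% 0.8)
  mat <- simulate_gene_loss(tree, s$n_background %||% 2000, model, seed)
  tree_path <- file.path(out_dir, "tree.nwk")
  mat_path <- file.path(out_dir, "profiles.tsv")
  write_newick(tree, tree_path)
  write_profiles(mat, mat_path)
  state$profiles <- mat
  state$module <- model$module_members
  c(tree_path, mat_path)
}

stage_events <- function(s, seed, out_dir, state) {
  s <- s %||% list()
  cfg <- as_event_config(
    n_genes = s$n_genes %||% 200,
    frac_u12_genes = s$frac_u12_genes %||% 0.3,
    n_events = s$n_events %||% 2000,
    aa_enrichment_fold = s$aa_enrichment_fold %||% 3,
    seed = seed)
  models <- simulate_gene_models(cfg)
  events <- simulate_as_events(cfg, models$u12_introns, models$exons)
  bed <- file.path(out_dir, "u12_introns.bed")
  gm <- file.path(out_dir, "gene_models.bed")
  ev <- file.path(out_dir, "events.tsv")
  write_bed(models$u12_introns, bed)
  write_gene_models_bed12(models$exons, gm)
  write_as_events(events, ev)
  state$events <- events
  state$gene_models <- models$exons
  state$u12 <- models$u12_introns
  c(bed, gm, ev)
}

stage_emsa <- function(s, seed, out_dir, state) {
  s <- s %||% list()
  cfg <- binding_config(kd_true = s$kd_true %||% 2.14,
                        bmax_true = s$bmax_true %||% 1,
                        noise_sd = s$noise_sd %||% 0.02,
                        n_replicates = s$n_replicates %||% 3,
                        seed = seed)
  dat <- simulate_emsa(cfg)
  path <- file.path(out_dir, "emsa.tsv")
  utils::write.table(dat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  state$emsa <- dat
  path
}

stage_coevolve <- function(s, out_dir, state) {
  s <- s %||% list()
  mat <- if (!is.null(s$matrix)) build_profiles(s$matrix) else state$profiles
  if (is.null(mat)) config_error("coevolve stage needs a `matrix` or a profiles stage")
  query <- s$query %||% state$module[1L]
  reference <- s$reference %||% setdiff(state$module, query)
  ranking <- rank_coevolution(query, mat)
  rank_path <- file.path(out_dir, "ranking.tsv")
  write_ranking(ranking, rank_path)
  out <- rank_path
  if (length(reference) > 0L) {
    rec <- evaluate_recovery(ranking, reference, k = s$k %||% 20)
    rec_path <- file.path(out_dir, "recovery.json")
    write_json_out(list(reference_set = rec$reference_set,
                        ranks = as.list(rec$ranks),
                        top_k_hits = rec$top_k_hits, k = rec$k,
                        auc = rec$auc), rec_path)
    out <- c(out, rec_path)
  }
  out
}

stage_splice <- function(s, out_dir, state) {
  s <- s %||% list()
  events <- if (!is.null(s$events)) read_as_events(s$events) else state$events
  u12 <- if (!is.null(s$u12_bed)) {
    merge_u12_annotations(s$u12_bed)
  } else state$u12
  models <- if (!is.null(s$gene_models)) {
    read_gene_models(s$gene_models)
  } else state$gene_models
  if (is.null(events) || is.null(u12) || is.null(models)) {
    config_error("splice stage needs events/u12_bed/gene_models or an events stage")
  }
  sig <- filter_significant_events(events, s$pr_min %||% 0.9,
                                   s$dpsi_min %||% 0.05)
  cls <- classify_events(sig, u12, models)
  cls_path <- file.path(out_dir, "classified_events.tsv")
  utils::write.table(cls$events, cls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  types <- intersect(c("AA", "AD", "CE", "RI"),
                     unique(cls$events$event_type))
  enr <- lapply(types, function(t) {
    r <- enrichment_test(cls$events, t)
    list(event_type = t, counts = as.list(r$counts),
         fold_vs_background = r$fold_vs_background,
         fold_vs_overall = r$fold_vs_overall,
         p_upper = r$p_upper, p_lower = r$p_lower,
         p_two_sided = r$p_two_sided)
  })
  enr_path <- file.path(out_dir, "enrichment.json")
  write_json_out(enr, enr_path)
  c(cls_path, enr_path)
}

stage_fit <- function(s, out_dir, state) {
  s <- s %||% list()
  dat <- if (!is.null(s$data)) read_binding_table(s$data) else state$emsa
  if (is.null(dat)) config_error("fit stage needs `data` or an emsa stage")
  est <- fit_one_site(dat,
                      init = if (!is.null(s$init_kd)) {
                        c(s$init_kd, s$init_bmax %||% max(dat$fraction_bound))
                      })
  path <- file.path(out_dir, "kd_estimate.json")
  write_json_out(list(kd = est$kd, bmax = est$bmax, kd_se = est$kd_se,
                      bmax_se = est$bmax_se, rss = est$rss,
                      n_obs = est$n_obs), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
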