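#' Load a pipeline run configuration
#'
#' Reads a YAML file describing one end-to-end run: input paths
#' (`compounds`, `predictions`, `module_annotations`, `gmt`, optional
#' `cohort`), screening thresholds (`screen:` ob_min / caco2_min / dl_min /
#' inclusive), network flags (`prune_isolated`, `normalized_betweenness`),
#' enrichment options (`enrich_mode`, `alpha`), chemometrics options
#' (`n_components`, `cv_folds`, `n_perm`), a `seed` and an `out_dir`.
#' Referenced input files must exist at load time.
#'
#' @param path YAML file path.
#' @return A named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(screen = list(), prune_isolated = FALSE,
                   normalized_betweenness = TRUE,
                   enrich_mode = "standard", alpha = 0.05,
                   n_components = 2, cv_folds = 7, n_perm = 200,
                   seed = 1, out_dir = "netpharm-out")
  cfg <- utils::modifyList(defaults, cfg)
  for (key in c("compounds", "predictions", "module_annotations", "gmt")) {
    if (is.null(cfg[[key]])) {
      stop("config lacks required input path: ", key, call. = FALSE)
    }
  }
  for (key in intersect(c("compounds", "predictions", "module_annotations",
                          "gmt", "cohort"), names(cfg))) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("configured input does not exist: ", cfg[[key]], call. = FALSE)
    }
  }
  cfg
}

# Compounds of a module: screened compounds with >= 1 kept interaction to a
# module target; herbs: all herbs attributed to those compounds.
.module_members <- function(screened, kept_edges, module_targets) {
  e <- kept_edges[kept_edges$target %in% module_targets, , drop = FALSE]
  comp <- intersect(screened$compound_id, unique(e$compound_id))
  e <- e[e$compound_id %in% comp, , drop = FALSE]
  hl <- strsplit(screened$herbs[match(comp, screened$compound_id)], ";",
                 fixed = TRUE)
  attr_edges <- data.frame(herb = trimws(unlist(hl)),
                           compound = rep(comp, lengths(hl)),
                           stringsAsFactors = FALSE)
  attr_edges <- attr_edges[nzchar(attr_edges$herb), , drop = FALSE]
  list(compounds = comp, herbs = sort(unique(attr_edges$herb)),
       targets = sort(unique(e$target)),
       attribution = attr_edges,
       interaction = data.frame(compound = e$compound_id, target = e$target,
                                stringsAsFactors = FALSE))
}

#' Run the full network-pharmacology pipeline
#'
#' Executes, in order: ADMET screening, interaction filtering, module
#' assignment of targets, construction of the hemorheology and coagulopathy
#' herb-compound-target networks with centrality ranking, pathway
#' over-representation per module, cross-module overlap analysis of
#' compounds / targets / significant pathways, and (when a cohort file is
#' configured) the chemometric evaluation: all-group PLS-DA with group
#' distance-to-control ranking, control-vs-model PLS-DA with VIP scores and
#' permutation validation, and summary one-way ANOVA per index.
#'
#' All intermediate tables are written as TSV under `out_dir`, networks as
#' SIF, and a single `summary.json` (deterministic key order, 9 significant
#' digits) plus a `manifest.json` recording the configuration and seed.
#' A stage failure aborts with the stage name; outputs of completed stages
#' are preserved.
#'
#' @param config A config list (see [read_run_config()]) or the path to a
#'   YAML config file.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  compounds <- stage("read", read_compound_table(config$compounds))
  preds <- stage("read", read_prediction_table(config$predictions))
  mod_ann <- stage("read", read_module_annotations(config$module_annotations))
  collection <- stage("read", read_gmt(config$gmt))

  scr_cfg <- do.call(screen_config, config$screen)
  screened <- stage("screen", apply_admet_filter(compounds, scr_cfg))
  .write_tsv(screened, file.path(out_dir, "screened_compounds.tsv"))

  kept <- stage("filter_predictions", filter_predictions(preds))
  kept <- kept[kept$compound_id %in% screened$compound_id, , drop = FALSE]
  .write_tsv(kept, file.path(out_dir, "kept_interactions.tsv"))

  modules <- stage("assign_modules",
                   assign_modules(unique(kept$target), mod_ann))

  summary <- list(seed = config$seed,
                  n_compounds_screened = nrow(screened),
                  n_interactions_kept = nrow(kept),
                  module_target_sizes = list(
                    hemorheology = length(modules$hemorheology),
                    coagulopathy = length(modules$coagulopathy),
                    shared = length(modules$shared)))

  nets <- list()
  enrich_hits <- list()
  for (mod in c("hemorheology", "coagulopathy")) {
    mem <- .module_members(screened, kept, modules[[mod]])
    net <- stage("network", build_network(
      mem$herbs, mem$compounds, mem$targets,
      mem$attribution, mem$interaction, module_name = mod,
      prune_isolated = isTRUE(config$prune_isolated)))
    nets[[mod]] <- net
    cent <- stage("centrality",
                  centrality_table(net, normalized = isTRUE(config$normalized_betweenness)))
    .write_tsv(cent, file.path(out_dir, paste0("centrality_", mod, ".tsv")))
    write_sif(net, file.path(out_dir, paste0("network_", mod, ".sif")))
    er <- stage("enrich", enrich(mem$targets, collection,
                                 mode = config$enrich_mode,
                                 alpha = config$alpha))
    .write_tsv(er, file.path(out_dir, paste0("enrichment_", mod, ".tsv")))
    enrich_hits[[mod]] <- er$category_id[er$significant]
    summary[[paste0("network_", mod)]] <- list(
      nodes = nrow(net$nodes), edges = nrow(net$edges),
      herbs = sum(net$nodes$type == "herb"),
      compounds = sum(net$nodes$type == "compound"),
      targets = sum(net$nodes$type == "target"),
      top_compounds_by_degree = rank_top_k(cent, "degree", 10,
                                           node_type = "compound")$node_id,
      top_targets_by_degree = rank_top_k(cent, "degree", 10,
                                         node_type = "target")$node_id,
      n_enriched = sum(er$significant))
  }

  comp_overlap <- overlap(nets$hemorheology$nodes$id[nets$hemorheology$nodes$type == "compound"],
                          nets$coagulopathy$nodes$id[nets$coagulopathy$nodes$type == "compound"])
  targ_overlap <- overlap(modules$hemorheology, modules$coagulopathy)
  path_overlap <- overlap(enrich_hits$hemorheology, enrich_hits$coagulopathy)
  summary$overlap <- list(
    compounds = unclass(comp_overlap)[c("size_a", "size_b", "size_union",
                                        "size_intersection")],
    targets = unclass(targ_overlap)[c("size_a", "size_b", "size_union",
                                      "size_intersection")],
    pathways = unclass(path_overlap)[c("size_a", "size_b", "size_union",
                                       "size_intersection")])

  summary$herb_contribution <- stage("herb_contribution",
    herb_contribution(nets$hemorheology, nets$coagulopathy,
                      screened[, c("compound_id", "herbs")]))
  .write_tsv(summary$herb_contribution,
             file.path(out_dir, "herb_contribution.tsv"))

  if (!is.null(config$cohort)) {
    cohort <- stage("read", read_cohort(config$cohort))
    x <- as.matrix(cohort[, cohort_index_names()])
    model_all <- stage("chemo", plsda(x, cohort$group,
                                      n_components = config$n_components,
                                      cv_folds = config$cv_folds))
    ranking <- group_distance_ranking(model_all$scores, cohort$group, "control")
    cm <- cohort$group %in% c("control", "model")
    model_cm <- stage("chemo", plsda(x[cm, , drop = FALSE],
                                     droplevels(cohort$group[cm]),
                                     n_components = config$n_components,
                                     cv_folds = config$cv_folds))
    vips <- vip(model_cm)
    perm <- stage("chemo", permutation_validate(
      x[cm, , drop = FALSE], droplevels(cohort$group[cm]), model_cm,
      n_perm = config$n_perm, seed = config$seed))
    av <- .cohort_summary_anova(cohort)
    vt <- data.frame(index = names(vips), vip = unname(vips))
    .write_tsv(vt, file.path(out_dir, "vip.tsv"))
    .write_tsv(ranking, file.path(out_dir, "group_distance.tsv"))
    .write_tsv(av$anova, file.path(out_dir, "anova.tsv"))
    summary$chemometrics <- list(
      plsda_all = list(r2x = model_all$r2x_cum[config$n_components],
                       r2y = model_all$r2y_cum[config$n_components],
                       q2 = model_all$q2),
      group_distance = ranking,
      plsda_control_model = list(r2x = model_cm$r2x_cum[config$n_components],
                                 r2y = model_cm$r2y_cum[config$n_components],
                                 q2 = model_cm$q2),
      vip = as.list(vips),
      permutation = list(n_perm = config$n_perm, valid = perm$valid,
                         r2_intercept = perm$r2_intercept,
                         q2_intercept = perm$q2_intercept))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 9, pretty = TRUE)
  manifest <- list(package = "netpharm",
                   version = as.character(utils::packageVersion("netpharm")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 9, pretty = TRUE)
  invisible(summary)
}

# Per-index summary ANOVA of a raw cohort (via the summary-statistic path so
# the printed-table workflow and the raw-data workflow share one code path).
.cohort_summary_anova <- function(cohort) {
  idx <- cohort_index_names()
  by_g <- split(cohort[idx], cohort$group)
  means <- do.call(rbind, lapply(by_g, colMeans))
  sds <- do.call(rbind, lapply(by_g, function(d) apply(d, 2, stats::sd)))
  ns <- vapply(by_g, nrow, integer(1))
  summary_anova(means, sds, ns,
                control = if ("control" %in% rownames(means)) "control" else NULL,
                model_group = if ("model" %in% rownames(means)) "model" else NULL)
}
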