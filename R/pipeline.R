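#' Read a run configuration
#'
#' Loads a YAML or JSON run configuration (by file extension) and checks
#' its schema before any compute. Required keys: `out_dir`, and
#' `inputs$mrna`, `inputs$mirna`, `inputs$clinical`. Per-modality blocks
#' `mrna:`/`mirna:` hold `method` (kmeans|spectral|community), `k`,
#' `seed`, `n_restarts`, `similarity`, `log_transform`, `normalize`,
#' `feature_list`; a `graph:` block holds `metric`, `threshold`,
#' `layout_seed`, `layout_iterations`; an `integrate:` block holds `gap`.
#' Missing optional keys fall back to documented defaults.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`), or a list
#'   already in config shape.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                               simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required")
  for (key in c("mrna", "mirna", "clinical"))
    if (is.null(cfg$inputs[[key]]))
      stop("config error: inputs$", key, " is required")
  defaults <- list(method = "kmeans", k = 2, seed = 1, n_restarts = 10,
                   similarity = "euclidean_rbf", log_transform = FALSE,
                   normalize = "none", feature_list = NULL)
  for (mod in c("mrna", "mirna")) {
    blk <- cfg[[mod]] %||% list()
    for (nm in names(defaults))
      if (is.null(blk[[nm]])) blk[[nm]] <- defaults[[nm]]
    if (!blk$method %in% c("kmeans", "spectral", "community"))
      stop("config error: ", mod, "$method must be kmeans, spectral or community")
    if (blk$method %in% c("kmeans", "spectral") && blk$k < 2)
      stop("config error: ", mod, "$k must be at least 2")
    cfg[[mod]] <- blk
  }
  gdef <- list(metric = "euclidean", threshold = 0.2, layout_seed = 1,
               layout_iterations = 300)
  g <- cfg$graph %||% list()
  for (nm in names(gdef)) if (is.null(g[[nm]])) g[[nm]] <- gdef[[nm]]
  cfg$graph <- g
  if (is.null(cfg$integrate$gap)) cfg$integrate$gap <- 0.02
  cfg
}

# Load inputs, align, feature-select, preprocess: shared front half of
# the cluster and integrate commands.
prepare_inputs <- function(cfg) {
  mrna <- load_expression(cfg$inputs$mrna, "mRNA")
  mirna <- load_expression(cfg$inputs$mirna, "miRNA")
  clin <- load_clinical(cfg$inputs$clinical,
                        columns = cfg$clinical_columns %||%
                          formals(load_clinical)$columns)
  al <- align_modalities(mrna, mirna, clin)
  mats <- list(mrna = al$a, mirna = al$b)
  for (mod in c("mrna", "mirna")) {
    blk <- cfg[[mod]]
    if (!is.null(blk$feature_list)) {
      fl <- load_feature_list(blk$feature_list, mats[[mod]]$modality)
      mats[[mod]] <- select_features(mats[[mod]], fl)
    }
    mats[[mod]] <- preprocess(mats[[mod]],
                              log_transform = isTRUE(blk$log_transform),
                              normalize = blk$normalize)
  }
  list(mats = mats, clin = al$clin)
}

cluster_one_modality <- function(mat, blk, graph_cfg) {
  if (blk$method == "kmeans") {
    kmeans_cluster(mat, k = blk$k, seed = blk$seed,
                   n_restarts = blk$n_restarts)
  } else if (blk$method == "spectral") {
    spectral_cluster(mat, k = blk$k, seed = blk$seed,
                     similarity = blk$similarity,
                     n_restarts = blk$n_restarts)
  } else {
    S <- similarity_matrix(mat, metric = graph_cfg$metric)
    community_cluster(sparsify(S, graph_cfg$threshold), seed = blk$seed,
                      modality = mat$modality)
  }
}

write_manifest <- function(cfg, out_dir, extra = list()) {
  inputs <- unlist(cfg$inputs)
  manifest <- c(list(
    package = "omicstrat",
    version = as.character(utils::packageVersion("omicstrat")),
    r_version = R.version.string,
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(inputs)),
    config = cfg[setdiff(names(cfg), "inputs")]), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the per-modality clustering phase
#'
#' Batch equivalent of the clustering phase: loads and aligns the inputs,
#' clusters each modality, and writes per-modality artifacts into
#' `out_dir`: `<mod>_labels.csv`, `<mod>_silhouette.json`,
#' `<mod>_ordered.tsv` + `<mod>_blocks.json` (heatmap backing data),
#' `<mod>_edges.tsv`/`<mod>_vertices.tsv` (thresholded similarity graph
#' with force-directed layout), plus a `manifest.json` recording inputs,
#' hashes, parameters and seeds. Pure function of (config, input files).
#'
#' @param config Path to a YAML/JSON run config, or an equivalent list
#'   (see [read_run_config]).
#' @return Invisibly, a list with the two [cluster_assignment]s, the
#'   aligned clinical table and the prepared matrices.
#' @export
run_cluster <- function(config) {
  cfg <- read_run_config(config)
  prep <- prepare_inputs(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assigns <- list()
  for (mod in c("mrna", "mirna")) {
    mat <- prep$mats[[mod]]
    blk <- cfg[[mod]]
    assign <- cluster_one_modality(mat, blk, cfg$graph)
    assigns[[mod]] <- assign
    utils::write.csv(data.frame(sample_id = assign$sample_ids,
                                label = assign$labels),
                     file.path(out_dir, paste0(mod, "_labels.csv")),
                     row.names = FALSE, quote = FALSE)
    if (assign$k >= 2) {
      sil <- silhouette_scores(mat, assign)
      jsonlite::write_json(
        list(per_sample_scores = as.list(sil$per_sample_scores),
             per_cluster_mean = sil$per_cluster_mean,
             overall_mean = sil$overall_mean,
             ordering = sil$ordering),
        file.path(out_dir, paste0(mod, "_silhouette.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      message(mod, ": single cluster, silhouette skipped")
    }
    om <- ordered_matrix(mat, assign)
    write_expression(om$matrix, file.path(out_dir, paste0(mod, "_ordered.tsv")))
    jsonlite::write_json(list(boundaries = om$boundaries),
                         file.path(out_dir, paste0(mod, "_blocks.json")),
                         digits = NA, pretty = TRUE)
    S <- similarity_matrix(mat, metric = cfg$graph$metric)
    g <- sparsify(S, cfg$graph$threshold)
    g <- force_layout(g, seed = cfg$graph$layout_seed,
                      iterations = cfg$graph$layout_iterations)
    export_graph(g, file.path(out_dir, mod), assign = assign)
  }
  write_manifest(cfg, out_dir)
  invisible(list(assignments = assigns, clin = prep$clin,
                 matrices = prep$mats))
}

#' Read a declarative subgroup-selections file
#'
#' YAML/JSON replacement for clicking blocks and ribbons: a top-level
#' `selections:` list whose entries have a `name` and optional `blocks`
#' (pairs `[axis, label]`), `ribbons` (pairs `[label_a, label_b]`) or
#' `complement_of: <name>` referring to an earlier selection.
#'
#' @param path Selections file path, or an equivalent list.
#' @param model A laid-out `parallel_sets_model`.
#' @return Named list of `subgroup_selection` objects.
#' @export
read_selections <- function(path, model) {
  spec <- if (is.list(path)) path
          else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                                simplifyVector = FALSE)
          else yaml::read_yaml(path)
  entries <- spec$selections %||% spec
  out <- list()
  for (e in entries) {
    if (is.null(e$name)) stop("selection without a name")
    if (!is.null(e$complement_of)) {
      base <- out[[e$complement_of]]
      if (is.null(base))
        stop("complement_of refers to unknown selection '", e$complement_of, "'")
      out[[e$name]] <- complement_subgroup(model, base, e$name)
    } else {
      to_pairs <- function(x) if (is.null(x)) NULL else
        lapply(x, function(p) as.integer(unlist(p)))
      out[[e$name]] <- select_subgroup(model, e$name,
                                       blocks = to_pairs(e$blocks),
                                       ribbons = to_pairs(e$ribbons))
    }
  }
  out
}

#' Run the integrative stratification phase
#'
#' Recomputes the per-modality clusterings from the config (pure batch
#' semantics), cross-tabulates them into a parallel-sets model with
#' layout geometry, resolves the declared subgroup selections, and
#' compares their survival. Writes `parallel_sets.json`,
#' `survival.json`, `survival_curves.csv` and a manifest into `out_dir`.
#'
#' @param config Run config path or list (see [read_run_config]).
#' @param selections Selections file path or list (see [read_selections]).
#' @return Invisibly, a list with `model`, `subgroups` and `comparison`.
#' @export
run_integrate <- function(config, selections) {
  cfg <- read_run_config(config)
  res <- run_cluster(cfg)
  model <- cross_tabulate(res$assignments$mrna, res$assignments$mirna)
  model <- layout_parallel_sets(model, gap = cfg$integrate$gap)
  subgroups <- read_selections(selections, model)
  comparison <- compare_subgroups(res$clin, unname(subgroups))
  out_dir <- cfg$out_dir
  write_parallel_sets_json(model, file.path(out_dir, "parallel_sets.json"))
  write_survival_comparison(comparison,
                            json_path = file.path(out_dir, "survival.json"),
                            csv_path = file.path(out_dir,
                                                 "survival_curves.csv"))
  invisible(list(model = model, subgroups = subgroups,
                 comparison = comparison))
}

#' Simulate a cohort and write fixture files
#'
#' Builds a [cohort_spec] from a YAML/JSON file (or uses the default /
#' interaction scenario) and writes pipeline-ready fixture files.
#'
#' @param out_dir Output directory.
#' @param spec Optional spec file path or list of [cohort_spec] arguments;
#'   `"interaction"` selects the packaged [interaction_scenario].
#' @param seed Seed override (applied on top of the spec's seed if given).
#' @return Invisibly, the fixture paths.
#' @export
run_simulate <- function(out_dir, spec = NULL, seed = NULL) {
  cohort <- if (identical(spec, "interaction")) {
    interaction_scenario(seed %||% 1)
  } else {
    args <- if (is.null(spec)) list()
            else if (is.list(spec)) spec
            else if (grepl("\\.json$", spec)) jsonlite::read_json(spec,
                                                                  simplifyVector = TRUE)
            else yaml::read_yaml(spec)
    # YAML/JSON encode the tables as row lists
    for (nm in c("mixing", "hazard_table"))
      if (is.list(args[[nm]]))
        args[[nm]] <- do.call(rbind, lapply(args[[nm]], unlist))
    if (!is.null(seed)) args$seed <- seed
    generate_cohort(do.call(cohort_spec, args))
  }
  invisible(write_fixture(out_dir, cohort))
}
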