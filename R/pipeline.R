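#' Configuration for a full pipeline run
#'
#' Validates and assembles everything [run_pipeline()] needs: where the
#' input series come from (a synthetic [study_config()] or a directory of
#' series-bundle subdirectories), QC thresholds, the configuration grid
#' (batch methods and union methods), DEG thresholds, ANOVA factors,
#' ranking/classification options, an output directory and the root seed.
#'
#' @param study A [study_config()] for synthetic input, or NULL when
#'   `input_dir` is given.
#' @param input_dir Directory whose subdirectories are series bundles
#'   (read with [read_series_bundle()]).
#' @param out_dir Output directory for artifacts and the manifest
#'   (required).
#' @param qc QC options: `d_threshold`, `max_rounds`, `flag_rule`,
#'   `enabled`.
#' @param grid Grid options: `methods`, `unions`.
#' @param deg DEG thresholds: `lfc_min`, `p_max`, `p_type`.
#' @param anova_factors Factors for the robustness ANOVA.
#' @param classify Classification options: `schemes`, `k_folds`, `k_mi`,
#'   `samples_per_class` (Ward representatives), `max_genes`.
#' @param seed Root seed for fold assignment and MI jitter.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(study = NULL, input_dir = NULL, out_dir = NULL,
                            qc = list(), grid = list(), deg = list(),
                            anova_factors = c("TYPE", "BATCH", "METHOD",
                                              "COUNTRY"),
                            classify = list(), seed = 20180511) {
  if (is.null(out_dir)) stopf("pipeline_config: out_dir is required")
  if (is.null(study) && is.null(input_dir))
    stopf("pipeline_config: give either a study config or an input_dir")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stopf("pipeline_config: input_dir does not exist: %s", input_dir)
  if (!is.null(study)) validate_study_config(study)
  qc <- utils::modifyList(list(enabled = TRUE, d_threshold = 0.15,
                               max_rounds = 10, flag_rule = "majority"), qc)
  grid <- utils::modifyList(list(methods = batch_methods(),
                                 unions = c("mean", "median")), grid)
  deg <- utils::modifyList(list(lfc_min = 4.0, p_max = 0.001,
                                p_type = "raw"), deg)
  classify <- utils::modifyList(list(schemes = c("loo", "kfold"),
                                     k_folds = 10, k_mi = 3,
                                     samples_per_class = 5,
                                     max_genes = NULL), classify)
  if (deg$lfc_min <= 0 || deg$p_max <= 0) stopf("DEG thresholds must be > 0")
  bad <- setdiff(grid$methods, batch_methods())
  if (length(bad)) stopf("unknown batch method(s): %s",
                         paste(bad, collapse = ", "))
  structure(list(study = study, input_dir = input_dir, out_dir = out_dir,
                 qc = qc, grid = grid, deg = deg,
                 anova_factors = anova_factors, classify = classify,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Maps the YAML keys onto [pipeline_config()] arguments; a `study` block
#' is passed to [study_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  study <- if (!is.null(y$study)) do.call(study_config, y$study) else NULL
  pipeline_config(study = study, input_dir = y$input_dir,
                  out_dir = y$out_dir, qc = y$qc %||% list(),
                  grid = y$grid %||% list(), deg = y$deg %||% list(),
                  anova_factors = y$anova_factors %||%
                    c("TYPE", "BATCH", "METHOD", "COUNTRY"),
                  classify = y$classify %||% list(),
                  seed = y$seed %||% 20180511)
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[skinsig] ", fmt), ...))
}

#' Run the full integration and profiling pipeline
#'
#' Executes the complete phase sequence on one configuration: simulate or
#' ingest series bundles, per-series QC screening, scale homogenization,
#' the batch-method x union-method configuration grid with moderated-t DEG
#' selection, the configuration intersection, the least-squares deviation
#' ANOVA and Ward clustering of the surviving configurations, and mRMR
#' ranking with incremental cross-validated SVM curves. All artifacts are
#' written under `config$out_dir` as TSV/JSON, and a manifest JSON records
#' the seed, per-stage outputs and file checksums; identical configuration
#' and seed give identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage progress messages (default TRUE).
#' @return The run manifest (named list), invisibly; the full stage
#'   results are attached as attribute `"results"`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("skinsig")),
                   seed = config$seed, stages = list())

  # --- ingest / simulate -------------------------------------------------
  truth <- NULL
  if (!is.null(config$study)) {
    log_stage(verbose, "generating synthetic study (%d series)",
              config$study$n_series)
    sim <- generate_study(config$study)
    bundles <- sim$bundles
    truth <- sim$truth
  } else {
    dirs <- list.dirs(config$input_dir, recursive = FALSE)
    log_stage(verbose, "reading %d series bundle(s) from %s", length(dirs),
              config$input_dir)
    bundles <- lapply(dirs, read_series_bundle)
    names(bundles) <- vapply(bundles, function(b) b$series_id, "")
  }
  manifest$stages$input <- list(n_series = length(bundles),
                                series = names(bundles))

  # --- qc ----------------------------------------------------------------
  qc_reports <- list()
  if (isTRUE(config$qc$enabled)) {
    for (nm in names(bundles)) {
      b <- ensure_log2_scale(bundles[[nm]])
      rep_ <- qc_screen(b, d_threshold = config$qc$d_threshold,
                        max_rounds = config$qc$max_rounds,
                        flag_rule = config$qc$flag_rule)
      qc_reports[[nm]] <- rep_
      bundles[[nm]] <- apply_qc(bundles[[nm]], rep_)
    }
    removed <- sum(vapply(qc_reports, function(r) length(r$removed), 0L))
    log_stage(verbose, "QC removed %d sample(s)", removed)
    jsonlite::write_json(
      lapply(qc_reports, function(r)
        list(series = r$series_id, removed = r$removed,
             rounds = r$n_rounds, status = r$status)),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, pretty = TRUE)
    manifest$stages$qc <- list(removed_total = removed)
  }

  # --- grid --------------------------------------------------------------
  log_stage(verbose, "running %d x %d configuration grid",
            length(config$grid$methods), length(config$grid$unions))
  grid <- run_configuration_grid(
    bundles, methods = config$grid$methods, unions = config$grid$unions,
    lfc_min = config$deg$lfc_min, p_max = config$deg$p_max,
    p_type = config$deg$p_type)
  utils::write.table(
    data.frame(batch_method = rownames(grid$counts), grid$counts,
               check.names = FALSE),
    file.path(out_dir, "grid_deg_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$grid <- list(cells = length(grid$counts),
                               counts = as.list(as.data.frame(grid$counts)))

  # --- intersection ------------------------------------------------------
  inter <- intersect_configurations(grid)
  log_stage(verbose, "final DEG intersection: %d gene(s) from %d configuration(s)",
            length(inter$genes), length(inter$contributing))
  writeLines(inter$genes, file.path(out_dir, "final_degs.txt"))
  manifest$stages$intersection <- list(n_genes = length(inter$genes),
                                       contributing = inter$contributing,
                                       status = inter$status)
  if (!is.null(truth))
    manifest$stages$intersection$planted_recovered <-
      length(intersect(inter$genes, truth$planted_deg_symbols))

  results <- list(bundles = bundles, truth = truth, qc = qc_reports,
                  grid = grid, intersection = inter)

  if (length(inter$genes)) {
    ref_cfg <- grid$configs[[inter$contributing[1]]]
    summ <- summarize_degs(ref_cfg$selection, ref_cfg$contrast_table,
                           genes = inter$genes)
    utils::write.table(summ, file.path(out_dir, "deg_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$deg_summary <- summ

    # --- robustness ANOVA + clustering ----------------------------------
    variants <- grid$configs[inter$contributing]
    variants <- Filter(function(v) !is.null(v$expression), variants)
    if (length(variants) >= 2) {
      obs <- ls_deviation_table(variants, variants[[1]]$samples,
                                genes = inter$genes)
      anova_tab <- tryCatch(
        anova_main_effects(obs, factors = config$anova_factors),
        error = function(e) {
          log_stage(verbose, "ANOVA with all factors failed (%s); retrying without COUNTRY",
                    conditionMessage(e))
          anova_main_effects(obs, factors = setdiff(config$anova_factors,
                                                    "COUNTRY"))
        })
      utils::write.table(as.data.frame(anova_tab),
                         file.path(out_dir, "anova.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$ls_deviation <- obs
      results$anova <- anova_tab
    }
    wc <- ward_cluster(ref_cfg$expression[inter$genes, , drop = FALSE],
                       ref_cfg$samples$class_label,
                       samples_per_class = config$classify$samples_per_class)
    writeLines(wc$newick, file.path(out_dir, "dendrogram.nwk"))
    utils::write.table(
      data.frame(sample_id = wc$leaf_order,
                 class = wc$representative_classes[wc$leaf_order]),
      file.path(out_dir, "dendrogram_leaves.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$ward <- wc

    # --- ranking + classification ---------------------------------------
    log_stage(verbose, "mRMR ranking and incremental CV curves on %d gene(s)",
              length(inter$genes))
    ranking <- mrmr_rank(ref_cfg$expression[inter$genes, , drop = FALSE],
                         ref_cfg$samples$class_label,
                         k_mi = config$classify$k_mi,
                         jitter_seed = config$seed)
    utils::write.table(as.data.frame(ranking),
                       file.path(out_dir, "mrmr_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    curves <- incremental_curves(
      ref_cfg$expression, ref_cfg$samples$class_label, ranking,
      schemes = config$classify$schemes, k_folds = config$classify$k_folds,
      seed = config$seed, max_genes = config$classify$max_genes)
    utils::write.table(curves$curves, file.path(out_dir, "cv_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(curves$per_class,
                       file.path(out_dir, "cv_per_class.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$ranking <- ranking
    results$cv <- curves
    best7 <- curves$curves[curves$curves$taxonomy == "7-class", ]
    manifest$stages$classification <- list(
      n_ranked = nrow(ranking),
      best_7class_accuracy = max(best7$accuracy))
  } else {
    log_stage(verbose, "no final DEGs; skipping downstream stages")
  }

  files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$checksums <- as.list(stats::setNames(
    unname(tools::md5sum(files)), basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}
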