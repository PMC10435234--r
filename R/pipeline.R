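#' Pipeline configuration
#'
#' A pipeline run analyzes either a synthetic scenario (see
#' [default_scenario()]) or real data given as paths; exactly one of the
#' two must be present. Real-data configs name a directory of per-specimen
#' NIfTI label volumes, a specimen metadata TSV (`specimen_id`,
#' `population`, `file`), an ontology TSV, and optionally a landmark CSV.
#'
#' @param scenario a `scenario` list for synthetic runs, or `NULL`.
#' @param paths named list (`volumes_meta`, `ontology`, `landmarks`) for
#'   real-data runs, or `NULL`.
#' @param level ontology level to analyze (`fine`, `developmental`,
#'   `major`).
#' @param linkage,k,h clustering settings (see [cluster_regions()]).
#' @param n_perm permutation count for shape statistics.
#' @param seed integer seed recorded in every output.
#' @param dv_axis dorsoventral grid axis for depth profiling.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, paths = NULL, level = "fine",
                            linkage = "average", k = NULL, h = NULL,
                            n_perm = 199L, seed = 1L, dv_axis = 3L) {
  if (is.null(scenario) == is.null(paths))
    .config_error("exactly one of `scenario` and `paths` must be given")
  if (!is.null(paths)) {
    need <- c("volumes_meta", "ontology")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      .config_error("missing required path key(s): ",
                    paste(miss, collapse = ", "))
  }
  structure(list(scenario = scenario, paths = paths, level = level,
                 linkage = linkage, k = k, h = h,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 dv_axis = as.integer(dv_axis)),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#' @param path YAML file; a `scenario:` block is passed through
#'   [default_scenario()], other keys to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) y$scenario <- do.call(default_scenario, y$scenario)
  do.call(pipeline_config, y)
}

.config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("cavemorph_config_error",
                                             "error", "condition")))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (for synthetic configs) -> volumes -> compare ->
#' covary -> shapes -> integrate, writing all artifacts plus a JSON report
#' (settings, seed, package version, summary statistics) to `out_dir`.
#' The report carries no timestamps or absolute paths, so an identical
#' config and seed yields a byte-identical report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return The report, invisibly; written to `out_dir/report.json` along
#'   with TSV/NIfTI artifacts listed in the report's `manifest`.
#' @export
run_full_pipeline <- function(config, out_dir = tempfile("cavemorph_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(fn, writer) {
    writer(file.path(out_dir, fn))
    manifest <<- c(manifest, fn)
  }
  report <- list(package = "cavemorph",
                 version = as.character(utils::packageVersion("cavemorph")),
                 seed = config$seed,
                 settings = list(level = config$level,
                                 linkage = config$linkage,
                                 k = config$k, h = config$h,
                                 n_perm = config$n_perm))
  synthetic <- !is.null(config$scenario)

  # --- simulate / load ------------------------------------------------
  if (synthetic) {
    cohort <- simulate_cohort(config$scenario, seed = config$seed)
    vt <- cohort$volumes$table
    landmarks <- cohort$landmarks
    rep_vol <- NULL
    region_labels <- NULL
    if (isTRUE(config$scenario$render)) {
      rep_vol <- cohort$label_volumes[[1L]]
    } else {
      # render one representative individual for the depth profile
      lv <- render_cohort_label_volumes(
        vt$fractions[1L, , drop = FALSE],
        cohort$spec$assignment,
        grid_shape = config$scenario$grid_shape,
        brain_fill = config$scenario$brain_fill,
        voxel_size = config$scenario$voxel_size,
        dv_axis = config$scenario$dv_axis,
        seed = config$seed + 3L)
      rep_vol <- lv[[1L]]
      region_labels <- attr(lv, "region_labels")
    }
    if (is.null(region_labels))
      region_labels <- attr(cohort$label_volumes, "region_labels")
  } else {
    meta <- utils::read.delim(config$paths$volumes_meta,
                              stringsAsFactors = FALSE)
    if (!all(c("specimen_id", "population", "file") %in% names(meta)))
      .config_error("volumes_meta needs columns specimen_id, population, file")
    base_dir <- dirname(config$paths$volumes_meta)
    vols <- lapply(file.path(base_dir, meta$file), read_label_volume,
                   dv_axis = config$dv_axis)
    names(vols) <- meta$specimen_id
    onto <- load_ontology(config$paths$ontology)
    vt <- volume_table_from_volumes(vols, meta$population, onto,
                                    level = config$level)
    landmarks <- if (!is.null(config$paths$landmarks))
      read_landmark_table(config$paths$landmarks) else NULL
    rep_vol <- if (config$level == "fine") vols[[1L]]
               else aggregate_labels(vols[[1L]], onto, config$level)
    region_labels <- stats::setNames(as.integer(colnames(vt$fractions)),
                                     colnames(vt$fractions))
    cohort <- NULL
  }
  emit("volume_table.tsv", function(p) write_volume_table(vt, p))

  # --- compare populations --------------------------------------------
  pops <- table(vt$population)
  if (length(pops) >= 2L && all(pops >= 2L)) {
    stats_tab <- compare_groups(vt)
    emit("group_stats.tsv", function(p)
      utils::write.table(stats_tab, p, sep = "\t", row.names = FALSE,
                         quote = FALSE))
    report$compare <- list(n_regions = nrow(stats_tab),
                           n_significant_raw =
                             sum(stats_tab$p < 0.05, na.rm = TRUE))
  }

  # --- covariation ----------------------------------------------------
  corr <- volume_correlation_matrix(vt)
  partition <- cluster_regions(corr, linkage = config$linkage,
                               k = config$k, h = config$h)
  emit("volume_correlation.tsv", function(p) write_correlation_matrix(corr, p))
  emit("volume_partition.tsv", function(p) write_partition(partition, p))
  sizes <- table(partition$cluster)
  big <- as.integer(names(sizes)[sizes >= 2L])
  block_tests <- list()
  if (length(big) >= 2L) {
    for (pr in utils::combn(big, 2L, simplify = FALSE)) {
      bt <- cluster_block_test(corr, partition, pr)
      block_tests[[paste(pr, collapse = "_vs_")]] <-
        bt[c("t", "df", "p", "mean_within", "mean_between")]
    }
  }
  depth <- NULL
  if (!is.null(rep_vol) && !is.null(region_labels)) {
    lab_part <- partition
    names(lab_part$cluster) <- as.character(
      region_labels[names(partition$cluster)])
    depth <- cluster_depth_profile(lab_part, rep_vol,
                                   path = file.path(out_dir, "cluster_map.nii.gz"))
    manifest <- c(manifest, "cluster_map.nii.gz")
    emit("cluster_depth.tsv", function(p)
      utils::write.table(depth$profile, p, sep = "\t", row.names = FALSE,
                         quote = FALSE))
  }
  report$covary <- list(
    n_clusters = length(unique(partition$cluster)),
    cut = partition$cut,
    block_tests = block_tests,
    depth = if (!is.null(depth))
      stats::setNames(round(depth$profile$mean_depth, 6),
                      paste0("cluster", depth$profile$cluster)))

  # --- shapes + integration -------------------------------------------
  if (!is.null(landmarks)) {
    pc1 <- pc1_score_matrix(landmarks, vt)
    sma <- shape_module_analysis(pc1, linkage = config$linkage,
                                 k = config$k, h = config$h)
    emit("pc1_scores.tsv", function(p)
      utils::write.table(
        data.frame(specimen_id = rownames(pc1$scores), pc1$scores,
                   check.names = FALSE),
        p, sep = "\t", row.names = FALSE, quote = FALSE))
    emit("shape_correlation.tsv", function(p)
      write_correlation_matrix(sma$correlation, p))
    emit("shape_partition.tsv", function(p) write_partition(sma$partition, p))
    ari_shape_volume <- partition_agreement(sma$partition, partition)
    report$shapes <- list(
      n_regions = ncol(pc1$scores),
      n_specimens = nrow(pc1$scores),
      flipped = unname(which(pc1$flipped)),
      n_shape_clusters = length(unique(sma$partition$cluster)),
      ari_shape_vs_volume = ari_shape_volume)
  }
  if (synthetic) {
    truth <- stats::setNames(as.character(cohort$spec$assignment),
                             names(cohort$spec$assignment))
    report$recovery <- list(
      ari_volume_vs_truth = partition_agreement(partition$cluster,
                                                .as_membership(truth)),
      ari_shape_vs_truth = if (!is.null(landmarks))
        partition_agreement(sma$partition$cluster, .as_membership(truth)),
      mean_between_module_correlation = {
        m1 <- names(truth)[truth == unique(truth)[1L]]
        m2 <- names(truth)[truth != unique(truth)[1L]]
        mean(corr$r[m1, m2])
      })
  }
  report$manifest <- manifest
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

# named character/factor membership vector -> integer cluster ids
.as_membership <- function(x) {
  stats::setNames(as.integer(factor(x)), names(x))
}
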