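#' Configuration of an end-to-end pipeline run
#'
#' Bundles every stage's settings: the synthetic cohort, the CER/NER split
#' percentile, which delineations / modalities / rankers / classifiers to
#' evaluate, the feature-count range, and the master seed that every
#' stochastic stage derives its stream from.
#'
#' @param cohort A [cohort_config()].
#' @param percentile CER/NER split percentile (default 0.90).
#' @param delineations Subset of `c("total", "cer_ner")`.
#' @param modalities Subset of `c("cmri", "pwi", "dki", "cpd")`.
#' @param rankers Subset of the six [rank_features()] methods.
#' @param classifiers List of [classifier_spec()]s.
#' @param n_features Feature counts for round-2 evaluation (subset of 1..10).
#' @param ranker_trees Trees for the ranking forests (default 10000).
#' @param seed Master seed for selection/classification stages.
#' @param alpha Significance level for the group comparison.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            percentile = 0.90,
                            delineations = DELINEATIONS,
                            modalities = names(MODALITY_SETS),
                            rankers = c("mRMR", "ReliefF", "InfoGain", "Chi2",
                                        "RF_MDA", "RF_MDG"),
                            classifiers = default_classifier_specs(),
                            n_features = 1:10,
                            ranker_trees = 10000L,
                            seed = 1L,
                            alpha = 0.05) {
  if (!inherits(cohort, "cohort_config")) abort("`cohort` must be a cohort_config")
  delineations <- match.arg(delineations, DELINEATIONS, several.ok = TRUE)
  modalities <- match.arg(modalities, names(MODALITY_SETS), several.ok = TRUE)
  if (any(n_features < 1) || any(n_features > 10)) {
    abort("`n_features` must lie in 1..10")
  }
  structure(
    list(cohort = cohort, percentile = percentile,
         delineations = delineations, modalities = modalities,
         rankers = rankers, classifiers = classifiers,
         n_features = as.integer(n_features),
         ranker_trees = as.integer(ranker_trees),
         seed = as.integer(seed), alpha = alpha),
    class = "pipeline_config"
  )
}

# FNV-1a hash of a serialized object; cheap provenance checksum.
object_checksum <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L)[-seq_len(14)])
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the whole pipeline end to end
#'
#' simulate -> delineate/extract -> scale -> rank-and-fuse -> classify ->
#' compare, in memory, with one log line per stage. With `output_dir` set,
#' each stage's artifact is persisted as a plain file (feature tables and
#' grid as CSV, fused feature sets and group statistics as JSON) together
#' with a `run_manifest.json` recording the package version, seed and
#' per-stage checksums.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional artifact directory.
#' @param quiet Suppress per-stage log lines.
#' @return An object of class `gbm_pipeline_result`: list with `manifest`,
#'   `features` (per delineation), `ranked` (per dataset), `grid`
#'   (the [run_grid()] tibble) and `groupings` (the four
#'   [dunn_sidak_compare()] results, when the grid covers the full axes).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created by pipeline_config()")
  }
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  say("[simulate] generating cohort (seed %d)", config$cohort$seed)
  cohort <- generate_cohort(config$cohort)
  say("[simulate] %d time points, checksum %s",
      nrow(cohort$manifest), object_checksum(cohort$manifest))

  features <- list()
  for (del in config$delineations) {
    say("[extract] delineation %s", del)
    features[[del]] <- scale_features(
      extract_features(cohort, delineation = del,
                       percentile = config$percentile))
  }

  ranked <- list()
  for (del in config$delineations) {
    for (mod in config$modalities) {
      tag <- paste(del, mod, sep = "_")
      say("[select] dataset %s", tag)
      cols <- modality_columns(features[[del]], mod)
      sub <- features[[del]][c("patient_id", "time_index", "label", cols)]
      ranked[[tag]] <- lopocv_rank_round(
        sub, methods = config$rankers,
        seed = derive_seed(config$seed, paste("select", tag)),
        dataset = tag, n_trees = config$ranker_trees)
    }
  }

  say("[classify] %d x %d x %d x %d grid",
      length(config$delineations), length(config$modalities),
      length(config$classifiers), length(config$n_features))
  grid <- run_grid(features, ranked, classifiers = config$classifiers,
                   delineations = config$delineations,
                   modalities = config$modalities,
                   n_features = config$n_features,
                   seed = derive_seed(config$seed, "classify"))

  groupings <- tryCatch(build_groupings(grid, alpha = config$alpha),
                        error = function(e) {
                          warn(sprintf("group comparison skipped: %s",
                                       conditionMessage(e)))
                          NULL
                        })

  result <- structure(
    list(manifest = cohort$manifest, features = features, ranked = ranked,
         grid = grid, groupings = groupings, config = config),
    class = "gbm_pipeline_result"
  )

  if (!is.null(output_dir)) {
    write_pipeline_artifacts(result, output_dir)
    say("[write] artifacts in %s", output_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  for (del in names(result$features)) {
    utils::write.csv(result$features[[del]],
                     file.path(output_dir, sprintf("features_%s.csv", del)),
                     row.names = FALSE)
  }
  ranked_dir <- file.path(output_dir, "ranked")
  dir.create(ranked_dir, showWarnings = FALSE)
  for (tag in names(result$ranked)) {
    rs <- result$ranked[[tag]]
    jsonlite::write_json(
      list(dataset = tag,
           fused_top10 = rs$fused[c("feature", "score")],
           n_rankings = rs$n_rankings),
      file.path(ranked_dir, paste0(tag, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(result$grid, file.path(output_dir, "grid.csv"),
                   row.names = FALSE)
  if (!is.null(result$groupings)) {
    stats_dir <- file.path(output_dir, "stats")
    dir.create(stats_dir, showWarnings = FALSE)
    for (scheme in names(result$groupings)) {
      ph <- result$groupings[[scheme]]
      jsonlite::write_json(
        list(scheme = scheme, H = ph$kw$statistic, p = ph$kw$p_value,
             top_group = ph$top_group, groups = ph$groups),
        file.path(stats_dir, paste0(scheme, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(
    list(package = "gliorad",
         version = as.character(utils::packageVersion("gliorad")),
         seed = result$config$seed,
         cohort_seed = result$config$cohort$seed,
         stages = list(manifest = object_checksum(result$manifest),
                       features = object_checksum(result$features),
                       ranked = object_checksum(lapply(result$ranked,
                                                       function(r) r$fused)),
                       grid = object_checksum(result$grid))),
    file.path(output_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.gbm_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<gbm_pipeline_result> %d time points, %d grid cells, best BAR %.3f\n",
    nrow(x$manifest), nrow(x$grid), max(x$grid$bar)))
  best <- x$grid[which.max(x$grid$bar), ]
  cat(sprintf("  best cell: %s / %s / %s / k = %d\n", best$delineation,
              best$modality, best$classifier, best$n_features))
  invisible(x)
}
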