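## End-to-end orchestration: simulate -> fit -> features -> classify ->
## shift report, with a resolved-config capture next to every run.

#' Pipeline configuration
#'
#' Builds (and validates) the configuration for [run_pipeline()]. Settings
#' are namespaced per stage; unspecified fields take the package defaults.
#' A configuration can be round-tripped through YAML unchanged.
#'
#' @param simulate list: `n_per_class`, `experiment` ("three_class" or
#'   "concentration"), `radius_cv`, `duration`, `sample_rate`,
#'   `pressure_mbar`, `temperature`.
#' @param spectral list: `segment_length`, `overlap`, `window_name`,
#'   `reference_peak`.
#' @param features list: `iqr_k`, `per_class`.
#' @param classify list: `n_iter`, `test_fraction`, `n_neighbors`,
#'   `min_dist`, `ntree`, `feature_subset`.
#' @param master_seed integer master seed for the whole run.
#' @return validated config list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = list(), spectral = list(),
                            features = list(), classify = list(),
                            master_seed = 1) {
  cfg <- list(
    simulate = utils::modifyList(list(
      n_per_class = 10, experiment = "three_class", radius_cv = 0.1,
      duration = 0.5, sample_rate = 1e6, pressure_mbar = 3.5,
      temperature = 300), simulate),
    spectral = utils::modifyList(list(
      segment_length = 2^14, overlap = 0.5, window_name = "hann",
      reference_peak = "f1"), spectral),
    features = utils::modifyList(list(iqr_k = 1.5, per_class = FALSE),
                                 features),
    classify = utils::modifyList(list(
      n_iter = 300, test_fraction = 0.2, n_neighbors = 50, min_dist = 0.0,
      ntree = 300, feature_subset = NULL), classify),
    master_seed = as.integer(master_seed))
  # a NULL feature_subset means "all features" and must survive
  # serialization round trips
  if (!"feature_subset" %in% names(cfg$classify))
    cfg$classify["feature_subset"] <- list(NULL)
  v <- function(ok, field)
    if (!ok) stop("invalid config: ", field, call. = FALSE)
  v(cfg$simulate$n_per_class >= 1, "simulate.n_per_class")
  v(cfg$simulate$experiment %in% c("three_class", "concentration"),
    "simulate.experiment")
  v(cfg$simulate$radius_cv >= 0 && cfg$simulate$radius_cv <= 0.5,
    "simulate.radius_cv")
  v(cfg$simulate$duration > 0, "simulate.duration")
  v(cfg$classify$test_fraction > 0 && cfg$classify$test_fraction <= 0.5,
    "classify.test_fraction")
  v(cfg$classify$n_iter >= 1, "classify.n_iter")
  v(cfg$spectral$overlap >= 0 && cfg$spectral$overlap < 1,
    "spectral.overlap")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort of detector traces, fits the three-peak spectral
#' model to every particle, assembles and outlier-filters the feature
#' table, runs the supervised UMAP embedding and the MCCV random-forest
#' classification, evaluates the frequency-shift model scenarios, and
#' writes everything (plus the resolved configuration) into `output_dir`:
#' `manifest.csv`, `features.csv`, `features_filtered.csv` (+ JSON
#' sidecars), `embedding.csv`, `mccv.json`, `shift.json`, `config.yaml`
#' and `plots/*.png`. The run is a deterministic function of the
#' configuration.
#'
#' @param config a [pipeline_config()] (or a path to a YAML file of one).
#' @param output_dir directory to create/write into.
#' @param plots write PNG plots (default `TRUE`).
#' @return invisibly, a list with the in-memory stage results: `cohort`,
#'   `fits`, `features`, `filtered`, `embedding`, `mccv`, `shift`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir,
                         plots = TRUE) {
  if (is.character(config))
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(output_dir, "config.yaml"))

  sc <- config$simulate
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }

  cohort <- stage("simulate", {
    trap <- trap_params(pressure_mbar = sc$pressure_mbar,
                        temperature = sc$temperature)
    generate_cohort(sc$n_per_class, classes = cohort_classes(sc$experiment),
                    radius_cv = sc$radius_cv, trap = trap,
                    duration = sc$duration, sample_rate = sc$sample_rate,
                    seed = config$master_seed)
  })
  utils::write.csv(cohort$manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)

  sp <- config$spectral
  fits <- stage("fit", lapply(cohort$traces, function(tr)
    trap_fit(tr, segment_length = sp$segment_length, overlap = sp$overlap,
             window_name = sp$window_name,
             reference_peak = sp$reference_peak)))

  feats <- stage("features", assemble_features(fits))
  write_feature_table(feats, file.path(output_dir, "features.csv"),
                      meta = list(n_excluded = attr(feats, "n_excluded")))
  filt <- stage("filter", remove_outliers(feats, k = config$features$iqr_k,
                                          per_class = config$features$per_class))
  write_feature_table(filt$table,
                      file.path(output_dir, "features_filtered.csv"),
                      meta = list(iqr_k = config$features$iqr_k,
                                  per_class = config$features$per_class,
                                  n_removed = nrow(filt$removed),
                                  removed_reasons = filt$removed$reason,
                                  stats = filt$stats))
  message(sprintf("outlier filter: %d of %d rows removed",
                  nrow(filt$removed), nrow(feats)))

  cl <- config$classify
  emb <- stage("embed", embed_umap(filt$table, n_neighbors = cl$n_neighbors,
                                   min_dist = cl$min_dist,
                                   seed = config$master_seed,
                                   feature_subset = cl$feature_subset))
  utils::write.csv(data.frame(umap1 = emb$coords[, 1],
                              umap2 = emb$coords[, 2],
                              class = emb$labels),
                   file.path(output_dir, "embedding.csv"), row.names = FALSE)

  mc <- stage("classify", mccv(filt$table, n_iter = cl$n_iter,
                               test_fraction = cl$test_fraction,
                               forest_settings = list(ntree = cl$ntree),
                               feature_subset = cl$feature_subset,
                               seed = config$master_seed))
  jsonlite::write_json(
    list(settings = mc$settings[setdiff(names(mc$settings), "forest")],
         accuracies = mc$accuracies,
         summary = list(mean = mc$mean_acc, min = mc$min_acc,
                        max = mc$max_acc, mean_oob = mean(mc$oob_errors)),
         mean_importance = as.list(mc$mean_importance)),
    file.path(output_dir, "mccv.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  shift <- stage("shift", shift_report())
  jsonlite::write_json(shift, file.path(output_dir, "shift.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (plots) {
    pd <- file.path(output_dir, "plots")
    dir.create(pd, showWarnings = FALSE)
    grDevices::png(file.path(pd, "psd_peaks.png"), 1200, 420, res = 110)
    cls <- vapply(fits, function(f) f$metadata$class_label, "")
    first_per_class <- fits[match(unique(cls), cls)]
    plot(first_per_class[[1]], extra = first_per_class[-1])
    grDevices::dev.off()
    grDevices::png(file.path(pd, "embedding.png"), 640, 560, res = 110)
    plot(emb)
    grDevices::dev.off()
    grDevices::png(file.path(pd, "mccv_accuracy.png"), 800, 420, res = 110)
    plot(mc, "accuracy")
    grDevices::dev.off()
    grDevices::png(file.path(pd, "mccv_importance.png"), 700, 560, res = 110)
    plot(mc, "importance")
    grDevices::dev.off()
  }
  invisible(list(cohort = cohort, fits = fits, features = feats,
                 filtered = filt, embedding = emb, mccv = mc,
                 shift = shift))
}
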