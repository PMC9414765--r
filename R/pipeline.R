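# End-to-end orchestration: (synthetic or supplied) spectra -> optional
# preprocessing -> band selection -> per-arm hyperparameter optimization ->
# final training -> evaluation. One global seed fans out to fixed
# per-stage offsets so any stage can be re-run in isolation reproducibly.

#' Pipeline configuration
#'
#' @param spectra a [seed_spectra_table()] with class labels, or a path to
#'   a spectra CSV ([read_spectra_csv()]), or `NULL` to generate synthetic
#'   data from `synthetic`.
#' @param synthetic a [synthetic_config()] used when `spectra` is `NULL`
#'   (its `rng_seed` is overridden by the global `seed`).
#' @param preprocess preprocessing method, see [preprocess_table()].
#' @param band_mode `"full"` (all bands), `"rfimp"` (positive RF
#'   importance) or `"cars"` (CARS subset).
#' @param algorithms model arms to run: any of `"rf"` (fixed baseline
#'   forest with 5 trees, 3 features per split), `"ssa-rf"`, `"jyssa-rf"`.
#' @param train_fraction stratified train share (default 0.8).
#' @param cv_folds folds for the optimizer's fitness (default 5).
#' @param pop_size,max_iter optimizer budget per arm.
#' @param n_trees_max upper bound of the tree-count search interval.
#' @param baseline_params plain-RF arm hyperparameters.
#' @param seed global integer seed.
#' @param out_dir optional directory for artifacts (spectra.csv,
#'   bands.json, history_<arm>.csv, report_<arm>.json, manifest.json).
#' @return Object of class `PipelineConfig`.
#' @export
pipeline_config <- function(spectra = NULL, synthetic = synthetic_config(),
                            preprocess = "none",
                            band_mode = c("full", "rfimp", "cars"),
                            algorithms = c("rf", "ssa-rf", "jyssa-rf"),
                            train_fraction = 0.8, cv_folds = 5L,
                            pop_size = 10L, max_iter = 10L,
                            n_trees_max = 100L,
                            baseline_params = rf_hyperparams(5, 3),
                            seed = 1L, out_dir = NULL) {
  band_mode <- match.arg(band_mode)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  structure(list(spectra = spectra, synthetic = synthetic,
                 preprocess = preprocess, band_mode = band_mode,
                 algorithms = algorithms, train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 n_trees_max = as.integer(n_trees_max),
                 baseline_params = baseline_params,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "PipelineConfig")
}

stage_seed <- function(config, offset) config$seed * 100L + offset

#' Run the full classification pipeline
#'
#' Executes the enabled stages in order and returns a self-describing
#' manifest: the data provenance, selected bands, and per-arm tuned
#' hyperparameters, optimization history and test-set
#' [evaluate_predictions()] report. Identical configs and seeds give
#' identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param verbose print one progress line per stage.
#' @return List of class `PipelineManifest`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  # -- stage: input spectra ------------------------------------------------
  if (is.null(config$spectra)) {
    syn <- config$synthetic
    syn$rng_seed <- stage_seed(config, 1L)
    table <- generate_table(syn)$table
    provenance <- "synthetic"
  } else if (is.character(config$spectra)) {
    table <- read_spectra_csv(config$spectra)
    provenance <- config$spectra
  } else {
    table <- config$spectra
    provenance <- "in-memory"
  }
  if (is.null(table$class_label))
    stop_input("pipeline stage 'input': spectra table has no class labels")
  say("input: %d seeds x %d bands (%s)", nrow(table$spectra),
      ncol(table$spectra), provenance)

  # -- stage: preprocessing ------------------------------------------------
  table <- preprocess_table(table, config$preprocess)
  say("preprocess: %s", config$preprocess)

  # -- stage: band selection ----------------------------------------------
  bands <- switch(config$band_mode,
    full = seq_len(ncol(table$spectra)),
    rfimp = {
      sc <- rf_band_importance(table, seed = stage_seed(config, 11L))
      b <- select_positive_importance(sc)
      if (length(b) < 2L) b <- order(-sc$importance)[1:2]
      sort(b)
    },
    cars = cars_select(table$spectra, table$class_label,
                       seed = stage_seed(config, 21L))$selected)
  X <- table$spectra[, bands, drop = FALSE]
  y <- table$class_label
  say("bands: %s -> %d of %d", config$band_mode, length(bands),
      ncol(table$spectra))

  # -- stage: split --------------------------------------------------------
  train <- stratified_split(y, config$train_fraction,
                            seed = stage_seed(config, 31L))
  Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
  Xte <- X[!train, , drop = FALSE]; yte <- y[!train]

  bounds <- rbind(c(1, 1), c(config$n_trees_max, ncol(X)))
  inner_seed <- stage_seed(config, 41L)
  fitness <- function(pos)
    fitness_from_position(pos, Xtr, ytr, cv_folds = config$cv_folds,
                          inner_seed = inner_seed, bounds = bounds)

  arms <- list()
  for (alg in config$algorithms) {
    arm <- list(algorithm = alg)
    if (alg == "rf") {
      arm$params <- config$baseline_params
    } else {
      cfg <- jyssa_config(lower = bounds[1, ], upper = bounds[2, ],
                          pop_size = config$pop_size,
                          max_iter = config$max_iter,
                          use_elite = (alg == "jyssa-rf"),
                          rng_seed = stage_seed(config, 51L))
      opt <- jyssa_optimize(fitness, cfg)
      p <- pmin(pmax(round(opt$best_position), bounds[1, ]), bounds[2, ])
      arm$params <- rf_hyperparams(p[1], p[2])
      arm$best_fitness <- opt$best_fitness
      arm$history <- opt$history
    }
    fit <- train_final(Xtr, ytr, arm$params,
                       seed = stage_seed(config, 61L))
    arm$report <- evaluate_predictions(yte, rf_predict(fit, Xte))
    say("%s: trees=%d mtry=%d accuracy=%.3f", alg, arm$params$n_trees,
        arm$params$n_features_per_split, arm$report$accuracy)
    arms[[alg]] <- arm
  }

  manifest <- structure(list(
    provenance = provenance,
    seed = config$seed,
    preprocess = config$preprocess,
    band_mode = config$band_mode,
    bands = bands,
    n_train = sum(train), n_test = sum(!train),
    arms = arms,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "PipelineManifest")

  if (!is.null(config$out_dir)) write_manifest(manifest, table, config)
  manifest
}

write_manifest <- function(manifest, table, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  write_spectra_csv(table, out("spectra.csv"))
  jsonlite::write_json(
    list(mode = config$band_mode, band_index = manifest$bands,
         wavelength_nm = table$wavelengths_nm[manifest$bands]),
    out("bands.json"), auto_unbox = TRUE, digits = NA)
  for (alg in names(manifest$arms)) {
    arm <- manifest$arms[[alg]]
    tag <- gsub("[^a-z]", "", alg)
    if (!is.null(arm$history))
      write.csv(data.frame(iteration = seq_along(arm$history),
                           fg = arm$history),
                out(paste0("history_", tag, ".csv")), row.names = FALSE)
    rep <- arm$report
    jsonlite::write_json(
      list(algorithm = alg, seed = config$seed,
           n_trees = arm$params$n_trees,
           n_features_per_split = arm$params$n_features_per_split,
           accuracy = rep$accuracy,
           class = rownames(rep$confusion),
           precision = as.numeric(rep$precision),
           recall = as.numeric(rep$recall),
           sample_size = as.integer(rep$support),
           confusion = rep$confusion),
      out(paste0("report_", tag, ".json")), auto_unbox = TRUE, digits = NA,
      matrix = "rowmajor")
  }
  jsonlite::write_json(
    list(seed = config$seed, provenance = manifest$provenance,
         preprocess = manifest$preprocess, band_mode = manifest$band_mode,
         n_bands = length(manifest$bands),
         arms = lapply(manifest$arms, function(a)
           list(n_trees = a$params$n_trees,
                n_features_per_split = a$params$n_features_per_split,
                accuracy = a$report$accuracy))),
    out("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.PipelineManifest <- function(x, ...) {
  cat(sprintf("PipelineManifest: %s data, bands=%s (%d), seed=%d\n",
              x$provenance, x$band_mode, length(x$bands), x$seed))
  for (alg in names(x$arms)) {
    a <- x$arms[[alg]]
    cat(sprintf("  %-9s trees=%3d mtry=%3d accuracy=%.3f\n", alg,
                a$params$n_trees, a$params$n_features_per_split,
                a$report$accuracy))
  }
  invisible(x)
}
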