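## End-to-end orchestration: simulate (optional) -> inclusion filter ->
## stratified split -> per-fold calibrate + train -> evaluate -> two-factor
## sweeps, with every artifact written to the output directory and hashed
## into a run manifest. Identical config + seed reproduce identical
## artifacts byte for byte.

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param input_csv Optional cohort CSV (as written by
#'   [write_cohort_csv()]); if `NULL`, `cohort` must be supplied and a
#'   cohort is simulated.
#' @param cohort Optional [cohort_config()] for simulation.
#' @param schema Feature schema (default shipped 145-column schema).
#' @param net A [net_config()] template (`input_width` and seed are set by
#'   the pipeline).
#' @param target_sensitivity Minority sensitivity target for class-weight
#'   calibration.
#' @param calibrate If `FALSE`, train at `fixed_w_pos` instead of
#'   calibrating.
#' @param fixed_w_pos Class weight used when `calibrate = FALSE`.
#' @param sweeps List of two-factor sweep definitions, each a list with
#'   `factor_a`, `factor_b` and optional `deltas_a`, `deltas_b`. Defaults
#'   to the two study grids: transport x defibrillation delay and
#'   transport x drug delay.
#' @param summary_mode Summary used in sweeps (see
#'   [summarize_predictions()]).
#' @param color_limit_percent Symmetric color-scale limit for rendered
#'   heatmaps (default 6).
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, input_csv = NULL, cohort = NULL,
                       schema = build_schema(),
                       net = net_config(input_width = schema_width(schema)),
                       target_sensitivity = 0.80,
                       calibrate = TRUE, fixed_w_pos = NULL,
                       sweeps = list(
                         list(factor_a = "contact_to_arrival",
                              factor_b = "contact_to_first_defib"),
                         list(factor_a = "contact_to_arrival",
                              factor_b = "contact_to_first_drug")),
                       summary_mode = "mean_probability",
                       color_limit_percent = 6) {
  if (is.null(input_csv) && is.null(cohort)) {
    stop_config("run_config needs either 'input_csv' or a 'cohort' simulation config")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 input_csv = input_csv, cohort = cohort, schema = schema,
                 net = net, target_sensitivity = target_sensitivity,
                 calibrate = calibrate, fixed_w_pos = fixed_w_pos,
                 sweeps = sweeps, summary_mode = summary_mode,
                 color_limit_percent = color_limit_percent),
            class = "run_config")
}

metrics_to_list <- function(m) {
  list(sensitivity_pos = m$sensitivity_pos,
       sensitivity_neg = m$sensitivity_neg,
       average_class_sensitivity = m$average_class_sensitivity,
       auroc = m$auroc,
       auroc_ci = as.list(m$auroc_ci),
       confusion = as.list(m$confusion))
}

#' Serialize a trained model to JSON
#'
#' Stores every layer's weights, biases, batch-norm parameters and running
#' statistics, the network configuration, the class weights and the
#' encoder's standardization parameters (full precision).
#' @param model A `prog_net`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  layers <- lapply(model$layers, function(ly) {
    out <- list(W = ly$W, b = ly$b)
    for (nm in c("gamma", "beta", "run_mean", "run_var")) {
      if (!is.null(ly[[nm]])) out[[nm]] <- ly[[nm]]
    }
    out
  })
  jsonlite::write_json(
    list(layers = layers,
         config = unclass(model$config),
         weights = unclass(model$weights),
         threshold = model$threshold,
         training_log = model$training_log,
         standardization = list(centers = model$encoder$centers,
                                scales = model$encoder$scales)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: simulate (optional) -> inclusion filter -> stratified 5-group
#' split (one group held out as test) -> per-fold class-weight calibration
#' and training -> validation and test evaluation -> two-factor sweeps on
#' the test group. Writes cohort CSV (if simulated), split JSON, four model
#' JSON files, a metrics report, grid CSVs with JSON sidecars, and a
#' manifest hashing every artifact.
#'
#' @param config A [run_config()].
#' @return The manifest (data frame of file names and MD5 hashes),
#'   invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)
  stage <- "load"
  tryCatch({
    if (!is.null(config$input_csv)) {
      cohort <- read_cohort_csv(config$input_csv)
    } else {
      stage <- "simulate"
      cc <- config$cohort
      cc$seed <- derive_seed(config$seed, 1)
      cohort <- generate_cohort(cc)
      path <- file.path(config$out_dir, "cohort.csv")
      write_cohort_csv(cohort, path)
      emit(path)
    }

    stage <- "filter"
    filt <- apply_inclusion_filters(cohort)
    included <- filt$included
    path <- file.path(config$out_dir, "inclusion_tally.json")
    jsonlite::write_json(filt$tally, path, auto_unbox = TRUE)
    emit(path)

    stage <- "split"
    plan <- stratified_split(included$outcome_cpc12, k = 5L,
                             seed = derive_seed(config$seed, 2))
    path <- file.path(config$out_dir, "split.json")
    write_split_json(plan, path)
    emit(path)

    stage <- "train"
    net <- config$net
    net$seed <- derive_seed(config$seed, 3)
    ensemble <- run_cv(included, plan, config$schema, net,
                       target_sensitivity = config$target_sensitivity,
                       calibrate = config$calibrate,
                       fixed_w_pos = config$fixed_w_pos)
    for (i in seq_along(ensemble$models)) {
      path <- file.path(config$out_dir, sprintf("model_fold%d.json", i))
      write_model_json(ensemble$models[[i]], path)
      emit(path)
    }

    stage <- "evaluate"
    test_idx <- test_indices(plan)
    test_records <- included[test_idx, , drop = FALSE]
    test_metrics <- evaluate_model(
      stats::predict(ensemble, test_records),
      labels = test_records$outcome_cpc12, threshold = ensemble$threshold)
    path <- file.path(config$out_dir, "metrics.json")
    jsonlite::write_json(
      list(folds = lapply(ensemble$fold_metrics, metrics_to_list),
           test = metrics_to_list(test_metrics),
           class_weights = lapply(ensemble$models,
                                  function(m) m$weights$w_pos)),
      path, auto_unbox = TRUE, digits = NA)
    emit(path)

    stage <- "sweep"
    train_records <- included[plan$group != plan$test_group, , drop = FALSE]
    grids <- list()
    for (sw in config$sweeps) {
      grid <- two_factor_grid(ensemble, test_records,
                              adjustment_spec(sw$factor_a),
                              adjustment_spec(sw$factor_b),
                              deltas_a = sw$deltas_a, deltas_b = sw$deltas_b,
                              summary_mode = config$summary_mode,
                              train_records = train_records)
      base <- sprintf("grid_%s_x_%s", sw$factor_a, sw$factor_b)
      path <- file.path(config$out_dir, paste0(base, ".csv"))
      emit(write_grid_csv(grid, path))
      grids[[base]] <- grid
    }

    stage <- "manifest"
    manifest <- data.frame(file = basename(artifacts),
                           md5 = unname(tools::md5sum(artifacts)),
                           stringsAsFactors = FALSE)
    jsonlite::write_json(list(seed = config$seed, files = manifest),
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    attr(manifest, "grids") <- grids
    attr(manifest, "ensemble") <- ensemble
    invisible(manifest)
  }, error = function(e) {
    partial <- data.frame(file = basename(artifacts),
                          md5 = unname(tools::md5sum(artifacts)),
                          stringsAsFactors = FALSE)
    try(jsonlite::write_json(list(failed_stage = stage, files = partial),
                             file.path(config$out_dir, "manifest.json"),
                             auto_unbox = TRUE), silent = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Render a two-factor grid as a heatmap
#'
#' Diverging color scale clipped symmetrically at the configured percent
#' limit (out-of-range cells render at the extreme); the zero-adjustment
#' cell is outlined with a square box, and axes are labelled in minutes.
#'
#' @param grid A `heatmap_grid`.
#' @param color_limit_percent Symmetric clip limit (default 6).
#' @param file Optional output path (`.svg` with cairo when available,
#'   else `.png`); when `NULL` the ggplot object is returned unrendered.
#' @return The ggplot object, invisibly when written to file.
#' @export
render_heatmap <- function(grid, color_limit_percent = 6, file = NULL) {
  stopifnot(inherits(grid, "heatmap_grid"))
  df <- expand.grid(a = grid$deltas_a, b = grid$deltas_b)
  df$value <- as.vector(grid$cells)
  zero <- df$a == 0 & df$b == 0
  p <- ggplot2::ggplot(df, ggplot2::aes(x = b, y = a, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[zero, , drop = FALSE], fill = NA,
                       color = "black", linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "#F7F7F7", high = "#B2182B",
      limits = c(-color_limit_percent, color_limit_percent),
      oob = scales::squish,
      name = "% change\npredicted CPC1/2") +
    ggplot2::labs(x = paste(grid$factor_b, "adjustment (min)"),
                  y = paste(grid$factor_a, "adjustment (min)")) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (is.null(file)) return(p)
  if (grepl("\\.svg$", file) && capabilities("cairo")) {
    grDevices::svg(file, width = 7, height = 6)
  } else {
    file <- sub("\\.svg$", ".png", file)
    grDevices::png(file, width = 700, height = 600)
  }
  print(p)
  grDevices::dev.off()
  invisible(p)
}
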