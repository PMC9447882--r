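## Four-fold cross-validated model ensemble.
##
## Each fold fits its own feature encoder on its training records only (no
## leakage of standardization statistics), calibrates its own class weight
## on its validation group, and contributes one model to the ensemble used
## by the counterfactual sweeps. Ensemble prediction is the arithmetic mean
## of the four members' probabilities.

#' Train the cross-validated model ensemble
#'
#' @param records Included cohort records (post inclusion filter).
#' @param plan A [stratified_split()] plan over `records`.
#' @param schema Feature schema (default shipped 145-column schema).
#' @param config A [net_config()]; its `input_width` is overridden by the
#'   schema width and its seed is re-derived per fold.
#' @param target_sensitivity Minority sensitivity target for per-fold class
#'   weight calibration.
#' @param calibrate If `FALSE`, skip calibration and train every fold at
#'   `fixed_w_pos`.
#' @param fixed_w_pos Positive-class weight used when `calibrate = FALSE`.
#' @param label_field Column holding the outcome label.
#' @return Object of class `prog_ensemble`: `models` (4 `prog_net`s, each
#'   carrying its encoder), `fold_metrics` (per-fold validation
#'   [evaluate_model()] reports), `calibrations`, and the split plan.
#' @export
run_cv <- function(records, plan, schema = build_schema(),
                   config, target_sensitivity = 0.80,
                   calibrate = TRUE, fixed_w_pos = NULL,
                   label_field = "outcome_cpc12") {
  stopifnot(inherits(plan, "split_plan"))
  if (nrow(records) != plan$n) {
    stop_config("records (%d rows) inconsistent with split plan (n = %d)",
                nrow(records), plan$n)
  }
  labels <- as.logical(records[[label_field]])
  folds <- cv_folds(plan)
  models <- list(); fold_metrics <- list(); calibrations <- list()
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    enc <- fit_encode(records[fold$train, , drop = FALSE], schema)
    x_train <- enc$matrix
    x_val <- encode_records(records[fold$validation, , drop = FALSE],
                            enc$encoder)
    y_train <- labels[fold$train]
    y_val <- labels[fold$validation]
    fold_config <- config
    fold_config$input_width <- ncol(x_train)
    fold_config$seed <- derive_seed(config$seed, 100 + i)
    if (calibrate) {
      cal <- calibrate_class_weights(x_train, y_train, x_val, y_val,
                                     fold_config,
                                     target_sensitivity = target_sensitivity)
      model <- cal$model
      calibrations[[i]] <- cal
    } else {
      w <- fixed_w_pos %||% 1
      model <- train_model(x_train, y_train, fold_config,
                           class_weights(w_pos = w))
      calibrations[[i]] <- NULL
    }
    model$encoder <- enc$encoder
    model$validation_group <- fold$validation_group
    models[[i]] <- model
    fold_metrics[[i]] <- evaluate_model(stats::predict(model, x_val),
                                        labels = y_val,
                                        threshold = model$threshold)
  }
  structure(list(models = models, fold_metrics = fold_metrics,
                 calibrations = calibrations, plan = plan,
                 schema = schema, threshold = 0.5),
            class = "prog_ensemble")
}

#' @export
print.prog_ensemble <- function(x, ...) {
  cat("Prognostic ensemble of", length(x$models), "cross-validation models\n")
  for (i in seq_along(x$fold_metrics)) {
    m <- x$fold_metrics[[i]]
    cat(sprintf("  fold %d (val group %d): avg class sens %.3f, AUROC %.3f\n",
                i, x$models[[i]]$validation_group,
                m$average_class_sensitivity, m$auroc))
  }
  invisible(x)
}

#' Ensemble prediction: mean of member probabilities
#'
#' @param object A `prog_ensemble`.
#' @param records Raw cohort records (each member encodes them with its own
#'   stored encoder) or, if `encoded = TRUE`, a ready design matrix.
#' @param encoded Set `TRUE` when `records` is already a design matrix.
#' @param ... Unused.
#' @export
predict.prog_ensemble <- function(object, records, encoded = FALSE, ...) {
  rowMeans(cpc_probabilities(object, records, encoded = encoded))
}

#' Per-model CPC1/2 probabilities for a set of records
#'
#' Generic predictor contract consumed by the counterfactual module:
#' implementations return an `n x n_models` matrix of probabilities.
#' @param object Predictor (ensemble, single model, or stub).
#' @param records Raw cohort records.
#' @param ... Method-specific arguments.
#' @export
cpc_probabilities <- function(object, records, ...) {
  UseMethod("cpc_probabilities")
}

#' @rdname cpc_probabilities
#' @param encoded Set `TRUE` when `records` is already a design matrix.
#' @export
cpc_probabilities.prog_ensemble <- function(object, records, encoded = FALSE, ...) {
  vapply(object$models, function(m) {
    x <- if (encoded) records else encode_records(records, m$encoder)
    stats::predict(m, x)
  }, numeric(nrow(records)))
}

#' @rdname cpc_probabilities
#' @export
cpc_probabilities.prog_net <- function(object, records, encoded = FALSE, ...) {
  x <- if (encoded) records else encode_records(records, object$encoder)
  matrix(stats::predict(object, x), ncol = 1)
}

#' Deterministic stub predictor for pipeline verification
#'
#' Wraps a plain `function(records) -> probabilities` as a predictor usable
#' wherever a trained ensemble is: counterfactual sweeps, summaries and
#' grids. Used to verify the sweep machinery against closed-form oracles.
#'
#' @param fun Function mapping a records data frame to probabilities.
#' @param n_models Number of identical pseudo-members to report (affects
#'   only the count summary mode's averaging, which is invariant to it).
#' @export
stub_predictor <- function(fun, n_models = 1L) {
  structure(list(fun = fun, n_models = as.integer(n_models)),
            class = "cpc_stub")
}

#' @rdname cpc_probabilities
#' @export
cpc_probabilities.cpc_stub <- function(object, records, ...) {
  p <- object$fun(records)
  matrix(rep(p, object$n_models), ncol = object$n_models)
}

#' @export
predict.cpc_stub <- function(object, records, ...) {
  rowMeans(cpc_probabilities(object, records))
}
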