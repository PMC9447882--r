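## Per-class sensitivity and AUROC evaluation.
##
## Accuracy alone is uninformative at ~4% outcome prevalence, so models are
## judged by per-class sensitivities (and their unweighted mean) together
## with the rank-based AUROC and its DeLong 95% confidence interval.

#' Evaluate predictions against labels
#'
#' @param object A trained `prog_net`, a `prog_ensemble`, or a numeric
#'   vector of predicted probabilities.
#' @param x Design matrix (ignored when `object` is already a probability
#'   vector).
#' @param labels Logical / 0-1 outcomes; both classes must be present.
#' @param threshold Classification threshold (default 0.5).
#' @return Object of class `metrics_report`: `sensitivity_pos`,
#'   `sensitivity_neg`, `average_class_sensitivity`, `auroc`, `auroc_ci`
#'   (95%, DeLong), and the confusion counts.
#' @export
evaluate_model <- function(object, x = NULL, labels, threshold = 0.5) {
  probs <- if (is.numeric(object)) object else stats::predict(object, x)
  y <- as.logical(labels)
  if (length(probs) != length(y)) stop_config("predictions and labels differ in length")
  if (!any(y) || all(y)) {
    stop_config("labels contain a single class; AUROC undefined")
  }
  pred <- probs >= threshold
  tp <- sum(pred & y); fn <- sum(!pred & y)
  tn <- sum(!pred & !y); fp <- sum(pred & !y)
  roc <- pROC::roc(response = y, predictor = probs, quiet = TRUE,
                   levels = c(FALSE, TRUE), direction = "<")
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  structure(list(
    sensitivity_pos = tp / (tp + fn),
    sensitivity_neg = tn / (tn + fp),
    average_class_sensitivity = (tp / (tp + fn) + tn / (tn + fp)) / 2,
    auroc = as.numeric(pROC::auc(roc)),
    auroc_ci = c(low = ci[1], high = ci[3]),
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    threshold = threshold), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("sensitivity CPC1/2: %.3f  non-CPC1/2: %.3f  average: %.3f\n",
              x$sensitivity_pos, x$sensitivity_neg,
              x$average_class_sensitivity))
  cat(sprintf("AUROC: %.3f (95%% CI %.3f-%.3f)\n",
              x$auroc, x$auroc_ci[1], x$auroc_ci[2]))
  invisible(x)
}

#' Calibrate the minority-class weight
#'
#' Searches for the smallest positive-class weight whose validation
#' minority-class sensitivity reaches the target (less the tolerance):
#' a coarse geometric walk `w_pos = 1, 2, 4, ... , w_max`, stopped at the
#' first qualifying weight, followed by geometric bisection between the
#' last failing and first qualifying weights. Choosing the smallest
#' qualifying weight keeps the majority-class sensitivity maximal among
#' qualifying weights (the two sensitivities trade off monotonically in
#' expectation).
#'
#' @param train_x,train_y Training design matrix and labels.
#' @param val_x,val_y Validation design matrix and labels (both classes
#'   required).
#' @param config A [net_config()].
#' @param target_sensitivity Minority sensitivity target (default 0.80).
#' @param tolerance Acceptance tolerance below target (default 0.02).
#' @param w_max Upper end of the geometric grid.
#' @param refine_steps Geometric bisection refinements after bracketing.
#' @param fit_fun Optional `function(w_pos)` returning validation
#'   probabilities (and optionally a model): either a numeric vector or a
#'   list with elements `probs` and `model`. Defaults to training a
#'   [train_model()] network. Injectable for calibration tests.
#' @param threshold Classification threshold used when measuring
#'   sensitivities.
#' @return List of class `weight_calibration`: `weights` (a
#'   [class_weights()]), `model` (fit at the selected weight, when
#'   available), `trace` (data frame of every `(w_pos, sens_pos, sens_neg)`
#'   evaluated), `achieved` sensitivities and `calibration_failed` flag.
#' @export
calibrate_class_weights <- function(train_x = NULL, train_y = NULL,
                                    val_x = NULL, val_y,
                                    config = NULL,
                                    target_sensitivity = 0.80,
                                    tolerance = 0.02,
                                    w_max = 64,
                                    refine_steps = 3L,
                                    fit_fun = NULL,
                                    threshold = 0.5) {
  y <- as.logical(val_y)
  if (!any(y) || all(y)) stop_config("validation set must contain both classes")
  if (is.null(fit_fun)) {
    fit_fun <- function(w_pos) {
      model <- train_model(train_x, train_y, config,
                           class_weights(w_pos = w_pos))
      list(probs = stats::predict(model, val_x), model = model)
    }
  }
  evals <- list()
  eval_w <- function(w) {
    key <- format(w, digits = 12)
    if (!is.null(evals[[key]])) return(evals[[key]])
    res <- fit_fun(w)
    if (is.numeric(res)) res <- list(probs = res, model = NULL)
    pred <- res$probs >= threshold
    out <- list(w_pos = w,
                sens_pos = sum(pred & y) / sum(y),
                sens_neg = sum(!pred & !y) / sum(!y),
                model = res$model)
    evals[[key]] <<- out
    out
  }
  qualifies <- function(e) e$sens_pos >= target_sensitivity - tolerance

  # Coarse geometric walk, stopped at the first qualifying weight.
  w <- 1
  lo <- NULL; hi <- NULL
  while (w <= w_max) {
    e <- eval_w(w)
    if (qualifies(e)) { hi <- e; break }
    lo <- e
    w <- w * 2
  }
  if (!is.null(hi) && is.null(lo)) {
    chosen <- hi                           # already qualifies at w_pos = 1
  } else if (is.null(hi)) {
    chosen <- NULL                         # nothing qualified
  } else {
    for (i in seq_len(refine_steps)) {
      mid <- eval_w(sqrt(lo$w_pos * hi$w_pos))
      if (qualifies(mid)) hi <- mid else lo <- mid
    }
    chosen <- hi
  }
  failed <- is.null(chosen)
  if (failed) {
    # Return the best-achieving weight with a calibration-failure flag.
    best <- which.max(vapply(evals, `[[`, 0, "sens_pos"))
    chosen <- evals[[best]]
  }
  trace <- do.call(rbind, lapply(evals, function(e) {
    data.frame(w_pos = e$w_pos, sens_pos = e$sens_pos, sens_neg = e$sens_neg)
  }))
  trace <- trace[order(trace$w_pos), , drop = FALSE]
  rownames(trace) <- NULL
  structure(list(weights = class_weights(w_pos = chosen$w_pos),
                 model = chosen$model,
                 trace = trace,
                 achieved = c(sens_pos = chosen$sens_pos,
                              sens_neg = chosen$sens_neg),
                 target_sensitivity = target_sensitivity,
                 tolerance = tolerance,
                 calibration_failed = failed),
            class = "weight_calibration")
}

#' @export
print.weight_calibration <- function(x, ...) {
  cat(sprintf("selected w_pos = %.4g (minority sensitivity %.3f, majority %.3f)%s\n",
              x$weights$w_pos, x$achieved["sens_pos"], x$achieved["sens_neg"],
              if (x$calibration_failed) " [calibration FAILED]" else ""))
  invisible(x)
}
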