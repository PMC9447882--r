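## Counterfactual what-if sweeps over held-out test records.
##
## A sweep adds a signed delta (minutes, or years for age) to one time
## factor for the eligible subset of test records, re-encodes the adjusted
## records with each model's stored training-time encoder, re-predicts, and
## summarizes the change relative to the unadjusted baseline as a percent.
## Two-factor grids apply two deltas simultaneously (each under its own
## eligibility mask), which exposes interaction structure the single-factor
## sweeps cannot show. Baselines are always computed over the entire test
## set; ineligible records are never modified and dilute the percent
## change, mirroring a baseline defined on the full unadjusted test data.

cf_factors <- function() {
  list(
    age_years = list(column = "age_years", eligibility = "all", units = "years"),
    call_to_contact = list(column = "call_to_contact_min",
                           eligibility = "all", units = "minutes"),
    contact_to_arrival = list(column = "contact_to_arrival_min",
                              eligibility = "all", units = "minutes"),
    contact_to_first_defib = list(column = "defib_time_min",
                                  eligibility = "shockable_initial_rhythm",
                                  units = "minutes"),
    contact_to_first_drug = list(column = "adrenaline_time_min",
                                 eligibility = "drug_eligible_not_ems_witnessed",
                                 units = "minutes")
  )
}

#' Specification of a single-factor counterfactual adjustment
#'
#' @param factor One of `age_years`, `call_to_contact`,
#'   `contact_to_arrival`, `contact_to_first_defib`,
#'   `contact_to_first_drug`.
#' @param eligibility Eligibility predicate; defaults to the factor's
#'   canonical one: everyone for age and the two transport intervals,
#'   shockable initial rhythm for the defibrillation delay, and
#'   drug-receiving patients whose arrest was not witnessed by EMS
#'   personnel (firefighter, paramedic, emergency lifesaver) for the drug
#'   delay.
#' @param clamp_floor Adjusted values are floored here (default 0 minutes).
#' @return Object of class `adjustment_spec`.
#' @export
adjustment_spec <- function(factor,
                            eligibility = NULL,
                            clamp_floor = 0) {
  info <- cf_factors()[[factor]]
  if (is.null(info)) {
    stop_config("unknown adjustment factor '%s' (known: %s)", factor,
                paste(names(cf_factors()), collapse = ", "))
  }
  structure(list(factor = factor, column = info$column,
                 eligibility = eligibility %||% info$eligibility,
                 units = info$units, clamp_floor = clamp_floor),
            class = "adjustment_spec")
}

eligibility_mask <- function(records, spec) {
  switch(spec$eligibility,
         all = rep(TRUE, nrow(records)),
         shockable_initial_rhythm =
           records$defib_performed &
           records$first_rhythm %in% shockable_rhythms(),
         drug_eligible_not_ems_witnessed =
           records$adrenaline_given &
           !(records$witness_type %in% ems_witness_types()),
         stop_config("unknown eligibility predicate '%s'", spec$eligibility))
}

#' Apply a counterfactual time adjustment to records
#'
#' Only eligible records are modified: the factor's value is shifted by
#' `delta` and floored at the spec's clamp floor. All other fields are
#' untouched and the input collection is not mutated.
#'
#' @param records Test records.
#' @param spec An [adjustment_spec()].
#' @param delta Signed shift in the factor's units.
#' @return Adjusted copy of `records`.
#' @export
adjust_records <- function(records, spec, delta) {
  stopifnot(inherits(spec, "adjustment_spec"))
  mask <- eligibility_mask(records, spec)
  out <- records
  out[[spec$column]][mask] <- pmax(out[[spec$column]][mask] + delta,
                                   spec$clamp_floor)
  out
}

#' Summarize ensemble predictions over a record set
#'
#' @param object Predictor (ensemble, model or stub).
#' @param records Records to predict (raw; encoding uses each model's
#'   stored encoder).
#' @param summary_mode `"mean_probability"` (mean predicted CPC1/2
#'   probability over all records and models) or `"predicted_count"` (mean
#'   over models of the number of records predicted CPC1/2 at the
#'   threshold).
#' @param threshold Threshold for the count mode.
#' @return Scalar summary value.
#' @export
summarize_predictions <- function(object, records,
                                  summary_mode = c("mean_probability",
                                                   "predicted_count"),
                                  threshold = 0.5) {
  summary_mode <- match.arg(summary_mode)
  if (nrow(records) == 0L) stop_config("cannot summarize an empty record set")
  pm <- cpc_probabilities(object, records)
  if (summary_mode == "mean_probability") mean(pm)
  else mean(colSums(pm >= threshold))
}

#' Percent change relative to a baseline summary
#'
#' `100 * (adjusted - baseline) / baseline`.
#' @param adjusted,baseline Summary values; `baseline` must be positive.
#' @export
relative_change <- function(adjusted, baseline) {
  if (!is.finite(baseline) || baseline <= 0) {
    stop_config("relative change undefined: baseline summary is %s",
                format(baseline))
  }
  100 * (adjusted - baseline) / baseline
}

default_deltas <- function(factor) {
  switch(factor,
         age_years = c(-5, 0, 5),
         call_to_contact = c(0, 10, 20),
         contact_to_arrival = c(-5, 0, 10, 20),
         contact_to_first_defib = -5:5,
         contact_to_first_drug = -5:5,
         stop_config("no default deltas for factor '%s'", factor))
}

#' Single-factor sensitivity sweep
#'
#' Shifts one factor by each delta in turn and reports the percent change
#' of the prediction summary versus the unadjusted baseline. Default delta
#' sets follow the study's sensitivity analysis: age +/- 5 years; call to
#' contact +10 and +20 min; contact to arrival -5, +10 and +20 min.
#'
#' @param object Predictor (ensemble, model or stub).
#' @param records Test records.
#' @param factor Factor name (see [adjustment_spec()]).
#' @param deltas Numeric deltas; defaults per factor.
#' @param summary_mode,threshold Passed to [summarize_predictions()].
#' @param clamp_floor Floor for adjusted values.
#' @return Data frame with `delta`, `summary` and `percent_change`.
#' @export
single_factor_sweep <- function(object, records, factor, deltas = NULL,
                                summary_mode = "mean_probability",
                                threshold = 0.5, clamp_floor = 0) {
  deltas <- deltas %||% default_deltas(factor)
  if (!length(deltas)) stop_config("deltas must be nonempty")
  spec <- adjustment_spec(factor, clamp_floor = clamp_floor)
  baseline <- summarize_predictions(object, records, summary_mode, threshold)
  res <- vapply(deltas, function(d) {
    summarize_predictions(object, adjust_records(records, spec, d),
                          summary_mode, threshold)
  }, numeric(1))
  data.frame(delta = deltas, summary = res,
             percent_change = vapply(res, relative_change, numeric(1),
                                     baseline = baseline))
}

#' Two-factor simultaneous adjustment grid
#'
#' Applies every pair of deltas from the two axes simultaneously (each
#' factor under its own eligibility mask), re-predicts, and maps the
#' percent change versus the single unadjusted baseline. The zero-zero cell
#' is exactly 0 by construction.
#'
#' @param object Predictor (ensemble, model or stub).
#' @param records Test records.
#' @param spec_a,spec_b [adjustment_spec()]s for two *different* factors.
#' @param deltas_a,deltas_b Numeric axes; each must contain 0. Defaults:
#'   transport-like factors -10..+10 min, intervention delays -5..+5 min.
#' @param summary_mode,threshold Passed to [summarize_predictions()].
#' @param train_records Optional training records used to report, per axis
#'   delta, the fraction of adjusted eligible test values that fall inside
#'   the central 98% range of the corresponding training values (a
#'   trained-region coverage diagnostic: cells built from sparsely trained
#'   regions mislead).
#' @return Object of class `heatmap_grid`: `cells` (percent-change matrix,
#'   rows = axis a), `deltas_a`, `deltas_b`, `baseline`, `summary_mode`,
#'   `n_eligible` per factor, and optional `trained_coverage`.
#' @export
two_factor_grid <- function(object, records, spec_a, spec_b,
                            deltas_a = NULL, deltas_b = NULL,
                            summary_mode = "mean_probability",
                            threshold = 0.5, train_records = NULL) {
  stopifnot(inherits(spec_a, "adjustment_spec"),
            inherits(spec_b, "adjustment_spec"))
  if (spec_a$factor == spec_b$factor) {
    stop_config("the two axes must target different factors (both are '%s')",
                spec_a$factor)
  }
  grid_default <- function(factor) {
    if (factor %in% c("contact_to_first_defib", "contact_to_first_drug")) -5:5
    else (-10):10
  }
  deltas_a <- deltas_a %||% grid_default(spec_a$factor)
  deltas_b <- deltas_b %||% grid_default(spec_b$factor)
  if (!any(deltas_a == 0) || !any(deltas_b == 0)) {
    stop_config("each delta axis must contain 0 (the unadjusted row/column)")
  }
  baseline <- summarize_predictions(object, records, summary_mode, threshold)
  cells <- matrix(NA_real_, length(deltas_a), length(deltas_b),
                  dimnames = list(as.character(deltas_a),
                                  as.character(deltas_b)))
  for (i in seq_along(deltas_a)) {
    adj_a <- adjust_records(records, spec_a, deltas_a[i])
    for (j in seq_along(deltas_b)) {
      adj <- adjust_records(adj_a, spec_b, deltas_b[j])
      cells[i, j] <- relative_change(
        summarize_predictions(object, adj, summary_mode, threshold), baseline)
    }
  }
  n_eligible <- c(sum(eligibility_mask(records, spec_a)),
                  sum(eligibility_mask(records, spec_b)))
  names(n_eligible) <- c(spec_a$factor, spec_b$factor)
  coverage <- NULL
  if (!is.null(train_records)) {
    coverage <- list(
      trained_coverage_axis(records, train_records, spec_a, deltas_a),
      trained_coverage_axis(records, train_records, spec_b, deltas_b))
    names(coverage) <- c(spec_a$factor, spec_b$factor)
  }
  structure(list(cells = cells, deltas_a = deltas_a, deltas_b = deltas_b,
                 factor_a = spec_a$factor, factor_b = spec_b$factor,
                 baseline = baseline, summary_mode = summary_mode,
                 n_eligible = n_eligible, trained_coverage = coverage),
            class = "heatmap_grid")
}

# Fraction of adjusted eligible test values inside the central 98% range of
# the eligible training values for the same factor.
trained_coverage_axis <- function(records, train_records, spec, deltas) {
  tv <- train_records[[spec$column]][eligibility_mask(train_records, spec)]
  tv <- tv[!is.na(tv)]
  ev <- records[[spec$column]][eligibility_mask(records, spec)]
  ev <- ev[!is.na(ev)]
  if (!length(tv) || !length(ev)) {
    return(stats::setNames(rep(NA_real_, length(deltas)), deltas))
  }
  rng <- stats::quantile(tv, c(0.01, 0.99), names = FALSE)
  vapply(stats::setNames(deltas, deltas), function(d) {
    adj <- pmax(ev + d, spec$clamp_floor)
    mean(adj >= rng[1] & adj <= rng[2])
  }, numeric(1))
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("Two-factor grid: %s (rows, %d deltas) x %s (cols, %d deltas)\n",
              x$factor_a, length(x$deltas_a), x$factor_b, length(x$deltas_b)))
  cat(sprintf("  baseline %s = %.5g; cells are %% change; n eligible: %s\n",
              x$summary_mode, x$baseline,
              paste(names(x$n_eligible), x$n_eligible, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Write a heatmap grid as CSV plus a JSON sidecar
#'
#' The CSV has axis-b deltas as the header row and axis-a deltas as the
#' first column; the sidecar records the baseline, summary mode and
#' eligibility counts.
#' @param grid A `heatmap_grid`.
#' @param path CSV output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @export
write_grid_csv <- function(grid, path) {
  df <- data.frame(delta = grid$deltas_a, grid$cells, check.names = FALSE)
  names(df) <- c(paste0(grid$factor_a, "_delta"), as.character(grid$deltas_b))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(factor_a = grid$factor_a, factor_b = grid$factor_b,
         baseline = grid$baseline, summary_mode = grid$summary_mode,
         n_eligible = as.list(grid$n_eligible),
         trained_coverage = grid$trained_coverage),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}
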