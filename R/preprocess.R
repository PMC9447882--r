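## Inclusion filtering and design-matrix encoding.
##
## The 24 activity items are encoded into a fixed-width numeric design
## matrix: categorical items as one-hot groups with an explicit missing
## level, fully observed continuous items (age, intervention counts)
## standardized on the fitting records, the two adjustable EMS intervals
## (call to contact, contact to hospital arrival) kept as raw minutes, and
## interventions not performed on every patient (defibrillation, adrenaline)
## as a non-performance flag plus a one-hot minute-binned time-to-
## performance group. The shipped default schema encodes to exactly 145
## columns.

#' Apply the study inclusion filters
#'
#' Retains adult (age >= 18) records with a cardiogenic cause of arrest and
#' tallies the exclusions per reason (a record failing both criteria counts
#' under both, and once in the union).
#'
#' @param records Cohort data frame with `age_years` and `cause_cardiogenic`.
#' @return List with `included` (filtered data frame) and `tally` (named
#'   counts: `recorded`, `under_18`, `non_cardiogenic`, `excluded`,
#'   `included`, plus `inclusion_percent`).
#' @export
apply_inclusion_filters <- function(records) {
  for (nm in c("age_years", "cause_cardiogenic")) {
    bad <- which(is.na(records[[nm]]))
    if (length(bad)) {
      stop_config("record(s) %s missing required field '%s'",
                  paste(utils::head(bad, 5), collapse = ", "), nm)
    }
  }
  under <- records$age_years < 18
  noncardio <- !records$cause_cardiogenic
  keep <- !under & !noncardio
  tally <- inclusion_tally(recorded = nrow(records),
                           under_18 = sum(under),
                           non_cardiogenic = sum(noncardio),
                           included = sum(keep))
  list(included = records[keep, , drop = FALSE], tally = tally)
}

#' Build an inclusion tally / filter report
#'
#' @param recorded Total records before filtering.
#' @param under_18,non_cardiogenic Counts failing each criterion.
#' @param included Count retained.
#' @return Named list including `inclusion_percent` (rounded to the nearest
#'   whole percent, as reported in registry flowcharts).
#' @export
inclusion_tally <- function(recorded, under_18, non_cardiogenic, included) {
  list(recorded = recorded, under_18 = under_18,
       non_cardiogenic = non_cardiogenic,
       excluded = recorded - included, included = included,
       inclusion_percent = round(100 * included / recorded))
}

#' Default encoder declarations for the 24 activity items
#'
#' One declaration per model input item (the arrest cause and the outcome
#' are not encoded). Encoder kinds:
#' \describe{
#'   \item{onehot}{categorical with explicit missing level}
#'   \item{standardize}{continuous, standardized on the fitting records}
#'   \item{raw_minutes}{adjustable EMS interval kept in natural units}
#'   \item{intervention_binned}{non-performance flag + one-hot one-minute
#'     time bins (default)}
#'   \item{intervention_time}{non-performance flag + raw time channel
#'     (config alternative)}
#' }
#' Defibrillation time uses bins 0..30 and an open 31+ bin; adrenaline time
#' bins 0..54 and 55+, reflecting its longer right tail. The declarations
#' total exactly 145 encoded columns.
#'
#' @param binned_intervention_times If `FALSE`, intervention times are
#'   encoded as raw-minute channels instead of minute bins (width then
#'   drops below 145).
#' @return List of declarations consumed by [build_schema()].
#' @export
default_field_declarations <- function(binned_intervention_times = TRUE) {
  lev <- cohort_levels()
  kind_int <- if (binned_intervention_times) "intervention_binned" else "intervention_time"
  decl <- list(
    list(field = "age_years", kind = "standardize"),
    list(field = "sex", kind = "onehot", levels = lev$sex),
    list(field = "guideline_era", kind = "onehot", levels = lev$guideline_era),
    list(field = "witnessed", kind = "onehot", levels = lev$witnessed),
    list(field = "witness_type", kind = "onehot", levels = lev$witness_type),
    list(field = "bystander_cpr", kind = "onehot", levels = lev$bystander_cpr),
    list(field = "bystander_cpr_actions", kind = "onehot",
         levels = lev$bystander_cpr_actions),
    list(field = "bystander_aed", kind = "onehot", levels = lev$bystander_aed),
    list(field = "ems_lifesaver", kind = "onehot", levels = lev$ems_lifesaver),
    list(field = "ems_doctor", kind = "onehot", levels = lev$ems_doctor),
    list(field = "first_rhythm", kind = "onehot", levels = lev$first_rhythm),
    list(field = "defib_time_min", kind = kind_int,
         performed_field = "defib_performed", max_bin = 30),
    list(field = "defib_count", kind = "standardize"),
    list(field = "adrenaline_time_min", kind = kind_int,
         performed_field = "adrenaline_given", max_bin = 54),
    list(field = "adrenaline_count", kind = "standardize"),
    list(field = "medication_route", kind = "onehot", levels = lev$medication_route),
    list(field = "advanced_airway", kind = "onehot", levels = lev$advanced_airway),
    list(field = "call_to_contact_min", kind = "raw_minutes"),
    list(field = "contact_to_arrival_min", kind = "raw_minutes"),
    list(field = "prehospital_rosc", kind = "onehot", levels = lev$prehospital_rosc)
  )
  decl
}

encoder_width <- function(d) {
  switch(d$kind,
         onehot = length(d$levels) + 1L,            # + explicit missing level
         standardize = 1L,
         raw_minutes = 1L,
         intervention_time = 2L,                    # flag + raw time channel
         intervention_binned = as.integer(1L + d$max_bin + 2L), # flag + bins 0..max + open
         stop_config("unknown encoder kind '%s'", d$kind))
}

encoder_colnames <- function(d) {
  switch(d$kind,
         onehot = paste0(d$field, "=", c(d$levels, "missing")),
         standardize = paste0(d$field, "__std"),
         raw_minutes = d$field,
         intervention_time = c(paste0(d$field, "__not_performed"), d$field),
         intervention_binned = c(paste0(d$field, "__not_performed"),
                                 paste0(d$field, "=", c(0:d$max_bin,
                                                        paste0(d$max_bin + 1, "plus")))))
}

#' Build a feature schema from encoder declarations
#'
#' @param declarations List of encoder declarations (see
#'   [default_field_declarations()]); each source field may appear exactly
#'   once.
#' @return Object of class `feature_schema` with per-encoder widths, column
#'   labels, total `width`, and the set of adjustable raw-minute channels.
#' @export
build_schema <- function(declarations = default_field_declarations()) {
  fields <- vapply(declarations, `[[`, "", "field")
  if (anyDuplicated(fields)) {
    stop_config("duplicate field declaration: %s",
                paste(unique(fields[duplicated(fields)]), collapse = ", "))
  }
  widths <- vapply(declarations, encoder_width, 1L)
  cols <- unlist(lapply(declarations, encoder_colnames))
  structure(
    list(declarations = declarations, fields = fields, widths = widths,
         columns = cols, width = sum(widths),
         raw_minute_fields = fields[vapply(declarations, `[[`, "", "kind") == "raw_minutes"]),
    class = "feature_schema"
  )
}

#' Total encoded width of a schema
#' @param schema A `feature_schema`.
#' @export
schema_width <- function(schema) schema$width

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema:", length(x$declarations), "encoders,",
      x$width, "encoded columns\n")
  for (i in seq_along(x$declarations)) {
    d <- x$declarations[[i]]
    cat(sprintf("  %-24s %-20s width %d\n", d$field, d$kind, x$widths[i]))
  }
  invisible(x)
}

encode_one <- function(d, records, centers = NULL, scales = NULL) {
  n <- nrow(records)
  v <- records[[d$field]]
  if (d$kind == "onehot") {
    lv <- c(d$levels, "missing")
    m <- matrix(0, n, length(lv))
    idx <- match(as.character(v), d$levels)
    unseen <- !is.na(v) & is.na(idx)
    if (any(unseen)) {
      warning(sprintf("field '%s': %d unseen level value(s) mapped to missing",
                      d$field, sum(unseen)), call. = FALSE)
    }
    idx[is.na(idx)] <- length(lv)
    m[cbind(seq_len(n), idx)] <- 1
    m
  } else if (d$kind == "standardize") {
    m <- matrix((v - centers[[d$field]]) / scales[[d$field]], n, 1)
    m
  } else if (d$kind == "raw_minutes") {
    matrix(as.numeric(v), n, 1)
  } else if (d$kind == "intervention_time") {
    performed <- as.logical(records[[d$performed_field]])
    t <- ifelse(performed, as.numeric(v), 0)
    cbind(as.numeric(!performed), t)
  } else if (d$kind == "intervention_binned") {
    performed <- as.logical(records[[d$performed_field]])
    nb <- d$max_bin + 2L                 # bins 0..max_bin plus open top bin
    m <- matrix(0, n, 1L + nb)
    m[!performed, 1] <- 1
    pi <- which(performed)
    if (length(pi)) {
      b <- pmin(pmax(floor(as.numeric(v[pi])), 0), d$max_bin + 1L)
      m[cbind(pi, 2L + b)] <- 1
    }
    m
  } else {
    stop_config("unknown encoder kind '%s'", d$kind)
  }
}

# Population standard deviation (divides by n), matching fixed-parameter
# standardization of a full fitting set.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Fit the encoding on a set of records and encode them
#'
#' Standardization parameters (mean, population standard deviation) are
#' computed from these records only and stored for later application to
#' held-out or counterfactually adjusted data. A zero-variance continuous
#' column falls back to scale 1 with a warning.
#'
#' @param records Records that passed the inclusion filters.
#' @param schema A [build_schema()] result.
#' @return List of class `ohca_encoded` with `matrix` (n x width design
#'   matrix, labelled columns) and `encoder` (class `ohca_encoder`: schema
#'   plus stored standardization parameters).
#' @export
fit_encode <- function(records, schema = build_schema()) {
  stopifnot(inherits(schema, "feature_schema"))
  centers <- list(); scales <- list()
  for (d in schema$declarations) {
    if (d$kind == "standardize") {
      v <- records[[d$field]]
      if (anyNA(v)) stop_config("standardized field '%s' contains missing values", d$field)
      centers[[d$field]] <- mean(v)
      s <- pop_sd(v)
      if (s == 0) {
        warning(sprintf("field '%s' has zero variance; using scale 1", d$field),
                call. = FALSE)
        s <- 1
      }
      scales[[d$field]] <- s
    }
  }
  encoder <- structure(list(schema = schema, centers = centers, scales = scales),
                       class = "ohca_encoder")
  structure(list(matrix = encode_records(records, encoder), encoder = encoder),
            class = "ohca_encoded")
}

#' Apply a fitted encoding to records
#'
#' Uses the stored standardization parameters; never re-fits. Unseen
#' categorical levels map to the missing level with a warning.
#'
#' @param records Records to encode.
#' @param encoder An `ohca_encoder` from [fit_encode()].
#' @return Numeric design matrix with labelled columns and the record `id`s
#'   as row names (when present).
#' @export
encode_records <- function(records, encoder) {
  if (!inherits(encoder, "ohca_encoder")) {
    stop_config("encoder must be an 'ohca_encoder' from fit_encode()")
  }
  schema <- encoder$schema
  missing_fields <- setdiff(schema$fields, names(records))
  if (length(missing_fields)) {
    stop_config("records lack field(s) declared in schema: %s",
                paste(missing_fields, collapse = ", "))
  }
  parts <- lapply(schema$declarations, encode_one, records = records,
                  centers = encoder$centers, scales = encoder$scales)
  m <- do.call(cbind, parts)
  colnames(m) <- schema$columns
  if (!is.null(records$id)) rownames(m) <- as.character(records$id)
  if (anyNA(m)) stop_config("encoded matrix contains undefined values")
  m
}
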