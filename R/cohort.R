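## Synthetic Utstein-style cohort generator.
##
## Emulates the structure of a prefectural out-of-hospital cardiac-arrest
## (OHCA) registry: one row per resuscitation attempt, 24 activity items,
## a rare favourable neurological outcome (cerebral performance category
## 1-2 at one month), right-skewed EMS time intervals, and intervention
## eligibility rules (defibrillation only with a shockable initial rhythm).
## Outcomes are drawn from a known logistic model with transport-by-
## intervention interaction terms so downstream stages can be tested
## against ground truth.

#' Canonical activity items of a cohort record
#'
#' Returns the 24 Utstein-style data items carried by each record: 22 model
#' input factors plus the arrest cause (used only by the inclusion filter)
#' and the CPC 1-2 outcome label.
#'
#' @return A data frame with columns `item` (column name in the cohort data
#'   frame) and `type` (`"minutes"`, `"years"`, `"count"`, `"category"` or
#'   `"boolean"`).
#' @export
activity_items <- function() {
  data.frame(
    item = c("age_years", "sex", "guideline_era", "witnessed", "witness_type",
             "bystander_cpr", "bystander_cpr_actions", "bystander_aed",
             "ems_lifesaver", "ems_doctor", "first_rhythm",
             "defib_performed", "defib_count", "defib_time_min",
             "adrenaline_given", "adrenaline_count", "adrenaline_time_min",
             "medication_route", "advanced_airway",
             "call_to_contact_min", "contact_to_arrival_min",
             "prehospital_rosc", "cause_cardiogenic", "outcome_cpc12"),
    type = c("years", "category", "category", "category", "category",
             "category", "category", "category",
             "category", "category", "category",
             "boolean", "count", "minutes",
             "boolean", "count", "minutes",
             "category", "category",
             "minutes", "minutes",
             "category", "boolean", "boolean"),
    stringsAsFactors = FALSE
  )
}

# Categorical level sets used by generator and encoder alike.
cohort_levels <- function() {
  list(
    sex = c("male", "female"),
    guideline_era = c("g2010", "g2015"),
    witnessed = c("yes", "no"),
    witness_type = c("none", "family", "friends", "colleagues", "passers_by",
                     "firefighter", "paramedic", "emergency_lifesaver", "other"),
    bystander_cpr = c("yes", "no"),
    bystander_cpr_actions = c("none", "compressions_only",
                              "compressions_and_ventilations"),
    bystander_aed = c("yes", "no"),
    ems_lifesaver = c("yes", "no"),
    ems_doctor = c("yes", "no"),
    first_rhythm = c("VF", "pulseless_VT", "PEA", "asystole", "other"),
    medication_route = c("yes", "no"),
    advanced_airway = c("yes", "no"),
    prehospital_rosc = c("yes", "no")
  )
}

shockable_rhythms <- function() c("VF", "pulseless_VT")
ems_witness_types <- function() c("firefighter", "paramedic", "emergency_lifesaver")

#' Ground-truth outcome effect model
#'
#' Defines the logistic model from which synthetic outcomes are drawn:
#' `logit P(CPC1/2) = intercept + sum(coefficients * centred features) +
#' interaction terms`. Time effects are log-odds per minute, age per year.
#' The two interaction coefficients act on centred
#' (transport minutes) x (intervention delay minutes) products, and apply
#' only to records that actually received the intervention.
#'
#' Default magnitudes are set so the generative model's intrinsic (Bayes)
#' discriminability matches the published full AUROC of the real-registry
#' prognostic model (about 0.94): every minute of delay in transport,
#' defibrillation and adrenaline carries odds ratios of about 0.90, 0.80
#' and 0.88 respectively; a shockable initial rhythm, a witnessed arrest
#' and bystander CPR improve the odds. Negative interaction coefficients
#' make intervention delays more harmful when transport is also prolonged
#' (a synergistic worsening).
#'
#' @param intercept Log-odds intercept. Usually recalibrated by
#'   [generate_cohort()] to hit the configured outcome prevalence.
#' @param age,transport,defib_delay,drug_delay Log-odds per year / minute.
#' @param shockable,witnessed,bystander_cpr Log-odds for the indicator being
#'   true.
#' @param transport_x_defib,transport_x_drug Interaction log-odds per
#'   minute squared.
#' @param reference Centring constants (minutes / years) at which the main
#'   effects are anchored.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(intercept = stats::qlogis(0.04),
                         age = -0.11,
                         transport = -0.10,
                         defib_delay = -0.22,
                         drug_delay = -0.13,
                         shockable = 3.2,
                         witnessed = 1.3,
                         bystander_cpr = 0.9,
                         transport_x_defib = -0.012,
                         transport_x_drug = -0.009,
                         reference = list(age = 80, transport = 28,
                                          defib_delay = 4, drug_delay = 16)) {
  vals <- c(intercept, age, transport, defib_delay, drug_delay, shockable,
            witnessed, bystander_cpr, transport_x_defib, transport_x_drug,
            unlist(reference))
  if (any(!is.finite(vals))) {
    stop_config("effect_model: all coefficients must be finite")
  }
  structure(
    list(intercept = intercept, age = age, transport = transport,
         defib_delay = defib_delay, drug_delay = drug_delay,
         shockable = shockable, witnessed = witnessed,
         bystander_cpr = bystander_cpr,
         transport_x_defib = transport_x_defib,
         transport_x_drug = transport_x_drug,
         reference = reference),
    class = "effect_model"
  )
}

#' Effect model with every coefficient set to zero
#'
#' Outcomes then occur with probability `plogis(intercept)` regardless of
#' covariates; useful for calibration tests.
#' @param intercept Log-odds intercept.
#' @export
null_effect_model <- function(intercept = stats::qlogis(0.04)) {
  effect_model(intercept = intercept, age = 0, transport = 0,
               defib_delay = 0, drug_delay = 0, shockable = 0,
               witnessed = 0, bystander_cpr = 0,
               transport_x_defib = 0, transport_x_drug = 0)
}

#' True outcome probability under the generative model
#'
#' Evaluates the logistic generative model for each record. Records that did
#' not receive an intervention contribute no delay or interaction term for
#' it; missing witnessed / bystander-CPR categories contribute zero (the
#' effect is attached to an observed "yes").
#'
#' @param records Cohort data frame (rows are patients).
#' @param effects An [effect_model()].
#' @return Numeric vector of probabilities in (0, 1).
#' @export
true_outcome_probability <- function(records, effects) {
  stopifnot(inherits(effects, "effect_model"))
  lp <- effects$intercept + linear_predictor(records, effects)
  stats::plogis(lp)
}

# Linear predictor excluding the intercept (used by the intercept
# calibration bisection).
linear_predictor <- function(records, effects) {
  ref <- effects$reference
  tr <- records$contact_to_arrival_min - ref$transport
  lp <- effects$age * (records$age_years - ref$age) + effects$transport * tr
  lp <- lp + effects$shockable *
    as.numeric(records$first_rhythm %in% shockable_rhythms())
  lp <- lp + effects$witnessed *
    as.numeric(!is.na(records$witnessed) & records$witnessed == "yes")
  lp <- lp + effects$bystander_cpr *
    as.numeric(!is.na(records$bystander_cpr) & records$bystander_cpr == "yes")
  dfb <- records$defib_performed
  if (any(dfb)) {
    dd <- records$defib_time_min[dfb] - ref$defib_delay
    lp[dfb] <- lp[dfb] + effects$defib_delay * dd +
      effects$transport_x_defib * tr[dfb] * dd
  }
  adr <- records$adrenaline_given
  if (any(adr)) {
    rd <- records$adrenaline_time_min[adr] - ref$drug_delay
    lp[adr] <- lp[adr] + effects$drug_delay * rd +
      effects$transport_x_drug * tr[adr] * rd
  }
  lp
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults are calibrated to the overall column of the source registry's
#' patient-background table: ~4% CPC1/2 prevalence, ~12% defibrillated,
#' ~36% receiving adrenaline, log-normal EMS time intervals matched by
#' moment fitting to the published medians and interquartile ranges
#' (call to contact 8 [7, 10] min, contact to hospital arrival 28 [22, 36]
#' min, contact to shock 4 min, contact to adrenaline 16 [12, 21] min).
#'
#' @param n_records Number of pre-filter records to generate.
#' @param prevalence_target Target CPC1/2 prevalence among records passing
#'   the inclusion filter (adults, cardiogenic cause).
#' @param rhythm_mix Named probabilities over first monitored rhythms
#'   (must sum to 1). The default puts 13% of records in shockable rhythms
#'   so that, with defibrillation restricted to shockable rhythms, the
#'   defibrillated fraction can reach its ~12% target.
#' @param defib_fraction Overall fraction of records defibrillated.
#' @param adrenaline_fraction Fraction receiving adrenaline.
#' @param time_distributions Per-variable log-normal parameters
#'   (`meanlog`, `sdlog`) in minutes.
#' @param missingness Named per-categorical-field probability of a missing
#'   value (missing completely at random). Placeholder defaults; the real
#'   registry's rates are not published.
#' @param effects An [effect_model()] supplying the generative outcome
#'   model.
#' @param exclusion_fractions List with `under_18` and `non_cardiogenic`
#'   fractions; defaults make ~72% of records survive the inclusion filter.
#' @param calibrate_intercept If `TRUE` (default) the intercept is tuned by
#'   bisection so the expected prevalence among included records equals
#'   `prevalence_target`.
#' @param seed Integer seed; identical config and seed reproduce the
#'   identical cohort byte for byte.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_records = 8000,
                          prevalence_target = 0.04,
                          rhythm_mix = c(VF = 0.12, pulseless_VT = 0.01,
                                         PEA = 0.195, asystole = 0.625,
                                         other = 0.05),
                          defib_fraction = 0.12,
                          adrenaline_fraction = 0.36,
                          time_distributions = list(
                            call_to_contact_min = list(meanlog = log(8), sdlog = 0.264),
                            contact_to_arrival_min = list(meanlog = log(28), sdlog = 0.365),
                            defib_time_min = list(meanlog = log(4), sdlog = 1.028),
                            adrenaline_time_min = list(meanlog = log(16), sdlog = 0.415)),
                          missingness = NULL,
                          effects = effect_model(),
                          exclusion_fractions = list(under_18 = 0.03,
                                                     non_cardiogenic = 0.26),
                          calibrate_intercept = TRUE,
                          seed = 1L) {
  if (is.null(missingness)) {
    soft <- c("sex", "guideline_era", "witnessed", "witness_type",
              "bystander_cpr", "bystander_cpr_actions", "bystander_aed",
              "ems_lifesaver", "ems_doctor", "medication_route",
              "advanced_airway", "prehospital_rosc")
    missingness <- stats::setNames(rep(0.02, length(soft)), soft)
  }
  cfg <- structure(
    list(n_records = n_records, prevalence_target = prevalence_target,
         rhythm_mix = rhythm_mix, defib_fraction = defib_fraction,
         adrenaline_fraction = adrenaline_fraction,
         time_distributions = time_distributions,
         missingness = missingness, effects = effects,
         exclusion_fractions = exclusion_fractions,
         calibrate_intercept = calibrate_intercept,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_records) || length(cfg$n_records) != 1L ||
      is.na(cfg$n_records) || cfg$n_records < 0 ||
      cfg$n_records != round(cfg$n_records)) {
    stop_config("config field 'n_records' must be a nonnegative integer")
  }
  assert_fraction(cfg$prevalence_target, "prevalence_target", open = TRUE)
  assert_fraction(cfg$defib_fraction, "defib_fraction")
  assert_fraction(cfg$adrenaline_fraction, "adrenaline_fraction")
  rm <- cfg$rhythm_mix
  if (is.null(names(rm)) ||
      !setequal(names(rm), cohort_levels()$first_rhythm)) {
    stop_config("config field 'rhythm_mix' must be named over rhythms %s",
                paste(cohort_levels()$first_rhythm, collapse = ", "))
  }
  if (any(rm < 0) || abs(sum(rm) - 1) > 1e-8) {
    stop_config("config field 'rhythm_mix' probabilities must be nonnegative and sum to 1")
  }
  for (nm in names(cfg$time_distributions)) {
    td <- cfg$time_distributions[[nm]]
    if (!is.finite(td$meanlog) || !is.finite(td$sdlog) || td$sdlog < 0) {
      stop_config("config field 'time_distributions$%s' must give finite meanlog and nonnegative sdlog", nm)
    }
  }
  for (nm in names(cfg$missingness)) {
    assert_fraction(cfg$missingness[[nm]], paste0("missingness$", nm))
  }
  assert_fraction(cfg$exclusion_fractions$under_18, "exclusion_fractions$under_18")
  assert_fraction(cfg$exclusion_fractions$non_cardiogenic, "exclusion_fractions$non_cardiogenic")
  if (!inherits(cfg$effects, "effect_model")) {
    stop_config("config field 'effects' must be an effect_model")
  }
  invisible(cfg)
}

#' Generate a synthetic Utstein-style cohort
#'
#' Draws a pre-filter cohort (including under-18 and non-cardiogenic records
#' so the inclusion filter is exercisable) with covariates matching the
#' configured marginal distributions, then draws CPC1/2 outcomes from the
#' configured [effect_model()]. When `calibrate_intercept` is set, the
#' intercept is found by bisection on the realized covariates so that the
#' mean outcome probability among includable records equals
#' `prevalence_target`; the calibrated value is attached as the
#' `"calibrated_intercept"` attribute.
#'
#' Eligibility coherence is enforced by construction: defibrillation occurs
#' only with a shockable first monitored rhythm, and intervention times or
#' counts exist only when the intervention was performed.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per record and the columns of
#'   [activity_items()] plus `id`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- as.integer(config$n_records)
  lev <- cohort_levels()
  if (n == 0L) return(empty_cohort())

  with_seed(config$seed, {
    excl <- config$exclusion_fractions
    under18 <- stats::runif(n) < excl$under_18
    # Adult ages: 110 minus a log-normal, matching median 81 [71, 87].
    adult_age <- pmin(pmax(round(110 - stats::rlnorm(n, log(29), 0.391)), 18), 105)
    age <- ifelse(under18, sample(1:17, n, replace = TRUE), adult_age)
    cause <- stats::runif(n) >= excl$non_cardiogenic

    draw_cat <- function(levels, probs) {
      levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
    }
    sex <- draw_cat(lev$sex, c(0.56, 0.44))
    era <- draw_cat(lev$guideline_era, c(0.53, 0.47))
    witnessed <- ifelse(stats::runif(n) < 0.40, "yes", "no")
    # Witness type conditional on a witnessed arrest (registry proportions).
    wt_probs <- c(family = 1692, friends = 91, colleagues = 71,
                  passers_by = 65, other = 703, firefighter = 2,
                  paramedic = 172, emergency_lifesaver = 502)
    wtype <- rep("none", n)
    wi <- which(witnessed == "yes")
    if (length(wi)) {
      wtype[wi] <- names(wt_probs)[sample.int(length(wt_probs), length(wi),
                                              replace = TRUE,
                                              prob = wt_probs / sum(wt_probs))]
    }
    bcpr <- ifelse(stats::runif(n) < 0.52, "yes", "no")
    actions <- rep("none", n)
    ci <- which(bcpr == "yes")
    if (length(ci)) {
      actions[ci] <- ifelse(stats::runif(length(ci)) < 0.89,
                            "compressions_only", "compressions_and_ventilations")
    }
    aed <- ifelse(stats::runif(n) < 0.016, "yes", "no")
    lifesaver <- ifelse(stats::runif(n) < 0.98, "yes", "no")
    doctor <- ifelse(stats::runif(n) < 0.056, "yes", "no")
    rhythm <- draw_cat(lev$first_rhythm,
                       config$rhythm_mix[lev$first_rhythm])
    airway <- ifelse(stats::runif(n) < 0.89, "yes", "no")
    route <- ifelse(stats::runif(n) < 0.46, "yes", "no")
    rosc <- ifelse(stats::runif(n) < 0.10, "yes", "no")

    draw_time <- function(name) {
      td <- config$time_distributions[[name]]
      pmax(round(stats::rlnorm(n, td$meanlog, td$sdlog)), 0)
    }
    call_to_contact <- draw_time("call_to_contact_min")
    contact_to_arrival <- draw_time("contact_to_arrival_min")

    shockable <- rhythm %in% shockable_rhythms()
    p_shock <- sum(config$rhythm_mix[shockable_rhythms()])
    p_defib_given_shock <- if (p_shock > 0) {
      min(config$defib_fraction / p_shock, 1)
    } else 0
    defib <- shockable & (stats::runif(n) < p_defib_given_shock)
    defib_count <- ifelse(defib, 1 + stats::rpois(n, 1.0), 0)
    defib_time <- ifelse(defib, draw_time("defib_time_min"), NA_real_)

    adren <- stats::runif(n) < config$adrenaline_fraction
    adren_count <- ifelse(adren, 1 + stats::rpois(n, 0.7), 0)
    adren_time <- ifelse(adren, draw_time("adrenaline_time_min"), NA_real_)

    records <- data.frame(
      id = seq_len(n),
      age_years = age, sex = sex, guideline_era = era,
      witnessed = witnessed, witness_type = wtype,
      bystander_cpr = bcpr, bystander_cpr_actions = actions,
      bystander_aed = aed, ems_lifesaver = lifesaver, ems_doctor = doctor,
      first_rhythm = rhythm,
      defib_performed = defib, defib_count = defib_count,
      defib_time_min = defib_time,
      adrenaline_given = adren, adrenaline_count = adren_count,
      adrenaline_time_min = adren_time,
      medication_route = route, advanced_airway = airway,
      call_to_contact_min = call_to_contact,
      contact_to_arrival_min = contact_to_arrival,
      prehospital_rosc = rosc,
      cause_cardiogenic = cause,
      stringsAsFactors = FALSE
    )

    # Outcome from the generative model, intercept optionally recalibrated
    # on the included (adult, cardiogenic) subset.
    lp <- linear_predictor(records, config$effects)
    included <- records$age_years >= 18 & records$cause_cardiogenic
    intercept <- config$effects$intercept
    if (config$calibrate_intercept && any(included)) {
      intercept <- calibrate_intercept(lp[included], config$prevalence_target)
    }
    p <- stats::plogis(intercept + lp)
    records$outcome_cpc12 <- stats::runif(n) < p

    # MCAR missingness on soft categorical fields only; eligibility-bearing
    # fields (rhythm, intervention flags) stay complete.
    for (nm in names(config$missingness)) {
      pr <- config$missingness[[nm]]
      if (pr > 0 && nm %in% names(records)) {
        records[[nm]][stats::runif(n) < pr] <- NA
      }
    }

    attr(records, "calibrated_intercept") <- intercept
    records
  })
}

empty_cohort <- function() {
  items <- activity_items()$item
  out <- data.frame(id = integer(0))
  for (it in items) out[[it]] <- logical(0)
  out
}

#' Bisection on the intercept so mean logistic(c + lp) hits a target
#' @noRd
calibrate_intercept <- function(lp, target, lo = -25, hi = 25, iter = 80L) {
  f <- function(c0) mean(stats::plogis(c0 + lp)) - target
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Write a cohort to CSV
#'
#' One row per record, header with canonical column names, missing
#' categoricals as empty fields. Output is byte-identical for identical
#' cohorts.
#' @param records Cohort data frame.
#' @param path Output file path.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort_csv()]
#' @param path File path.
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  for (nm in c("defib_performed", "adrenaline_given", "cause_cardiogenic",
               "outcome_cpc12")) {
    if (nm %in% names(out)) out[[nm]] <- as.logical(out[[nm]])
  }
  out
}

#' Read a cohort generator configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [cohort_config()]; the effect
#' model may be given as a named list under `effects`.
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$effects)) raw$effects <- do.call(effect_model, raw$effects)
  if (!is.null(raw$rhythm_mix)) raw$rhythm_mix <- unlist(raw$rhythm_mix)
  do.call(cohort_config, raw)
}
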