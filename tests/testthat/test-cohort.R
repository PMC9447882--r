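test_that("generation is reproducible and writes byte-identical CSV", {
  coh1 <- make_cohort(500, seed = 7)
  coh2 <- make_cohort(500, seed = 7)
  expect_identical(coh1, coh2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(coh1, f1); write_cohort_csv(coh2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  coh3 <- make_cohort(500, seed = 8)
  expect_false(identical(coh1$outcome_cpc12, coh3$outcome_cpc12))
  back <- read_cohort_csv(f1)
  expect_equal(back$age_years, coh1$age_years)
  expect_identical(back$outcome_cpc12, coh1$outcome_cpc12)
  expect_identical(back$first_rhythm, coh1$first_rhythm)
})

test_that("null effect model hits the intercept-implied prevalence at large n", {
  # Monte-Carlo bound: 4 binomial standard errors at n = 50,000 is < 0.0036
  coh <- generate_cohort(cohort_config(
    n_records = 50000, prevalence_target = 0.04,
    effects = null_effect_model(stats::qlogis(0.04)),
    exclusion_fractions = list(under_18 = 0, non_cardiogenic = 0),
    calibrate_intercept = FALSE, seed = 3))
  expect_lt(abs(mean(coh$outcome_cpc12) - 0.04), 0.003)
})

test_that("intercept auto-calibration controls prevalence under nonzero effects", {
  coh <- generate_cohort(cohort_config(
    n_records = 50000, prevalence_target = 0.04,
    exclusion_fractions = list(under_18 = 0, non_cardiogenic = 0), seed = 4))
  expect_lt(abs(mean(coh$outcome_cpc12) - 0.04), 0.005)
})

test_that("defaults reproduce the registry's intervention and exclusion rates", {
  coh <- generate_cohort(cohort_config(n_records = 20000, seed = 5))
  # defibrillation performed in ~12% of records
  expect_lt(abs(mean(coh$defib_performed) - 0.12), 0.01)
  expect_lt(abs(mean(coh$adrenaline_given) - 0.36), 0.015)
  included <- coh$age_years >= 18 & coh$cause_cardiogenic
  # ~72% survive the inclusion filter (0.97 * 0.74)
  expect_lt(abs(mean(included) - 0.7178), 0.015)
  # time medians near the published ones
  expect_lt(abs(median(coh$call_to_contact_min) - 8), 1)
  expect_lt(abs(median(coh$contact_to_arrival_min) - 28), 2)
  expect_lt(abs(median(coh$adrenaline_time_min, na.rm = TRUE) - 16), 2)
})

test_that("eligibility coherence holds in generated data", {
  coh <- make_cohort(5000, seed = 6, no_exclusions = FALSE)
  shockable <- coh$first_rhythm %in% c("VF", "pulseless_VT")
  expect_true(all(!coh$defib_performed | shockable))
  expect_identical(is.na(coh$defib_time_min), !coh$defib_performed)
  expect_identical(is.na(coh$adrenaline_time_min), !coh$adrenaline_given)
  expect_true(all(coh$defib_count[!coh$defib_performed] == 0))
  times <- c(coh$call_to_contact_min, coh$contact_to_arrival_min,
             coh$defib_time_min[coh$defib_performed],
             coh$adrenaline_time_min[coh$adrenaline_given])
  expect_true(all(times >= 0))
})

test_that("n_records = 0 yields an empty cohort without error", {
  coh <- generate_cohort(cohort_config(n_records = 0))
  expect_s3_class(coh, "data.frame")
  expect_identical(nrow(coh), 0L)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(prevalence_target = 1.2), "prevalence_target")
  expect_error(cohort_config(defib_fraction = -0.1), "defib_fraction")
  expect_error(cohort_config(rhythm_mix = c(VF = 0.5, pulseless_VT = 0.5,
                                            PEA = 0.5, asystole = 0, other = 0)),
               "rhythm_mix")
  expect_error(cohort_config(n_records = -5), "n_records")
  expect_error(effect_model(transport = Inf), "finite")
})

test_that("true outcome probability matches closed forms and the 2x2 oracle", {
  rec <- data.frame(
    age_years = 80, sex = "male", guideline_era = "g2010", witnessed = "no",
    witness_type = "none", bystander_cpr = "no", bystander_cpr_actions = "none",
    bystander_aed = "no", ems_lifesaver = "yes", ems_doctor = "no",
    first_rhythm = "asystole", defib_performed = FALSE, defib_count = 0,
    defib_time_min = NA_real_, adrenaline_given = FALSE, adrenaline_count = 0,
    adrenaline_time_min = NA_real_, medication_route = "no",
    advanced_airway = "no", call_to_contact_min = 8,
    contact_to_arrival_min = 28, prehospital_rosc = "no",
    cause_cardiogenic = TRUE, stringsAsFactors = FALSE)

  # all coefficients 0, intercept 0 -> exactly 1/2
  expect_equal(true_outcome_probability(rec, null_effect_model(0)), 0.5)

  # single transport coefficient: logistic(intercept + beta * (t - ref))
  em <- null_effect_model(-3); em$transport <- -0.08
  for (t_min in c(10, 28, 45)) {
    r <- rec; r$contact_to_arrival_min <- t_min
    expect_equal(true_outcome_probability(r, em),
                 stats::plogis(-3 - 0.08 * (t_min - 28)))
  }

  # interaction: difference-in-differences of the log-odds over a 2x2 of
  # (transport, drug delay) equals gamma * (t1-t0) * (d1-d0)
  em2 <- null_effect_model(-2)
  em2$transport_x_drug <- -0.01
  cells <- expand.grid(t = c(20, 35), d = c(10, 25))
  lo <- mapply(function(t_min, d_min) {
    r <- rec
    r$contact_to_arrival_min <- t_min
    r$adrenaline_given <- TRUE; r$adrenaline_count <- 1
    r$adrenaline_time_min <- d_min
    stats::qlogis(true_outcome_probability(r, em2))
  }, cells$t, cells$d)
  did <- (lo[4] - lo[3]) - (lo[2] - lo[1])
  expect_equal(did, -0.01 * (35 - 20) * (25 - 10), tolerance = 1e-10)
})

test_that("cohort configs round-trip through YAML and JSON", {
  cfg <- cohort_config(n_records = 123, prevalence_target = 0.05, seed = 9)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_records = 123, prevalence_target = 0.05, seed = 9),
                   yml)
  cfg2 <- read_cohort_config(yml)
  expect_identical(cfg2$n_records, cfg$n_records)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg))
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_records = 123, prevalence_target = 0.05,
                            seed = 9, effects = list(transport = -0.2)),
                       jsn, auto_unbox = TRUE)
  cfg3 <- read_cohort_config(jsn)
  expect_equal(cfg3$effects$transport, -0.2)
})
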