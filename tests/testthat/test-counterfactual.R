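test_that("adjustments respect eligibility, clamping and immutability", {
  coh <- make_cohort(300, seed = 31)
  spec <- adjustment_spec("contact_to_first_defib")

  # delta = 0 is the identity
  expect_identical(adjust_records(coh, spec, 0), coh)

  # non-shockable records are untouched by defibrillation-delay shifts
  adj <- adjust_records(coh, spec, -2)
  untouched <- !(coh$defib_performed &
                   coh$first_rhythm %in% c("VF", "pulseless_VT"))
  expect_identical(adj[untouched, ], coh[untouched, ])

  # clamping at the floor
  one <- coh[which(coh$defib_performed)[1], ]
  one$defib_time_min <- 2
  adj1 <- adjust_records(one, spec, -5)
  expect_equal(adj1$defib_time_min, 0)

  # the input collection is not mutated
  before <- coh$defib_time_min
  invisible(adjust_records(coh, spec, 3))
  expect_identical(coh$defib_time_min, before)

  expect_error(adjustment_spec("not_a_factor"), "unknown adjustment factor")
})

test_that("drug-delay eligibility excludes EMS-witnessed arrests", {
  coh <- make_cohort(500, seed = 32)
  spec <- adjustment_spec("contact_to_first_drug")
  adj <- adjust_records(coh, spec, 5)
  moved <- which(!is.na(adj$adrenaline_time_min) &
                   adj$adrenaline_time_min != coh$adrenaline_time_min)
  expect_true(all(coh$adrenaline_given[moved]))
  expect_false(any(coh$witness_type[moved] %in%
                     c("firefighter", "paramedic", "emergency_lifesaver")))
  ems_wit <- which(coh$adrenaline_given & coh$witness_type %in%
                     c("firefighter", "paramedic", "emergency_lifesaver"))
  expect_identical(adj$adrenaline_time_min[ems_wit],
                   coh$adrenaline_time_min[ems_wit])
})

test_that("prediction summaries match scalar oracles", {
  coh <- make_cohort(1000, seed = 33)
  const <- stub_predictor(function(r) rep(0.04, nrow(r)), n_models = 4)
  expect_equal(summarize_predictions(const, coh), 0.04)
  expect_equal(summarize_predictions(const, coh, "predicted_count"), 0)

  # logistic stub with known coefficients on 3 hand-written records
  rec3 <- coh[1:3, ]
  rec3$contact_to_arrival_min <- c(10, 28, 40)
  stub <- stub_predictor(function(r) {
    stats::plogis(-2 - 0.05 * (r$contact_to_arrival_min - 28))
  })
  hand <- mean(stats::plogis(-2 - 0.05 * (c(10, 28, 40) - 28)))
  expect_equal(summarize_predictions(stub, rec3), hand)

  expect_error(summarize_predictions(const, coh[0, ]), "empty")
})

test_that("relative change follows its arithmetic definition", {
  expect_equal(relative_change(0.04, 0.04), 0)
  expect_equal(relative_change(0.05, 0.04), 25)
  expect_equal(relative_change(0.03, 0.04), -25)
  expect_error(relative_change(0.05, 0), "baseline")
})

test_that("single-factor sweeps move in the generative direction", {
  coh <- make_cohort(1500, seed = 34)
  stub <- truth_stub(effect_model(), attr(coh, "calibrated_intercept"))

  sweep_tr <- single_factor_sweep(stub, coh, "contact_to_arrival",
                                  deltas = c(-5, 0, 10, 20))
  expect_equal(sweep_tr$percent_change[sweep_tr$delta == 0], 0)
  expect_gt(sweep_tr$percent_change[sweep_tr$delta == -5], 0)
  expect_lt(sweep_tr$percent_change[sweep_tr$delta == 10], 0)
  expect_lt(sweep_tr$percent_change[sweep_tr$delta == 20],
            sweep_tr$percent_change[sweep_tr$delta == 10])

  sweep_age <- single_factor_sweep(stub, coh, "age_years", deltas = c(-5, 0, 5))
  expect_lt(sweep_age$percent_change[sweep_age$delta == 5], 0)
  expect_gt(sweep_age$percent_change[sweep_age$delta == -5], 0)

  # default delta sets follow the published sensitivity analysis
  expect_identical(ohcasweep:::default_deltas("age_years"), c(-5, 0, 5))
  expect_identical(ohcasweep:::default_deltas("call_to_contact"), c(0, 10, 20))
  expect_identical(ohcasweep:::default_deltas("contact_to_arrival"),
                   c(-5, 0, 10, 20))
})

test_that("grid cells match an independent brute-force recomputation", {
  coh <- make_cohort(100, seed = 35)
  stub <- truth_stub(effect_model(), stats::qlogis(0.05))
  spec_a <- adjustment_spec("contact_to_arrival")
  spec_b <- adjustment_spec("contact_to_first_drug")
  deltas <- -2:2
  g <- two_factor_grid(stub, coh, spec_a, spec_b, deltas, deltas)

  # brute force, written independently of the package's sweep machinery:
  # copy records, shift eligible values by hand, evaluate the same logistic
  # model, average, convert to percent of baseline
  em <- effect_model(); em$intercept <- stats::qlogis(0.05)
  prob_of <- function(df) mean(true_outcome_probability(df, em))
  base <- prob_of(coh)
  ems <- c("firefighter", "paramedic", "emergency_lifesaver")
  for (i in seq_along(deltas)) {
    for (j in seq_along(deltas)) {
      df <- coh
      df$contact_to_arrival_min <- pmax(df$contact_to_arrival_min + deltas[i], 0)
      elig <- df$adrenaline_given & !(df$witness_type %in% ems)
      df$adrenaline_time_min[elig] <-
        pmax(df$adrenaline_time_min[elig] + deltas[j], 0)
      want <- 100 * (prob_of(df) - base) / base
      got <- g$cells[i, j]
      expect_lt(abs(got - want) / max(abs(want), 1e-12), 1e-10)
    }
  }
})

test_that("grids from a no-interaction stub are additive at small deltas", {
  coh <- make_cohort(800, seed = 36)
  em <- effect_model(transport_x_defib = 0, transport_x_drug = 0)
  stub <- truth_stub(em, attr(coh, "calibrated_intercept"))
  g <- two_factor_grid(stub, coh,
                       adjustment_spec("contact_to_arrival"),
                       adjustment_spec("contact_to_first_drug"),
                       deltas_a = -1:1, deltas_b = -1:1)
  # relative changes compound multiplicatively, so additivity is assessed on
  # log1p(cell/100); without an interaction term the residual is first-order
  # zero there
  lc <- log1p(g$cells / 100)
  res <- lc[3, 3] - lc[3, 2] - lc[2, 3] + lc[2, 2]
  expect_lt(abs(res), 5e-4)
  # the same stub with the default (nonzero) interaction coefficients leaves
  # a residual an order of magnitude larger, so the metric is discriminating
  g2 <- two_factor_grid(truth_stub(effect_model(),
                                   attr(coh, "calibrated_intercept")),
                        coh, adjustment_spec("contact_to_arrival"),
                        adjustment_spec("contact_to_first_drug"),
                        deltas_a = -1:1, deltas_b = -1:1)
  lc2 <- log1p(g2$cells / 100)
  expect_gt(abs(lc2[3, 3] - lc2[3, 2] - lc2[2, 3] + lc2[2, 2]), 5 * abs(res))
})

test_that("grid structure: zero cell, axes, eligibility counts, coverage", {
  coh <- make_cohort(400, seed = 37)
  stub <- truth_stub(effect_model(), stats::qlogis(0.04))
  spec_a <- adjustment_spec("contact_to_arrival")
  spec_b <- adjustment_spec("contact_to_first_defib")
  g <- two_factor_grid(stub, coh, spec_a, spec_b, -3:3, -2:2,
                       train_records = coh)
  expect_identical(dim(g$cells), c(7L, 5L))
  expect_identical(g$cells["0", "0"], 0)
  expect_identical(unname(g$n_eligible[1]), nrow(coh))
  expect_identical(unname(g$n_eligible[2]),
                   sum(coh$defib_performed &
                         coh$first_rhythm %in% c("VF", "pulseless_VT")))
  cov <- g$trained_coverage[[2]]
  expect_length(cov, 5)
  expect_true(all(cov >= 0 & cov <= 1))
  # the unadjusted column sits fully inside its own central range
  expect_gte(cov[["0"]], 0.95)

  # single-cell all-zero axes
  g0 <- two_factor_grid(stub, coh, spec_a, spec_b, 0, 0)
  expect_identical(as.numeric(g0$cells), 0)

  expect_error(two_factor_grid(stub, coh, spec_a, spec_a), "different factors")
  expect_error(two_factor_grid(stub, coh, spec_a, spec_b, 1:3, -2:2), "contain 0")
})

test_that("grid CSV round-trips with its JSON sidecar", {
  coh <- make_cohort(150, seed = 38)
  stub <- truth_stub(effect_model(), stats::qlogis(0.04))
  g <- two_factor_grid(stub, coh, adjustment_spec("contact_to_arrival"),
                       adjustment_spec("contact_to_first_drug"), -1:1, -1:1)
  path <- tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), g$cells, ignore_attr = TRUE)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(side$baseline, g$baseline)
  expect_identical(side$summary_mode, "mean_probability")
})
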