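# Shared fixtures: small synthetic cohorts, tiny network configs, and
# independent oracles (finite differences, brute-force grid recomputation,
# pair-counting AUROC) used across the suite.

make_cohort <- function(n, seed, prevalence = 0.04, effects = effect_model(),
                        no_exclusions = TRUE) {
  excl <- if (no_exclusions) list(under_18 = 0, non_cardiogenic = 0)
          else list(under_18 = 0.03, non_cardiogenic = 0.26)
  generate_cohort(cohort_config(n_records = n, prevalence_target = prevalence,
                                effects = effects, exclusion_fractions = excl,
                                seed = seed))
}

tiny_net <- function(input_width, seed = 1L, epochs = 10L) {
  net_config(input_width = input_width, hidden_widths = c(8L, 6L, 4L),
             batch_size = 50L, epochs = epochs, seed = seed)
}

# Truth predictor: generative probabilities with a frozen intercept.
truth_stub <- function(effects, intercept) {
  effects$intercept <- intercept
  stub_predictor(function(r) true_outcome_probability(r, effects))
}

# Central finite differences of a scalar function of the flat parameter
# vector (the independent gradient oracle).
fd_gradient <- function(lossfn, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (lossfn(tp) - lossfn(tm)) / (2 * h)
  }, numeric(1))
}

# Mean additivity residual of log1p(cell/100) over the corner region where
# both factors are delayed; isolates interaction sign from the
# multiplicative compounding of relative changes.
corner_log_residual <- function(grid, amin = 5, bmin = 5) {
  lc <- log1p(grid$cells / 100)
  i0 <- which(grid$deltas_a == 0)
  j0 <- which(grid$deltas_b == 0)
  r <- outer(seq_along(grid$deltas_a), seq_along(grid$deltas_b),
             Vectorize(function(i, j) lc[i, j] - lc[i, j0] - lc[i0, j]))
  mean(r[grid$deltas_a >= amin, grid$deltas_b >= bmin])
}
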