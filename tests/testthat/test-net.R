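test_that("weighted binary cross-entropy matches hand evaluation", {
  # symmetric case: p = 1/2 everywhere gives log 2 regardless of labels
  expect_equal(weighted_bce(rep(0.5, 8), rbinom(8, 1, 0.5)), log(2))
  # scalar hand evaluation with weights (3, 1)
  expect_equal(weighted_bce(c(0.9, 0.2), c(1, 0), class_weights(3, 1)),
               (3 * -log(0.9) + -log(0.8)) / 2, tolerance = 1e-12)
  expect_equal((3 * -log(0.9) + -log(0.8)) / 2, 0.2696, tolerance = 1e-4)
  expect_error(weighted_bce(c(0.5, 0.5), 1), "length")
})

test_that("weighted loss reduces to unweighted at (1,1) and scales linearly", {
  set.seed(1)
  p <- runif(50, 0.01, 0.99); y <- rbinom(50, 1, 0.3)
  plain <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(weighted_bce(p, y, class_weights(1, 1)), plain)
  expect_equal(weighted_bce(p, y, class_weights(3, 3)),
               3 * weighted_bce(p, y, class_weights(1, 1)))
})

test_that("analytic gradients match central finite differences (incl. batch norm)", {
  nc <- net_config(input_width = 3, hidden_widths = c(3L, 3L, 3L),
                   dropout_rate = 0, seed = 42)
  set.seed(42)
  layers <- ohcasweep:::init_params(nc)
  X <- matrix(rnorm(24), 8)
  y <- rbinom(8, 1, 0.5)
  theta <- ohcasweep:::flatten_params(layers)

  lossfn <- function(th) {
    ohcasweep:::cpp_loss_grads(ohcasweep:::unflatten_params(th, layers),
                               X, y, 2.5, 1, TRUE, 0, NULL)$loss
  }
  ga <- ohcasweep:::flatten_grads(
    ohcasweep:::cpp_loss_grads(layers, X, y, 2.5, 1, TRUE, 0, NULL)$grads)
  gfd <- fd_gradient(lossfn, theta)
  rel <- abs(ga - gfd) / pmax(abs(ga), abs(gfd), 1e-8)
  expect_lt(max(rel), 1e-4)

  # with a fixed dropout mask the masked path is differentiated correctly
  set.seed(9)
  masks <- lapply(c(3, 3, 3), function(d) matrix(rbinom(8 * d, 1, 0.8) / 0.8, 8))
  lossfn2 <- function(th) {
    ohcasweep:::cpp_loss_grads(ohcasweep:::unflatten_params(th, layers),
                               X, y, 2.5, 1, TRUE, 0.2, masks)$loss
  }
  ga2 <- ohcasweep:::flatten_grads(
    ohcasweep:::cpp_loss_grads(layers, X, y, 2.5, 1, TRUE, 0.2, masks)$grads)
  expect_lt(max(abs(ga2 - fd_gradient(lossfn2, theta)) /
                  pmax(abs(ga2), 1e-8)), 1e-4)

  # and without batch norm (plain affine blocks carry a bias)
  nc3 <- net_config(input_width = 3, hidden_widths = c(3L, 3L, 3L),
                    dropout_rate = 0, batch_norm = FALSE, seed = 43)
  set.seed(43)
  l3 <- ohcasweep:::init_params(nc3)
  th3 <- ohcasweep:::flatten_params(l3)
  lossfn3 <- function(th) {
    ohcasweep:::cpp_loss_grads(ohcasweep:::unflatten_params(th, l3),
                               X, y, 1, 1, TRUE, 0, NULL)$loss
  }
  ga3 <- ohcasweep:::flatten_grads(
    ohcasweep:::cpp_loss_grads(l3, X, y, 1, 1, TRUE, 0, NULL)$grads)
  expect_lt(max(abs(ga3 - fd_gradient(lossfn3, th3)) /
                  pmax(abs(ga3), 1e-8)), 1e-4)
})

test_that("compiled kernel and R reference implementation agree exactly", {
  nc <- net_config(input_width = 5, hidden_widths = c(4L, 3L, 3L),
                   dropout_rate = 0, seed = 7)
  set.seed(7)
  layers <- ohcasweep:::init_params(nc)
  X <- matrix(rnorm(60), 12); y <- rbinom(12, 1, 0.4)
  rg <- ohcasweep:::net_loss_grads(layers, X, y, class_weights(3), nc)
  cg <- ohcasweep:::cpp_loss_grads(layers, X, y, 3, 1, TRUE, 0, NULL)
  expect_equal(rg$loss, cg$loss, tolerance = 1e-14)
  expect_equal(ohcasweep:::flatten_grads(rg$grads),
               ohcasweep:::flatten_grads(cg$grads), tolerance = 1e-12)
  # inference paths agree too
  model <- list(layers = layers, config = nc)
  class(model) <- "prog_net"
  expect_equal(predict(model, X),
               ohcasweep:::net_forward(layers, X, nc, training = FALSE)$p,
               tolerance = 1e-12)
})

test_that("training separates a linearly separable problem", {
  set.seed(11)
  n <- 200
  x <- cbind(rnorm(n), rnorm(n))
  y <- as.integer(x[, 1] + x[, 2] > 0)
  nc <- net_config(input_width = 2, hidden_widths = c(8L, 4L, 3L),
                   dropout_rate = 0, batch_size = 20L, epochs = 50L,
                   learning_rate = 0.005, seed = 2)
  model <- train_model(x, y, nc)
  acc <- mean((predict(model, x) >= 0.5) == y)
  expect_gte(acc, 0.95)
  # independent oracle: plain logistic regression reaches the same
  glm_acc <- mean((suppressWarnings(
    stats::predict(stats::glm(y ~ x, family = "binomial"),
                   type = "response")) >= 0.5) == y)
  expect_gte(glm_acc, 0.95)
  # loss trends downward on separable data
  expect_lt(mean(utils::tail(model$training_log, 5)),
            mean(utils::head(model$training_log, 5)))
})

test_that("training under permuted labels yields chance-level AUROC", {
  set.seed(12)
  n <- 400
  x <- matrix(rnorm(n * 4), n)
  y <- sample(rep(c(TRUE, FALSE), each = n / 2))   # labels independent of x
  nc <- tiny_net(4, seed = 3, epochs = 20L)
  model <- train_model(x[1:300, ], y[1:300], nc)
  m <- evaluate_model(predict(model, x[301:400, ]), labels = y[301:400])
  expect_lt(abs(m$auroc - 0.5), 0.15)
})

test_that("training is deterministic and prediction is batch-invariant", {
  set.seed(13)
  x <- matrix(rnorm(300 * 5), 300); y <- rbinom(300, 1, 0.2)
  nc <- tiny_net(5, seed = 4)
  m1 <- train_model(x, y, nc)
  m2 <- train_model(x, y, nc)
  expect_identical(m1$layers, m2$layers)
  p_all <- predict(m1, x[1:7, ])
  p_one <- vapply(1:7, function(i) predict(m1, x[i, , drop = FALSE]),
                  numeric(1))
  # inference-mode contract: batching must not change predictions (up to
  # BLAS summation order)
  expect_equal(p_all, p_one, tolerance = 1e-12)
  expect_identical(predict(m1, x[c(3, 3), ])[1],
                   predict(m1, x[c(3, 3), ])[2])  # duplicate rows
  expect_true(all(p_all > 0 & p_all < 1))
})

test_that("undefined design-matrix values are rejected before training", {
  x <- matrix(rnorm(40), 10); x[3, 2] <- NA
  expect_error(train_model(x, rbinom(10, 1, 0.5), tiny_net(4)),
               "undefined")
  expect_error(train_model(matrix(rnorm(40), 10), rbinom(10, 1, 0.5),
                           tiny_net(5)), "input_width")
})

test_that("predictions recover the generative ordering on a synthetic cohort", {
  coh <- make_cohort(5000, seed = 14)
  plan <- stratified_split(coh$outcome_cpc12, seed = 15)
  enc <- fit_encode(coh[plan$group != plan$test_group, ], build_schema())
  nc <- net_config(input_width = ncol(enc$matrix), epochs = 15L, seed = 16)
  model <- train_model(enc$matrix,
                       coh$outcome_cpc12[plan$group != plan$test_group],
                       nc, class_weights(10))
  test_rec <- coh[plan$group == plan$test_group, ]
  p <- predict(model, encode_records(test_rec, enc$encoder))
  em <- effect_model(); em$intercept <- attr(coh, "calibrated_intercept")
  truth <- true_outcome_probability(test_rec, em)
  expect_gt(cor(p, truth, method = "spearman"), 0.5)
})
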