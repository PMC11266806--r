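test_that("forward pass produces valid, deterministic probabilities", {
  m <- build_model(seed = 3)
  set.seed(1)
  x <- array(rnorm(5 * 100 * 6), c(5, 100, 6))
  p <- predict_cytonet(m, x)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # identical builds under the same seed give identical outputs
  expect_identical(predict_cytonet(build_model(seed = 3), x), p)
  expect_false(identical(predict_cytonet(build_model(seed = 4), x), p))
  # single fragment / fragment_tensor input forms
  expect_equal(dim(predict_cytonet(m, x[1, , ])), c(1, 2))
})

test_that("channel attention adds exactly its parameter budget", {
  m_att <- build_model(model_spec(attention = TRUE), seed = 1)
  m_no <- build_model(model_spec(attention = FALSE), seed = 1)
  # squeeze-excitation arithmetic: F4*(F4/r) + F4/r + (F4/r)*F4 + F4
  f4 <- 128; r <- 4
  expect_equal(n_parameters(m_att) - n_parameters(m_no),
               f4 * (f4 / r) + f4 / r + (f4 / r) * f4 + f4)
  x <- array(rnorm(2 * 100 * 6), c(2, 100, 6))
  expect_equal(rowSums(predict_cytonet(m_no, x)), rep(1, 2), tolerance = 1e-6)
})

test_that("training separates linearly separable fragments", {
  ds <- separable_fragments(150, seed = 5)
  fit <- train_cytonet(build_model(seed = 1), ds$x, ds$y,
                       training_config(epochs = 20, seed = 1, patience = 3))
  expect_gt(tail(fit$history$test_accuracy, 1), 0.99)
  expect_lte(nrow(fit$history), 20)
  # loss curve decreases overall
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  # training is reproducible: same seed + data -> same confusion matrix
  fit2 <- train_cytonet(build_model(seed = 1), ds$x, ds$y,
                        training_config(epochs = 20, seed = 1, patience = 3))
  cm1 <- evaluate_cytonet(fit$model, ds$x[fit$split$test, , ],
                          ds$y[fit$split$test])
  cm2 <- evaluate_cytonet(fit2$model, ds$x[fit2$split$test, , ],
                          ds$y[fit2$split$test])
  expect_identical(cm1$counts, cm2$counts)
})

test_that("permuted labels train to chance level", {
  ds <- separable_fragments(500, seed = 6)
  set.seed(42)
  y_perm <- sample(ds$y)
  fit <- train_cytonet(build_model(seed = 2), ds$x, y_perm,
                       training_config(epochs = 3, seed = 2, patience = 3))
  acc <- tail(fit$history$test_accuracy, 1)
  expect_lt(abs(acc - 0.5), 0.03)
})

test_that("training rejects degenerate configurations", {
  ds <- separable_fragments(20, seed = 7)
  expect_error(training_config(epochs = 0), "epochs")
  expect_error(train_cytonet(build_model(seed = 1), ds$x,
                             rep("WBC", length(ds$y))), "class")
})

test_that("evaluation yields confusion matrices with the right marginals", {
  truth <- c(rep("WBC", 40), rep("TUMOR", 10))
  # perfect predictor
  cm <- confusion_matrix(truth, truth)
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)
  expect_equal(unname(cm$tpr), c(1, 1))
  # constant predictor: one TPR 100%, the other 0%
  cm2 <- confusion_matrix(truth, rep("WBC", 50))
  expect_equal(unname(cm2$tpr), c(1, 0))
  expect_equal(cm2$accuracy, 0.8)
  expect_equal(unname(rowSums(cm2$counts)), c(40, 10))
  m <- build_model(seed = 1)
  expect_error(evaluate_cytonet(m, array(0, c(0, 100, 6)), character(0)),
               "empty")
})

test_that("the gating baseline behaves like a rectangular gate", {
  f <- data.frame(estimated_diameter = c(8, 18, 18, 8),
                  opacity_2_05 = c(0.85, 0.7, 0.9, 0.7))
  expect_equal(gating_baseline(f, 13, 0.8),
               c("WBC", "TUMOR", "WBC", "WBC"))
  expect_equal(gating_baseline(f, -Inf, Inf), rep("TUMOR", 4))
  expect_equal(gating_baseline(f, Inf, Inf), rep("WBC", 4))
  expect_length(gating_baseline(f[0, ], 13, 0.8), 0)
})

test_that("accuracy degrades monotonically as populations overlap", {
  # shrink the separation between the two classes; average test accuracy
  # over 3 seeds must not increase
  run <- function(gap, seed) {
    ds <- separable_fragments(60, seed = seed, noise_sd = 0.5, gap = gap)
    fit <- train_cytonet(build_model(seed = seed), ds$x, ds$y,
                         training_config(epochs = 4, seed = seed,
                                         patience = 2))
    tail(fit$history$test_accuracy, 1)
  }
  acc_wide <- mean(vapply(1:3, function(s) run(1.0, s), numeric(1)))
  acc_narrow <- mean(vapply(1:3, function(s) run(0.05, s), numeric(1)))
  expect_gte(acc_wide, acc_narrow)
})

test_that("model checkpoints round-trip through JSON", {
  ds <- separable_fragments(30, seed = 8)
  fit <- train_cytonet(build_model(seed = 1), ds$x, ds$y,
                       training_config(epochs = 2, seed = 1))
  path <- file.path(withr::local_tempdir(), "model.json")
  write_model(fit$model, path)
  m2 <- read_model(path)
  expect_equal(predict_cytonet(m2, ds$x[1:4, , ]),
               predict_cytonet(fit$model, ds$x[1:4, , ]), tolerance = 1e-12)
  # schema guard
  bad <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad$schema <- "something-else"
  jsonlite::write_json(bad, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(path), "schema")
})
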