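nn_archs <- c("lstm", "cnn", "mcnn", "transformer", "tcn")

rand_batch <- function(n = 4, W = 6, C = 5, D = 3, seed = 41) {
  withr::with_seed(seed, list(
    x = array(rnorm(n * W * C), c(n, W, C)),
    demo = matrix(rnorm(n * D), n, D),
    y = matrix(rbinom(n * C, 1, 0.4), n, C)
  ))
}

test_that("analytic gradients match numerical differentiation for every architecture", {
  b <- rand_batch()
  for (arch in nn_archs) {
    model <- build_model(model_spec(arch, W = 6, C = 5, D = 3), seed = 42)
    res <- labforecast:::nn_loss_and_grads(model, b$x, b$demo, b$y, train = TRUE)
    worst <- 0
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      idxs <- unique(round(seq(1, length(p), length.out = min(4, length(p)))))
      for (ii in idxs) {
        eps <- 1e-5
        up <- model; up$params[[nm]][ii] <- p[ii] + eps
        dn <- model; dn$params[[nm]][ii] <- p[ii] - eps
        num <- (labforecast:::nn_loss_and_grads(up, b$x, b$demo, b$y)$loss -
                  labforecast:::nn_loss_and_grads(dn, b$x, b$demo, b$y)$loss) / (2 * eps)
        ana <- res$grads[[nm]][ii]
        rel <- abs(num - ana) / max(1e-6, abs(num) + abs(ana))
        worst <- max(worst, rel)
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("untrained sigmoid heads emit probabilities strictly inside (0, 1)", {
  b <- rand_batch(n = 8)
  for (arch in nn_archs) {
    model <- build_model(model_spec(arch, W = 6, C = 5, D = 3), seed = 43)
    p <- predict_probabilities(model, list(x = b$x, demo = b$demo))
    expect_equal(dim(p), c(8, 5))
    expect_true(all(p > 0 & p < 1))
    p2 <- predict_probabilities(model, list(x = b$x, demo = b$demo))
    expect_identical(p, p2)
  }
})

test_that("specs validate kernel sizes, architecture names and head shapes", {
  expect_error(model_spec("resnet", W = 6, C = 5), "unknown architecture")
  expect_error(model_spec("cnn", W = 6, C = 5, kernel = 7), "kernel")
  expect_error(model_spec("mcnn", W = 3, C = 5, kernels = c(2, 4)), "kernel")
  expect_error(model_spec("cnn", W = 6, C = 5, bogus = 1), "bogus")

  # dual-stream topology: two kernel widths, concatenated before the head
  spec <- model_spec("mcnn", W = 6, C = 5, D = 3)
  m <- build_model(spec, seed = 44)
  expect_equal(nrow(m$params$s1_K), 2 * 5)
  expect_equal(nrow(m$params$s2_K), 4 * 5)
  f_total <- ((6 - 2 + 1) + (6 - 4 + 1)) * spec$filters
  expect_equal(nrow(m$params$head_W1), f_total + 3)
})

test_that("causal TCN blocks preserve sequence length at every layer", {
  b <- rand_batch(n = 3)
  model <- build_model(model_spec("tcn", W = 6, C = 5, D = 3), seed = 45)
  fw <- labforecast:::nn_forward(model, b$x, b$demo, train = FALSE)
  for (ly in fw$cache$layers) {
    expect_equal(dim(ly$z)[2], 6)
  }
  # causality: perturbing the last step leaves earlier outputs untouched
  x2 <- b$x
  x2[, 6, ] <- x2[, 6, ] + 5
  fw2 <- labforecast:::nn_forward(model, x2, b$demo, train = FALSE)
  expect_equal(fw$cache$layers[[3]]$z[, 1:5, ], fw2$cache$layers[[3]]$z[, 1:5, ])
})

test_that("the learned time encoding has its stated structure", {
  steps <- 0:5
  expect_error(time_encode(steps, list(w = 1, b = 0)), "components")
  # zero frequencies: periodic components constant across steps
  e <- time_encode(steps, list(w = c(0.3, 0, 0), b = c(0.1, 0.7, -0.2)))
  expect_equal(e[, 2], rep(sin(0.7), 6))
  expect_equal(e[, 3], rep(sin(-0.2), 6))
  # unit-slope, zero-intercept linear component reproduces the step index
  e2 <- time_encode(steps, list(w = c(1, 0.5), b = c(0, 0)))
  expect_equal(e2[, 1], as.numeric(steps))
  # nonzero slope separates distinct steps
  expect_false(any(duplicated(e2[, 1])))
})

test_that("classification thresholds strictly and monotonically", {
  expect_equal(classify(matrix(0.5), th = 0.5)[1, 1], 0L)
  expect_equal(classify(matrix(1, 2, 3), th = 0.5), matrix(1L, 2, 3))
  expect_error(classify(matrix(1.2)), "0, 1")
  expect_error(classify(matrix(0.4), th = 1), "threshold")
  withr::with_seed(46, {
    p <- matrix(runif(200), 20, 10)
    positives <- vapply(seq(0.05, 0.95, by = 0.05),
                        function(th) sum(classify(p, th)), numeric(1))
    expect_true(all(diff(positives) <= 0))
  })
})

test_that("the early-stopping rule matches its hand-simulated cases", {
  # strict improvement by >= delta each epoch: never stops
  expect_true(is.na(labforecast:::early_stop_epoch(seq(2, 0.1, by = -0.05), 0.01, 10)))
  # constant validation loss: patience exhausts at epoch 10
  expect_equal(labforecast:::early_stop_epoch(rep(0.7, 30), 0.01, 10), 10L)
  # improvement then plateau from epoch 3: stop 10 epochs into the plateau
  expect_equal(labforecast:::early_stop_epoch(c(1, 0.5, rep(0.495, 15)), 0.01, 10), 12L)
  # sub-delta drift never resets the counter
  expect_equal(labforecast:::early_stop_epoch(seq(1, by = -0.001, length.out = 40), 0.01, 10), 10L)
})

test_that("training is seed-reproducible and its history well-formed", {
  cohort <- persistence_benchmark_cohort(12, seed = 47)
  ds <- build_dataset(preprocess_cohort(cohort), W = 4, seed = 47)
  tc <- train_config(max_epochs = 4, seed = 47)
  spec <- model_spec("cnn", W = 4, C = 25, filters = 8, head_hidden = 16)
  m1 <- train_model(build_model(spec, seed = 48), ds, tc)
  m2 <- train_model(build_model(spec, seed = 48), ds, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 4)
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_accuracy", "val_f1") %in%
                    names(m1$history)))
  expect_identical(predict_probabilities(m1, ds$test), predict_probabilities(m2, ds$test))

  m3 <- train_model(build_model(spec, seed = 49), ds, tc)
  expect_false(identical(m1$params, m3$params))

  expect_s3_class(tidy(m1), "tbl_df")
  expect_equal(glance(m1)$epochs, 4L)
})

test_that("a non-finite loss aborts with an epoch/batch diagnostic", {
  b <- rand_batch(n = 8, W = 4, C = 3)
  x <- b$x; x[8, 1, 1] <- Inf  # row 8 lands in the training partition
  ds <- make_manual_dataset(x, b$demo, matrix(rbinom(24, 1, 0.5), 8, 3))
  spec <- model_spec("cnn", W = 4, C = 3, filters = 4, head_hidden = 8)
  expect_error(
    train_model(build_model(spec, seed = 50), ds,
                train_config(max_epochs = 2, batch_size = 8, seed = 50)),
    "epoch"
  )
})

test_that("boosting solves a separable single-feature task exactly", {
  withr::with_seed(51, {
    n <- 120
    x <- array(rnorm(n * 2 * 1), c(n, 2, 1), dimnames = list(NULL, NULL, "ch1"))
    demo <- matrix(0, n, 3)
    y <- matrix(as.integer(x[, 2, 1] > 0), n, 1, dimnames = list(NULL, "ch1"))
  })
  ds <- make_manual_dataset(x, demo, y)
  fit <- fit_boosting(ds, model_spec("gbm", W = 2, C = 1, nrounds = 50),
                      train_config(seed = 51))
  prob <- predict_probabilities(fit, ds$train)
  acc <- mean(classify(prob, 0.5) == ds$train$y)
  expect_equal(acc, 1.0)
  expect_equal(nrow(fit$history), 1)
})

test_that("a constant training label degenerates to its prior probability", {
  withr::with_seed(52, {
    n <- 40
    x <- array(rnorm(n * 2 * 2), c(n, 2, 2), dimnames = list(NULL, NULL, c("ch1", "ch2")))
    y <- cbind(ch1 = rep(0L, n), ch2 = rbinom(n, 1, 0.5))
  })
  ds <- make_manual_dataset(x, matrix(0, n, 3), y)
  expect_warning(fit <- fit_boosting(ds, model_spec("gbm", W = 2, C = 2, nrounds = 10),
                                     train_config(seed = 52)),
                 "constant")
  prob <- predict_probabilities(fit, ds$train)
  expect_true(all(prob[, 1] == 0))
  expect_equal(length(fit$boosters), 2)
  expect_true(fit$constant[1])
  expect_false(fit$constant[2])
})

test_that("predicting an empty sample set returns an empty matrix", {
  model <- build_model(model_spec("cnn", W = 4, C = 3, filters = 4), seed = 53)
  empty <- list(x = array(0, c(0, 4, 3)), demo = matrix(0, 0, 3))
  p <- predict_probabilities(model, empty)
  expect_equal(dim(p), c(0, 3))
  expect_error(
    predict_probabilities(model, list(x = array(0, c(2, 5, 3)), demo = matrix(0, 2, 3))),
    "shape"
  )
})

test_that("models beat the majority baseline on the persistence benchmark", {
  cohort <- persistence_benchmark_cohort(30, seed = 54)
  ds <- build_dataset(preprocess_cohort(cohort), W = 6, seed = 54)
  majority <- max(mean(ds$test$y), 1 - mean(ds$test$y))
  tc <- train_config(max_epochs = 12, seed = 54)
  for (arch in c("mcnn", "lstm")) {
    fitted <- train_model(build_model(model_spec(arch, W = 6, C = 25), seed = 54), ds, tc)
    acc <- micro_metrics(confusion_counts(
      classify(predict_probabilities(fitted, ds$test), 0.5), ds$test$y
    ))$accuracy
    expect_gt(acc, majority)
  }
})
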