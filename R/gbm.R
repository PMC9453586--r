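# Gradient-boosting baseline: one binary boosted-tree classifier per label
# (one-vs-rest) on the flattened window concatenated with demographics.

flatten_inputs <- function(x, demo) {
  n <- dim(x)[1]
  xf <- x
  dim(xf) <- c(n, dim(x)[2] * dim(x)[3])
  cbind(xf, demo)
}

#' Fit the gradient-boosting baseline
#'
#' Trains one binary boosted-tree model per lab channel on the flattened
#' `W x C` window plus demographics (input width `W*C + D`). A label that is
#' constant in the training data gets no booster: its predicted probability
#' degenerates to the training prior (flagged with a warning, not fatal).
#'
#' @param dataset A `lab_dataset`.
#' @param spec A [model_spec()] with `architecture = "gbm"` (built
#'   automatically when omitted).
#' @param config A [train_config()]; only `th` and `seed` are used (boosting
#'   has its own round count in the spec).
#' @return A trained `lab_model` whose `$boosters` holds the per-label
#'   models; `$history` records final train/validation metrics.
#' @export
fit_boosting <- function(dataset, spec = NULL, config = train_config()) {
  stopifnot(inherits(dataset, "lab_dataset"))
  spec <- spec %||% model_spec("gbm", W = dataset$W, C = length(dataset$channels))
  stopifnot(spec$architecture == "gbm")
  train <- dataset$train
  if (train$n == 0) stop_named("training partition is empty")
  X <- flatten_inputs(train$x, train$demo)
  C <- ncol(train$y)
  boosters <- vector("list", C)
  priors <- rep(NA_real_, C)
  constant <- logical(C)
  for (j in seq_len(C)) {
    yj <- train$y[, j]
    if (length(unique(yj)) < 2) {
      constant[j] <- TRUE
      priors[j] <- mean(yj)
      next
    }
    dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(yj), nthread = 1)
    boosters[[j]] <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = spec$max_depth,
                    eta = spec$eta, nthread = 1, seed = config$seed),
      data = dtrain, nrounds = spec$nrounds, verbose = 0
    )
  }
  if (any(constant)) {
    warn(sprintf("label(s) constant in training data, degenerating to the prior: %s",
                 paste(dataset$channels[constant], collapse = ", ")))
  }
  model <- structure(
    list(spec = spec, boosters = boosters, priors = priors, constant = constant,
         state = list(), params = list(), seed = config$seed,
         history = tibble::tibble(), threshold = config$th),
    class = "lab_model"
  )
  train_prob <- gbm_predict(model, train$x, train$demo)
  hist_row <- tibble::tibble(
    epoch = 1L,
    train_loss = bce_loss(train_prob, train$y),
    val_loss = NA_real_, val_accuracy = NA_real_, val_f1 = NA_real_
  )
  if (dataset$validation$n > 0) {
    vp <- gbm_predict(model, dataset$validation$x, dataset$validation$demo)
    vm <- score_predictions(vp, dataset$validation$y, config$th)
    hist_row$val_loss <- bce_loss(vp, dataset$validation$y)
    hist_row$val_accuracy <- vm$accuracy
    hist_row$val_f1 <- vm$f1
  }
  model$history <- hist_row
  model
}

gbm_predict <- function(model, x, demo) {
  X <- flatten_inputs(x, demo)
  n <- nrow(X)
  C <- model$spec$C
  out <- matrix(0, n, C)
  dX <- NULL
  for (j in seq_len(C)) {
    out[, j] <- if (model$constant[j]) {
      rep(model$priors[j], n)
    } else {
      if (is.null(dX)) dX <- xgboost::xgb.DMatrix(X, nthread = 1)
      predict(model$boosters[[j]], dX)
    }
  }
  out
}
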