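#' Describe a predictor architecture
#'
#' Builds the hyperparameter record for one of the six predictor families:
#' `lstm`, `cnn`, `mcnn` (dual-stream CNN), `transformer` (self-attention
#' with learned time encoding), `tcn` (causal dilated convolutions) or `gbm`
#' (gradient boosting on the flattened window). Defaults are deliberately
#' small, desk-scale settings; every field can be overridden.
#'
#' @param architecture One of `"lstm"`, `"cnn"`, `"mcnn"`, `"transformer"`,
#'   `"tcn"`, `"gbm"`.
#' @param W Window length in grid steps.
#' @param C Number of lab channels (= number of output labels).
#' @param D Number of demographic features (default 3: age, sex, weight).
#' @param ... Architecture-specific overrides: `units` (lstm), `filters` and
#'   `kernel` (cnn/tcn), `filters` and `kernels` (mcnn), `d_model`, `heads`,
#'   `t2v_k` (transformer), `dilations` (tcn), `nrounds`, `max_depth`, `eta`
#'   (gbm), `head_hidden` (all neural families).
#' @return A list of class `model_spec`.
#' @export
#' @examples
#' model_spec("mcnn", W = 6, C = 25)
model_spec <- function(architecture, W, C, D = 3, ...) {
  known <- c("lstm", "cnn", "mcnn", "transformer", "tcn", "gbm")
  if (!architecture %in% known) {
    stop_named("unknown architecture '%s' (expected one of %s)",
               architecture, paste(known, collapse = ", "))
  }
  defaults <- switch(architecture,
    lstm = list(units = 48, head_hidden = 64),
    cnn = list(filters = 48, kernel = 3, head_hidden = 64),
    mcnn = list(filters = 32, kernels = c(2, 4), head_hidden = 64),
    transformer = list(d_model = 32, heads = 2, t2v_k = 8, head_hidden = 64),
    tcn = list(filters = 32, kernel = 2, dilations = c(1, 2, 4), head_hidden = 64),
    gbm = list(nrounds = 200, max_depth = 6, eta = 0.1)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    stop_named("unknown hyperparameter(s) for %s: %s", architecture, paste(bad, collapse = ", "))
  }
  spec <- utils::modifyList(defaults, over)
  spec$architecture <- architecture
  spec$W <- as.integer(W); spec$C <- as.integer(C); spec$D <- as.integer(D)
  ks <- c(spec$kernel, spec$kernels)
  if (!is.null(ks) && any(ks > W)) stop_named("kernel size exceeds window length W = %d", W)
  if (architecture == "transformer" && spec$d_model %% spec$heads != 0) {
    stop_named("d_model must be divisible by the number of heads")
  }
  structure(spec, class = "model_spec")
}

#' Instantiate an untrained model from a specification
#'
#' Initializes all parameters (Glorot-uniform) for the neural families. The
#' result already satisfies the prediction contract — its sigmoid head emits
#' probabilities strictly inside (0, 1) — but carries no training history.
#' `gbm` models have no free parameters before fitting; use
#' [fit_boosting()] directly.
#'
#' @param spec A [model_spec()].
#' @param seed Initialization seed.
#' @return A list of class `lab_model` (`params`, `state`, `spec`, `seed`,
#'   empty `history`).
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$architecture == "gbm") {
    stop_named("gbm models are fitted with fit_boosting(); build_model() covers the neural families")
  }
  params <- with_seed(derive_seed(seed, paste0("init/", spec$architecture)), {
    switch(spec$architecture,
      lstm = lstm_init(spec),
      cnn = cnn_init(spec),
      mcnn = mcnn_init(spec),
      transformer = transformer_init(spec),
      tcn = tcn_init(spec)
    )
  })
  state <- switch(spec$architecture,
    lstm = lstm_state_init(spec),
    transformer = list(heads = spec$heads),
    tcn = list(dilations = spec$dilations),
    list()
  )
  structure(
    list(spec = spec, params = params, state = state, seed = as.integer(seed),
         history = tibble::tibble(), threshold = 0.5),
    class = "lab_model"
  )
}

# Forward dispatch shared by training and inference.
nn_forward <- function(model, x, demo, train = FALSE) {
  fn <- switch(model$spec$architecture,
    lstm = lstm_forward, cnn = cnn_forward, mcnn = mcnn_forward,
    transformer = transformer_forward, tcn = tcn_forward
  )
  fn(model$params, model$state, x, demo, train)
}

nn_backward <- function(model, cache, dlogits) {
  fn <- switch(model$spec$architecture,
    lstm = lstm_backward, cnn = cnn_backward, mcnn = mcnn_backward,
    transformer = transformer_backward, tcn = tcn_backward
  )
  fn(model$params, cache, dlogits)
}

# Loss and full gradient set on one batch (training mode); the workhorse for
# both the optimizer and the numerical gradient checks.
nn_loss_and_grads <- function(model, x, demo, y, train = TRUE) {
  fw <- nn_forward(model, x, demo, train = train)
  loss <- bce_loss(fw$prob, y)
  grads <- nn_backward(model, fw$cache, bce_dlogits(fw$prob, y))
  list(loss = loss, grads = grads, prob = fw$prob, state = fw$state)
}

#' Predict abnormality probabilities
#'
#' Runs a fitted (or freshly initialized) model on a stacked sample
#' partition and returns the per-label probabilities. Inference is
#' deterministic: identical inputs give identical rows.
#'
#' @param model A `lab_model` (neural or boosting).
#' @param samples A stacked partition (e.g. `dataset$test` or the result of
#'   [cohort_samples()]), or a list with elements `x` `[n, W, C]` and `demo`
#'   `[n, D]`.
#' @return An `n x C` matrix of probabilities in `[0, 1]`.
#' @export
predict_probabilities <- function(model, samples) {
  stopifnot(inherits(model, "lab_model"))
  x <- samples$x; demo <- samples$demo
  if (length(dim(x)) != 3 || dim(x)[2] != model$spec$W || dim(x)[3] != model$spec$C) {
    stop_named("sample array shape %s does not match the model's (W=%d, C=%d)",
               paste(dim(x), collapse = "x"), model$spec$W, model$spec$C)
  }
  if (dim(x)[1] == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = model$spec$C))
  }
  if (model$spec$architecture == "gbm") {
    return(gbm_predict(model, x, demo))
  }
  nn_forward(model, x, demo, train = FALSE)$prob
}

#' Threshold probabilities into binary predictions
#'
#' A label is called abnormal iff its probability strictly exceeds `th`;
#' a probability exactly at the threshold is called normal.
#'
#' @param prob Probability matrix with entries in `[0, 1]`.
#' @param th Threshold in (0, 1) (default 0.5).
#' @return An integer 0/1 matrix of the same shape.
#' @export
#' @examples
#' classify(matrix(c(0.2, 0.5, 0.9), 1), th = 0.5)
classify <- function(prob, th = 0.5) {
  prob <- as.matrix(prob)
  if (th <= 0 || th >= 1) stop_named("threshold must be in (0, 1)")
  if (any(prob < 0 | prob > 1)) stop_named("probabilities must lie in [0, 1]")
  out <- (prob > th) * 1L
  storage.mode(out) <- "integer"
  out
}

#' @export
print.lab_model <- function(x, ...) {
  trained <- nrow(x$history) > 0
  cat(sprintf("<lab_model> %s (W=%d, C=%d, D=%d) — %s\n",
              x$spec$architecture, x$spec$W, x$spec$C, x$spec$D,
              if (trained) sprintf("trained, %d epochs", max(x$history$epoch)) else "untrained"))
  invisible(x)
}
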