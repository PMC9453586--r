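#' Training configuration
#'
#' Settings shared by every architecture: binary cross-entropy is always the
#' loss; training stops at `max_epochs` or when the validation loss has not
#' improved on its running best by at least `min_delta` for `patience`
#' consecutive epochs.
#'
#' @param max_epochs Upper bound on training epochs (default 60).
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate Adam step size (default 0.005).
#' @param min_delta Minimum validation-loss improvement that resets the
#'   early-stopping counter (default 0.01).
#' @param patience Consecutive non-improving epochs tolerated (default 10).
#' @param th Decision threshold used for the accuracy/F1 columns of the
#'   training history (default 0.5).
#' @param seed Seed for batch shuffling (default 1).
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_epochs = 60, batch_size = 64, learning_rate = 0.005,
                         min_delta = 0.01, patience = 10, th = 0.5, seed = 1) {
  stopifnot(max_epochs >= 1, batch_size >= 1, learning_rate > 0,
            min_delta >= 0, patience >= 1, th > 0, th < 1)
  structure(
    list(max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, min_delta = min_delta,
         patience = as.integer(patience), th = th, seed = as.integer(seed)),
    class = "train_config"
  )
}

# Early-stopping rule as a pure function over a validation-loss trace: the
# running best is seeded with the first epoch's loss (which therefore counts
# as non-improving), and training stops at the first epoch where `patience`
# consecutive epochs have failed to beat the best by `min_delta`. Returns the
# stopping epoch, or NA if the trace never triggers it.
early_stop_epoch <- function(val_losses, min_delta = 0.01, patience = 10) {
  if (length(val_losses) == 0) return(NA_integer_)
  best <- val_losses[1]
  wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - min_delta) {
      best <- val_losses[e]
      wait <- 0L
    } else {
      best <- min(best, val_losses[e])
      wait <- wait + 1L
    }
    if (wait >= patience) return(e)
  }
  NA_integer_
}

#' Train a neural model with mini-batch Adam and early stopping
#'
#' Minimizes mean binary cross-entropy over all `C` labels. Batches are
#' reshuffled every epoch from the configured seed, so two runs with
#' identical data, spec and seeds produce bitwise-identical parameters and
#' histories under single-threaded execution. A non-finite loss aborts with
#' a diagnostic naming the epoch and batch.
#'
#' @param model An untrained `lab_model` from [build_model()].
#' @param dataset A `lab_dataset` with non-empty train and validation
#'   partitions.
#' @param config A [train_config()].
#' @return The trained `lab_model`; `$history` holds one row per epoch
#'   (`epoch`, `train_loss`, `val_loss`, `val_accuracy`, `val_f1`).
#' @export
train_model <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "lab_model"), inherits(dataset, "lab_dataset"),
            inherits(config, "train_config"))
  if (model$spec$architecture == "gbm") {
    stop_named("use fit_boosting() for the gbm architecture")
  }
  train <- dataset$train; val <- dataset$validation
  if (train$n == 0 || val$n == 0) stop_named("train and validation partitions must be non-empty")
  opt <- adam_init(model$params)
  history <- vector("list", config$max_epochs)
  val_losses <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, sprintf("epoch/%d", epoch)),
                     sample.int(train$n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      xb <- train$x[idx, , , drop = FALSE]
      db <- train$demo[idx, , drop = FALSE]
      yb <- train$y[idx, , drop = FALSE]
      res <- nn_loss_and_grads(model, xb, db, yb, train = TRUE)
      if (!is.finite(res$loss)) {
        stop_named("non-finite training loss at epoch %d, batch %d — reduce the learning rate",
                   epoch, b)
      }
      model$state <- res$state
      upd <- adam_step(model$params, res$grads, opt, config$learning_rate)
      model$params <- upd$params
      opt <- upd$opt
      epoch_loss <- epoch_loss + res$loss * length(idx)
    }
    vp <- nn_forward(model, val$x, val$demo, train = FALSE)$prob
    vmet <- score_predictions(vp, val$y, config$th)
    val_losses <- c(val_losses, bce_loss(vp, val$y))
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_loss = epoch_loss / train$n,
      val_loss = val_losses[epoch],
      val_accuracy = vmet$accuracy,
      val_f1 = vmet$f1
    )
    if (!is.na(early_stop_epoch(val_losses, config$min_delta, config$patience))) break
  }
  model$history <- dplyr::bind_rows(history)
  model$threshold <- config$th
  model$train_config <- config
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted model
#'
#' @param x A trained `lab_model`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `val_accuracy`, `val_f1`.
#' @export
tidy.lab_model <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x A trained `lab_model`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, epochs trained, final
#'   train/validation loss and validation accuracy/F1.
#' @export
glance.lab_model <- function(x, ...) {
  if (nrow(x$history) == 0) {
    return(tibble::tibble(architecture = x$spec$architecture, epochs = 0L))
  }
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    architecture = x$spec$architecture,
    epochs = as.integer(last$epoch),
    train_loss = last$train_loss,
    val_loss = last$val_loss,
    val_accuracy = last$val_accuracy,
    val_f1 = last$val_f1
  )
}

#' Plot training curves
#'
#' Validation loss, accuracy and F1 against epoch for one or more fitted
#' models — the shape of the usual training-diagnostics figures.
#'
#' @param models A trained `lab_model` or a (optionally named) list of them.
#' @return A ggplot object.
#' @export
plot_training_history <- function(models) {
  if (inherits(models, "lab_model")) models <- list(models)
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$spec$architecture, character(1))
  }
  df <- purrr::imap_dfr(models, function(m, nm) dplyr::mutate(m$history, model = nm))
  long <- tidyr::pivot_longer(
    dplyr::select(df, "model", "epoch", "val_loss", "val_accuracy", "val_f1"),
    cols = c("val_loss", "val_accuracy", "val_f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value, colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lab_model <- function(object, ...) plot_training_history(object)
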