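#' Pooled multilabel confusion counts
#'
#' Tallies true/false positives/negatives over every `(sample, label)` cell
#' of a pair of binary matrices — the pooling that micro-averaging is built
#' on.
#'
#' @param predicted,truth Binary (0/1) matrices of identical shape.
#' @return A one-row tibble of class `confusion_counts` with columns `tp`,
#'   `fp`, `tn`, `fn`, `n_cells`.
#' @export
#' @examples
#' confusion_counts(matrix(c(1, 0, 1, 1), 2), matrix(c(1, 0, 0, 1), 2))
confusion_counts <- function(predicted, truth) {
  predicted <- as.matrix(predicted)
  truth <- as.matrix(truth)
  if (!identical(dim(predicted), dim(truth))) {
    stop_named("predicted and truth must have identical shapes")
  }
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop_named("confusion counts require binary 0/1 entries")
  }
  out <- tibble::tibble(
    tp = sum(predicted == 1 & truth == 1),
    fp = sum(predicted == 1 & truth == 0),
    tn = sum(predicted == 0 & truth == 0),
    fn = sum(predicted == 0 & truth == 1),
    n_cells = length(truth)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Micro-averaged accuracy, precision, recall and F1
#'
#' Computes the four headline metrics from pooled confusion counts:
#' `accuracy = (TP + TN) / total`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, `f1 = 2PR / (P + R)`. Any division by zero
#' yields 0 and raises the `zero_division` flag.
#'
#' @param counts A `confusion_counts` row (or anything with `tp`, `fp`,
#'   `tn`, `fn`).
#' @return A one-row tibble of class `lab_metrics`: the four metrics, the
#'   counts, and `zero_division`.
#' @export
micro_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop_named("cannot compute metrics on zero cells")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  zero_division <- anyNA(c(precision, recall, f1))
  out <- tibble::tibble(
    accuracy = (tp + tn) / total,
    precision = precision %+na% 0,
    recall = recall %+na% 0,
    f1 = f1 %+na% 0,
    tp = tp, fp = fp, tn = tn, fn = fn,
    zero_division = zero_division
  )
  class(out) <- c("lab_metrics", class(out))
  out
}

# Convenience: metrics of a probability matrix against binary truth.
score_predictions <- function(prob, truth, th = 0.5) {
  micro_metrics(confusion_counts(classify(prob, th), truth))
}

#' Two-cohort cross-generalization experiment
#'
#' The full comparison harness: for each direction (train on cohort A, train
#' on cohort B) and each architecture, preprocess the training cohort,
#' re-preprocess the other cohort with the training cohort's hold times,
#' build a shuffled train/validation/test dataset, fit the model with early
#' stopping, and report micro-averaged metrics both on the training cohort's
#' held-out test split ("within") and on the entire other cohort's sample
#' set ("cross"). All arms share the same window length and decision
#' threshold. An architecture that fails to train loses only its own rows.
#'
#' @param cohort_a,cohort_b Two `lab_cohort`s (e.g. hospital A / hospital B).
#' @param architectures Character vector of architecture names; default all
#'   six families.
#' @param W Window length (default 6).
#' @param th Decision threshold on predicted probabilities (default 0.5).
#' @param seed Master seed for shuffling, initialization and training.
#' @param train_config A [train_config()] shared across architectures.
#' @param fractions Split fractions, see [build_dataset()].
#' @param preprocess_args List of arguments forwarded to
#'   [preprocess_cohort()].
#' @param model_overrides Named list (by architecture) of hyperparameter
#'   overrides passed to [model_spec()].
#' @return A tibble of class `lab_comparison`: one row per
#'   `(train_cohort, architecture, test_set)` with the four metrics and
#'   confusion counts.
#' @export
run_comparison <- function(cohort_a, cohort_b,
                           architectures = c("lstm", "cnn", "mcnn", "transformer", "tcn", "gbm"),
                           W = 6, th = 0.5, seed = 1,
                           train_config = labforecast::train_config(),
                           fractions = c(train = 0.68, validation = 0.12, test = 0.20),
                           preprocess_args = list(),
                           model_overrides = list()) {
  stopifnot(inherits(cohort_a, "lab_cohort"), inherits(cohort_b, "lab_cohort"))
  cohorts <- list(A = cohort_a, B = cohort_b)
  rows <- list()
  for (dir_name in names(cohorts)) {
    train_raw <- cohorts[[dir_name]]
    other_raw <- cohorts[[setdiff(names(cohorts), dir_name)]]
    ht <- estimate_hold_times(
      train_raw,
      coverage_threshold = preprocess_args$coverage_threshold %||% 0.9,
      step_hours = preprocess_args$step_hours %||% 4
    )
    pp <- function(coh) do.call(preprocess_cohort, c(list(coh, hold_times = ht), preprocess_args))
    train_grid <- pp(train_raw)
    other_grid <- pp(other_raw)
    ds <- build_dataset(train_grid, W = W, fractions = fractions,
                        seed = derive_seed(seed, paste0("split/", dir_name)))
    cross <- cohort_samples(other_grid, ds)
    for (arch in architectures) {
      row_seed <- derive_seed(seed, paste0("fit/", dir_name, "/", arch))
      res <- tryCatch({
        fitted <- fit_architecture(arch, ds, train_config, row_seed, model_overrides[[arch]])
        within <- score_predictions(predict_probabilities(fitted, ds$test), ds$test$y, th)
        crossm <- score_predictions(predict_probabilities(fitted, cross), cross$y, th)
        dplyr::bind_rows(
          dplyr::mutate(within, test_set = "within", .before = 1),
          dplyr::mutate(crossm, test_set = "cross", .before = 1)
        )
      }, error = function(e) {
        warn(sprintf("architecture %s failed in direction %s: %s", arch, dir_name, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        rows[[length(rows) + 1]] <- dplyr::mutate(
          res, train_cohort = dir_name, architecture = arch, .before = 1
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lab_comparison", class(out))
  out
}

# Dispatch one architecture through the shared train/predict contract.
fit_architecture <- function(arch, dataset, config, seed, overrides = NULL) {
  config$seed <- seed
  if (arch == "gbm") {
    spec <- do.call(model_spec, c(list(architecture = "gbm",
                                       W = dataset$W, C = length(dataset$channels)),
                                  overrides %||% list()))
    fit_boosting(dataset, spec, config)
  } else {
    spec <- do.call(model_spec, c(list(architecture = arch,
                                       W = dataset$W, C = length(dataset$channels)),
                                  overrides %||% list()))
    train_model(build_model(spec, seed = seed), dataset, config)
  }
}

#' @export
autoplot.lab_comparison <- function(object, metric = "accuracy", ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$architecture, y = .data[[metric]], fill = .data$test_set)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$train_cohort, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = metric, fill = "test set") +
    ggplot2::theme_minimal()
}
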