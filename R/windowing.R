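#' Binarize lab values against their reference ranges
#'
#' Maps numeric lab values to the abnormality labels the models predict:
#' 0 iff `normal_low <= value <= normal_high` (closed interval — a value
#' exactly on a boundary counts as normal), else 1.
#'
#' @param values A named numeric vector, or a matrix with channel column
#'   names, of lab values in raw channel units.
#' @param ranges A reference-range tibble (`channel`, `normal_low`,
#'   `normal_high`), e.g. from [reference_ranges()].
#' @return An integer vector (or matrix) of 0/1 labels in the same shape.
#' @export
#' @examples
#' binarize_labels(c(sodium = 140, potassium = 5.9), reference_ranges())
binarize_labels <- function(values, ranges) {
  nm <- if (is.matrix(values)) colnames(values) else names(values)
  if (is.null(nm)) stop_named("values must carry channel names")
  idx <- match(nm, ranges$channel)
  if (anyNA(idx)) {
    stop_named("no reference range for channel(s): %s", paste(nm[is.na(idx)], collapse = ", "))
  }
  lo <- ranges$normal_low[idx]
  hi <- ranges$normal_high[idx]
  if (is.matrix(values)) {
    out <- 1L - (sweep(values, 2, lo, ">=") & sweep(values, 2, hi, "<="))
    storage.mode(out) <- "integer"
    dimnames(out) <- dimnames(values)
    out
  } else {
    out <- as.integer(!(values >= lo & values <= hi))
    names(out) <- nm
    out
  }
}

#' Extract moving-window samples from one gridded stay
#'
#' Slides a window of `W` consecutive grid steps over a complete stay; the
#' step immediately after the window supplies the binary target. A stay of
#' `L >= W + 1` steps yields exactly `L - W` samples with target indices
#' `m = W .. L-1` (0-based) and inputs `X_{m-W} .. X_{m-1}`. A short stay
#' (`2 <= L <= W`) yields one sample whose inputs `X_0 .. X_{L-2}` are
#' left-padded with zero rows to length `W`, targeting its last step. Stays
#' with fewer than 2 steps yield nothing.
#'
#' @param stay A complete `gridded_stay` (no missing cells).
#' @param W Window length in grid steps (>= 2; default 6).
#' @param ranges Reference-range table used to binarize the target row.
#' @return A list of samples; each is a list with `x` (`W x C` matrix, raw
#'   units, padding rows zero), `demo` (one-row demographics tibble), `y`
#'   (named 0/1 integer vector of length `C`), `stay_id`, `target_step`
#'   (0-based), `n_pad` (number of zero padding rows).
#' @export
extract_windows <- function(stay, W = 6, ranges = reference_ranges()) {
  stopifnot(inherits(stay, "gridded_stay"))
  if (W < 2) stop_named("window length W must be >= 2")
  if (any(stay$mask == "missing")) {
    stop_named("stay %s still has missing cells; run the preprocessing chain first", stay$stay_id)
  }
  L <- nrow(stay$values)
  C <- ncol(stay$values)
  if (L < 2) return(list())
  mk <- function(x, m, n_pad) {
    list(
      x = x, demo = stay$demographics,
      y = binarize_labels(stay$values[m + 1L, ], ranges),
      stay_id = stay$stay_id, target_step = m, n_pad = n_pad
    )
  }
  if (L >= W + 1) {
    lapply(seq(W, L - 1L), function(m) {
      mk(stay$values[(m - W + 1L):m, , drop = FALSE], m, 0L)
    })
  } else {
    x <- rbind(
      matrix(0, nrow = W - (L - 1L), ncol = C, dimnames = list(NULL, colnames(stay$values))),
      stay$values[seq_len(L - 1L), , drop = FALSE]
    )
    list(mk(x, L - 1L, W - (L - 1L)))
  }
}

# Largest-remainder apportionment of n samples into the given fractions.
split_sizes <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Stack a list of samples into the dense arrays the models consume.
stack_samples <- function(samples, channel_names) {
  n <- length(samples)
  W <- nrow(samples[[1]]$x)
  C <- length(channel_names)
  x <- array(0, dim = c(n, W, C), dimnames = list(NULL, NULL, channel_names))
  y <- matrix(0L, nrow = n, ncol = C, dimnames = list(NULL, channel_names))
  demo <- matrix(0, nrow = n, ncol = 3, dimnames = list(NULL, c("age", "sex", "weight")))
  n_pad <- integer(n)
  stay_id <- character(n)
  target_step <- integer(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    x[i, , ] <- s$x[, channel_names]
    y[i, ] <- s$y[channel_names]
    demo[i, ] <- c(s$demo$age, as.numeric(s$demo$sex == "male"), s$demo$weight)
    n_pad[i] <- s$n_pad
    stay_id[i] <- s$stay_id
    target_step[i] <- s$target_step
  }
  list(x = x, demo = demo, y = y, n_pad = n_pad, stay_id = stay_id,
       target_step = target_step, n = n)
}

# z-score a stacked partition in place with training statistics; zero padding
# rows are left exactly zero so they stay inert under the architectures.
normalize_partition <- function(part, norm) {
  if (part$n == 0) return(part)
  W <- dim(part$x)[2]
  for (i in seq_len(part$n)) {
    rows <- seq_len(W) > part$n_pad[i]
    part$x[i, rows, ] <- sweep(
      sweep(part$x[i, rows, , drop = FALSE], 3, norm$x_mean),
      3, norm$x_sd, "/"
    )
  }
  part$demo <- sweep(sweep(part$demo, 2, norm$demo_mean), 2, norm$demo_sd, "/")
  part
}

#' Build a shuffled, normalized train/validation/test dataset
#'
#' Pools moving-window samples from every stay in the cohort, shuffles them
#' (so windows from one stay can land in different partitions), splits by the
#' given fractions with largest-remainder rounding, and z-scores inputs using
#' statistics computed from the training partition only (zero padding rows
#' excluded, and kept at exactly zero). Demographics are encoded
#' (sex: female 0 / male 1) and z-scored with training statistics; targets
#' remain in raw 0/1 units.
#'
#' @param gridded A complete `gridded_cohort`.
#' @param W Window length in grid steps (default 6).
#' @param ranges Reference-range table (defaults to the cohort's channels).
#' @param fractions Named or positional `(train, validation, test)`
#'   fractions; must be positive and sum to 1. Default `c(0.68, 0.12, 0.20)`.
#' @param seed Shuffle seed.
#' @return A list of class `lab_dataset` with partitions `train`,
#'   `validation`, `test` (each holding `x` `[n, W, C]`, `demo` `[n, 3]`,
#'   `y` `[n, C]`, provenance vectors), the normalization statistics, `W`,
#'   `channels`, `fractions` and `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), n_stays = 8, seed = 2)
#' ds <- cohort |> preprocess_cohort() |> build_dataset(W = 6, seed = 2)
#' dim(ds$train$x)
build_dataset <- function(gridded, W = 6, ranges = NULL,
                          fractions = c(train = 0.68, validation = 0.12, test = 0.20),
                          seed = 1) {
  stopifnot(inherits(gridded, "gridded_cohort"))
  if (length(gridded$stays) == 0) stop_named("cohort has no stays")
  if (length(fractions) != 3 || any(fractions < 0)) {
    stop_named("fractions must be three non-negative numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-8) stop_named("fractions must sum to 1")
  ranges <- ranges %||% reference_ranges(gridded$channels)
  samples <- unlist(
    lapply(gridded$stays, extract_windows, W = W, ranges = ranges),
    recursive = FALSE
  )
  if (length(samples) == 0) stop_named("no samples could be extracted (all stays shorter than 2 steps)")
  perm <- with_seed(derive_seed(seed, "shuffle"), sample.int(length(samples)))
  samples <- samples[perm]
  sizes <- split_sizes(length(samples), fractions)
  idx <- split(seq_along(samples), rep(c("train", "validation", "test"), times = sizes))
  channel_names <- gridded$channels$channel
  parts <- lapply(c(train = "train", validation = "validation", test = "test"), function(p) {
    sel <- samples[idx[[p]] %||% integer(0)]
    if (length(sel) == 0) {
      return(list(x = array(0, c(0, W, length(channel_names))),
                  demo = matrix(0, 0, 3), y = matrix(0L, 0, length(channel_names)),
                  n_pad = integer(0), stay_id = character(0),
                  target_step = integer(0), n = 0L))
    }
    stack_samples(sel, channel_names)
  })
  norm <- training_normalization(parts$train)
  parts <- lapply(parts, normalize_partition, norm = norm)
  structure(
    list(
      train = parts$train, validation = parts$validation, test = parts$test,
      norm = norm, W = as.integer(W), channels = channel_names,
      ranges = ranges, fractions = fractions, seed = as.integer(seed)
    ),
    class = "lab_dataset"
  )
}

# Per-channel and per-demographic z-score statistics from the training
# partition, padding rows excluded. Degenerate (constant) features get sd 1.
training_normalization <- function(train) {
  if (train$n == 0) stop_named("training partition is empty; cannot compute normalization")
  W <- dim(train$x)[2]
  C <- dim(train$x)[3]
  rows <- NULL
  flat <- do.call(rbind, lapply(seq_len(train$n), function(i) {
    keep <- seq_len(W) > train$n_pad[i]
    matrix(train$x[i, keep, ], ncol = C)
  }))
  x_mean <- colMeans(flat)
  x_sd <- apply(flat, 2, sd)
  x_sd[!is.finite(x_sd) | x_sd == 0] <- 1
  demo_mean <- colMeans(train$demo)
  demo_sd <- apply(train$demo, 2, sd)
  demo_sd[!is.finite(demo_sd) | demo_sd == 0] <- 1
  list(x_mean = x_mean, x_sd = x_sd, demo_mean = demo_mean, demo_sd = demo_sd)
}

#' Windows from a whole cohort under externally supplied normalization
#'
#' Extracts every moving-window sample from a (preprocessed) cohort and
#' normalizes it with the statistics of another dataset — the cross-cohort
#' evaluation path, where the second hospital's data must be scaled with the
#' training hospital's statistics.
#'
#' @param gridded A complete `gridded_cohort`.
#' @param dataset A `lab_dataset` supplying `W`, ranges and normalization.
#' @return A stacked, normalized sample partition (same shape as
#'   `dataset$test`).
#' @export
cohort_samples <- function(gridded, dataset) {
  stopifnot(inherits(gridded, "gridded_cohort"), inherits(dataset, "lab_dataset"))
  samples <- unlist(
    lapply(gridded$stays, extract_windows, W = dataset$W, ranges = dataset$ranges),
    recursive = FALSE
  )
  part <- stack_samples(samples, dataset$channels)
  normalize_partition(part, dataset$norm)
}

#' @export
print.lab_dataset <- function(x, ...) {
  cat(sprintf(
    "<lab_dataset> W=%d, %d channels; train/validation/test = %d/%d/%d samples\n",
    x$W, length(x$channels), x$train$n, x$validation$n, x$test$n
  ))
  invisible(x)
}
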