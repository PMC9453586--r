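# Shared fixtures: small channel panels and hand-built cohorts, constructed
# in code so every expected value can be derived by eye.

make_panel <- function(n_ch = 3, normal_low = 10, normal_high = 20,
                       baseline_sd = 1.25, ar = 0.5, episode_rate = 0.05,
                       episode_persistence = 0.85, sampling = 4,
                       missing_prob = 0.2, outlier_prob = 0.01) {
  tibble::tibble(
    channel = paste0("ch", seq_len(n_ch)),
    normal_low = normal_low, normal_high = normal_high,
    baseline_mean = (normal_low + normal_high) / 2,
    baseline_sd = baseline_sd, ar_coefficient = ar,
    episode_rate = episode_rate, episode_persistence = episode_persistence,
    sampling_period_hours = sampling, missing_prob = missing_prob,
    outlier_prob = outlier_prob
  )
}

# A raw cohort assembled directly from a measurement table, for preprocessing
# tests whose expected outputs are enumerated by hand.
make_manual_cohort <- function(measurements, durations, channels) {
  stay_ids <- unique(durations$stay_id)
  structure(
    list(
      measurements = measurements,
      demographics = tibble::tibble(
        stay_id = stay_ids, age = 60, sex = "female", weight = 80
      ),
      durations = durations,
      true_state = tibble::tibble(),
      outlier_truth = tibble::tibble(),
      channels = channels,
      config = NULL,
      seed = 0L
    ),
    class = "lab_cohort"
  )
}

# A complete gridded stay built from an explicit L x C value matrix.
make_gridded_stay <- function(values, stay_id = "s1", step_hours = 4) {
  structure(
    list(
      stay_id = stay_id,
      demographics = tibble::tibble(stay_id = stay_id, age = 60, sex = "male", weight = 80),
      values = values,
      mask = matrix("observed", nrow(values), ncol(values), dimnames = dimnames(values)),
      step_hours = step_hours,
      duration_h = nrow(values) * step_hours
    ),
    class = "gridded_stay"
  )
}

# A ready-made lab_dataset wrapped around explicit arrays, for model tests
# that need full control over the learning problem.
make_manual_dataset <- function(x, demo, y, val_frac = 0.25) {
  n <- dim(x)[1]
  n_val <- max(1, floor(n * val_frac))
  idx_val <- seq_len(n_val)
  idx_tr <- setdiff(seq_len(n), idx_val)
  part <- function(idx) {
    list(x = x[idx, , , drop = FALSE], demo = demo[idx, , drop = FALSE],
         y = y[idx, , drop = FALSE], n_pad = rep(0L, length(idx)),
         stay_id = paste0("s", idx), target_step = rep(0L, length(idx)),
         n = length(idx))
  }
  channels <- dimnames(x)[[3]] %||% paste0("ch", seq_len(dim(x)[3]))
  structure(
    list(
      train = part(idx_tr), validation = part(idx_val), test = part(idx_val),
      norm = list(x_mean = rep(0, dim(x)[3]), x_sd = rep(1, dim(x)[3]),
                  demo_mean = rep(0, ncol(demo)), demo_sd = rep(1, ncol(demo))),
      W = dim(x)[2], channels = channels,
      ranges = NULL, fractions = c(train = 0.75, validation = 0.25, test = 0),
      seed = 1L
    ),
    class = "lab_dataset"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
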