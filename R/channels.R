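#' Default 25-channel ICU laboratory panel
#'
#' Returns the default panel of 25 laboratory channels used throughout the
#' package: common chemistry, hematology, blood-gas and coagulation analytes
#' relevant to mechanically ventilated ICU patients, each with the adult
#' reference range (`normal_low`, `normal_high`) used to binarize values into
#' normal (0) / abnormal (1), plus the generative parameters the synthetic
#' cohort simulator needs.
#'
#' Generative columns: `baseline_mean` / `baseline_sd` describe the stationary
#' in-range behaviour of the channel; `ar_coefficient` is the lag-1
#' autocorrelation of its mean-reverting fluctuation; `episode_rate` and
#' `episode_persistence` parameterize the two-state Markov chain of abnormal
#' drift episodes, and `episode_direction` is the channel's characteristic
#' direction of derangement (+1 rises when abnormal, -1 falls);
#' `sampling_period_hours` is the typical measurement cadence;
#' `missing_prob` and `outlier_prob` are the per-measurement dropout and
#' gross-corruption probabilities.
#'
#' @return A tibble with one row per channel.
#' @export
#' @examples
#' default_lab_channels()
default_lab_channels <- function() {
  p <- tibble::tribble(
    ~channel,      ~normal_low, ~normal_high, ~sampling_period_hours,
    "wbc",                 4.0,         11.0,  4,
    "hemoglobin",         12.0,         17.0,  4,
    "hematocrit",         36.0,         50.0,  4,
    "platelets",         150.0,        400.0,  8,
    "sodium",            136.0,        145.0,  4,
    "potassium",           3.5,          5.0,  4,
    "chloride",           98.0,        106.0,  4,
    "bicarbonate",        22.0,         28.0,  4,
    "bun",                 8.0,         20.0,  8,
    "creatinine",          0.6,          1.2,  8,
    "glucose",            70.0,        110.0,  4,
    "calcium",             8.6,         10.3,  4,
    "magnesium",           1.7,          2.3,  8,
    "phosphate",           2.5,          4.5,  8,
    "lactate",             0.5,          2.2,  4,
    "ph",                 7.35,         7.45,  4,
    "paco2",              35.0,         45.0,  4,
    "pao2",               75.0,        100.0,  4,
    "albumin",             3.5,          5.5, 24,
    "bilirubin",           0.3,          1.2, 24,
    "alt",                10.0,         40.0, 24,
    "ast",                10.0,         40.0, 24,
    "inr",                 0.9,          1.2,  8,
    "ptt",                25.0,         35.0,  8,
    "fibrinogen",        200.0,        400.0, 24
  )
  # characteristic direction of derangement in ventilated ICU patients:
  # +1 rises when abnormal (e.g. lactate, creatinine), -1 falls (e.g.
  # hemoglobin, platelets, albumin, pao2)
  down <- c("hemoglobin", "hematocrit", "platelets", "sodium", "bicarbonate",
            "calcium", "albumin", "pao2", "fibrinogen", "ph")
  dplyr::mutate(
    p,
    baseline_mean = (.data$normal_low + .data$normal_high) / 2,
    # sd chosen so the in-range baseline sits ~4 sd away from either
    # boundary: out-of-episode values are almost always normal.
    baseline_sd = (.data$normal_high - .data$normal_low) / 8,
    ar_coefficient = 0.7,
    episode_rate = 0.05,
    episode_persistence = 0.9,
    episode_direction = ifelse(.data$channel %in% down, -1, 1),
    missing_prob = 0.2,
    outlier_prob = 0.005
  )
}

#' Validate a channel specification table
#'
#' Checks the invariants every channel table must satisfy before simulation or
#' preprocessing: ranges ordered, probabilities in `[0, 1]`, autocorrelation in
#' `[0, 1)`, positive cadence.
#'
#' @param channels A tibble shaped like [default_lab_channels()].
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending channel and column.
#' @export
validate_channel_specs <- function(channels) {
  required <- c(
    "channel", "normal_low", "normal_high", "baseline_mean", "baseline_sd",
    "ar_coefficient", "episode_rate", "episode_persistence",
    "sampling_period_hours", "missing_prob", "outlier_prob"
  )
  missing_cols <- setdiff(required, names(channels))
  if (length(missing_cols) > 0) {
    stop_named("channel table is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(channels) < 1) stop_named("channel table must have at least one channel")
  if (anyDuplicated(channels$channel)) stop_named("channel names must be unique")
  check <- function(cond, what) {
    bad <- channels$channel[!cond]
    if (length(bad) > 0) stop_named("invalid %s for channel(s): %s", what, paste(bad, collapse = ", "))
  }
  check(channels$normal_low < channels$normal_high, "reference range (normal_low < normal_high required)")
  check(channels$baseline_sd >= 0, "baseline_sd (must be >= 0)")
  check(channels$ar_coefficient >= 0 & channels$ar_coefficient < 1, "ar_coefficient (must be in [0,1))")
  for (col in c("episode_rate", "episode_persistence", "missing_prob", "outlier_prob")) {
    vals <- channels[[col]]
    bad <- channels$channel[vals < 0 | vals > 1]
    if (length(bad) > 0) stop_named("invalid %s (must be in [0,1]) for channel(s): %s", col, paste(bad, collapse = ", "))
  }
  check(channels$sampling_period_hours > 0, "sampling_period_hours (must be > 0)")
  if ("episode_direction" %in% names(channels)) {
    check(channels$episode_direction %in% c(-1, 1), "episode_direction (must be -1 or +1)")
  }
  invisible(channels)
}

#' Extract the reference-range table from a channel specification
#'
#' @param channels A channel table as from [default_lab_channels()].
#' @return A tibble with columns `channel`, `normal_low`, `normal_high`.
#' @export
reference_ranges <- function(channels = default_lab_channels()) {
  validate_channel_specs(channels)
  dplyr::select(channels, "channel", "normal_low", "normal_high")
}
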