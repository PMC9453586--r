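#' Configuration for the synthetic ICU cohort generator
#'
#' Bundles everything [generate_cohort()] needs: the channel panel, the stay
#' duration distribution, observation noise and timing jitter, demographic
#' marginals, and switches for the two corruption processes (missingness and
#' gross outliers). The defaults describe the study conditions the generator
#' emulates: stays of 12-72 hours on a 4-hour grid, a mostly 4-hourly lab
#' cadence with heavy per-channel missingness, and rare gross outliers.
#'
#' @param channels Channel panel tibble, see [default_lab_channels()].
#' @param duration_range Integer 2-vector: inclusive range of stay lengths in
#'   4-hour grid steps (default 3..18, i.e. 12-72 h); durations are drawn
#'   uniformly from this range.
#' @param obs_noise_sd Observation noise standard deviation, expressed as a
#'   multiple of each channel's `baseline_sd` (default 0.1).
#' @param jitter_hours Measurement times are the channel's cadence grid plus
#'   `U(0, jitter_hours)` jitter (default 1), making sampling irregular.
#' @param inject_missingness Drop measurements at each channel's
#'   `missing_prob`? Default `TRUE`.
#' @param inject_outliers Corrupt measurements at each channel's
#'   `outlier_prob`? Default `TRUE`.
#' @param outlier_multiplier Magnitude multiplier for injected outliers, in
#'   units of the channel's reference-range width (default 10).
#' @param female_rate Bernoulli probability that a simulated patient is
#'   female (default 0.4).
#' @param age_mean,age_sd Age marginal (years), truncated to \[18, 95\].
#' @param weight_mean,weight_sd Weight marginal (kg), truncated to \[35, 200\].
#' @param coupling Optional tibble (`source`, `target`, `weight`) of
#'   cross-channel episode coupling: while `source` is in an abnormal episode,
#'   `target`'s per-step episode entry probability is increased by `weight`.
#'   Default `NULL` (off).
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(inject_outliers = FALSE)
#' cohort <- generate_cohort(cfg, n_stays = 5, seed = 1)
cohort_config <- function(channels = default_lab_channels(),
                          duration_range = c(3L, 18L),
                          obs_noise_sd = 0.1,
                          jitter_hours = 1,
                          inject_missingness = TRUE,
                          inject_outliers = TRUE,
                          outlier_multiplier = 10,
                          female_rate = 0.4,
                          age_mean = 65, age_sd = 15,
                          weight_mean = 82, weight_sd = 20,
                          coupling = NULL) {
  validate_channel_specs(channels)
  stopifnot(
    length(duration_range) == 2, duration_range[1] >= 1,
    duration_range[1] <= duration_range[2],
    obs_noise_sd >= 0, jitter_hours >= 0,
    female_rate >= 0, female_rate <= 1,
    outlier_multiplier > 1
  )
  if (!is.null(coupling)) {
    stopifnot(all(c("source", "target", "weight") %in% names(coupling)))
    stopifnot(all(coupling$source %in% channels$channel), all(coupling$target %in% channels$channel))
  }
  structure(
    list(
      channels = channels,
      duration_range = as.integer(duration_range),
      obs_noise_sd = obs_noise_sd,
      jitter_hours = jitter_hours,
      inject_missingness = inject_missingness,
      inject_outliers = inject_outliers,
      outlier_multiplier = outlier_multiplier,
      female_rate = female_rate,
      age_mean = age_mean, age_sd = age_sd,
      weight_mean = weight_mean, weight_sd = weight_sd,
      coupling = coupling
    ),
    class = "cohort_config"
  )
}

#' Shift a generator configuration to emulate a second hospital
#'
#' Produces a "hospital B" variant of a configuration by shifting every
#' channel's baseline (in units of its `baseline_sd`) and its missingness
#' rate. Structurally mirrors training on one care system and testing on
#' another, where calibration and documentation practice differ.
#'
#' @param config A [cohort_config()].
#' @param baseline_shift Baseline shift in per-channel `baseline_sd` units
#'   (default 1).
#' @param missing_shift Additive shift of each channel's `missing_prob`,
#'   clipped to \[0, 0.95\] (default 0.1).
#' @return A new `cohort_config`.
#' @export
shift_cohort_config <- function(config, baseline_shift = 1, missing_shift = 0.1) {
  stopifnot(inherits(config, "cohort_config"))
  ch <- config$channels
  ch$baseline_mean <- ch$baseline_mean + baseline_shift * ch$baseline_sd
  ch$missing_prob <- pmin(pmax(ch$missing_prob + missing_shift, 0), 0.95)
  config$channels <- ch
  config
}

# Simulate the latent per-channel dynamics of one stay on the 4-hour grid:
# a mean-reverting AR(1) fluctuation around baseline plus a two-state Markov
# "episode" process that, while active, adds a drift placing the latent mean
# outside the reference range. Returns per-channel value and episode paths.
simulate_latent <- function(channels, duration_steps, coupling = NULL) {
  n_ch <- nrow(channels)
  vals <- matrix(NA_real_, nrow = duration_steps, ncol = n_ch,
                 dimnames = list(NULL, channels$channel))
  epis <- matrix(FALSE, nrow = duration_steps, ncol = n_ch,
                 dimnames = list(NULL, channels$channel))
  # order channels so coupling sources are simulated before their targets
  order_idx <- seq_len(n_ch)
  if (!is.null(coupling)) {
    src_first <- match(unique(coupling$source), channels$channel)
    order_idx <- c(src_first, setdiff(order_idx, src_first))
  }
  for (j in order_idx) {
    spec <- channels[j, ]
    range_w <- spec$normal_high - spec$normal_low
    # episode drift magnitude: beyond the nearer boundary by a quarter range
    # plus 3 sd, so in-episode values are abnormal with near-certainty
    push_hi <- (spec$normal_high - spec$baseline_mean) + 0.25 * range_w + 3 * spec$baseline_sd
    push_lo <- (spec$baseline_mean - spec$normal_low) + 0.25 * range_w + 3 * spec$baseline_sd
    extra_rate <- rep(0, duration_steps)
    if (!is.null(coupling)) {
      links <- coupling[coupling$target == spec$channel, , drop = FALSE]
      if (nrow(links) > 0) {
        for (li in seq_len(nrow(links))) {
          src_path <- epis[, links$source[li]]
          # source episode state at the previous step raises entry probability
          extra_rate <- extra_rate + links$weight[li] * c(0, as.numeric(src_path[-duration_steps]))
        }
      }
    }
    rate <- pmin(spec$episode_rate + extra_rate, 1)
    pers <- spec$episode_persistence
    # stationary start keeps the marginal episode fraction at its closed form;
    # an absorbing chain (persistence 1) has no stationary law, so it starts
    # in the absorbed state with probability 1/2 for balanced label classes
    pi0 <- if (pers >= 1) {
      if (spec$episode_rate > 0) 0.5 else 0
    } else if (spec$episode_rate + (1 - pers) > 0) {
      spec$episode_rate / (spec$episode_rate + (1 - pers))
    } else 0
    in_ep <- runif(1) < pi0
    direction <- if ("episode_direction" %in% names(spec)) spec$episode_direction else 1
    ar <- spec$ar_coefficient
    innov_sd <- spec$baseline_sd * sqrt(1 - ar^2)
    e <- rnorm(1, 0, spec$baseline_sd)
    for (t in seq_len(duration_steps)) {
      if (t > 1) {
        e <- ar * e + rnorm(1, 0, innov_sd)
        in_ep <- if (in_ep) runif(1) < pers else runif(1) < rate[t]
      }
      drift <- if (in_ep) direction * (if (direction > 0) push_hi else push_lo) else 0
      vals[t, j] <- spec$baseline_mean + drift + e
      epis[t, j] <- in_ep
    }
  }
  list(values = vals, episodes = epis)
}

#' Simulate one ICU stay
#'
#' Draws latent 4-hourly dynamics for every channel (mean-reverting AR(1)
#' around baseline, plus Markov abnormal-drift episodes that make near-future
#' abnormality predictable from recent history), then records noisy
#' measurements at each channel's irregular sampling times.
#'
#' @param config A [cohort_config()].
#' @param duration_steps Stay length in grid steps (3..18 under the default
#'   configuration's duration range).
#' @param seed Integer seed; the stay is a deterministic function of
#'   `(config, duration_steps, seed)`.
#' @param stay_id Identifier for the stay (default `"stay_1"`).
#' @param step_hours Grid step in hours (default 4).
#' @return A list of class `lab_stay` with elements `stay_id`,
#'   `demographics` (one-row tibble), `measurements` (tibble: `channel`,
#'   `time_h`, `value`), `true_state` (tibble of latent per-step values and
#'   episode flags, kept for oracle tests), `duration_h`, `n_steps`.
#' @export
simulate_stay <- function(config, duration_steps, seed, stay_id = "stay_1",
                          step_hours = 4) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.numeric(duration_steps) || duration_steps < 1) {
    stop_named("duration_steps must be a positive integer, got %s", format(duration_steps))
  }
  channels <- config$channels
  if (nrow(channels) < 1) stop_named("channel specification list is empty")
  duration_steps <- as.integer(duration_steps)
  duration_h <- duration_steps * step_hours
  with_seed(seed, {
    demo <- tibble::tibble(
      stay_id = stay_id,
      age = rtruncnorm(1, config$age_mean, config$age_sd, 18, 95),
      sex = if (runif(1) < config$female_rate) "female" else "male",
      weight = rtruncnorm(1, config$weight_mean, config$weight_sd, 35, 200)
    )
    latent <- simulate_latent(channels, duration_steps, config$coupling)
    meas <- purrr::map_dfr(seq_len(nrow(channels)), function(j) {
      spec <- channels[j, ]
      base_times <- seq(0, duration_h - 1e-9, by = spec$sampling_period_hours)
      jit <- runif(length(base_times), 0, config$jitter_hours)
      times <- pmin(base_times + jit, duration_h - 1e-6)
      bins <- pmin(floor(times / step_hours) + 1, duration_steps)
      noise <- rnorm(length(times), 0, config$obs_noise_sd * spec$baseline_sd)
      tibble::tibble(
        channel = spec$channel,
        time_h = times,
        value = latent$values[bins, j] + noise
      )
    })
    meas <- dplyr::arrange(meas, .data$channel, .data$time_h)
    true_state <- tibble::tibble(
      stay_id = stay_id,
      step = rep(seq_len(duration_steps) - 1L, times = nrow(channels)),
      channel = rep(channels$channel, each = duration_steps),
      value = as.vector(latent$values),
      episode = as.vector(latent$episodes)
    )
    structure(
      list(
        stay_id = stay_id,
        demographics = demo,
        measurements = dplyr::mutate(meas, stay_id = stay_id, .before = 1),
        true_state = true_state,
        duration_h = duration_h,
        n_steps = duration_steps,
        step_hours = step_hours
      ),
      class = "lab_stay"
    )
  })
}

#' Randomly drop measurements from a stay
#'
#' Each measurement is independently removed with its channel's
#' `missing_prob`, emulating the heavy, channel-dependent missingness of real
#' lab extracts.
#'
#' @param stay A `lab_stay` from [simulate_stay()].
#' @param channels Channel table supplying `missing_prob` per channel.
#' @param seed Integer seed.
#' @return The stay with a thinned `measurements` table.
#' @export
inject_missingness <- function(stay, channels, seed) {
  stopifnot(inherits(stay, "lab_stay"))
  validate_channel_specs(channels)
  p <- channels$missing_prob[match(stay$measurements$channel, channels$channel)]
  if (anyNA(p)) stop_named("measurements contain channels absent from the channel table")
  with_seed(seed, {
    keep <- runif(nrow(stay$measurements)) >= p
    stay$measurements <- stay$measurements[keep, , drop = FALSE]
  })
  stay
}

#' Inject gross outliers into a stay's measurements
#'
#' Each measurement is, with its channel's `outlier_prob`, replaced by
#' `baseline_mean +/- magnitude_multiplier * (normal_high - normal_low)` —
#' a transcription-error-scale corruption. The indices of corrupted rows are
#' returned so outlier-detection recall can be scored against ground truth.
#'
#' @param stay A `lab_stay`.
#' @param channels Channel table supplying `outlier_prob` and ranges.
#' @param magnitude_multiplier Corruption size in range-width units; must
#'   exceed 1 (default 10).
#' @param seed Integer seed.
#' @return A list: `stay` (corrupted) and `corrupted` (integer row indices
#'   into `stay$measurements`).
#' @export
inject_outliers <- function(stay, channels, magnitude_multiplier = 10, seed = 1) {
  stopifnot(inherits(stay, "lab_stay"))
  validate_channel_specs(channels)
  if (magnitude_multiplier <= 1) stop_named("magnitude_multiplier must be > 1")
  idx <- match(stay$measurements$channel, channels$channel)
  p <- channels$outlier_prob[idx]
  with_seed(seed, {
    hit <- which(runif(nrow(stay$measurements)) < p)
    if (length(hit) > 0) {
      sign <- ifelse(runif(length(hit)) < 0.5, -1, 1)
      j <- idx[hit]
      stay$measurements$value[hit] <-
        channels$baseline_mean[j] +
        sign * magnitude_multiplier * (channels$normal_high[j] - channels$normal_low[j])
    }
  })
  list(stay = stay, corrupted = hit)
}

#' Generate a synthetic ICU cohort
#'
#' Simulates `n_stays` independent stays under a [cohort_config()], applies
#' the configured missingness and outlier corruption, and assembles the
#' long-format measurement and demographics tables every downstream stage
#' consumes. Identical `(config, n_stays, seed)` triples give identical
#' cohorts.
#'
#' @param config A [cohort_config()].
#' @param n_stays Number of stays (>= 1).
#' @param seed Integer seed.
#' @return A list of class `lab_cohort`: `measurements` (tibble `stay_id`,
#'   `channel`, `time_h`, `value`), `demographics` (tibble `stay_id`, `age`,
#'   `sex`, `weight`), `durations` (tibble `stay_id`, `n_steps`,
#'   `duration_h`), `true_state` (latent grid values and episode flags),
#'   `outlier_truth` (tibble of injected-outlier locations), `channels`,
#'   `config`, `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), n_stays = 3, seed = 7)
#' cohort$measurements
generate_cohort <- function(config, n_stays, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.numeric(n_stays) || n_stays < 1) stop_named("n_stays must be >= 1")
  n_stays <- as.integer(n_stays)
  dur <- with_seed(derive_seed(seed, "durations"), {
    sample(seq(config$duration_range[1], config$duration_range[2]), n_stays, replace = TRUE)
  })
  stays <- vector("list", n_stays)
  outlier_truth <- vector("list", n_stays)
  for (i in seq_len(n_stays)) {
    sid <- sprintf("stay_%04d", i)
    st <- simulate_stay(config, dur[i], derive_seed(seed, paste0("stay/", sid)), stay_id = sid)
    if (config$inject_missingness) {
      st <- inject_missingness(st, config$channels, derive_seed(seed, paste0("miss/", sid)))
    }
    if (config$inject_outliers) {
      res <- inject_outliers(st, config$channels, config$outlier_multiplier,
                             derive_seed(seed, paste0("outl/", sid)))
      st <- res$stay
      if (length(res$corrupted) > 0) {
        outlier_truth[[i]] <- st$measurements[res$corrupted, c("stay_id", "channel", "time_h", "value")]
      }
    }
    stays[[i]] <- st
  }
  structure(
    list(
      measurements = purrr::map_dfr(stays, "measurements"),
      demographics = purrr::map_dfr(stays, "demographics"),
      durations = tibble::tibble(
        stay_id = purrr::map_chr(stays, "stay_id"),
        n_steps = as.integer(dur),
        duration_h = as.numeric(dur * 4)
      ),
      true_state = purrr::map_dfr(stays, "true_state"),
      outlier_truth = dplyr::bind_rows(outlier_truth),
      channels = config$channels,
      config = config,
      seed = as.integer(seed)
    ),
    class = "lab_cohort"
  )
}

#' @export
print.lab_cohort <- function(x, ...) {
  cat(sprintf(
    "<lab_cohort> %d stays, %d channels, %d measurements (seed %d)\n",
    nrow(x$durations), nrow(x$channels), nrow(x$measurements), x$seed
  ))
  invisible(x)
}

#' Noiseless persistence benchmark cohort
#'
#' The canonical learnability benchmark: every channel is sampled exactly on
#' the 4-hour grid with no observation noise, no missingness and no
#' outliers, and abnormal episodes are absorbing
#' (`episode_persistence = 1`, entry rate 0.02, half the channels starting
#' in the absorbed state). The next step's abnormality vector is then a
#' deterministic function of the last observed row except at the rare
#' episode entries, so any adequate sequence model should recover it almost
#' perfectly — the floor every architecture is tested against.
#'
#' @param n_stays Number of stays.
#' @param seed Integer seed.
#' @return A `lab_cohort`.
#' @export
persistence_benchmark_cohort <- function(n_stays, seed) {
  channels <- dplyr::mutate(
    default_lab_channels(),
    episode_persistence = 1,
    episode_rate = 0.02,
    sampling_period_hours = 4,
    missing_prob = 0,
    outlier_prob = 0
  )
  cfg <- cohort_config(
    channels = channels, obs_noise_sd = 0, jitter_hours = 0,
    inject_missingness = FALSE, inject_outliers = FALSE
  )
  generate_cohort(cfg, n_stays, seed)
}

#' Micro-F1 of the naive persistence predictor on latent abnormality
#'
#' Scores the baseline that predicts the next step's abnormality vector to be
#' identical to the current step's, using the cohort's latent (noise-free)
#' grid states. On a well-configured generator this floor is high, which
#' certifies that next-step abnormality is learnable from history.
#'
#' @param cohort A `lab_cohort` with `true_state` retained.
#' @return A one-row tibble of micro-averaged metrics (see [micro_metrics()]).
#' @export
persistence_baseline <- function(cohort) {
  stopifnot(inherits(cohort, "lab_cohort"), nrow(cohort$true_state) > 0)
  rng <- reference_ranges(cohort$channels)
  ts <- dplyr::left_join(cohort$true_state, rng, by = "channel")
  ts$abnormal <- as.integer(ts$value < ts$normal_low | ts$value > ts$normal_high)
  ts <- dplyr::arrange(ts, .data$stay_id, .data$channel, .data$step)
  grp <- paste(ts$stay_id, ts$channel)
  n <- nrow(ts)
  same_grp <- grp[-1] == grp[-n]
  pred <- ts$abnormal[-n][same_grp]
  truth <- ts$abnormal[-1][same_grp]
  micro_metrics(confusion_counts(matrix(pred, ncol = 1), matrix(truth, ncol = 1)))
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Writes `measurements.csv`, `demographics.csv`, a `channels.yaml` channel /
#' generator description and, when present, `true_state.csv`. The CSV schema
#' is the drop-in point for real extracts: any table of
#' (stay_id, channel, time_h, value) rows plus per-stay demographics can be
#' read back with [read_cohort()].
#'
#' @param cohort A `lab_cohort`.
#' @param dir Output directory (created if needed).
#' @param true_state Also write the latent state table? Default `FALSE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, true_state = FALSE) {
  stopifnot(inherits(cohort, "lab_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$measurements, file.path(dir, "measurements.csv"), row.names = FALSE)
  utils::write.csv(cohort$demographics, file.path(dir, "demographics.csv"), row.names = FALSE)
  utils::write.csv(cohort$durations, file.path(dir, "durations.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(seed = cohort$seed, channels = lapply(seq_len(nrow(cohort$channels)), function(i) as.list(cohort$channels[i, ]))),
    file.path(dir, "channels.yaml")
  )
  if (true_state && nrow(cohort$true_state) > 0) {
    utils::write.csv(cohort$true_state, file.path(dir, "true_state.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from the on-disk CSV/YAML schema
#'
#' @param dir Directory written by [write_cohort()] (or holding real extracts
#'   in the same schema).
#' @return A `lab_cohort`.
#' @export
read_cohort <- function(dir) {
  meas <- tibble::as_tibble(utils::read.csv(file.path(dir, "measurements.csv")))
  demo <- tibble::as_tibble(utils::read.csv(file.path(dir, "demographics.csv")))
  durs <- tibble::as_tibble(utils::read.csv(file.path(dir, "durations.csv")))
  ychan <- yaml::read_yaml(file.path(dir, "channels.yaml"))
  channels <- purrr::map_dfr(ychan$channels, tibble::as_tibble)
  ts_path <- file.path(dir, "true_state.csv")
  true_state <- if (file.exists(ts_path)) tibble::as_tibble(utils::read.csv(ts_path)) else tibble::tibble()
  structure(
    list(
      measurements = meas, demographics = demo, durations = durs,
      true_state = true_state, outlier_truth = tibble::tibble(),
      channels = channels, config = NULL,
      seed = as.integer(ychan$seed %||% NA_integer_)
    ),
    class = "lab_cohort"
  )
}
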