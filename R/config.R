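#' Default experiment configuration
#'
#' The full configuration tree for a reproducible two-cohort experiment:
#' generator blocks for cohorts A and B, preprocessing settings, windowing
#' settings, the architecture list with hyperparameter overrides, the
#' training configuration, an output directory and the global seed from
#' which every stage seed is derived. Field defaults follow the package's
#' standard operating point: 4-hour grid, window `W = 6`, threshold
#' `th = 0.5`.
#'
#' @return A nested named list of class `experiment_config`.
#' @export
default_experiment_config <- function() {
  structure(
    list(
      seed = 1L,
      output_dir = "labforecast_output",
      cohort_a = list(n_stays = 100L, baseline_shift = 0, missing_shift = 0),
      cohort_b = list(n_stays = 100L, baseline_shift = 1, missing_shift = 0.1),
      generator = list(
        obs_noise_sd = 0.1, jitter_hours = 1,
        inject_missingness = TRUE, inject_outliers = TRUE,
        outlier_multiplier = 10
      ),
      preprocessing = list(
        step_hours = 4, coverage_threshold = 0.9, tukey_k = 1.5,
        knn_k = 5L, svd_rank = NULL, max_missing_fraction = 0.5
      ),
      windowing = list(
        W = 6L,
        fractions = c(train = 0.68, validation = 0.12, test = 0.20)
      ),
      models = list(
        architectures = c("lstm", "cnn", "mcnn", "transformer", "tcn", "gbm")
      ),
      training = list(
        max_epochs = 60L, batch_size = 64L, learning_rate = 0.005,
        min_delta = 0.01, patience = 10L, th = 0.5
      )
    ),
    class = "experiment_config"
  )
}

# Recursive merge of user values over defaults, failing closed on unknown
# keys so typos cannot silently fall back to defaults.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop_named("unknown configuration key(s): %s",
               paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (nm in names(user)) {
    val <- if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      merge_config(defaults[[nm]], user[[nm]], paste0(path, ".", nm))
    } else {
      user[[nm]]
    }
    # defaults[nm] <- list(val) keeps explicit-NULL keys instead of deleting them
    defaults[nm] <- list(val)
  }
  defaults
}

validate_experiment_config <- function(cfg) {
  fail <- function(key, msg) stop_named("invalid configuration: %s %s", key, msg)
  th <- cfg$training$th
  if (!is.numeric(th) || th <= 0 || th >= 1) fail("training.th (threshold)", "must be in (0, 1)")
  fr <- unlist(cfg$windowing$fractions)
  if (length(fr) != 3 || any(fr <= 0)) fail("windowing.fractions", "must be three positive numbers")
  if (abs(sum(fr) - 1) > 1e-8) fail("windowing.fractions", "must sum to 1")
  if (cfg$windowing$W < 2) fail("windowing.W", "must be >= 2")
  if (cfg$preprocessing$step_hours <= 0) fail("preprocessing.step_hours", "must be > 0")
  ct <- cfg$preprocessing$coverage_threshold
  if (ct <= 0 || ct > 1) fail("preprocessing.coverage_threshold", "must be in (0, 1]")
  if (cfg$preprocessing$tukey_k <= 0) fail("preprocessing.tukey_k", "must be > 0")
  if (cfg$preprocessing$knn_k < 1) fail("preprocessing.knn_k", "must be >= 1")
  mmf <- cfg$preprocessing$max_missing_fraction
  if (mmf < 0 || mmf > 1) fail("preprocessing.max_missing_fraction", "must be in [0, 1]")
  if (cfg$cohort_a$n_stays < 1 || cfg$cohort_b$n_stays < 1) fail("cohort_*.n_stays", "must be >= 1")
  bad <- setdiff(cfg$models$architectures, c("lstm", "cnn", "mcnn", "transformer", "tcn", "gbm"))
  if (length(bad) > 0) fail("models.architectures", sprintf("unknown: %s", paste(bad, collapse = ", ")))
  if (cfg$training$patience < 1) fail("training.patience", "must be >= 1")
  if (cfg$training$min_delta < 0) fail("training.min_delta", "must be >= 0")
  invisible(cfg)
}

#' Load and validate an experiment configuration from YAML
#'
#' Reads a YAML file, injects defaults for anything unspecified (an empty
#' file yields the full default configuration), rejects unknown keys, and
#' checks every constraint with an error naming the offending key.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop_named("configuration file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_experiment_config(), user)
  fr <- unlist(cfg$windowing$fractions)
  if (length(fr) == 3) {
    names(fr) <- c("train", "validation", "test")
    cfg$windowing$fractions <- fr
  }
  class(cfg) <- "experiment_config"
  validate_experiment_config(cfg)
  cfg
}

#' Write an experiment configuration to YAML
#'
#' Inverse of [load_experiment_config()]: `load(dump(cfg))` reproduces
#' `cfg`, so the effective configuration can be written next to outputs for
#' provenance.
#'
#' @param cfg An `experiment_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(cfg, path) {
  validate_experiment_config(cfg)
  out <- unclass(cfg)
  out$windowing$fractions <- as.list(out$windowing$fractions)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a full two-cohort experiment from a configuration
#'
#' Generates both cohorts, runs the comparison harness over the configured
#' architectures and writes the metric report (CSV + JSON) plus the
#' effective configuration to the output directory.
#'
#' @param cfg An `experiment_config` (default: the package defaults).
#' @return The comparison tibble, invisibly annotated with the config.
#' @export
run_experiment <- function(cfg = default_experiment_config()) {
  validate_experiment_config(cfg)
  gen <- cfg$generator
  base_cfg <- cohort_config(
    obs_noise_sd = gen$obs_noise_sd, jitter_hours = gen$jitter_hours,
    inject_missingness = gen$inject_missingness,
    inject_outliers = gen$inject_outliers,
    outlier_multiplier = gen$outlier_multiplier
  )
  mk <- function(block, label) {
    cc <- shift_cohort_config(base_cfg, block$baseline_shift, block$missing_shift)
    generate_cohort(cc, block$n_stays, derive_seed(cfg$seed, paste0("cohort/", label)))
  }
  cohort_a <- mk(cfg$cohort_a, "A")
  cohort_b <- mk(cfg$cohort_b, "B")
  tc <- train_config(
    max_epochs = cfg$training$max_epochs, batch_size = cfg$training$batch_size,
    learning_rate = cfg$training$learning_rate, min_delta = cfg$training$min_delta,
    patience = cfg$training$patience, th = cfg$training$th
  )
  result <- run_comparison(
    cohort_a, cohort_b,
    architectures = cfg$models$architectures,
    W = cfg$windowing$W, th = cfg$training$th, seed = cfg$seed,
    train_config = tc,
    fractions = unlist(cfg$windowing$fractions),
    preprocess_args = cfg$preprocessing[c("step_hours", "coverage_threshold", "tukey_k",
                                          "knn_k", "svd_rank", "max_missing_fraction")]
  )
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result, file.path(cfg$output_dir, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(result, file.path(cfg$output_dir, "comparison.json"), digits = NA)
  write_experiment_config(cfg, file.path(cfg$output_dir, "config.yaml"))
  invisible(result)
}
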