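#' Discretize irregular measurements onto a fixed time grid
#'
#' Assigns every measurement to the grid bin `floor(time_h / step_hours)`
#' (bin `m` covers hours `[m * step, (m + 1) * step)`, 0-based, so bin 0
#' starts at admission). When several measurements of one channel land in the
#' same bin, the latest is kept — the most recent value is the clinically
#' operative one. Unfilled cells are marked `missing`.
#'
#' @param cohort A `lab_cohort`.
#' @param step_hours Grid step in hours (default 4).
#' @return A list of class `gridded_cohort`: `stays` (named list of
#'   `gridded_stay` objects, each with an `L x C` `values` matrix and a
#'   congruent `mask` of `"observed"`/`"held"`/`"imputed"`/`"missing"`),
#'   `channels`, `step_hours`, plus bookkeeping slots filled by later stages.
#' @export
discretize <- function(cohort, step_hours = 4) {
  stopifnot(inherits(cohort, "lab_cohort"))
  if (step_hours <= 0) stop_named("step_hours must be > 0")
  channels <- cohort$channels$channel
  stays <- list()
  for (i in seq_len(nrow(cohort$durations))) {
    sid <- cohort$durations$stay_id[i]
    duration_h <- cohort$durations$duration_h[i]
    L <- as.integer(ceiling(duration_h / step_hours))
    meas <- cohort$measurements[cohort$measurements$stay_id == sid, , drop = FALSE]
    if (any(meas$time_h < 0) || any(meas$time_h >= duration_h)) {
      stop_named("stay %s has measurement times outside [0, duration)", sid)
    }
    values <- matrix(NA_real_, nrow = L, ncol = length(channels),
                     dimnames = list(NULL, channels))
    mask <- matrix("missing", nrow = L, ncol = length(channels),
                   dimnames = list(NULL, channels))
    if (nrow(meas) > 0) {
      bin <- floor(meas$time_h / step_hours) + 1L
      # latest measurement in a bin wins: process in time order
      ord <- order(meas$time_h)
      for (r in ord) {
        values[bin[r], meas$channel[r]] <- meas$value[r]
        mask[bin[r], meas$channel[r]] <- "observed"
      }
    }
    stays[[sid]] <- structure(
      list(
        stay_id = sid,
        demographics = cohort$demographics[cohort$demographics$stay_id == sid, , drop = FALSE],
        values = values, mask = mask,
        step_hours = step_hours, duration_h = duration_h
      ),
      class = "gridded_stay"
    )
  }
  structure(
    list(
      stays = stays,
      channels = cohort$channels,
      step_hours = step_hours,
      hold_times = NULL,
      outlier_removals = NULL,
      discarded_stays = character(0)
    ),
    class = "gridded_cohort"
  )
}

#' @export
print.gridded_cohort <- function(x, ...) {
  cat(sprintf(
    "<gridded_cohort> %d stays x %d channels on a %g-hour grid; %d stays discarded\n",
    length(x$stays), nrow(x$channels), x$step_hours, length(x$discarded_stays)
  ))
  invisible(x)
}

#' Estimate per-channel maximum hold times from measurement cadence
#'
#' For each channel, pools the consecutive inter-measurement time differences
#' across all stays, sorts the distinct gap values ascending, and takes as
#' hold time the smallest gap at which the cumulative count fraction reaches
#' `coverage_threshold`. The result is rounded to the nearest positive
#' multiple of `step_hours`. Channels with fewer than two measurements
#' cohort-wide fall back to `step_hours` and are flagged.
#'
#' @param cohort A `lab_cohort` (raw measurements).
#' @param coverage_threshold Fraction of gaps the hold time must cover, in
#'   `(0, 1]` (default 0.9).
#' @param step_hours Grid step used for rounding (default 4).
#' @return A tibble of class `hold_time_table`: `channel`, `hold_time_h`,
#'   `n_gaps`, `fallback`, with the threshold recorded as an attribute.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), n_stays = 10, seed = 1)
#' estimate_hold_times(cohort, coverage_threshold = 0.9)
estimate_hold_times <- function(cohort, coverage_threshold = 0.9, step_hours = 4) {
  stopifnot(inherits(cohort, "lab_cohort"))
  if (coverage_threshold <= 0 || coverage_threshold > 1) {
    stop_named("coverage_threshold must be in (0, 1]")
  }
  gaps_tbl <- cohort$measurements |>
    dplyr::arrange(.data$stay_id, .data$channel, .data$time_h) |>
    dplyr::group_by(.data$stay_id, .data$channel) |>
    dplyr::reframe(gap = diff(.data$time_h))
  out <- purrr::map_dfr(cohort$channels$channel, function(ch) {
    gaps <- gaps_tbl$gap[gaps_tbl$channel == ch]
    if (length(gaps) < 1) {
      return(tibble::tibble(channel = ch, hold_time_h = step_hours,
                            n_gaps = 0L, fallback = TRUE))
    }
    tibble::tibble(
      channel = ch,
      hold_time_h = hold_time_from_gaps(gaps, coverage_threshold, step_hours),
      n_gaps = length(gaps),
      fallback = FALSE
    )
  })
  if (any(out$fallback)) {
    warn(sprintf("hold time fell back to %g h for channel(s): %s",
                 step_hours, paste(out$channel[out$fallback], collapse = ", ")))
  }
  attr(out, "coverage_threshold") <- coverage_threshold
  class(out) <- c("hold_time_table", class(out))
  out
}

# Core cumulative-coverage rule on one channel's pooled gap multiset.
hold_time_from_gaps <- function(gaps, coverage_threshold, step_hours) {
  tab <- table(gaps)
  distinct <- as.numeric(names(tab))
  cum_frac <- cumsum(as.numeric(tab)) / length(gaps)
  ht <- distinct[which(cum_frac >= coverage_threshold)[1]]
  max(step_hours, round(ht / step_hours) * step_hours)
}

#' Forward-fill a gridded cohort by sample-and-hold
#'
#' Each observed value is held (repeated forward in time) until the next
#' observation of the same channel or until the channel's maximum hold time
#' elapses: the cell `j` grid steps after an observation is filled iff
#' `j * step_hours <= hold_time`. Cells beyond the hold horizon stay
#' `missing` — a stale value is treated as corrupted rather than carried
#' indefinitely. Observed cells are never overwritten and filling never goes
#' backward in time.
#'
#' @param gridded A `gridded_cohort` from [discretize()].
#' @param hold_times A `hold_time_table` from [estimate_hold_times()]
#'   covering every channel.
#' @return The cohort with held cells filled and marked `"held"`.
#' @export
sample_and_hold <- function(gridded, hold_times) {
  stopifnot(inherits(gridded, "gridded_cohort"))
  channels <- colnames(gridded$stays[[1]]$values)
  ht <- hold_times$hold_time_h[match(channels, hold_times$channel)]
  if (anyNA(ht)) {
    stop_named("hold_times is missing channel(s): %s",
               paste(channels[is.na(ht)], collapse = ", "))
  }
  max_steps <- floor(ht / gridded$step_hours)
  gridded$stays <- lapply(gridded$stays, function(stay) {
    L <- nrow(stay$values)
    for (j in seq_along(channels)) {
      last_obs <- NA_integer_
      for (m in seq_len(L)) {
        if (stay$mask[m, j] == "observed") {
          last_obs <- m
        } else if (!is.na(last_obs) && (m - last_obs) <= max_steps[j]) {
          stay$values[m, j] <- stay$values[last_obs, j]
          stay$mask[m, j] <- "held"
        }
      }
    }
    stay
  })
  gridded$hold_times <- hold_times
  gridded
}

#' Remove gross outliers with Tukey fences
#'
#' Computes per-channel quartiles (linear interpolation between order
#' statistics) over all observed and held cells cohort-wide, and blanks any
#' cell outside `[Q1 - k * IQR, Q3 + k * IQR]` back to `missing` so the
#' imputation stage refills it. Fence membership is closed: values equal to a
#' fence are kept, so a constant channel (IQR 0) loses nothing. Channels with
#' fewer than 4 finite cells are left untouched and flagged.
#'
#' @param gridded A `gridded_cohort` after [sample_and_hold()].
#' @param k Fence multiplier (> 0, default 1.5).
#' @return The cohort, with a `outlier_removals` tibble (`channel`,
#'   `n_removed`, `flagged`) recorded on it.
#' @export
remove_outliers_tukey <- function(gridded, k = 1.5) {
  stopifnot(inherits(gridded, "gridded_cohort"))
  if (k <= 0) stop_named("Tukey fence multiplier k must be > 0")
  channels <- colnames(gridded$stays[[1]]$values)
  pooled <- lapply(seq_along(channels), function(j) {
    unlist(lapply(gridded$stays, function(stay) {
      stay$values[stay$mask[, j] %in% c("observed", "held"), j]
    }), use.names = FALSE)
  })
  removals <- tibble::tibble(channel = channels, n_removed = 0L, flagged = FALSE)
  fences <- matrix(NA_real_, nrow = length(channels), ncol = 2)
  for (j in seq_along(channels)) {
    vals <- pooled[[j]][is.finite(pooled[[j]])]
    if (length(vals) < 4) {
      removals$flagged[j] <- TRUE
      next
    }
    q <- quantile(vals, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    fences[j, ] <- c(q[1] - k * iqr, q[2] + k * iqr)
  }
  gridded$stays <- lapply(gridded$stays, function(stay) {
    for (j in seq_along(channels)) {
      if (is.na(fences[j, 1])) next
      cand <- stay$mask[, j] %in% c("observed", "held")
      out <- cand & (stay$values[, j] < fences[j, 1] | stay$values[, j] > fences[j, 2])
      out[is.na(out)] <- FALSE
      if (any(out)) {
        stay$values[out, j] <- NA_real_
        stay$mask[out, j] <- "missing"
        removals$n_removed[j] <<- removals$n_removed[j] + sum(out)
      }
    }
    stay
  })
  if (any(removals$flagged)) {
    warn(sprintf("Tukey test skipped (fewer than 4 finite cells) for channel(s): %s",
                 paste(removals$channel[removals$flagged], collapse = ", ")))
  }
  gridded$outlier_removals <- removals
  gridded
}

#' Discard stays with too much missing data
#'
#' Removes every stay whose missing-cell fraction (over the full `L x C`
#' grid, after sample-and-hold) is strictly greater than
#' `max_missing_fraction`; a stay at exactly the threshold is retained.
#'
#' @param gridded A `gridded_cohort`.
#' @param max_missing_fraction Discard threshold (default 0.5).
#' @return The cohort with offending stays removed; their ids accumulate in
#'   `discarded_stays`.
#' @export
filter_stays <- function(gridded, max_missing_fraction = 0.5) {
  stopifnot(inherits(gridded, "gridded_cohort"))
  frac <- vapply(gridded$stays, function(stay) mean(stay$mask == "missing"), numeric(1))
  drop <- names(frac)[frac > max_missing_fraction]
  gridded$discarded_stays <- c(gridded$discarded_stays, drop)
  gridded$stays <- gridded$stays[setdiff(names(gridded$stays), drop)]
  gridded
}

#' Impute remaining missing cells (kNN, optional SVD pass, mean fallback)
#'
#' Stacks all stay-time rows cohort-wide. Every row with missing cells finds
#' its `k` nearest complete rows (Euclidean distance over the row's observed,
#' z-scored channels) and fills each hole with their mean; rows with no
#' usable neighbours fall back to the cohort channel mean. An optional final
#' pass replaces the imputed cells by their rank-`svd_rank` SVD
#' reconstruction of the completed matrix, exploiting cross-channel
#' structure. The output has zero missing cells; filled cells are marked
#' `"imputed"`.
#'
#' @param gridded A `gridded_cohort` (after sample-and-hold / outlier
#'   removal / stay filtering).
#' @param k Number of nearest neighbours (default 5).
#' @param svd_rank Rank of the optional SVD smoothing pass; `NULL` (default)
#'   skips it.
#' @param max_pool Largest number of complete donor rows used for neighbour
#'   search; beyond it a deterministic subsample keeps the search tractable.
#' @return The cohort with `values` complete and finite everywhere.
#' @export
impute_missing <- function(gridded, k = 5, svd_rank = NULL, max_pool = 1000) {
  stopifnot(inherits(gridded, "gridded_cohort"), k >= 1)
  channels <- colnames(gridded$stays[[1]]$values)
  X <- do.call(rbind, lapply(gridded$stays, function(s) s$values))
  Msk <- do.call(rbind, lapply(gridded$stays, function(s) s$mask))
  obs <- Msk != "missing"
  dead <- channels[colSums(obs) == 0]
  if (length(dead) > 0) {
    stop_named("channel(s) entirely missing cohort-wide: %s", paste(dead, collapse = ", "))
  }
  ch_mean <- vapply(seq_along(channels), function(j) mean(X[obs[, j], j]), numeric(1))
  ch_sd <- vapply(seq_along(channels), function(j) sd(X[obs[, j], j]), numeric(1))
  ch_sd[!is.finite(ch_sd) | ch_sd == 0] <- 1
  Z <- sweep(sweep(X, 2, ch_mean), 2, ch_sd, "/")
  complete <- which(rowSums(!obs) == 0)
  incomplete <- which(rowSums(!obs) > 0)
  if (length(complete) > max_pool) {
    # deterministic thinning: evenly spaced donors over the stacked rows
    complete <- complete[round(seq(1, length(complete), length.out = max_pool))]
  }
  filled <- X
  imputed_cells <- !obs
  if (length(incomplete) > 0 && length(complete) > 0) {
    donors <- Z[complete, , drop = FALSE]
    for (r in incomplete) {
      s <- which(obs[r, ])
      if (length(s) == 0) {
        filled[r, ] <- ifelse(obs[r, ], X[r, ], ch_mean)
        next
      }
      d2 <- rowMeans((donors[, s, drop = FALSE] -
                        matrix(Z[r, s], nrow(donors), length(s), byrow = TRUE))^2)
      nn <- complete[order(d2)[seq_len(min(k, length(complete)))]]
      fill_vals <- colMeans(X[nn, , drop = FALSE])
      miss <- !obs[r, ]
      filled[r, miss] <- fill_vals[miss]
    }
  } else if (length(incomplete) > 0) {
    for (r in incomplete) {
      miss <- !obs[r, ]
      filled[r, miss] <- ch_mean[miss]
    }
  }
  if (!is.null(svd_rank) && any(imputed_cells)) {
    # iterative low-rank completion: repeatedly replace the imputed cells by
    # their rank-r SVD reconstruction until the fill converges, so a matrix
    # of exact rank <= r is recovered (up to numerical precision) wherever
    # its observed entries pin it down
    r <- min(svd_rank, ncol(filled), nrow(filled))
    for (it in seq_len(200)) {
      dec <- svd(filled, nu = r, nv = r)
      recon <- dec$u %*% (diag(dec$d[seq_len(r)], r, r)) %*% t(dec$v)
      delta <- max(abs(recon[imputed_cells] - filled[imputed_cells]))
      filled[imputed_cells] <- recon[imputed_cells]
      if (delta < 1e-10) break
    }
  }
  # scatter back into the per-stay matrices
  offset <- 0L
  gridded$stays <- lapply(gridded$stays, function(stay) {
    L <- nrow(stay$values)
    rows <- offset + seq_len(L)
    offset <<- offset + L
    miss <- stay$mask == "missing"
    stay$values <- filled[rows, , drop = FALSE]
    stay$mask[miss] <- "imputed"
    stay
  })
  gridded
}

#' Run the full preprocessing chain
#'
#' Composes the stages in order: discretize onto the 4-hour grid, estimate
#' hold times from measurement cadence (or reuse a table estimated on a
#' training cohort, for leakage-free cross-cohort evaluation),
#' sample-and-hold, Tukey outlier removal, discard stays with too much
#' missing data, and impute the remainder. The result is complete and
#' finite everywhere.
#'
#' @param cohort A `lab_cohort`.
#' @param step_hours Grid step (default 4).
#' @param coverage_threshold Hold-time coverage fraction (default 0.9).
#' @param tukey_k Fence multiplier (default 1.5).
#' @param knn_k Imputation neighbour count (default 5).
#' @param svd_rank Optional SVD pass rank (default `NULL`).
#' @param max_missing_fraction Stay discard threshold (default 0.5).
#' @param hold_times Optional externally estimated `hold_time_table`; when
#'   given, hold times are not re-estimated from `cohort`.
#' @return A complete `gridded_cohort`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), n_stays = 5, seed = 1)
#' gridded <- preprocess_cohort(cohort)
preprocess_cohort <- function(cohort, step_hours = 4, coverage_threshold = 0.9,
                              tukey_k = 1.5, knn_k = 5, svd_rank = NULL,
                              max_missing_fraction = 0.5, hold_times = NULL) {
  if (is.null(hold_times)) {
    hold_times <- estimate_hold_times(cohort, coverage_threshold, step_hours)
  }
  cohort |>
    discretize(step_hours = step_hours) |>
    sample_and_hold(hold_times) |>
    remove_outliers_tukey(k = tukey_k) |>
    filter_stays(max_missing_fraction = max_missing_fraction) |>
    impute_missing(k = knn_k, svd_rank = svd_rank)
}
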