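panel1 <- function() make_panel(n_ch = 1, missing_prob = 0, outlier_prob = 0)

cohort_from_times <- function(times, values = NULL, duration_h = NULL, channels = panel1()) {
  values <- values %||% rep(15, length(times))
  duration_h <- duration_h %||% (4 * ceiling((max(times) + 0.001) / 4))
  meas <- tibble::tibble(stay_id = "s1", channel = channels$channel[1],
                         time_h = times, value = values)
  make_manual_cohort(meas, tibble::tibble(stay_id = "s1", n_steps = as.integer(duration_h / 4),
                                          duration_h = duration_h), channels)
}

test_that("discretization bins measurements and keeps the latest value per bin", {
  g <- discretize(cohort_from_times(0, duration_h = 16))
  stay <- g$stays$s1
  expect_equal(stay$mask[, 1], c("observed", rep("missing", 3)))

  g2 <- discretize(cohort_from_times(c(1, 3), values = c(100, 200), duration_h = 8))
  expect_equal(unname(g2$stays$s1$values[1, 1]), 200)
  expect_equal(unname(g2$stays$s1$mask[2, 1]), "missing")

  g3 <- discretize(cohort_from_times(c(0, 40), duration_h = 44))
  expect_equal(nrow(g3$stays$s1$values), 11)
})

test_that("measurements beyond the stay duration are rejected", {
  cohort <- cohort_from_times(c(0, 30), duration_h = 16)
  expect_error(discretize(cohort), "outside")
})

test_that("hold times follow the cumulative-coverage rule on pooled gaps", {
  # gap multiset {4,4,4,4,4,8,24}: cumulative fractions 5/7, 6/7, 7/7
  times <- cumsum(c(0, 4, 4, 4, 4, 4, 8, 24))
  cohort <- cohort_from_times(times, duration_h = 56)
  ht90 <- estimate_hold_times(cohort, coverage_threshold = 0.9)
  expect_equal(ht90$hold_time_h, 24)
  ht70 <- estimate_hold_times(cohort, coverage_threshold = 0.7)
  expect_equal(ht70$hold_time_h, 4)
  ht_all <- estimate_hold_times(cohort, coverage_threshold = 1)
  expect_equal(ht_all$hold_time_h, 24)
})

test_that("uniform 4-hour gaps give a 4-hour hold time at any threshold", {
  cohort <- cohort_from_times(seq(0, 40, by = 4), duration_h = 44)
  for (th in c(0.1, 0.5, 0.9, 1)) {
    expect_equal(estimate_hold_times(cohort, coverage_threshold = th)$hold_time_h, 4)
  }
})

test_that("raising the coverage threshold never decreases a hold time", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      gaps <- sample(c(4, 8, 12, 24, 48), size = sample(3:30, 1), replace = TRUE)
      hts <- vapply(c(0.3, 0.5, 0.7, 0.9, 1),
                    function(th) labforecast:::hold_time_from_gaps(gaps, th, 4),
                    numeric(1))
      expect_true(all(diff(hts) >= 0))
    }
  })
})

test_that("channels without repeat measurements fall back to the grid step", {
  cohort <- cohort_from_times(0, duration_h = 8)
  expect_warning(ht <- estimate_hold_times(cohort), "fell back")
  expect_equal(ht$hold_time_h, 4)
  expect_true(ht$fallback)
})

test_that("sample-and-hold fills within the hold horizon and stops at it", {
  # observation at step 0, hold 8 h, next observation at step 5:
  # steps 1-2 held, steps 3-4 missing
  cohort <- cohort_from_times(c(0, 20), values = c(1, 2), duration_h = 24)
  ht <- tibble::tibble(channel = "ch1", hold_time_h = 8)
  g <- sample_and_hold(discretize(cohort), ht)
  stay <- g$stays$s1
  expect_equal(stay$mask[, 1],
               c("observed", "held", "held", "missing", "missing", "observed"))
  expect_equal(stay$values[, 1], c(1, 1, 1, NA, NA, 2))
})

test_that("sample-and-hold is idempotent and preserves every observation", {
  cohort <- generate_cohort(cohort_config(channels = make_panel(missing_prob = 0.4),
                                          inject_outliers = FALSE), 10, seed = 22)
  g0 <- discretize(cohort)
  ht <- estimate_hold_times(cohort)
  g1 <- sample_and_hold(g0, ht)
  for (sid in names(g0$stays)) {
    obs <- g0$stays[[sid]]$mask == "observed"
    expect_identical(g1$stays[[sid]]$mask[obs], g0$stays[[sid]]$mask[obs])
    expect_identical(g1$stays[[sid]]$values[obs], g0$stays[[sid]]$values[obs])
    # no backward fill: cells before a channel's first observation stay missing
    for (j in seq_len(ncol(obs))) {
      first <- which(obs[, j])[1]
      if (!is.na(first) && first > 1) {
        expect_true(all(g1$stays[[sid]]$mask[seq_len(first - 1), j] == "missing"))
      }
    }
  }
  g2 <- sample_and_hold(g1, ht)
  expect_identical(g2$stays, g1$stays)
})

test_that("Tukey fences remove the planted extreme and spare clean data", {
  cohort <- cohort_from_times(seq(0, 16, by = 4), values = c(1, 2, 3, 4, 100),
                              duration_h = 20)
  ht <- tibble::tibble(channel = "ch1", hold_time_h = 4)
  g <- sample_and_hold(discretize(cohort), ht) |> remove_outliers_tukey(k = 1.5)
  expect_equal(g$outlier_removals$n_removed, 1L)
  expect_true(is.na(g$stays$s1$values[5, 1]))
  expect_equal(g$stays$s1$values[1:4, 1], c(1, 2, 3, 4))
})

test_that("a constant channel survives the degenerate IQR = 0 fences", {
  cohort <- cohort_from_times(seq(0, 16, by = 4), values = rep(7, 5), duration_h = 20)
  g <- discretize(cohort) |> remove_outliers_tukey()
  expect_equal(g$outlier_removals$n_removed, 0L)
  expect_true(all(g$stays$s1$values[, 1] == 7))
})

test_that("channels with under four finite cells are flagged, not filtered", {
  cohort <- cohort_from_times(c(0, 4), values = c(1, 1e6), duration_h = 8)
  expect_warning(g <- discretize(cohort) |> remove_outliers_tukey(), "skipped")
  expect_true(g$outlier_removals$flagged)
  expect_equal(g$outlier_removals$n_removed, 0L)
})

test_that("values inside their own fences are never removed", {
  cohort <- generate_cohort(cohort_config(channels = make_panel(outlier_prob = 0),
                                          inject_outliers = FALSE), 15, seed = 23)
  g <- sample_and_hold(discretize(cohort), estimate_hold_times(cohort))
  pooled <- lapply(seq_len(3), function(j) {
    unlist(lapply(g$stays, function(s) s$values[s$mask[, j] != "missing", j]))
  })
  gt <- remove_outliers_tukey(g)
  for (j in 1:3) {
    q <- quantile(pooled[[j]], c(0.25, 0.75), type = 7, names = FALSE)
    lo <- q[1] - 1.5 * (q[2] - q[1]); hi <- q[2] + 1.5 * (q[2] - q[1])
    # exactly the cells outside their own fences are removed, no others
    expect_equal(gt$outlier_removals$n_removed[j],
                 sum(pooled[[j]] < lo | pooled[[j]] > hi))
  }
})

test_that("stay filtering uses a strict missing-fraction threshold", {
  # 4-step single-channel stay: observed, held, missing, missing -> fraction 0.5 is kept
  cohort <- cohort_from_times(0, values = 1, duration_h = 16)
  ht <- tibble::tibble(channel = "ch1", hold_time_h = 4)
  g <- sample_and_hold(discretize(cohort), ht)
  expect_equal(mean(g$stays$s1$mask == "missing"), 0.5)
  kept <- filter_stays(g, max_missing_fraction = 0.5)
  expect_length(kept$stays, 1)
  dropped <- filter_stays(g, max_missing_fraction = 0.49)
  expect_length(dropped$stays, 0)
  expect_equal(dropped$discarded_stays, "s1")
})

test_that("kNN imputation honours its forced cases", {
  values <- matrix(c(1, 2, 3,
                     1, 2, NA), nrow = 2, byrow = TRUE,
                   dimnames = list(NULL, paste0("ch", 1:3)))
  mask <- matrix(c(rep("observed", 5), "missing"), nrow = 2, byrow = TRUE)
  stay <- make_gridded_stay(values)
  stay$mask <- mask
  g <- structure(list(stays = list(s1 = stay), channels = make_panel(n_ch = 3),
                      step_hours = 4, hold_times = NULL, outlier_removals = NULL,
                      discarded_stays = character(0)), class = "gridded_cohort")
  out <- impute_missing(g, k = 1)
  # the single complete row forces the fill
  expect_equal(unname(out$stays$s1$values[2, 3]), 3)
  expect_equal(unname(out$stays$s1$mask[2, 3]), "imputed")

  complete <- impute_missing(g, k = 1)
  again <- impute_missing(complete, k = 1)
  expect_identical(again$stays$s1$values, complete$stays$s1$values)
})

test_that("the SVD pass completes an exactly rank-1 matrix", {
  withr::with_seed(24, {
    u <- runif(40, 1, 2); v <- runif(5, 1, 2)
    M <- outer(u, v)
    mask <- matrix("observed", 40, 5)
    deleted <- sample(length(M), 20)
    values <- M; values[deleted] <- NA
    mask[deleted] <- "missing"
  })
  dimnames(values) <- list(NULL, paste0("ch", 1:5))
  stay <- make_gridded_stay(values)
  stay$mask <- mask
  g <- structure(list(stays = list(s1 = stay), channels = make_panel(n_ch = 5),
                      step_hours = 4, hold_times = NULL, outlier_removals = NULL,
                      discarded_stays = character(0)), class = "gridded_cohort")
  out <- impute_missing(g, k = 3, svd_rank = 1)
  expect_lt(max(abs(out$stays$s1$values[deleted] - M[deleted])), 1e-6)
})

test_that("a channel missing everywhere is a named error", {
  values <- matrix(c(1, NA, 2, NA), 2, 2, dimnames = list(NULL, c("ch1", "ch2")))
  mask <- matrix(c("observed", "missing"), 2, 2, byrow = FALSE)
  mask[, 2] <- "missing"
  stay <- make_gridded_stay(values)
  stay$mask <- mask
  g <- structure(list(stays = list(s1 = stay), channels = make_panel(n_ch = 2),
                      step_hours = 4, hold_times = NULL, outlier_removals = NULL,
                      discarded_stays = character(0)), class = "gridded_cohort")
  expect_error(impute_missing(g), "ch2")
})

test_that("the full pipeline leaves no missing cells under varied corruption", {
  for (mp in c(0, 0.3, 0.6)) {
    cohort <- generate_cohort(
      cohort_config(channels = make_panel(n_ch = 4, missing_prob = mp, outlier_prob = 0.02)),
      n_stays = 8, seed = 25 + round(10 * mp)
    )
    g <- preprocess_cohort(cohort)
    for (stay in g$stays) {
      expect_false(any(stay$mask == "missing"))
      expect_true(all(is.finite(stay$values)))
    }
  }
})
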