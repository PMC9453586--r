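test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(channels = make_panel())
  a <- generate_cohort(cfg, n_stays = 6, seed = 11)
  b <- generate_cohort(cfg, n_stays = 6, seed = 11)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$true_state, b$true_state)
  c <- generate_cohort(cfg, n_stays = 6, seed = 12)
  expect_false(identical(a$measurements, c$measurements))
})

test_that("cohorts have unique stay ids, valid demographics and durations", {
  cohort <- generate_cohort(cohort_config(channels = make_panel()), n_stays = 40, seed = 2)
  expect_equal(nrow(cohort$durations), 40)
  expect_equal(anyDuplicated(cohort$durations$stay_id), 0)
  expect_true(all(cohort$durations$n_steps >= 3 & cohort$durations$n_steps <= 18))
  expect_true(all(cohort$demographics$age > 0))
  expect_true(all(cohort$demographics$weight > 0))
  expect_true(all(cohort$demographics$sex %in% c("female", "male")))
  expect_true(all(cohort$measurements$time_h >= 0))
  durs <- cohort$durations$duration_h[match(cohort$measurements$stay_id, cohort$durations$stay_id)]
  expect_true(all(cohort$measurements$time_h < durs))
})

test_that("degenerate dynamics reduce every recorded value to the baseline", {
  panel <- make_panel(ar = 0, episode_rate = 0, baseline_sd = 0,
                      missing_prob = 0, outlier_prob = 0)
  cfg <- cohort_config(channels = panel, obs_noise_sd = 0,
                       inject_missingness = FALSE, inject_outliers = FALSE)
  stay <- simulate_stay(cfg, duration_steps = 10, seed = 3)
  expect_true(all(stay$measurements$value == panel$baseline_mean[1]))
  expect_true(all(stay$true_state$value == panel$baseline_mean[1]))
})

test_that("an episode under persistence 1 is absorbing", {
  panel <- make_panel(n_ch = 2, episode_rate = 0.3, episode_persistence = 1)
  cfg <- cohort_config(channels = panel, inject_missingness = FALSE,
                       inject_outliers = FALSE)
  stay <- simulate_stay(cfg, duration_steps = 18, seed = 4)
  for (ch in panel$channel) {
    ep <- stay$true_state$episode[stay$true_state$channel == ch]
    first <- which(ep)[1]
    if (!is.na(first)) expect_true(all(ep[first:length(ep)]))
  }
})

test_that("long-run abnormality fraction matches the two-state chain's stationary law", {
  # entry 0.1, persistence 0.9 -> stationary episode fraction 0.1/(0.1+0.1) = 0.5
  panel <- make_panel(n_ch = 1, episode_rate = 0.1, episode_persistence = 0.9,
                      missing_prob = 0, outlier_prob = 0)
  cfg <- cohort_config(channels = panel, duration_range = c(3L, 10000L),
                       inject_missingness = FALSE, inject_outliers = FALSE)
  stay <- simulate_stay(cfg, duration_steps = 10000, seed = 5)
  abnormal <- with(stay$true_state, value < panel$normal_low | value > panel$normal_high)
  expect_equal(mean(abnormal), 0.5, tolerance = 0.1)
  expect_lt(abs(mean(stay$true_state$episode) - 0.5), 0.05)
})

test_that("missingness injection is a per-channel Bernoulli thinning", {
  panel <- make_panel(n_ch = 1, missing_prob = 0.3)
  cfg <- cohort_config(channels = panel, inject_missingness = FALSE,
                       inject_outliers = FALSE, jitter_hours = 0,
                       duration_range = c(3L, 1200L))
  stay <- simulate_stay(cfg, duration_steps = 1000, seed = 6)
  n0 <- nrow(stay$measurements)

  none <- inject_missingness(stay, dplyr::mutate(panel, missing_prob = 0), seed = 7)
  expect_identical(none$measurements, stay$measurements)
  all_gone <- inject_missingness(stay, dplyr::mutate(panel, missing_prob = 1), seed = 7)
  expect_equal(nrow(all_gone$measurements), 0)

  thinned <- inject_missingness(stay, panel, seed = 8)
  expected <- 0.7 * n0
  expect_lt(abs(nrow(thinned$measurements) - expected), 3 * sqrt(n0 * 0.3 * 0.7))
})

test_that("outlier injection reports exactly the corrupted rows", {
  panel <- make_panel(n_ch = 1, outlier_prob = 0, missing_prob = 0)
  cfg <- cohort_config(channels = panel, inject_missingness = FALSE,
                       inject_outliers = FALSE, jitter_hours = 0)
  stay <- simulate_stay(cfg, duration_steps = 5, seed = 9)

  res0 <- inject_outliers(stay, panel, magnitude_multiplier = 10, seed = 1)
  expect_length(res0$corrupted, 0)
  expect_identical(res0$stay$measurements, stay$measurements)

  all_panel <- dplyr::mutate(panel, outlier_prob = 1)
  res1 <- inject_outliers(stay, all_panel, magnitude_multiplier = 10, seed = 1)
  expect_length(res1$corrupted, nrow(stay$measurements))
  expect_error(inject_outliers(stay, panel, magnitude_multiplier = 1), "multiplier")
})

test_that("multiplier-10 outliers land outside Tukey fences of the clean sample", {
  panel <- make_panel(n_ch = 1, missing_prob = 0, outlier_prob = 0.3)
  cfg <- cohort_config(channels = panel, inject_missingness = FALSE,
                       inject_outliers = FALSE, jitter_hours = 0,
                       duration_range = c(3L, 300L))
  stay <- simulate_stay(cfg, duration_steps = 200, seed = 10)
  clean <- stay$measurements$value
  res <- inject_outliers(stay, panel, magnitude_multiplier = 10, seed = 11)
  expect_gt(length(res$corrupted), 0)
  q <- quantile(clean, c(0.25, 0.75), type = 7, names = FALSE)
  fences <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
  corrupted_vals <- res$stay$measurements$value[res$corrupted]
  expect_true(all(corrupted_vals < fences[1] | corrupted_vals > fences[2]))
})

test_that("stay durations are uniform over the configured step range", {
  cfg <- cohort_config(channels = make_panel(n_ch = 1), inject_missingness = FALSE,
                       inject_outliers = FALSE)
  cohort <- generate_cohort(cfg, n_stays = 1000, seed = 13)
  # discrete uniform on 3..18 has mean 10.5, sd ~4.61
  expect_equal(mean(cohort$durations$n_steps), 10.5, tolerance = 0.05)
  expect_true(all(cohort$durations$n_steps %in% 3:18))
})

test_that("marginal abnormality rate is monotone in the episode entry rate", {
  fracs <- vapply(c(0.02, 0.1, 0.3), function(rate) {
    panel <- make_panel(n_ch = 1, episode_rate = rate, missing_prob = 0, outlier_prob = 0)
    cfg <- cohort_config(channels = panel, duration_range = c(3L, 4000L),
                         inject_missingness = FALSE, inject_outliers = FALSE)
    stay <- simulate_stay(cfg, duration_steps = 4000, seed = 14)
    with(stay$true_state, mean(value < panel$normal_low | value > panel$normal_high))
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("the persistence predictor clears the learnability floor", {
  panel <- make_panel(n_ch = 5, episode_persistence = 0.92, episode_rate = 0.05)
  cfg <- cohort_config(channels = panel, obs_noise_sd = 0.05,
                       inject_missingness = FALSE, inject_outliers = FALSE)
  cohort <- generate_cohort(cfg, n_stays = 150, seed = 15)
  expect_gte(persistence_baseline(cohort)$f1, 0.8)
})

test_that("cohorts round-trip through the CSV/YAML schema", {
  cohort <- generate_cohort(cohort_config(channels = make_panel()), n_stays = 4, seed = 16)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir, true_state = TRUE)
  expect_true(all(file.exists(file.path(dir, c("measurements.csv", "demographics.csv", "channels.yaml")))))
  back <- read_cohort(dir)
  expect_equal(back$measurements$value, cohort$measurements$value, tolerance = 1e-6)
  expect_equal(back$measurements$channel, cohort$measurements$channel)
  expect_equal(back$channels$normal_low, cohort$channels$normal_low)
  expect_equal(nrow(back$true_state), nrow(cohort$true_state))
})
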