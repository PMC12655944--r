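test_that("comatose profile concentrates PSD power at 1-7 Hz", {
  set.seed(1)
  sig <- synthesize_segment(comatose_profile(), sampling_rate = 200)
  fracs <- apply(sig, 1, oracle_band_fraction, fs = 200, band = c(1, 7))
  expect_true(all(fracs >= 0.70))
})

test_that("alpha-dominant profile inverts the band ordering", {
  set.seed(2)
  sig <- synthesize_segment(healthy_profile(), sampling_rate = 200)
  alpha <- apply(sig, 1, oracle_band_fraction, fs = 200, band = c(8, 13))
  delta <- apply(sig, 1, oracle_band_fraction, fs = 200, band = c(1, 4))
  expect_true(mean(alpha) > mean(delta))
})

test_that("degenerate profile with no generating terms is silent", {
  p <- spectral_profile(c(delta = 0, theta = 0, alpha = 0, beta = 0),
                        noise_sd = 0)
  sig <- synthesize_segment(p, sampling_rate = 100)
  expect_true(all(sig == 0))
  expect_identical(dim(sig), c(20L, 200L))
})

test_that("segment shape, rate validation and effect-channel checks hold", {
  set.seed(3)
  sig <- synthesize_segment(comatose_profile(), sampling_rate = 128,
                            duration = 2)
  expect_identical(dim(sig), c(20L, 256L))
  expect_identical(rownames(sig), eeg_channels())
  expect_error(synthesize_segment(comatose_profile(), sampling_rate = 50),
               class = "comafusion_config_error")
  expect_silent(synthesize_segment(comatose_profile(), sampling_rate = 50,
                                   check_rate = FALSE))
  expect_error(synthesize_segment(comatose_profile(), sampling_rate = 100,
                                  effect_channels = "XX"))
})

test_that("segment synthesis is deterministic given the random state", {
  set.seed(99); a <- synthesize_segment(comatose_profile(), 100)
  set.seed(99); b <- synthesize_segment(comatose_profile(), 100)
  expect_identical(a, b)
})

test_that("cohort generation conserves the configured cell counts", {
  counts <- tibble::tibble(etiology = c("Stroke", "Neoplasia", "Hydrocephalus"),
                           favorable = c(6, 3, 0), unfavorable = c(3, 0, 6))
  cfg <- cohort_config(n_patients = 6, segments_per_patient = 3,
                       sampling_rate = 100, etiology_outcome_counts = counts,
                       sex_counts = c(male = 4, female = 2), seed = 4)
  coh <- generate_cohort(cfg)
  got <- dplyr::count(coh$segments, etiology, outcome)
  for (i in seq_len(nrow(got))) {
    expected <- counts[[got$outcome[i]]][counts$etiology == got$etiology[i]]
    expect_equal(got$n[i], expected)
  }
  expect_equal(nrow(coh$segments), 18)
  expect_true(all(coh$patients$age > 0))
  expect_equal(as.integer(table(coh$patients$sex)[c("male", "female")]),
               c(4L, 2L))
})

test_that("an indivisible cell count is rejected naming the cell", {
  cfg <- cohort_config(n_patients = 2, segments_per_patient = 10,
                       sampling_rate = 100,
                       etiology_outcome_counts = tibble::tibble(
                         etiology = c("Stroke"), favorable = 15,
                         unfavorable = 5),
                       sex_counts = c(male = 1, female = 1))
  expect_error(generate_cohort(cfg), "Stroke.*favorable",
               class = "comafusion_config_error")
})

test_that("an empty cohort is empty, not an error", {
  cfg <- cohort_config(n_patients = 0, segments_per_patient = 10,
                       sampling_rate = 100,
                       etiology_outcome_counts = tibble::tibble(
                         etiology = "Stroke", favorable = 0, unfavorable = 0),
                       sex_counts = c(male = 0, female = 0))
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$patients), 0)
  expect_equal(nrow(coh$segments), 0)
})

test_that("identical configurations give bit-identical cohorts", {
  cfg <- two_class_config(n_per_class = 2, segments_per_patient = 2, seed = 8)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$segments$signal, b$segments$signal)
})

test_that("planted amplitude effect matches a direct RMS oracle within 5%", {
  cfg <- two_class_config(n_per_class = 10, effect_size = 1.5,
                          age_outcome_shift = 0, seed = 12)
  coh <- generate_cohort(cfg)
  expect_gte(nrow(coh$segments), 200)
  rms <- function(sig) {
    mean(apply(sig[cfg$effect_channels, , drop = FALSE], 1,
               function(x) sqrt(mean(x^2))))
  }
  by_class <- tapply(vapply(coh$segments$signal, rms, numeric(1)),
                     coh$segments$outcome, mean)
  ratio <- by_class[["unfavorable"]] / by_class[["favorable"]]
  expect_lt(abs(ratio - 1.5) / 1.5, 0.05)
})

test_that("effect_size 1 plants no spectral difference between classes", {
  cfg <- two_class_config(n_per_class = 8, effect_size = 1,
                          age_outcome_shift = 0, seed = 13)
  coh <- generate_cohort(cfg)
  lowfrac <- vapply(coh$segments$signal, function(sig) {
    mean(apply(sig, 1, function(x) {
      band_power(x, cfg$sampling_rate, c(1, 7)) /
        band_power(x, cfg$sampling_rate, c(0.5, 45))
    }))
  }, numeric(1))
  by_class <- tapply(lowfrac, coh$segments$outcome, mean)
  expect_lt(abs(by_class[["unfavorable"]] - by_class[["favorable"]]), 0.02)
})

test_that("cohorts round-trip through the CSV layout", {
  coh <- generate_cohort(two_class_config(n_per_class = 2,
                                          segments_per_patient = 2, seed = 30))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("patients.csv", "segments.csv",
                                               "signals.csv")))))
  back <- read_cohort(dir)
  expect_equal(back$patients$patient_id, coh$patients$patient_id)
  expect_equal(back$patients$age, coh$patients$age, tolerance = 1e-6)
  expect_equal(back$segments$outcome, coh$segments$outcome)
  for (i in seq_len(nrow(coh$segments))) {
    expect_equal(back$segments$signal[[i]], coh$segments$signal[[i]],
                 tolerance = 1e-6)
  }
})
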