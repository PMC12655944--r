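#' Standard 20-channel montage of the 10-20 system
#'
#' Electrode labels, in fixed order, for the 20-channel EEG cap assumed
#' throughout the package. The order defines the channel axis of every
#' segment matrix and the channel-major ordering of time-domain features.
#'
#' @return Character vector of 20 montage labels (`FP1` ... `O2`).
#' @export
#' @examples
#' eeg_channels()
eeg_channels <- function() {
  c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8", "T3", "C3", "CZ",
    "C4", "T4", "T5", "P3", "PZ", "P4", "T6", "O1", "OZ", "O2")
}

#' Conventional EEG frequency bands
#'
#' @return Named list of `c(lo, hi)` band edges in Hz for delta (1-4),
#'   theta (4-7), alpha (8-13) and beta (13-30).
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 7), alpha = c(8, 13), beta = c(13, 30))
}

#' Spectral profile of a synthetic EEG class
#'
#' Describes the band-power composition of synthesized signals: relative
#' power weights over the four conventional bands, broadband noise, and an
#' overall amplitude. Weights are relative; they are normalized to sum to 1
#' at synthesis time, and the fraction of (noise-free) signal power falling
#' in band `b` equals its normalized weight.
#'
#' @param band_weights Named numeric of non-negative relative power weights
#'   for `delta`, `theta`, `alpha`, `beta`. At least one must be positive
#'   unless all are zero (which, with `noise_sd = 0`, yields silence).
#' @param noise_sd Standard deviation of additive white noise, in microvolts.
#' @param amplitude_scale Root-mean-square amplitude of the band-limited
#'   part of the signal, in microvolts.
#' @param amplitude_jitter Log-scale standard deviation of a per-channel,
#'   per-segment multiplicative amplitude factor (log-normal, median 1),
#'   emulating the natural fluctuation of EEG power between segments; 0
#'   disables it. Band-power fractions are unaffected.
#' @return A `spectral_profile` object.
#' @export
#' @examples
#' spectral_profile(c(delta = 0.55, theta = 0.30, alpha = 0.10, beta = 0.05))
spectral_profile <- function(band_weights, noise_sd = 2, amplitude_scale = 20,
                             amplitude_jitter = 0.2) {
  bands <- names(eeg_bands())
  assert_that(all(bands %in% names(band_weights)),
              "band_weights must name delta, theta, alpha and beta")
  w <- as.numeric(band_weights[bands])
  assert_that(all(is.finite(w)) && all(w >= 0),
              "band_weights must be non-negative and finite")
  assert_that(noise_sd >= 0 && amplitude_scale >= 0 && amplitude_jitter >= 0,
              "noise_sd, amplitude_scale and amplitude_jitter must be non-negative")
  structure(list(band_weights = setNames(w, bands),
                 noise_sd = noise_sd,
                 amplitude_scale = amplitude_scale,
                 amplitude_jitter = amplitude_jitter),
            class = "spectral_profile")
}

#' Comatose and alpha-dominant reference profiles
#'
#' `comatose_profile()` concentrates power at low frequencies (delta and
#' theta, 1-7 Hz), the hallmark of comatose EEG; `healthy_profile()` is an
#' alpha-dominant contrast resembling an awake resting recording.
#'
#' @param noise_sd,amplitude_scale,amplitude_jitter Passed to [spectral_profile()].
#' @return A `spectral_profile`.
#' @export
comatose_profile <- function(noise_sd = 2, amplitude_scale = 20,
                             amplitude_jitter = 0.2) {
  spectral_profile(c(delta = 0.55, theta = 0.30, alpha = 0.10, beta = 0.05),
                   noise_sd = noise_sd, amplitude_scale = amplitude_scale,
                   amplitude_jitter = amplitude_jitter)
}

#' @rdname comatose_profile
#' @export
healthy_profile <- function(noise_sd = 2, amplitude_scale = 20,
                            amplitude_jitter = 0.2) {
  spectral_profile(c(delta = 0.10, theta = 0.15, alpha = 0.60, beta = 0.15),
                   noise_sd = noise_sd, amplitude_scale = amplitude_scale,
                   amplitude_jitter = amplitude_jitter)
}

#' Etiology-by-outcome segment counts of the reference cohort
#'
#' Segment counts per coma etiology and outcome for the 60-patient,
#' 600-segment reference cohort (10 segments per patient; favorable =
#' survival, unfavorable = death).
#'
#' @return Tibble with columns `etiology`, `favorable`, `unfavorable`.
#' @export
reference_etiology_counts <- function() {
  tibble::tribble(
    ~etiology,                      ~favorable, ~unfavorable,
    "Traumatic Brain Injury",              170,           30,
    "Metabolic Coma",                       50,          130,
    "Stroke",                               50,           70,
    "Post Anoxic Encephalopathy",           20,            0,
    "Neoplasia",                             0,           20,
    "Hydroelectrolytic Disorders",          10,            0,
    "Firearm Injury",                        0,           10,
    "Chronic Subdural Hematoma",             0,           10,
    "Hydrocephalus",                         0,           10,
    "Hypoxic Encephalopathy",                0,           10,
    "Neurocysticercosis",                    0,           10
  )
}

#' Configure a synthetic comatose cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults
#' replicate the composition of the reference study cohort: 60 patients with
#' 10 two-second segments each (600 segments), the etiology-by-outcome
#' segment counts of [reference_etiology_counts()] (300 favorable / 300
#' unfavorable), ages 49.16 +/- 19.18 years truncated to 18-95, 44 males
#' and 16 females, and delta/theta-dominant spectra in both classes.
#'
#' The outcome manifests in the signal as an amplitude ratio: on
#' `effect_channels` (right-anterior/central electrodes by default),
#' unfavorable-outcome segments are scaled by `effect_size`. `effect_size
#' = 1` plants no signal. An optional age-outcome association shifts the
#' mean age of unfavorable patients up by `age_outcome_shift` years (and
#' favorable down by the same amount), keeping the overall mean; the default
#' 10-year shift emulates the clinically expected poorer recovery of older
#' patients.
#'
#' @param n_patients,segments_per_patient Cohort size.
#' @param sampling_rate Sampling rate in Hz; the study's recordings span
#'   100-600 Hz, and rates outside that range are rejected unless
#'   `check_rate = FALSE`.
#' @param duration Segment length in seconds (fixed at 2 s in the study).
#' @param etiology_outcome_counts Tibble like [reference_etiology_counts()]
#'   giving segment counts per (etiology, outcome) cell. Each cell must be
#'   divisible by `segments_per_patient`.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param age_outcome_shift Years separating the class age means (see above).
#' @param sex_counts Named counts (`male`, `female`) summing to `n_patients`.
#' @param class_profiles Named list mapping `favorable`/`unfavorable` to a
#'   [spectral_profile()].
#' @param effect_channels Channels carrying the planted outcome effect.
#' @param effect_size Amplitude ratio unfavorable / favorable on the effect
#'   channels.
#' @param check_rate Set `FALSE` to allow sampling rates outside 100-600 Hz.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A `cohort_config` object.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_patients
cohort_config <- function(n_patients = 60,
                          segments_per_patient = 10,
                          sampling_rate = 250,
                          duration = 2,
                          etiology_outcome_counts = reference_etiology_counts(),
                          age_mean = 49.16,
                          age_sd = 19.18,
                          age_range = c(18, 95),
                          age_outcome_shift = 10,
                          sex_counts = c(male = 44, female = 16),
                          class_profiles = list(favorable = comatose_profile(),
                                                unfavorable = comatose_profile()),
                          effect_channels = c("T6", "F4", "T4", "O2", "FZ", "CZ"),
                          effect_size = 1.5,
                          check_rate = TRUE,
                          seed = 1L) {
  if (check_rate) {
    assert_that(sampling_rate >= 100 && sampling_rate <= 600,
                "sampling_rate must lie in [100, 600] Hz (set check_rate = FALSE to override)",
                class = "comafusion_config_error")
  }
  assert_that(all(effect_channels %in% eeg_channels()),
              "effect_channels must be a subset of eeg_channels()")
  assert_that(all(c("male", "female") %in% names(sex_counts)) &&
                sum(sex_counts) == n_patients,
              "sex_counts must name male and female and sum to n_patients")
  assert_that(all(c("favorable", "unfavorable") %in% names(class_profiles)),
              "class_profiles must map favorable and unfavorable")
  assert_that(effect_size > 0, "effect_size must be positive")
  structure(list(n_patients = n_patients,
                 segments_per_patient = segments_per_patient,
                 sampling_rate = sampling_rate,
                 duration = duration,
                 etiology_outcome_counts = etiology_outcome_counts,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 age_outcome_shift = age_outcome_shift,
                 sex_counts = sex_counts,
                 class_profiles = class_profiles,
                 effect_channels = effect_channels,
                 effect_size = effect_size,
                 check_rate = check_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Synthesize one multichannel EEG segment
#'
#' Builds a channels-by-samples matrix as a sum of band-limited sinusoids
#' with random frequencies and phases per channel, weighted so the fraction
#' of sinusoidal power in each band equals the profile's normalized band
#' weight, plus white noise. Channels listed in `effect_channels` are scaled
#' by `effect_size` (the whole channel, so the RMS ratio is exact in
#' expectation). Consumes the current R random stream: seed the stream for
#' reproducibility.
#'
#' @param profile A [spectral_profile()].
#' @param sampling_rate Hz; must lie in 100-600 unless `check_rate = FALSE`.
#' @param duration Seconds.
#' @param channel_labels Channel names (rows of the output).
#' @param effect_channels Subset of `channel_labels` scaled by `effect_size`.
#' @param effect_size Amplitude multiplier for effect channels.
#' @param n_components Sinusoids drawn per band and channel.
#' @param check_rate Set `FALSE` to allow out-of-range sampling rates.
#' @return Numeric matrix `length(channel_labels)` x `round(sampling_rate *
#'   duration)` in microvolts, rownames = `channel_labels`.
#' @export
#' @examples
#' set.seed(1)
#' x <- synthesize_segment(comatose_profile(), sampling_rate = 100)
#' dim(x)
synthesize_segment <- function(profile, sampling_rate, duration = 2,
                               channel_labels = eeg_channels(),
                               effect_channels = character(),
                               effect_size = 1,
                               n_components = 3L,
                               check_rate = TRUE) {
  assert_that(inherits(profile, "spectral_profile"), "profile must be a spectral_profile")
  if (check_rate) {
    assert_that(sampling_rate >= 100 && sampling_rate <= 600,
                "sampling_rate must lie in [100, 600] Hz (set check_rate = FALSE to override)",
                class = "comafusion_config_error")
  }
  n <- round(sampling_rate * duration)
  assert_that(n >= 2, "duration x sampling_rate must give at least 2 samples")
  assert_that(all(effect_channels %in% channel_labels),
              "effect_channels must be a subset of channel_labels")
  bands <- eeg_bands()
  w <- profile$band_weights
  wn <- if (sum(w) > 0) w / sum(w) else w
  t_axis <- (seq_len(n) - 1) / sampling_rate
  n_ch <- length(channel_labels)
  sig <- matrix(0, nrow = n_ch, ncol = n, dimnames = list(channel_labels, NULL))
  for (ch in seq_len(n_ch)) {
    x <- numeric(n)
    jitter <- if (profile$amplitude_jitter > 0)
      exp(rnorm(1, 0, profile$amplitude_jitter)) else 1
    for (b in names(bands)) {
      if (wn[[b]] <= 0) next
      # frequencies on the segment's FFT bin grid (k / duration), so band
      # power does not leak across band edges in short windows
      kmin <- ceiling(bands[[b]][1] * duration)
      kmax <- max(kmin, floor(bands[[b]][2] * duration) - 1L)
      bins <- seq(kmin, kmax)
      freqs <- sample_from(bins, n_components,
                           replace = length(bins) < n_components) / duration
      phases <- runif(n_components, 0, 2 * pi)
      comp <- numeric(n)
      for (j in seq_len(n_components)) {
        comp <- comp + sin(2 * pi * freqs[j] * t_axis + phases[j])
      }
      # each sinusoid has RMS 1/sqrt(2); sqrt(2/n_components) makes the band
      # component unit-RMS, sqrt(wn) then allocates the power fraction
      x <- x + jitter * profile$amplitude_scale * sqrt(wn[[b]]) *
        sqrt(2 / n_components) * comp
    }
    if (profile$noise_sd > 0) x <- x + rnorm(n, sd = profile$noise_sd)
    if (channel_labels[ch] %in% effect_channels) x <- x * effect_size
    sig[ch, ] <- x
  }
  sig
}

#' Generate a synthetic comatose-patient cohort
#'
#' Emits a patient table and a segment collection with exactly the
#' etiology-by-outcome composition of the configuration. Each synthetic
#' patient carries one etiology and one outcome; patient counts per cell are
#' the configured segment counts divided by `segments_per_patient` (an
#' indivisible cell is an error naming the cell). The whole cohort is a
#' deterministic function of the configuration, including its seed; the
#' caller's random stream is left untouched.
#'
#' @param config A [cohort_config()].
#' @return An `eeg_cohort`: list with
#'   * `patients` — tibble `patient_id`, `age`, `sex`, `etiology`, `outcome`;
#'   * `segments` — tibble `patient_id`, `segment_index` (0-based),
#'     `etiology`, `outcome`, `sampling_rate`, and list-column `signal` of
#'     channels-by-samples matrices;
#'   * `config` — the configuration used.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(
#'   n_patients = 2, segments_per_patient = 2, sampling_rate = 100,
#'   etiology_outcome_counts = tibble::tibble(
#'     etiology = c("Stroke", "Metabolic Coma"),
#'     favorable = c(2, 0), unfavorable = c(0, 2)),
#'   sex_counts = c(male = 1, female = 1), seed = 7))
#' coh$patients
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  counts <- config$etiology_outcome_counts
  spp <- config$segments_per_patient
  long <- tidyr::pivot_longer(counts, c("favorable", "unfavorable"),
                              names_to = "outcome", values_to = "n_segments")
  long <- dplyr::filter(long, .data$n_segments > 0)
  bad <- dplyr::filter(long, .data$n_segments %% spp != 0)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "etiology_outcome_counts cell (%s, %s) = %d is not divisible by segments_per_patient = %d",
      bad$etiology[1], bad$outcome[1], bad$n_segments[1], spp),
      class = "comafusion_config_error")
  }
  long$n_patients <- long$n_segments %/% spp
  total_patients <- sum(long$n_patients)
  assert_that(total_patients == config$n_patients,
              sprintf("etiology_outcome_counts imply %d patients but n_patients = %d",
                      total_patients, config$n_patients),
              class = "comafusion_config_error")

  if (config$n_patients == 0) {
    return(structure(list(
      patients = tibble::tibble(patient_id = character(), age = numeric(),
                                sex = character(), etiology = character(),
                                outcome = character()),
      segments = tibble::tibble(patient_id = character(), segment_index = integer(),
                                etiology = character(), outcome = character(),
                                sampling_rate = numeric(), signal = list()),
      config = config), class = "eeg_cohort"))
  }

  with_local_seed(config$seed, {
    patients <- tidyr::uncount(
      dplyr::select(long, "etiology", "outcome", "n_patients"),
      weights = .data$n_patients)
    patients$patient_id <- sprintf("P%03d", seq_len(nrow(patients)))
    # sex assignment: marginal counts only, independent of outcome
    sexes <- rep(c("male", "female"),
                 times = c(config$sex_counts[["male"]], config$sex_counts[["female"]]))
    patients$sex <- sample(sexes)
    shift <- ifelse(patients$outcome == "unfavorable",
                    config$age_outcome_shift / 2, -config$age_outcome_shift / 2)
    patients$age <- vapply(shift, function(s) {
      rtruncnorm1(config$age_mean + s, config$age_sd, config$age_range)
    }, numeric(1))
    patients <- tibble::as_tibble(
      patients[, c("patient_id", "age", "sex", "etiology", "outcome")])

    segs <- tidyr::expand_grid(patient_id = patients$patient_id,
                               segment_index = seq_len(spp) - 1L)
    segs <- dplyr::left_join(segs,
                             patients[, c("patient_id", "etiology", "outcome")],
                             by = "patient_id")
    segs$sampling_rate <- config$sampling_rate
    segs$signal <- purrr::map(seq_len(nrow(segs)), function(i) {
      out <- segs$outcome[i]
      eff <- if (out == "unfavorable") config$effect_size else 1
      synthesize_segment(config$class_profiles[[out]],
                         sampling_rate = config$sampling_rate,
                         duration = config$duration,
                         effect_channels = config$effect_channels,
                         effect_size = eff,
                         check_rate = config$check_rate)
    })
    structure(list(patients = patients, segments = tibble::as_tibble(segs),
                   config = config),
              class = "eeg_cohort")
  })
}

# one truncated-normal draw by rejection (bounds are loose: a handful of tries)
rtruncnorm1 <- function(mean, sd, range) {
  for (i in 1:10000) {
    x <- rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  abort("truncated-normal rejection sampling failed; check age_range")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d patients, %d segments (%g Hz, %g s)\n",
              nrow(x$patients), nrow(x$segments),
              x$config$sampling_rate, x$config$duration))
  print(dplyr::count(x$patients, .data$etiology, .data$outcome))
  invisible(x)
}

#' Band power of a single channel
#'
#' Integrates the raw periodogram (squared FFT magnitude) of one channel
#' over a frequency band. Used to check the spectral contract of synthetic
#' segments.
#'
#' @param x Numeric vector (one channel's samples).
#' @param sampling_rate Hz.
#' @param band `c(lo, hi)` in Hz, or a band name from [eeg_bands()].
#' @return Power (sum of periodogram ordinates) in the band.
#' @export
band_power <- function(x, sampling_rate, band) {
  if (is.character(band)) band <- eeg_bands()[[band]]
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * sampling_rate / n
  keep <- freqs >= band[1] & freqs < band[2] & freqs <= sampling_rate / 2
  sum(p[keep])
}

#' Write / read a cohort as plain-text files
#'
#' Serializes a cohort to a directory: `patients.csv` (one row per patient),
#' `segments.csv` (one row per segment: `patient_id`, `segment_index`,
#' `etiology`, `outcome`, `sampling_rate`, `n_samples`) and `signals.csv`
#' (long format: one row per channel per segment, samples as columns
#' `s1...sN`). `read_cohort()` inverts the layout.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` an
#'   `eeg_cohort` (without the generating `config`).
#' @export
write_cohort <- function(cohort, dir) {
  assert_that(inherits(cohort, "eeg_cohort"), "cohort must be an eeg_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  seg_meta <- dplyr::mutate(
    dplyr::select(cohort$segments, -"signal"),
    n_samples = vapply(cohort$segments$signal, ncol, integer(1)))
  utils::write.csv(seg_meta, file.path(dir, "segments.csv"), row.names = FALSE)
  rows <- purrr::map2(cohort$segments$signal,
                      seq_len(nrow(cohort$segments)), function(sig, i) {
    cbind(data.frame(patient_id = cohort$segments$patient_id[i],
                     segment_index = cohort$segments$segment_index[i],
                     channel = rownames(sig)),
          as.data.frame(sig, col.names = paste0("s", seq_len(ncol(sig)))))
  })
  signals <- dplyr::bind_rows(rows)
  names(signals)[-(1:3)] <- paste0("s", seq_len(ncol(signals) - 3))
  utils::write.csv(signals, file.path(dir, "signals.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  patients <- tibble::as_tibble(utils::read.csv(file.path(dir, "patients.csv")))
  seg_meta <- tibble::as_tibble(utils::read.csv(file.path(dir, "segments.csv")))
  signals <- utils::read.csv(file.path(dir, "signals.csv"))
  key <- paste(signals$patient_id, signals$segment_index)
  sig_list <- purrr::map2(seg_meta$patient_id, seg_meta$segment_index, function(p, i) {
    block <- signals[key == paste(p, i), , drop = FALSE]
    m <- as.matrix(block[, -(1:3), drop = FALSE])
    rownames(m) <- block$channel
    colnames(m) <- NULL
    m
  })
  seg_meta$n_samples <- NULL
  seg_meta$signal <- sig_list
  structure(list(patients = patients, segments = seg_meta, config = NULL),
            class = "eeg_cohort")
}
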