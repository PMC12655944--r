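#' Time-domain features of one EEG segment
#'
#' Computes the five per-channel time-domain statistics — mean, minimum,
#' maximum, standard deviation and variance — for every channel of a
#' segment, in channel-major order (all five statistics of channel 1, then
#' channel 2, ...). Variance and standard deviation use the population
#' convention (divide by the number of samples, not N - 1).
#'
#' @param signal Channels-by-samples numeric matrix with channel rownames,
#'   or a one-row segment slice from an `eeg_cohort`.
#' @return Named numeric vector of length `5 * nrow(signal)`, names
#'   `"<CHANNEL>_<stat>"` with stat in `mean`, `min`, `max`, `std`, `var`.
#' @export
#' @examples
#' m <- matrix(1:8, nrow = 2, dimnames = list(c("C3", "C4"), NULL))
#' extract_td_features(m)
extract_td_features <- function(signal) {
  assert_that(is.matrix(signal) && is.numeric(signal), "signal must be a numeric matrix")
  assert_that(ncol(signal) >= 2, "signal needs at least 2 samples per channel")
  if (anyNA(signal)) abort("signal contains NA values", class = "comafusion_data_error")
  chans <- rownames(signal) %||% paste0("CH", seq_len(nrow(signal)))
  n <- ncol(signal)
  mu <- rowMeans(signal)
  v <- rowMeans(signal^2) - mu^2      # population variance
  v <- pmax(v, 0)                     # guard tiny negative rounding
  stats_mat <- cbind(mean = mu,
                     min = apply(signal, 1, min),
                     max = apply(signal, 1, max),
                     std = sqrt(v),
                     var = v)
  out <- as.numeric(t(stats_mat))
  names(out) <- as.vector(t(outer(chans, colnames(stats_mat), paste, sep = "_")))
  out
}

#' Time-domain feature matrix for a segment collection
#'
#' @param segments Segment tibble from an `eeg_cohort` (needs `patient_id`,
#'   `segment_index`, `signal`).
#' @return Tibble: `patient_id`, `segment_index`, then one column per
#'   time-domain feature in registry order.
#' @export
td_feature_matrix <- function(segments) {
  feats <- purrr::map(segments$signal, extract_td_features)
  mat <- do.call(rbind, feats)
  dplyr::bind_cols(segments[, c("patient_id", "segment_index")],
                   tibble::as_tibble(mat))
}

#' Categorical schema for patient features
#'
#' Fixes the category levels used by one-hot encoding. With the default
#' 2-level sex and 11-level etiology schema, the encoded patient vector has
#' length 14 (age + 2 + 11).
#'
#' @param sex_levels,etiology_levels Character vectors of allowed levels.
#' @return A `patient_schema` object.
#' @export
patient_schema <- function(sex_levels = c("male", "female"),
                           etiology_levels = reference_etiology_counts()$etiology) {
  assert_that(length(sex_levels) >= 1 && length(etiology_levels) >= 1,
              "schema levels must be non-empty")
  structure(list(sex_levels = sex_levels, etiology_levels = etiology_levels),
            class = "patient_schema")
}

# stable column-safe name for an etiology level
etiology_feature_name <- function(x) paste0("etiology_", gsub("[^A-Za-z0-9]+", "_", x))

#' One-hot encode a patient record
#'
#' Encodes age as-is and sex / etiology as one-hot blocks in schema order.
#' A category absent from the schema is an error naming the label — never a
#' silent zero block. Outcome is the prediction target and is never encoded
#' as a feature.
#'
#' @param record One-row data frame (or list) with `age`, `sex`, `etiology`.
#' @param schema A [patient_schema()].
#' @return Named numeric vector: `age`, `sex_<level>`..., `etiology_<level>`...
#' @export
#' @examples
#' encode_patient_features(list(age = 60, sex = "male", etiology = "Stroke"),
#'                         patient_schema())
encode_patient_features <- function(record, schema = patient_schema()) {
  assert_that(inherits(schema, "patient_schema"), "schema must be a patient_schema")
  sex <- as.character(record$sex)
  eti <- as.character(record$etiology)
  if (!sex %in% schema$sex_levels) {
    abort(sprintf("unknown sex level '%s' (schema: %s)", sex,
                  paste(schema$sex_levels, collapse = ", ")),
          class = "comafusion_schema_error")
  }
  if (!eti %in% schema$etiology_levels) {
    abort(sprintf("unknown etiology label '%s'", eti),
          class = "comafusion_schema_error")
  }
  out <- c(age = as.numeric(record$age),
           setNames(as.numeric(schema$sex_levels == sex),
                    paste0("sex_", schema$sex_levels)),
           setNames(as.numeric(schema$etiology_levels == eti),
                    etiology_feature_name(schema$etiology_levels)))
  out
}

#' Build the multimodal feature registry
#'
#' The registry fixes the ordered index space over which GA feature masks
#' operate: the patient block first (age, one-hot sex, one-hot etiology),
#' then the time-domain block in channel-major order. With the default
#' schema and the 20-channel montage the registry holds 14 + 100 = 114
#' names.
#'
#' @param schema A [patient_schema()].
#' @param channel_labels Channel names of the montage.
#' @return A `feature_registry`: tibble with columns `name` and `block`
#'   (`"patient"` or `"td"`).
#' @export
#' @examples
#' nrow(build_registry())
build_registry <- function(schema = patient_schema(),
                           channel_labels = eeg_channels()) {
  p_names <- c("age",
               paste0("sex_", schema$sex_levels),
               etiology_feature_name(schema$etiology_levels))
  td_names <- as.vector(t(outer(channel_labels,
                                c("mean", "min", "max", "std", "var"),
                                paste, sep = "_")))
  reg <- tibble::tibble(name = c(p_names, td_names),
                        block = c(rep("patient", length(p_names)),
                                  rep("td", length(td_names))))
  assert_that(!anyDuplicated(reg$name), "registry names must be unique")
  structure(reg, class = c("feature_registry", class(reg)))
}

#' Assemble the fused auxiliary feature matrix for a cohort
#'
#' One row per segment, columns in registry order: the patient features
#' (repeated across a patient's segments) followed by the segment's
#' time-domain features.
#'
#' @param cohort An `eeg_cohort`.
#' @param registry A [build_registry()] result.
#' @param schema The [patient_schema()] matching the registry.
#' @return Tibble: `patient_id`, `segment_index`, `outcome`, then one column
#'   per registry feature.
#' @export
assemble_feature_matrix <- function(cohort, registry = build_registry(),
                                    schema = patient_schema()) {
  pat <- cohort$patients
  p_feats <- do.call(rbind, purrr::map(seq_len(nrow(pat)), function(i) {
    encode_patient_features(pat[i, ], schema)
  }))
  p_tbl <- dplyr::bind_cols(pat[, "patient_id"], tibble::as_tibble(p_feats))
  td <- td_feature_matrix(cohort$segments)
  out <- dplyr::left_join(
    dplyr::left_join(cohort$segments[, c("patient_id", "segment_index", "outcome")],
                     p_tbl, by = "patient_id"),
    td, by = c("patient_id", "segment_index"))
  got <- setdiff(names(out), c("patient_id", "segment_index", "outcome"))
  assert_that(identical(got, registry$name),
              "assembled feature columns do not match the registry order")
  out
}

#' Apply a binary feature mask
#'
#' Keeps the features whose mask entry is 1, preserving order. Accepts a
#' named numeric vector, a plain matrix, or a feature tibble (whose key
#' columns `patient_id`, `segment_index`, `outcome` pass through untouched).
#'
#' @param features Vector, matrix, or feature tibble.
#' @param mask Integer/logical vector over the feature columns.
#' @return Same shape as the input, reduced to the selected features.
#' @export
#' @examples
#' apply_mask(c(a = 1, b = 2, c = 3), c(1, 0, 1))
apply_mask <- function(features, mask) {
  mask <- as.integer(mask)
  assert_that(!anyNA(mask) && all(mask %in% c(0L, 1L)), "mask entries must be 0 or 1")
  keep <- mask == 1L
  if (is.data.frame(features)) {
    key <- intersect(c("patient_id", "segment_index", "outcome"), names(features))
    feat_cols <- setdiff(names(features), key)
    assert_that(length(feat_cols) == length(mask),
                "mask length must equal the number of feature columns")
    features[, c(key, feat_cols[keep]), drop = FALSE]
  } else if (is.matrix(features)) {
    assert_that(ncol(features) == length(mask),
                "mask length must equal the number of feature columns")
    features[, keep, drop = FALSE]
  } else {
    assert_that(length(features) == length(mask),
                "mask length must equal the feature vector length")
    features[keep]
  }
}

#' Standard scaling fitted on the training partition
#'
#' `fit_scaler()` computes per-feature means and standard deviations on
#' training rows only; `apply_scaler()` standardizes any compatible matrix
#' with those statistics. A zero-variance feature has its standard deviation
#' clamped to 1, so a constant feature scales to all zeros.
#'
#' @param x Numeric matrix or feature data frame (key columns `patient_id`,
#'   `segment_index`, `outcome` are ignored and passed through).
#' @return `fit_scaler()` a `feature_scaler`; `apply_scaler()` the scaled
#'   input in the same shape.
#' @export
#' @examples
#' sc <- fit_scaler(matrix(1:6, ncol = 2))
#' apply_scaler(sc, matrix(1:6, ncol = 2))
fit_scaler <- function(x) {
  m <- scaler_matrix(x)
  n <- nrow(m)
  assert_that(n >= 1, "cannot fit a scaler on zero rows")
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(sweep(m, 2, mu)^2))  # population sd
  sdv[sdv == 0] <- 1
  structure(list(mean = mu, sd = sdv, names = colnames(m)),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  assert_that(inherits(scaler, "feature_scaler"), "scaler must be a feature_scaler")
  if (is.data.frame(x)) {
    key <- intersect(c("patient_id", "segment_index", "outcome"), names(x))
    m <- scaler_matrix(x)
    scaled <- sweep(sweep(m, 2, scaler$mean), 2, scaler$sd, "/")
    dplyr::bind_cols(x[, key, drop = FALSE], tibble::as_tibble(scaled))
  } else {
    m <- scaler_matrix(x)
    sweep(sweep(m, 2, scaler$mean), 2, scaler$sd, "/")
  }
}

#' Serialize a feature registry to JSON
#'
#' Writes the ordered feature names with their block labels; reading the
#' file back reproduces the registry exactly.
#'
#' @param registry A `feature_registry`.
#' @param path Output file.
#' @return `path` invisibly / the registry.
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(list(name = registry$name, block = registry$block),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- tibble::tibble(name = payload$name, block = payload$block)
  structure(reg, class = c("feature_registry", class(reg)))
}

scaler_matrix <- function(x) {
  if (is.data.frame(x)) {
    key <- intersect(c("patient_id", "segment_index", "outcome"), names(x))
    as.matrix(x[, setdiff(names(x), key), drop = FALSE])
  } else {
    as.matrix(x)
  }
}
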