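#' Hold-out split specification
#'
#' Stratified 40/40/20 train/validation/test split. By default the split is
#' patient-grouped (no patient's segments span partitions, the leakage-safe
#' protocol); `unit = "segment"` replicates the literal segment-level
#' protocol instead.
#'
#' @param fractions Named fractions `train`, `validation`, `test`, summing
#'   to 1.
#' @param unit `"patient"` (grouped, default) or `"segment"`.
#' @param seed Seed for the shuffle.
#' @return A `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.4, validation = 0.4, test = 0.2),
                       unit = c("patient", "segment"), seed = 1L) {
  assert_that(abs(sum(fractions) - 1) < 1e-8, "fractions must sum to 1")
  assert_that(all(c("train", "validation", "test") %in% names(fractions)),
              "fractions must name train, validation and test")
  structure(list(fractions = fractions, unit = match.arg(unit),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Cross-validation specification
#'
#' Patient-level stratified k-fold CV: folds partition the patient set,
#' sizes differ by at most one patient, and outcome proportions per fold
#' stay within one patient of the global proportions.
#'
#' @param n_folds Number of folds (5 in the study protocol).
#' @param seed Seed for the shuffle.
#' @return A `cv_spec`.
#' @export
cv_spec <- function(n_folds = 5, seed = 1L) {
  assert_that(n_folds >= 2, "need at least 2 folds")
  structure(list(n_folds = n_folds, seed = as.integer(seed)), class = "cv_spec")
}

# stratified allocation of one class's rows into named partitions
allocate_fractions <- function(n, fractions) {
  counts <- floor(n * fractions)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * fractions - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Stratified hold-out split
#'
#' Splits patients (or segments) into train/validation/test partitions,
#' stratified by outcome, reproducibly by seed. With the default patient
#' unit, partitions never share a patient.
#'
#' @param data Patient table (unit `"patient"`) or segment table (unit
#'   `"segment"`); must carry `outcome` and `patient_id`.
#' @param spec A [split_spec()].
#' @return Named list `train`, `validation`, `test` of row slices of `data`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(
#'   n_patients = 10, segments_per_patient = 1, sampling_rate = 100,
#'   etiology_outcome_counts = tibble::tibble(
#'     etiology = "Stroke", favorable = 5, unfavorable = 5),
#'   sex_counts = c(male = 5, female = 5), seed = 1))
#' sp <- make_holdout_split(coh$patients, split_spec(seed = 2))
#' vapply(sp, nrow, integer(1))
make_holdout_split <- function(data, spec = split_spec()) {
  assert_that(inherits(spec, "split_spec"), "spec must be a split_spec")
  assert_that("outcome" %in% names(data), "data must carry an outcome column")
  parts <- c("train", "validation", "test")
  with_local_seed(spec$seed, {
    assign_part <- rep(NA_character_, nrow(data))
    for (cls in unique(data$outcome)) {
      rows <- which(data$outcome == cls)
      if (length(rows) < length(parts)) {
        abort(sprintf("class '%s' has %d %ss, fewer than the %d partitions",
                      cls, length(rows), spec$unit, length(parts)),
              class = "comafusion_split_error")
      }
      rows <- sample(rows)
      counts <- allocate_fractions(length(rows), spec$fractions[parts])
      lab <- rep(parts, times = counts)
      assign_part[rows] <- lab
    }
    setNames(purrr::map(parts, function(p) data[assign_part == p, , drop = FALSE]),
             parts)
  })
}

#' Patient-level stratified CV folds
#'
#' @param patients Patient table with `patient_id` and `outcome`.
#' @param spec A [cv_spec()].
#' @return List of `n_folds` character vectors of patient ids: disjoint,
#'   jointly exhaustive, stratified by outcome.
#' @export
make_patient_cv_folds <- function(patients, spec = cv_spec()) {
  assert_that(inherits(spec, "cv_spec"), "spec must be a cv_spec")
  k <- spec$n_folds
  with_local_seed(spec$seed, {
    folds <- vector("list", k)
    offset <- 0L
    for (cls in unique(patients$outcome)) {
      ids <- sample(patients$patient_id[patients$outcome == cls])
      for (i in seq_along(ids)) {
        f <- ((offset + i - 1L) %% k) + 1L
        folds[[f]] <- c(folds[[f]], ids[i])
      }
      offset <- offset + length(ids)
    }
    folds
  })
}

#' Majority vote over one patient's segment predictions
#'
#' Returns the modal label. An even split is an error unless `tie_break`
#' names the label to fall back on; under the study protocol nine binary
#' votes can never tie.
#'
#' @param labels Vector/factor of segment-level predicted labels.
#' @param tie_break Optional label returned on ties.
#' @return The winning label (character).
#' @export
#' @examples
#' majority_vote(c(rep("favorable", 5), rep("unfavorable", 4)))
majority_vote <- function(labels, tie_break = NULL) {
  labels <- as.character(labels)
  assert_that(length(labels) >= 1, "no votes to aggregate")
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) {
    if (is.null(tie_break)) {
      abort(sprintf("majority vote tied over %d votes; set tie_break to resolve",
                    length(labels)),
            class = "comafusion_vote_error")
    }
    return(as.character(tie_break))
  }
  names(tab)[1]
}

#' Confusion counts from predictions
#'
#' @param truth,pred Label vectors.
#' @param positive The positive class (`unfavorable` by default, the
#'   clinical detection target).
#' @return List with `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_counts <- function(truth, pred, positive = "unfavorable") {
  truth <- as.character(truth); pred <- as.character(pred)
  assert_that(length(truth) == length(pred), "truth and pred must align")
  list(TP = sum(truth == positive & pred == positive),
       FN = sum(truth == positive & pred != positive),
       FP = sum(truth != positive & pred == positive),
       TN = sum(truth != positive & pred != positive))
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1 of the positive class, macro F1
#' (unweighted mean of the two per-class F1 scores) and geometric mean
#' (square root of the two class recalls). Zero-denominator
#' precision/recall conventionally score 0.
#'
#' @param cm Confusion counts: a list/one-row data frame with `TP`, `FN`,
#'   `FP`, `TN` (e.g. from [confusion_counts()]).
#' @param level Annotation only: `"patient"` or `"segment"`.
#' @return One-row tibble of metrics plus the counts.
#' @export
#' @examples
#' compute_metrics(list(TP = 3, FN = 3, FP = 0, TN = 6))
compute_metrics <- function(cm, level = "patient") {
  TP <- cm$TP; FN <- cm$FN; FP <- cm$FP; TN <- cm$TN
  assert_that(all(c(TP, FN, FP, TN) >= 0), "confusion counts must be non-negative")
  total <- TP + FN + FP + TN
  accuracy <- safe_div(TP + TN, total)
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  f1_pos <- safe_div(2 * precision * recall, precision + recall)
  prec_neg <- safe_div(TN, TN + FN)
  rec_neg <- safe_div(TN, TN + FP)
  f1_neg <- safe_div(2 * prec_neg * rec_neg, prec_neg + rec_neg)
  tibble::tibble(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1_pos, f1_macro = (f1_pos + f1_neg) / 2,
                 g_mean = sqrt(recall * rec_neg),
                 TP = TP, FN = FN, FP = FP, TN = TN, level = level)
}

#' Macro F1 of predictions
#'
#' @inheritParams confusion_counts
#' @return Macro F1 between 0 and 1.
#' @export
macro_f1 <- function(truth, pred, positive = "unfavorable") {
  compute_metrics(confusion_counts(truth, pred, positive))$f1_macro
}

#' Roster of comparison models
#'
#' The monomodal and multimodal baselines evaluated alongside the
#' GA-optimized model: MLPs on patient, time-domain, or both feature
#' blocks, and CNN-LSTM variants fusing none, patient, time-domain, or both
#' blocks with the EEG latent state.
#'
#' @return Named list of entries `list(type, blocks)`.
#' @export
default_model_roster <- function() {
  list(
    mlp_patient         = list(type = "mlp",    blocks = "patient"),
    mlp_td              = list(type = "mlp",    blocks = "td"),
    mlp_patient_td      = list(type = "mlp",    blocks = "both"),
    cnn_lstm_baseline   = list(type = "fusion", blocks = "none"),
    cnn_lstm_patient    = list(type = "fusion", blocks = "patient"),
    cnn_lstm_td         = list(type = "fusion", blocks = "td"),
    cnn_lstm_patient_td = list(type = "fusion", blocks = "both"))
}

# assemble eeg tensor / aux matrix / labels for a set of segments
prepare_model_data <- function(segments, features, blocks, registry,
                               n_samples = NULL) {
  aux <- NULL
  if (blocks != "none") {
    keep_names <- switch(blocks,
      patient = registry$name[registry$block == "patient"],
      td = registry$name[registry$block == "td"],
      both = registry$name,
      abort(sprintf("unknown feature blocks '%s'", blocks)))
    feat <- dplyr::semi_join(features, segments,
                             by = c("patient_id", "segment_index"))
    feat <- feat[match(paste(segments$patient_id, segments$segment_index),
                       paste(feat$patient_id, feat$segment_index)), ]
    aux <- as.matrix(feat[, keep_names, drop = FALSE])
  }
  list(eeg = eeg_tensor(segments, n_samples = n_samples, scale = FALSE),
       aux = aux,
       y = segments$outcome,
       patient_id = segments$patient_id)
}

# train one roster model and return patient-level metrics on test segments
fit_and_score <- function(entry, train_segs, test_segs, features, registry,
                          fusion_spec, seed, mlp_epochs = 30,
                          n_samples = NULL) {
  tr <- prepare_model_data(train_segs, features, entry$blocks, registry,
                           n_samples = n_samples)
  te <- prepare_model_data(test_segs, features, entry$blocks, registry,
                           n_samples = n_samples)
  if (!is.null(tr$aux)) {
    sc <- fit_scaler(tr$aux)
    tr$aux <- apply_scaler(sc, tr$aux)
    te$aux <- apply_scaler(sc, te$aux)
  }
  if (entry$type == "mlp") {
    model <- build_mlp_baseline(ncol(tr$aux), seed = seed)
    model <- train_model(model, x = tr$aux, y = tr$y, epochs = mlp_epochs,
                         seed = seed)
    pred <- predict_segments(model, x = te$aux)
  } else {
    n_aux <- if (is.null(tr$aux)) 0 else ncol(tr$aux)
    model <- build_fusion_model(fusion_spec, dim(tr$eeg)[2:3],
                                n_aux_features = n_aux, seed = seed)
    model <- train_model(model, tr$eeg, tr$aux, tr$y, seed = seed)
    pred <- predict_segments(model, te$eeg, te$aux)
  }
  votes <- tibble::tibble(patient_id = te$patient_id,
                          truth = te$y, pred = as.character(pred$pred))
  per_patient <- dplyr::summarise(
    dplyr::group_by(votes, .data$patient_id),
    truth = .data$truth[1],
    pred = majority_vote(.data$pred, tie_break = outcome_levels()[1]),
    .groups = "drop")
  seg_metrics <- compute_metrics(confusion_counts(votes$truth, votes$pred),
                                 level = "segment")
  pat_metrics <- compute_metrics(
    confusion_counts(per_patient$truth, per_patient$pred), level = "patient")
  dplyr::bind_rows(pat_metrics, seg_metrics)
}

#' Compare models under the study's evaluation protocol
#'
#' Evaluates each roster model under (a) the stratified hold-out split
#' (train + validation merged for training, test for scoring) and (b)
#' patient-level stratified k-fold CV. Only the first `n_vote_segments`
#' segments of each patient are used; each patient's label is the majority
#' vote of its segment predictions. Metrics are reported at both patient
#' and segment level, with `unfavorable` as the positive class.
#'
#' @param cohort An `eeg_cohort`.
#' @param roster Model roster, as [default_model_roster()].
#' @param registry,schema Feature registry and [patient_schema()].
#' @param fusion_spec [architecture_spec()] used for every CNN-LSTM entry.
#' @param split,cv [split_spec()] / [cv_spec()]; pass `NULL` to skip a
#'   scheme.
#' @param n_vote_segments Segments per patient entering classification and
#'   voting (9 in the study protocol; later segments are kept in the cohort
#'   but excluded here).
#' @param mlp_epochs Training epochs for MLP entries.
#' @param seed Base seed for model training.
#' @return Tibble: `model`, `scheme` (`holdout`/`cv`), `fold`, `level`, and
#'   the metric columns of [compute_metrics()].
#' @export
run_comparison <- function(cohort, roster = default_model_roster(),
                           registry = build_registry(),
                           schema = patient_schema(),
                           fusion_spec = reference_architecture(),
                           split = split_spec(), cv = cv_spec(),
                           n_vote_segments = 9, mlp_epochs = 30, seed = 1L) {
  features <- assemble_feature_matrix(cohort, registry, schema)
  segs <- dplyr::filter(cohort$segments, .data$segment_index < n_vote_segments)
  out <- list()
  if (!is.null(split)) {
    sp <- make_holdout_split(cohort$patients, split)
    train_ids <- c(sp$train$patient_id, sp$validation$patient_id)
    tr_segs <- dplyr::filter(segs, .data$patient_id %in% train_ids)
    te_segs <- dplyr::filter(segs, .data$patient_id %in% sp$test$patient_id)
    for (nm in names(roster)) {
      res <- fit_and_score(roster[[nm]], tr_segs, te_segs, features, registry,
                           fusion_spec, seed = seed, mlp_epochs = mlp_epochs)
      out[[length(out) + 1]] <- dplyr::mutate(res, model = nm,
                                              scheme = "holdout", fold = NA_integer_)
    }
  }
  if (!is.null(cv)) {
    folds <- make_patient_cv_folds(cohort$patients, cv)
    for (f in seq_along(folds)) {
      tr_segs <- dplyr::filter(segs, !.data$patient_id %in% folds[[f]])
      te_segs <- dplyr::filter(segs, .data$patient_id %in% folds[[f]])
      for (nm in names(roster)) {
        res <- fit_and_score(roster[[nm]], tr_segs, te_segs, features, registry,
                             fusion_spec, seed = seed + f,
                             mlp_epochs = mlp_epochs)
        out[[length(out) + 1]] <- dplyr::mutate(res, model = nm,
                                                scheme = "cv", fold = f)
      }
    }
  }
  dplyr::relocate(dplyr::bind_rows(out), "model", "scheme", "fold", "level")
}

#' Summarize a comparison table
#'
#' Collapses [run_comparison()] output to one row per model and scheme:
#' hold-out metrics as-is, CV metrics as mean and standard deviation across
#' folds.
#'
#' @param results Output of [run_comparison()].
#' @param level Metric level to keep (`"patient"` by default).
#' @return Tibble with mean/sd metric columns.
#' @export
summarize_comparison <- function(results, level = "patient") {
  res <- dplyr::filter(results, .data$level == !!level)
  dplyr::summarise(
    dplyr::group_by(res, .data$model, .data$scheme),
    dplyr::across(c("accuracy", "f1_macro", "precision", "recall"),
                  list(mean = mean, sd = sd)),
    .groups = "drop")
}

#' Full GA optimization of the fusion model on a cohort
#'
#' The end-to-end driver: builds the stratified patient-grouped hold-out
#' split, assembles tensors and the auxiliary feature matrix, runs
#' `config$n_runs` GA replicates on the train/validation splits with the
#' wrapper fitness of [make_fusion_fitness()], then retrains each run's
#' best chromosome on train + validation and scores it on the held-out test
#' patients (majority vote over the first `n_vote_segments` segments).
#'
#' @param cohort An `eeg_cohort`.
#' @param registry,schema Feature registry and [patient_schema()].
#' @param genome [make_default_schema()]-style genome schema over `registry`.
#' @param config A [ga_config()].
#' @param split A [split_spec()].
#' @param max_epochs Epoch cap during fitness evaluation (final retraining
#'   uses each chromosome's full epoch gene).
#' @param n_vote_segments Segments per patient used for classification.
#' @return List: `runs` (a `ga_runs`), `frequency` (from
#'   [aggregate_runs()]), `results` (per-run test metrics tibble).
#' @export
optimize_coma_model <- function(cohort, registry = build_registry(),
                                schema = patient_schema(),
                                genome = make_default_schema(registry),
                                config = ga_config(), split = split_spec(),
                                max_epochs = 15, n_vote_segments = 9) {
  features <- assemble_feature_matrix(cohort, registry, schema)
  segs <- dplyr::filter(cohort$segments, .data$segment_index < n_vote_segments)
  sp <- make_holdout_split(cohort$patients, split)
  seg_of <- function(ids) dplyr::filter(segs, .data$patient_id %in% ids)
  n_samples <- max(vapply(segs$signal, ncol, integer(1)))
  part <- function(ids) {
    d <- prepare_model_data(seg_of(ids), features, "both", registry,
                            n_samples = n_samples)
    list(eeg = d$eeg, aux = d$aux, y = d$y, patient_id = d$patient_id)
  }
  tr <- part(sp$train$patient_id)
  va <- part(sp$validation$patient_id)
  te <- part(sp$test$patient_id)
  fitness <- make_fusion_fitness(tr, va, genome, max_epochs = max_epochs,
                                 base_seed = config$base_seed)
  runs <- run_ga_replicates(genome, fitness, config)
  trva <- part(c(sp$train$patient_id, sp$validation$patient_id))
  results <- purrr::imap(unclass(runs), function(run, i) {
    dec <- decode_chromosome(run$best$chromosome, genome)
    n_sel <- sum(dec$mask)
    if (n_sel > 0) {
      sc <- fit_scaler(apply_mask(trva$aux, dec$mask))
      aux_tr <- apply_scaler(sc, apply_mask(trva$aux, dec$mask))
      aux_te <- apply_scaler(sc, apply_mask(te$aux, dec$mask))
    } else {
      aux_tr <- aux_te <- NULL
    }
    sd_i <- chromosome_seed(run$best$chromosome, config$base_seed + i)
    model <- build_fusion_model(dec$spec, dim(trva$eeg)[2:3],
                                n_aux_features = n_sel, seed = sd_i)
    model <- train_model(model, trva$eeg, aux_tr, trva$y, seed = sd_i)
    pred <- predict_segments(model, te$eeg, aux_te)
    votes <- tibble::tibble(patient_id = te$patient_id, truth = te$y,
                            pred = as.character(pred$pred))
    per_patient <- dplyr::summarise(
      dplyr::group_by(votes, .data$patient_id),
      truth = .data$truth[1],
      pred = majority_vote(.data$pred, tie_break = outcome_levels()[1]),
      .groups = "drop")
    m <- compute_metrics(confusion_counts(per_patient$truth, per_patient$pred))
    dplyr::mutate(m, run = i, fitness = run$best$fitness,
                  n_selected = n_sel)
  })
  list(runs = runs, frequency = aggregate_runs(runs),
       results = dplyr::bind_rows(results))
}
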