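# Shared fixtures, oracles and lazily cached heavy computations.
# Everything is generated in code; seeds are fixed so the suite is
# deterministic.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# small two-etiology, balanced-outcome configuration
two_class_config <- function(n_per_class = 10, segments_per_patient = 10,
                             sampling_rate = 100, effect_size = 1.5,
                             age_outcome_shift = 10, seed = 42, ...) {
  spp <- segments_per_patient
  cohort_config(
    n_patients = 2 * n_per_class,
    segments_per_patient = spp,
    sampling_rate = sampling_rate,
    etiology_outcome_counts = tibble::tibble(
      etiology = c("Stroke", "Metabolic Coma"),
      favorable = c(n_per_class * spp, 0),
      unfavorable = c(0, n_per_class * spp)),
    sex_counts = c(male = n_per_class, female = n_per_class),
    effect_size = effect_size,
    age_outcome_shift = age_outcome_shift,
    seed = seed, ...)
}

# the full 60-patient / 600-segment replication cohort (heavy; cached)
reference_cohort <- function() {
  memo("reference_cohort", generate_cohort(cohort_config(seed = 42)))
}

tiny_spec <- function(filters = 4, lstm_units = 8, dense_units = 8,
                      epochs = 3, lr = 1e-3, batch = 16, pool = 4) {
  architecture_spec(
    conv_layers = list(list(filters = filters, kernel_size = 5,
                            pool_size = pool, activation = "relu")),
    lstm_layers = list(list(units = lstm_units)),
    dense_layers = list(list(units = dense_units, dropout = 0)),
    training = list(learning_rate = lr, batch_size = batch, epochs = epochs,
                    optimizer = "adam"))
}

# reduced genome schema over a registry: one tiny trainable architecture
# family so GA fitness evaluations stay cheap
small_genome <- function(registry, lr_domain = c(1e-3, 3e-3), pool = 4,
                         batch = 32, epochs = 3) {
  genes <- list()
  for (nm in registry$name) {
    genes[[length(genes) + 1]] <- gene_spec(paste0("sel_", nm), "boolean",
                                            c(0, 1), "part1")
  }
  add <- function(name, kind, domain, group) {
    genes[[length(genes) + 1]] <<- gene_spec(name, kind, domain, group)
  }
  add("conv_depth", "ordered", 1, "part2a")
  add("conv1_filters", "ordered", 4, "part2a")
  add("conv1_kernel", "ordered", 5, "part2a")
  add("conv1_pool", "ordered", pool, "part2a")
  add("lstm_depth", "ordered", 1, "part2b")
  add("lstm1_units", "ordered", 8, "part2b")
  add("dense_depth", "ordered", 1, "part2c")
  add("dense1_units", "ordered", 8, "part2c")
  add("dense1_dropout", "ordered", 0, "part2c")
  add("learning_rate", "ordered", lr_domain, "part2d")
  add("batch_size", "ordered", batch, "part2d")
  add("epochs", "ordered", epochs, "part2d")
  add("optimizer", "nominal", "adam", "part2d")
  add("activation", "nominal", "relu", "part2d")
  genome_schema(dplyr::bind_rows(genes), registry$name)
}

# 20-bit pure feature-selection schema + count-ones surrogate fitness
bitstring_schema <- function(n_bits = 20) {
  names <- paste0("bit", seq_len(n_bits))
  genes <- dplyr::bind_rows(lapply(names, function(nm) {
    gene_spec(paste0("sel_", nm), "boolean", c(0, 1), "part1")
  }))
  genome_schema(genes, names)
}

count_ones_fitness <- function(chromosome) mean(unlist(chromosome))

# ---- independent oracles ----

# brute-force time-domain statistics, one channel at a time
oracle_td <- function(signal) {
  out <- c()
  for (ch in rownames(signal)) {
    x <- signal[ch, ]
    n <- length(x)
    m <- sum(x) / n
    v <- sum((x - m)^2) / n
    out <- c(out, setNames(c(m, min(x), max(x), sqrt(v), v),
                           paste0(ch, "_", c("mean", "min", "max", "std", "var"))))
  }
  out
}

# band-power fraction via stats::spec.pgram (independent periodogram route)
oracle_band_fraction <- function(x, fs, band) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, plot = FALSE)
  keep <- sp$freq >= band[1] & sp$freq < band[2]
  sum(sp$spec[keep]) / sum(sp$spec)
}

# ---- heavy shared computations (cached across test files) ----

# count-ones GA: 10 seeded runs on a 20-bit schema, 30 generations
count_ones_runs <- function() {
  memo("count_ones_runs", {
    schema <- bitstring_schema(20)
    cfg <- ga_config(population_size = 30, generations = 30, n_runs = 10,
                     base_seed = 100)
    run_ga_replicates(schema, count_ones_fitness, cfg)
  })
}

# planted-feature recovery: cohort whose EEG carries no class signal and
# whose etiologies are balanced across outcomes (so no clinical feature
# leaks the label); six auxiliary registry features (age + five channel-std
# features) are planted with a 1.2-sd class shift — mild enough that
# fitness keeps rewarding additional planted features; 6 reduced GA runs
# (population 10, generations 10, one tiny trainable network family) must
# select planted features more often than background.
planted_channels <- c("T6", "F4", "T4", "O2", "FZ")

planted_recovery <- function() {
  memo("planted_recovery", {
    schema_p <- patient_schema(etiology_levels = c("Stroke", "Metabolic Coma"))
    registry <- build_registry(schema_p, planted_channels)
    cfg <- cohort_config(
      n_patients = 20, segments_per_patient = 10, sampling_rate = 100,
      etiology_outcome_counts = tibble::tibble(
        etiology = c("Stroke", "Metabolic Coma"),
        favorable = c(50, 50), unfavorable = c(50, 50)),
      sex_counts = c(male = 10, female = 10),
      effect_size = 1, age_outcome_shift = 0, seed = 7)
    coh <- generate_cohort(cfg)
    feats <- assemble_feature_matrix(coh, build_registry(schema_p), schema_p)
    planted <- c("age", paste0(planted_channels, "_std"))
    for (nm in planted) {
      s <- sd(feats[[nm]])
      feats[[nm]] <- feats[[nm]] +
        ifelse(feats$outcome == "unfavorable", 1.2 * s, 0)
    }
    sp <- make_holdout_split(coh$patients,
                             split_spec(c(train = 0.4, validation = 0.4,
                                          test = 0.2), seed = 11))
    part <- function(ids) {
      segs <- dplyr::filter(coh$segments, patient_id %in% ids)
      fe <- feats[match(paste(segs$patient_id, segs$segment_index),
                        paste(feats$patient_id, feats$segment_index)), ]
      list(eeg = eeg_tensor(segs, scale = FALSE),
           aux = as.matrix(fe[, registry$name]),
           y = segs$outcome)
    }
    tr <- part(sp$train$patient_id)
    va <- part(sp$validation$patient_id)
    genome <- small_genome(registry, lr_domain = 3e-3, pool = 8,
                           batch = 16, epochs = 8)
    fitness <- make_fusion_fitness(tr, va, genome, max_epochs = 8,
                                   base_seed = 0)
    cfg_ga <- ga_config(population_size = 10, generations = 10, n_runs = 6,
                        base_seed = 500)
    runs <- run_ga_replicates(genome, fitness, cfg_ga)
    freq <- aggregate_runs(runs)
    list(freq = freq, planted = planted, runs = runs)
  })
}

# separable cohort: a mild but cleanly learnable amplitude effect (ratio
# 1.1) plus the default age-outcome association; multimodal CNN-LSTM vs
# time-domain-only MLP under patient-level 5-fold CV
separable_comparison <- function() {
  memo("separable_comparison", {
    coh <- generate_cohort(two_class_config(n_per_class = 15,
                                            effect_size = 1.1, seed = 21))
    roster <- list(
      cnn_lstm_patient_td = list(type = "fusion", blocks = "both"),
      mlp_td = list(type = "mlp", blocks = "td"))
    run_comparison(coh, roster,
                   fusion_spec = tiny_spec(filters = 8, lstm_units = 16,
                                           dense_units = 16, epochs = 10),
                   split = NULL, cv = cv_spec(n_folds = 5, seed = 3),
                   seed = 17)
  })
}
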