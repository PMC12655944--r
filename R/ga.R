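#' Genetic-algorithm settings
#'
#' Defaults follow the study protocol: population 30, 30 generations,
#' crossover probability 0.6, per-gene mutation probability 2/n (n = genes
#' in the chromosome), binary tournaments, 10 independent runs. Replacement
#' is elitist: parents and offspring are pooled and the best
#' `population_size` individuals survive, so the best fitness never
#' decreases across generations; `elitism` (2 by default) sets how many
#' population slots are reserved for survivors rather than new offspring
#' (`population_size - elitism` offspring per generation).
#' The fitness cache (keyed by a full-chromosome hash) skips
#' retraining duplicated chromosomes; disable it to reproduce the literal
#' training budget.
#'
#' @param population_size,generations,crossover_prob,tournament_size,elitism
#'   Core loop parameters.
#' @param mutation_prob Per-gene mutation probability; `NULL` means 2/n.
#' @param n_runs,base_seed Replicate runs; run `i` uses seed `base_seed + i`.
#' @param fitness_cache Cache fitness by chromosome hash.
#' @param window_radius Neighbors considered on each side by the window
#'   mutation of ordered genes.
#' @return A `ga_config`.
#' @export
ga_config <- function(population_size = 30, generations = 30,
                      crossover_prob = 0.6, mutation_prob = NULL,
                      tournament_size = 2, elitism = 2,
                      n_runs = 10, base_seed = 1L,
                      fitness_cache = TRUE, window_radius = 2) {
  assert_that(crossover_prob >= 0 && crossover_prob <= 1,
              "crossover_prob must be a probability")
  assert_that(is.null(mutation_prob) ||
                (mutation_prob >= 0 && mutation_prob <= 1),
              "mutation_prob must be a probability")
  assert_that(elitism >= 0 && elitism < population_size,
              "elitism must be smaller than the population size")
  assert_that(tournament_size == 2,
              "only binary tournaments are implemented")
  structure(list(population_size = population_size, generations = generations,
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 tournament_size = tournament_size, elitism = elitism,
                 n_runs = n_runs, base_seed = as.integer(base_seed),
                 fitness_cache = fitness_cache, window_radius = window_radius),
            class = "ga_config")
}

#' Binary tournament selection
#'
#' Draws two distinct individuals uniformly and returns the fitter; fitness
#' ties break uniformly at random. A single-individual population returns
#' that individual (degenerate case).
#'
#' @param population List of individuals, each `list(chromosome, fitness)`.
#' @return One individual.
#' @export
tournament_select <- function(population) {
  n <- length(population)
  assert_that(n >= 1, "population must be non-empty")
  if (n == 1) return(population[[1]])
  idx <- sample.int(n, 2)
  a <- population[[idx[1]]]; b <- population[[idx[2]]]
  if (a$fitness > b$fitness) a
  else if (b$fitness > a$fitness) b
  else if (runif(1) < 0.5) a else b
}

#' Two-point crossover
#'
#' With probability `p_c`, two distinct cut points are drawn at gene
#' boundaries and the inner slice is exchanged between the parents;
#' otherwise the children are copies of the parents.
#'
#' @param parent1,parent2 Chromosomes sharing one schema.
#' @param p_c Crossover probability.
#' @return List of two chromosomes.
#' @export
#' @examples
#' set.seed(1)
#' p1 <- structure(as.list(rep(0, 6)), names = paste0("g", 1:6), class = "chromosome")
#' p2 <- structure(as.list(rep(1, 6)), names = paste0("g", 1:6), class = "chromosome")
#' two_point_crossover(p1, p2, p_c = 1)
two_point_crossover <- function(parent1, parent2, p_c) {
  assert_that(length(parent1) == length(parent2) &&
                identical(names(parent1), names(parent2)),
              "parents must share one schema")
  c1 <- parent1; c2 <- parent2
  if (runif(1) < p_c) {
    n <- length(parent1)
    cuts <- sort(sample.int(n + 1, 2) - 1L)  # boundaries 0..n, distinct
    if (cuts[2] > cuts[1]) {
      span <- (cuts[1] + 1):cuts[2]
      c1[span] <- parent2[span]
      c2[span] <- parent1[span]
    }
  }
  list(c1, c2)
}

#' Typed mutation
#'
#' Each gene mutates independently with probability `p_m` using the
#' operator matching its kind: boolean genes flip; ordered genes draw
#' uniformly from up to `window_radius` neighbors below and above the
#' current value in the sorted domain (current value excluded; a singleton
#' domain is a no-op); nominal genes redraw uniformly from the other
#' categories (so a two-level nominal gene behaves like a boolean one).
#'
#' @param chromosome A schema-valid chromosome.
#' @param schema Its [genome_schema()].
#' @param p_m Per-gene mutation probability.
#' @param window_radius Window half-width for ordered genes.
#' @return The mutated chromosome (schema-valid by construction).
#' @export
mutate_chromosome <- function(chromosome, schema, p_m, window_radius = 2) {
  hits <- runif(length(chromosome)) < p_m
  for (i in which(hits)) {
    kind <- schema$genes$kind[i]
    dom <- schema$genes$domain[[i]]
    v <- chromosome[[i]]
    if (kind == "boolean") {
      chromosome[[i]] <- 1 - v
    } else if (kind == "ordered") {
      pos <- match(v, dom)
      cand <- setdiff(max(1, pos - window_radius):min(length(dom), pos + window_radius),
                      pos)
      if (length(cand) > 0) chromosome[[i]] <- dom[sample_from(cand)]
    } else {
      cand <- dom[dom != v]
      if (length(cand) > 0) chromosome[[i]] <- sample_from(cand)
    }
  }
  chromosome
}

chromosome_seed <- function(chromosome, base_seed) {
  h <- rlang::hash(unclass(chromosome))
  (base_seed + strtoi(substr(h, 1, 7), 16L)) %% .Machine$integer.max
}

#' Fitness service backed by the fusion model
#'
#' Builds the wrapper fitness used by the GA: a chromosome is decoded into
#' a feature mask and an architecture, the masked auxiliary features are
#' standard-scaled with training-set statistics, the fusion model is
#' trained on the training split, and the fitness is the macro F1 of its
#' segment-level predictions on the validation split. Degenerate
#' chromosomes (pooling collapse, non-finite loss) score the worst fitness,
#' 0, so evolution continues. Training is deterministic per chromosome
#' (seeded by a chromosome hash mixed with `base_seed`).
#'
#' @param train,validation Lists with `eeg` (tensor `B x T x C`), `aux`
#'   (matrix/tibble with one column per registry feature, registry order)
#'   and `y` (labels).
#' @param schema The [genome_schema()] chromosomes conform to.
#' @param max_epochs Hard cap on training epochs during fitness evaluation.
#' @param base_seed Mixed into each chromosome's training seed.
#' @return A function `chromosome -> macro-F1 between 0 and 1`.
#' @export
make_fusion_fitness <- function(train, validation, schema,
                                max_epochs = 15, base_seed = 0L) {
  tr_aux <- as.matrix(scaler_matrix(train$aux))
  va_aux <- as.matrix(scaler_matrix(validation$aux))
  assert_that(ncol(tr_aux) == length(schema$registry_names),
              "train aux columns must match the schema's registry")
  input_shape <- dim(train$eeg)[2:3]
  function(chromosome) {
    tryCatch({
      dec <- decode_chromosome(chromosome, schema)
      n_sel <- sum(dec$mask)
      if (n_sel > 0) {
        m_tr <- apply_mask(tr_aux, dec$mask)
        m_va <- apply_mask(va_aux, dec$mask)
        sc <- fit_scaler(m_tr)
        m_tr <- apply_scaler(sc, m_tr)
        m_va <- apply_scaler(sc, m_va)
      } else {
        m_tr <- m_va <- NULL
      }
      sd <- chromosome_seed(chromosome, base_seed)
      model <- build_fusion_model(dec$spec, input_shape, n_aux_features = n_sel,
                                  seed = sd)
      model <- train_model(model, train$eeg, m_tr, train$y,
                           epochs = min(dec$spec$training$epochs, max_epochs),
                           seed = sd)
      pred <- predict_segments(model, validation$eeg, m_va)
      macro_f1(validation$y, pred$pred)
    },
    comafusion_architecture_error = function(e) 0,
    comafusion_training_error = function(e) 0)
  }
}

#' Evaluate (and cache) a chromosome's fitness
#'
#' @param chromosome A chromosome.
#' @param fitness A fitness function (e.g. [make_fusion_fitness()]).
#' @param cache Optional environment used as a hash-keyed fitness cache.
#' @return Numeric fitness; attribute `cache_hit` says whether a stored
#'   value was reused.
#' @export
evaluate_fitness <- function(chromosome, fitness, cache = NULL) {
  if (!is.null(cache)) {
    key <- rlang::hash(unclass(chromosome))
    if (!is.null(cache[[key]])) {
      return(structure(cache[[key]], cache_hit = TRUE))
    }
    f <- fitness(chromosome)
    cache[[key]] <- f
    structure(f, cache_hit = FALSE)
  } else {
    structure(fitness(chromosome), cache_hit = FALSE)
  }
}

#' Run the genetic algorithm
#'
#' Executes the full loop — random initialization, fitness evaluation,
#' binary tournament selection, two-point crossover, typed mutation, and
#' elitist replacement (parents and offspring pooled, best
#' `population_size` kept) — for `generations` generations. Fully
#' reproducible given `seed`.
#'
#' @param schema A [genome_schema()].
#' @param fitness Function `chromosome -> numeric` (higher is better).
#' @param config A [ga_config()].
#' @param seed Seed for this run.
#' @return A `ga_run`: `best` (`chromosome`, `fitness`), `history` tibble
#'   (`generation`, `best`, `mean`, `sd`, `evaluations`, `cache_hits`),
#'   `population`, `mask` (best chromosome's feature mask, when the schema
#'   has part-1 genes), `config`, `seed`.
#' @export
run_ga <- function(schema, fitness, config = ga_config(), seed = 1L) {
  p_m <- config$mutation_prob %||% (2 / length(schema))
  cache <- if (config$fitness_cache) new.env(parent = emptyenv()) else NULL
  n_evals <- 0L; n_hits <- 0L
  eval1 <- function(chrom) {
    f <- evaluate_fitness(chrom, fitness, cache)
    n_evals <<- n_evals + 1L
    if (isTRUE(attr(f, "cache_hit"))) n_hits <<- n_hits + 1L
    list(chromosome = chrom, fitness = as.numeric(f))
  }
  with_local_seed(seed, {
    pop <- purrr::map(seq_len(config$population_size),
                      function(i) eval1(random_chromosome(schema)))
    hist <- list()
    snap <- function(gen) {
      fs <- vapply(pop, function(x) x$fitness, numeric(1))
      hist[[length(hist) + 1]] <<- tibble::tibble(
        generation = gen, best = max(fs), mean = mean(fs), sd = sd(fs),
        evaluations = n_evals, cache_hits = n_hits)
    }
    snap(0L)
    for (gen in seq_len(config$generations)) {
      n_off <- config$population_size - config$elitism
      offspring <- list()
      while (length(offspring) < n_off) {
        pa <- tournament_select(pop)$chromosome
        pb <- tournament_select(pop)$chromosome
        kids <- two_point_crossover(pa, pb, config$crossover_prob)
        for (k in kids) {
          if (length(offspring) < n_off) {
            offspring[[length(offspring) + 1]] <-
              mutate_chromosome(k, schema, p_m, config$window_radius)
          }
        }
      }
      offspring <- purrr::map(offspring, eval1)
      # elitist replacement: parents and offspring compete; the best
      # population_size individuals survive (order() is stable, so parents
      # win fitness ties and the best-so-far individual is always retained)
      pool <- c(pop, offspring)
      ord <- order(vapply(pool, function(x) x$fitness, numeric(1)),
                   decreasing = TRUE)
      pop <- pool[head(ord, config$population_size)]
      snap(gen)
    }
    fs <- vapply(pop, function(x) x$fitness, numeric(1))
    best <- pop[[which.max(fs)]]
    mask <- NULL
    if (any(schema$genes$group == "part1")) {
      mask <- vapply(schema$registry_names, function(nm) {
        as.integer(best$chromosome[[paste0("sel_", nm)]])
      }, integer(1))
    }
    structure(list(best = best, population = pop,
                   history = dplyr::bind_rows(hist), mask = mask,
                   config = config, schema = schema, seed = seed,
                   evaluations = n_evals, cache_hits = n_hits),
              class = "ga_run")
  })
}

#' Replicate GA runs with distinct seeds
#'
#' Runs the GA `config$n_runs` times; run `i` uses seed
#' `config$base_seed + i`.
#'
#' @inheritParams run_ga
#' @return A `ga_runs` list of [run_ga()] results.
#' @export
run_ga_replicates <- function(schema, fitness, config = ga_config()) {
  runs <- purrr::map(seq_len(config$n_runs), function(i) {
    run_ga(schema, fitness, config, seed = config$base_seed + i)
  })
  structure(runs, class = "ga_runs")
}

#' Feature-selection frequency across GA runs
#'
#' Per-feature frequency with which the best individual of each run
#' selected the feature, plus the subset at or above a reporting threshold
#' (50% of runs by default).
#'
#' @param results A `ga_runs` list (or plain list of `ga_run`s with masks).
#' @param threshold Reporting threshold on the frequency, between 0 and 1.
#' @return Tibble: `feature`, `n_selected`, `frequency` (percent),
#'   `above_threshold`; ordered by the schema's registry.
#' @export
aggregate_runs <- function(results, threshold = 0.5) {
  assert_that(length(results) > 0, "no GA runs to aggregate",
              class = "comafusion_error")
  masks <- purrr::map(unclass(results), "mask")
  assert_that(all(!vapply(masks, is.null, logical(1))),
              "every run must carry a feature mask")
  m <- do.call(rbind, masks)
  tibble::tibble(feature = colnames(m) %||% results[[1]]$schema$registry_names,
                 n_selected = unname(colSums(m)),
                 frequency = unname(100 * colMeans(m)),
                 above_threshold = unname(colMeans(m) >= threshold))
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf("<ga_run> seed %s: best fitness %.4f after %d generations (%d evaluations, %d cache hits)\n",
              format(x$seed), x$best$fitness, max(x$history$generation),
              x$evaluations, x$cache_hits))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ga_run <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.ga_run <- function(x, ...) {
  tibble::tibble(best_fitness = x$best$fitness,
                 generations = max(x$history$generation),
                 evaluations = x$evaluations,
                 cache_hits = x$cache_hits,
                 n_selected = if (!is.null(x$mask)) sum(x$mask) else NA_integer_,
                 seed = x$seed)
}
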