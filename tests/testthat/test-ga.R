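mk_ind <- function(fitness, bits = c(0, 0)) {
  list(chromosome = structure(as.list(bits),
                              names = paste0("g", seq_along(bits)),
                              class = "chromosome"),
       fitness = fitness)
}

test_that("tournament selection returns the fitter of two draws", {
  pop <- list(mk_ind(0.9), mk_ind(0.1))
  set.seed(1)
  for (i in 1:50) expect_equal(tournament_select(pop)$fitness, 0.9)
  expect_equal(tournament_select(list(mk_ind(0.5)))$fitness, 0.5)
})

test_that("equal-fitness tournaments select uniformly", {
  pop <- lapply(1:5, function(i) {
    ind <- mk_ind(0.5)
    ind$id <- i
    ind
  })
  set.seed(2)
  picks <- replicate(10000, tournament_select(pop)$id)
  expect_gt(stats::chisq.test(table(picks))$p.value, 0.001)
})

test_that("two-point crossover swaps a contiguous inner slice", {
  p1 <- mk_ind(0, rep(0, 6))$chromosome
  p2 <- mk_ind(0, rep(1, 6))$chromosome
  set.seed(3)
  kids <- two_point_crossover(p1, p1, p_c = 1)
  expect_identical(kids[[1]], p1)
  set.seed(3)
  kids <- two_point_crossover(p1, p2, p_c = 0)
  expect_identical(kids[[1]], p1)
  expect_identical(kids[[2]], p2)
  # locate a seed whose cut points are (2, 4) and check the hand-worked swap
  seed_24 <- NULL
  for (s in 1:200) {
    set.seed(s)
    runif(1)                       # the p_c draw
    if (identical(sort(sample.int(7, 2) - 1L), c(2L, 4L))) { seed_24 <- s; break }
  }
  expect_false(is.null(seed_24))
  set.seed(seed_24)
  kids <- two_point_crossover(p1, p2, p_c = 1)
  expect_equal(unlist(kids[[1]]), c(g1 = 0, g2 = 0, g3 = 1, g4 = 1, g5 = 0, g6 = 0))
  expect_equal(unlist(kids[[2]]), c(g1 = 1, g2 = 1, g3 = 0, g4 = 0, g5 = 1, g6 = 1))
  # children always decompose as prefix/inner-swap/suffix
  set.seed(4)
  for (i in 1:200) {
    k <- two_point_crossover(p1, p2, p_c = 1)[[1]]
    v <- unlist(k)
    runs <- rle(v)$values
    expect_true(length(runs) <= 3 && all(runs %in% c(0, 1)))
  }
})

test_that("typed mutations follow the flip / window / redraw rules", {
  genes <- dplyr::bind_rows(
    gene_spec("sel_a", "boolean", c(0, 1), "part1"),
    gene_spec("ord", "ordered", 1:5, "part2a"),
    gene_spec("single", "ordered", 7, "part2a"),
    gene_spec("nom", "nominal", c("x", "y", "z"), "part2d"))
  schema <- genome_schema(genes, "a")
  base <- structure(list(sel_a = 0, ord = 3, single = 7, nom = "x"),
                    class = "chromosome")
  set.seed(5)
  draws <- replicate(4000, unlist(mutate_chromosome(base, schema, p_m = 1)[c("ord")]))
  expect_true(all(draws %in% c(1, 2, 4, 5)))          # window radius 2, current excluded
  expect_gt(stats::chisq.test(table(draws))$p.value, 0.001)
  m <- mutate_chromosome(base, schema, p_m = 1)
  expect_equal(m$sel_a, 1)                             # boolean flip
  expect_equal(m$single, 7)                            # singleton no-op
  expect_true(m$nom %in% c("y", "z"))                  # redraw excludes current
  low <- base; low$ord <- 1
  lows <- replicate(500, mutate_chromosome(low, schema, p_m = 1)$ord)
  expect_true(all(lows %in% c(2, 3)))                  # boundary window
  # window radius 1 option
  r1 <- replicate(500, mutate_chromosome(base, schema, p_m = 1,
                                         window_radius = 1)$ord)
  expect_true(all(r1 %in% c(2, 4)))
})

test_that("operators always emit schema-valid chromosomes (fuzz)", {
  registry <- build_registry(
    patient_schema(etiology_levels = c("Stroke", "Metabolic Coma")),
    c("T6", "F4"))
  schema <- small_genome(registry)
  set.seed(6)
  n_checked <- 0
  for (i in 1:2500) {
    a <- random_chromosome(schema)
    b <- random_chromosome(schema)
    kids <- two_point_crossover(a, b, p_c = 0.6)
    m1 <- mutate_chromosome(kids[[1]], schema, p_m = 2 / length(schema))
    m2 <- mutate_chromosome(kids[[2]], schema, p_m = 2 / length(schema))
    validate_chromosome(kids[[1]], schema)
    validate_chromosome(kids[[2]], schema)
    validate_chromosome(m1, schema)
    validate_chromosome(m2, schema)
    n_checked <- n_checked + 4
  }
  expect_gte(n_checked, 10000)
})

test_that("fitness evaluation caches by chromosome hash", {
  calls <- 0
  stub <- function(chromosome) { calls <<- calls + 1; 1.0 }
  ch <- mk_ind(0, c(1, 0, 1))$chromosome
  expect_equal(as.numeric(evaluate_fitness(ch, stub)), 1.0)  # perfect oracle
  cache <- new.env(parent = emptyenv())
  f1 <- evaluate_fitness(ch, stub, cache)
  f2 <- evaluate_fitness(ch, stub, cache)
  expect_equal(as.numeric(f1), as.numeric(f2))
  expect_false(attr(f1, "cache_hit"))
  expect_true(attr(f2, "cache_hit"))
  expect_equal(calls, 2)  # once uncached + once to fill the cache
})

test_that("count-ones GA reaches the known optimum in at least 9/10 runs", {
  runs <- count_ones_runs()
  reached <- vapply(unclass(runs), function(r) r$best$fitness == 1, logical(1))
  expect_gte(sum(reached), 9)
})

test_that("elitism makes the best fitness non-decreasing", {
  runs <- count_ones_runs()
  for (r in unclass(runs)) {
    expect_true(all(diff(r$history$best) >= 0))
  }
})

test_that("training budget is bounded by pop x (generations + 1)", {
  runs <- count_ones_runs()
  cfg <- runs[[1]]$config
  for (r in unclass(runs)) {
    trainings <- r$evaluations - r$cache_hits
    expect_lte(trainings, cfg$population_size * (cfg$generations + 1))
  }
})

test_that("zero generations returns the best random individual", {
  schema <- bitstring_schema(10)
  run <- run_ga(schema, count_ones_fitness,
                ga_config(population_size = 8, generations = 0), seed = 9)
  expect_equal(nrow(run$history), 1)
  fs <- vapply(run$population, function(x) x$fitness, numeric(1))
  expect_equal(run$best$fitness, max(fs))
})

test_that("GA runs replay exactly under the same seed", {
  schema <- bitstring_schema(10)
  cfg <- ga_config(population_size = 6, generations = 5)
  a <- run_ga(schema, count_ones_fitness, cfg, seed = 31)
  b <- run_ga(schema, count_ones_fitness, cfg, seed = 31)
  expect_identical(a$best$chromosome, b$best$chromosome)
  expect_equal(a$history, b$history)
})

test_that("selection frequencies aggregate across runs", {
  schema <- bitstring_schema(3)
  fake_run <- function(mask) {
    structure(list(mask = stats::setNames(mask, schema$registry_names),
                   schema = schema), class = "ga_run")
  }
  runs <- c(lapply(1:7, function(i) fake_run(c(1L, 1L, 0L))),
            lapply(1:3, function(i) fake_run(c(1L, 0L, 0L))))
  freq <- aggregate_runs(runs)
  expect_equal(freq$frequency, c(100, 70, 0))
  expect_equal(freq$above_threshold, c(TRUE, TRUE, FALSE))
  expect_error(aggregate_runs(list()), class = "comafusion_error")
})

test_that("the GA recovers planted informative features above background", {
  pr <- planted_recovery()
  freq <- pr$freq
  planted <- freq$frequency[freq$feature %in% pr$planted]
  background <- freq$frequency[!freq$feature %in% pr$planted]
  expect_gt(mean(planted), mean(background))
  p <- stats::wilcox.test(planted, background, alternative = "greater",
                          exact = FALSE)$p.value
  expect_lt(p, 0.05)
})
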