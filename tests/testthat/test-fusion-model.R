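test_that("fusion width equals D_LSTM + n_aux (dimension law)", {
  m <- build_fusion_model(reference_architecture(), c(256, 20),
                          n_aux_features = 38, seed = 1)
  expect_equal(m$contract$D_LSTM, 128)
  expect_equal(m$contract$fusion_dim, 166)
  expect_equal(nrow(m$net$dense[[1]]$W), 166)  # introspection
  # holds across random specs
  set.seed(4)
  for (i in 1:10) {
    sp <- decode_chromosome(random_chromosome(make_default_schema()),
                            make_default_schema())$spec
    naux <- sample(0:20, 1)
    mm <- tryCatch(build_fusion_model(sp, c(512, 20), naux),
                   comafusion_architecture_error = function(e) NULL)
    if (is.null(mm)) next
    d_in <- if (length(mm$net$dense) > 0) nrow(mm$net$dense[[1]]$W)
            else nrow(mm$net$out$W)
    expect_equal(d_in, mm$contract$D_LSTM + naux)
  }
})

test_that("pooling collapse raises an architecture error", {
  sp <- tiny_spec(pool = 4)
  expect_error(build_fusion_model(sp, c(3, 20), 0),
               class = "comafusion_architecture_error")
})

test_that("EEG-only baseline runs and softmax rows are normalized", {
  set.seed(5)
  m <- build_fusion_model(tiny_spec(), c(64, 20), n_aux_features = 0, seed = 2)
  eeg <- array(rnorm(7 * 64 * 20), c(7, 64, 20))
  pred <- predict_segments(m, eeg)
  expect_equal(nrow(pred), 7)
  expect_true(all(pred$prob_favorable >= 0 & pred$prob_unfavorable >= 0))
  expect_equal(pred$prob_favorable + pred$prob_unfavorable, rep(1, 7),
               tolerance = 1e-6)
})

test_that("one training epoch on eight segments records one finite loss", {
  set.seed(6)
  m <- build_fusion_model(tiny_spec(), c(64, 8), n_aux_features = 2, seed = 3)
  eeg <- array(rnorm(8 * 64 * 8), c(8, 64, 8))
  aux <- matrix(rnorm(16), 8)
  y <- rep(outcome_levels(), 4)
  m <- train_model(m, eeg, aux, y, epochs = 1, seed = 1)
  expect_equal(nrow(m$history), 1)
  expect_true(is.finite(m$history$loss))
  expect_s3_class(generics::tidy(m), "tbl_df")
  expect_equal(generics::glance(m)$fusion_dim, m$contract$fusion_dim)
})

test_that("a linearly separable auxiliary feature is fit within 30 epochs", {
  set.seed(7)
  B <- 60
  y <- rep(outcome_levels(), each = B / 2)
  eeg <- array(rnorm(B * 64 * 4), c(B, 64, 4))   # frozen noise
  aux <- cbind(ifelse(y == "unfavorable", 1, -1) + rnorm(B, sd = 0.1))
  m <- build_fusion_model(tiny_spec(epochs = 30, batch = 8), c(64, 4),
                          n_aux_features = 1, seed = 4)
  m <- train_model(m, eeg, aux, y, epochs = 30, seed = 2)
  acc <- mean(predict_segments(m, eeg, aux)$pred == y)
  expect_gte(acc, 0.95)
})

test_that("training is deterministic given the seed", {
  set.seed(8)
  eeg <- array(rnorm(10 * 64 * 4), c(10, 64, 4))
  aux <- matrix(rnorm(20), 10)
  y <- rep(outcome_levels(), 5)
  fit <- function() {
    m <- build_fusion_model(tiny_spec(), c(64, 4), 2, seed = 11)
    train_model(m, eeg, aux, y, epochs = 2, seed = 11)
  }
  a <- fit(); b <- fit()
  expect_identical(rlang::hash(a$net), rlang::hash(b$net))
})

test_that("probability ties break toward the favorable class", {
  m <- build_fusion_model(tiny_spec(), c(64, 4), 0, seed = 5)
  m$net$out$W[] <- 0
  m$net$out$b[] <- 0
  eeg <- array(rnorm(3 * 64 * 4), c(3, 64, 4))
  pred <- predict_segments(m, eeg)
  expect_equal(pred$prob_favorable, rep(0.5, 3))
  expect_true(all(pred$pred == "favorable"))
})

test_that("prediction is invariant to batch partitioning", {
  set.seed(9)
  m <- build_fusion_model(tiny_spec(), c(64, 4), 2, seed = 6)
  eeg <- array(rnorm(5 * 64 * 4), c(5, 64, 4))
  aux <- matrix(rnorm(10), 5)
  whole <- predict_segments(m, eeg, aux)
  one_by_one <- dplyr::bind_rows(lapply(1:5, function(i) {
    predict_segments(m, eeg[i, , , drop = FALSE], aux[i, , drop = FALSE])
  }))
  expect_equal(whole, one_by_one, tolerance = 1e-12)
})

test_that("the MLP baseline has hidden width = inputs and sigmoid output", {
  for (n in c(14, 114)) {
    m <- build_mlp_baseline(n, seed = 1)
    expect_identical(dim(m$net$hidden$W), as.integer(c(n, n)))
  }
  m <- build_mlp_baseline(5, seed = 2)
  x <- matrix(rnorm(50), 10)
  pred <- predict_segments(m, x = x)
  expect_true(all(pred$prob_unfavorable > 0 & pred$prob_unfavorable < 1))
  expect_equal(m$training$learning_rate, 1e-4)
  expect_equal(m$training$epochs, 30)
})

test_that("informative auxiliary features beat the EEG-only baseline", {
  set.seed(10)
  B <- 120
  y <- rep(outcome_levels(), each = B / 2)
  eeg <- array(rnorm(B * 64 * 4), c(B, 64, 4))  # frozen noise: uninformative
  aux <- cbind(ifelse(y == "unfavorable", 1, -1) + rnorm(B, sd = 0.3),
               rnorm(B))
  tr <- c(1:40, 61:100); va <- c(41:60, 101:120)
  fit_f1 <- function(naux) {
    m <- build_fusion_model(tiny_spec(epochs = 15, batch = 16), c(64, 4),
                            naux, seed = 21)
    m <- train_model(m, eeg[tr, , , drop = FALSE],
                     if (naux > 0) aux[tr, , drop = FALSE] else NULL,
                     y[tr], seed = 21)
    pred <- predict_segments(m, eeg[va, , , drop = FALSE],
                             if (naux > 0) aux[va, , drop = FALSE] else NULL)
    macro_f1(y[va], pred$pred)
  }
  f1_multi <- fit_f1(2)
  f1_eeg <- fit_f1(0)
  expect_gte(f1_multi, f1_eeg + 0.2)
})
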