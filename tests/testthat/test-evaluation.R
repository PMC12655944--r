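balanced_patients <- function(n = 60) {
  tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                 outcome = rep(outcome_levels(), each = n / 2))
}

test_that("the 40/40/20 stratified hold-out gives 24/24/12 balanced patients", {
  sp <- make_holdout_split(balanced_patients(), split_spec(seed = 1))
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 24L, validation = 24L, test = 12L))
  for (part in sp) {
    tab <- table(part$outcome)
    expect_equal(unname(tab[["favorable"]]), unname(tab[["unfavorable"]]))
  }
  expect_equal(nrow(sp$test), 12)
  expect_equal(sum(sp$test$outcome == "favorable"), 6)
})

test_that("partitions are patient-disjoint and seed-reproducible", {
  pats <- balanced_patients()
  a <- make_holdout_split(pats, split_spec(seed = 7))
  expect_length(intersect(a$train$patient_id, a$test$patient_id), 0)
  expect_length(intersect(a$train$patient_id, a$validation$patient_id), 0)
  expect_length(intersect(a$validation$patient_id, a$test$patient_id), 0)
  b <- make_holdout_split(pats, split_spec(seed = 7))
  expect_identical(a, b)
  c2 <- make_holdout_split(pats, split_spec(seed = 8))
  expect_false(identical(a$test$patient_id, c2$test$patient_id))
})

test_that("a class smaller than the partition count is rejected", {
  pats <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                         outcome = c("favorable", "favorable", "favorable",
                                     "unfavorable"))
  expect_error(make_holdout_split(pats, split_spec()),
               class = "comafusion_split_error")
})

test_that("patient CV folds are equal-sized, stratified and exhaustive", {
  pats <- balanced_patients()
  folds <- make_patient_cv_folds(pats, cv_spec(n_folds = 5, seed = 2))
  expect_length(folds, 5)
  expect_equal(vapply(folds, length, integer(1)), rep(12L, 5))
  for (f in folds) {
    expect_equal(sum(pats$outcome[pats$patient_id %in% f] == "favorable"), 6)
  }
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  }
  expect_setequal(unlist(folds), pats$patient_id)
})

test_that("majority voting picks the mode and guards ties", {
  expect_equal(majority_vote(c(rep("favorable", 5), rep("unfavorable", 4))),
               "favorable")
  expect_equal(majority_vote(rep("unfavorable", 9)), "unfavorable")
  expect_error(majority_vote(c("favorable", "unfavorable")),
               class = "comafusion_vote_error")
  expect_equal(majority_vote(c("favorable", "unfavorable"),
                             tie_break = "favorable"), "favorable")
  # nine binary votes can never tie: exhaustive over favorable-vote counts
  for (k in 0:9) {
    votes <- c(rep("favorable", k), rep("unfavorable", 9 - k))
    expect_no_error(majority_vote(votes))
  }
})

test_that("metrics reproduce the hand-computed confusion-matrix examples", {
  perfect <- compute_metrics(list(TP = 6, FN = 0, FP = 0, TN = 6))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1_macro, 1)
  expect_equal(perfect$g_mean, 1)
  m <- compute_metrics(list(TP = 3, FN = 3, FP = 0, TN = 6))
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 1)
  expect_equal(m$f1, 2 / 3)
  all_pos <- compute_metrics(list(TP = 6, FN = 0, FP = 6, TN = 0))
  expect_equal(all_pos$accuracy, 0.5)
  expect_equal(all_pos$f1_macro, 1 / 3)
})

test_that("metric formulas agree with brute-force recounting to 1e-12", {
  set.seed(11)
  for (i in 1:1000) {
    counts <- as.list(stats::setNames(sample(0:40, 4, replace = TRUE),
                                      c("TP", "FN", "FP", "TN")))
    if (sum(unlist(counts)) == 0) next
    truth <- c(rep("unfavorable", counts$TP + counts$FN),
               rep("favorable", counts$FP + counts$TN))
    pred <- c(rep("unfavorable", counts$TP), rep("favorable", counts$FN),
              rep("unfavorable", counts$FP), rep("favorable", counts$TN))
    cm <- confusion_counts(truth, pred)
    expect_identical(cm, counts)
    m <- compute_metrics(cm)
    # independent recomputation from the raw pairs
    acc <- mean(truth == pred)
    prec <- if (sum(pred == "unfavorable") == 0) 0 else
      sum(truth == "unfavorable" & pred == "unfavorable") / sum(pred == "unfavorable")
    rec <- if (sum(truth == "unfavorable") == 0) 0 else
      sum(truth == "unfavorable" & pred == "unfavorable") / sum(truth == "unfavorable")
    f1p <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(m$accuracy, acc, tolerance = 1e-12)
    expect_equal(m$precision, prec, tolerance = 1e-12)
    expect_equal(m$recall, rec, tolerance = 1e-12)
    expect_equal(m$f1, f1p, tolerance = 1e-12)
  }
})

test_that("macro F1 of a constant single-class predictor on balance is 1/3", {
  truth <- rep(outcome_levels(), 6)
  pred <- rep("unfavorable", 12)
  expect_equal(macro_f1(truth, pred), 1 / 3)
})

test_that("the comparison harness votes over exactly nine segments per patient", {
  coh <- memo("tiny_comparison_cohort",
              generate_cohort(two_class_config(n_per_class = 4,
                                               segments_per_patient = 10,
                                               seed = 15)))
  roster <- list(mlp_patient = list(type = "mlp", blocks = "patient"))
  res <- run_comparison(coh, roster, split = split_spec(seed = 5), cv = NULL,
                        mlp_epochs = 3, seed = 1)
  pat <- dplyr::filter(res, level == "patient")
  seg <- dplyr::filter(res, level == "segment")
  n_test <- pat$TP + pat$FN + pat$FP + pat$TN
  expect_equal(seg$TP + seg$FN + seg$FP + seg$TN, n_test * 9)
})

test_that("comparison results do not depend on roster order", {
  coh <- memo("tiny_comparison_cohort",
              generate_cohort(two_class_config(n_per_class = 4,
                                               segments_per_patient = 10,
                                               seed = 15)))
  r1 <- list(mlp_patient = list(type = "mlp", blocks = "patient"),
             mlp_td = list(type = "mlp", blocks = "td"))
  r2 <- rev(r1)
  a <- run_comparison(coh, r1, split = split_spec(seed = 5), cv = NULL,
                      mlp_epochs = 3, seed = 1)
  b <- run_comparison(coh, r2, split = split_spec(seed = 5), cv = NULL,
                      mlp_epochs = 3, seed = 1)
  a <- dplyr::arrange(a, model, level)
  b <- dplyr::arrange(b, model, level)
  expect_equal(a, b)
})

test_that("the multimodal fusion model dominates the TD-only MLP in CV", {
  res <- separable_comparison()
  s <- summarize_comparison(res)
  f1_fusion <- s$f1_macro_mean[s$model == "cnn_lstm_patient_td"]
  f1_mlp <- s$f1_macro_mean[s$model == "mlp_td"]
  expect_gte(f1_fusion, 0.90)
  expect_gt(f1_fusion, f1_mlp)
})
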