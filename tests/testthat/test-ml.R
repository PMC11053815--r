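# Helper: widely separated two-class data that every family can fit exactly.
separable_data <- function(n_per_class = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    f1 = c(runif(n_per_class, 2, 3), runif(n_per_class, -3, -2)),
    f2 = c(runif(n_per_class, 1, 2), runif(n_per_class, -2, -1)),
    label = rep(c(1L, 0L), each = n_per_class)
  )
}

test_that("confusion metrics agree with a counting oracle on random vectors", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    pred <- rbinom(n, 1, runif(1))
    truth <- rbinom(n, 1, runif(1))
    got <- classification_metrics(pred, truth)
    want <- oracle_metrics(pred, truth)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("threshold-sweep AUC equals the mid-rank Mann-Whitney statistic", {
  set.seed(67)
  for (i in 1:200) {
    n <- sample(6:80, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    score <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties often
    expect_equal(auc_roc(score, truth), oracle_auc_mw(score, truth),
                 tolerance = 1e-9)
  }
  expect_error(auc_roc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC cross-checks against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(71)
  for (i in 1:20) {
    truth <- c(0, 1, rbinom(40, 1, 0.5))
    score <- round(rnorm(42), 1)
    expect_equal(auc_roc(score, truth),
                 as.numeric(pROC::auc(pROC::roc(truth, score,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-9)
  }
})

test_that("stratified folds balance sizes and class ratio", {
  set.seed(73)
  y <- rep(c(1L, 0L), c(109, 654))
  folds <- stratified_folds(y, k = 5, seed = 2)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 1L)
  pos_per_fold <- tapply(y, folds, sum)
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1L)
  # same seed, same assignment
  expect_identical(folds, stratified_folds(y, k = 5, seed = 2))
})

test_that("all families reach perfect metrics on separable data", {
  d <- separable_data()
  for (fam in c("rf_classifier", "svm_classifier", "gnb_classifier",
                "mlp_classifier")) {
    r <- five_fold_cv(d, model_spec(fam, c("f1", "f2"), seed = 3))
    expect_equal(r$mean$accuracy, 1.0, info = fam)
    expect_equal(r$mean$tpr, 1.0, info = fam)
  }
  for (fam in c("linear_regression", "logistic_regression",
                "rf_regression", "gb_regression")) {
    r <- five_fold_cv(d, model_spec(fam, c("f1", "f2"), seed = 3))
    expect_equal(r$mean$auc, 1.0, info = fam)
  }
})

test_that("CV rejects degenerate inputs", {
  d <- separable_data()
  d_one <- d; d_one$label <- 1L
  expect_error(five_fold_cv(d_one, model_spec("rf_classifier", "f1")),
               "both classes")
  d_na <- d; d_na$f1[3] <- NA
  expect_error(five_fold_cv(d_na, model_spec("rf_classifier", c("f1", "f2"))),
               "NA")
  expect_error(five_fold_cv(d, model_spec("rf_classifier", "nope")),
               "absent")
  tiny <- d[c(1:5, 41:45), ]
  expect_error(five_fold_cv(tiny, model_spec("rf_classifier", "f1")),
               "at least")
})

test_that("feature-combination search enumerates subsets and finds the signal", {
  d <- separable_data(n_per_class = 30, seed = 5)
  search1 <- feature_combination_search(d, "rf_classifier", "f1", seed = 1)
  expect_equal(nrow(search1$results), 1L)

  set.seed(79)
  d$noise1 <- rnorm(nrow(d)); d$noise2 <- rnorm(nrow(d))
  search3 <- feature_combination_search(d, "rf_classifier",
                                        c("f1", "noise1", "noise2"),
                                        seed = 1)
  expect_equal(nrow(search3$results), 7L)  # 2^3 - 1
  expect_true("f1" %in% search3$best$features)
  # tie-break prefers fewer features: the single signal feature wins
  expect_equal(search3$best$features, "f1")
})

test_that("final models expose normalized importances and reproducible fits", {
  d <- generate_training_dataset(synthetic_config(seed = 8))
  cls <- model_spec("rf_classifier",
                    c("antigenicity", "hydropathicity", "mhcflurry_rank",
                      "wt_mut_rank_ratio", "stability_halflife"), seed = 8)
  rnk <- model_spec("linear_regression",
                    c("mhcflurry_rank", "wt_mut_rank_ratio",
                      "stability_halflife"), seed = 8)
  m1 <- train_final_models(d, cls, rnk)
  expect_equal(sum(m1$importance), 1.0, tolerance = 1e-9)
  expect_true(all(m1$importance >= 0))

  newx <- generate_training_dataset(synthetic_config(seed = 99))[1:50, ]
  newx$mutant_sequence <- replicate(50, random_peptide(9))
  newx$allele <- "HLA-A*02:01"
  r1 <- classify_and_rank(newx, m1)
  m2 <- train_final_models(d, cls, rnk)
  r2 <- classify_and_rank(newx, m2)
  expect_equal(r1, r2)
})

test_that("binding rank dominates importance when it carries the signal", {
  hits <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(seed = s)
    d <- generate_training_dataset(cfg)
    m <- train_final_models(
      d,
      model_spec("rf_classifier",
                 c("mhcflurry_rank", "hydropathicity"), seed = s),
      model_spec("linear_regression", "mhcflurry_rank", seed = s)
    )
    if (names(which.max(m$importance)) == "mhcflurry_rank") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("classified pairs sort by ID, then score, then lexicographic keys", {
  d <- separable_data(30, seed = 11)
  models <- train_final_models(
    d,
    model_spec("rf_classifier", c("f1", "f2"), seed = 1),
    model_spec("linear_regression", c("f1", "f2"), seed = 1)
  )
  set.seed(83)
  pairs <- data.frame(
    mutant_sequence = replicate(40, random_peptide(9)),
    allele = sample(default_allele_panel("I")$allele, 40, replace = TRUE),
    f1 = runif(40, -3, 3), f2 = runif(40, -2, 2),
    stringsAsFactors = FALSE
  )
  ranked <- classify_and_rank(pairs, models)
  expect_true(all(diff(ranked$id_label) <= 0))  # positives first, always
  for (id in unique(ranked$id_label)) {
    sub <- ranked[ranked$id_label == id, ]
    expect_true(all(diff(sub$score) <= 1e-12))
  }
  # equal ID and score -> lexicographic (epitope, allele)
  tie <- data.frame(
    mutant_sequence = c("CCCCCCCCC", "AAAAAAAAA", "AAAAAAAAA"),
    allele = c("HLA-A*01:01", "HLA-B*07:02", "HLA-A*01:01"),
    f1 = 2.5, f2 = 1.5, stringsAsFactors = FALSE
  )
  rt <- classify_and_rank(tie, models)
  expect_equal(rt$mutant_sequence, c("AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC"))
  expect_equal(rt$allele[1:2], c("HLA-A*01:01", "HLA-B*07:02"))
})

test_that("saturated ranker scores trigger the too-close-to-compare warning", {
  d <- separable_data(40, seed = 13)
  models <- train_final_models(
    d,
    model_spec("rf_classifier", c("f1", "f2"), seed = 1),
    model_spec("logistic_regression", c("f1", "f2"), seed = 1)
  )
  pairs <- data.frame(
    mutant_sequence = replicate(30, random_peptide(9)),
    allele = "HLA-A*02:01",
    f1 = c(runif(15, 2, 3), runif(15, -3, -2)),
    f2 = c(runif(15, 1, 2), runif(15, -2, -1)),
    stringsAsFactors = FALSE
  )
  expect_warning(classify_and_rank(pairs, models), "too close to compare")
})

test_that("epitope screening reports the fraction with a positive pair", {
  d <- generate_training_dataset(synthetic_config(seed = 14))
  models <- train_final_models(
    d,
    model_spec("rf_classifier",
               c("antigenicity", "hydropathicity", "mhcflurry_rank",
                 "wt_mut_rank_ratio", "stability_halflife"), seed = 14),
    model_spec("linear_regression",
               c("mhcflurry_rank", "wt_mut_rank_ratio",
                 "stability_halflife"), seed = 14)
  )
  reg <- build_registry(seed = 14)
  set.seed(89)
  eps <- unique(replicate(12, random_peptide(9)))
  res <- screen_epitope_list(eps, default_allele_panel("I"), models, reg)
  expect_equal(nrow(res$per_epitope), length(eps))
  expect_equal(res$fraction, mean(res$per_epitope$any_positive))
  expect_gte(res$fraction, 0); expect_lte(res$fraction, 1)
  expect_error(screen_epitope_list(character(0), default_allele_panel("I"),
                                   models, reg),
               "empty")
})
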