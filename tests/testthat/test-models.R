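test_that("LOSO folds partition the table, one fold per subject", {
  tab <- small_table() # 3 subjects
  folds <- loso_folds(tab)
  expect_length(folds, 3L)
  test_idx <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(test_idx)), seq_len(nrow(tab)))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L) # no leakage
    expect_identical(unique(tab$subject_id[f$test]), f$subject)
    expect_false(f$subject %in% tab$subject_id[f$train])
  }
  # two subjects: complementary folds
  tab2 <- tab[tab$subject_id %in% c("S1", "S2"), ]
  f2 <- loso_folds(tab2)
  expect_length(f2, 2L)
  expect_identical(sort(c(f2[[1]]$test, f2[[2]]$test)), seq_len(nrow(tab2)))
  expect_error(loso_folds(tab[tab$subject_id == "S1", ]), "2 subjects")
})

test_that("the target muscle is excluded from the feature set", {
  tab <- small_table()
  folds <- loso_folds(tab)
  fp <- fit_predict_target(tab[folds[[1]]$train, ], tab[folds[[1]]$test, ],
                           "supraspinatus", model_spec("knn"))
  expect_false("supraspinatus" %in% fp$features)
  expect_setequal(fp$features,
                  c(setdiff(emg_muscles(), "supraspinatus"),
                    "movement_code"))
  expect_length(fp$predictions, length(folds[[1]]$test))
  expect_error(
    fit_predict_target(tab[0, ], tab, "trapezius", model_spec("knn")),
    "empty")
  expect_error(
    fit_predict_target(tab[setdiff(names(tab), "trapezius")], tab,
                       "trapezius", model_spec("knn")),
    "absent")
})

test_that("a tree ensemble memorizes when test equals train", {
  tab <- small_table()
  sub <- tab[tab$subject_id == "S1", ][1:60, ]
  fp <- fit_predict_target(sub, sub, "trapezius", model_spec("xgb"))
  expect_lt(mse(sub$trapezius, fp$predictions), 1e-3)
})

test_that("k-NN predicts a constant when the training target is constant", {
  tab <- small_table()[1:80, ]
  tab$trapezius <- 0.6
  fp <- fit_predict_target(tab, tab[1:10, ], "trapezius",
                           model_spec("knn"))
  expect_equal(fp$predictions, rep(0.6, 10))
})

test_that("seeded stochastic learners are run-to-run deterministic", {
  tab <- small_table()
  tr <- tab[tab$subject_id != "S1", ][1:150, ]
  te <- tab[tab$subject_id == "S1", ][1:40, ]
  for (kind in c("adaboost", "xgb")) {
    a <- fit_predict_target(tr, te, "infraspinatus",
                            model_spec(kind, seed = 5))
    b <- fit_predict_target(tr, te, "infraspinatus",
                            model_spec(kind, seed = 5))
    expect_identical(a$predictions, b$predictions)
  }
})

test_that("the AdaBoost.R2 learner captures a smooth nonlinear signal", {
  set.seed(4)
  X <- matrix(runif(400), ncol = 2)
  y <- sin(2 * pi * X[, 1]) + 0.5 * X[, 2]
  tr <- data.frame(subject_id = "S1", movement_code = 0, y = y, X)
  names(tr)[4:5] <- c("f1", "f2")
  fit <- emgdose:::adaboost_r2_fit(as.matrix(tr[c("f1", "f2")]), tr$y)
  pred <- emgdose:::adaboost_r2_predict(fit, as.matrix(tr[c("f1", "f2")]))
  expect_gt(r_squared(tr$y, pred), 0.9)
})

test_that("run_comparison produces one result per model x fold x muscle", {
  tab <- small_table()
  rep <- run_comparison(tab, list(model_spec("knn"), model_spec("xgb")))
  expect_s3_class(rep, "cv_report")
  expect_identical(nrow(rep$folds), 2L * 3L * 6L)
  expect_true(all(rep$folds$mse >= 0))
  expect_true(all(rep$folds$r2 <= 1))
  expect_true(all(rep$folds$n_test_windows > 0))
  # grand mean equals the mean over fold x muscle cells
  for (k in c("knn", "xgb")) {
    d <- rep$folds[rep$folds$model == k, ]
    expect_equal(rep$grand$mean_r2[rep$grand$model == k], mean(d$r2))
    expect_equal(rep$grand$mean_mse[rep$grand$model == k], mean(d$mse))
  }
  # ranked by R2 first
  expect_true(!is.unsorted(rev(rep$grand$mean_r2)))
  # hyperparameters recorded for reproducibility
  expect_named(rep$hyperparameters, c("knn", "xgb"))
  expect_equal(rep$hyperparameters$knn$k, 5L)
})

test_that("per-muscle summary groups the six muscles by anatomical layer", {
  tab <- small_table()
  rep <- run_comparison(tab, model_spec("knn"))
  pm <- per_muscle_summary(rep)
  expect_identical(nrow(pm), 6L)
  expect_identical(sum(pm$layer == "superficial"), 3L)
  expect_identical(sum(pm$layer == "deep"), 3L)
  # unweighted grand mean equals the mean of per-muscle means (balanced
  # design)
  expect_equal(mean(pm$r2), rep$grand$mean_r2)
  expect_equal(mean(pm$mse), rep$grand$mean_mse)
})

test_that("an unstructured cohort yields no cross-subject predictability", {
  # no shared drive, identical gains, flat envelope: the only variation in
  # windowed RMS is independent estimation noise, so held-out R2 sits
  # near zero
  cfg <- cohort_config(n_subjects = 3, n_sessions = 1,
                       duration_per_trial = 4,
                       shared_drive_correlation = 0,
                       gain_table = make_default_gain_table(high = 1,
                                                            low = 1),
                       envelope_period_s = 0, seed = 55)
  tab <- build_feature_table(generate_cohort(cfg))
  rep <- run_comparison(tab, model_spec("xgb", seed = 1))
  expect_lt(rep$grand$mean_r2, 0.1)
})

test_that("window-weighted aggregation is available and differs only by weights", {
  tab <- small_table()
  u <- run_comparison(tab, model_spec("knn"))
  w <- run_comparison(tab, model_spec("knn"),
                      aggregation = "window_weighted")
  d <- u$folds
  expect_equal(w$grand$mean_r2,
               weighted.mean(d$r2, d$n_test_windows))
})
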