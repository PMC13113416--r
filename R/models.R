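#' Specify a regression model for the cross-subject benchmark
#'
#' The menu mirrors the four learners benchmarked for cross-subject
#' muscle-activation prediction: support vector regression, k-nearest
#' neighbours, adaptive boosting (AdaBoost.R2 over shallow regression
#' trees) and gradient-boosted trees. Hyperparameters default to the
#' established implementations' defaults and are recorded in the report so
#' every run is reproducible from its config.
#'
#' @param kind One of `"svr"`, `"knn"`, `"adaboost"`, `"xgb"`.
#' @param hyperparameters Named list overriding the defaults below.
#' @param seed Integer seed applied around each fit (stochastic learners).
#' @return An object of class `model_spec`.
#' @details Defaults: SVR — radial kernel, cost 1, epsilon 0.1
#'   (e1071::svm); KNN — k = 5 (caret::knnreg); AdaBoost — 50 estimators,
#'   linear loss, depth-3 rpart trees; XGBoost — 100 rounds, eta 0.3,
#'   max_depth 6 (xgboost).
#' @examples
#' model_spec("xgb")
#' model_spec("knn", list(k = 3))
#' @export
model_spec <- function(kind = c("xgb", "svr", "knn", "adaboost"),
                       hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svr = list(kernel = "radial", cost = 1, epsilon = 0.1),
    knn = list(k = 5L),
    adaboost = list(n_estimators = 50L, maxdepth = 3L, loss = "linear"),
    xgb = list(nrounds = 100L, eta = 0.3, max_depth = 6L, subsample = 1,
               objective = "reg:squarederror")
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$kind, "(",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = "=", collapse = ", "),
      ") seed", x$seed, "\n")
  invisible(x)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: the test rows are all and only that subject's
#' windows, the training rows everything else. Folds partition the table.
#'
#' @param table An [build_feature_table()] result (or any data.frame with a
#'   `subject_id` column).
#' @return List of folds, each `list(subject, train, test)` with integer
#'   row indices.
#' @export
loso_folds <- function(table) {
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out validation needs at least 2 subjects",
         call. = FALSE)
  lapply(subjects, function(s) {
    test <- which(table$subject_id == s)
    list(subject = s, train = setdiff(seq_len(nrow(table)), test),
         test = test)
  })
}

model_matrix_for <- function(table, target_muscle, muscles,
                             movement_onehot = FALSE) {
  feats <- setdiff(muscles, target_muscle)
  X <- as.matrix(as.data.frame(table)[feats])
  if (movement_onehot) {
    mv <- factor(table$movement_code, levels = 0:3)
    oh <- stats::model.matrix(~ mv - 1)
    colnames(oh) <- paste0("movement_", levels(mv))
    X <- cbind(X, oh)
  } else {
    X <- cbind(X, movement_code = as.numeric(table$movement_code))
  }
  X
}

#' Fit one model on the training rows and predict the held-out rows
#'
#' Features are the five non-target muscles' normalized RMS plus the
#' encoded movement; the target is the target muscle's normalized RMS.
#' Training time is measured around the fit call only.
#'
#' @param train,test Data frames of feature-table rows sharing columns.
#' @param target_muscle Muscle whose activation is predicted.
#' @param spec A [model_spec()].
#' @param muscles Full muscle set (default [emg_muscles()]).
#' @param movement_onehot Encode movement as four indicator columns instead
#'   of a single numeric code (default FALSE, mirroring label encoding).
#' @return List with `predictions` (test-row order), `train_time`
#'   (seconds) and `features` (feature column names used).
#' @export
fit_predict_target <- function(train, test, target_muscle, spec,
                               muscles = emg_muscles(),
                               movement_onehot = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (!target_muscle %in% names(train))
    stop("target column '", target_muscle, "' absent from training data",
         call. = FALSE)
  if (!nrow(train)) stop("empty training set", call. = FALSE)
  Xtr <- model_matrix_for(train, target_muscle, muscles, movement_onehot)
  Xte <- model_matrix_for(test, target_muscle, muscles, movement_onehot)
  y <- train[[target_muscle]]
  hp <- spec$hyperparameters

  fit_fun <- switch(spec$kind,
    svr = function() {
      fit <- e1071::svm(x = Xtr, y = y, type = "eps-regression",
                        kernel = hp$kernel, cost = hp$cost,
                        epsilon = hp$epsilon)
      function(X) as.numeric(stats::predict(fit, X))
    },
    knn = function() {
      fit <- caret::knnreg(Xtr, y, k = hp$k)
      function(X) as.numeric(stats::predict(fit, as.data.frame(X)))
    },
    adaboost = function() {
      fit <- adaboost_r2_fit(Xtr, y, n_estimators = hp$n_estimators,
                             maxdepth = hp$maxdepth, loss = hp$loss)
      function(X) adaboost_r2_predict(fit, X)
    },
    xgb = function() {
      fit <- xgboost::xgboost(
        x = Xtr, y = y, nrounds = hp$nrounds,
        objective = hp$objective, learning_rate = hp$eta,
        max_depth = hp$max_depth, subsample = hp$subsample,
        nthreads = 1, seed = spec$seed, verbosity = 0)
      function(X) as.numeric(stats::predict(fit, X))
    }
  )
  t0 <- proc.time()[["elapsed"]]
  predictor <- with_seed(spec$seed, fit_fun())
  train_time <- proc.time()[["elapsed"]] - t0
  list(predictions = predictor(Xte), train_time = train_time,
       features = colnames(Xtr))
}

# AdaBoost.R2 (Drucker 1997) over rpart regression trees: weighted
# resampling, linear/square/exponential loss, weighted-median prediction.
adaboost_r2_fit <- function(X, y, n_estimators = 50L, maxdepth = 3L,
                            loss = c("linear", "square", "exponential")) {
  loss <- match.arg(loss)
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(y = y, X, check.names = FALSE)
  models <- list()
  betas <- numeric(0)
  for (t in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(y ~ ., data = df[idx, , drop = FALSE],
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, xval = 0,
                          minsplit = 2))
    pred <- stats::predict(fit, df)
    ar <- abs(pred - y)
    d <- max(ar)
    if (d == 0) { # perfect learner: keep it with full confidence and stop
      models[[length(models) + 1L]] <- fit
      betas <- c(betas, 1e-10)
      break
    }
    l <- switch(loss,
                linear = ar / d,
                square = (ar / d)^2,
                exponential = 1 - exp(-ar / d))
    lbar <- sum(w * l)
    if (lbar >= 0.5) break
    beta <- lbar / (1 - lbar)
    models[[length(models) + 1L]] <- fit
    betas <- c(betas, beta)
    w <- w * beta^(1 - l)
    w <- w / sum(w)
  }
  if (!length(models))
    stop("adaboost: first weak learner already exceeded 0.5 weighted loss",
         call. = FALSE)
  structure(list(models = models, betas = betas), class = "adaboost_r2")
}

adaboost_r2_predict <- function(object, X) {
  P <- vapply(object$models,
              function(m) stats::predict(m, as.data.frame(X)),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  wts <- log(1 / object$betas)
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= 0.5 * sum(wts))[1]]
  })
}

#' Run the full LOSO model comparison
#'
#' For every model spec, fold and target muscle, fits on the other
#' subjects' windows and scores the held-out subject: one
#' `(model, fold, muscle)` result row with MSE, R-squared, train time and
#' test size. Grand means aggregate over all fold x muscle cells
#' (unweighted by default; `"window_weighted"` weights cells by test-window
#' count), with fold-wise dispersion. Models are ranked by grand
#' R-squared first and MSE second.
#'
#' @param table An [build_feature_table()] result.
#' @param specs List of [model_spec()]s (a single spec is accepted).
#' @param targets Target muscles (default: all six).
#' @param aggregation `"unweighted"` (default) or `"window_weighted"`.
#' @param movement_onehot See [fit_predict_target()].
#' @param keep_predictions Retain pooled test-set predictions per model
#'   (needed to build an [activation_profile()]).
#' @return An object of class `cv_report`: list with `folds` (one row per
#'   model x fold x muscle), `grand` (per-model means, dispersion, total
#'   train time, ranked), `hyperparameters`, `aggregation`, and optionally
#'   `predictions`.
#' @export
run_comparison <- function(table, specs, targets = NULL,
                           aggregation = c("unweighted", "window_weighted"),
                           movement_onehot = FALSE,
                           keep_predictions = FALSE) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L)
  aggregation <- match.arg(aggregation)
  muscles <- attr(table, "muscles")
  if (is.null(muscles)) muscles <- intersect(emg_muscles(), names(table))
  if (is.null(targets)) targets <- muscles
  folds <- loso_folds(table)

  rows <- list()
  preds <- list()
  for (spec in specs) {
    for (fold in folds) {
      train <- table[fold$train, , drop = FALSE]
      test <- table[fold$test, , drop = FALSE]
      for (m in targets) {
        fp <- fit_predict_target(train, test, m, spec, muscles,
                                 movement_onehot)
        rows[[length(rows) + 1L]] <- data.frame(
          model = spec$kind, held_out_subject = fold$subject,
          target_muscle = m, mse = mse(test[[m]], fp$predictions),
          r2 = r_squared(test[[m]], fp$predictions),
          train_time = fp$train_time, n_test_windows = nrow(test))
        if (keep_predictions)
          preds[[length(preds) + 1L]] <- data.frame(
            model = spec$kind, subject_id = test$subject_id,
            movement = test$movement, movement_code = test$movement_code,
            window_index = test$window_index, muscle = m,
            observed = test[[m]], predicted = fp$predictions)
      }
    }
  }
  fold_df <- do.call(rbind, rows)
  rownames(fold_df) <- NULL

  grand <- do.call(rbind, lapply(unique(fold_df$model), function(k) {
    d <- fold_df[fold_df$model == k, ]
    w <- if (aggregation == "window_weighted") d$n_test_windows
         else rep(1, nrow(d))
    data.frame(model = k,
               mean_mse = stats::weighted.mean(d$mse, w),
               mean_r2 = stats::weighted.mean(d$r2, w),
               sd_mse = stats::sd(d$mse), sd_r2 = stats::sd(d$r2),
               total_train_time = sum(d$train_time),
               n_fits = nrow(d))
  }))
  grand <- grand[order(-grand$mean_r2, grand$mean_mse), ]
  rownames(grand) <- NULL

  structure(list(
    folds = fold_df, grand = grand,
    hyperparameters = stats::setNames(
      lapply(specs, function(s) c(s$hyperparameters, seed = s$seed)),
      vapply(specs, `[[`, "", "kind")),
    aggregation = aggregation,
    predictions = if (keep_predictions) do.call(rbind, preds) else NULL
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  cat("Leave-one-subject-out cross-validation report\n")
  cat(sprintf("  %d folds x %d target muscle(s), aggregation: %s\n",
              length(unique(x$folds$held_out_subject)),
              length(unique(x$folds$target_muscle)), x$aggregation))
  print(format(x$grand, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  list(grand = object$grand, per_muscle = per_muscle_summary(object))
}

#' Per-muscle performance summary, grouped by anatomical layer
#'
#' Mean MSE and R-squared per target muscle across folds, tagged
#' superficial/deep, per model.
#'
#' @param report A [run_comparison()] result.
#' @param model Optional model kind to restrict to.
#' @param layer_map Named muscle -> layer map.
#' @return Data frame with one row per model x muscle.
#' @export
per_muscle_summary <- function(report, model = NULL,
                               layer_map = muscle_layer_map()) {
  stopifnot(inherits(report, "cv_report"))
  d <- report$folds
  if (!is.null(model)) d <- d[d$model == model, ]
  if (!nrow(d)) stop("no fold results for the requested model", call. = FALSE)
  agg <- stats::aggregate(cbind(mse, r2) ~ model + target_muscle, data = d,
                          FUN = mean)
  agg$layer <- unname(layer_map[agg$target_muscle])
  agg <- agg[order(agg$model, agg$layer == "deep", agg$target_muscle), ]
  rownames(agg) <- NULL
  agg
}

#' Pooled LOSO test-set predictions for every target muscle
#'
#' Convenience wrapper: runs [run_comparison()] for a single model with
#' `keep_predictions = TRUE` and returns the pooled held-out predictions,
#' the input expected by [activation_profile()].
#'
#' @inheritParams run_comparison
#' @param spec A single [model_spec()].
#' @return Data frame of pooled out-of-fold predictions (one row per
#'   window x target muscle).
#' @export
loso_predict_all <- function(table, spec, targets = NULL,
                             movement_onehot = FALSE) {
  rep <- run_comparison(table, spec, targets = targets,
                        movement_onehot = movement_onehot,
                        keep_predictions = TRUE)
  rep$predictions
}
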