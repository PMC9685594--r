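# Regression models mapping descriptor vectors to the CV of maximum
# transmission: standardization, Lasso (glmnet), and a stacked ensemble of
# gradient-boosted trees + random forest + L1-penalized linear base learners
# combined by a non-negativity-constrained linear meta-learner fitted on
# out-of-fold base predictions.

#' Assemble a training table
#'
#' @param features Numeric matrix (rows = ions, columns = registry features).
#' @param target Numeric vector of target CVs (volts), one per row.
#' @param registry The [feature_registry()] the features were computed with.
#' @param ids Optional ion identifiers (defaults to feature row names).
#' @return Object of class `training_table`.
#' @export
training_table <- function(features, target, registry = feature_registry(),
                           ids = rownames(features)) {
  features <- as.matrix(features)
  if (nrow(features) != length(target)) stop("features/target length mismatch")
  if (!all(is.finite(features)) || !all(is.finite(target))) {
    stop("training table contains non-finite values")
  }
  structure(list(features = features, target = as.numeric(target),
                 registry = registry, ids = ids),
            class = "training_table")
}

#' @export
print.training_table <- function(x, ...) {
  cat("<training_table> ", nrow(x$features), " ions x ",
      ncol(x$features), " features\n", sep = "")
  invisible(x)
}

#' Standardize the feature columns of a training table
#'
#' Each column is centered by its training mean and scaled by its training
#' standard deviation; zero-variance columns map to all zeros. The statistics
#' are returned for reuse at prediction time.
#'
#' @param table A [training_table()] with at least 2 rows.
#' @return List with `table` (standardized `training_table`), `center` and
#'   `scale` (named vectors; `scale` is 1 for zero-variance columns).
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "training_table"))
  if (nrow(table$features) < 2L) stop("standardization needs >= 2 rows")
  ctr <- colMeans(table$features)
  scl <- apply(table$features, 2, stats::sd)
  scl[scl == 0] <- 1
  std <- sweep(sweep(table$features, 2, ctr), 2, scl, "/")
  tab <- table
  tab$features <- std
  list(table = tab, center = ctr, scale = scl)
}

apply_standardization <- function(features, center, scale) {
  sweep(sweep(as.matrix(features), 2, center), 2, scale, "/")
}

#' Fit an L1-penalized (Lasso) linear model
#'
#' Features are standardized internally so coefficients are directly
#' comparable; `penalty = "cv"` selects the penalty by k-fold cross-validated
#' mean absolute error over glmnet's log-spaced path (plain minimum, no
#' one-standard-error rule).
#'
#' @param table A [training_table()].
#' @param penalty Non-negative numeric penalty (lambda, on the standardized
#'   scale) or `"cv"` (requires >= 10 rows).
#' @param nfolds Folds for cross-validated penalty selection.
#' @param seed Seed controlling fold assignment.
#' @return Object of class `cv_linear_model` holding intercept, coefficients
#'   (standardized scale), standardization statistics, penalty and registry.
#' @export
fit_lasso <- function(table, penalty = "cv", nfolds = 5, seed = 1) {
  stopifnot(inherits(table, "training_table"))
  std <- standardize(table)
  x <- std$table$features
  y <- table$target
  if (stats::sd(y) == 0) {
    # constant target: every coefficient is shrunk away at any penalty
    return(structure(list(
      intercept = y[1],
      coefficients = stats::setNames(rep(0, ncol(x)), colnames(x)),
      center = std$center, scale = std$scale,
      penalty = if (identical(penalty, "cv")) 0 else penalty,
      registry = table$registry), class = "cv_linear_model"))
  }
  if (identical(penalty, "cv")) {
    if (nrow(x) < 10L) stop("cv-selected penalty needs >= 10 rows")
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cvfit <- glmnet::cv.glmnet(x, y, alpha = 1, standardize = FALSE,
                               type.measure = "mae", foldid = foldid)
    lambda <- cvfit$lambda.min
    cf <- as.numeric(stats::coef(cvfit$glmnet.fit, s = lambda))
  } else {
    stopifnot(is.numeric(penalty), penalty >= 0)
    lambda <- penalty
    fit <- glmnet::glmnet(x, y, alpha = 1, standardize = FALSE)
    cf <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                                 alpha = 1, standardize = FALSE))
  }
  structure(list(intercept = cf[1],
                 coefficients = stats::setNames(cf[-1], colnames(x)),
                 center = std$center, scale = std$scale,
                 penalty = lambda, registry = table$registry),
            class = "cv_linear_model")
}

#' @export
print.cv_linear_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("<cv_linear_model> lambda = ", signif(x$penalty, 4), ", ", nz,
      " nonzero of ", length(x$coefficients), " coefficients\n", sep = "")
  invisible(x)
}

#' Rank standardized coefficients of a fitted linear model
#'
#' Coefficients are reported on the standardized (per-SD) scale, sorted by
#' absolute value descending; ties are broken by registry order.
#'
#' @param model A fitted [fit_lasso()] model.
#' @param threshold Drop coefficients with `|beta| <=` this value (default 0
#'   keeps the full ranking of nonzero coefficients).
#' @return data.frame with `feature` and `coefficient`.
#' @export
standardized_coefficients <- function(model, threshold = 0) {
  if (!inherits(model, "cv_linear_model")) stop("model is not a fitted linear model")
  cf <- model$coefficients
  keep <- abs(cf) > threshold
  cf <- cf[keep]
  ord <- order(-abs(cf), match(names(cf), model$registry$features))
  data.frame(feature = names(cf)[ord], coefficient = unname(cf[ord]))
}

# ---- stacked ensemble -------------------------------------------------------

default_ensemble_config <- function() {
  list(
    nfolds = 5,
    xgb = list(nrounds = 150, eta = 0.08, max_depth = 4,
               subsample = 0.8, colsample_bytree = 0.8),
    rf = list(num.trees = 300, min.node.size = 5),
    lasso = list(nfolds = 5))
}

fit_base_learners <- function(x, y, config, seed) {
  set.seed(seed)
  xgb <- xgboost::xgboost(
    x, y, objective = "reg:squarederror", nrounds = config$xgb$nrounds,
    learning_rate = config$xgb$eta, max_depth = config$xgb$max_depth,
    subsample = config$xgb$subsample,
    colsample_bytree = config$xgb$colsample_bytree,
    nthreads = 1, seed = seed, verbosity = 0)
  rf <- ranger::ranger(x = x, y = y, num.trees = config$rf$num.trees,
                       min.node.size = config$rf$min.node.size,
                       seed = seed, num.threads = 1)
  if (stats::sd(y) == 0) {
    lasso <- structure(list(constant = y[1]), class = "constant_learner")
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(config$lasso$nfolds), length(y)))
    lasso <- glmnet::cv.glmnet(x, y, alpha = 1, standardize = TRUE,
                               type.measure = "mae", foldid = foldid)
  }
  list(xgb = xgb, rf = rf, lasso = lasso)
}

predict_base_learners <- function(learners, x) {
  lasso_pred <- if (inherits(learners$lasso, "constant_learner")) {
    rep(learners$lasso$constant, nrow(x))
  } else {
    as.numeric(stats::predict(learners$lasso, newx = x, s = "lambda.min"))
  }
  cbind(xgb = stats::predict(learners$xgb, x),
        rf = stats::predict(learners$rf, data = x, num.threads = 1)$predictions,
        lasso = lasso_pred)
}

# Non-negative least squares blend with a free intercept: minimizing over
# (a, w >= 0) of ||y - a - Pw||^2 reduces to NNLS on the centered design.
fit_meta_learner <- function(oof, y) {
  ctr_p <- colMeans(oof)
  ctr_y <- mean(y)
  sol <- pracma::lsqnonneg(sweep(oof, 2, ctr_p), y - ctr_y)
  w <- stats::setNames(sol$x, colnames(oof))
  list(weights = w, intercept = ctr_y - sum(ctr_p * w))
}

#' Fit a stacked-ensemble CV regressor
#'
#' Trains three base learners (gradient-boosted trees, a random forest, and
#' an L1-penalized linear model) on the full table, and a
#' non-negativity-constrained linear meta-learner on out-of-fold base
#' predictions from k-fold splitting. Fully deterministic given `seed`.
#'
#' @param table A [training_table()] with at least 50 rows.
#' @param config Ensemble configuration (see `default_ensemble_config`
#'   structure); `NULL` for the pinned defaults.
#' @param seed Integer seed controlling folds and learners.
#' @return Object of class `cv_ensemble_model`.
#' @export
fit_stacked_ensemble <- function(table, config = NULL, seed = 1) {
  stopifnot(inherits(table, "training_table"))
  if (is.null(config)) config <- default_ensemble_config()
  x <- table$features
  y <- table$target
  if (nrow(x) < 50L) stop("stacked ensemble needs >= 50 rows")
  if (nrow(x) < config$nfolds) stop("fewer rows than folds")
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(config$nfolds), nrow(x)))
  oof <- matrix(NA_real_, nrow(x), 3, dimnames = list(NULL, c("xgb", "rf", "lasso")))
  for (k in seq_len(config$nfolds)) {
    tr <- foldid != k
    learners_k <- fit_base_learners(x[tr, , drop = FALSE], y[tr], config,
                                    seed = seed + k)
    oof[!tr, ] <- predict_base_learners(learners_k, x[!tr, , drop = FALSE])
  }
  meta <- fit_meta_learner(oof, y)
  learners <- fit_base_learners(x, y, config, seed = seed)
  structure(list(learners = learners, meta = meta, config = config,
                 seed = seed, registry = table$registry,
                 n_features = ncol(x), feature_names = colnames(x)),
            class = "cv_ensemble_model")
}

#' @export
print.cv_ensemble_model <- function(x, ...) {
  cat("<cv_ensemble_model> base learners: xgb, rf, lasso; meta weights: ",
      paste(sprintf("%s=%.3f", names(x$meta$weights), x$meta$weights),
            collapse = ", "), "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Predict CVs from a fitted model
#'
#' @param object A `cv_linear_model` or `cv_ensemble_model`.
#' @param features Numeric matrix of descriptor vectors aligned to the
#'   model's registry (plus the constraint column for a refined model).
#' @param ... Unused.
#' @return Numeric vector of predicted CVs (volts), one per row.
#' @export
predict.cv_linear_model <- function(object, features, ...) {
  features <- as.matrix(features)
  check_feature_names(object, features)
  if (!nrow(features)) return(numeric(0))
  std <- apply_standardization(features, object$center, object$scale)
  as.numeric(object$intercept + std %*% object$coefficients)
}

#' @rdname predict.cv_linear_model
#' @export
predict.cv_ensemble_model <- function(object, features, ...) {
  features <- as.matrix(features)
  check_feature_names(object, features)
  if (!nrow(features)) return(numeric(0))
  base <- predict_base_learners(object$learners, features)
  as.numeric(object$meta$intercept + base %*% object$meta$weights)
}

check_feature_names <- function(model, features) {
  expected <- if (inherits(model, "cv_ensemble_model")) {
    model$feature_names
  } else {
    names(model$coefficients)
  }
  got <- colnames(features)
  if (ncol(features) != length(expected) ||
      (!is.null(got) && !identical(got, expected))) {
    stop("feature registry mismatch: model expects [",
         paste(utils::head(expected, 3), collapse = ", "), ", ... x",
         length(expected), "], got [",
         paste(utils::head(got, 3), collapse = ", "), ", ... x",
         ncol(features), "]")
  }
  invisible(TRUE)
}

#' Evaluate CV predictions
#'
#' @param predictions Predicted CVs (volts).
#' @param targets Observed/target CVs (volts), same length.
#' @param grid Optional [cv_grid()]; when given, absolute errors are grouped
#'   by rounding each target to the nearest grid CV and per-bin accumulation
#'   curves are included.
#' @param thresholds Error thresholds (volts) for the accumulation curves.
#' @return List of class `cv_eval` with `mae`, `r2`, `n` and (with a grid)
#'   `per_bin`, a data.frame of per-bin accumulation curves.
#' @export
evaluate <- function(predictions, targets, grid = NULL,
                     thresholds = seq(0, 30, by = 2.5)) {
  if (length(predictions) != length(targets)) stop("length mismatch")
  if (!length(targets)) stop("evaluate needs >= 1 pair")
  err <- abs(predictions - targets)
  sse <- sum((predictions - targets)^2)
  sst <- sum((targets - mean(targets))^2)
  out <- list(mae = mean(err),
              r2 = if (sst > 0) 1 - sse / sst else NA_real_,
              n = length(targets))
  if (!is.null(grid)) {
    bins <- vapply(targets, function(t) grid[which.min(abs(grid - t))],
                   numeric(1))
    by_bin <- split(err, bins)
    per_bin <- do.call(rbind, Map(function(e, b) {
      data.frame(bin = as.numeric(b), threshold = thresholds,
                 fraction = accumulation_curve(e, thresholds))
    }, by_bin, names(by_bin)))
    rownames(per_bin) <- NULL
    out$per_bin <- per_bin
  }
  class(out) <- "cv_eval"
  out
}

#' @export
print.cv_eval <- function(x, ...) {
  cat("<cv_eval> n = ", x$n, ", MAE = ", round(x$mae, 3), " V, R2 = ",
      round(x$r2, 3), "\n", sep = "")
  invisible(x)
}
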