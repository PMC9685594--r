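reg <- feature_registry()

test_that("standardization centers, scales, and zeroes constant columns", {
  x <- toy_features(40, 4, seed = 1)
  x[, 2] <- 3  # constant column
  tab <- training_table(x, rnorm(40), reg)
  std <- standardize(tab)
  z <- std$table$features
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_equal(unname(apply(z[, -2], 2, sd)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(z[, 2] == 0))
  # stored statistics reproduce the transform
  expect_equal(faimscv:::apply_standardization(x, std$center, std$scale), z)
  expect_error(standardize(training_table(x[1, , drop = FALSE], 0, reg)),
               ">= 2 rows")
})

test_that("lasso recovers a single-feature target as penalty vanishes", {
  x <- toy_features(200, 6, seed = 2)
  xs <- scale(x)
  y <- as.numeric(xs[, 3])
  m <- fit_lasso(training_table(x, y, reg), penalty = 1e-5)
  cf <- m$coefficients
  expect_lt(abs(cf["f3"] - 1), 1e-3)
  expect_lt(max(abs(cf[names(cf) != "f3"])), 1e-3)
})

test_that("degenerate lasso fits behave as the shrinkage limits dictate", {
  x <- toy_features(60, 4, seed = 3)
  const <- training_table(x, rep(-45, 60), reg)
  m0 <- fit_lasso(const, penalty = 0.1)
  expect_true(all(m0$coefficients == 0))
  expect_equal(m0$intercept, -45)

  y <- x[, 1] + rnorm(60, 0, 0.1)
  mbig <- fit_lasso(training_table(x, y, reg), penalty = 1e6)
  expect_true(all(mbig$coefficients == 0))
})

test_that("the number of active coefficients is non-increasing in penalty", {
  x <- toy_features(150, 8, seed = 4)
  y <- 2 * x[, 1] - x[, 2] + 0.5 * x[, 5] + rnorm(150, 0, 0.3)
  tab <- training_table(x, y, reg)
  nz <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.8, 3),
               function(lam) sum(fit_lasso(tab, penalty = lam)$coefficients != 0),
               numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("standardized coefficients are scale-invariant and ranked", {
  x <- toy_features(150, 5, seed = 5)
  y <- 3 * x[, 2] - x[, 4] + rnorm(150, 0, 0.2)
  m1 <- fit_lasso(training_table(x, y, reg), penalty = 0.01)
  x_rescaled <- x
  x_rescaled[, 2] <- x[, 2] * 10
  m2 <- fit_lasso(training_table(x_rescaled, y, reg), penalty = 0.01)
  expect_equal(m2$coefficients[["f2"]], m1$coefficients[["f2"]],
               tolerance = 1e-6)

  ranked <- standardized_coefficients(m1)
  expect_identical(ranked$feature[1], "f2")
  expect_true(all(diff(abs(ranked$coefficient)) <= 0))
  expect_error(standardized_coefficients(list()), "not a fitted")
})

test_that("the stacked ensemble is deterministic and sane on easy targets", {
  x <- toy_features(250, 5, seed = 6)
  y <- 2 * x[, 1] - x[, 3] + 0.5 * x[, 5]
  tr <- 1:200; te <- 201:250
  tab <- training_table(x[tr, ], y[tr], reg)

  m <- fit_stacked_ensemble(tab, seed = 11)
  m_again <- fit_stacked_ensemble(tab, seed = 11)
  expect_identical(predict(m, x[te, ]), predict(m_again, x[te, ]))

  # noiseless linear target: ensemble at least matches the lasso
  lasso <- fit_lasso(tab, seed = 11)
  mae_ens <- mean(abs(predict(m, x[te, ]) - y[te]))
  mae_lasso <- mean(abs(predict(lasso, x[te, ]) - y[te]))
  expect_lte(mae_ens, mae_lasso + 0.05)

  # constant target collapses to the constant
  mc <- fit_stacked_ensemble(training_table(x[tr, ], rep(-50, 200), reg),
                             seed = 11)
  expect_equal(predict(mc, x[te, ]), rep(-50, 50), tolerance = 1e-6)

  expect_error(fit_stacked_ensemble(training_table(x[1:20, ], y[1:20], reg)),
               ">= 50 rows")
})

test_that("the ensemble ties or beats its best base learner on the benchmark", {
  sim <- simulate_cv_dataset(sim_config(n_peptides = 400, seed = 21))
  tab <- make_training_table(sim$profiles, "weighted",
                             include_single_observations = FALSE)
  n <- nrow(tab$features)
  set.seed(22)
  te <- sample(n, round(0.25 * n))
  tr_tab <- training_table(tab$features[-te, ], tab$target[-te], reg,
                           tab$ids[-te])
  m <- fit_stacked_ensemble(tr_tab, seed = 23)
  base <- faimscv:::predict_base_learners(m$learners, tab$features[te, ])
  mae_base <- apply(abs(base - tab$target[te]), 2, mean)
  mae_ens <- mean(abs(predict(m, tab$features[te, ]) - tab$target[te]))
  expect_lte(mae_ens, min(mae_base) * 1.05)
})

test_that("prediction respects order, emptiness and registry identity", {
  x <- toy_features(120, 4, seed = 7)
  y <- x[, 1] + rnorm(120, 0, 0.1)
  m <- fit_lasso(training_table(x, y, reg), penalty = 0.01)
  p <- predict(m, x)
  perm <- sample(120)
  expect_equal(predict(m, x[perm, ]), p[perm])
  expect_length(predict(m, x[0, , drop = FALSE]), 0L)
  bad <- x
  colnames(bad) <- paste0("g", 1:4)
  expect_error(predict(m, bad), "registry mismatch")
  expect_error(predict(m, x[, 1:3]), "registry mismatch")
})

test_that("training-set predictions of a zero-noise linear fit are exact", {
  x <- toy_features(100, 3, seed = 8)
  y <- -40 + 2 * x[, 1] - 3 * x[, 2]
  m <- fit_lasso(training_table(x, y, reg), penalty = 1e-7)
  expect_lt(max(abs(predict(m, x) - y)), 1e-4)
})

test_that("evaluation metrics match hand-derived values", {
  ev <- evaluate(c(1, 1), c(0, 2))
  expect_equal(ev$mae, 1)
  expect_equal(ev$r2, 0)

  perfect <- evaluate(c(-40, -50, -60), c(-40, -50, -60))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)

  y <- c(-42, -48, -55, -61)
  mean_pred <- evaluate(rep(mean(y), 4), y)
  expect_equal(mean_pred$r2, 0)

  # translation equivariance
  set.seed(9)
  pred <- rnorm(30, -50, 5); obs <- pred + rnorm(30)
  e1 <- evaluate(pred, obs)
  e2 <- evaluate(pred + 7, obs + 7)
  expect_equal(e1$mae, e2$mae)
  expect_equal(e1$r2, e2$r2)

  expect_error(evaluate(1:3, 1:2), "length mismatch")
})

test_that("per-bin error curves group targets on the acquisition grid", {
  grid <- cv_grid(seq(-40, -60, -10))
  ev <- evaluate(c(-41, -49, -58, -62), c(-40, -50, -60, -60), grid = grid,
                 thresholds = c(1, 2, 5))
  expect_setequal(unique(ev$per_bin$bin), c(-40, -50, -60))
  b60 <- subset(ev$per_bin, bin == -60)
  expect_equal(b60$fraction, c(0, 1, 1))  # errors 2 and 2 at the -60 bin
})
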