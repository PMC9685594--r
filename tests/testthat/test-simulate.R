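test_that("peptide generation is reproducible, tryptic-like and in range", {
  cfg <- sim_config(n_peptides = 60, seed = 41)
  a <- generate_peptides(cfg)
  b <- generate_peptides(cfg)
  expect_identical(a, b)
  expect_true(all(substr(a$sequence, nchar(a$sequence), nchar(a$sequence))
                  %in% c("K", "R")))
  expect_true(all(nchar(a$sequence) >= 7 & nchar(a$sequence) <= 30))
  expect_true(all(a$charge %in% 2:4))
})

test_that("true optima follow the configured generative model", {
  # degenerate: no descriptors, no residual -> optimum is a function of charge
  cfg0 <- sim_config(n_peptides = 80, seed = 42, descriptor_weights = numeric(0),
                     residual_sd = 0)
  ions <- generate_peptides(cfg0)
  truth <- assign_true_cv(ions, cfg0)
  expect_equal(truth$true_cv, cfg0$intercept + cfg0$charge_weight * ions$charge)
  expect_length(unique(truth$true_cv[ions$charge == 2]), 1L)

  # single-descriptor model: optimum perfectly correlated with the descriptor
  cfg1 <- sim_config(n_peptides = 80, seed = 43, charge_weight = 0,
                     descriptor_weights = c(qsar_mswhim_MSWHIM1 = 3),
                     residual_sd = 0)
  ions1 <- generate_peptides(cfg1)
  truth1 <- assign_true_cv(ions1, cfg1)
  feats <- featurize_table(ions1$sequence, ions1$charge)
  expect_equal(abs(cor(truth1$true_cv, feats[, "qsar_mswhim_MSWHIM1"])), 1,
               tolerance = 1e-9)

  # default: higher charge means more negative optimum
  cfg <- sim_config(n_peptides = 300, seed = 44)
  truth_d <- assign_true_cv(generate_peptides(cfg), cfg)
  expect_lt(cor(truth_d$charge, truth_d$true_cv), 0)
})

test_that("noise-free profiles peak at the true optimum", {
  cfg <- sim_config(seed = 45, noise_cv = 0)
  ion <- peptide_ion("SIMPLEPEPTIDEK", 2)
  p <- simulate_profile(ion, true_cv = -45, amplitude = 1e6, cfg)
  expect_equal(peak_cv(p), -45)
  # symmetric grid around the optimum: weighted mean equals the optimum
  grid_sym <- cv_grid(seq(-25, -65, -5))
  cfg_sym <- sim_config(seed = 45, noise_cv = 0, grid = grid_sym)
  p_sym <- simulate_profile(ion, true_cv = -45, amplitude = 1e6, cfg_sym)
  expect_equal(weighted_average_cv(p_sym), -45)

  # amplitude below the absolute detection floor: fully censored
  p_empty <- simulate_profile(ion, true_cv = -45,
                              amplitude = cfg$detection_floor / 2, cfg)
  expect_length(p_empty$cv, 0L)
})

test_that("censoring is bounded by the relative detection threshold", {
  cfg <- sim_config(seed = 46, noise_cv = 0, detection_floor = 0)
  p <- simulate_profile(peptide_ion("SIMPLEPEPTIDEK", 2), -45, 1e6, cfg)
  # detected bins are exactly those within the threshold window
  halfwidth <- cfg$sigma * sqrt(2 * log(1 / cfg$threshold))
  grid <- as.numeric(cfg$grid)
  expect_setequal(p$cv, grid[abs(grid - (-45)) <= halfwidth])
})

test_that("training tables honour target choice and single-observation filter", {
  cfg <- sim_config(n_peptides = 120, seed = 47)
  sim <- simulate_cv_dataset(cfg)
  nd <- vapply(sim$profiles, function(p) length(p$cv), integer(1))

  tab_all <- make_training_table(sim$profiles, "weighted", TRUE)
  tab_f <- make_training_table(sim$profiles, "weighted", FALSE)
  expect_equal(nrow(tab_all$features), sum(nd >= 1))
  expect_equal(nrow(tab_f$features), sum(nd >= 2))
  expect_lte(nrow(tab_all$features), length(sim$profiles))

  # zero-noise on-grid optima: the peak target recovers the truth exactly
  cfg0 <- sim_config(n_peptides = 40, seed = 48, noise_cv = 0, residual_sd = 0,
                     descriptor_weights = numeric(0), intercept = -20,
                     charge_weight = -10)  # optima at -40/-50/-60, on-grid
  sim0 <- simulate_cv_dataset(cfg0)
  tab0 <- make_training_table(sim0$profiles, "peak", TRUE)
  truth0 <- cfg0$intercept + cfg0$charge_weight *
    as.numeric(sub(".*/", "", tab0$ids))
  expect_equal(unname(tab0$target), truth0)
})

test_that("simulated datasets serialize to long format and back losslessly", {
  sim <- simulate_cv_dataset(sim_config(n_peptides = 30, seed = 49))
  long <- profiles_to_long(sim$profiles)
  rebuilt <- build_profiles(long)
  nonempty <- Filter(function(p) length(p$cv) > 0, sim$profiles)
  expect_equal(length(rebuilt), length(nonempty))
  for (key in names(nonempty)) {
    expect_equal(rebuilt[[key]]$cv, nonempty[[key]]$cv)
    expect_equal(rebuilt[[key]]$intensity, nonempty[[key]]$intensity)
  }
})

test_that("detected spans are narrow and widen with amplitude", {
  sim <- simulate_cv_dataset(sim_config(n_peptides = 500, seed = 50))
  s <- profile_summaries(sim$profiles)
  expect_gte(mean(s$span <= 20), 0.9)
  amp <- sim$truth$amplitude[match(rownames(s),
                                   paste0(sim$truth$sequence, "/",
                                          sim$truth$charge))]
  med <- tapply(s$span, cut(rank(amp, ties.method = "first"), 5), median)
  expect_true(all(diff(med) >= 0))
})
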