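# Synthetic benchmark: tryptic-like peptides with charge- and
# descriptor-dependent transmission optima, Gaussian (in CV) transmission
# profiles, multiplicative log-normal intensity noise, and detection
# censoring on a discrete CV grid.

#' Simulation configuration
#'
#' Defaults emulate a short-gradient style acquisition: an 11-point CV grid
#' from -20 to -70 V in -5 V steps, 5 V transmission peak width, a 5%
#' relative detection threshold, and a charge-dominated generative model for
#' the true optimum placing 2+ ions near -45 V and 3+ ions near -57 V
#' (higher charge, more negative optimum). The true optimum also receives
#' small contributions from two standardized descriptors (MS-WHIM1 and
#' z-scale z3 sequence means) and a 4 V Gaussian residual, so that an
#' empirical pilot constraint carries information beyond the features. The
#' 4 V residual makes the feature-unexplained spread of the optimum match
#' the error magnitude a sequence-only model shows on real FAIMS data.
#'
#' @param n_peptides Number of peptides to simulate.
#' @param length_range Integer range of sequence lengths.
#' @param charge_probs Named probabilities over charges 2..4.
#' @param grid [cv_grid()] of acquisition CVs.
#' @param sigma Transmission peak width (V, SD of the Gaussian kernel).
#' @param amplitude_meanlog,amplitude_sdlog Log-normal peak amplitude.
#' @param threshold Relative detection threshold (fraction of amplitude).
#' @param detection_floor Absolute detection floor (intensity a.u.): observed
#'   values below it are censored regardless of amplitude, emulating the
#'   instrument noise floor. This is what makes intense peptides show wider
#'   detected CV spans; a purely relative threshold is amplitude-invariant.
#' @param noise_cv Coefficient of variation of multiplicative intensity noise.
#' @param intercept,charge_weight True-optimum linear model: CV =
#'   intercept + charge_weight x charge + sum(descriptor effects) + residual.
#' @param descriptor_weights Named vector of per-SD effects (V) on the
#'   optimum for descriptor features (names as in the registry).
#' @param residual_sd SD (V) of the residual on the true optimum.
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_peptides = 500,
                       length_range = c(7L, 30L),
                       charge_probs = c("2" = 0.6, "3" = 0.3, "4" = 0.1),
                       grid = cv_grid(seq(-20, -70, by = -5)),
                       sigma = 5,
                       amplitude_meanlog = log(1e6),
                       amplitude_sdlog = 1.2,
                       threshold = 0.05,
                       detection_floor = 2e4,
                       noise_cv = 0.2,
                       intercept = -21,
                       charge_weight = -12,
                       descriptor_weights = c(qsar_mswhim_MSWHIM1 = 3,
                                              qsar_zscales_Z3 = -2),
                       residual_sd = 4,
                       seed = 1) {
  stopifnot(sigma > 0, threshold > 0, threshold < 1, n_peptides >= 1)
  structure(list(n_peptides = n_peptides, length_range = length_range,
                 charge_probs = charge_probs, grid = grid, sigma = sigma,
                 amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog, threshold = threshold,
                 detection_floor = detection_floor,
                 noise_cv = noise_cv, intercept = intercept,
                 charge_weight = charge_weight,
                 descriptor_weights = descriptor_weights,
                 residual_sd = residual_sd, seed = seed),
            class = "sim_config")
}

#' Generate random tryptic-like peptide ions
#'
#' Sequences are uniform over the canonical alphabet with a C-terminal K or
#' R; lengths uniform in the configured range; charges drawn from the
#' configured distribution. Reproducible by `config$seed`.
#'
#' @param config A [sim_config()].
#' @return data.frame with `sequence` and `charge`.
#' @export
generate_peptides <- function(config) {
  set.seed(config$seed)
  n <- config$n_peptides
  lens <- sample(config$length_range[1]:config$length_range[2], n, replace = TRUE)
  sequences <- vapply(lens, function(L) {
    paste0(paste(sample(AA_ALPHABET, L - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
  charges <- as.integer(sample(names(config$charge_probs), n, replace = TRUE,
                               prob = config$charge_probs))
  data.frame(sequence = sequences, charge = charges)
}

#' Assign true transmission optima to simulated ions
#'
#' True CV = intercept + charge_weight x charge + sum over configured
#' descriptors of weight x standardized descriptor + Gaussian residual.
#' Descriptors are standardized within the simulated cohort.
#'
#' @param ions data.frame from [generate_peptides()].
#' @param config A [sim_config()].
#' @param registry Registry used to compute descriptor effects.
#' @return data.frame of class `sim_truth`: `sequence`, `charge`, `true_cv`,
#'   `amplitude`, plus a `detectable` list-column of grid CVs at which the
#'   expected (noise-free) intensity clears the detection threshold.
#' @export
assign_true_cv <- function(ions, config, registry = feature_registry()) {
  set.seed(config$seed + 1L)
  n <- nrow(ions)
  cv_true <- config$intercept + config$charge_weight * ions$charge
  dw <- config$descriptor_weights
  if (length(dw)) {
    feats <- featurize_table(ions$sequence, ions$charge, registry)
    for (f in names(dw)) {
      col <- feats[, f]
      s <- stats::sd(col)
      z <- if (s > 0) (col - mean(col)) / s else col * 0
      cv_true <- cv_true + dw[[f]] * z
    }
  }
  cv_true <- cv_true + stats::rnorm(n, 0, config$residual_sd)
  amplitude <- stats::rlnorm(n, config$amplitude_meanlog, config$amplitude_sdlog)
  detectable <- lapply(seq_len(n), function(i) {
    expected <- exp(-(as.numeric(config$grid) - cv_true[i])^2 /
                      (2 * config$sigma^2))
    as.numeric(config$grid)[expected >= config$threshold]
  })
  out <- data.frame(sequence = ions$sequence, charge = ions$charge,
                    true_cv = cv_true, amplitude = amplitude)
  out$detectable <- detectable
  class(out) <- c("sim_truth", class(out))
  out
}

#' Simulate one CV transmission profile
#'
#' Expected intensity at grid CV v is
#' `amplitude * exp(-(v - true_cv)^2 / (2 sigma^2))`, multiplied by
#' log-normal noise with the configured coefficient of variation; values
#' below `threshold * amplitude` or below the absolute `detection_floor` are
#' censored (absent from the profile).
#'
#' @param ion A [peptide_ion()].
#' @param true_cv,amplitude Ground-truth optimum (V) and peak amplitude.
#' @param config A [sim_config()].
#' @return A [cv_profile()] (possibly with zero detected bins).
#' @export
simulate_profile <- function(ion, true_cv, amplitude, config) {
  grid <- as.numeric(config$grid)
  expected <- amplitude * exp(-(grid - true_cv)^2 / (2 * config$sigma^2))
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- stats::rlnorm(length(grid), -sdlog^2 / 2, sdlog)
  } else {
    noise <- rep(1, length(grid))
  }
  obs <- expected * noise
  floor_abs <- if (is.null(config$detection_floor)) 0 else config$detection_floor
  detected <- obs >= pmax(config$threshold * amplitude, floor_abs)
  cv_profile(ion, grid[detected], obs[detected])
}

#' Simulate a pilot acquisition at arbitrary plan CVs
#'
#' A prospective pilot acquires at the three plan CVs themselves (which need
#' not lie on the archival grid). Intensities follow the same generative
#' model and censoring as [simulate_profile()].
#'
#' @param plan 3-CV pilot plan from [plan_pilot()].
#' @param true_cv,amplitude Ground truth for the ion.
#' @param config A [sim_config()].
#' @return Named numeric vector of observed intensities keyed by plan CV
#'   (censored CVs absent), suitable for [derive_constraint()].
#' @export
simulate_pilot <- function(plan, true_cv, amplitude, config) {
  expected <- amplitude * exp(-(plan - true_cv)^2 / (2 * config$sigma^2))
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- stats::rlnorm(length(plan), -sdlog^2 / 2, sdlog)
  } else {
    noise <- rep(1, length(plan))
  }
  obs <- expected * noise
  floor_abs <- if (is.null(config$detection_floor)) 0 else config$detection_floor
  detected <- obs >= pmax(config$threshold * amplitude, floor_abs)
  stats::setNames(obs[detected], plan[detected])
}

#' Simulate a full CV-resolved dataset
#'
#' @param config A [sim_config()].
#' @param registry Registry used for descriptor-dependent optima.
#' @return List with `ions`, `truth` (see [assign_true_cv()]) and `profiles`
#'   (named list of [cv_profile()], keyed `sequence/charge`; empty profiles
#'   are kept so censoring is observable).
#' @export
simulate_cv_dataset <- function(config = sim_config(),
                                registry = feature_registry()) {
  ions <- generate_peptides(config)
  truth <- assign_true_cv(ions, config, registry)
  set.seed(config$seed + 2L)
  profiles <- lapply(seq_len(nrow(truth)), function(i) {
    simulate_profile(peptide_ion(truth$sequence[i], truth$charge[i]),
                     truth$true_cv[i], truth$amplitude[i], config)
  })
  names(profiles) <- ion_key(truth$sequence, truth$charge)
  list(ions = ions, truth = truth, profiles = profiles)
}

#' Build a training table from profiles
#'
#' Featurizes each detected ion and computes the chosen target statistic
#' (intensity-weighted average CV, or the peak CV).
#'
#' @param profiles Named list of [cv_profile()] objects.
#' @param target `"weighted"` or `"peak"`.
#' @param include_single_observations Keep ions detected at a single CV?
#' @param registry A [feature_registry()].
#' @return A [training_table()].
#' @export
make_training_table <- function(profiles, target = c("weighted", "peak"),
                                include_single_observations = TRUE,
                                registry = feature_registry()) {
  target <- match.arg(target)
  if (!length(profiles)) stop("no profiles supplied")
  nd <- vapply(profiles, n_detected, integer(1))
  keep <- if (include_single_observations) nd >= 1L else nd >= 2L
  profiles <- profiles[keep]
  if (!length(profiles)) stop("no profiles left after filtering")
  seqs <- vapply(profiles, function(p) p$ion$sequence, character(1))
  charges <- vapply(profiles, function(p) p$ion$charge, integer(1))
  stat <- if (target == "weighted") weighted_average_cv else peak_cv
  y <- vapply(profiles, stat, numeric(1))
  training_table(featurize_table(seqs, charges, registry), y, registry,
                 ids = ion_key(seqs, charges))
}

#' Turn simulated profiles into a long-format observation table
#'
#' @param profiles Named list of [cv_profile()] objects.
#' @return data.frame with `sequence`, `charge`, `cv`, `intensity` (one row
#'   per detected bin; empty profiles contribute none).
#' @export
profiles_to_long <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    if (!n_detected(p)) return(NULL)
    data.frame(sequence = p$ion$sequence, charge = p$ion$charge,
               cv = p$cv, intensity = p$intensity)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sequence = character(0), charge = integer(0),
                      cv = numeric(0), intensity = numeric(0))
  }
  rownames(out) <- NULL
  out
}
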