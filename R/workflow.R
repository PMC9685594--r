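# Two-stage pilot/refine workflow: a low-precision stage-1 prediction seeds a
# 3-CV pilot acquisition; the most intense pilot CV becomes an empirical
# constraint feeding a refined stage-2 model.

CONSTRAINT_FEATURE <- "constraint_cv"
PILOT_OFFSET <- 5  # volts above/below the stage-1 prediction

#' Plan a 3-CV pilot acquisition around a stage-1 prediction
#'
#' @param stage1_cv Finite predicted CV (volts).
#' @param grid_range Optional length-2 numeric; candidates outside it trigger
#'   a warning (values pass through unclamped).
#' @return Numeric vector of 3 candidate CVs (prediction - 5, prediction,
#'   prediction + 5), each rounded to 0.1 V.
#' @examples
#' plan_pilot(-48)  # -53 -48 -43
#' @export
plan_pilot <- function(stage1_cv, grid_range = NULL) {
  if (length(stage1_cv) != 1L || !is.finite(stage1_cv)) {
    stop("stage-1 CV must be a single finite value")
  }
  plan <- round_cv(stage1_cv + c(-PILOT_OFFSET, 0, PILOT_OFFSET))
  if (!is.null(grid_range) &&
      (any(plan < min(grid_range)) || any(plan > max(grid_range)))) {
    warning("pilot plan extends outside the acquisition CV range")
  }
  plan
}

#' Derive the empirical constraint from pilot observations
#'
#' Returns the plan CV with the highest observed intensity; ties are broken
#' toward the plan center (the stage-1 prediction). With no detection at any
#' plan CV the ion is uncovered and `NA` is returned (callers fall back to
#' the stage-1 CV).
#'
#' @param plan 3-CV pilot plan from [plan_pilot()].
#' @param observations Named numeric vector mapping plan CVs (as names, at
#'   0.1 V resolution) to observed intensities; omit undetected CVs.
#' @return The constraint CV, or `NA_real_` when uncovered.
#' @export
derive_constraint <- function(plan, observations) {
  stopifnot(length(plan) == 3L)
  if (!length(observations)) return(NA_real_)
  obs_cv <- round_cv(as.numeric(names(observations)))
  if (!all(obs_cv %in% round_cv(plan))) {
    stop("pilot observations must be keyed by plan CVs")
  }
  best <- obs_cv[observations == max(observations)]
  if (length(best) == 1L) return(best)
  center <- plan[2]
  best[which.min(abs(best - center))]
}

#' Fit the refined (stage-2) ensemble with empirical constraints
#'
#' Trains a stacked ensemble on the descriptor features plus one additional
#' input: the constraint CV observed in the pilot (77 inputs under the
#' default registry). Ensemble defaults match [fit_stacked_ensemble()].
#'
#' @param table A [training_table()] of descriptor features.
#' @param constraints Numeric vector of constraint CVs, one per table row
#'   (named by ion id or positional).
#' @param config Optional ensemble configuration.
#' @param seed Integer seed.
#' @return A `cv_ensemble_model` whose feature set ends in `constraint_cv`.
#' @export
fit_model2 <- function(table, constraints, config = NULL, seed = 1) {
  stopifnot(inherits(table, "training_table"))
  if (!is.null(names(constraints)) && !is.null(table$ids)) {
    missing <- setdiff(table$ids, names(constraints))
    if (length(missing)) {
      stop("missing constraint for ion(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    constraints <- constraints[table$ids]
  }
  if (length(constraints) != nrow(table$features)) {
    stop("one constraint per training row is required")
  }
  if (anyNA(constraints)) {
    stop("missing constraint for ion(s): ",
         paste(utils::head(table$ids[is.na(constraints)], 5), collapse = ", "))
  }
  x2 <- cbind(table$features, as.numeric(constraints))
  colnames(x2) <- c(colnames(table$features), CONSTRAINT_FEATURE)
  t2 <- training_table(x2, table$target, table$registry, table$ids)
  fit_stacked_ensemble(t2, config = config, seed = seed)
}

#' Run the two-stage prediction for a set of ions
#'
#' Composes stage-1 prediction, pilot planning, constraint derivation and
#' stage-2 prediction. Uncovered ions (no detection at any pilot CV) keep the
#' stage-1 CV with `covered = FALSE`.
#'
#' @param features Descriptor matrix for the ions (registry order).
#' @param model1 Stage-1 `cv_ensemble_model` (76 inputs).
#' @param model2 Stage-2 `cv_ensemble_model` (77 inputs incl. constraint), or
#'   `NULL` to stop after the pilot.
#' @param pilot_observations List (one element per ion, input order) of named
#'   intensity vectors keyed by pilot CV, as in [derive_constraint()].
#' @return data.frame with `id`, `stage1_cv`, `constraint_cv`, `stage2_cv`,
#'   `final_cv` and `covered`, rows in input order.
#' @export
predict_two_stage <- function(features, model1, model2, pilot_observations) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(pilot_observations) == n)
  if (!is.null(model2) &&
      !identical(c(model1$feature_names, CONSTRAINT_FEATURE),
                 model2$feature_names)) {
    stop("model 1 and model 2 must share the same descriptor registry")
  }
  stage1 <- predict(model1, features)
  constraint <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    constraint[i] <- derive_constraint(plan_pilot(stage1[i]),
                                       pilot_observations[[i]])
  }
  covered <- !is.na(constraint)
  stage2 <- rep(NA_real_, n)
  if (!is.null(model2) && any(covered)) {
    x2 <- cbind(features[covered, , drop = FALSE], constraint[covered])
    colnames(x2) <- model2$feature_names
    stage2[covered] <- predict(model2, x2)
  }
  data.frame(id = if (is.null(rownames(features))) seq_len(n) else rownames(features),
             stage1_cv = stage1, constraint_cv = constraint,
             stage2_cv = stage2,
             final_cv = ifelse(is.na(stage2), stage1, stage2),
             covered = covered, row.names = NULL)
}

#' Fraction of ions covered by their pilot plans
#'
#' An ion is covered when at least one of its pilot CVs falls in its
#' detectable CV set (membership at 0.1 V resolution).
#'
#' @param plans List of pilot plans (one 3-CV vector per ion), named by ion.
#' @param detectability Named list mapping each ion to its detectable CV set.
#' @return Fraction of covered ions.
#' @export
coverage <- function(plans, detectability) {
  missing <- setdiff(names(plans), names(detectability))
  if (length(missing)) {
    stop("no detectability entry for ion(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  covered <- vapply(names(plans), function(id) {
    any(round_cv(plans[[id]]) %in% round_cv(detectability[[id]]))
  }, logical(1))
  mean(covered)
}
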