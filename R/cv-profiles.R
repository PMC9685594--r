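# CV-resolved transmission profiles and their summary statistics.

#' Round a compensation voltage to instrument resolution (0.1 V)
#' @param cv Numeric vector of CVs (volts).
#' @return Rounded CVs.
#' @export
round_cv <- function(cv) round(cv, 1)

#' Construct a CV grid
#'
#' @param values Unique CV values in volts (typically negative). Stored
#'   most-positive to most-negative.
#' @return Numeric vector of class `cv_grid`.
#' @examples
#' cv_grid(seq(-20, -70, by = -5))
#' @export
cv_grid <- function(values) {
  values <- round_cv(as.numeric(values))
  if (length(values) < 1L || anyNA(values)) stop("grid needs at least 1 finite CV")
  if (anyDuplicated(values)) stop("grid CVs must be unique")
  structure(sort(values, decreasing = TRUE), class = "cv_grid")
}

#' Construct a single CV transmission profile
#'
#' A profile maps grid CVs to strictly positive observed intensities; a CV
#' absent from the map means the ion was not detected there.
#'
#' @param ion A [peptide_ion()].
#' @param cv Numeric vector of CVs at which the ion was detected.
#' @param intensity Positive intensities, same length as `cv`.
#' @return Object of class `cv_profile`.
#' @export
cv_profile <- function(ion, cv, intensity) {
  cv <- round_cv(as.numeric(cv))
  intensity <- as.numeric(intensity)
  stopifnot(length(cv) == length(intensity))
  if (anyDuplicated(cv)) stop("duplicate CVs in profile; aggregate first")
  if (length(intensity) && any(!is.finite(intensity) | intensity <= 0)) {
    stop("profile intensities must be strictly positive")
  }
  ord <- order(cv, decreasing = TRUE)
  structure(list(ion = ion, cv = cv[ord], intensity = intensity[ord]),
            class = "cv_profile")
}

#' @export
print.cv_profile <- function(x, ...) {
  cat("<cv_profile> ", x$ion$sequence, "/", x$ion$charge, "+ : ",
      length(x$cv), " CV bins\n", sep = "")
  invisible(x)
}

n_detected <- function(profile) length(profile$cv)

assert_nonempty <- function(profile) {
  if (!n_detected(profile)) stop("profile has no detected CV bins")
  invisible(profile)
}

#' Normalize a profile to its maximum intensity
#'
#' @param profile A non-empty [cv_profile()].
#' @return A `cv_profile` with intensities in (0, 1]; the maximum maps to 1.
#' @export
normalize_profile <- function(profile) {
  assert_nonempty(profile)
  profile$intensity <- profile$intensity / max(profile$intensity)
  profile
}

#' Intensity-weighted average CV of a profile
#'
#' @param profile A non-empty [cv_profile()].
#' @return Weighted mean CV in volts.
#' @export
weighted_average_cv <- function(profile) {
  assert_nonempty(profile)
  sum(profile$intensity * profile$cv) / sum(profile$intensity)
}

#' CV of maximum observed intensity
#'
#' Intensity ties are broken toward the profile's weighted-average CV; an
#' exactly equidistant residual tie is broken toward the more negative CV.
#'
#' @param profile A non-empty [cv_profile()].
#' @return Peak CV in volts.
#' @export
peak_cv <- function(profile) {
  assert_nonempty(profile)
  cand <- profile$cv[profile$intensity == max(profile$intensity)]
  if (length(cand) == 1L) return(cand)
  wav <- weighted_average_cv(profile)
  d <- abs(cand - wav)
  cand <- cand[d == min(d)]
  min(cand)
}

#' Detected CV span of a profile
#'
#' @param profile A non-empty [cv_profile()].
#' @return `|max detected CV - min detected CV|` in volts.
#' @export
cv_span <- function(profile) {
  assert_nonempty(profile)
  max(profile$cv) - min(profile$cv)
}

#' Fraction of total intensity in the most intense CV bin
#'
#' @param profile A non-empty [cv_profile()].
#' @return Fraction in (0, 1].
#' @export
top_bin_fraction <- function(profile) {
  assert_nonempty(profile)
  max(profile$intensity) / sum(profile$intensity)
}

#' Summarize a profile
#'
#' @param profile A non-empty [cv_profile()].
#' @return One-row data.frame with sequence, charge, `peak_cv`,
#'   `weighted_cv`, `span`, `top_bin_fraction` and `n_detected`.
#' @export
profile_summary <- function(profile) {
  assert_nonempty(profile)
  data.frame(sequence = profile$ion$sequence, charge = profile$ion$charge,
             peak_cv = peak_cv(profile),
             weighted_cv = weighted_average_cv(profile),
             span = cv_span(profile),
             top_bin_fraction = top_bin_fraction(profile),
             n_detected = n_detected(profile))
}

#' Summarize a collection of profiles
#'
#' @param profiles List of [cv_profile()] objects.
#' @return data.frame with one row per profile (empty profiles are skipped).
#' @export
profile_summaries <- function(profiles) {
  keep <- vapply(profiles, n_detected, integer(1)) > 0
  do.call(rbind, lapply(profiles[keep], profile_summary))
}

#' Keep profiles detected in at least k CV bins
#'
#' @param profiles List of [cv_profile()] objects.
#' @param k Minimum number of detected CV bins (>= 1).
#' @return List with `profiles` (the retained list) and `retained_fraction`
#'   (NA for empty input).
#' @export
filter_min_detections <- function(profiles, k) {
  stopifnot(k >= 1)
  if (!length(profiles)) {
    return(list(profiles = profiles, retained_fraction = NA_real_))
  }
  keep <- vapply(profiles, n_detected, integer(1)) >= k
  list(profiles = profiles[keep], retained_fraction = mean(keep))
}

#' Accumulation curve of values against thresholds
#'
#' For each threshold `t`, the fraction of `values` that are `<= t`; the
#' standard presentation of CV spans and absolute prediction errors.
#'
#' @param values Non-empty numeric vector of non-negative values.
#' @param thresholds Ordered numeric thresholds.
#' @return Numeric vector of fractions, one per threshold.
#' @export
accumulation_curve <- function(values, thresholds) {
  if (!length(values)) stop("accumulation_curve needs non-empty values")
  vapply(thresholds, function(t) mean(values <= t), numeric(1))
}

#' Build profiles from a long-format data.frame
#'
#' Rows carry (sequence, charge, cv, intensity); sequences are stripped of
#' modification annotations, and duplicate (ion, cv) observations (e.g. from
#' multiple runs) are summed before profile construction.
#'
#' @param df data.frame with columns `sequence`, `charge`, `cv`, `intensity`.
#' @return Named list of [cv_profile()] objects keyed by `sequence/charge`.
#' @export
build_profiles <- function(df) {
  stopifnot(all(c("sequence", "charge", "cv", "intensity") %in% names(df)))
  if (!nrow(df)) return(stats::setNames(list(), character(0)))
  df$sequence <- vapply(as.character(df$sequence), strip_modifications,
                        character(1), USE.NAMES = FALSE)
  df$cv <- round_cv(df$cv)
  agg <- stats::aggregate(intensity ~ sequence + charge + cv, data = df, FUN = sum)
  keys <- ion_key(agg$sequence, agg$charge)
  out <- lapply(split(seq_len(nrow(agg)), keys), function(idx) {
    cv_profile(peptide_ion(agg$sequence[idx[1]], agg$charge[idx[1]]),
               agg$cv[idx], agg$intensity[idx])
  })
  out[unique(keys)]
}
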