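# File formats: long-format CV observation TSV, MaxQuant-style run-table
# adapter, PRM inclusion-list CSV, model bundles.

#' Read a long-format CV observation table into profiles
#'
#' The file is tab-separated with a header; `columns` maps the roles to the
#' actual column names. Modification annotations are stripped and duplicate
#' (ion, cv) rows (e.g. multiple runs) are summed.
#'
#' @param path TSV file path.
#' @param columns Named character vector with entries `sequence`, `charge`,
#'   `cv`, `intensity`.
#' @return Named list of [cv_profile()] objects.
#' @export
read_long_tsv <- function(path,
                          columns = c(sequence = "sequence", charge = "charge",
                                      cv = "cv", intensity = "intensity")) {
  need <- c("sequence", "charge", "cv", "intensity")
  if (!all(need %in% names(columns))) {
    stop("column map must name: ", paste(need, collapse = ", "))
  }
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  missing <- setdiff(unname(columns[need]), names(raw))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  df <- data.frame(sequence = raw[[columns[["sequence"]]]],
                   charge = raw[[columns[["charge"]]]],
                   cv = raw[[columns[["cv"]]]],
                   intensity = raw[[columns[["intensity"]]]])
  for (col in c("charge", "cv", "intensity")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad)) {
      stop("unparsable ", col, " value '", df[[col]][bad[1]], "' at line ",
           bad[1] + 1L, " of ", path)
    }
    df[[col]] <- val
  }
  log_msg("info", sprintf("read %d observation rows from %s", nrow(df), path))
  profiles <- build_profiles(df)
  log_msg("info", sprintf("built %d ion profiles", length(profiles)))
  profiles
}

#' Write profiles to a long-format TSV
#'
#' @param profiles Named list of [cv_profile()] objects (or a long-format
#'   data.frame with columns sequence/charge/cv/intensity).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_tsv <- function(profiles, path) {
  df <- if (is.data.frame(profiles)) profiles else profiles_to_long(profiles)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adapt a per-run quantitation table to long-format records
#'
#' For MaxQuant-style evidence layouts where each row carries a run
#' identifier but no CV: CVs are assigned by an explicit run-to-CV map (one
#' CV per injection). Runs without a mapping are an error - silent CV
#' misassignment would corrupt training targets.
#'
#' @param path TSV file with header.
#' @param run_cv_map Named numeric vector: run identifier -> CV (volts).
#' @param columns Named character vector with entries `sequence`, `charge`,
#'   `intensity`, `run`.
#' @return Long-format data.frame with `sequence`, `charge`, `cv`,
#'   `intensity`, `run`.
#' @export
adapt_run_table <- function(path, run_cv_map,
                            columns = c(sequence = "Sequence",
                                        charge = "Charge",
                                        intensity = "Intensity",
                                        run = "Raw file")) {
  raw <- utils::read.delim(path, check.names = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  runs <- as.character(raw[[columns[["run"]]]])
  unmapped <- setdiff(unique(runs), names(run_cv_map))
  if (length(unmapped)) {
    stop("no CV mapping for run(s): ", paste(unmapped, collapse = ", "))
  }
  data.frame(sequence = as.character(raw[[columns[["sequence"]]]]),
             charge = as.integer(raw[[columns[["charge"]]]]),
             cv = as.numeric(run_cv_map[runs]),
             intensity = as.numeric(raw[[columns[["intensity"]]]]),
             run = runs)
}

#' Monoisotopic precursor m/z of a peptide ion
#'
#' `(sum of monoisotopic residue masses + water + charge x proton) / charge`.
#'
#' @param ion A [peptide_ion()] (or sequence string with `charge` given).
#' @param charge Charge when `ion` is a bare sequence.
#' @return Precursor m/z.
#' @examples
#' precursor_mz(peptide_ion("PEPTIDEK", 2))
#' @export
precursor_mz <- function(ion, charge = NULL) {
  if (!inherits(ion, "peptide_ion")) {
    if (is.null(charge)) stop("charge required for a bare sequence")
    if (charge < 1) stop("charge must be >= 1")
    ion <- peptide_ion(ion, charge)
  }
  chars <- strsplit(ion$sequence, "")[[1]]
  (sum(AA_MONO_MASS[chars]) + MASS_WATER_MONO +
     ion$charge * MASS_PROTON) / ion$charge
}

#' Write a PRM inclusion list
#'
#' Vendor-neutral CSV with header `m/z,z,CV` (plus `t_start,t_end` when
#' retention-time windows are present); m/z to 4 decimals, CV to 1 decimal,
#' rows in input order.
#'
#' @param targets data.frame with columns `mz`, `z`, `cv` and optionally
#'   `t_start`, `t_end` (minutes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prm_list <- function(targets, path) {
  if (!nrow(targets)) stop("empty PRM target list")
  stopifnot(all(c("mz", "z", "cv") %in% names(targets)),
            all(targets$mz > 0), all(targets$z >= 1))
  has_rt <- all(c("t_start", "t_end") %in% names(targets))
  header <- if (has_rt) "m/z,z,CV,t_start,t_end" else "m/z,z,CV"
  rows <- sprintf("%.4f,%d,%.1f", targets$mz, as.integer(targets$z),
                  targets$cv)
  if (has_rt) {
    rows <- paste0(rows, sprintf(",%.2f,%.2f", targets$t_start, targets$t_end))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a PRM inclusion list written by [write_prm_list()]
#'
#' @param path CSV path.
#' @return data.frame with `mz`, `z`, `cv` (and `t_start`, `t_end` if present).
#' @export
read_prm_list <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  out <- data.frame(mz = df[["m/z"]], z = as.integer(df[["z"]]),
                    cv = df[["CV"]])
  if (all(c("t_start", "t_end") %in% names(df))) {
    out$t_start <- df$t_start
    out$t_end <- df$t_end
  }
  out
}

BUNDLE_FORMAT <- "faimscv-bundle-1"

#' Save a fitted model as a self-describing bundle
#'
#' The bundle records the format version, the feature registry (families,
#' pKa set, feature order), the model object and its seed, so predictions
#' are reproducible from the file alone.
#'
#' @param model A `cv_linear_model` or `cv_ensemble_model`.
#' @param path Output path (.rds).
#' @return `path`, invisibly.
#' @export
save_model_bundle <- function(model, path) {
  stopifnot(inherits(model, c("cv_linear_model", "cv_ensemble_model")))
  saveRDS(list(format = BUNDLE_FORMAT,
               class = class(model)[1],
               registry = model$registry,
               seed = if (!is.null(model$seed)) model$seed else NA_integer_,
               model = model),
          path)
  invisible(path)
}

#' Load a model bundle
#'
#' @param path Bundle path written by [save_model_bundle()].
#' @return The fitted model.
#' @export
load_model_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, BUNDLE_FORMAT)) {
    stop("not a model bundle (format '", bundle$format, "')")
  }
  bundle$model
}

# ---- logging ----------------------------------------------------------------

LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

log_msg <- function(level, msg) {
  threshold <- getOption("faimscv.log_level", "info")
  if (LOG_LEVELS[[level]] >= LOG_LEVELS[[threshold]]) {
    message(sprintf("[faimscv %s] %s", level, msg))
  }
  invisible(NULL)
}
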