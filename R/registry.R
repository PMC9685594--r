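# Feature registry: the stable, ordered definition of the descriptor vector.

DEFAULT_QSAR_FAMILIES <- c("cruciani", "mswhim", "zscales", "tscales",
                           "protfp", "stscales", "vhse", "blosum-indices")

#' Build a feature registry
#'
#' A registry pins the ordered feature names and block structure of the
#' descriptor vector: one charge feature, 18 residue-class composition
#' features (count and mole percent for 9 overlapping classes), 7 basic
#' physicochemical properties, and the per-sequence means of the selected
#' QSAR descriptor families. The default family selection
#' (cruciani + mswhim + zscales + tscales + protfp + stscales + vhse +
#' blosum-indices) contributes 50 QSAR features for a 76-feature vector in
#' total. All ten shipped families may be selected instead.
#'
#' @param qsar_families Character vector of scale-family names
#'   (see [scale_families()]).
#' @param pka_set Name of the pinned pKa set used for the charge/pI features;
#'   `"emboss"` (default) or `"lehninger"`.
#' @return An object of class `feature_registry` with elements `features`
#'   (ordered names), `blocks` (named list of index vectors), `qsar_families`,
#'   `pka_set` and `version`.
#' @examples
#' reg <- feature_registry()
#' length(reg$features)  # 76
#' @export
feature_registry <- function(qsar_families = DEFAULT_QSAR_FAMILIES,
                             pka_set = "emboss") {
  unknown <- setdiff(qsar_families, names(QSAR_SCALES))
  if (length(unknown)) {
    stop("unknown QSAR families: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(qsar_families)) stop("duplicated QSAR families")
  if (!pka_set %in% names(PKA_SETS)) {
    stop("unknown pKa set '", pka_set, "'; available: ",
         paste(names(PKA_SETS), collapse = ", "))
  }
  comp_names <- as.vector(t(outer(names(AA_CLASSES), c("count", "pct"),
                                  function(a, b) paste(a, b, sep = "_"))))
  phys_names <- c("mw", "pI", "charge_pH7", "hydrophobicity_kd",
                  "aliphatic_index", "instability_index", "boman_index")
  qsar_names <- unlist(lapply(qsar_families, function(f) {
    paste(f, colnames(QSAR_SCALES[[f]]), sep = "_")
  }), use.names = FALSE)
  features <- c("charge", paste0("comp_", comp_names),
                paste0("phys_", phys_names), paste0("qsar_", qsar_names))
  blocks <- list(
    charge = 1L,
    composition = seq_along(comp_names) + 1L,
    physicochemical = seq_along(phys_names) + 1L + length(comp_names),
    qsar = seq_along(qsar_names) + 1L + length(comp_names) + length(phys_names))
  structure(list(features = features, blocks = blocks,
                 qsar_families = qsar_families, pka_set = pka_set,
                 version = SCALE_TABLE_VERSION),
            class = "feature_registry")
}

#' @export
print.feature_registry <- function(x, ...) {
  cat("<feature_registry> v", x$version, ": ", length(x$features),
      " features (charge ", length(x$blocks$charge), " / composition ",
      length(x$blocks$composition), " / physicochemical ",
      length(x$blocks$physicochemical), " / qsar ", length(x$blocks$qsar),
      ")\n", sep = "")
  cat("  QSAR families:", paste(x$qsar_families, collapse = ", "), "\n")
  cat("  pKa set:", x$pka_set, "\n")
  invisible(x)
}

#' @export
length.feature_registry <- function(x) length(x$features)

#' Serialize a feature registry to JSON
#'
#' @param registry A [feature_registry()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "feature_registry"))
  jsonlite::write_json(
    list(qsar_families = registry$qsar_families, pka_set = registry$pka_set,
         version = registry$version, features = registry$features),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a feature registry from JSON
#'
#' The registry is rebuilt from its family selection and the reconstructed
#' feature order is checked against the serialized one.
#'
#' @param path JSON file written by [write_registry()].
#' @return A `feature_registry`.
#' @export
read_registry <- function(path) {
  stored <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- feature_registry(qsar_families = stored$qsar_families,
                          pka_set = stored$pka_set)
  if (!identical(reg$features, stored$features)) {
    stop("registry file feature order does not match this package's tables")
  }
  reg
}

registries_match <- function(a, b) {
  identical(a$features, b$features) && identical(a$pka_set, b$pka_set)
}
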