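# Sequence descriptors: composition, physicochemical properties, QSAR family
# means, and the combined 76-feature vector.

#' Construct a peptide ion
#'
#' @param sequence Peptide sequence; may carry MaxQuant-style modification
#'   annotations, which are stripped.
#' @param charge Positive charge state, integer in 1..8.
#' @return An object of class `peptide_ion` with `$sequence` (bare canonical
#'   sequence) and `$charge`.
#' @examples
#' peptide_ion("_AM(Oxidation (M))K_", 2)
#' @export
peptide_ion <- function(sequence, charge) {
  seq <- strip_modifications(sequence)
  charge <- as.integer(charge)
  if (length(charge) != 1L || is.na(charge) || charge < 1L || charge > 8L) {
    stop("charge must be a single integer in [1, 8]")
  }
  structure(list(sequence = seq, charge = charge), class = "peptide_ion")
}

#' @export
print.peptide_ion <- function(x, ...) {
  cat("<peptide_ion> ", x$sequence, "/", x$charge, "+\n", sep = "")
  invisible(x)
}

ion_key <- function(sequence, charge) paste0(sequence, "/", charge)

assert_canonical <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (length(bad)) {
    stop("non-canonical residue(s) in sequence: ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(sequence)
}

#' Strip modification annotations from a peptide sequence
#'
#' Removes leading/trailing underscores and any parenthesized or bracketed
#' annotation spans (nesting supported, as in `"AM(Oxidation (M))K"`), then
#' validates that the remainder uses only the 20 canonical residue letters.
#'
#' @param annotated Annotated sequence string.
#' @return Bare canonical sequence.
#' @examples
#' strip_modifications("_AM(Oxidation (M))K_")  # "AMK"
#' @export
strip_modifications <- function(annotated) {
  if (length(annotated) != 1L || is.na(annotated)) {
    stop("sequence must be a single string")
  }
  chars <- strsplit(gsub("_", "", annotated), "")[[1]]
  depth <- 0L
  keep <- logical(length(chars))
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "[")) {
      depth <- depth + 1L
    } else if (ch %in% c(")", "]")) {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced modification brackets in '", annotated, "'")
    } else if (depth == 0L) {
      keep[i] <- TRUE
    }
  }
  if (depth != 0L) stop("unbalanced modification brackets in '", annotated, "'")
  out <- paste(chars[keep], collapse = "")
  if (!nzchar(out)) stop("sequence empty after stripping modifications")
  assert_canonical(out)
  out
}

#' Residue-class composition features
#'
#' For each of nine (overlapping) residue classes - Tiny, Small, Aliphatic,
#' Aromatic, NonPolar, Polar, Charged, Basic, Acidic - returns the residue
#' count and the mole percent (count / length x 100).
#'
#' @param sequence Bare canonical sequence.
#' @return Named numeric vector of length 18.
#' @export
aa_composition <- function(sequence) {
  assert_canonical(sequence)
  chars <- strsplit(sequence, "")[[1]]
  out <- numeric(0)
  for (cls in names(AA_CLASSES)) {
    n <- sum(chars %in% AA_CLASSES[[cls]])
    out <- c(out, n, n / length(chars) * 100)
    names(out)[length(out) - 1:0] <- paste(cls, c("count", "pct"), sep = "_")
  }
  out
}

peptide_net_charge <- function(chars, pH, pka) {
  pos_pka <- c(pka$nterm,
               rep(pka$K, sum(chars == "K")),
               rep(pka$R, sum(chars == "R")),
               rep(pka$H, sum(chars == "H")))
  neg_pka <- c(pka$cterm,
               rep(pka$D, sum(chars == "D")),
               rep(pka$E, sum(chars == "E")),
               rep(pka$C, sum(chars == "C")),
               rep(pka$Y, sum(chars == "Y")))
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

# Bisection on the monotone-decreasing net-charge function.
solve_pi <- function(chars, pka, tol = 1e-8) {
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (peptide_net_charge(chars, mid, pka) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Basic physicochemical properties of a peptide
#'
#' Returns seven properties from pinned published tables and formulas:
#' average molecular weight (Da), isoelectric point (bisection on the
#' Henderson-Hasselbalch net-charge function), net charge at pH 7, mean
#' Kyte-Doolittle hydropathy, Ikai aliphatic index, Guruprasad instability
#' index, and the Boman protein-interaction index. Sequences shorter than two
#' residues get an instability index of 0 with a warning (the dipeptide
#' weight table needs at least one residue pair).
#'
#' @param sequence Bare canonical sequence.
#' @param pka_set Name of the pKa set (see [feature_registry()]).
#' @return Named numeric vector of length 7.
#' @export
physicochemical <- function(sequence, pka_set = "emboss") {
  assert_canonical(sequence)
  pka <- PKA_SETS[[match.arg(pka_set, names(PKA_SETS))]]
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  mw <- sum(AA_AVG_MASS[chars]) + MASS_WATER_AVG
  pI <- solve_pi(chars, pka)
  charge7 <- peptide_net_charge(chars, 7, pka)
  kd <- mean(KYTE_DOOLITTLE[chars])
  pct <- function(aa) sum(chars == aa) / n * 100
  aliphatic <- sum(vapply(names(ALIPHATIC_COEF),
                          function(a) ALIPHATIC_COEF[[a]] * pct(a), numeric(1)))
  if (n < 2) {
    warning("instability index undefined for single-residue sequence; using 0")
    instab <- 0
  } else {
    instab <- 10 / n * sum(DIWV[cbind(chars[-n], chars[-1])])
  }
  boman <- mean(BOMAN_SCALE[chars])
  c(mw = mw, pI = pI, charge_pH7 = charge7, hydrophobicity_kd = kd,
    aliphatic_index = aliphatic, instability_index = instab,
    boman_index = boman)
}

#' Per-sequence means of one QSAR descriptor family
#'
#' @param sequence Bare canonical sequence.
#' @param family Scale-family name (see [scale_families()]).
#' @return Named numeric vector, one arithmetic mean per family component.
#' @examples
#' qsar_profile("LLLL", "zscales")  # equals the z-scale row of L
#' @export
qsar_profile <- function(sequence, family) {
  assert_canonical(sequence)
  tab <- scale_table(family)
  chars <- strsplit(sequence, "")[[1]]
  missing <- setdiff(chars, rownames(tab))
  if (length(missing)) {
    stop("residue(s) ", paste(missing, collapse = ", "),
         " missing from scale family '", family, "'")
  }
  colMeans(tab[chars, , drop = FALSE])
}

#' Compute the descriptor vector of a peptide ion
#'
#' Concatenates, in registry order, the charge, the 18 composition features,
#' the 7 physicochemical properties and the selected QSAR family means; 76
#' values under the default registry. Raw (unstandardized) values are
#' returned; standardization is a model concern.
#'
#' @param ion A [peptide_ion()] (or anything `peptide_ion()` accepts via a
#'   list with `sequence` and `charge`).
#' @param registry A [feature_registry()].
#' @return Named numeric vector aligned to `registry$features`.
#' @examples
#' v <- featurize(peptide_ion("ELVISLIVESK", 2))
#' length(v)  # 76
#' @export
featurize <- function(ion, registry = feature_registry()) {
  if (!inherits(ion, "peptide_ion")) ion <- peptide_ion(ion$sequence, ion$charge)
  vals <- c(charge = as.numeric(ion$charge),
            stats::setNames(aa_composition(ion$sequence),
                            registry$features[registry$blocks$composition]),
            stats::setNames(physicochemical(ion$sequence, registry$pka_set),
                            registry$features[registry$blocks$physicochemical]),
            stats::setNames(
              unlist(lapply(registry$qsar_families, qsar_profile,
                            sequence = ion$sequence), use.names = FALSE),
              registry$features[registry$blocks$qsar]))
  stopifnot(identical(names(vals), registry$features), all(is.finite(vals)))
  vals
}

#' Featurize a table of peptide ions into a matrix
#'
#' @param sequences Character vector of (possibly annotated) sequences.
#' @param charges Integer vector of charges, recycled if length 1.
#' @param registry A [feature_registry()].
#' @return Numeric matrix, one row per ion, columns = registry features;
#'   row names are `sequence/charge` keys.
#' @export
featurize_table <- function(sequences, charges, registry = feature_registry()) {
  if (length(charges) == 1L) charges <- rep(charges, length(sequences))
  stopifnot(length(sequences) == length(charges))
  rows <- mapply(function(s, z) featurize(peptide_ion(s, z), registry),
                 sequences, charges, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), 0, length(registry$features))
  colnames(m) <- registry$features
  rownames(m) <- ion_key(vapply(sequences, strip_modifications, character(1)),
                         charges)
  m
}
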