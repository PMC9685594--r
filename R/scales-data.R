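# Pinned per-residue constants: QSAR descriptor scales, physicochemical scales,
# pKa sets and residue masses. Residue order is alphabetical by one-letter code
# throughout. Values follow the original publications as tabulated in this
# package; see ?scale_table for the family references.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.aa_matrix <- function(values, components) {
  m <- matrix(values, nrow = 20, byrow = TRUE,
              dimnames = list(AA_ALPHABET, components))
  stopifnot(!anyNA(m))
  m
}

# Cruciani properties (Cruciani et al. 2004): PP1 polarity/hydrophilicity,
# PP2 steric bulk/polarizability, PP3 hydrogen-bonding.
QSAR_CRUCIANI <- .aa_matrix(c(
  -0.96, -0.76,  0.31,
  -0.55, -0.47,  0.19,
   1.00, -0.89, -1.00,
   0.94, -0.54, -0.99,
  -0.85,  0.48, -0.58,
  -0.88, -1.00,  0.49,
   0.67,  0.11,  0.37,
  -0.94,  0.04, -0.18,
   0.60,  0.10,  1.00,
  -0.90,  0.03, -0.24,
  -0.82,  0.03, -0.08,
   0.82, -0.57,  0.02,
  -0.81, -0.40, -0.07,
   0.75, -0.40,  0.13,
   0.80,  0.63,  0.99,
   0.41, -0.82,  0.57,
   0.36, -0.53,  0.87,
  -0.90, -0.30, -0.29,
  -0.83,  1.00, -0.48,
  -0.27,  0.83, -0.36), paste0("PP", 1:3))

# MS-WHIM scores (Zaliani & Gancia 1999): statistics of the 3D molecular
# surface electrostatic potential.
QSAR_MSWHIM <- .aa_matrix(c(
  -0.73,  0.20, -0.62,
  -0.66,  0.26, -0.27,
   0.11, -1.00, -0.96,
   0.24, -0.39, -0.04,
   0.76,  0.85, -0.34,
  -0.31, -0.28, -0.75,
   0.84,  0.67, -0.78,
  -0.91,  0.83, -0.25,
  -0.51,  0.08,  0.70,
  -0.74,  0.72, -0.16,
  -0.70,  1.00, -0.32,
   0.14,  0.20, -0.66,
  -0.43,  0.73, -0.60,
   0.30,  1.00, -0.30,
  -0.22,  0.27,  1.00,
  -0.80,  0.61, -1.00,
  -0.58,  0.85, -0.89,
  -1.00,  0.79, -0.58,
   1.00,  0.98, -0.47,
   0.97,  0.66, -0.23), paste0("MSWHIM", 1:3))

# z-scales (Sandberg et al. 1998): z1 lipophilicity, z2 steric/polarizability,
# z3 polarity/charge, z4-z5 electronegativity/electrophilicity.
QSAR_ZSCALES <- .aa_matrix(c(
   0.24, -2.32,  0.60, -0.14,  1.30,
   0.84, -1.67,  3.71,  0.18, -2.65,
   3.98,  0.93,  1.93, -2.46,  0.75,
   3.11,  0.26, -0.11, -3.04, -0.25,
  -4.22,  1.94,  1.06,  0.54, -0.62,
   2.05, -4.06,  0.36, -0.82, -0.38,
   2.47,  1.95,  0.26,  3.90,  0.09,
  -3.89, -1.73, -1.71, -0.84,  0.26,
   2.29,  0.89, -2.49,  1.49,  0.31,
  -4.28, -1.30, -1.49, -0.72,  0.84,
  -2.85, -0.22,  0.47,  1.94, -0.98,
   3.05,  1.62,  1.04, -1.15,  1.61,
  -1.66,  0.27,  1.84,  0.70,  2.00,
   1.75,  0.50, -1.44, -1.34,  0.66,
   3.52,  2.50, -3.50,  1.99, -0.17,
   2.39, -1.07,  1.15, -1.39,  0.67,
   0.75, -2.18, -1.12, -1.46, -0.40,
  -2.59, -2.64, -1.54, -0.85, -0.02,
  -4.36,  3.94,  0.59,  3.44, -1.59,
  -2.54,  2.44,  0.43,  0.04, -1.47), paste0("Z", 1:5))

# T-scales (Tian et al. 2007): principal components of topological descriptors.
QSAR_TSCALES <- .aa_matrix(c(
  -9.11, -1.63,  0.63,  1.04,  2.26,
  -7.35, -0.86, -0.33,  0.80,  0.98,
  -4.65,  0.75,  1.39, -0.40,  1.05,
  -3.03,  1.82,  0.51, -0.58,  0.43,
   0.49, -0.94, -0.63, -1.27, -0.44,
 -10.61, -1.21, -0.12,  0.75,  3.25,
  -1.01, -1.31,  0.01, -1.81, -0.21,
  -4.25, -0.28, -0.15,  1.40, -0.21,
  -2.59,  2.34, -1.69,  0.41, -0.21,
  -4.38,  0.28, -0.49,  1.45,  0.02,
  -4.08,  0.98, -2.34,  1.64, -0.79,
  -4.62,  0.66,  1.16, -0.22,  0.93,
  -5.11, -3.54, -0.53, -0.36, -0.29,
  -3.00,  1.72,  0.28, -0.39,  0.33,
   0.23,  3.89, -1.16, -0.39, -0.06,
  -7.44, -0.65,  0.68, -0.17,  1.58,
  -5.97, -0.62,  1.11,  0.31,  0.95,
  -5.87, -0.94,  0.28,  1.10,  0.48,
   5.73, -2.67, -0.07, -1.96, -0.54,
   2.08, -0.47,  0.07, -1.67, -0.35), paste0("T", 1:5))

# FASGAI vectors (Liang & Li 2008): factor analysis of general amino acid
# physicochemical information, 6 factors.
QSAR_FASGAI <- .aa_matrix(c(
  -0.59, -1.30, -0.73,  1.57, -0.15, -0.22,
  -0.85, -0.33, -0.23,  0.16, -1.02,  0.33,
  -0.88,  1.00, -0.43, -0.45,  0.34, -1.15,
  -0.81,  0.72,  0.39, -0.35,  1.04, -1.07,
   1.39, -0.27,  0.41,  0.35, -0.68,  0.42,
  -0.92, -1.79, -1.74,  0.81,  0.34,  0.48,
   0.44,  0.60,  0.07, -1.04,  0.56,  1.07,
   1.34, -0.89, -0.29,  0.16, -0.54, -0.05,
  -0.68,  1.00,  0.50, -0.68,  1.06,  0.38,
   1.22, -0.83, -0.26,  0.54, -0.09, -0.33,
   1.12, -0.26, -0.51, -0.49, -0.47,  0.64,
  -0.92,  0.66, -0.33, -0.52,  0.09, -0.81,
  -0.17, -0.12, -1.81, -1.35, -0.51,  1.69,
  -0.76,  0.69,  0.19, -0.42,  0.62, -0.56,
  -0.69,  1.52,  0.74, -0.71,  0.45,  0.44,
  -0.71, -0.46, -0.79,  0.17,  0.12, -0.65,
  -0.41, -0.48, -0.40,  0.37, -0.34, -0.59,
   1.09, -1.07, -0.32,  0.54, -0.29, -0.35,
   1.60,  0.84,  1.68,  0.09, -0.65,  0.69,
   1.00,  0.52,  1.23, -0.39, -0.32,  0.11), paste0("F", 1:6))

# ProtFP descriptors (van Westen et al. 2013): PCA of AAindex-style
# physicochemical properties, 8 components.
QSAR_PROTFP <- .aa_matrix(c(
  -3.49,  0.50, -2.52,  1.04,  0.23,  0.68, -0.94,  0.28,
  -1.28, -2.74,  0.26, -1.06, -3.42,  1.64,  1.04, -0.35,
   2.49, -1.57, -1.70, -1.62,  0.72, -0.65,  0.43,  1.11,
   3.02, -0.21, -0.87, -1.50,  1.42, -0.32,  1.16, -0.95,
  -3.03,  2.82,  1.55, -0.27, -0.55, -0.64, -0.10,  0.68,
   0.67, -3.37, -3.70,  1.45,  0.52, -0.38,  0.23, -0.32,
   1.72,  0.91,  0.26, -0.48, -1.01,  2.02, -1.60, -0.35,
  -4.17,  0.25,  1.11,  1.23,  0.12, -0.96, -0.85, -0.45,
   3.21,  0.75, -0.29,  1.10, -1.42, -1.67, -0.90, -0.07,
  -3.93,  0.54,  0.84,  1.06,  0.48, -1.01,  0.52,  0.26,
  -2.74,  0.76,  0.67, -0.30,  1.60,  1.01,  1.52,  1.05,
   2.28, -0.81, -1.15, -1.15,  0.30,  0.88,  0.22,  1.00,
   0.65, -1.54, -0.35, -3.05, -1.12, -0.86,  1.00,  0.22,
   2.31,  0.36, -0.45, -0.71,  0.68,  0.61,  1.20, -1.12,
   3.52,  1.50, -0.40,  2.09,  0.85,  0.67, -0.78,  0.22,
   1.19, -2.01, -1.57, -0.26, -0.35,  0.02,  0.09, -1.07,
   0.74, -1.40, -0.10,  0.27, -0.23,  0.30, -1.55, -0.48,
  -3.79, -0.85,  0.98,  1.36, -0.27, -0.51, -0.75, -0.34,
  -1.41,  4.04,  1.49, -1.27,  0.69, -0.34, -0.61, -1.13,
  -0.96,  2.87,  0.66, -0.80, -1.26, -0.39,  0.67,  1.81), paste0("ProtFP", 1:8))

# ST-scales (Yang et al. 2010): PCA of structural/topological properties.
QSAR_STSCALES <- .aa_matrix(c(
  -1.55, -0.79, -0.63,  0.24, -0.46, -2.23,  0.28,  1.22,
  -1.28, -0.54,  0.51, -0.89, -0.62, -1.30,  0.06,  1.60,
   0.58, -0.99, -1.50, -1.25,  0.55, -0.11, -0.90, -1.00,
   0.61, -0.40, -0.71, -1.37,  1.06,  0.01,  0.33, -0.37,
   0.10,  0.71,  1.35,  1.25,  0.88,  1.05,  0.52, -0.17,
  -1.84, -1.77, -1.26,  0.86,  0.51, -1.72,  0.34,  0.86,
   0.37,  0.55,  0.09, -0.17,  0.12,  0.67, -1.52,  0.47,
  -0.77,  0.67,  0.98,  1.08, -0.39,  0.26,  0.26, -0.33,
   1.09,  0.12, -0.25,  0.46, -0.73, -0.40,  1.16,  0.48,
  -0.74,  0.72,  0.90,  1.02, -0.71,  0.16,  0.61,  0.20,
  -0.60,  0.77,  0.46,  0.27,  1.39,  0.54,  0.10,  0.20,
   0.33, -0.89, -0.82, -0.86,  0.18,  0.37, -0.29, -0.61,
  -0.83, -1.33, -0.88, -1.04, -1.90,  0.75, -0.60, -0.50,
   0.58, -0.11, -0.02, -0.85,  0.54,  0.44,  0.84, -0.71,
   1.55,  0.84, -0.38,  0.92, -0.77,  0.57,  0.52,  0.54,
  -0.56, -1.00, -0.87, -0.49,  0.06, -0.79, -0.46,  0.21,
  -0.40, -0.70, -0.27, -0.25, -0.37, -0.57, -0.63,  0.09,
  -0.93,  0.18,  0.53,  1.00, -0.79, -0.41,  0.11,  0.03,
   1.04,  2.10,  1.42,  0.39,  0.17,  0.82,  0.29, -0.61,
   0.48,  1.23,  0.80,  0.07, -0.34,  0.46, -0.88, -0.19), paste0("ST", 1:8))

# VHSE scales (Mei et al. 2005): hydrophobic (1-2), steric (3-4) and
# electronic (5-8) principal properties.
QSAR_VHSE <- .aa_matrix(c(
   0.15, -1.11, -1.35, -0.92,  0.02, -0.91,  0.36, -0.48,
   0.18, -1.67, -0.46, -0.21,  0.00,  1.20, -1.61, -0.19,
  -1.15,  0.67, -0.41, -0.01, -2.68,  1.31,  0.03,  0.56,
  -1.18,  0.40,  0.10,  0.36, -2.16, -0.17,  0.91,  0.02,
   1.52,  0.61,  0.96, -0.16,  0.25,  0.28, -1.33, -0.20,
  -0.20, -1.53, -2.63,  2.28, -0.53, -1.18,  2.01, -1.34,
  -0.43, -0.25,  0.37,  0.19,  0.51,  1.28,  0.93,  0.65,
   1.27, -0.14,  0.30, -1.80,  0.30, -1.61, -0.16, -0.13,
  -1.17,  0.70,  0.70,  0.80,  1.64,  0.67,  1.63,  0.13,
   1.36,  0.07,  0.26, -0.80,  0.22, -1.37,  0.08, -0.62,
   1.01, -0.53,  0.43,  0.00,  0.23,  0.10, -0.86, -0.68,
  -0.99,  0.00, -0.37,  0.69, -0.55,  0.85,  0.73, -0.80,
   0.22, -0.17, -0.50,  0.05, -0.01, -1.34, -0.19,  3.56,
  -0.96,  0.12,  0.18,  0.16,  0.09,  0.42, -0.20, -0.41,
  -1.47,  1.45,  1.24,  1.27,  1.55,  1.47,  1.30,  0.83,
  -0.67, -0.86, -1.07, -0.41, -0.32,  0.27, -0.64,  0.11,
  -0.34, -0.51, -0.55, -1.06, -0.06, -0.01, -0.79,  0.39,
   0.76, -0.92, -0.17, -1.91,  0.22, -1.40, -0.24, -0.03,
   1.50,  2.06,  1.79,  0.75,  0.75, -0.13, -1.01, -0.85,
   0.61,  1.60,  1.17,  0.73,  0.53,  0.25, -0.96, -0.52), paste0("VHSE", 1:8))

# BLOSUM indices (Georgiev 2009): VARIMAX components of BLOSUM62-derived
# substitution profiles.
QSAR_BLOSUM <- .aa_matrix(c(
   0.08, -0.13, -0.44,  0.00,  0.35, -0.20,  0.07,  0.09, -0.16,  0.04,
   0.48,  0.38, -0.06, -0.31, -0.29,  0.21, -0.36,  0.09,  0.17, -0.09,
  -0.67, -0.28,  0.26, -0.12,  0.18,  0.31,  0.03, -0.22,  0.12,  0.14,
  -0.64, -0.11,  0.12,  0.21,  0.26, -0.07, -0.18,  0.13, -0.10, -0.06,
   0.60,  0.26,  0.31,  0.22, -0.01, -0.17,  0.12, -0.05, -0.21,  0.08,
  -0.33, -0.63, -0.31, -0.36, -0.20,  0.11,  0.21,  0.13,  0.06, -0.02,
  -0.25,  0.31, -0.01, -0.18,  0.06,  0.30,  0.28,  0.26, -0.07, -0.19,
   0.61, -0.06,  0.28,  0.21,  0.07,  0.24, -0.10, -0.07,  0.18,  0.05,
  -0.58,  0.12, -0.04,  0.32, -0.10, -0.16,  0.22, -0.12,  0.14,  0.00,
   0.54, -0.04,  0.25,  0.18,  0.15,  0.06, -0.05,  0.13, -0.12, -0.16,
   0.44,  0.11,  0.18,  0.08,  0.32,  0.11,  0.19, -0.26,  0.06,  0.16,
  -0.52, -0.20,  0.09, -0.30,  0.10, -0.16, -0.27,  0.10, -0.09,  0.09,
  -0.36, -0.49,  0.11,  0.34, -0.37, -0.15, -0.40, -0.15, -0.10,  0.04,
  -0.47,  0.13, -0.03,  0.21,  0.19, -0.07,  0.26,  0.25,  0.20,  0.12,
  -0.51,  0.27, -0.08,  0.27, -0.13,  0.25, -0.11,  0.10, -0.10,  0.15,
  -0.26, -0.27, -0.23, -0.19,  0.13, -0.10,  0.05, -0.31,  0.10, -0.05,
  -0.10, -0.24, -0.15,  0.02, -0.03,  0.10,  0.08,  0.16,  0.26,  0.12,
   0.56, -0.19,  0.26,  0.26, -0.05, -0.02,  0.06,  0.14,  0.02, -0.10,
   0.54,  0.53,  0.25, -0.21, -0.29, -0.27, -0.06,  0.05,  0.12, -0.11,
   0.31,  0.42,  0.14, -0.17, -0.09, -0.29,  0.02, -0.18, -0.19,  0.06),
  paste0("BLOSUM", 1:10))

# Kidera factors (Kidera et al. 1985): 10 orthogonal factors from 188
# physical properties.
QSAR_KIDERA <- .aa_matrix(c(
  -1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08,  0.21, -0.48,
   0.12, -0.89,  0.45, -1.05, -0.71,  2.41,  1.52, -0.69,  1.13,  1.10,
   0.58, -0.22, -1.58,  0.81, -0.92,  0.15, -1.52,  0.47,  0.76,  0.70,
  -1.45,  0.19, -1.61,  1.17, -1.31,  0.40,  0.04,  0.38, -0.35, -0.12,
  -0.21,  0.98, -0.36, -1.43,  0.22, -0.81,  0.67,  1.10,  1.71, -0.44,
   1.46, -1.96, -0.23, -0.16,  0.10, -0.11,  1.32,  2.36, -1.66,  0.46,
  -0.41,  0.52, -0.28,  0.28,  1.61,  1.01, -1.85,  0.47,  1.13,  1.63,
  -0.73, -0.16,  1.79, -0.77, -0.54,  0.03, -0.83,  0.51,  0.66, -1.78,
  -0.34,  0.82, -0.23,  1.70,  1.54, -1.62,  1.15, -0.08, -0.48,  0.60,
  -1.04,  0.00, -0.24, -1.10, -0.55, -2.05,  0.96, -0.76,  0.45,  0.93,
  -1.40,  0.18, -0.42, -0.73,  2.00,  1.52,  0.26,  0.11, -1.27,  0.27,
   1.14, -0.07, -0.12,  0.81,  0.18,  0.37, -0.09,  1.23,  1.10, -1.73,
   2.06, -0.33, -1.15, -0.75,  0.88, -0.45,  0.30, -2.30,  0.74, -0.28,
  -0.47,  0.24,  0.07,  1.10,  1.10,  0.59,  0.84, -0.71, -0.03, -2.33,
   0.22,  1.27,  1.37,  1.87, -1.70,  0.46,  0.92, -0.39,  0.23,  0.93,
   0.81, -1.08,  0.16,  0.42, -0.21, -0.43, -1.89, -1.15, -0.97, -0.23,
   0.26, -0.70,  1.21,  0.63, -0.10,  0.21,  0.24, -1.15, -0.56,  0.19,
  -0.74, -0.71,  2.04, -0.40,  0.50, -0.81, -1.07,  0.06, -0.46,  0.65,
   0.30,  2.10, -0.72, -1.57, -1.16,  0.57, -0.48, -0.40, -2.30, -0.60,
   1.38,  1.48,  0.80, -0.56,  0.00, -0.68, -0.31,  1.03, -0.05,  0.53),
  paste0("KF", 1:10))

QSAR_SCALES <- list(
  cruciani = QSAR_CRUCIANI,
  mswhim   = QSAR_MSWHIM,
  zscales  = QSAR_ZSCALES,
  tscales  = QSAR_TSCALES,
  fasgai   = QSAR_FASGAI,
  protfp   = QSAR_PROTFP,
  stscales = QSAR_STSCALES,
  vhse     = QSAR_VHSE,
  `blosum-indices` = QSAR_BLOSUM,
  kidera   = QSAR_KIDERA)

SCALE_TABLE_VERSION <- "1.0"

# Residue classes for the composition block. Classes overlap by design
# (e.g. H is Aromatic, Polar, Charged and Basic).
AA_CLASSES <- list(
  Tiny      = c("A", "C", "G", "S", "T"),
  Small     = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
  Aliphatic = c("A", "I", "L", "V"),
  Aromatic  = c("F", "H", "W", "Y"),
  NonPolar  = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W"),
  Polar     = c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "Y"),
  Charged   = c("D", "E", "H", "K", "R"),
  Basic     = c("H", "K", "R"),
  Acidic    = c("D", "E"))

# Kyte & Doolittle (1982) hydropathy.
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Boman (2003) protein-interaction potential: per-residue solubility values
# (hydrophilic positive). No value was published for proline; 0 by convention.
BOMAN_SCALE <- c(
  A = -1.81, C = -1.28, D = 8.72, E = 6.81, F = -2.98, G = -0.94,
  H = 4.66, I = -4.92, K = 5.55, L = -4.92, M = -2.35, N = 6.64,
  P = 0.00, Q = 5.54, R = 14.92, S = 3.40, T = 2.57, V = -4.04,
  W = -2.33, Y = 0.14)

# Ikai (1980) aliphatic-index coefficients (on mole percents).
ALIPHATIC_COEF <- c(A = 1.0, V = 2.9, I = 3.9, L = 3.9)

# Guruprasad et al. (1990) dipeptide instability weight values (DIWV);
# rows = first residue, cols = second residue.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34),
  nrow = 20, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))

# Monoisotopic residue masses (Da).
AA_MONO_MASS <- c(
  A = 71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G = 57.021464, H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P = 97.052764, Q = 128.058578, R = 156.101111, S = 87.032028,
  T = 101.047679, V = 99.068414, W = 186.079313, Y = 163.063329)

# Average residue masses (Da).
AA_AVG_MASS <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)

MASS_WATER_MONO <- 18.0105646863
MASS_WATER_AVG <- 18.01528
MASS_PROTON <- 1.007276466621

# Ionizable-group pKa sets. Positive groups: N-terminus, K, R, H.
# Negative groups: C-terminus, D, E, C, Y.
PKA_SETS <- list(
  emboss = list(
    nterm = 8.6, cterm = 3.6,
    K = 10.8, R = 12.5, H = 6.5, D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
  lehninger = list(
    nterm = 9.69, cterm = 2.34,
    K = 10.53, R = 12.48, H = 6.00, D = 3.65, E = 4.25, C = 8.33, Y = 10.07))

#' Retrieve a pinned per-residue QSAR scale table
#'
#' The package ships ten standard amino-acid descriptor families as plain-text
#' (R source) package data: `cruciani` (3 components), `mswhim` (3),
#' `zscales` (5), `tscales` (5), `fasgai` (6), `protfp` (8), `stscales` (8),
#' `vhse` (8), `blosum-indices` (10) and `kidera` (10). Each table has one row
#' per canonical residue (alphabetical one-letter order) and one column per
#' component.
#'
#' @param family Family name, one of `names(scale_families())`.
#' @return A 20-row numeric matrix, residues in rows, components in columns.
#' @examples
#' scale_table("mswhim")["W", ]
#' @export
scale_table <- function(family) {
  if (!family %in% names(QSAR_SCALES)) {
    stop("unknown scale family '", family, "'; available: ",
         paste(names(QSAR_SCALES), collapse = ", "))
  }
  QSAR_SCALES[[family]]
}

#' List available QSAR scale families and their component counts
#'
#' @return Named integer vector: family name -> number of components.
#' @export
scale_families <- function() {
  vapply(QSAR_SCALES, ncol, integer(1))
}
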