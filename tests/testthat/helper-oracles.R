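# Shared fixtures and independent oracles used across test files.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_sequence <- function(len, tryptic = FALSE) {
  body <- sample(AAS, if (tryptic) len - 1 else len, replace = TRUE)
  if (tryptic) body <- c(body, sample(c("K", "R"), 1))
  paste(body, collapse = "")
}

# Brute-force per-position averaging oracle for QSAR family means: walks the
# sequence position by position and accumulates each component sum.
oracle_family_mean <- function(sequence, table) {
  chars <- strsplit(sequence, "")[[1]]
  acc <- rep(0, ncol(table))
  for (ch in chars) acc <- acc + as.numeric(table[ch, ])
  acc / length(chars)
}

# Set-enumeration oracle for composition features.
oracle_composition <- function(sequence, classes) {
  chars <- strsplit(sequence, "")[[1]]
  out <- numeric(0)
  for (cls in names(classes)) {
    cnt <- 0
    for (ch in chars) if (ch %in% classes[[cls]]) cnt <- cnt + 1
    out <- c(out, cnt, cnt / length(chars) * 100)
  }
  out
}

# Small random regression fixture with named feature columns.
toy_features <- function(n, p, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
}
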