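test_that("modification stripping yields bare canonical sequences", {
  expect_identical(strip_modifications("_AM(Oxidation (M))K_"), "AMK")
  expect_identical(strip_modifications("PEPTIDEK"), "PEPTIDEK")
  expect_identical(strip_modifications("AC[+57.0215]DK"), "ACDK")
  expect_error(strip_modifications("PEPTIDEX"), "non-canonical")
  expect_error(strip_modifications("_(Acetyl)_"), "empty")
  expect_error(strip_modifications("AM(OxK"), "unbalanced")
})

test_that("composition features follow the pinned class memberships", {
  g <- aa_composition("G")
  expect_equal(unname(g["Tiny_count"]), 1)
  expect_equal(unname(g["Tiny_pct"]), 100)
  expect_equal(unname(g["Aromatic_count"]), 0)

  kr <- aa_composition("KR")
  expect_equal(unname(kr["Basic_count"]), 2)
  expect_equal(unname(kr["Basic_pct"]), 100)
  expect_equal(unname(kr["Acidic_count"]), 0)

  # one of each residue: counts equal class cardinalities, pct = count * 5
  full <- aa_composition(paste(AAS, collapse = ""))
  card <- c(Tiny = 5, Small = 9, Aliphatic = 4, Aromatic = 4, NonPolar = 10,
            Polar = 10, Charged = 5, Basic = 3, Acidic = 2)
  for (cls in names(card)) {
    expect_equal(unname(full[paste0(cls, "_count")]), unname(card[cls]))
    expect_equal(unname(full[paste0(cls, "_pct")]), unname(card[cls]) * 5)
  }
})

test_that("physicochemical properties match their defining formulas", {
  gg <- physicochemical("GG")
  expect_equal(unname(gg["hydrophobicity_kd"]), -0.4)

  # aliphatic index of poly-Ala: 100 mole percent Ala, coefficient 1
  expect_equal(unname(physicochemical("AAAA")["aliphatic_index"]), 100)

  # net charge at the reported pI is zero by definition of the pI
  for (s in c("PEPTIDEK", "KRRH", "DDEEY", "ACDEFGHIK")) {
    props <- physicochemical(s)
    pI <- unname(props["pI"])
    expect_gt(pI, 0); expect_lt(pI, 14)
    chars <- strsplit(s, "")[[1]]
    expect_lt(abs(faimscv:::peptide_net_charge(chars, pI, faimscv:::PKA_SETS$emboss)),
              1e-4)
  }

  expect_warning(p1 <- physicochemical("G"), "instability")
  expect_equal(unname(p1["instability_index"]), 0)
  expect_error(physicochemical(""), "non-empty")
})

test_that("QSAR family means equal the brute-force averaging oracle", {
  # homopolymer and single-residue checks against the pinned tables
  expect_equal(unname(qsar_profile("W", "mswhim")),
               unname(scale_table("mswhim")["W", ]))
  expect_equal(unname(qsar_profile("LLLL", "zscales")),
               unname(scale_table("zscales")["L", ]))

  set.seed(101)
  for (i in 1:100) {
    s <- random_sequence(sample(7:30, 1))
    for (fam in names(scale_families())) {
      expect_lt(max(abs(qsar_profile(s, fam) -
                          oracle_family_mean(s, scale_table(fam)))), 1e-9)
    }
  }
  expect_error(qsar_profile("ACDK", "nosuchfamily"), "unknown scale family")
})

test_that("every shipped scale family defines 20 residue values", {
  fams <- scale_families()
  expect_equal(unname(fams[c("cruciani", "mswhim", "zscales", "tscales",
                             "fasgai", "protfp", "stscales", "vhse",
                             "blosum-indices", "kidera")]),
               c(3L, 3L, 5L, 5L, 6L, 8L, 8L, 8L, 10L, 10L))
  for (fam in names(fams)) {
    tab <- scale_table(fam)
    expect_equal(nrow(tab), 20L)
    expect_true(all(is.finite(tab)))
  }
})

test_that("featurization is structured, deterministic and modification-blind", {
  reg <- feature_registry()
  expect_equal(length(reg$features), 76L)
  expect_equal(lengths(reg$blocks)[c("charge", "composition",
                                     "physicochemical", "qsar")],
               c(charge = 1L, composition = 18L, physicochemical = 7L,
                 qsar = 50L))

  v <- featurize(peptide_ion("ELVISLIVESK", 2), reg)
  expect_length(v, 76L)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), reg$features)

  expect_identical(v, featurize(peptide_ion("ELVISLIVESK", 2), reg))
  expect_identical(featurize(peptide_ion("_ELVISM(Oxidation (M))K_", 2), reg),
                   featurize(peptide_ion("ELVISMK", 2), reg))
})

test_that("per-residue-scale features of homopolymers are length-invariant", {
  reg <- feature_registry()
  idx <- c(reg$blocks$qsar,
           match(c("phys_hydrophobicity_kd", "phys_boman_index"), reg$features))
  for (aa in c("A", "W", "K")) {
    v4 <- featurize(peptide_ion(strrep(aa, 4), 2), reg)
    v9 <- featurize(peptide_ion(strrep(aa, 9), 2), reg)
    expect_equal(v4[idx], v9[idx], tolerance = 1e-12)
  }
})

test_that("the registry is configurable and serializes losslessly", {
  reg66 <- feature_registry(qsar_families = names(scale_families()))
  expect_equal(length(reg66$features), 1 + 18 + 7 + 66)
  expect_error(feature_registry(qsar_families = "bogus"), "unknown QSAR")
  expect_error(feature_registry(pka_set = "bogus"), "unknown pKa set")

  path <- withr::local_tempfile(fileext = ".json")
  write_registry(feature_registry(pka_set = "lehninger"), path)
  back <- read_registry(path)
  expect_identical(back$features, feature_registry()$features)
  expect_identical(back$pka_set, "lehninger")
})

test_that("peptide ions validate charge and sequence", {
  expect_error(peptide_ion("PEPTIDEK", 0), "charge")
  expect_error(peptide_ion("PEPTIDEK", 9), "charge")
  expect_identical(peptide_ion("PEPTIDEK", 3)$charge, 3L)
})

test_that("shipped plain-text scale tables match the in-code constants", {
  dir <- system.file("extdata", "scales", package = "faimscv")
  for (fam in names(scale_families())) {
    path <- file.path(dir, paste0(fam, "-v1.0.tsv"))
    expect_true(file.exists(path))
    df <- utils::read.delim(path, check.names = FALSE)
    tab <- scale_table(fam)
    expect_identical(df$residue, rownames(tab))
    expect_equal(as.matrix(df[, -1]), tab, ignore_attr = "dimnames",
                 tolerance = 1e-12)
  }
})
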