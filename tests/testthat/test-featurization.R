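# Featurization: canonicalization/dedup, label resolution, fused
# fingerprint blocks, min-max normalization, external table loading.

test_that("canonicalization collapses duplicates and drops metals", {
  rec <- data.frame(
    smiles = c("C", "C", "OCC", "CCO", "[Na+].[Cl-]", "c1ccccc1"),
    label = c(1, 1, 0, 0, 1, 1),
    source = "s1")
  out <- canonicalize_and_dedupe(rec)
  # "C" twice -> one record; "OCC"/"CCO" same structure -> one record;
  # the sodium salt is removed by the metal rule
  expect_equal(nrow(out), 3L)
  expect_false(any(grepl("Na", out$canonical_smiles)))
  expect_equal(anyDuplicated(out$canonical_smiles), 0L)
})

test_that("unparseable SMILES are dropped with a warning, not an error", {
  rec <- data.frame(smiles = c("CCO", "xyz123"), label = c(1, 0),
                    source = "s1")
  expect_warning(out <- canonicalize_and_dedupe(rec), "unparseable")
  expect_equal(nrow(out), 1L)
})

test_that("label resolution applies priority override and 80% consensus", {
  tab <- data.frame(
    canonical_smiles = c(rep("A", 5), rep("B", 3), rep("C", 4)),
    source = c(paste0("s", 1:5), paste0("s", 1:3), c("dilirank", "s1",
                                                     "s2", "s3")),
    label = c(1, 1, 1, 1, 0,   1, 1, 0,   0, 1, 1, 1))
  out <- resolve_labels(tab, priority_sources = "dilirank")
  # A: 4/5 = 0.8 agreement -> kept as 1; B: 2/3 < 0.8 -> dropped;
  # C: priority source says 0 -> kept as 0 despite 3 votes for 1
  expect_equal(out$label[out$canonical_smiles == "A"], 1L)
  expect_false("B" %in% out$canonical_smiles)
  expect_equal(out$label[out$canonical_smiles == "C"], 0L)
  expect_equal(nrow(out), 2L)
})

test_that("conflicting same-rank priority labels drop the compound", {
  tab <- data.frame(canonical_smiles = "A",
                    source = c("dilirank", "livertox"),
                    label = c(0, 1))
  # different ranks: highest priority wins, no warning
  expect_warning(
    out <- resolve_labels(tab,
                          priority_sources = c("dilirank", "livertox")),
    NA)
  expect_equal(out$label, 0L)
  # one priority source reporting both labels is an unresolvable conflict
  tab2 <- data.frame(canonical_smiles = c("A", "A"), source = "dilirank",
                     label = c(0, 1))
  expect_warning(out2 <- resolve_labels(tab2, priority_sources = "dilirank"),
                 "conflicting")
  expect_equal(nrow(out2), 0L)
})

test_that("fused fingerprints have the documented block layout", {
  fm <- compute_fused_fingerprints("CC(=O)Oc1ccccc1C(=O)O")
  expect_s3_class(fm, "fused_features")
  expect_equal(fm$blocks$name, c("ECFP2", "MACCS", "RDKIT2D", "PUBCHEM"))
  expect_equal(fm$blocks$width, c(2048L, 167L, 200L, 881L))
  expect_equal(ncol(fm$values), 3296L)
  expect_equal(fm$column_kinds[2216], "continuous")  # first RDKIT2D column
  expect_true(all(fm$column_kinds[1:2215] == "binary"))
  bin_cols <- fm$column_kinds == "binary"
  expect_true(all(fm$values[, bin_cols] %in% c(0, 1)))
})

test_that("MACCS keys agree with an independent implementation", {
  # on-bit key numbers computed with RDKit's MACCS implementation (frozen)
  rdkit_keys <- list(
    "CC(=O)Oc1ccccc1C(=O)O" = c(89, 113, 123, 126, 127, 136, 139, 140, 143,
                                144, 146, 150, 152, 154, 157, 159, 160,
                                162, 163, 164, 165),
    "c1ccccc1C(=O)O" = c(123, 139, 154, 157, 159, 162, 163, 164, 165))
  m <- fp_maccs(names(rdkit_keys))
  for (i in seq_along(rdkit_keys)) {
    expect_equal(which(m[i, ] == 1L) - 1L, rdkit_keys[[i]])
  }
})

test_that("featurization is deterministic and width-additive", {
  smi <- c("C", "CCO")
  a <- compute_fused_fingerprints(smi, blocks = c("ECFP2", "MACCS"))
  b <- compute_fused_fingerprints(smi, blocks = c("ECFP2", "MACCS"))
  expect_identical(a$values, b$values)
  expect_equal(ncol(a$values), 2048L + 167L)
  expect_gte(sum(a$values[1, 1:2048]), 1)  # methane sets at least one bit
  expect_error(compute_fused_fingerprints("not_a_smiles$$"), "row 1")
})

test_that("the shipped descriptor name list pins the RDKIT2D block", {
  shipped <- readLines(system.file("extdata", "descriptors_2d_v1.txt",
                                   package = "rega"))
  expect_length(shipped, 200L)
  expect_identical(shipped, rega:::descriptor_2d_names())
  vals <- fp_rdkit2d("CCO")
  expect_identical(colnames(vals), shipped)
  expect_true(all(is.finite(vals)))
})

test_that("min-max normalization follows the fit-rows rule", {
  fm <- fused_features(matrix(c(2, 4, 6, 5, 5, 5), ncol = 2),
                       c("continuous", "continuous"))
  out <- minmax_fit_apply(fm)
  expect_equal(out$values[, 1], c(0, 0.5, 1))
  expect_equal(out$values[, 2], c(0, 0, 0))  # constant column -> 0
  fm2 <- fused_features(matrix(c(2, 4, 10), ncol = 1), "continuous")
  out2 <- minmax_fit_apply(fm2, fit_rows = 1:2)
  expect_equal(out2$values[, 1], c(0, 1, 1))  # clipped on non-fit row
  expect_error(minmax_fit_apply(out2), "already normalized")
  expect_error(minmax_fit_apply(fm2, integer(0)), "nonempty")
})

test_that("normalization is idempotent on the fitting set", {
  set.seed(3)
  fm <- fused_features(matrix(runif(60, -5, 5), 10, 6),
                       rep("continuous", 6))
  once <- minmax_fit_apply(fm)
  again <- once
  again$normalization <- list(state = "raw", mins = NULL, maxs = NULL)
  twice <- minmax_fit_apply(again)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
})

test_that("external feature tables validate binary columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = c(0, 1, 0, 1), b = c(1, 1, 0, 0),
                       c = c(0.2, -1.5, 3.2, 0)), path, row.names = FALSE)
  fm <- load_feature_table(path, c("binary", "binary", "continuous"))
  expect_equal(ncol(fm$values), 3L)
  expect_equal(fm$blocks$width, 3L)
  write.csv(data.frame(a = c(0, 0.5), b = c(1, 0)), path,
            row.names = FALSE)
  expect_error(load_feature_table(path, c("binary", "binary")), "outside")
  writeLines("", path)
  expect_error(load_feature_table(path, "binary"))
})

test_that("feature matrices round-trip through CSV + metadata", {
  fx <- planted_fixture(seed = 9,
                        spec = synthetic_spec(n = 20, n_binary = 6,
                                              n_continuous = 4, m_binary = 2,
                                              m_continuous = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fx$features, path)
  back <- read_feature_matrix(path)
  expect_equal(back$values, unname(fx$features$values), tolerance = 1e-9)
  expect_equal(back$column_kinds, fx$features$column_kinds)
  expect_equal(back$blocks$name, fx$features$blocks$name)
  expect_equal(back$labels, fx$features$labels)
})
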