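test_that("feature table maps KNO3 to its ion descriptors", {
  ft <- build_feature_table("KNO3")
  expect_identical(ft$cation_symbol, "K")
  expect_identical(ft$anion_symbol, "NO3")
  expect_identical(ft$cation_charge, 1L)
  expect_identical(ft$anion_charge, -1L)
  expect_identical(ft$cation_nutrient_class, "macronutrient")
  expect_equal(ft$cation_mass, 39.10, tolerance = 1e-3)
  expect_equal(ft$anion_mass, 62.00, tolerance = 1e-3)
  expect_equal(ft$salt_molar_mass, 101.1, tolerance = 1e-2)
})

test_that("unknown ions are rejected by name", {
  expect_error(build_feature_table("XyCl2"), "unknown cation 'Xy'")
  expect_error(build_feature_table("KQq3"), "unknown anion")
})

test_that("every panel salt parses with balanced charges", {
  ft <- build_feature_table(salt_panel())
  expect_identical(nrow(ft), 29L)
  expect_true(all(ft$n_cation * ft$cation_charge +
                    ft$n_anion * ft$anion_charge == 0L))
  expect_true(all(ft$salt_molar_mass > 0))
  # spot checks on stoichiometry
  expect_identical(ft$n_anion[ft$salt_name == "Ca(NO3)2"], 2L)
  expect_identical(ft$n_cation[ft$salt_name == "K2SO4"], 2L)
  expect_identical(ft$anion_symbol[ft$salt_name == "NH4H2PO4"], "H2PO4")
})

test_that("feature matrix one-hot encodes over the fixed class vocabulary", {
  m <- feature_matrix(build_feature_table(c("KNO3", "LaCl3")))
  expect_true(all(c("cation_class_macronutrient", "anion_class_micronutrient")
                  %in% colnames(m)))
  expect_equal(unname(m[1, "cation_class_macronutrient"]), 1)
  expect_equal(unname(m[2, "cation_class_heavy_metal"]), 1)
  expect_equal(unname(rowSums(m[, grep("^cation_class", colnames(m))])),
               c(1, 1))
})

test_that("two-range binning splits at ratio 1", {
  expect_identical(as.integer(bin_uptake(c(0.5, 1.0, 1.01, 6), 2)),
                   c(0L, 0L, 1L, 1L))
})

test_that("multi-range binning fixes 1 and splits equally up to the max", {
  lab <- bin_uptake(c(0.5, 3, 5, 7), 4)
  expect_identical(as.integer(lab), 0:3)
  expect_equal(attr(lab, "boundaries"), c(1, 3, 5, 7))
  # boundary membership: bins are right-closed above 1
  lab2 <- bin_uptake(c(1, 3, 5, 7, 2.99, 3.01), 4)
  expect_identical(as.integer(lab2), c(0L, 1L, 2L, 3L, 1L, 2L))
  # everything at or below 1: one occupied class
  lab3 <- bin_uptake(c(0.2, 0.9, 1.0), 3)
  expect_identical(as.integer(lab3), c(0L, 0L, 0L))
  expect_error(bin_uptake(c(1, 2), 7), "between 2 and 6")
  expect_error(bin_uptake(numeric(0), 3), "empty")
  expect_error(bin_uptake(c(1, Inf), 2), "finite")
})

test_that("F1 from confusion handles perfect, balanced and degenerate cases", {
  expect_equal(f1_from_confusion(diag(c(3, 5, 7))), 1)
  even <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(f1_from_confusion(even, "binary"), 0.5)
  expect_equal(f1_from_confusion(even, "macro"), 0.5)
  # class never present and never predicted is excluded from the macro mean
  cm <- matrix(0L, 3, 3)
  cm[1, 1] <- 4; cm[2, 2] <- 2; cm[2, 1] <- 2
  with_empty <- f1_from_confusion(cm, "macro")
  cm2 <- cm[1:2, 1:2]
  expect_equal(with_empty, f1_from_confusion(cm2, "macro"))
  # 0/0 -> 0 convention: a class present but never predicted scores 0
  cm3 <- matrix(c(4, 2, 0, 0), 2)
  expect_equal(f1_from_confusion(cm3, "macro"),
               mean(c(2 * (4 / 6) * 1 / (4 / 6 + 1), 0)))
  expect_error(f1_from_confusion(matrix(1:6, 2)), "square")
})

test_that("macro F1 is invariant under consistent class permutation", {
  set.seed(31)
  cm <- matrix(rpois(16, 4), 4)
  perm <- sample(4)
  expect_equal(f1_from_confusion(cm[perm, perm]), f1_from_confusion(cm),
               tolerance = 1e-12)
})

test_that("cross-validation partitions samples and is reproducible", {
  d <- generate_ml_dataset(80, class_signal_strength = 1, n_ranges = 3,
                           seed = 4)
  r1 <- crossval_classify(d$features, d$labels, seed = 7)
  r2 <- crossval_classify(d$features, d$labels, seed = 7)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_identical(r1$f1, r2$f1)
  expect_identical(r1$per_fold_confusions, r2$per_fold_confusions)
  # partition: every sample in exactly one test fold
  expect_identical(sort(unique(r1$fold_assignment)), 1:5)
  expect_identical(length(r1$fold_assignment), 80L)
  # confusions sum to the fold test sizes and pool to n
  sizes <- tabulate(r1$fold_assignment, 5)
  expect_identical(vapply(r1$per_fold_confusions, sum, numeric(1)),
                   as.numeric(sizes))
  expect_equal(sum(r1$pooled_confusion), 80)
})

test_that("a single perfectly separating feature yields F1 = 1", {
  set.seed(32)
  # discrete feature values (as ion descriptors are), so held-out points
  # coincide with training values and any separating split is exact
  x <- matrix(rep(c(-1, 1), 30)[sample.int(60)], 60, 1)
  y <- as.integer(x[, 1] > 0)
  for (s in c(1, 99)) {
    expect_equal(crossval_classify(x, y, seed = s)$f1, 1)
  }
})

test_that("stratified folds keep every class in each fold when possible", {
  set.seed(33)
  y <- rep(0:2, times = c(10, 10, 10))
  x <- matrix(rnorm(90), 30, 3)
  r <- crossval_classify(x, y, n_folds = 5, seed = 2)
  for (f in 1:5) {
    expect_setequal(unique(y[r$fold_assignment == f]), 0:2)
  }
  expect_length(r$degenerate_folds, 0L)
})
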