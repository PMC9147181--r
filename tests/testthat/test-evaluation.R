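# Metrics, the repeated 2:1:1 protocol, leakage protection, ablation
# bookkeeping and importance counting.

test_that("confusion metrics match hand-computed values", {
  # TP=3 FP=1 FN=2 TN=4: ACC 0.7, precision 0.75, recall 0.6, F1 2/3
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m <- compute_metrics(labels, pred)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3, 1, 2, 4))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / 3)
  # perfect prediction
  mp <- compute_metrics(labels, labels, scores = labels)
  expect_equal(c(mp$accuracy, mp$f1, mp$auc), c(1, 1, 1))
  # zero-division convention
  mz <- compute_metrics(c(1, 1, 0), c(0, 0, 0))
  expect_equal(mz$f1, 0)
  expect_equal(mz$precision, 0)
})

test_that("AUC equals brute-force pair counting, including ties", {
  m <- compute_metrics(c(1, 0, 1, 0), c(1, 1, 0, 0),
                       scores = c(0.9, 0.8, 0.3, 0.1))
  expect_equal(m$auc, 0.75)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    got <- compute_metrics(labels, rbinom(n, 1, 0.5), scores)$auc
    expect_equal(got, bruteforce_auc(labels, scores))
  }
  # cross-check against an independent library implementation
  set.seed(18)
  labels <- rbinom(40, 1, 0.5)
  scores <- rnorm(40)
  expect_equal(compute_metrics(labels, labels, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
  # single-class labels: AUC undefined
  expect_true(is.na(compute_metrics(c(1, 1), c(1, 0), c(0.5, 0.2))$auc))
})

test_that("2:1:1 splits are disjoint, exhaustive and seeded", {
  sp <- make_splits(8, seed = 1)
  expect_length(sp, 5)
  s <- sp[[1]]
  expect_length(s$train, 4)
  expect_length(s$validation, 2)
  expect_length(s$test, 2)
  for (s in sp) {
    all_rows <- c(s$train, s$validation, s$test)
    expect_equal(sort(all_rows), 1:8)
  }
  expect_identical(make_splits(101, seed = 9), make_splits(101, seed = 9))
  expect_false(identical(make_splits(101, seed = 9)[[1]]$train,
                         make_splits(101, seed = 10)[[1]]$train))
})

test_that("training artifacts never depend on validation/test rows", {
  fx <- planted_fixture(seed = 20)
  sp <- make_splits(nrow(fx$features$values), seed = 20,
                    n_repeats = 1)[[1]]
  poisoned <- fx$features
  poisoned$values[c(sp$validation, sp$test),
                  fx$features$column_kinds == "continuous"] <- NaN
  norm <- minmax_fit_apply(poisoned, sp$train)
  # normalization fitted on train rows only: finite mins/maxs, clean train
  expect_true(all(is.finite(norm$normalization$mins)))
  expect_true(all(is.finite(norm$normalization$maxs)))
  expect_true(all(is.finite(norm$values[sp$train, ])))
  # poison sentinels survive on held-out rows (they were never touched)
  expect_true(anyNA(norm$values[sp$test, ]))
  # rotation and ensemble training on train rows never see the sentinels
  X <- norm$values
  attr(X, "column_kinds") <- norm$column_kinds
  ind <- matrix(c(1:10, 81:90), 2, 10)
  ens <- train_ensemble(ind, X[sp$train, ], fx$y[sp$train],
                        column_kinds = norm$column_kinds, seed = 21)
  expect_gte(length(ens$slots), 1)
  expect_true(all(is.finite(decision_scores(ens, X[sp$train, ]))))
})

test_that("importance counting matches the direct-count oracle", {
  pop <- list(matrix(c(1, 1, 2, 3, 3, 3), 2, 3, byrow = TRUE))
  imp <- feature_importance(pop)
  expect_equal(imp$counts$feature, c(3L, 1L, 2L))
  expect_equal(imp$counts$count, c(3L, 2L, 1L))
  expect_equal(sum(imp$counts$count), 6)
  # conservation: sum of counts = M * K * Sfs; permutation invariance
  set.seed(23)
  pop2 <- lapply(1:4, function(i) matrix(sample.int(30, 12, TRUE), 3, 4))
  imp2 <- feature_importance(pop2)
  expect_equal(sum(imp2$counts$count), 4 * 3 * 4)
  imp_perm <- feature_importance(rev(pop2))
  expect_identical(imp2$counts, imp_perm$counts)
  # top_n = Sf lists every observed feature
  expect_equal(sort(feature_importance(pop2, top_n = 30)$top),
               sort(unique(unlist(pop2))))
  # per-block aggregation
  blocks <- data.frame(name = c("A", "B"), width = c(10L, 20L),
                       offset = c(0L, 10L))
  imp3 <- feature_importance(pop, top_n = 2, blocks = blocks)
  expect_equal(imp3$block_summary$count_in_top, c(2L, 0L))
  expect_equal(imp3$block_summary$ratio, c(0.2, 0))
})

test_that("block subsetting and ablation bookkeeping line up", {
  fx <- planted_fixture(seed = 25,
                        spec = synthetic_spec(n = 60, n_binary = 10,
                                              n_continuous = 6,
                                              m_binary = 4,
                                              m_continuous = 2, seed = 25))
  fm <- fx$features
  only_bin <- subset_blocks(fm, "BIN")
  expect_equal(ncol(only_bin$values), 10)
  expect_true(all(only_bin$column_kinds == "binary"))
  expect_identical(subset_blocks(fm, "all"), fm)
  expect_error(subset_blocks(fm, "NOPE"), "unknown")
  both <- subset_blocks(fm, c("BIN", "CONT"))
  expect_equal(both$values, fm$values)
})

test_that("run_cv reports per-fold and mean metrics consistently", {
  spec <- synthetic_spec(n = 80, n_binary = 16, n_continuous = 8,
                         m_binary = 6, m_continuous = 3, seed = 30)
  d <- generate_planted_dataset(spec)
  cfg <- ga_config(generations = 1, pop_size = 2, k = 2, subset_size = 4,
                   n_features = 24, base_learner = base_learner_rf(10),
                   seed = 30)
  res <- run_cv(d$features, d$labels, cfg,
                splits = make_splits(80, seed = 30, n_repeats = 2))
  expect_equal(nrow(res$folds), 2)
  expect_equal(res$mean[["f1"]], mean(res$folds$f1))
  expect_equal(res$mean[["accuracy"]], mean(res$folds$accuracy))
  expect_length(res$curves, 2)
  expect_true(all(vapply(res$curves,
                         function(cv) all(diff(cv$best_val_f1) >= 0),
                         logical(1))))
})
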