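# Evaluation harness: confusion-matrix metrics with rank-statistic AUC, the
# repeated 2:1:1 train/validation/test protocol, the block-ablation harness,
# and final-generation feature-importance counting.

#' Classification metrics from labels, predictions and scores
#'
#' Computes the confusion counts and accuracy, precision, recall and F1 of
#' the positive class (zero-division convention: 0), plus AUC as the
#' Mann-Whitney rank statistic on `scores` with half credit for score ties.
#' AUC is `NA` when only one class is present or no scores are given.
#'
#' @param labels 0/1 true labels.
#' @param predictions 0/1 predicted labels.
#' @param scores optional real-valued decision scores for AUC.
#' @return list with `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`,
#'   `recall`, `f1`, `auc`.
#' @export
compute_metrics <- function(labels, predictions, scores = NULL) {
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  stopifnot(length(labels) == length(predictions),
            all(labels %in% c(0L, 1L)), all(predictions %in% c(0L, 1L)))
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  tn <- sum(labels == 0L & predictions == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  auc <- NA_real_
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(labels))
    n1 <- sum(labels == 1L)
    n0 <- sum(labels == 0L)
    if (n1 > 0 && n0 > 0) {
      r <- rank(scores)  # average ranks give ties half credit
      auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / length(labels),
       precision = precision, recall = recall, f1 = f1, auc = auc)
}

#' Repeated random 2:1:1 train/validation/test splits
#'
#' Five (by default) independent random partitions of the rows into
#' training, validation and test sets in ratio 2:1:1, with sizes
#' `floor(n/2)`, `floor(n/4)` and the remainder. Each repetition uses its
#' own stream derived from `seed`.
#'
#' @param n number of rows (at least 8).
#' @param seed master seed.
#' @param n_repeats number of repetitions.
#' @return list of splits, each with integer index vectors `train`,
#'   `validation`, `test` and a `fold` id.
#' @export
make_splits <- function(n, seed = 1L, n_repeats = 5L) {
  stopifnot(n >= 8)
  lapply(seq_len(n_repeats), function(f) {
    perm <- with_seed(derive_seed(seed, "split", f), sample.int(n))
    n_train <- floor(n / 2)
    n_val <- floor(n / 4)
    list(fold = f,
         train = sort(perm[seq_len(n_train)]),
         validation = sort(perm[n_train + seq_len(n_val)]),
         test = sort(perm[(n_train + n_val + 1L):n]))
  })
}

# normalize a fused matrix on the training rows and expose the plain value
# matrix with a column_kinds attribute for the rotation/boosting layers
prepare_fold_matrix <- function(features, train_rows) {
  fm <- if (features$normalization$state == "raw") {
    minmax_fit_apply(features, train_rows)
  } else features
  X <- fm$values
  attr(X, "column_kinds") <- fm$column_kinds
  X
}

#' Run the full evolution protocol over repeated splits
#'
#' For each split: min-max normalization is fitted on the training rows
#' only, the GA evolves on (train, validation), the final best individual's
#' ensemble is retrained on the training rows, and the held-out test rows
#' are scored. Reports per-fold metrics, their mean, and the per-fold
#' evolution curves.
#'
#' @param features a raw [fused_features] object.
#' @param labels 0/1 labels (defaults to `features$labels`).
#' @param config a [ga_config()]; its `n_features` must match the matrix.
#' @param splits optional list from [make_splits()]; by default five
#'   repetitions derived from `config$seed`.
#' @param verbose print progress.
#' @return list with `folds` (per-fold data frames row), `mean` (named
#'   vector of mean accuracy/F1/AUC), and `curves` / `runs` per fold.
#' @export
run_cv <- function(features, labels = features$labels, config,
                   splits = NULL, verbose = FALSE) {
  stopifnot(inherits(features, "fused_features"), !is.null(labels))
  n <- nrow(features$values)
  stopifnot(length(labels) == n,
            config$n_features == ncol(features$values))
  if (is.null(splits)) splits <- make_splits(n, seed = config$seed)
  folds <- list()
  curves <- list()
  runs <- list()
  for (sp in splits) {
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, "fold", sp$fold)
    X <- prepare_fold_matrix(features, sp$train)
    kinds <- attr(X, "column_kinds")
    res <- evolve(fold_cfg,
                  train_x = X[sp$train, , drop = FALSE],
                  train_y = labels[sp$train],
                  val_x = X[sp$validation, , drop = FALSE],
                  val_y = labels[sp$validation],
                  column_kinds = kinds,
                  test_x = X[sp$test, , drop = FALSE],
                  test_y = labels[sp$test],
                  verbose = verbose)
    ens <- train_ensemble(res$best_individual, X[sp$train, , drop = FALSE],
                          labels[sp$train], column_kinds = kinds,
                          base_learner = fold_cfg$base_learner,
                          retries = fold_cfg$retries,
                          seed = derive_seed(fold_cfg$seed, "final"))
    test_x <- X[sp$test, , drop = FALSE]
    pred <- predict_labels(ens, test_x)
    sc <- decision_scores(ens, test_x)
    m <- compute_metrics(labels[sp$test], pred, sc)
    folds[[sp$fold]] <- data.frame(
      fold = sp$fold, accuracy = m$accuracy, precision = m$precision,
      recall = m$recall, f1 = m$f1, auc = m$auc,
      best_val_f1 = res$best_fitness)
    curves[[sp$fold]] <- res$curve
    runs[[sp$fold]] <- res
    if (verbose) {
      rega_msg(sprintf("fold %d: test ACC %.3f F1 %.3f AUC %.3f", sp$fold,
                       m$accuracy, m$f1, m$auc))
    }
  }
  folds <- do.call(rbind, folds)
  list(folds = folds,
       mean = c(accuracy = mean(folds$accuracy), f1 = mean(folds$f1),
                auc = mean(folds$auc)),
       curves = curves, runs = runs)
}

#' Block-ablation harness
#'
#' Re-runs the full protocol restricted to each requested block
#' combination and collects the mean test metrics in a tidy table.
#'
#' @param features a raw [fused_features] object with named blocks.
#' @param labels 0/1 labels.
#' @param combinations list of character vectors of block names (or the
#'   string `"all"` for the unrestricted matrix).
#' @param config a [ga_config()]; `n_features` is adjusted per combination.
#' @param verbose print progress.
#' @return data frame with one row per combination: `combination`,
#'   `n_features`, `accuracy`, `f1`, `auc`.
#' @export
ablation <- function(features, labels = features$labels, combinations,
                     config, verbose = FALSE) {
  rows <- lapply(combinations, function(combo) {
    fm <- subset_blocks(features, combo)
    cfg <- config
    cfg$n_features <- ncol(fm$values)
    res <- run_cv(fm, labels, cfg, verbose = verbose)
    data.frame(combination = paste(combo, collapse = "+"),
               n_features = cfg$n_features,
               accuracy = res$mean[["accuracy"]], f1 = res$mean[["f1"]],
               auc = res$mean[["auc"]])
  })
  do.call(rbind, rows)
}

#' Feature-importance counts over a final population
#'
#' Counts the occurrences of every feature index across all genes of all
#' individuals, ranks them descending (ties broken by ascending index), and
#' aggregates the `top_n` set per block (count and count / block width).
#'
#' @param population list of individuals (index matrices).
#' @param top_n number of top-ranked features to aggregate (default all).
#' @param blocks optional block data frame (`name`, `width`, `offset`) from
#'   a [fused_features] object for the per-block aggregation.
#' @return list with `counts` (data frame `feature`, `count` in rank
#'   order), `top` (the top-n feature indices) and, when `blocks` is given,
#'   `block_summary` (`name`, `count_in_top`, `ratio`).
#' @export
feature_importance <- function(population, top_n = NULL, blocks = NULL) {
  stopifnot(length(population) > 0)
  genes <- unlist(lapply(population, as.integer))
  tab <- table(genes)
  counts <- data.frame(feature = as.integer(names(tab)),
                       count = as.integer(tab))
  counts <- counts[order(-counts$count, counts$feature), , drop = FALSE]
  rownames(counts) <- NULL
  if (is.null(top_n)) top_n <- nrow(counts)
  top <- counts$feature[seq_len(min(top_n, nrow(counts)))]
  out <- list(counts = counts, top = top, total = length(genes))
  if (!is.null(blocks)) {
    out$block_summary <- do.call(rbind, lapply(seq_len(nrow(blocks)),
      function(i) {
        lo <- blocks$offset[i] + 1L
        hi <- blocks$offset[i] + blocks$width[i]
        n_in <- sum(top >= lo & top <= hi)
        data.frame(name = blocks$name[i], count_in_top = n_in,
                   ratio = n_in / blocks$width[i])
      }))
  }
  out
}
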