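# AdaBoost-style chain of K weak classifiers over the K rotated feature
# subsets of one individual. Training weights start uniform; each slot draws
# a weighted bootstrap, fits its base learner on the rotated sample, is
# scored on the rotated full training set (weighted error epsilon), and
# casts votes with weight ln(1/beta), beta = epsilon / (1 - epsilon).
# Slots with epsilon = 0 or epsilon >= 0.5 are discarded and retried with
# reinitialized uniform weights.

#' Uniform initial sample weights
#'
#' @param n number of training samples.
#' @return numeric vector of length `n`, each `1/n`, summing to 1.
#' @export
init_weights <- function(n) {
  if (n < 1L) stop("n must be >= 1")
  rep(1 / n, n)
}

#' Weighted bootstrap sample
#'
#' Draws `n` row indices i.i.d. with replacement with probability `w`.
#' Uses the ambient RNG stream.
#'
#' @param n sample size (and length of `w`).
#' @param w sample weight distribution.
#' @return integer vector of `n` row indices.
#' @export
weighted_bootstrap <- function(n, w) {
  stopifnot(length(w) == n, all(w >= 0), abs(sum(w) - 1) < 1e-9)
  sample.int(n, n, replace = TRUE, prob = w)
}

#' Weighted classification error
#'
#' `epsilon = sum_j w_j * l_j` with `l_j = 1` iff the prediction differs
#' from the label.
#'
#' @param predictions,labels equal-length 0/1 vectors.
#' @param w sample weights.
#' @return epsilon in `[0, 1]`.
#' @export
weighted_error <- function(predictions, labels, w) {
  stopifnot(length(predictions) == length(labels),
            length(labels) == length(w))
  sum(w * (predictions != labels))
}

#' Confidence ratio beta
#'
#' `beta = epsilon / (1 - epsilon)`; defined only on `0 < epsilon < 0.5`
#' (the caller must apply the ignore-and-retry guard outside this range),
#' giving a vote weight `ln(1/beta) > 0`.
#'
#' @param epsilon weighted error of a slot.
#' @return beta in `(0, 1)`.
#' @export
compute_beta <- function(epsilon) {
  if (!(epsilon > 0 && epsilon < 0.5)) {
    stop("beta undefined for epsilon = ", epsilon,
         " (guard: slot must be ignored when epsilon = 0 or epsilon >= 0.5)")
  }
  epsilon / (1 - epsilon)
}

#' Boosting weight update
#'
#' `w'_j = w_j beta^(1 - l_j) / sum_i w_i beta^(1 - l_i)`: correctly
#' classified rows (`l = 0`) shrink by `beta`, misclassified rows keep their
#' raw weight, and the vector is renormalized to sum 1.
#'
#' @param w current sample weights.
#' @param beta slot confidence ratio in `(0, 1)`.
#' @param l 0/1 misclassification indicator per sample.
#' @return updated weight vector summing to 1.
#' @export
update_weights <- function(w, beta, l) {
  stopifnot(length(w) == length(l), all(l %in% c(0, 1)),
            beta > 0, beta < 1)
  raw <- w * beta^(1 - l)
  raw / sum(raw)
}

#' Random-forest base learner (50 trees)
#'
#' The default weak classifier: a random forest with `ntree` trees fitted on
#' a rotated feature-subset matrix. Any list with `fit(X, y)` and
#' `predict(model, X)` members (both on plain numeric matrices, labels 0/1)
#' can be supplied instead through the GA config.
#'
#' @param ntree number of trees.
#' @return a base-learner spec list.
#' @importFrom randomForest randomForest
#' @export
base_learner_rf <- function(ntree = 50L) {
  list(
    name = sprintf("random_forest_%d", ntree),
    fit = function(X, y) {
      randomForest::randomForest(x = X, y = factor(y, levels = c(0L, 1L)),
                                 ntree = ntree)
    },
    # threshold the tree-vote fraction instead of predict()'s random
    # tie-break so predictions are deterministic given the fitted forest
    predict = function(model, X) {
      votes <- predict(model, X, type = "vote")
      as.integer(votes[, "1"] > 0.5)
    })
}

#' Train the rotation-boosting ensemble of one individual
#'
#' For each of the individual's K feature subsets in order: fit the subset
#' rotation on the full training rows, draw a weighted bootstrap of size N,
#' fit the base learner on the rotated bootstrap, score the rotated full
#' training set to get the weighted error `epsilon`, and either accept the
#' slot (`0 < epsilon < 0.5`: compute beta, update the weights) or discard
#' it, reset the weights to uniform and retry the slot with a fresh
#' bootstrap up to `retries` times before leaving it empty. If no slot
#' survives, the ensemble falls back to the training-majority label.
#'
#' @param individual integer matrix `K x Sfs` of 1-based feature indices
#'   (one row per subset), or a list of K integer vectors.
#' @param X numeric training matrix (full feature space, already
#'   normalized).
#' @param y 0/1 training labels.
#' @param column_kinds character vector of `"binary"`/`"continuous"` per
#'   column of `X`; defaults to the `column_kinds` attribute of `X`.
#' @param base_learner a base-learner spec (default [base_learner_rf()]).
#' @param retries retry cap per slot (default 5).
#' @param seed optional integer; when given, training runs under a local
#'   RNG stream seeded with it.
#' @return an object of class `rotation_boost_ensemble`.
#' @export
train_ensemble <- function(individual, X, y,
                           column_kinds = attr(X, "column_kinds"),
                           base_learner = base_learner_rf(),
                           retries = 5L, seed = NULL) {
  if (is.null(column_kinds)) stop("column_kinds must be supplied")
  if (is.list(individual)) {
    individual <- do.call(rbind, individual)
  }
  individual <- matrix(as.integer(individual), nrow = nrow(individual))
  y <- as.integer(y)
  n <- nrow(X)
  stopifnot(length(y) == n, all(y %in% c(0L, 1L)))
  run <- function() {
    w <- init_weights(n)
    slots <- list()
    for (k in seq_len(nrow(individual))) {
      slot <- NULL
      for (attempt in seq_len(retries + 1L)) {
        rot <- try(fit_rotation(X, partition_columns(individual[k, ],
                                                     column_kinds)),
                   silent = TRUE)
        if (inherits(rot, "try-error")) break  # degenerate subset: skip slot
        Xr <- apply_rotation(rot, X)
        idx <- weighted_bootstrap(n, w)
        model <- base_learner$fit(Xr[idx, , drop = FALSE], y[idx])
        pred <- base_learner$predict(model, Xr)
        eps <- weighted_error(pred, y, w)
        if (eps > 0 && eps < 0.5) {
          beta <- compute_beta(eps)
          w <- update_weights(w, beta, as.integer(pred != y))
          slot <- list(rotation = rot, model = model, epsilon = eps,
                       beta = beta, vote_weight = log(1 / beta),
                       predict = base_learner$predict)
          break
        }
        w <- init_weights(n)  # ignore slot, reinitialize, retry
      }
      if (!is.null(slot)) slots[[length(slots) + 1L]] <- slot
    }
    slots
  }
  slots <- if (is.null(seed)) run() else with_seed(seed, run())
  fallback <- if (sum(y == 1L) > sum(y == 0L)) 1L else 0L
  if (length(slots) == 0L) {
    rega_warn("no valid boosting slot; ensemble falls back to the ",
              "training-majority label ", fallback)
  }
  structure(list(slots = slots, fallback = fallback,
                 base_learner = base_learner$name,
                 column_kinds = column_kinds),
            class = "rotation_boost_ensemble")
}

# per-row class supports (mu_0, mu_1): each valid slot casts ln(1/beta) for
# the class it predicts
ensemble_supports <- function(ensemble, X) {
  n <- nrow(X)
  mu <- matrix(0, n, 2L)
  for (slot in ensemble$slots) {
    Xr <- apply_rotation(slot$rotation, X)
    pred <- ensemble_base_predict(ensemble, slot, Xr)
    mu[cbind(seq_len(n), pred + 1L)] <-
      mu[cbind(seq_len(n), pred + 1L)] + slot$vote_weight
  }
  mu
}

ensemble_base_predict <- function(ensemble, slot, Xr) {
  slot$predict(slot$model, Xr)
}

#' Predict class labels by weighted vote
#'
#' Support for class t is the sum of `ln(1/beta_k)` over valid slots
#' predicting t; the label is the argmax, with exact ties broken toward
#' class 0. With no valid slot every row gets the training-majority
#' fallback label.
#'
#' @param ensemble a trained `rotation_boost_ensemble`.
#' @param X numeric matrix over the full feature space.
#' @return integer vector of 0/1 labels.
#' @export
predict_labels <- function(ensemble, X) {
  if (length(ensemble$slots) == 0L) {
    return(rep(ensemble$fallback, nrow(X)))
  }
  mu <- ensemble_supports(ensemble, X)
  as.integer(mu[, 2] > mu[, 1])
}

#' Real-valued decision scores
#'
#' `score = mu_1 - mu_0` per row; thresholding at 0 (ties toward 0)
#' reproduces [predict_labels()]. Used for AUC.
#'
#' @inheritParams predict_labels
#' @return numeric score vector.
#' @export
decision_scores <- function(ensemble, X) {
  if (length(ensemble$slots) == 0L) {
    return(rep(ifelse(ensemble$fallback == 1L, 1, -1), nrow(X)))
  }
  mu <- ensemble_supports(ensemble, X)
  mu[, 2] - mu[, 1]
}
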