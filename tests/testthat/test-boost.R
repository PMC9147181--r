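# Boosting chain: weight arithmetic against hand/brute-force evaluation,
# the epsilon guard, weighted voting, and reproducibility.

test_that("initial weights are uniform and sum to one", {
  expect_equal(init_weights(4), rep(0.25, 4))
  expect_equal(init_weights(1), 1)
  expect_equal(sum(init_weights(37)), 1, tolerance = 1e-12)
  expect_error(init_weights(0))
})

test_that("weighted bootstrap follows the weight distribution", {
  set.seed(2)
  idx <- weighted_bootstrap(3, c(1, 0, 0))
  expect_equal(idx, rep(1L, 3))
  # uniform weights: per-row draw counts within 4 sigma of Binomial(N, 1/n)
  n <- 400
  idx2 <- weighted_bootstrap(n, rep(1 / n, n))
  expect_length(idx2, n)
  counts <- tabulate(idx2, n)
  sigma <- sqrt(n * (1 / n) * (1 - 1 / n))
  expect_true(all(abs(counts - 1) <= 4 * sigma + 1))
})

test_that("weighted error sums the weights of misclassified rows", {
  w <- c(0.1, 0.2, 0.3, 0.4)
  labels <- c(0, 0, 0, 0)
  pred <- c(0, 1, 0, 1)  # rows 2 and 4 wrong
  expect_equal(weighted_error(pred, labels, w), 0.6)
  expect_equal(weighted_error(labels, labels, w), 0)
  expect_equal(weighted_error(1 - labels, labels, w), 1)
})

test_that("beta follows the closed form with its guard", {
  expect_equal(compute_beta(0.25), 1 / 3)
  expect_equal(log(1 / compute_beta(0.25)), log(3))
  expect_equal(compute_beta(1 / 3), 0.5)
  expect_error(compute_beta(0.5), "guard")
  expect_error(compute_beta(0), "guard")
})

test_that("weight update matches the worked example and brute force", {
  expect_equal(update_weights(rep(1 / 3, 3), 0.5, c(0, 0, 1)),
               c(0.25, 0.25, 0.5))
  # all-correct: the beta factors cancel under normalization
  w <- c(0.2, 0.3, 0.5)
  expect_equal(update_weights(w, 0.4, c(0, 0, 0)), w)
  # brute-force per-element evaluation on random triples
  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    w <- runif(n); w <- w / sum(w)
    l <- rbinom(n, 1, 0.4)
    beta <- runif(1, 0.05, 0.95)
    raw <- vapply(seq_len(n), function(j) w[j] * beta^(1 - l[j]),
                  numeric(1))
    expect_equal(update_weights(w, beta, l), raw / sum(raw),
                 tolerance = 1e-12)
    expect_equal(sum(update_weights(w, beta, l)), 1, tolerance = 1e-12)
  }
})

test_that("misclassified rows gain weight and correct rows lose it", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    w <- runif(n); w <- w / sum(w)
    l <- rbinom(n, 1, 0.5)
    if (all(l == 0) || all(l == 1)) next
    eps <- runif(1, 0.05, 0.45)
    w2 <- update_weights(w, compute_beta(eps), l)
    expect_true(all(w2[l == 1] > w[l == 1]))
    expect_true(all(w2[l == 0] < w[l == 0]))
  }
})

test_that("weighted voting matches brute-force support enumeration", {
  mk <- function(betas, votes) {
    # minimal ensemble stub exercising the voting path
    identity_rot <- structure(list(
      partition = list(continuous_cols = 1L, binary_cols = integer(0)),
      pca = list(means = 0, loadings = matrix(1, 1, 1), r = 1L),
      mca = NULL, r = 1L), class = "subset_rotation")
    slots <- lapply(seq_along(betas), function(i) {
      list(rotation = identity_rot, model = votes[i], beta = betas[i],
           vote_weight = log(1 / betas[i]),
           predict = function(model, X) rep(model, nrow(X)))
    })
    structure(list(slots = slots, fallback = 0L),
              class = "rotation_boost_ensemble")
  }
  X1 <- matrix(0, 1, 1)
  # worked case: betas (0.5, 0.5, 1/3), votes (1, 1, 0):
  # mu1 = 2 ln 2 > mu0 = ln 3 -> label 1
  ens <- mk(c(0.5, 0.5, 1 / 3), c(1L, 1L, 0L))
  expect_equal(predict_labels(ens, X1), 1L)
  expect_equal(decision_scores(ens, X1), 2 * log(2) - log(3))
  # exact tie -> 0
  ens_tie <- mk(c(0.5, 0.5), c(1L, 0L))
  expect_equal(predict_labels(ens_tie, X1), 0L)
  expect_equal(decision_scores(ens_tie, X1), 0)
  # single voter
  expect_equal(predict_labels(mk(0.4, 1L), X1), 1L)
  # random ensembles against brute-force enumeration
  set.seed(15)
  for (i in 1:25) {
    k <- sample(1:6, 1)
    betas <- runif(k, 0.05, 0.95)
    votes <- rbinom(k, 1, 0.5)
    mu1 <- sum(log(1 / betas)[votes == 1])
    mu0 <- sum(log(1 / betas)[votes == 0])
    want <- if (mu1 > mu0) 1L else 0L
    ens_i <- mk(betas, as.integer(votes))
    expect_equal(predict_labels(ens_i, X1), want)
    expect_equal(decision_scores(ens_i, X1), mu1 - mu0)
  }
})

test_that("training produces valid slots on learnable data", {
  fx <- planted_fixture(seed = 7)
  set.seed(41)
  ind <- matrix(sample.int(120, 3 * 20, replace = TRUE), 3, 20)
  ens <- train_ensemble(ind, fx$X, fx$y, seed = 11)
  expect_s3_class(ens, "rotation_boost_ensemble")
  expect_lte(length(ens$slots), 3L)
  expect_gte(length(ens$slots), 1L)
  for (slot in ens$slots) {
    expect_gt(slot$epsilon, 0)
    expect_lt(slot$epsilon, 0.5)
    expect_gt(slot$vote_weight, 0)
  }
  m <- compute_metrics(fx$y, predict_labels(ens, fx$X))
  expect_gte(m$f1, 0.9)
})

test_that("a perfect base learner trips the epsilon guard into fallback", {
  # 1-NN memorizes the training set: epsilon = 0 on every attempt, so all
  # slots are discarded and the ensemble degrades to the majority label
  one_nn <- list(
    name = "one_nn",
    fit = function(X, y) list(X = X, y = y),
    predict = function(model, X) {
      apply(X, 1, function(r) {
        model$y[which.min(colSums((t(model$X) - r)^2))]
      })
    })
  # two well-separated clusters: any bootstrap's 1-NN classifies the full
  # training set perfectly, so epsilon = 0 on every attempt
  set.seed(30)
  X <- cbind(rep(c(-5, 5), each = 10) + runif(20, -0.5, 0.5),
             runif(20, -0.5, 0.5))
  y <- rep(c(0L, 1L), each = 10)
  attr(X, "column_kinds") <- rep("continuous", 2)
  ind <- matrix(sample.int(2, 10, replace = TRUE), 1, 10)
  expect_warning(
    ens <- train_ensemble(ind, X, y, base_learner = one_nn, retries = 2,
                          seed = 3),
    "falls back")
  expect_length(ens$slots, 0)
  expect_equal(predict_labels(ens, X), rep(ens$fallback, 20))
})

test_that("scores are sign-consistent with labels and runs reproduce", {
  fx <- planted_fixture(seed = 12)
  ind <- matrix(seq_len(40), 2, 20)
  e1 <- train_ensemble(ind, fx$X, fx$y, seed = 5)
  e2 <- train_ensemble(ind, fx$X, fx$y, seed = 5)
  p1 <- predict_labels(e1, fx$X)
  expect_identical(p1, predict_labels(e2, fx$X))
  s1 <- decision_scores(e1, fx$X)
  expect_identical(s1, decision_scores(e2, fx$X))
  expect_equal(as.integer(s1 > 0), p1)
})
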