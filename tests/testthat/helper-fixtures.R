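# Shared fixtures: all built in code at test time.

# default planted fixture, normalized, with column_kinds attached
planted_fixture <- function(seed = 1L, spec = synthetic_spec(seed = seed)) {
  d <- generate_planted_dataset(spec)
  fm <- minmax_fit_apply(d$features)
  X <- fm$values
  attr(X, "column_kinds") <- fm$column_kinds
  list(X = X, y = d$labels, kinds = fm$column_kinds, blocks = fm$blocks,
       informative = d$informative, features = d$features)
}

# a fast GA config for structural tests (not the desk-scale study config)
tiny_config <- function(n_features, seed = 1L) {
  ga_config(generations = 2L, pop_size = 4L, k = 2L, subset_size = 5L,
            n_features = n_features, base_learner = base_learner_rf(15L),
            seed = seed)
}

# the desk-scale study run (default planted fixture, T=10, M=10, K=4,
# Sfs=20, fixed seed), computed once and shared between acceptance blocks
desk_scale_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- planted_fixture(seed = 1)
      cfg <- ga_config(generations = 10, pop_size = 10, k = 4,
                       subset_size = 20, n_features = 120, seed = 1)
      sp <- make_splits(nrow(fx$X), seed = 1, n_repeats = 1)[[1]]
      res <- evolve(cfg, fx$X[sp$train, ], fx$y[sp$train],
                    fx$X[sp$validation, ], fx$y[sp$validation], fx$kinds)
      cache <<- list(res = res, fx = fx)
    }
    cache
  }
})

# brute-force MCA row principal coordinates: indicator table -> relative
# frequencies -> standardized residual matrix -> SVD, written independently
# of the package implementation
bruteforce_mca_rows <- function(B, tol = 1e-10) {
  Z <- cbind(1 - B, B)
  keep <- apply(Z, 2, function(v) var(v) > 0)
  Z <- Z[, keep, drop = FALSE]
  P <- Z / sum(Z)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %*% t(cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  sel <- sv$d > tol * max(sv$d)
  # row principal coordinates F = D_r^{-1/2} U D
  sweep(sv$u[, sel, drop = FALSE], 1, sqrt(r), "/") %*%
    diag(sv$d[sel], sum(sel))
}

# brute-force AUC by all-pairs concordance counting with half credit for
# ties
bruteforce_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
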