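# Feature-subset rotation in the Rotation-Forest sense: the subset's
# continuous columns are replaced by their full-rank PCA projection and its
# binary columns by multiple correspondence analysis (MCA) row coordinates;
# the two projected parts are merged column-wise. All non-degenerate
# components are kept, so the subset is rotated, not reduced.

ROTATION_SV_TOL <- 1e-10  # singular values <= tol * largest treated as zero

#' Partition a feature subset by column kind
#'
#' Deduplicates the subset (first occurrence kept) and routes every retained
#' index to the continuous or binary part according to `column_kinds`.
#'
#' @param subset integer vector of 1-based column indices (duplicates
#'   permitted, as in GA individuals).
#' @param column_kinds character vector of `"binary"`/`"continuous"` for the
#'   full feature space.
#' @return list with integer vectors `continuous_cols` and `binary_cols`.
#' @export
partition_columns <- function(subset, column_kinds) {
  subset <- as.integer(subset)
  stopifnot(all(subset >= 1L), all(subset <= length(column_kinds)))
  subset <- subset[!duplicated(subset)]
  list(continuous_cols = subset[column_kinds[subset] == "continuous"],
       binary_cols = subset[column_kinds[subset] == "binary"])
}

# PCA keeping every component of nonzero variance. Sign convention: the
# largest-magnitude entry of each loading vector is positive.
fit_pca <- function(X) {
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)
  sv <- svd(Xc)
  keep <- sv$d > ROTATION_SV_TOL * max(sv$d, .Machine$double.eps)
  if (!any(keep)) return(NULL)
  load <- sv$v[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  list(means = means, loadings = load, r = ncol(load))
}

apply_pca <- function(fit, X) {
  sweep(X, 2, fit$means) %*% fit$loadings
}

# MCA on the complete disjunctive coding of binary features: each feature
# contributes a 0-indicator and a 1-indicator column; constant features are
# dropped. The decomposition is the SVD of the standardized residual matrix
# S = D_r^{-1/2} (P - r c^T) D_c^{-1/2} of the relative-frequency table P
# with row/column margins r, c. Row principal coordinates are stored via the
# transition formula (profile - c)^T D_c^{-1/2} V diag over retained axes,
# so unseen rows project through the stored fit without refitting.
fit_mca <- function(X) {
  X <- as.matrix(X)
  keep <- apply(X, 2, function(v) length(unique(v)) > 1L)
  if (!any(keep)) return(NULL)
  X <- X[, keep, drop = FALSE]
  q <- ncol(X)
  Z <- cbind(1 - X, X)  # 0-indicators then 1-indicators
  P <- Z / sum(Z)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  sel <- sv$d > ROTATION_SV_TOL * max(sv$d, .Machine$double.eps)
  if (!any(sel)) return(NULL)
  V <- sv$v[, sel, drop = FALSE]
  d <- sv$d[sel]
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  list(kept_features = which(keep), q = q, col_masses = cm, V = V, d = d,
       r = length(d))
}

# Row principal coordinates for any rows (fitting rows reproduce the fit).
apply_mca <- function(fit, X) {
  X <- as.matrix(X)[, fit$kept_features, drop = FALSE]
  Z <- cbind(1 - X, X)
  profiles <- Z / fit$q  # each row of Z sums to q
  centered <- sweep(profiles, 2, fit$col_masses)
  centered %*% (diag(1 / sqrt(fit$col_masses), length(fit$col_masses)) %*%
                  fit$V)
}

#' Fit a subset rotation
#'
#' Fits PCA on the centered continuous columns and MCA on the binary columns
#' of the subset, both on the supplied training rows; all components above
#' the degeneracy tolerance are kept.
#'
#' @param X numeric training matrix over the full feature space.
#' @param partition a [partition_columns()] result.
#' @return an object of class `subset_rotation` with output width
#'   `r = r_c + r_b`.
#' @export
fit_rotation <- function(X, partition) {
  stopifnot(nrow(X) >= 2)
  pca <- NULL
  mca <- NULL
  if (length(partition$continuous_cols)) {
    pca <- fit_pca(X[, partition$continuous_cols, drop = FALSE])
  }
  if (length(partition$binary_cols)) {
    mca <- fit_mca(X[, partition$binary_cols, drop = FALSE])
  }
  if (is.null(pca) && is.null(mca)) {
    stop("degenerate subset: no usable continuous or binary columns")
  }
  structure(list(partition = partition, pca = pca, mca = mca,
                 r = (if (is.null(pca)) 0L else pca$r) +
                     (if (is.null(mca)) 0L else mca$r)),
            class = "subset_rotation")
}

#' Apply a fitted subset rotation
#'
#' Projects any rows of the full feature space through the stored fit
#' (no refitting) and merges `[continuous-projected | binary-projected]`.
#'
#' @param rot a `subset_rotation`.
#' @param X numeric matrix with the full feature-space columns.
#' @return numeric matrix with `nrow(X)` rows and `rot$r` columns.
#' @export
apply_rotation <- function(rot, X) {
  parts <- list()
  if (!is.null(rot$pca)) {
    parts <- c(parts, list(apply_pca(
      rot$pca, X[, rot$partition$continuous_cols, drop = FALSE])))
  }
  if (!is.null(rot$mca)) {
    parts <- c(parts, list(apply_mca(
      rot$mca, X[, rot$partition$binary_cols, drop = FALSE])))
  }
  out <- do.call(cbind, parts)
  dimnames(out) <- NULL
  out
}
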