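# Synthetic fixture generator: mixed binary/continuous feature matrices
# with a planted informative subset and balanced binary labels, emulating
# the statistical shape of a fused fingerprint matrix; plus multi-source
# label tables with controlled agreement for exercising the curation rules.

#' Specification of a planted synthetic dataset
#'
#' The default emulates a small fused fingerprint matrix: 300 samples over
#' 120 features (80 binary + 40 continuous in two blocks), 30 informative
#' features (20 binary + 10 continuous, the first indices of each block),
#' binary effect `P(bit = 1) = 0.8 / 0.2` for the positive/negative class,
#' continuous class-mean shift 1.5 at unit variance, balanced classes.
#'
#' @param n samples.
#' @param n_binary,n_continuous features per block (binary block first).
#' @param m_binary,m_continuous informative features per block (taken from
#'   the start of each block).
#' @param p1,p0 informative-bit probabilities given class 1 / class 0.
#' @param delta class-mean shift of informative continuous features.
#' @param rho positive-class probability.
#' @param seed generator seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 300L, n_binary = 80L, n_continuous = 40L,
                           m_binary = 20L, m_continuous = 10L,
                           p1 = 0.8, p0 = 0.2, delta = 1.5, rho = 0.5,
                           seed = 1L) {
  stopifnot(p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1, rho > 0, rho < 1,
            m_binary <= n_binary, m_continuous <= n_continuous)
  structure(list(n = as.integer(n), n_binary = as.integer(n_binary),
                 n_continuous = as.integer(n_continuous),
                 m_binary = as.integer(m_binary),
                 m_continuous = as.integer(m_continuous),
                 p1 = p1, p0 = p0, delta = delta, rho = rho,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a planted-signal dataset
#'
#' Labels are Bernoulli(rho). Informative binary columns are
#' Bernoulli(p_y), non-informative ones Bernoulli(0.5); informative
#' continuous columns are Normal(delta * y, 1), non-informative ones
#' Normal(0, 1). The binary block precedes the continuous block and the
#' informative indices are returned for recovery checks.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `features` (a labeled [fused_features] with blocks
#'   `BIN` and `CONT`), `labels`, and `informative` (1-based column
#'   indices of the planted features).
#' @export
generate_planted_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    y <- stats::rbinom(n, 1L, spec$rho)
    pb <- matrix(0.5, n, spec$n_binary)
    if (spec$m_binary > 0) {
      pb[, seq_len(spec$m_binary)] <- ifelse(y == 1L, spec$p1, spec$p0)
    }
    bin <- matrix(stats::rbinom(n * spec$n_binary, 1L, as.vector(pb)),
                  n, spec$n_binary)
    mu <- matrix(0, n, spec$n_continuous)
    if (spec$m_continuous > 0) {
      mu[, seq_len(spec$m_continuous)] <- spec$delta * y
    }
    cont <- matrix(stats::rnorm(n * spec$n_continuous), n,
                   spec$n_continuous) + mu
    blocks <- data.frame(
      name = c("BIN", "CONT"), kind = c("binary", "continuous"),
      width = c(spec$n_binary, spec$n_continuous),
      offset = c(0L, spec$n_binary), stringsAsFactors = FALSE)
    fm <- fused_features(cbind(bin, cont),
                         rep(c("binary", "continuous"),
                             c(spec$n_binary, spec$n_continuous)),
                         blocks, labels = y)
    informative <- c(seq_len(spec$m_binary),
                     spec$n_binary + seq_len(spec$m_continuous))
    list(features = fm, labels = y, informative = informative)
  })
}

#' Generate a multi-source label table with controlled agreement
#'
#' Builds a table of synthetic compound identifiers observed by several
#' sources with a prescribed per-compound agreement fraction, so each
#' curation branch (priority override, consensus keep, below-threshold
#' drop) can be exercised at known counts. For each compound a true label
#' is drawn and `round(agreement * n_sources)` sources report it; the
#' remaining sources report the flipped label.
#'
#' @param n_compounds number of compounds.
#' @param n_sources number of sources (at least 2), named `"src1"`...
#' @param agreement agreement fraction in `[0.5, 1]`, recycled per
#'   compound.
#' @param priority_compounds optional integer indices of compounds that
#'   additionally appear in a source named `"priority"` with the flipped
#'   label (to exercise the override rule).
#' @param seed generator seed.
#' @return data frame with columns `canonical_smiles`, `source`, `label`,
#'   plus attribute `true_labels`.
#' @export
generate_multisource_labels <- function(n_compounds, n_sources = 5L,
                                        agreement = 1.0,
                                        priority_compounds = integer(0),
                                        seed = 1L) {
  stopifnot(n_sources >= 2)
  agreement <- rep_len(agreement, n_compounds)
  with_seed(seed, {
    rows <- list()
    true <- stats::rbinom(n_compounds, 1L, 0.5)
    for (i in seq_len(n_compounds)) {
      id <- sprintf("CMP%04d", i)
      n_agree <- round(agreement[i] * n_sources)
      labs <- c(rep(true[i], n_agree), rep(1L - true[i],
                                           n_sources - n_agree))
      rows[[length(rows) + 1L]] <- data.frame(
        canonical_smiles = id, source = paste0("src", seq_len(n_sources)),
        label = labs, stringsAsFactors = FALSE)
      if (i %in% priority_compounds) {
        rows[[length(rows) + 1L]] <- data.frame(
          canonical_smiles = id, source = "priority",
          label = 1L - true[i], stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "true_labels") <- true
    out
  })
}
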