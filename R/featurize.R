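# Fused fingerprint computation: splice the enabled fingerprint blocks,
# in the fixed order ECFP2, MACCS, RDKIT2D, PUBCHEM, into one fused feature
# matrix with per-column kind and block provenance.

REGA_BLOCKS <- data.frame(
  name = c("ECFP2", "MACCS", "RDKIT2D", "PUBCHEM"),
  kind = c("binary", "binary", "continuous", "binary"),
  width = c(2048L, 167L, 200L, 881L),
  stringsAsFactors = FALSE)

#' Fused molecular fingerprint matrix
#'
#' Computes the enabled fingerprint blocks for each molecule and splices them
#' column-wise into a [fused_features] matrix. Blocks are always laid out in
#' the fixed order ECFP2 (2048-bit circular fingerprint, radius 1), MACCS
#' (167 structural key positions), RDKIT2D (pinned 200-descriptor continuous
#' 2D set) and PUBCHEM (881 substructure key positions), restricted to
#' `blocks`. With all four blocks the fused width is 3296.
#'
#' @param smiles character vector of SMILES; every entry must be parseable
#'   (unparseable input is a hard error naming the offending row).
#' @param blocks subset of `c("ECFP2", "MACCS", "RDKIT2D", "PUBCHEM")`
#'   (case-insensitive).
#' @param labels optional 0/1 class labels attached to the matrix.
#' @return a [fused_features] object with `column_kinds` marking RDKIT2D
#'   columns continuous and all fingerprint bits binary.
#' @export
compute_fused_fingerprints <- function(smiles,
                                       blocks = c("ECFP2", "MACCS",
                                                  "RDKIT2D", "PUBCHEM"),
                                       labels = NULL) {
  stopifnot(length(smiles) > 0, length(blocks) > 0)
  blocks <- toupper(blocks)
  unknown <- setdiff(blocks, REGA_BLOCKS$name)
  if (length(unknown)) stop("unknown block(s): ", paste(unknown, collapse = ", "))
  enabled <- REGA_BLOCKS[REGA_BLOCKS$name %in% blocks, , drop = FALSE]
  for (i in seq_along(smiles)) {
    if (is.null(mol_graph(smiles[i]))) {
      stop("unparseable SMILES at row ", i, ": ", smiles[i])
    }
  }
  parts <- lapply(enabled$name, function(b) {
    switch(b,
           ECFP2 = fp_ecfp2(smiles),
           MACCS = fp_maccs(smiles),
           RDKIT2D = fp_rdkit2d(smiles),
           PUBCHEM = fp_pubchem(smiles))
  })
  values <- do.call(cbind, parts)
  dimnames(values) <- NULL
  kinds <- rep(ifelse(enabled$kind == "continuous", "continuous", "binary"),
               enabled$width)
  enabled$offset <- cumsum(c(0L, enabled$width[-nrow(enabled)]))
  fused_features(values, kinds, enabled, labels)
}
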