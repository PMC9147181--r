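# PubChem-style 881-position substructure key block. The layout follows the
# public CACTVS key organisation: bits 0-114 are hierarchic element counts,
# bits 115-262 are ESSSR ring counts stratified by ring size, saturation /
# aromaticity and element content, and bits 263-326 are simple bonded
# element pairs. The key definitions for these sections ship as versioned
# data files under extdata. Keys 327-880 (atom-environment and detailed
# SMARTS sections) are not evaluated in key-table v1 and are reported as 0;
# the block width is fixed at 881 regardless, so column offsets of fused
# matrices never depend on key-table coverage.

pubchem_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ec <- utils::read.delim(system.file("extdata",
        "pubchem_element_counts_v1.tsv", package = "rega"))
      ap <- utils::read.delim(system.file("extdata",
        "pubchem_atom_pairs_v1.tsv", package = "rega"))
      cache <<- list(element_counts = ec, atom_pairs = ap)
    }
    cache
  }
})

# ring-count section layout: (size, min_count) combinations, 7 category bits
# each, starting at bit 115
pubchem_ring_layout <- function() {
  combos <- rbind(
    cbind(3, 1:2), cbind(4, 1:2), cbind(5, 1:5), cbind(6, 1:5),
    cbind(7, 1:2), cbind(8, 1:2), cbind(9, 1), cbind(10, 1))
  data.frame(size = combos[, 1], min_count = combos[, 2],
             bit = 115L + (seq_len(nrow(combos)) - 1L) * 7L)
}

pubchem_keys_one <- function(g) {
  bits <- integer(881L)
  tabs <- pubchem_tables()
  el <- g$elements
  nH <- sum(g$implicit_h) + sum(el == "H")
  counts <- table(el)
  # section 1: element counts
  ec <- tabs$element_counts
  for (i in seq_len(nrow(ec))) {
    e <- ec$element[i]
    cnt <- if (e == "H") nH else if (e %in% names(counts)) counts[[e]] else 0
    if (cnt >= ec$min_count[i]) bits[ec$bit[i] + 1L] <- 1L
  }
  # section 2: ring counts
  rg <- g$rings
  layout <- pubchem_ring_layout()
  satarom <- rg$saturated | rg$aromatic
  for (i in seq_len(nrow(layout))) {
    s <- layout$size[i]; m <- layout$min_count[i]; b <- layout$bit[i]
    ofs <- if (s == 10) rg$size >= 10 else rg$size == s
    cat7 <- c(sum(ofs),
              sum(ofs & satarom & rg$carbon_only),
              sum(ofs & satarom & rg$has_n),
              sum(ofs & satarom & rg$has_hetero),
              sum(ofs & !satarom & rg$carbon_only),
              sum(ofs & !satarom & rg$has_n),
              sum(ofs & !satarom & rg$has_hetero))
    bits[b + which(cat7 >= m)] <- 1L
  }
  n_arom <- sum(rg$aromatic)
  n_het_arom <- sum(rg$aromatic & rg$has_hetero)
  for (m in 1:4) {
    if (n_arom >= m) bits[255L + (m - 1L) + 1L] <- 1L
    if (n_het_arom >= m) bits[259L + (m - 1L) + 1L] <- 1L
  }
  # section 3: bonded element pairs (X-H pairs use implicit hydrogens)
  ap <- tabs$atom_pairs
  bonded <- unique(c(paste(el[g$bonds$from], el[g$bonds$to]),
                     paste(el[g$bonds$to], el[g$bonds$from])))
  with_h <- unique(el[g$implicit_h > 0])
  for (i in seq_len(nrow(ap))) {
    e1 <- ap$elem1[i]; e2 <- ap$elem2[i]
    present <- if (e2 == "H") {
      e1 %in% with_h || paste(e1, "H") %in% bonded
    } else {
      paste(e1, e2) %in% bonded
    }
    if (present) bits[ap$bit[i] + 1L] <- 1L
  }
  bits
}

#' PubChem-style 881-position substructure keys
#'
#' Evaluates the v1 key table (element counts, ring counts, bonded element
#' pairs) for each molecule; see the package vignette for the coverage of
#' the key table. Bit-for-bit parity with the original CACTVS engine is not
#' promised; the block width is fixed at 881.
#'
#' @param smiles character vector of SMILES.
#' @return integer matrix, one row per molecule, 881 0/1 columns.
#' @export
fp_pubchem <- function(smiles) {
  out <- matrix(0L, length(smiles), 881L)
  for (i in seq_along(smiles)) {
    g <- mol_graph(smiles[i])
    if (is.null(g)) stop("PUBCHEM: cannot process SMILES (row ", i, "): ",
                         smiles[i])
    out[i, ] <- pubchem_keys_one(g)
  }
  out
}
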