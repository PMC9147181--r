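# Bit-vector fingerprint blocks computed through the OpenBabel command-line
# tool: 2048-bit circular (ECFP2, radius 1) fingerprints and the 167-position
# MACCS structural key set. OpenBabel's hex dump prints 32-bit words from the
# most significant word down; container bit b corresponds to MACCS key b + 1
# (verified against an independent MACCS implementation in the tests).

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("the 'obabel' command-line tool is required for ECFP2/MACCS blocks ",
         "but was not found on PATH")
  }
  p
}

# Run obabel's fingerprint output for one molecule; returns a 0/1 vector of
# length nbits, or NULL when the molecule cannot be processed.
ob_fingerprint_one <- function(smiles, fptype, nbits, fold_bits = NULL) {
  smi_file <- tempfile(fileext = ".smi")
  on.exit(unlink(smi_file))
  writeLines(smiles, smi_file)
  args <- c(smi_file, "-ofpt", paste0("-xf", fptype))
  if (!is.null(fold_bits)) args <- c(args, "-xN", fold_bits)
  out <- suppressWarnings(
    system2(obabel_path(), args, stdout = TRUE, stderr = FALSE))
  hex <- grep("^[0-9a-f ]+$", out, value = TRUE)
  words <- unlist(strsplit(trimws(hex), "\\s+"))
  words <- words[grepl("^[0-9a-f]{8}$", words)]
  if (!length(words)) {
    # a molecule with zero bits set still prints all-zero words; no words at
    # all means obabel failed on this input
    if (!any(grepl("bits set", out))) return(NULL)
  }
  parse_fpt_hex(words, nbits)
}

#' 2048-bit circular fingerprint of diameter 2 (ECFP2)
#'
#' Extended-connectivity fingerprint with radius 1, hashed and folded to
#' 2048 bits.
#'
#' @param smiles character vector of SMILES.
#' @return integer matrix, one row per molecule, 2048 0/1 columns.
#' @export
fp_ecfp2 <- function(smiles) {
  out <- matrix(0L, length(smiles), 2048L)
  for (i in seq_along(smiles)) {
    bits <- ob_fingerprint_one(smiles[i], "ECFP2", 2048L, fold_bits = 2048L)
    if (is.null(bits)) stop("ECFP2: cannot process SMILES (row ", i, "): ",
                            smiles[i])
    out[i, ] <- bits
  }
  out
}

#' 167-position MACCS structural keys
#'
#' Standard MACCS key set laid out on 167 positions: position j holds key j
#' for j = 1..166 and position 0 is the conventional unused padding bit.
#'
#' @param smiles character vector of SMILES.
#' @return integer matrix, one row per molecule, 167 0/1 columns.
#' @export
fp_maccs <- function(smiles) {
  out <- matrix(0L, length(smiles), 167L)
  for (i in seq_along(smiles)) {
    bits <- ob_fingerprint_one(smiles[i], "MACCS", 256L)
    if (is.null(bits)) stop("MACCS: cannot process SMILES (row ", i, "): ",
                            smiles[i])
    # container bit b (0-based) = key b + 1 = block position b + 1
    out[i, 2:167] <- bits[1:166]
  }
  out
}
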