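# Internal helpers: deterministic seed streams, obabel output parsing, logging.

#' Derive a reproducible sub-seed from a master seed
#'
#' Hashes the master seed together with an arbitrary sequence of integer or
#' character tags into a seed in `[1, 2^31 - 2]`. Used so that every source of
#' randomness (population init, per-generation genetic operators, per-slot
#' bootstraps, data splits) gets its own named stream derived from one master
#' seed, and evaluation order cannot change results.
#'
#' @param master integer master seed.
#' @param ... integer or character tags naming the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  tags <- list(...)
  # 64-bit-safe multiplicative hash carried in doubles (exact below 2^53)
  h <- (as.numeric(master) %% 2147483647) + 1
  for (tag in tags) {
    if (is.character(tag)) {
      codes <- utf8ToInt(paste(tag, collapse = "\r"))
    } else {
      codes <- as.numeric(tag)
    }
    for (v in codes) {
      h <- (h * 48271 + (v %% 2147483647) + 1) %% 2147483647
    }
    h <- (h * 16807 + 17) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# Parse openbabel's fpt hex dump into a 0/1 integer vector of length nbits.
# obabel prints 32-bit words most-significant word first; within a word the
# least-significant bit is bit 0. Bit b of the container is key (b + 1) in the
# 1-based key numbering used by the MACCS dictionary (calibrated against an
# independent MACCS implementation; see package tests).
parse_fpt_hex <- function(words, nbits) {
  words <- words[nzchar(words)]
  nwords <- length(words)
  bits <- integer(nwords * 32L)
  for (i in seq_len(nwords)) {
    val <- strtoi(substr(words[i], 1L, 4L), base = 16L) * 65536 +
      strtoi(substr(words[i], 5L, 8L), base = 16L)
    base <- (nwords - i) * 32L
    j <- 0L
    while (val > 0) {
      if (val %% 2 == 1) bits[base + j + 1L] <- 1L
      val <- val %/% 2
      j <- j + 1L
    }
  }
  length(bits) <- max(length(bits), nbits)
  bits[is.na(bits)] <- 0L
  bits[seq_len(nbits)]
}

rega_warn <- function(...) warning(..., call. = FALSE)

rega_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}

# stable order(): ties keep original position (base order is stable for a
# single key only when method = "radix" isn't needed; make it explicit)
order_stable_desc <- function(x) order(-x, seq_along(x))
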