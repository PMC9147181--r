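# Multi-source label curation: canonicalize SMILES, drop metals/rare
# elements and duplicates, then resolve conflicting labels across sources by
# priority override and an 80% consensus vote.

#' Default allowed-element set
#'
#' Organic-subset elements retained during curation; molecules containing any
#' other element (all metals, rare elements) are removed.
#' @export
REGA_ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                           "Cl", "Se", "Br", "I")

# Canonicalize one SMILES via OpenBabel; returns NA when unparseable,
# otherwise list(canonical=, elements=).
canonicalize_smiles <- function(smiles) {
  out <- try(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))),
    silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  can <- strsplit(trimws(out), "\t", fixed = TRUE)[[1]][1]
  if (is.na(can) || !nzchar(can)) return(NULL)
  txt <- try(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))),
    silent = TRUE)
  if (inherits(txt, "try-error")) return(NULL)
  ctab <- parse_ctab(txt)
  if (is.null(ctab)) return(NULL)
  list(canonical = can, elements = unique(ctab$elements))
}

#' Canonicalize molecule records, removing metals and duplicates
#'
#' Each input SMILES is converted to a single canonical form; records whose
#' molecule contains an element outside `allowed_elements` (by default all
#' metals and rare elements are excluded) are removed, as are exact duplicates
#' within a source (two SMILES spellings of the same structure collapse to one
#' record). Unparseable SMILES are dropped with a warning rather than raising
#' an error, so one corrupt row does not abort a curation run.
#'
#' @param records data frame with columns `smiles`, optional `label`
#'   (0/1/NA) and optional `source` (defaults to `"unknown"`).
#' @param allowed_elements character vector of permitted element symbols.
#'   Hydrogen is always permitted implicitly.
#' @return data frame with columns `raw_smiles`, `canonical_smiles`, `label`,
#'   `source`; one row per (source, canonical structure).
#' @export
canonicalize_and_dedupe <- function(records,
                                    allowed_elements = REGA_ALLOWED_ELEMENTS) {
  records <- as.data.frame(records)
  stopifnot("smiles" %in% names(records))
  if (!"label" %in% names(records)) records$label <- NA_integer_
  if (!"source" %in% names(records)) records$source <- "unknown"
  stopifnot(all(nzchar(records$smiles)))
  allowed <- union(allowed_elements, "H")
  keep <- logical(nrow(records))
  canonical <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    res <- canonicalize_smiles(records$smiles[i])
    if (is.null(res)) {
      rega_warn("dropping unparseable SMILES (row ", i, "): ",
                records$smiles[i])
      next
    }
    if (!all(res$elements %in% allowed)) {
      next  # metal / disallowed element
    }
    keep[i] <- TRUE
    canonical[i] <- res$canonical
  }
  out <- data.frame(raw_smiles = records$smiles[keep],
                    canonical_smiles = canonical[keep],
                    label = as.integer(records$label[keep]),
                    source = as.character(records$source[keep]),
                    stringsAsFactors = FALSE)
  # within each source keep one record per canonical structure
  out[!duplicated(out[, c("source", "canonical_smiles")]), , drop = FALSE]
}

#' Resolve conflicting labels across sources
#'
#' Implements the two-stage curation rule: a compound appearing in any
#' priority source takes that source's label (highest-priority first) and all
#' other rows for it are ignored; otherwise the majority label is kept iff
#' its agreement fraction is at least `consensus` (or all sources agree), and
#' the compound is dropped when agreement is below the threshold. Two priority
#' sources of the same rank that disagree also drop the compound (logged).
#'
#' @param table data frame with columns `canonical_smiles`, `source`, `label`.
#' @param priority_sources character vector of source ids in decreasing
#'   priority order.
#' @param consensus minimum agreement fraction among non-priority sources
#'   (default 0.8).
#' @return data frame with columns `canonical_smiles`, `label`, one row per
#'   surviving compound (input order of first appearance preserved).
#' @export
resolve_labels <- function(table, priority_sources = character(),
                           consensus = 0.8) {
  table <- as.data.frame(table)
  stopifnot(nrow(table) > 0,
            all(c("canonical_smiles", "source", "label") %in% names(table)))
  # drop exact duplicate rows only; a source reporting both labels for one
  # compound is a genuine conflict and must surface, not be collapsed
  table <- table[!duplicated(table[, c("canonical_smiles", "source",
                                       "label")]), , drop = FALSE]
  compounds <- unique(table$canonical_smiles)
  res_smiles <- character(0)
  res_label <- integer(0)
  for (cmp in compounds) {
    rows <- table[table$canonical_smiles == cmp, , drop = FALSE]
    prio_rank <- match(rows$source, priority_sources)
    if (any(!is.na(prio_rank))) {
      best <- min(prio_rank, na.rm = TRUE)
      labs <- unique(rows$label[!is.na(prio_rank) & prio_rank == best])
      if (length(labs) > 1L) {
        rega_warn("dropping compound with conflicting labels at priority ",
                  "rank ", best, ": ", cmp)
        next
      }
      res_smiles <- c(res_smiles, cmp)
      res_label <- c(res_label, as.integer(labs))
      next
    }
    tab <- table(rows$label)
    frac <- max(tab) / sum(tab)
    if (length(tab) == 1L || frac >= consensus) {
      maj <- as.integer(names(tab)[which.max(tab)])
      res_smiles <- c(res_smiles, cmp)
      res_label <- c(res_label, maj)
    }
    # else: agreement below threshold -> compound dropped
  }
  data.frame(canonical_smiles = res_smiles, label = res_label,
             stringsAsFactors = FALSE)
}
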