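# The fused feature matrix container: a numeric matrix plus per-column kind
# (binary / continuous), block provenance, optional labels, and normalization
# state. All downstream stages (rotation, boosting, GA, evaluation) consume
# this container.

#' Construct a fused feature matrix
#'
#' @param values numeric matrix, samples in rows.
#' @param column_kinds character vector, one of `"binary"`/`"continuous"` per
#'   column.
#' @param blocks data frame with columns `name`, `kind`, `width`, `offset`
#'   (0-based column index of block start). Blocks must tile the columns
#'   without gaps or overlap. If `NULL`, a single block named `"USER"` is
#'   created spanning all columns.
#' @param labels optional integer vector of 0/1 class labels.
#' @return an object of class `fused_features`.
#' @export
fused_features <- function(values, column_kinds, blocks = NULL, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sf <- ncol(values)
  column_kinds <- as.character(column_kinds)
  stopifnot(length(column_kinds) == sf)
  if (!all(column_kinds %in% c("binary", "continuous"))) {
    stop("column_kinds must be 'binary' or 'continuous'")
  }
  if (is.null(blocks)) {
    kind <- if (all(column_kinds == "binary")) "binary"
            else if (all(column_kinds == "continuous")) "continuous"
            else "mixed"
    blocks <- data.frame(name = "USER", kind = kind, width = sf, offset = 0L,
                         stringsAsFactors = FALSE)
  }
  blocks <- as.data.frame(blocks)
  blocks$width <- as.integer(blocks$width)
  blocks$offset <- as.integer(blocks$offset)
  if (sum(blocks$width) != sf) {
    stop("block widths (", sum(blocks$width), ") do not tile the ", sf,
         " columns")
  }
  expected_off <- cumsum(c(0L, blocks$width[-nrow(blocks)]))
  if (!identical(as.integer(blocks$offset), as.integer(expected_off))) {
    stop("block offsets must tile the column range without gaps or overlap")
  }
  bin <- column_kinds == "binary"
  if (any(bin)) {
    vals <- values[, bin, drop = FALSE]
    if (!all(vals %in% c(0, 1))) {
      bad <- which(apply(values, 2, function(v) !all(v %in% c(0, 1))) & bin)
      stop("declared binary column(s) contain values outside {0,1}: ",
           paste(bad, collapse = ", "))
    }
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    stopifnot(length(labels) == nrow(values), all(labels %in% c(0L, 1L)))
  }
  structure(
    list(values = values, column_kinds = column_kinds, blocks = blocks,
         labels = labels,
         normalization = list(state = "raw", mins = NULL, maxs = NULL)),
    class = "fused_features")
}

#' @export
print.fused_features <- function(x, ...) {
  cat("fused_features: ", nrow(x$values), " samples x ", ncol(x$values),
      " features (", sum(x$column_kinds == "binary"), " binary, ",
      sum(x$column_kinds == "continuous"), " continuous), ",
      x$normalization$state, "\n", sep = "")
  for (i in seq_len(nrow(x$blocks))) {
    cat(sprintf("  block %-8s %-10s width %5d offset %5d\n",
                x$blocks$name[i], x$blocks$kind[i], x$blocks$width[i],
                x$blocks$offset[i]))
  }
  if (!is.null(x$labels)) {
    cat("  labels: ", sum(x$labels == 1L), " positive / ",
        sum(x$labels == 0L), " negative\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.fused_features <- function(x) dim(x$values)

#' Min-max normalization fit on a row subset
#'
#' Rescales every column to `x' = (x - min x) / (max x - min x)` with the
#' per-column minimum and maximum computed on `fit_rows` only (typically the
#' training split, so no information leaks from validation/test rows).
#' Constant columns map to 0; values falling outside `[0, 1]` on non-fit rows
#' are clipped.
#'
#' @param fm a [fused_features] object with `normalization$state == "raw"`.
#' @param fit_rows integer row indices to fit the per-column min/max on.
#' @return the normalized `fused_features` object, with the fitted mins/maxs
#'   stored in `normalization`.
#' @export
minmax_fit_apply <- function(fm, fit_rows = seq_len(nrow(fm$values))) {
  stopifnot(inherits(fm, "fused_features"))
  if (fm$normalization$state != "raw") {
    stop("matrix is already normalized")
  }
  fit_rows <- as.integer(fit_rows)
  if (length(fit_rows) == 0L) stop("fit_rows must be nonempty")
  sub <- fm$values[fit_rows, , drop = FALSE]
  mins <- apply(sub, 2, min)
  maxs <- apply(sub, 2, max)
  rng <- maxs - mins
  out <- sweep(fm$values, 2, mins, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out[which(out < 0)] <- 0  # which() drops NA so sentinel rows pass through
  out[which(out > 1)] <- 1
  fm$values <- out
  fm$normalization <- list(state = "normalized", mins = mins, maxs = maxs)
  fm
}

#' Load a pre-computed feature table as a fused matrix
#'
#' Entry point for externally computed descriptor sets (e.g. Mold2 or PaDEL
#' tables): a rectangular numeric CSV plus a declaration of each column's
#' kind. The result is a single user-defined block.
#'
#' @param path CSV file with an optional header row; all cells numeric.
#' @param kinds either a character vector (length = number of columns) of
#'   `"binary"`/`"continuous"`, or the path to a sidecar text file holding one
#'   kind per line.
#' @param name block name for the loaded table.
#' @return a [fused_features] object.
#' @export
load_feature_table <- function(path, kinds, name = "USER") {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (nrow(tab) == 0L || ncol(tab) == 0L) stop("empty feature table: ", path)
  if (length(kinds) == 1L && file.exists(kinds)) {
    kinds <- trimws(readLines(kinds))
    kinds <- kinds[nzchar(kinds)]
  }
  if (length(kinds) != ncol(tab)) {
    stop("kinds length (", length(kinds), ") does not match column count (",
         ncol(tab), ")")
  }
  values <- as.matrix(tab)
  if (!is.numeric(values)) stop("feature table must be numeric: ", path)
  blocks <- data.frame(
    name = name,
    kind = if (all(kinds == "binary")) "binary"
           else if (all(kinds == "continuous")) "continuous" else "mixed",
    width = ncol(values), offset = 0L, stringsAsFactors = FALSE)
  fused_features(values, kinds, blocks)
}

#' Write a fused feature matrix to CSV plus a metadata sidecar
#'
#' The CSV holds the numeric values with `blockname_index` headers; the
#' sidecar (plain text, `<path>.meta`) records block specs, column kinds and
#' any fitted normalization min/max so the matrix round-trips exactly.
#'
#' @param fm a [fused_features] object.
#' @param path output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "fused_features"))
  hdr <- unlist(lapply(seq_len(nrow(fm$blocks)), function(i) {
    paste0(fm$blocks$name[i], "_", seq_len(fm$blocks$width[i]) - 1L)
  }))
  vals <- fm$values
  colnames(vals) <- hdr
  utils::write.csv(vals, path, row.names = FALSE)
  meta <- c(
    paste0("state\t", fm$normalization$state),
    paste0("block\t", fm$blocks$name, "\t", fm$blocks$kind, "\t",
           fm$blocks$width, "\t", fm$blocks$offset),
    paste0("kinds\t", paste(fm$column_kinds, collapse = ",")))
  if (!is.null(fm$labels)) {
    meta <- c(meta, paste0("labels\t", paste(fm$labels, collapse = ",")))
  }
  if (fm$normalization$state == "normalized") {
    meta <- c(meta,
              paste0("mins\t", paste(fm$normalization$mins, collapse = ",")),
              paste0("maxs\t", paste(fm$normalization$maxs, collapse = ",")))
  }
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path (the `<path>.meta` sidecar must exist alongside).
#' @return a [fused_features] object.
#' @export
read_feature_matrix <- function(path) {
  vals <- as.matrix(utils::read.csv(path, header = TRUE, check.names = FALSE))
  meta <- strsplit(readLines(paste0(path, ".meta")), "\t", fixed = TRUE)
  key <- vapply(meta, `[`, "", 1L)
  blocks <- do.call(rbind, lapply(meta[key == "block"], function(m) {
    data.frame(name = m[2], kind = m[3], width = as.integer(m[4]),
               offset = as.integer(m[5]), stringsAsFactors = FALSE)
  }))
  kinds <- strsplit(meta[[which(key == "kinds")]][2], ",", fixed = TRUE)[[1]]
  labels <- if (any(key == "labels")) {
    as.integer(strsplit(meta[[which(key == "labels")]][2], ",")[[1]])
  }
  state <- meta[[which(key == "state")]][2]
  if (state == "normalized") {
    # binary columns may hold normalized values; bypass the raw-domain check
    fm <- fused_features(matrix(0, nrow(vals), ncol(vals)), kinds, blocks,
                         labels)
    fm$values <- vals
    fm$normalization <- list(
      state = "normalized",
      mins = as.numeric(strsplit(meta[[which(key == "mins")]][2], ",")[[1]]),
      maxs = as.numeric(strsplit(meta[[which(key == "maxs")]][2], ",")[[1]]))
  } else {
    fm <- fused_features(vals, kinds, blocks, labels)
  }
  dimnames(fm$values) <- NULL
  fm
}

#' Restrict a fused matrix to a subset of its blocks
#'
#' @param fm a [fused_features] object.
#' @param block_names character vector of block names to keep, or `"all"`.
#' @return a [fused_features] object containing only the requested blocks.
#' @export
subset_blocks <- function(fm, block_names) {
  stopifnot(inherits(fm, "fused_features"))
  if (identical(block_names, "all")) return(fm)
  unknown <- setdiff(block_names, fm$blocks$name)
  if (length(unknown)) stop("unknown block name(s): ",
                            paste(unknown, collapse = ", "))
  keep <- fm$blocks[fm$blocks$name %in% block_names, , drop = FALSE]
  cols <- unlist(lapply(seq_len(nrow(keep)), function(i) {
    keep$offset[i] + seq_len(keep$width[i])
  }))
  keep$offset <- cumsum(c(0L, keep$width[-nrow(keep)]))
  out <- fm
  out$values <- fm$values[, cols, drop = FALSE]
  out$column_kinds <- fm$column_kinds[cols]
  out$blocks <- keep
  if (!is.null(fm$normalization$mins)) {
    out$normalization$mins <- fm$normalization$mins[cols]
    out$normalization$maxs <- fm$normalization$maxs[cols]
  }
  out
}
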