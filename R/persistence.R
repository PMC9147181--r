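# Model persistence: one self-contained file bundling the config echo, the
# fitted subset rotations, base-learner states and vote weights.

#' Save a trained ensemble to a model file
#'
#' @param ensemble a `rotation_boost_ensemble`.
#' @param path output file.
#' @param config optional config echoed into the file for provenance.
#' @export
save_ensemble <- function(ensemble, path, config = NULL) {
  stopifnot(inherits(ensemble, "rotation_boost_ensemble"))
  saveRDS(list(format = "rega_ensemble_v1", ensemble = ensemble,
               config = config), path)
  invisible(path)
}

#' Load an ensemble saved by [save_ensemble()]
#'
#' @param path model file.
#' @return the `rotation_boost_ensemble`.
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rega_ensemble_v1")) {
    stop("not a rega ensemble model file: ", path)
  }
  obj$ensemble
}
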