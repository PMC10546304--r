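#' Save a fusion model checkpoint
#'
#' Serializes the model with a self-describing header (format version,
#' package version, architecture settings) so checkpoints remain
#' loadable across package revisions.
#'
#' @param model A \linkS4class{FusionModel}.
#' @param path Output file path (.rds).
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "FusionModel"))
  obj <- list(format = "cystfuse-checkpoint",
              formatVersion = 1L,
              packageVersion = as.character(utils::packageVersion("cystfuse")),
              method = model@method, backbone = model@backbone,
              D = model@D, La = model@La, hidden = model@hidden,
              seed = model@seed, config = model@config,
              weights = model@weights)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a fusion model checkpoint
#'
#' @param path Path written by \code{\link{saveModel}}.
#' @return A \linkS4class{FusionModel}.
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$format, "cystfuse-checkpoint")) {
    stop("not a cystfuse checkpoint: ", path, call. = FALSE)
  }
  if (obj$formatVersion > 1L) {
    stop("checkpoint format version ", obj$formatVersion,
         " is newer than this package understands", call. = FALSE)
  }
  new("FusionModel", method = obj$method, backbone = obj$backbone,
      D = obj$D, La = obj$La, hidden = obj$hidden, weights = obj$weights,
      config = obj$config, seed = obj$seed)
}
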