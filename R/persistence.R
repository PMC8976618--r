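# Model archives: one file per model, with a format-version tag and
# structural validation (orthonormality) on read.

.ARCHIVE_VERSION <- 1L

#' Save / load a fitted model archive
#'
#' Serializes a \code{PCAModel}, \code{WaveletPCAModel}, \code{ICAModel} or
#' \code{SubpatternModel} to a single archive file with a format-version tag.
#' \code{readGelModel} re-validates the object (including basis/unmixing
#' orthonormality) before returning it.
#'
#' @param model the fitted model.
#' @param path archive file path.
#' @return \code{readGelModel}: the validated model object.
#' @export
saveGelModel <- function(model, path) {
  stopIfNot(is(model, "PCAModel") || is(model, "ICAModel") ||
              is(model, "SubpatternModel"), "unsupported model type")
  saveRDS(list(format_version = .ARCHIVE_VERSION,
               class = class(model), model = model), path)
  invisible(path)
}

#' @rdname saveGelModel
#' @export
readGelModel <- function(path) {
  stopIfNot(file.exists(path), paste0("archive not found: ", path))
  arch <- readRDS(path)
  stopIfNot(is.list(arch) && identical(arch$format_version, .ARCHIVE_VERSION),
            "unrecognized model archive format")
  model <- arch$model
  validObject(model)            # re-checks orthonormality/weight invariants
  model
}
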