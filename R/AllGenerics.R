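#' @rdname GelImageSet
#' @param x,object a \code{GelImageSet} or model object.
#' @export
setGeneric("imageDim", function(x) standardGeneric("imageDim"))

#' @rdname GelImageSet
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname GelImageSet
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GelImageSet
#' @param i sample index (integer or id string).
#' @export
setGeneric("getImage", function(x, i) standardGeneric("getImage"))

#' Project samples into a fitted feature space
#'
#' Maps images (or already-vectorized pixel data) to feature coordinates under
#' a fitted \code{PCAModel}, \code{WaveletPCAModel} or \code{ICAModel}.
#'
#' @param model a fitted model object.
#' @param x a \code{GelImageSet}, a single image matrix, or a numeric vector
#'   of vectorized pixels.
#' @param ... passed to methods.
#' @return a feature matrix (features x samples), or a vector for one sample.
#' @export
setGeneric("projectFeatures", function(model, x, ...) standardGeneric("projectFeatures"))

#' @rdname SubpatternModel
#' @param object a \code{SubpatternModel}.
#' @export
setGeneric("blockWeights", function(object) standardGeneric("blockWeights"))

#' @rdname ICAModel
#' @param object a fitted model.
#' @export
setGeneric("convergenceInfo", function(object) standardGeneric("convergenceInfo"))

#' @rdname ExperimentResult
#' @param object an \code{ExperimentResult}.
#' @export
setGeneric("meanRates", function(object) standardGeneric("meanRates"))

#' @rdname ExperimentResult
#' @export
setGeneric("rawRates", function(object) standardGeneric("rawRates"))
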