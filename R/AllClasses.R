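#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# ---------------------------------------------------------------- GelImageSet

#' GelImageSet: a labeled set of same-sized grayscale images
#'
#' Extends \linkS4class{SummarizedExperiment}: the single assay
#' \code{"pixels"} holds one row-major vectorized image per column (values in
#' [0,1]), \code{colData} carries the class label and sample id, and the
#' original image geometry is kept in the \code{imageDim} slot. Standard
#' \code{[} column subsetting therefore subsets samples.
#'
#' @param images list of numeric matrices, all the same size, values in [0,1].
#' @param labels character vector of class labels, one per image.
#' @param ids optional character vector of unique sample names.
#' @return a \code{GelImageSet}.
#' @examples
#' imgs <- replicate(4, matrix(runif(16 * 16), 16, 16), simplify = FALSE)
#' gs <- GelImageSet(imgs, labels = rep(c("a", "b"), each = 2))
#' imageDim(gs); classLabels(gs)
#' @aliases imageDim classLabels sampleIds getImage
#' @export
setClass("GelImageSet",
  contains = "SummarizedExperiment",
  representation(imageDim = "integer")
)

setValidity("GelImageSet", function(object) {
  msg <- character()
  if (!"pixels" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'pixels' is required")
  d <- object@imageDim
  if (length(d) != 2L || any(d < 2L))
    msg <- c(msg, "imageDim must be two integers >= 2")
  else if (prod(d) != nrow(object))
    msg <- c(msg, "prod(imageDim) must equal nrow (vectorized pixel count)")
  px <- SummarizedExperiment::assay(object, "pixels")
  if (length(px) && (!all(is.finite(px)) || min(px) < 0 || max(px) > 1))
    msg <- c(msg, "pixel values must be finite and within [0,1]")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain 'label'")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname GelImageSet-class
#' @export
GelImageSet <- function(images, labels, ids = NULL) {
  stopIfNot(is.list(images) && length(images) >= 1L, "'images' must be a non-empty list")
  dims <- unique(lapply(images, dim))
  stopIfNot(length(dims) == 1L, "all images must share the same dimensions")
  d <- as.integer(dims[[1L]])
  stopIfNot(length(labels) == length(images), "one label per image required")
  if (is.null(ids)) ids <- sprintf("img%04d", seq_along(images))
  px <- vapply(images, vectorizeImage, numeric(prod(d)))
  colnames(px) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pixels = px),
    colData = S4Vectors::DataFrame(label = as.character(labels),
                                   id = ids, row.names = ids)
  )
  new("GelImageSet", se, imageDim = d)
}

#' @rdname GelImageSet-class
#' @export
setMethod("imageDim", "GelImageSet", function(x) x@imageDim)

#' @rdname GelImageSet-class
#' @export
setMethod("classLabels", "GelImageSet", function(x)
  as.character(SummarizedExperiment::colData(x)$label))

#' @rdname GelImageSet-class
#' @export
setMethod("sampleIds", "GelImageSet", function(x) colnames(x))

#' @rdname GelImageSet-class
#' @export
setMethod("getImage", "GelImageSet", function(x, i) {
  devectorizeImage(SummarizedExperiment::assay(x, "pixels")[, i], x@imageDim)
})

setMethod("show", "GelImageSet", function(object) {
  lab <- classLabels(object)
  cat("GelImageSet:", ncol(object), "images of",
      paste(object@imageDim, collapse = "x"), "\n")
  cat("  classes (", length(unique(lab)), "): ",
      paste(utils::head(unique(lab), 8), collapse = ", "),
      if (length(unique(lab)) > 8) ", ..." else "", "\n", sep = "")
})

# pixel matrix (mn x samples), row-major vectorized
pixelMatrix <- function(x) SummarizedExperiment::assay(x, "pixels")

# ------------------------------------------------------------------ PCAModel

#' PCAModel: eigenbasis of a vectorized image set
#'
#' Holds the training mean, the full retained eigenvalue spectrum of the
#' (1/M-normalized) covariance, and the top-\code{retained} orthonormal
#' eigenvectors as projection basis.
#'
#' @slot mean numeric, training mean vector (length m*n).
#' @slot eigenvalues numeric, full spectrum above the numerical noise floor,
#'   non-increasing.
#' @slot basis matrix (m*n x retained), orthonormal columns.
#' @slot retained integer, feature dimension p.
#' @slot imageDim integer(2).
#' @export
setClass("PCAModel", representation(
  mean = "numeric", eigenvalues = "numeric", basis = "matrix",
  retained = "integer", imageDim = "integer"
))

setValidity("PCAModel", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (length(ev) && (is.unsorted(rev(ev)) || any(ev < -1e-12)))
    msg <- c(msg, "eigenvalues must be non-increasing and nonnegative")
  if (object@retained > ncol(object@basis))
    msg <- c(msg, "retained exceeds basis columns")
  if (ncol(object@basis)) {
    g <- crossprod(object@basis)
    if (max(abs(g - diag(ncol(g)))) > 1e-8)
      msg <- c(msg, "basis columns are not orthonormal (tol 1e-8)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel:", object@retained, "components on",
      paste(object@imageDim, collapse = "x"), "images;",
      length(object@eigenvalues), "eigenvalues retained\n")
})

#' @rdname ICAModel-class
#' @export
setMethod("convergenceInfo", "PCAModel", function(object) list(method = "eigen"))

# --------------------------------------------------------- WaveletPCAModel

#' WaveletPCAModel: PCA on the LL wavelet subband
#'
#' A \linkS4class{PCAModel} fitted on the low-frequency (LL) subband of a
#' Daubechies decomposition of each training image, plus the wavelet
#' configuration needed to preprocess new samples identically.
#'
#' Note: the inherited \code{imageDim} slot holds the LL-subband geometry the
#' PCA basis lives on; \code{origDim} holds the raw input image geometry.
#'
#' @slot wavelet character, e.g. "db2".
#' @slot level integer decomposition depth (only the final LL feeds PCA).
#' @slot origDim integer(2), geometry of the raw input images.
#' @export
setClass("WaveletPCAModel", contains = "PCAModel",
  representation(wavelet = "character", level = "integer", origDim = "integer"))

setMethod("show", "WaveletPCAModel", function(object) {
  cat("WaveletPCAModel:", object@wavelet, "level", object@level, "on",
      paste(object@origDim, collapse = "x"), "images, LL",
      paste(object@imageDim, collapse = "x"), "->",
      object@retained, "components\n")
})

# --------------------------------------------------- WaveletDecomposition

#' WaveletDecomposition: one-level 2-D DWT subbands
#'
#' @slot LL,HL,LH,HH coefficient matrices (identical shapes). LL is the
#'   low-frequency approximation; HL/LH/HH hold horizontal/vertical/diagonal
#'   detail.
#' @slot wavelet character wavelet name.
#' @slot level integer (1 for a single analysis step).
#' @slot boundary character boundary mode ("periodic").
#' @export
setClass("WaveletDecomposition", representation(
  LL = "matrix", HL = "matrix", LH = "matrix", HH = "matrix",
  wavelet = "character", level = "integer", boundary = "character"
))

setValidity("WaveletDecomposition", function(object) {
  dims <- list(dim(object@LL), dim(object@HL), dim(object@LH), dim(object@HH))
  if (length(unique(dims)) != 1L) "all four subbands must share one shape" else TRUE
})

setMethod("show", "WaveletDecomposition", function(object) {
  cat("WaveletDecomposition (", object@wavelet, ", ", object@boundary, "): subbands ",
      paste(dim(object@LL), collapse = "x"), "\n", sep = "")
})

# ------------------------------------------------------------------ ICAModel

#' ICAModel: whitening + FastICA unmixing for image features
#'
#' The feature map is \code{f(x) = unmixing \%*\% whitener \%*\% (x - center)}.
#' Rows of \code{unmixing} are orthonormal in whitened space (symmetric
#' orthogonalization), so training features have unit variance.
#'
#' @slot center numeric, mean of the training observations.
#' @slot whitener matrix (d x m*n) mapping centered data to unit covariance.
#' @slot whitenValues numeric, variances (eigenvalues) of the retained
#'   whitening directions.
#' @slot unmixing matrix W (components x d).
#' @slot mixingEstimate matrix (m*n x components), pseudo-inverse of the
#'   composite map; reconstructs data from features.
#' @slot nComponents integer.
#' @slot convergence list: iterations, residual, converged flag.
#' @slot imageDim integer(2) (length 0 for non-image data).
#' @aliases convergenceInfo
#' @export
setClass("ICAModel", representation(
  center = "numeric", whitener = "matrix", whitenValues = "numeric",
  unmixing = "matrix", mixingEstimate = "matrix", nComponents = "integer",
  convergence = "list", imageDim = "integer"
))

setValidity("ICAModel", function(object) {
  msg <- character()
  W <- object@unmixing
  if (nrow(W) != object@nComponents)
    msg <- c(msg, "unmixing rows must equal nComponents")
  if (nrow(W)) {
    g <- tcrossprod(W)
    if (max(abs(g - diag(nrow(W)))) > 1e-6)
      msg <- c(msg, "unmixing rows not orthonormal in whitened space (tol 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ICAModel", function(object) {
  cv <- object@convergence
  cat("ICAModel:", object@nComponents, "components;",
      if (isTRUE(cv$converged)) "converged" else "NOT converged",
      "after", cv$iterations, "iterations (residual",
      format(cv$residual, digits = 3), ")\n")
})

#' @rdname ICAModel-class
#' @export
setMethod("convergenceInfo", "ICAModel", function(object) object@convergence)

# ------------------------------------------------------------ SubpatternModel

#' SubpatternModel: per-block ICA features with adaptive voting weights
#'
#' Images are tiled into a non-overlapping block grid; each block carries an
#' independently fitted \linkS4class{ICAModel} plus its cached training
#' features. Per-block weights (nonnegative, summing to 1) scale each block's
#' nearest-neighbour vote.
#'
#' @slot grid integer(2), blocks per (row, col).
#' @slot blockShape integer(2), pixel shape of one block.
#' @slot blockModels list of \code{ICAModel}, row-major block order.
#' @slot blockFeatures list of feature matrices (components x n_train).
#' @slot trainLabels character.
#' @slot weights numeric, one per block, sums to 1.
#' @slot imageDim integer(2).
#' @slot metric character distance metric for the per-block votes.
#' @aliases blockWeights
#' @export
setClass("SubpatternModel", representation(
  grid = "integer", blockShape = "integer", blockModels = "list",
  blockFeatures = "list", trainLabels = "character", weights = "numeric",
  imageDim = "integer", metric = "character"
))

setValidity("SubpatternModel", function(object) {
  msg <- character()
  nb <- prod(object@grid)
  if (length(object@blockModels) != nb || length(object@blockFeatures) != nb)
    msg <- c(msg, "one model and feature cache per grid cell required")
  if (length(object@weights) != nb)
    msg <- c(msg, "one weight per block required")
  else {
    if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
    if (abs(sum(object@weights) - 1) > 1e-10)
      msg <- c(msg, "weights must sum to 1 (tol 1e-10)")
  }
  if (any(object@imageDim %% object@grid != 0))
    msg <- c(msg, "image dims must be divisible by the grid")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubpatternModel", function(object) {
  cat("SubpatternModel:", paste(object@grid, collapse = "x"), "grid of",
      paste(object@blockShape, collapse = "x"), "blocks,",
      object@blockModels[[1L]]@nComponents, "components/block,",
      length(object@trainLabels), "training images\n")
  cat("  weights:", paste(format(object@weights, digits = 3), collapse = " "), "\n")
})

#' @rdname SubpatternModel-class
#' @export
setMethod("blockWeights", "SubpatternModel", function(object) object@weights)

# ---------------------------------------------------------- experiment types

#' ExperimentConfig: repeated-random-split benchmark settings
#'
#' @slot algorithm one of "pca", "wavelet_pca", "ica", "subpattern_ica".
#' @slot trainPerClass integer P: training images drawn per class.
#' @slot dims integer vector of feature dimensions to sweep (ascending).
#' @slot repeats integer number of random splits averaged (default 10).
#' @slot seed integer master seed; repeat r uses a child stream of (seed, r).
#' @slot metric "euclidean" or "cosine".
#' @slot wavelet wavelet name for "wavelet_pca".
#' @slot grid integer(2) block grid for "subpattern_ica".
#' @slot betaOrder logical (default FALSE). For ICA sweeps: when FALSE, each
#'   swept dimension d fits its own d-component model (whitening capped at
#'   d); when TRUE, one model is fitted at the largest dimension and each
#'   sweep point selects the d smallest-beta components (needs balanced
#'   classes with P >= 2). The beta route is kept selectable but is prone to
#'   overfitting at small per-class counts.
#' @slot occludeTest list() or list(region = integer(4), fill = numeric(1)):
#'   occlusion applied to every test image after the split, for robustness
#'   benchmarks. Region is (row0, row1, col0, col1).
#' @export
setClass("ExperimentConfig", representation(
  algorithm = "character", trainPerClass = "integer", dims = "integer",
  repeats = "integer", seed = "integer", metric = "character",
  wavelet = "character", grid = "integer", betaOrder = "logical",
  occludeTest = "list"
))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("pca", "wavelet_pca", "ica", "subpattern_ica"))
    msg <- c(msg, "unknown algorithm (valid: pca, wavelet_pca, ica, subpattern_ica)")
  if (object@repeats < 1L) msg <- c(msg, "repeats must be >= 1")
  if (!length(object@dims) || is.unsorted(object@dims, strictly = TRUE))
    msg <- c(msg, "dims must be nonempty and strictly ascending")
  if (object@trainPerClass < 1L) msg <- c(msg, "trainPerClass must be >= 1")
  if (!object@metric %in% c("euclidean", "cosine"))
    msg <- c(msg, "metric must be 'euclidean' or 'cosine'")
  if (length(msg)) msg else TRUE
})

#' @rdname ExperimentConfig-class
#' @param algorithm,trainPerClass,dims,repeats,seed,metric,wavelet,grid,betaOrder,occludeTest
#'   see slots.
#' @export
experimentConfig <- function(algorithm, trainPerClass, dims, repeats = 10L,
                             seed = 1L, metric = "euclidean", wavelet = "db2",
                             grid = c(4L, 4L), betaOrder = FALSE,
                             occludeTest = list()) {
  new("ExperimentConfig", algorithm = algorithm,
      trainPerClass = as.integer(trainPerClass), dims = as.integer(dims),
      repeats = as.integer(repeats), seed = as.integer(seed), metric = metric,
      wavelet = wavelet, grid = as.integer(grid), betaOrder = betaOrder,
      occludeTest = occludeTest)
}

setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig:", object@algorithm, "| P =", object@trainPerClass,
      "| dims", paste(range(object@dims), collapse = ".."),
      "| repeats", object@repeats, "| seed", object@seed, "\n")
})

#' ExperimentResult: recognition rates from a repeated-split run
#'
#' @slot rates matrix (repeats x dims) of recognition rates in percent.
#' @slot dims integer, requested feature dimensions.
#' @slot effectiveDims integer, dimensions actually used (requested capped at
#'   the achievable rank per repeat; the reported value is the minimum cap).
#' @slot config the \code{ExperimentConfig} echo.
#' @aliases meanRates rawRates
#' @export
setClass("ExperimentResult", representation(
  rates = "matrix", dims = "integer", effectiveDims = "integer",
  config = "ExperimentConfig"
))

setValidity("ExperimentResult", function(object) {
  r <- object@rates
  if (length(r) && (min(r) < 0 || max(r) > 100))
    "rates must lie in [0, 100]" else TRUE
})

#' @rdname ExperimentResult-class
#' @export
setMethod("meanRates", "ExperimentResult", function(object) {
  m <- colMeans(object@rates)
  names(m) <- object@dims
  m
})

#' @rdname ExperimentResult-class
#' @export
setMethod("rawRates", "ExperimentResult", function(object) object@rates)

setMethod("show", "ExperimentResult", function(object) {
  cat("ExperimentResult:", object@config@algorithm, "P =",
      object@config@trainPerClass, "\n")
  print(round(meanRates(object), 2))
})

#' @rdname ExperimentResult-class
#' @param x an \code{ExperimentResult}.
#' @param ... ignored.
#' @export
as.data.frame.ExperimentResult <- function(x, ...) {
  data.frame(
    algorithm = x@config@algorithm,
    P = x@config@trainPerClass,
    dim = rep(x@dims, each = nrow(x@rates)),
    repeat_index = rep(seq_len(nrow(x@rates)), times = length(x@dims)),
    rate = as.vector(x@rates)
  )
}

# ----------------------------------------------------------- generator types

#' GelClassSpec: appearance parameters of one gel-state class
#'
#' The class ladder emulates progressive thermal gelation: as gel temperature
#' rises, pore density increases, darkening and texturing the image.
#'
#' @slot label class name.
#' @slot poreDensity expected pore count per image (Poisson mean).
#' @slot poreRadius numeric(2), min/max pore radius in pixels (min >= 1).
#' @slot baseIntensity background gray level in [0,1].
#' @slot textureScale correlation length (pixels) of the smooth background
#'   texture.
#' @slot layout "iid" (every image draws a fresh Poisson pore field) or
#'   "shared" (the class draws one characteristic pore configuration, and
#'   each image renders it with positional jitter plus a few extra pores —
#'   emulating repeated photographs of specimens in the same gel state).
#' @export
setClass("GelClassSpec", representation(
  label = "character", poreDensity = "numeric", poreRadius = "numeric",
  baseIntensity = "numeric", textureScale = "numeric", layout = "character"
))

setValidity("GelClassSpec", function(object) {
  msg <- character()
  if (object@poreDensity < 0) msg <- c(msg, "poreDensity must be >= 0")
  if (length(object@poreRadius) != 2L || object@poreRadius[1] < 1 ||
      diff(object@poreRadius) < 0)
    msg <- c(msg, "poreRadius must be (min, max) with min >= 1")
  if (object@baseIntensity < 0 || object@baseIntensity > 1)
    msg <- c(msg, "baseIntensity must lie in [0,1]")
  if (object@textureScale < 0) msg <- c(msg, "textureScale must be >= 0")
  if (!object@layout %in% c("iid", "shared"))
    msg <- c(msg, "layout must be 'iid' or 'shared'")
  if (length(msg)) msg else TRUE
})

#' @rdname GelClassSpec-class
#' @param label,poreDensity,poreRadius,baseIntensity,textureScale,layout see
#'   slots.
#' @export
gelClassSpec <- function(label, poreDensity, poreRadius = c(2, 5),
                         baseIntensity = 0.75, textureScale = 3,
                         layout = "iid") {
  new("GelClassSpec", label = label, poreDensity = poreDensity,
      poreRadius = poreRadius, baseIntensity = baseIntensity,
      textureScale = textureScale, layout = layout)
}

setMethod("show", "GelClassSpec", function(object) {
  cat("GelClassSpec '", object@label, "': density ", object@poreDensity,
      ", radius [", paste(object@poreRadius, collapse = ", "),
      "], base ", object@baseIntensity, "\n", sep = "")
})
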