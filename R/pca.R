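# PCA on vectorized images, using the transposed small-sample eigen trick:
# eigenpairs of the M x M Gram matrix X'X are mapped through X to eigenpairs
# of the mn x mn covariance C = (1/M) X X', avoiding the dense mn x mn solve.

#' Column-wise mean vector of a training matrix
#'
#' @param X numeric matrix holding one vectorized sample per column.
#' @return numeric vector, the arithmetic mean of the columns.
#' @export
meanVector <- function(X) {
  stopIfNot(is.matrix(X) && ncol(X) >= 1L, "X must be a matrix with >= 1 column")
  rowMeans(X)
}

# relative floor below which eigenvalues are treated as numerical noise
.EIG_TOL <- 1e-10

#' Eigendecomposition of the image covariance via the Gram matrix
#'
#' Computes eigenpairs of \eqn{C = (1/M) X X^T} for a centered
#' \eqn{mn \times M} matrix \code{Xc} without ever forming \eqn{C}: the
#' \eqn{M \times M} matrix \eqn{X^T X} is decomposed, each eigenvector
#' \eqn{\eta} is mapped to \eqn{X \eta} and normalized. Eigenvalues below
#' \code{1e-10} of the leading one are discarded as numerical noise; each
#' eigenvector's sign is fixed so its largest-magnitude entry is positive.
#'
#' @param Xc centered matrix (columns sum to zero across samples).
#' @return list(values, vectors): non-increasing eigenvalues of \eqn{C} and
#'   the matching orthonormal columns. An all-zero input yields an empty
#'   spectrum with \code{empty = TRUE}.
#' @export
eigSmallSample <- function(Xc) {
  stopIfNot(is.matrix(Xc) && ncol(Xc) >= 2L, "Xc must be a matrix with >= 2 columns")
  M <- ncol(Xc)
  G <- crossprod(Xc) / M                 # (1/M) X'X shares C's nonzero spectrum
  if (max(abs(G)) < .Machine$double.eps) {
    return(list(values = numeric(0),
                vectors = matrix(0, nrow(Xc), 0), empty = TRUE))
  }
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > .EIG_TOL * e$values[1L] & e$values > 0
  vals <- e$values[keep]
  U <- Xc %*% e$vectors[, keep, drop = FALSE]
  nrm <- sqrt(colSums(U^2))
  U <- sweep(U, 2L, nrm, "/")
  U <- fixSigns(U)
  list(values = vals, vectors = U, empty = FALSE)
}

# deterministic sign: largest-|entry| of each column made positive
fixSigns <- function(U) {
  if (!ncol(U)) return(U)
  s <- apply(U, 2L, function(u) sign(u[which.max(abs(u))]))
  sweep(U, 2L, ifelse(s == 0, 1, s), "*")
}

# core fit shared by fitPCA and fitWaveletPCA: X is mn x M (vectorized);
# p = NULL retains the full achievable rank
fitPCACore <- function(X, p, imageDim, class = "PCAModel", ...) {
  mu <- meanVector(X)
  e <- eigSmallSample(X - mu)
  r <- length(e$values)
  if (is.null(p)) p <- r
  if (p > r)
    stop("requested dimension p = ", p, " exceeds the achievable rank ", r,
         call. = FALSE)
  new(class, mean = mu, eigenvalues = e$values,
      basis = e$vectors[, seq_len(p), drop = FALSE], retained = as.integer(p),
      imageDim = as.integer(imageDim), ...)
}

#' Fit a PCA feature-extraction model on an image set
#'
#' @param train a \code{\link{GelImageSet}} of training images.
#' @param p number of principal components to retain (at most the achievable
#'   rank, which is bounded by the training count minus one).
#' @return a \linkS4class{PCAModel}.
#' @examples
#' gs <- generateGelDataset(gelGenConfig(nClasses = 3, perClass = 4,
#'                                       imageSize = c(16, 16), seed = 1))
#' m <- fitPCA(gs, p = 5)
#' dim(projectFeatures(m, gs))
#' @export
fitPCA <- function(train, p) {
  stopIfNot(is(train, "GelImageSet"), "train must be a GelImageSet")
  fitPCACore(pixelMatrix(train), p, imageDim(train))
}

#' @rdname projectFeatures
#' @export
setMethod("projectFeatures", "PCAModel", function(model, x, ...) {
  V <- asPixelColumns(x, model@imageDim)
  f <- crossprod(model@basis, V - model@mean)
  if (ncol(f) == 1L) as.vector(f) else f
})

# coerce GelImageSet / matrix image / vector to an mn x k column matrix
asPixelColumns <- function(x, imageDim) {
  if (is(x, "GelImageSet")) {
    stopIfNot(all(imageDim(x) == imageDim), "sample shape does not match the model")
    return(pixelMatrix(x))
  }
  if (is.matrix(x) && all(dim(x) == imageDim)) return(cbind(vectorizeImage(x)))
  if (is.numeric(x) && length(x) == prod(imageDim)) return(cbind(as.vector(x)))
  stop("sample shape does not match the model's image shape (",
       paste(imageDim, collapse = "x"), ")", call. = FALSE)
}

#' Reconstruct an image from PCA features
#'
#' @param model a \code{PCAModel}.
#' @param features feature vector (length \code{retained}).
#' @return reconstructed image matrix.
#' @export
reconstructImage <- function(model, features) {
  stopIfNot(length(features) == model@retained, "feature length must equal retained p")
  devectorizeImage(model@mean + as.vector(model@basis %*% features), model@imageDim)
}

#' Minimum mean squared reconstruction error at dimension p
#'
#' For a full eigenvalue spectrum, the smallest achievable mean squared error
#' when reconstructing from the top \code{p} components is the tail sum
#' \eqn{\sum_{i > p} \lambda_i}.
#'
#' @param eigenvalues full non-increasing spectrum (or a \code{PCAModel}).
#' @param p retained dimension, \code{0 <= p <= length(eigenvalues)}.
#' @return nonnegative scalar.
#' @export
reconstructionMSEMin <- function(eigenvalues, p) {
  if (is(eigenvalues, "PCAModel")) eigenvalues <- eigenvalues@eigenvalues
  n <- length(eigenvalues)
  stopIfNot(p >= 0 && p <= n, "p must lie in [0, length(eigenvalues)]")
  if (p >= n) 0 else sum(eigenvalues[(p + 1L):n])
}

#' Eigenvector sub-images for visual inspection
#'
#' Devectorizes the first \code{k} basis vectors back to image shape and
#' affinely rescales each to [0,1], ordered by descending eigenvalue.
#'
#' @param model a \code{PCAModel}.
#' @param k number of sub-images (at most \code{retained}).
#' @return list of \code{k} image matrices.
#' @export
featureSubimages <- function(model, k) {
  stopIfNot(k >= 1 && k <= model@retained, "k must lie in [1, retained]")
  lapply(seq_len(k), function(i)
    rescale01(devectorizeImage(model@basis[, i], model@imageDim)))
}
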