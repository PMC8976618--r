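#' @importFrom methods new is validObject slot
#' @importFrom stats rnorm runif rpois cor sd
#' @importFrom utils write.csv read.csv packageVersion
NULL

# Deterministic child-seed stream. Keeps results below 2^31 - 1 so the value
# is always a valid R integer seed; multiplier/increment are primes.
childSeed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  as.integer(((s * 48271) %% m + as.double(index) * 7919) %% m)
}

withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# row-major vectorization: rows of the image are concatenated end to end,
# matching reading order; the inverse reshapes by row.
#' Vectorize an image matrix (row-major)
#'
#' Rows are concatenated end to end, so a \eqn{m \times n} image becomes a
#' length-\eqn{mn} vector in reading order. \code{devectorizeImage} is the
#' exact inverse.
#'
#' @param pixels numeric matrix.
#' @return numeric vector of length \code{nrow(pixels) * ncol(pixels)}.
#' @examples
#' vectorizeImage(matrix(1:4, 2, 2, byrow = TRUE))
#' @export
vectorizeImage <- function(pixels) {
  stopIfNot(is.matrix(pixels), "'pixels' must be a matrix")
  as.vector(t(pixels))
}

#' @rdname vectorizeImage
#' @param v numeric vector of length \code{prod(dim)}.
#' @param dim integer(2), target (rows, cols).
#' @export
devectorizeImage <- function(v, dim) {
  dim <- as.integer(dim)
  stopIfNot(length(v) == prod(dim), "length(v) does not match dim")
  matrix(v, nrow = dim[1L], ncol = dim[2L], byrow = TRUE)
}

# affine rescale to [0,1]; constant input maps to all zeros
rescale01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(array(0, dim = dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
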