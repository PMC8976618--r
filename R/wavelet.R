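# One-level separable 2-D discrete wavelet transform (Daubechies family,
# periodized), and the Wavelet-PCA pipeline: PCA on the LL subband instead of
# the raw image.
#
# The analysis step is applied as an explicit orthogonal n x n operator (top
# half: even-shifted low-pass rows; bottom half: high-pass), so synthesis is
# exactly the transpose and perfect reconstruction / energy conservation hold
# to machine precision.

.DAUB_CACHE <- new.env(parent = emptyenv())

#' Daubechies scaling (low-pass analysis) filter
#'
#' Computed by spectral factorization of the Daubechies half-band polynomial
#' \eqn{P(y) = \sum_{k<N} \binom{N-1+k}{k} y^k}: its roots are mapped to the
#' z-plane, the minimum-phase half is kept, combined with the \eqn{(1+z)^N}
#' factor, and the result normalized to \eqn{\sum h = \sqrt 2}. Roots are
#' Newton-polished so the quadrature-mirror orthogonality
#' \eqn{\sum_n h_n h_{n+2k} = \delta_k} holds to ~1e-13.
#'
#' @param N number of vanishing moments, 1..8 ("db1".."db8"); db1 is Haar.
#' @return numeric filter of length \code{2N}.
#' @export
daubechiesFilter <- function(N) {
  stopIfNot(N %in% 1:8, "supported wavelets: db1..db8")
  key <- paste0("db", N)
  if (!is.null(.DAUB_CACHE[[key]])) return(.DAUB_CACHE[[key]])
  h <- if (N == 1) c(1, 1) / sqrt(2) else daubSpectralFactor(N)
  .DAUB_CACHE[[key]] <- h
  h
}

polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

daubSpectralFactor <- function(N) {
  p <- choose(N - 1 + 0:(N - 1), 0:(N - 1))
  # substitute y = (2 - z - 1/z)/4 and clear denominators:
  # sum_k p_k (-1 + 2z - z^2)^k (4z)^(N-1-k), a degree 2N-2 polynomial in z
  acc <- numeric(2L * N - 1L)
  for (k in 0:(N - 1)) {
    term <- p[k + 1L]
    if (k > 0) for (j in seq_len(k)) term <- polymul(term, c(-1, 2, -1))
    if (N - 1L - k > 0) for (j in seq_len(N - 1L - k)) term <- polymul(term, c(0, 4))
    acc[seq_along(term)] <- acc[seq_along(term)] + term
  }
  r <- polyroot(acc)
  dacc <- acc[-1L] * seq_len(length(acc) - 1L)
  horner <- function(cf, z) { s <- 0 + 0i; for (c in rev(cf)) s <- s * z + c; s }
  for (it in 1:50) r <- r - horner(acc, r) / horner(dacc, r)  # Newton polish
  keep <- r[Mod(r) < 1]                                       # minimum phase
  stopIfNot(length(keep) == N - 1L, "spectral factorization failed")
  h <- 1
  for (z0 in keep) h <- polymul(h, c(-z0, 1))
  for (j in seq_len(N)) h <- polymul(h, c(1, 1))
  h <- Re(h)
  h / sum(h) * sqrt(2)
}

# quadrature-mirror high-pass from the low-pass: g[m] = (-1)^m h[L-1-m]
qmfFilter <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1L)
}

# n x n orthogonal one-step analysis operator for a periodized signal:
# row k (k = 1..n/2) applies the low-pass filter starting at sample 2k-1
# (wrapping), rows n/2+1..n the high-pass. Cached per (n, wavelet).
.DWT_OP_CACHE <- new.env(parent = emptyenv())

dwtOperator <- function(n, wavelet) {
  key <- paste0(wavelet, "_", n)
  if (!is.null(.DWT_OP_CACHE[[key]])) return(.DWT_OP_CACHE[[key]])
  N <- as.integer(sub("^db", "", wavelet))
  h <- daubechiesFilter(N)
  g <- qmfFilter(h)
  L <- length(h)
  stopIfNot(n %% 2L == 0L && n >= L, "signal length must be even and >= filter length")
  W <- matrix(0, n, n)
  half <- n %/% 2L
  for (k in seq_len(half)) {
    pos <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    for (j in seq_len(L)) {
      W[k, pos[j]] <- W[k, pos[j]] + h[j]
      W[half + k, pos[j]] <- W[half + k, pos[j]] + g[j]
    }
  }
  .DWT_OP_CACHE[[key]] <- W
  W
}

#' One-level 2-D discrete wavelet transform
#'
#' Separable row/column filtering with the named Daubechies wavelet's
#' analysis pair plus dyadic downsampling, under periodization (the only
#' boundary mode; it keeps exact half sizes, exact orthogonality and hence
#' exact invertibility). Subbands are LL (approximation), HL (horizontal
#' detail), LH (vertical detail), HH (diagonal detail).
#'
#' @param image numeric matrix; both dimensions even and >= the filter length.
#' @param wavelet "db1".."db8" (default "db2").
#' @param boundary boundary mode; "periodic" is the supported mode.
#' @return a \linkS4class{WaveletDecomposition}.
#' @examples
#' d <- dwt2(matrix(rnorm(64 * 64), 64, 64))
#' max(abs(idwt2(d) - matrix(0, 64, 64))) >= 0  # round trip available
#' @export
dwt2 <- function(image, wavelet = "db2", boundary = "periodic") {
  stopIfNot(is.matrix(image), "image must be a matrix")
  if (!grepl("^db[1-8]$", wavelet))
    stop("unknown wavelet '", wavelet, "' (supported: ",
         paste0("db", 1:8, collapse = ", "), ")", call. = FALSE)
  stopIfNot(identical(boundary, "periodic"),
            "only the 'periodic' boundary mode is supported")
  m <- nrow(image); n <- ncol(image)
  Wr <- dwtOperator(m, wavelet)
  Wc <- if (n == m) Wr else dwtOperator(n, wavelet)
  cf <- Wr %*% image %*% t(Wc)
  hm <- m %/% 2L; hn <- n %/% 2L
  new("WaveletDecomposition",
      LL = cf[seq_len(hm), seq_len(hn), drop = FALSE],
      HL = cf[seq_len(hm), hn + seq_len(hn), drop = FALSE],
      LH = cf[hm + seq_len(hm), seq_len(hn), drop = FALSE],
      HH = cf[hm + seq_len(hm), hn + seq_len(hn), drop = FALSE],
      wavelet = wavelet, level = 1L, boundary = boundary)
}

#' Inverse one-level 2-D discrete wavelet transform
#'
#' Synthesis is the adjoint of the orthogonal analysis operator, so
#' \code{idwt2(dwt2(f))} reproduces \code{f} to machine precision.
#'
#' @param decomp a \code{WaveletDecomposition}.
#' @return reconstructed image matrix.
#' @export
idwt2 <- function(decomp) {
  stopIfNot(is(decomp, "WaveletDecomposition"), "decomp must be a WaveletDecomposition")
  validObject(decomp)
  cf <- rbind(cbind(decomp@LL, decomp@HL), cbind(decomp@LH, decomp@HH))
  m <- nrow(cf); n <- ncol(cf)
  Wr <- dwtOperator(m, decomp@wavelet)
  Wc <- if (n == m) Wr else dwtOperator(n, decomp@wavelet)
  t(Wr) %*% cf %*% Wc
}

# final-level LL of a (possibly multi-level) decomposition
llSubband <- function(image, wavelet, level) {
  ll <- image
  for (i in seq_len(level)) ll <- dwt2(ll, wavelet)@LL
  ll
}

#' Write the four subbands as grayscale images
#'
#' Each subband is affinely rescaled to [0,1] and written as
#' \code{<prefix>_LL.png} etc., for visual inspection of a decomposition.
#'
#' @param decomp a \code{WaveletDecomposition}.
#' @param prefix output path prefix.
#' @return invisibly, the four file paths.
#' @export
writeSubbandImages <- function(decomp, prefix) {
  paths <- character(4)
  bands <- c("LL", "HL", "LH", "HH")
  for (i in seq_along(bands)) {
    paths[i] <- paste0(prefix, "_", bands[i], ".png")
    writeImageFile(rescale01(slot(decomp, bands[i])), paths[i])
  }
  invisible(paths)
}

#' Fit the Wavelet-PCA pipeline
#'
#' Every training image is replaced by the final-level LL subband of its
#' Daubechies decomposition (a quarter of the pixels per level), and PCA is
#' fitted on the vectorized LL coefficients. Projection of new samples
#' applies the identical preprocessing.
#'
#' @param train a \code{\link{GelImageSet}}.
#' @param p number of principal components.
#' @param wavelet "db1".."db8" (default "db2").
#' @param level decomposition depth (default 1).
#' @return a \linkS4class{WaveletPCAModel}.
#' @export
fitWaveletPCA <- function(train, p, wavelet = "db2", level = 1L) {
  stopIfNot(is(train, "GelImageSet"), "train must be a GelImageSet")
  d <- imageDim(train)
  llDim <- d %/% (2L^level)
  stopIfNot(prod(llDim) < prod(d), "LL subband must be smaller than the image")
  X <- vapply(seq_len(ncol(train)), function(i)
    vectorizeImage(llSubband(getImage(train, i), wavelet, level)),
    numeric(prod(llDim)))
  fitPCACore(X, p, llDim, class = "WaveletPCAModel",
             wavelet = wavelet, level = as.integer(level), origDim = d)
}

#' @rdname projectFeatures
#' @export
setMethod("projectFeatures", "WaveletPCAModel", function(model, x, ...) {
  imgs <- if (is(x, "GelImageSet")) {
    stopIfNot(all(imageDim(x) == model@origDim), "sample shape does not match the model")
    lapply(seq_len(ncol(x)), function(i) getImage(x, i))
  } else if (is.matrix(x) && all(dim(x) == model@origDim)) {
    list(x)
  } else stop("sample shape does not match the model's image shape (",
              paste(model@origDim, collapse = "x"), ")", call. = FALSE)
  V <- vapply(imgs, function(im)
    vectorizeImage(llSubband(im, model@wavelet, model@level)),
    numeric(prod(model@imageDim)))
  f <- crossprod(model@basis, V - model@mean)
  if (ncol(f) == 1L) as.vector(f) else f
})
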