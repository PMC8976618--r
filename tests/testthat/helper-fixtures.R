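# Shared fixtures and independent oracles, built in code at test time.

# small labeled image set with random pixels (no class structure)
randomImageSet <- function(n = 6, size = c(8L, 8L), seed = 1L,
                           nClasses = 2L) {
  imgs <- withr::with_seed(seed, replicate(n, {
    matrix(runif(prod(size)), size[1L], size[2L])
  }, simplify = FALSE))
  GelImageSet(imgs, labels = rep(paste0("c", seq_len(nClasses)),
                                 length.out = n))
}

# small synthetic gel set via the generator; small pores and iid placement
# keep tiny images full-rank and well-conditioned
tinyGelSet <- function(nClasses = 3L, perClass = 4L, size = c(32L, 32L),
                       seed = 1L) {
  dens <- seq(3, 12, length.out = nClasses)
  classes <- lapply(seq_len(nClasses), function(i)
    gelClassSpec(sprintf("state%02d", i), poreDensity = dens[i],
                 poreRadius = c(1.5, 3), layout = "iid"))
  generateGelDataset(gelGenConfig(classes = classes, perClass = perClass,
                                  imageSize = size, seed = seed))
}

# dense-covariance eigen oracle: full mn x mn eigendecomposition of
# C = (1/M) Xc Xc^T (feasible for small mn only)
denseEigOracle <- function(Xc) {
  C <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > 1e-10 * e$values[1L]
  list(values = e$values[keep], vectors = e$vectors[, keep, drop = FALSE])
}

# naive separable convolution + dyadic downsampling oracle for the 2-D DWT,
# periodic boundary; independent of the operator-matrix implementation
naiveDwt2 <- function(image, wavelet) {
  N <- as.integer(sub("^db", "", wavelet))
  h <- daubechiesFilter(N)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  conv1 <- function(x, f) {            # y[k] = sum_j f[j] x[(2(k-1)+j-1) mod n + 1]
    n <- length(x)
    vapply(seq_len(n %/% 2L), function(k) {
      idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
      sum(f * x[idx])
    }, numeric(1))
  }
  lo <- t(apply(image, 1L, conv1, f = h))   # filter along rows' columns
  hi <- t(apply(image, 1L, conv1, f = g))
  list(
    LL = apply(lo, 2L, conv1, f = h),
    HL = apply(hi, 2L, conv1, f = h),
    LH = apply(lo, 2L, conv1, f = g),
    HH = apply(hi, 2L, conv1, f = g)
  )
}

# sign-invariant column comparison
maxAbsDiffUpToSign <- function(A, B) {
  max(vapply(seq_len(ncol(A)), function(j) {
    min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
  }, numeric(1)))
}

# exhaustive-scan 1-NN oracle
bruteForceNN <- function(trainFeatures, trainLabels, query) {
  apply(query, 2L, function(q) {
    d <- colSums((trainFeatures - q)^2)
    trainLabels[which.min(d)]
  })
}
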