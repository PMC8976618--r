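test_that("the mean vector is the arithmetic column mean", {
  expect_identical(meanVector(cbind(c(0, 0), c(2, 2))), c(1, 1))
  v <- c(3, -1, 7)
  expect_identical(meanVector(cbind(v)), v)
  X <- withr::with_seed(11, matrix(rnorm(40), 8, 5))
  oracle <- sapply(seq_len(8), function(k) sum(X[k, ]) / 5)
  expect_lt(max(abs(meanVector(X) - oracle)), 1e-12)
  expect_error(meanVector(matrix(0, 3, 0)), "column")
})

test_that("the small-sample eigen trick matches the dense covariance solve", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      X <- matrix(rnorm(16 * 5), 16, 5)
      Xc <- X - rowMeans(X)
      got <- eigSmallSample(Xc)
      want <- denseEigOracle(Xc)
      expect_length(got$values, length(want$values))
      expect_lt(max(abs(got$values - want$values) / want$values[1]), 1e-8)
      expect_lt(maxAbsDiffUpToSign(got$vectors, want$vectors), 1e-6)
    }
  })
  # rank-1 data has exactly one nonzero eigenvalue
  u <- withr::with_seed(1, rnorm(12)); v <- withr::with_seed(2, rnorm(4))
  r1 <- eigSmallSample(outer(u, v) - rowMeans(outer(u, v)))
  expect_lte(length(r1$values), 2L)   # centering a rank-1 set leaves rank <= 2
  dup <- cbind(u, u, u)
  expect_true(eigSmallSample(dup - rowMeans(dup))$empty)
})

test_that("fitted bases are orthonormal and bounded by the rank", {
  gs <- tinyGelSet(2, 3, c(16, 16), seed = 31)
  m <- fitPCA(gs, 5)
  B <- m@basis
  expect_lt(max(abs(crossprod(B) - diag(5))), 1e-8)
  expect_lte(length(m@eigenvalues), ncol(gs) - 1L)
  expect_error(fitPCA(gs, 50), "achievable rank")
  # two distinct training images support only p = 1
  two <- gs[, 1:2]
  expect_s4_class(fitPCA(two, 1), "PCAModel")
  expect_error(fitPCA(two, 2), "achievable rank")
})

test_that("projection is centered, orthonormal and matches a naive oracle", {
  gs <- tinyGelSet(3, 4, c(16, 16), seed = 41)
  m <- fitPCA(gs, 6)
  # the mean image projects to zero
  f0 <- projectFeatures(m, devectorizeImage(m@mean, m@imageDim))
  expect_lt(max(abs(f0)), 1e-10)
  # mean + c * u1 projects to (c, 0, ..., 0)
  c0 <- 0.37
  s1 <- m@mean + c0 * m@basis[, 1]
  f1 <- projectFeatures(m, s1)
  expect_lt(max(abs(f1 - c(c0, rep(0, 5)))), 1e-10)
  # naive double-loop oracle on a random sample
  x <- withr::with_seed(5, runif(256))
  got <- projectFeatures(m, x)
  want <- vapply(seq_len(6), function(i)
    sum(m@basis[, i] * (x - m@mean)), numeric(1))
  expect_lt(max(abs(got - want)), 1e-10)
  expect_error(projectFeatures(m, matrix(0, 4, 4)), "shape")
})

test_that("reconstruction error equals the discarded eigenvalue tail", {
  expect_identical(reconstructionMSEMin(c(4, 2, 1), 2), 1)
  expect_identical(reconstructionMSEMin(c(4, 2, 1), 3), 0)
  gs <- tinyGelSet(2, 5, c(16, 16), seed = 51)
  px <- SummarizedExperiment::assay(gs)
  full <- fitPCA(gs, length(eigSmallSample(px - rowMeans(px))$values))
  ev <- full@eigenvalues
  for (p in c(1L, 3L, length(ev))) {
    B <- full@basis[, seq_len(p), drop = FALSE]
    cent <- px - full@mean
    recon <- B %*% crossprod(B, cent)
    measured <- mean(colSums((cent - recon)^2))
    expect_lt(abs(measured - reconstructionMSEMin(ev, p)), 1e-8)
  }
  # total variance accounting: sum of eigenvalues = trace of C
  expect_lt(abs(sum(ev) - sum((px - full@mean)^2) / ncol(px)), 1e-8)
})

test_that("training features are mutually uncorrelated", {
  gs <- tinyGelSet(3, 4, c(16, 16), seed = 61)
  m <- fitPCA(gs, 8)
  f <- projectFeatures(m, gs)
  cv <- tcrossprod(f - rowMeans(f)) / ncol(f)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
  # and their variances are the eigenvalues (population normalization)
  expect_lt(max(abs(diag(cv) - m@eigenvalues[1:8])), 1e-8)
})

test_that("feature sub-images come back rescaled in eigenvalue order", {
  gs <- tinyGelSet(2, 6, c(16, 16), seed = 71)
  m <- fitPCA(gs, 6)
  subs <- featureSubimages(m, 6)
  expect_length(subs, 6L)
  for (im in subs) {
    expect_identical(dim(im), c(16L, 16L))
    expect_equal(range(im), c(0, 1))
  }
  expect_identical(subs[[1]],
                   gelFeatures:::rescale01(devectorizeImage(m@basis[, 1], c(16, 16))))
  expect_error(featureSubimages(m, 7), "k must")
})

test_that("model archives persist and validate on read", {
  gs <- tinyGelSet(2, 4, c(16, 16), seed = 81)
  m <- fitPCA(gs, 3)
  path <- tempfile(fileext = ".rds")
  saveGelModel(m, path)
  back <- readGelModel(path)
  expect_identical(back@basis, m@basis)
  expect_identical(back@eigenvalues, m@eigenvalues)
  # reconstruction from features inverts projection on the retained subspace
  f <- projectFeatures(m, gs[, 1])
  rec <- reconstructImage(m, f)
  expect_identical(dim(rec), c(16L, 16L))
  unlink(path)
})
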