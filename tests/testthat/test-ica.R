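test_that("whitening yields identity covariance on the retained directions", {
  X <- withr::with_seed(5, matrix(rnorm(10 * 200), 10, 200))
  wh <- whitenData(X, eigFloor = 0)
  expect_lt(max(abs(rowMeans(wh$Z))), 1e-10)
  cv <- tcrossprod(wh$Z) / (ncol(wh$Z) - 1)
  expect_lt(max(abs(cv - diag(nrow(wh$Z)))), 1e-8)
  # correlated 2-D Gaussian cloud, rho = 0.9, n = 5000
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  L <- chol(S)
  Y <- t(L) %*% withr::with_seed(6, matrix(rnorm(2 * 5000), 2, 5000))
  Z2 <- whitenData(Y, eigFloor = 0)$Z
  expect_lt(max(abs(stats::cov(t(Z2)) - diag(2))), 5e-2)
  # rank-1 data in 3-D whitens to one dimension
  u <- withr::with_seed(7, rnorm(500))
  R1 <- rbind(u, 2 * u, -u)
  expect_identical(nrow(whitenData(R1, eigFloor = 0)$Z), 1L)
  expect_error(whitenData(matrix(1, 3, 10)), "degenerate")
})

test_that("FastICA recovers pre-mixed independent uniform sources", {
  withr::with_seed(8, {
    S <- rbind(runif(3000, -1, 1), runif(3000, -1, 1))
    A <- matrix(c(1, 0.6, 0.4, 1), 2)
    wh <- whitenData(A %*% S, eigFloor = 0)
    core <- fastIcaCore(wh$Z, 2, seed = 99)
    Y <- core$W %*% wh$Z
    cm <- abs(stats::cor(t(S), t(Y)))
    best <- max(cm[1, 1] * cm[2, 2], cm[1, 2] * cm[2, 1])
    expect_gt(sqrt(best), 0.99)
    expect_true(core$converged)
    expect_true(core$identifiable)
  })
  # one component of a single non-Gaussian source is recovered up to sign
  withr::with_seed(9, {
    s <- runif(2000, -1, 1)
    wh <- whitenData(rbind(s, 0.5 * s), eigFloor = 0)
    core <- fastIcaCore(wh$Z, 1, seed = 1)
    expect_equal(abs(as.vector(core$W)), 1)
    expect_gt(abs(stats::cor(as.vector(core$W %*% wh$Z), s)), 0.999)
  })
})

test_that("pure Gaussian inputs are flagged unidentifiable", {
  Z <- withr::with_seed(10, matrix(rnorm(2 * 3000), 2, 3000))
  core <- fastIcaCore(whitenData(Z, eigFloor = 0)$Z, 2, seed = 4)
  expect_false(core$identifiable)
  expect_lt(max(abs(core$kurtosis)), 0.5)
})

test_that("identical seeds give bit-identical models", {
  gs <- tinyGelSet(3, 4, c(16, 16), seed = 12)
  m1 <- fitICAFeatures(gs, nComponents = 6, seed = 77)
  m2 <- fitICAFeatures(gs, nComponents = 6, seed = 77)
  expect_identical(m1@unmixing, m2@unmixing)
  expect_identical(m1@whitener, m2@whitener)
  m3 <- fitICAFeatures(gs, nComponents = 6, seed = 78)
  expect_false(identical(m3@unmixing, m1@unmixing))
})

test_that("image features are unit variance, centered and invertible", {
  gs <- tinyGelSet(3, 5, c(16, 16), seed = 13)
  m <- fitICAFeatures(gs, nComponents = 8, seed = 3)
  f <- projectFeatures(m, gs)
  # whitened-space contract: unit variance rows, orthonormal unmixing
  expect_lt(max(abs(apply(f, 1, stats::var) - 1)), 1e-6)
  expect_lt(max(abs(tcrossprod(m@unmixing) - diag(m@nComponents))), 1e-6)
  # the training mean projects to zero
  mu <- devectorizeImage(m@center, imageDim(gs))
  expect_lt(max(abs(projectFeatures(m, mu))), 1e-8)
  # pseudo-inverse reconstruction: the mean squared residual over the
  # training set equals exactly the variance discarded by whitening
  px <- SummarizedExperiment::assay(gs)
  M <- ncol(px)
  resid <- vapply(seq_len(M), function(i) {
    rec <- reconstructICAImage(m, projectFeatures(m, gs[, i]))
    sum((vectorizeImage(rec) - px[, i])^2)
  }, numeric(1))
  sampleEv <- eigen(stats::cov(t(px)), symmetric = TRUE, only.values = TRUE)$values
  discarded <- sum(sampleEv) - sum(m@whitenValues)
  expect_lt(abs(mean(resid) - discarded * (M - 1) / M), 1e-6)
})

test_that("the BSS demo separates all four canonical sources", {
  demo <- bssDemo(2000, seed = 5)
  expect_identical(dim(demo$sources), c(4L, 2000L))
  expect_true(all(demo$match$abs_correlation >= 0.95))
  expect_setequal(demo$match$component, 1:4)
  # identity mixing reduces to whitening + rotation
  demo2 <- bssDemo(2000, seed = 6, mixing = diag(4))
  expect_true(all(demo2$match$abs_correlation >= 0.99))
})

test_that("evaluation factors reproduce hand-enumerated distances", {
  sc <- evaluationFactors(cbind(c(0, 2, 10, 12)), c("a", "a", "b", "b"))
  expect_equal(sc$U, 2)
  expect_equal(sc$V, 10)
  expect_equal(sc$beta, 0.2)
  # perfectly discriminative feature: zero within-class spread
  sc2 <- evaluationFactors(cbind(c(1, 1, 5, 5)), c("a", "a", "b", "b"))
  expect_equal(sc2$beta, 0)
  # feature identical everywhere: no between-class separation
  sc3 <- evaluationFactors(cbind(rep(2, 4)), c("a", "a", "b", "b"))
  expect_identical(sc3$beta, Inf)
  expect_error(evaluationFactors(cbind(1:5), c("a", "a", "a", "b", "b")),
               "balanced")
})

test_that("larger between-class separation strictly lowers beta", {
  base <- c(0.1, -0.2, 0.15, -0.05)   # fixed within-class noise
  betas <- sapply(c(1, 2, 4, 8), function(gap) {
    f <- cbind(c(base[1:2], base[3:4] + gap))
    evaluationFactors(f, c("a", "a", "b", "b"))$beta
  })
  expect_true(all(diff(betas) < 0))
})

test_that("feature selection takes the smallest betas with stable ties", {
  sc <- data.frame(feature = 1:3, U = 1, V = 1, beta = c(0.5, 0.1, 0.3))
  expect_identical(selectFeatures(sc, 2), c(2L, 3L))
  expect_identical(selectFeatures(sc, 3), 1:3)
  tie <- data.frame(feature = 1:3, U = 1, V = 1, beta = c(0.2, 0.2, 0.1))
  expect_identical(selectFeatures(tie, 2), c(1L, 3L))
  expect_error(selectFeatures(sc, 4), "feature count")
  # CSV export marks the selected set
  path <- tempfile(fileext = ".csv")
  out <- writeFeatureScores(sc, path, k = 2)
  expect_identical(utils::read.csv(path)$selected, c(FALSE, TRUE, TRUE))
  unlink(path)
})

test_that("planted informative dimensions are recovered by selection", {
  hits <- vapply(1:25, function(s) withr::with_seed(s, {
    M <- 4L; N <- 10L
    lab <- rep(letters[1:M], each = N)
    f <- matrix(rnorm(M * N * 10), M * N, 10)
    mu <- matrix(rnorm(M * 3, sd = 2), M, 3)
    f[, 1:3] <- f[, 1:3] * 0.5 + mu[rep(1:M, each = N), ]
    setequal(selectFeatures(evaluationFactors(f, lab), 3), 1:3)
  }), logical(1))
  expect_gte(mean(hits), 0.9)
})
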