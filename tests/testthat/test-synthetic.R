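test_that("a degenerate class spec renders a constant image", {
  spec <- gelClassSpec("flat", 0, baseIntensity = 0.6, textureScale = 0)
  img <- generateGelImage(spec, c(16, 16), seed = 1, illuminationMax = 0,
                          textureAmp = 0)
  expect_true(all(img == 0.6))
})

test_that("image generation is seed-deterministic and in range", {
  spec <- gelClassSpec("s", 25)
  a <- generateGelImage(spec, c(32, 32), seed = 9)
  b <- generateGelImage(spec, c(32, 32), seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generateGelImage(spec, c(32, 32), seed = 10)))
  expect_true(all(is.finite(a)) && min(a) >= 0 && max(a) <= 1)
})

test_that("denser pore fields darken the image", {
  dense <- gelClassSpec("d", 40); sparse <- gelClassSpec("s", 5)
  darker <- vapply(1:25, function(s) {
    mean(generateGelImage(dense, c(32, 32), seed = s)) <
      mean(generateGelImage(sparse, c(32, 32), seed = s + 10000))
  }, logical(1))
  expect_gte(mean(darker), 0.95)
})

test_that("generated datasets are balanced with the stated structure", {
  gs <- generateGelDataset(gelGenConfig(nClasses = 10, perClass = 10,
                                        imageSize = c(32, 32), seed = 2))
  expect_identical(ncol(gs), 100L)
  expect_identical(as.vector(table(classLabels(gs))), rep(10L, 10))
  expect_identical(imageDim(gs), c(32L, 32L))
  expect_true(validObject(gs))
  # regeneration is exact
  gs2 <- generateGelDataset(gelGenConfig(nClasses = 10, perClass = 10,
                                         imageSize = c(32, 32), seed = 2))
  expect_identical(SummarizedExperiment::assay(gs),
                   SummarizedExperiment::assay(gs2))
})

test_that("identical class specs are indistinguishable (chance level)", {
  rates <- vapply(1:4, function(ds) {
    specs <- list(gelClassSpec("a", 20), gelClassSpec("b", 20))
    gs <- generateGelDataset(gelGenConfig(classes = specs, perClass = 10,
                                          imageSize = c(32, 32), seed = ds))
    unname(meanRates(runExperiment(gs, experimentConfig("pca", 5, dims = 4L,
                                                        repeats = 5, seed = 9))))
  }, numeric(1))
  expect_gt(mean(rates), 30)
  expect_lt(mean(rates), 70)
})

test_that("the first principal component tracks the gel-state order", {
  cl5 <- defaultGelClasses(5, layout = "iid")
  gs <- generateGelDataset(gelGenConfig(classes = cl5, perClass = 8,
                                        imageSize = c(32, 32), seed = 4))
  pm <- fitPCA(gs, 1)
  sc <- as.vector(projectFeatures(pm, gs))
  rho <- stats::cor(sc, rep(1:5, each = 8), method = "spearman")
  expect_gte(abs(rho), 0.8)
})

test_that("widening the class gap never hurts recognition", {
  rateAtGap <- function(gap, seed) {
    specs <- list(gelClassSpec("lo", 20),
                  gelClassSpec("hi", 20 + gap))
    gs <- generateGelDataset(gelGenConfig(classes = specs, perClass = 8,
                                          imageSize = c(32, 32), seed = seed))
    unname(meanRates(runExperiment(gs, experimentConfig("pca", 4, dims = 2L,
                                                        repeats = 4, seed = 7))))
  }
  gaps <- c(5, 25, 60)
  means <- vapply(gaps, function(g)
    mean(vapply(1:3, function(s) rateAtGap(g, s), numeric(1))), numeric(1))
  expect_true(all(diff(means) >= -5))   # monotone within sampling noise
})

test_that("BSS sources are standardized, uncorrelated and reproducible", {
  S <- generateBssSignals(2000, seed = 3)
  expect_identical(rownames(S), c("sine", "square", "sawtooth", "noise"))
  expect_lt(max(abs(rowMeans(S))), 1e-10)
  expect_lt(max(abs(apply(S, 1, stats::var) - 1)), 1e-6)
  cm <- stats::cor(t(S))
  expect_lte(max(abs(cm[upper.tri(cm)])), 0.1)
  expect_identical(S, generateBssSignals(2000, seed = 3))
  expect_error(generateBssSignals(100), ">= 512")
})

test_that("shared layouts make within-class structure, iid does not", {
  shared <- defaultGelClasses(2, layout = "shared")
  gsS <- generateGelDataset(gelGenConfig(classes = shared, perClass = 6,
                                         imageSize = c(32, 32), seed = 5))
  iid <- defaultGelClasses(2, layout = "iid")
  gsI <- generateGelDataset(gelGenConfig(classes = iid, perClass = 6,
                                         imageSize = c(32, 32), seed = 5))
  corWithin <- function(gs) {
    px <- SummarizedExperiment::assay(gs)
    idx <- which(classLabels(gs) == classLabels(gs)[1])
    mean(stats::cor(px[, idx])[upper.tri(diag(length(idx)))])
  }
  expect_gt(corWithin(gsS), corWithin(gsI))
})
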