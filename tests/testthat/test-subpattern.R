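test_that("block partition tiles the image exactly, row-major", {
  img <- matrix(1:64, 8, 8)
  b <- partitionBlocks(img, c(4, 4))
  expect_length(b, 16L)
  expect_identical(dim(b[[1]]), c(2L, 2L))
  expect_identical(b[[1]], img[1:2, 1:2])
  expect_identical(b[[2]], img[1:2, 3:4])      # row-major block order
  expect_identical(assembleBlocks(b, c(4, 4)), img)
  # the degenerate 1x1 grid is the whole image
  expect_identical(partitionBlocks(img, c(1, 1))[[1]], img)
  r <- withr::with_seed(2, matrix(rnorm(32 * 32), 32, 32))
  expect_identical(assembleBlocks(partitionBlocks(r, c(2, 4)), c(2, 4)), r)
  expect_error(partitionBlocks(img, c(3, 3)), "not divisible")
})

test_that("subpattern fits are deterministic with simplex weights", {
  gs <- tinyGelSet(3, 4, c(16, 16), seed = 14)
  m1 <- fitSubpattern(gs, grid = c(2, 2), nComponents = 4, seed = 5)
  m2 <- fitSubpattern(gs, grid = c(2, 2), nComponents = 4, seed = 5)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@blockFeatures, m2@blockFeatures)
  expect_length(m1@blockModels, 4L)
  expect_true(all(m1@weights >= 0))
  expect_lt(abs(sum(m1@weights) - 1), 1e-10)
  expect_identical(m1@blockShape, c(8L, 8L))
  expect_error(fitSubpattern(gs, grid = c(3, 3)), "not divisible")
})

test_that("adaptive weights normalize recognition rates", {
  gs <- tinyGelSet(2, 4, c(16, 16), seed = 15)
  m <- fitSubpattern(gs, grid = c(2, 2), nComponents = 4, seed = 6)
  # evaluating on the training set itself: every block is perfect, so
  # rates {1,1,1,1} normalize to uniform weights
  w <- adaptiveWeights(m, evalSet = gs)
  expect_equal(w, rep(0.25, 4))
  expect_error(adaptiveWeights(m, evalSet = gs[, 0]), "non-empty")
})

test_that("an occluded quadrant loses voting weight", {
  drops <- vapply(1:3, function(s) {
    b <- gelBenchmarkDataset(s, perClass = 8)
    sp <- randomSplit(b, 5, seed = s, repeatIndex = 1)
    ev <- occludeImages(sp$test, c(1L, 32L, 1L, 32L), fill = 0)
    m <- fitSubpattern(sp$train, grid = c(2, 2), nComponents = 8, seed = s)
    adaptiveWeights(m, ev)[1] < 0.25
  }, logical(1))
  expect_gte(sum(drops), 2L)
})

test_that("weighted votes aggregate per-block nearest neighbours", {
  gs <- tinyGelSet(3, 4, c(16, 16), seed = 16)
  m <- fitSubpattern(gs, grid = c(2, 2), nComponents = 4, seed = 7)
  # a training image wins its own class unanimously: score 1
  out <- classifyWeightedVote(m, getImage(gs, 1))
  expect_identical(out$label, classLabels(gs)[1])
  expect_equal(unname(out$scores[out$label]), 1)
  expect_equal(sum(out$scores), 1)
  # batch interface agrees with one-at-a-time calls
  batch <- classifyWeightedVote(m, gs)
  single <- vapply(seq_len(ncol(gs)), function(i)
    classifyWeightedVote(m, getImage(gs, i))$label, character(1))
  expect_identical(as.vector(batch), single)
  expect_error(classifyWeightedVote(m, matrix(0, 8, 8)), "shape")
})

test_that("a 1x1 grid reduces exactly to plain ICA with nearest neighbour", {
  gs <- generateGelDataset(gelGenConfig(nClasses = 4, perClass = 6,
                                        imageSize = c(32, 32), seed = 18))
  sp <- randomSplit(gs, 3, seed = 8, repeatIndex = 1)
  sub <- fitSubpattern(sp$train, grid = c(1, 1), nComponents = 8, seed = 42)
  predS <- as.vector(classifyWeightedVote(sub, sp$test))
  ica <- fitICAFeatures(sp$train, nComponents = 8, seed = 42)
  predI <- nearestNeighbor(projectFeatures(ica, sp$train),
                           classLabels(sp$train),
                           projectFeatures(ica, sp$test))
  expect_identical(predS, predI)
  expect_identical(blockWeights(sub), 1)
})

test_that("weight maps export as CSV and heat image", {
  gs <- tinyGelSet(2, 4, c(16, 16), seed = 19)
  m <- fitSubpattern(gs, grid = c(2, 2), nComponents = 3, seed = 9)
  csv <- tempfile(fileext = ".csv"); img <- tempfile(fileext = ".png")
  wm <- writeWeightMap(m, csv, img)
  expect_identical(dim(wm), c(2L, 2L))
  expect_equal(as.vector(t(wm)), m@weights)
  expect_true(file.exists(csv) && file.exists(img))
  unlink(c(csv, img))
})

test_that("subpattern models survive the archive round trip", {
  gs <- tinyGelSet(2, 4, c(16, 16), seed = 20)
  m <- fitSubpattern(gs, grid = c(2, 2), nComponents = 3, seed = 10)
  path <- tempfile(fileext = ".rds")
  saveGelModel(m, path)
  back <- readGelModel(path)
  expect_identical(back@weights, m@weights)
  expect_identical(as.vector(classifyWeightedVote(back, gs)),
                   as.vector(classifyWeightedVote(m, gs)))
  unlink(path)
})
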