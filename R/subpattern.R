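# Subpattern-ICA: tile each image into a non-overlapping block grid, fit
# FastICA features per block independently, weight each block by its own
# nearest-neighbour recognition rate, and classify by weighted voting.

#' Partition an image into a non-overlapping block grid
#'
#' @param image numeric matrix whose dimensions are divisible by the grid.
#' @param grid integer(2): blocks per (row, col).
#' @return list of block matrices in row-major block order;
#'   \code{assembleBlocks} is the exact inverse.
#' @examples
#' b <- partitionBlocks(matrix(1:16, 4, 4), c(2, 2))
#' identical(assembleBlocks(b, c(2, 2)), matrix(1:16, 4, 4))
#' @export
partitionBlocks <- function(image, grid) {
  grid <- as.integer(grid)
  d <- dim(image)
  if (any(d %% grid != 0L)) {
    valid <- Filter(function(g) all(d %% g == 0L), seq_len(min(d)))
    stop("image dims ", paste(d, collapse = "x"),
         " not divisible by grid ", paste(grid, collapse = "x"),
         " (valid square grids: ",
         paste(sprintf("%dx%d", valid, valid), collapse = ", "), ")",
         call. = FALSE)
  }
  bs <- d %/% grid
  out <- vector("list", prod(grid))
  b <- 0L
  for (i in seq_len(grid[1L])) {
    for (j in seq_len(grid[2L])) {
      b <- b + 1L
      out[[b]] <- image[((i - 1L) * bs[1L] + 1L):(i * bs[1L]),
                        ((j - 1L) * bs[2L] + 1L):(j * bs[2L]), drop = FALSE]
    }
  }
  out
}

#' @rdname partitionBlocks
#' @param blocks list of equally sized blocks in row-major block order.
#' @export
assembleBlocks <- function(blocks, grid) {
  grid <- as.integer(grid)
  stopIfNot(length(blocks) == prod(grid), "block count must equal prod(grid)")
  rows <- lapply(seq_len(grid[1L]), function(i)
    do.call(cbind, blocks[(i - 1L) * grid[2L] + seq_len(grid[2L])]))
  do.call(rbind, rows)
}

# row-major pixel indices (into a vectorized image) of each block
blockIndexSets <- function(imageDim, grid) {
  tpl <- devectorizeImage(seq_len(prod(imageDim)), imageDim)
  lapply(partitionBlocks(tpl, grid), vectorizeImage)
}

# per-block seed; block 1 reuses the master seed so a 1x1 grid reproduces the
# plain-ICA pipeline exactly
blockSeed <- function(seed, b) {
  as.integer((as.double(seed) + (b - 1) * 104729) %% 2147483647)
}

#' Fit a Subpattern-ICA model
#'
#' Each grid cell's sub-images (vectorized row-major) form an independent
#' observation set fitted with whitening + FastICA; training features are
#' cached per block for nearest-neighbour voting. Block weights are set by
#' leave-one-out recognition over the training set (see
#' \code{\link{adaptiveWeights}}); pass an explicit \code{evalSet} to use a
#' held-out split instead.
#'
#' @param train a \code{\link{GelImageSet}}.
#' @param grid integer(2) block grid (default 4x4).
#' @param nComponents components per block (capped at the block rank).
#' @param seed master seed; block b uses a derived stream, block 1 the seed
#'   itself.
#' @param metric distance for the per-block votes ("euclidean" or "cosine").
#' @param evalSet optional labeled \code{GelImageSet} for weight estimation.
#' @param betaOrder reorder each block's components by ascending evaluation
#'   factor beta (computed on the block's training features) so that
#'   truncated votes use the most discriminative components first; applied
#'   only when the training classes are balanced with >= 2 samples each.
#'   Irrelevant when voting at full dimension.
#' @param ... passed to \code{\link{runFastICA}}.
#' @return a \linkS4class{SubpatternModel}.
#' @export
fitSubpattern <- function(train, grid = c(4L, 4L), nComponents = 100L,
                          seed = 1L, metric = "euclidean", evalSet = NULL,
                          betaOrder = TRUE, ...) {
  stopIfNot(is(train, "GelImageSet"), "train must be a GelImageSet")
  grid <- as.integer(grid)
  d <- imageDim(train)
  if (any(d %% grid != 0L))
    stop("image dims ", paste(d, collapse = "x"), " not divisible by grid ",
         paste(grid, collapse = "x"), call. = FALSE)
  idxSets <- blockIndexSets(d, grid)
  px <- pixelMatrix(train)
  nb <- prod(grid)
  models <- vector("list", nb)
  feats <- vector("list", nb)
  for (b in seq_len(nb)) {
    Xb <- px[idxSets[[b]], , drop = FALSE]
    mb <- tryCatch(
      runFastICA(Xb, nComponents, seed = blockSeed(seed, b), ...),
      error = function(e) stop("block ", b, ": ", conditionMessage(e),
                               call. = FALSE))
    mb@imageDim <- as.integer(d %/% grid)
    fb <- projectFeatures(mb, Xb)
    if (is.null(dim(fb))) fb <- matrix(fb, nrow = 1L)
    labs <- classLabels(train)
    counts <- table(labs)
    if (betaOrder && nrow(fb) > 1L && min(counts) >= 2L &&
        length(unique(counts)) == 1L) {
      sc <- evaluationFactors(t(fb), labs)
      ord <- order(sc$beta, sc$feature)
      mb@unmixing <- mb@unmixing[ord, , drop = FALSE]
      mb@mixingEstimate <- mb@mixingEstimate[, ord, drop = FALSE]
      fb <- fb[ord, , drop = FALSE]
    }
    models[[b]] <- mb
    feats[[b]] <- fb
  }
  model <- new("SubpatternModel", grid = grid, blockShape = as.integer(d %/% grid),
               blockModels = models, blockFeatures = feats,
               trainLabels = classLabels(train),
               weights = rep(1 / nb, nb), imageDim = d, metric = metric)
  model@weights <- adaptiveWeights(model, evalSet)
  model
}

#' Adaptive per-block voting weights
#'
#' Every block is scored by the nearest-neighbour recognition rate its own
#' features achieve on \code{evalSet} (or, when none is given, by
#' leave-one-out over the cached training features — avoiding test-set
#' leakage). Rates are normalized to sum to 1; if every block scores zero,
#' uniform weights are returned.
#'
#' @param model a \linkS4class{SubpatternModel}.
#' @param evalSet optional labeled \code{GelImageSet} disjoint from training.
#' @return numeric weight vector (one per block, summing to 1).
#' @export
adaptiveWeights <- function(model, evalSet = NULL) {
  nb <- prod(model@grid)
  labs <- model@trainLabels
  rates <- numeric(nb)
  if (is.null(evalSet)) {
    for (b in seq_len(nb)) {
      f <- model@blockFeatures[[b]]
      n <- ncol(f)
      pred <- vapply(seq_len(n), function(i) {
        nearestNeighbor(f[, -i, drop = FALSE], labs[-i], f[, i], model@metric)
      }, character(1))
      rates[b] <- mean(pred == labs)
    }
  } else {
    stopIfNot(is(evalSet, "GelImageSet") && ncol(evalSet) >= 1L,
              "evalSet must be a non-empty GelImageSet")
    idxSets <- blockIndexSets(model@imageDim, model@grid)
    px <- pixelMatrix(evalSet)
    truth <- classLabels(evalSet)
    for (b in seq_len(nb)) {
      fq <- projectFeatures(model@blockModels[[b]], px[idxSets[[b]], , drop = FALSE])
      if (is.null(dim(fq))) fq <- matrix(fq, nrow = 1L)
      pred <- nearestNeighbor(model@blockFeatures[[b]], labs, fq, model@metric)
      rates[b] <- mean(pred == truth)
    }
  }
  if (sum(rates) == 0) rep(1 / nb, nb) else rates / sum(rates)
}

#' Weighted-vote classification of one or many samples
#'
#' Each block projects the query's corresponding sub-image into its own
#' feature space and votes for the class of the nearest training sub-image;
#' a class's score is the summed weight of the blocks voting for it, and the
#' highest score wins (ties to the lower class index, deterministically).
#'
#' @param model a \linkS4class{SubpatternModel}.
#' @param x a single image matrix or a \code{GelImageSet}.
#' @param dims optional per-block feature dimension truncation (leading
#'   components; capped at each block's component count).
#' @return for one sample, list(label, scores); for a set, a character
#'   vector of labels with the score matrix as attribute "scores".
#' @export
classifyWeightedVote <- function(model, x, dims = NULL) {
  if (is.matrix(x)) {
    stopIfNot(all(dim(x) == model@imageDim),
              "sample shape does not match the model")
    px <- cbind(vectorizeImage(x))
  } else {
    stopIfNot(is(x, "GelImageSet"), "x must be an image matrix or GelImageSet")
    stopIfNot(all(imageDim(x) == model@imageDim),
              "sample shape does not match the model")
    px <- pixelMatrix(x)
  }
  classes <- sort(unique(model@trainLabels))
  nq <- ncol(px)
  scores <- matrix(0, length(classes), nq, dimnames = list(classes, NULL))
  idxSets <- blockIndexSets(model@imageDim, model@grid)
  for (b in seq_len(prod(model@grid))) {
    ftr <- model@blockFeatures[[b]]
    if (!is.null(dims)) {
      kk <- min(dims, nrow(ftr))
      ftr <- ftr[seq_len(kk), , drop = FALSE]
    }
    fq <- projectFeatures(model@blockModels[[b]], px[idxSets[[b]], , drop = FALSE])
    if (is.null(dim(fq))) fq <- matrix(fq, ncol = nq)
    if (!is.null(dims)) fq <- fq[seq_len(nrow(ftr)), , drop = FALSE]
    votes <- nearestNeighbor(ftr, model@trainLabels, fq, model@metric)
    scores[cbind(match(votes, classes), seq_len(nq))] <-
      scores[cbind(match(votes, classes), seq_len(nq))] + model@weights[b]
  }
  labels <- classes[apply(scores, 2L, which.max)]   # which.max: lowest index wins ties
  if (nq == 1L && is.matrix(x)) {
    list(label = labels, scores = scores[, 1L])
  } else {
    attr(labels, "scores") <- scores
    labels
  }
}

#' Write the block-weight map
#'
#' Exports the per-block weights as a CSV matrix and, optionally, as a
#' rescaled grayscale heat image (lighter = larger weight).
#'
#' @param model a \linkS4class{SubpatternModel}.
#' @param csvPath output CSV path.
#' @param imagePath optional PNG path for the heat image.
#' @return invisibly, the weight matrix (grid shape).
#' @export
writeWeightMap <- function(model, csvPath, imagePath = NULL) {
  wm <- matrix(model@weights, model@grid[1L], model@grid[2L], byrow = TRUE)
  utils::write.csv(wm, csvPath, row.names = FALSE)
  if (!is.null(imagePath)) {
    up <- kronecker(rescale01(wm), matrix(1, 32, 32))
    writeImageFile(up, imagePath)
  }
  invisible(wm)
}
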