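# Nearest-neighbour classification, recognition-rate metrics, and the
# repeated-random-split experiment harness.

#' Nearest-neighbour classification
#'
#' Assigns each query the label of its minimum-distance training feature;
#' distance ties go to the lowest training index.
#'
#' @param trainFeatures matrix (features x n_train).
#' @param trainLabels character, one per training column.
#' @param query numeric vector, or matrix (features x n_query).
#' @param metric "euclidean" (default) or "cosine" (1 - cosine similarity).
#' @return character label(s), one per query.
#' @export
nearestNeighbor <- function(trainFeatures, trainLabels, query,
                            metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (!is.matrix(trainFeatures)) trainFeatures <- matrix(trainFeatures, nrow = 1L)
  if (!is.matrix(query)) {
    stopIfNot(length(query) == nrow(trainFeatures),
              "query dimension does not match training features")
    query <- matrix(query, nrow = nrow(trainFeatures))
  }
  stopIfNot(nrow(query) == nrow(trainFeatures),
            "query dimension does not match training features")
  stopIfNot(ncol(trainFeatures) == length(trainLabels),
            "one label per training feature required")
  if (metric == "euclidean") {
    tn <- colSums(trainFeatures^2)
    qn <- colSums(query^2)
    d2 <- outer(tn, qn, "+") - 2 * crossprod(trainFeatures, query)
  } else {
    tn <- sqrt(pmax(colSums(trainFeatures^2), 1e-300))
    qn <- sqrt(pmax(colSums(query^2), 1e-300))
    d2 <- 1 - crossprod(trainFeatures, query) / outer(tn, qn)
  }
  trainLabels[apply(d2, 2L, which.min)]   # which.min takes the lowest index on ties
}

#' Recognition rate in percent
#'
#' @param predicted,truth equal-length label vectors.
#' @return 100 * fraction correct.
#' @export
recognitionRate <- function(predicted, truth) {
  stopIfNot(length(predicted) == length(truth) && length(truth) >= 1L,
            "predicted and truth must have equal positive length")
  100 * mean(predicted == truth)
}

# occlude a rectangular region of every image in a set
#' Occlude a region of every image in a set
#'
#' Fills the rectangular region (row0..row1, col0..col1) of a fraction of the
#' images with a constant value — the local-corruption nuisance used in the
#' robustness benchmarks.
#'
#' @param x a \code{\link{GelImageSet}}.
#' @param region integer(4): (row0, row1, col0, col1), inclusive.
#' @param fill constant fill value in [0,1] (default 0).
#' @param fraction fraction of images affected (default 1 = all).
#' @param seed seed used to pick the affected images when fraction < 1.
#' @return a new \code{GelImageSet}.
#' @export
occludeImages <- function(x, region, fill = 0, fraction = 1, seed = 1L) {
  stopIfNot(length(region) == 4L, "region must be (row0, row1, col0, col1)")
  px <- pixelMatrix(x)
  d <- imageDim(x)
  mask <- matrix(FALSE, d[1L], d[2L])
  mask[region[1L]:region[2L], region[3L]:region[4L]] <- TRUE
  rows <- which(vectorizeImage(mask))
  pick <- if (fraction >= 1) seq_len(ncol(px)) else
    withSeed(childSeed(seed, 303L), sort(sample(ncol(px), round(fraction * ncol(px)))))
  px[rows, pick] <- fill
  out <- x
  SummarizedExperiment::assay(out, "pixels") <- px
  out
}

# eigen-based feature pairs, fitted once at full rank; sweeps truncate the
# leading (eigenvalue-ordered) components
eigenFeatures <- function(algorithm, train, test, config) {
  m <- switch(algorithm,
    pca = fitPCACore(pixelMatrix(train), NULL, imageDim(train)),
    wavelet_pca = fitWaveletPCA(train, NULL, wavelet = config@wavelet),
    stop("unknown algorithm '", algorithm, "' (valid: pca, wavelet_pca, ica, ",
         "subpattern_ica)", call. = FALSE)
  )
  list(train = projectFeatures(m, train), test = projectFeatures(m, test),
       rank = m@retained)
}

# ICA feature pair at one dimension d: a d-component model (whitening capped
# at d), using all d features
icaFeaturesAtDim <- function(train, test, d, seed) {
  m <- fitICAFeatures(train, nComponents = d, seed = seed)
  ftr <- projectFeatures(m, train)
  fte <- projectFeatures(m, test)
  if (is.null(dim(ftr))) { ftr <- matrix(ftr, 1L); fte <- matrix(fte, nrow = 1L) }
  list(train = ftr, test = fte, dim = m@nComponents)
}

#' Run a repeated-random-split recognition experiment
#'
#' For each repeat: draw a seeded per-class split, fit the configured
#' algorithm on the training half, sweep the requested feature dimensions,
#' classify the test half by nearest neighbour, and record the recognition
#' rate. Eigen-based models (PCA, Wavelet-PCA) are fitted once at full rank
#' and swept by truncating the eigenvalue-ordered components; ICA and
#' Subpattern-ICA have no canonical component order, so each swept dimension
#' d uses its own d-component fit (whitening capped at d) — unless
#' \code{betaOrder} selects the beta-ranked truncation route. Requested
#' dimensions above the achievable rank are capped at it. Optionally every
#' test image is occluded after the split (\code{occludeTest}), for
#' robustness benchmarks.
#'
#' @param dataset a balanced \code{\link{GelImageSet}}.
#' @param config an \code{\link{experimentConfig}}.
#' @return an \linkS4class{ExperimentResult}.
#' @export
runExperiment <- function(dataset, config) {
  validObject(config)
  counts <- table(classLabels(dataset))
  if (any(counts <= config@trainPerClass))
    stop("trainPerClass = ", config@trainPerClass,
         " is infeasible for the smallest class (", min(counts), ")",
         call. = FALSE)
  dims <- config@dims
  rates <- matrix(NA_real_, config@repeats, length(dims))
  effDim <- rep(Inf, length(dims))
  for (r in seq_len(config@repeats)) {
    sp <- randomSplit(dataset, config@trainPerClass, seed = config@seed,
                      repeatIndex = r)
    test <- sp$test
    if (length(config@occludeTest))
      test <- occludeImages(test, config@occludeTest$region,
                            fill = config@occludeTest$fill %||% 0)
    truth <- classLabels(test)
    repSeed <- childSeed(config@seed, 1000L + r)
    if (config@algorithm == "subpattern_ica") {
      # each swept dimension is its own per-block component count
      for (j in seq_along(dims)) {
        model <- fitSubpattern(sp$train, grid = config@grid,
                               nComponents = dims[j], seed = repSeed,
                               metric = config@metric)
        blockK <- min(vapply(model@blockModels, function(m) m@nComponents, 1L))
        pred <- classifyWeightedVote(model, test)
        rates[r, j] <- recognitionRate(as.vector(pred), truth)
        effDim[j] <- min(effDim[j], blockK)
      }
    } else if (config@algorithm == "ica") {
      if (config@betaOrder) {
        # spec'd alternative: one fit at the largest dimension, per-dim
        # selection of the d smallest-beta components (needs balance, P >= 2)
        ff <- icaFeaturesAtDim(sp$train, test, max(dims), repSeed)
        labs <- classLabels(sp$train)
        counts <- table(labs)
        ord <- if (nrow(ff$train) > 1L && min(counts) >= 2L &&
                   length(unique(counts)) == 1L) {
          sc <- evaluationFactors(t(ff$train), labs)
          order(sc$beta, sc$feature)
        } else seq_len(nrow(ff$train))
        for (j in seq_along(dims)) {
          k <- min(dims[j], ff$dim)
          sel <- ord[seq_len(k)]
          pred <- nearestNeighbor(ff$train[sel, , drop = FALSE], labs,
                                  ff$test[sel, , drop = FALSE], config@metric)
          rates[r, j] <- recognitionRate(pred, truth)
          effDim[j] <- min(effDim[j], k)
        }
      } else {
        for (j in seq_along(dims)) {
          ff <- icaFeaturesAtDim(sp$train, test, dims[j], repSeed)
          pred <- nearestNeighbor(ff$train, classLabels(sp$train), ff$test,
                                  config@metric)
          rates[r, j] <- recognitionRate(pred, truth)
          effDim[j] <- min(effDim[j], ff$dim)
        }
      }
    } else {
      ff <- eigenFeatures(config@algorithm, sp$train, test, config)
      for (j in seq_along(dims)) {
        k <- min(dims[j], ff$rank)
        pred <- nearestNeighbor(ff$train[seq_len(k), , drop = FALSE],
                                classLabels(sp$train),
                                ff$test[seq_len(k), , drop = FALSE],
                                config@metric)
        rates[r, j] <- recognitionRate(pred, truth)
        effDim[j] <- min(effDim[j], k)
      }
    }
  }
  new("ExperimentResult", rates = rates, dims = dims,
      effectiveDims = as.integer(effDim), config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export experiment results
#'
#' @param result an \code{ExperimentResult}.
#' @param csvPath long-format CSV (algorithm, P, dim, repeat_index, rate).
#' @param jsonPath optional JSON summary (config echo + mean rates).
#' @export
writeResultCSV <- function(result, csvPath, jsonPath = NULL) {
  df <- as.data.frame(result)
  utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    cfg <- result@config
    jsonlite::write_json(list(
      algorithm = cfg@algorithm, P = cfg@trainPerClass, dims = result@dims,
      effective_dims = result@effectiveDims, repeats = cfg@repeats,
      seed = cfg@seed, metric = cfg@metric,
      mean_rates = unname(meanRates(result))
    ), jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}

#' Plot a recognition-rate-versus-dimension curve
#'
#' @param results one \code{ExperimentResult} or a named list of them.
#' @param file optional PNG path; NULL plots to the active device.
#' @export
plotRecognitionCurve <- function(results, file = NULL) {
  if (is(results, "ExperimentResult")) results <- list(results)
  if (is.null(names(results)))
    names(results) <- vapply(results, function(r) r@config@algorithm, "")
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  dims <- results[[1L]]@dims
  ys <- vapply(results, meanRates, numeric(length(dims)))
  graphics::matplot(dims, ys, type = "b", pch = 19, lty = 1,
                    xlab = "feature dimension", ylab = "recognition rate (%)",
                    ylim = c(0, 100))
  graphics::legend("bottomright", legend = names(results), col = seq_along(results),
                   pch = 19, lty = 1, bty = "n")
  invisible(ys)
}
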