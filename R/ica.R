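# FastICA feature extraction: PCA-based whitening (small-sample trick for
# wide data), fixed-point iteration with symmetric orthogonalization, a
# blind-source-separation demonstration, and the intra-/inter-class distance
# feature-evaluation statistic beta with selection.

#' Whiten observation columns
#'
#' Centers the columns of \code{X} and maps them onto unit-covariance
#' coordinates by PCA. Retained directions must (i) lie within the leading
#' set covering \code{varRetained} of the total variance and (ii) carry at
#' least \code{eigFloor} of the leading eigenvalue. The relative floor
#' matters because whitening inflates every retained direction to unit
#' variance: directions far below the leading eigenvalue are dominated by
#' sampling noise, and once inflated they corrupt whitened-space distances.
#' Sample (n-1) normalization is used, so \code{cov(t(Z))} is the identity.
#'
#' @param X numeric matrix, one observation per column (>= 2 columns).
#' @param varRetained fraction of variance the retained directions must
#'   cover (default 0.999).
#' @param maxComponents optional hard cap on retained directions.
#' @param eigFloor relative eigenvalue floor (default 0.01 of the leading
#'   eigenvalue).
#' @return list(Z, whitener, center, values): whitened data (d x n), the
#'   d x nrow(X) whitening matrix, the column mean, and the variances of the
#'   retained directions.
#' @export
whitenData <- function(X, varRetained = 0.999, maxComponents = Inf,
                       eigFloor = 0.01) {
  stopIfNot(is.matrix(X) && ncol(X) >= 2L, "X must be a matrix with >= 2 columns")
  center <- rowMeans(X)
  Xc <- X - center
  n <- ncol(X)
  # eigen of the smaller of (1/(n-1)) XX' and its Gram counterpart
  if (nrow(X) <= n) {
    e <- eigen(tcrossprod(Xc) / (n - 1), symmetric = TRUE)
    vals <- e$values
    U <- e$vectors
  } else {
    e <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    vals <- e$values
    keep0 <- vals > 0
    U <- Xc %*% e$vectors[, keep0, drop = FALSE]
    U <- sweep(U, 2L, sqrt(colSums(U^2)), "/")
    vals <- vals[keep0]
  }
  if (vals[1L] < .Machine$double.eps)
    stop("degenerate input: no variance to whiten", call. = FALSE)
  keep <- vals > max(.EIG_TOL, eigFloor) * vals[1L]
  cum <- cumsum(vals[keep]) / sum(vals[keep])
  d <- min(which(cum >= varRetained), sum(keep), maxComponents)
  vals <- vals[seq_len(d)]
  U <- fixSigns(U[, seq_len(d), drop = FALSE])
  K <- sweep(t(U), 1L, sqrt(vals), "/")     # d x nrow(X)
  list(Z = K %*% Xc, whitener = K, center = center, values = vals)
}

#' Fixed-point FastICA on whitened data
#'
#' Symmetric (parallel) FastICA: all rows of the unmixing matrix are updated
#' together and re-orthogonalized by \eqn{(WW^T)^{-1/2}W} each sweep.
#' Convergence is declared when the largest rowwise update residual
#' \eqn{\max_i |1 - |\langle w_i^{new}, w_i \rangle||} falls below \code{tol};
#' non-convergence is reported in the returned info, not raised.
#'
#' @param Z whitened matrix (d x n), unit covariance rows.
#' @param nComponents number of components (<= d).
#' @param nonlinearity "logcosh" (default) or "gauss" contrast derivative.
#' @param tol convergence tolerance (default 1e-4).
#' @param maxIter maximum sweeps (default 200).
#' @param seed integer; the random orthogonal initialization is drawn under
#'   this seed, so identical seeds give identical results.
#' @return list(W, iterations, residual, converged, kurtosis, identifiable):
#'   \code{kurtosis} holds each component's excess kurtosis on \code{Z};
#'   \code{identifiable} is FALSE when every component is indistinguishable
#'   from Gaussian (|kurtosis| <= 0.5), i.e. the rotation is arbitrary.
#' @export
fastIcaCore <- function(Z, nComponents, nonlinearity = c("logcosh", "gauss"),
                        tol = 1e-4, maxIter = 200L, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  d <- nrow(Z); n <- ncol(Z)
  k <- as.integer(nComponents)
  stopIfNot(k >= 1L && k <= d, "nComponents must lie in [1, nrow(Z)]")
  g <- switch(nonlinearity,
    logcosh = function(u) list(gu = tanh(u), gpu = 1 - tanh(u)^2),
    gauss = function(u) { e <- exp(-u^2 / 2); list(gu = u * e, gpu = (1 - u^2) * e) })
  W <- withSeed(seed, {
    qr.Q(qr(matrix(rnorm(d * k), d, k)))[, seq_len(k), drop = FALSE]
  })
  W <- t(W)                                  # k x d, orthonormal rows
  symDecorrelate <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), nrow(W)) %*%
      t(e$vectors) %*% W
  }
  W <- symDecorrelate(W)
  res <- Inf; it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    gv <- g(W %*% Z)
    Wnew <- (gv$gu %*% t(Z)) / n - diag(rowMeans(gv$gpu), k) %*% W
    Wnew <- symDecorrelate(Wnew)
    res <- max(abs(1 - abs(rowSums(Wnew * W))))
    W <- Wnew
    if (res < tol) break
  }
  W <- t(fixSigns(t(W)))
  # identifiability: the contrast is flat on Gaussian inputs, where the
  # fixed point is an arbitrary rotation; excess kurtosis of the recovered
  # components indistinguishable from 0 flags the estimate as unreliable
  Y <- W %*% Z
  kurt <- rowMeans(Y^4) / rowMeans(Y^2)^2 - 3
  list(W = W, iterations = it, residual = res, converged = res < tol,
       kurtosis = as.vector(kurt),
       identifiable = any(abs(kurt) > 0.5))
}

# assemble an ICAModel from whitening + core results
buildICAModel <- function(wh, core, imageDim = integer(0)) {
  composite <- core$W %*% wh$whitener            # k x mn
  new("ICAModel", center = wh$center, whitener = wh$whitener,
      whitenValues = wh$values, unmixing = core$W,
      mixingEstimate = MASS::ginv(composite),
      nComponents = nrow(core$W),
      convergence = core[c("iterations", "residual", "converged",
                           "kurtosis", "identifiable")],
      imageDim = as.integer(imageDim))
}

#' Whiten and unmix a raw observation matrix
#'
#' Convenience wrapper: \code{\link{whitenData}} followed by
#' \code{\link{fastIcaCore}}, packaged as an \linkS4class{ICAModel}.
#'
#' The whitening stage retains at most \code{nComponents} directions (the
#' leading ones by variance), so a d-component model is an orthogonal
#' rotation of the top-d whitened subspace — the convention of the standard
#' FastICA implementations. The requested count is capped at the achievable
#' whitened rank.
#'
#' @inheritParams fastIcaCore
#' @param X raw observation matrix (variables x samples, one observation per
#'   column).
#' @param varRetained,eigFloor whitening retention controls (see
#'   \code{\link{whitenData}}).
#' @return an \linkS4class{ICAModel}.
#' @export
runFastICA <- function(X, nComponents, nonlinearity = "logcosh", tol = 1e-4,
                       maxIter = 200L, seed = 1L, varRetained = 0.999,
                       eigFloor = 0.01) {
  wh <- whitenData(X, varRetained = varRetained,
                   maxComponents = as.integer(nComponents),
                   eigFloor = eigFloor)
  k <- min(as.integer(nComponents), nrow(wh$Z))
  core <- fastIcaCore(wh$Z, k, nonlinearity = nonlinearity, tol = tol,
                      maxIter = maxIter, seed = seed)
  buildICAModel(wh, core)
}

#' @rdname projectFeatures
#' @export
setMethod("projectFeatures", "ICAModel", function(model, x, ...) {
  V <- if (is.matrix(x) && length(model@imageDim) == 2L &&
           all(dim(x) == model@imageDim)) {
    cbind(vectorizeImage(x))
  } else if (is(x, "GelImageSet")) {
    stopIfNot(all(imageDim(x) == model@imageDim), "sample shape does not match the model")
    pixelMatrix(x)
  } else if (is.numeric(x) && (is.matrix(x) || is.vector(x))) {
    m <- if (is.matrix(x)) x else cbind(x)
    stopIfNot(nrow(m) == length(model@center), "sample length does not match the model")
    m
  } else stop("unsupported sample type", call. = FALSE)
  f <- model@unmixing %*% (model@whitener %*% (V - model@center))
  if (ncol(f) == 1L) as.vector(f) else f
})

#' FastICA image features
#'
#' Treats the vectorized training images as the observation set (one image
#' per column), whitens, and estimates independent base-image coordinates;
#' \code{projectFeatures} then maps any image of the same shape to its
#' component coordinates.
#'
#' @param train a \code{\link{GelImageSet}}.
#' @param nComponents components to extract; capped at the whitened rank
#'   (default \code{min(100, rank)}).
#' @param seed integer seed.
#' @param ... passed to \code{\link{runFastICA}}.
#' @return an \linkS4class{ICAModel} with image geometry attached.
#' @export
fitICAFeatures <- function(train, nComponents = 100L, seed = 1L, ...) {
  stopIfNot(is(train, "GelImageSet"), "train must be a GelImageSet")
  model <- runFastICA(pixelMatrix(train), nComponents, seed = seed, ...)
  model@imageDim <- imageDim(train)
  model
}

#' Reconstruct an image from ICA features
#'
#' Uses the pseudo-inverse mixing estimate; exact up to the variance
#' truncated away during whitening.
#'
#' @param model an \code{ICAModel} fitted on images.
#' @param features feature vector of length \code{nComponents}.
#' @return image matrix.
#' @export
reconstructICAImage <- function(model, features) {
  stopIfNot(length(features) == model@nComponents,
            "feature length must equal nComponents")
  v <- model@center + as.vector(model@mixingEstimate %*% features)
  devectorizeImage(v, model@imageDim)
}

# ------------------------------------------------------------- BSS demo

# exhaustive permutation/sign matching of recovered vs source rows (small k)
matchComponents <- function(sources, recovered) {
  k <- nrow(sources)
  cm <- abs(stats::cor(t(sources), t(recovered)))
  perms <- permutations(k)
  best <- NULL; bestScore <- -Inf
  for (i in seq_len(nrow(perms))) {
    sc <- sum(cm[cbind(seq_len(k), perms[i, ])])
    if (sc > bestScore) { bestScore <- sc; best <- perms[i, ] }
  }
  data.frame(source = seq_len(k), component = best,
             abs_correlation = cm[cbind(seq_len(k), best)])
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    m <- cbind(i, sub + (sub >= i))
    out <- rbind(out, m)
  }
  out
}

#' Blind-source-separation demonstration
#'
#' Generates four canonical sources (sine, square, sawtooth, uniform noise),
#' mixes them with a seeded random full-rank 4x4 matrix, unmixes with
#' whitening + FastICA, and reports permutation/sign-matched absolute
#' correlations between sources and recovered components.
#'
#' @param nSamples number of time samples (>= 512; default 2000).
#' @param seed integer seed for sources, mixing matrix and FastICA.
#' @param mixing optional 4x4 mixing matrix (random if NULL).
#' @return list(sources, mixed, recovered, mixing, match): signal matrices
#'   (4 x n) and a match report data frame.
#' @export
bssDemo <- function(nSamples = 2000L, seed = 1L, mixing = NULL) {
  stopIfNot(nSamples >= 512L, "nSamples must be >= 512")
  S <- generateBssSignals(nSamples, seed = seed)
  A <- if (is.null(mixing)) {
    withSeed(childSeed(seed, 101L), {
      repeat {
        A0 <- matrix(runif(16, -1, 1), 4, 4)
        if (rcond(A0) > 1e-3) break
      }
      A0
    })
  } else mixing
  X <- A %*% S
  # exact 4x4 mixing: keep all four directions however ill-conditioned A is
  wh <- whitenData(X, varRetained = 1, eigFloor = 0)
  core <- fastIcaCore(wh$Z, nComponents = 4L, seed = childSeed(seed, 202L))
  Y <- core$W %*% wh$Z
  list(sources = S, mixed = X, recovered = Y, mixing = A,
       match = matchComponents(S, Y),
       converged = core$converged)
}

# ----------------------------------------------- feature evaluation (beta)

#' Intra-/inter-class feature evaluation factors
#'
#' For each feature j on a balanced set of M classes x N samples:
#' \code{U[j]} is the mean absolute within-class pairwise difference averaged
#' over classes; \code{V[j]} is the mean absolute difference between
#' per-class feature means over all class pairs; \code{beta[j] = U[j]/V[j]}.
#' Small beta marks a feature whose between-class spread dominates its
#' within-class spread, i.e. a discriminative feature. A feature with zero
#' between-class separation gets \code{beta = Inf}.
#'
#' @param features numeric matrix, samples x features.
#' @param labels class label per sample (balanced: every class the same
#'   size, >= 2).
#' @return data.frame(feature, U, V, beta).
#' @examples
#' f <- cbind(c(0, 2, 10, 12))
#' evaluationFactors(f, c("a", "a", "b", "b"))  # U = 2, V = 10, beta = 0.2
#' @export
evaluationFactors <- function(features, labels) {
  stopIfNot(is.matrix(features) && nrow(features) == length(labels),
            "features must be samples x features with one label per row")
  counts <- table(labels)
  if (length(unique(counts)) != 1L)
    stop("classes must be balanced (equal sample counts); got ",
         paste(counts, collapse = ", "), call. = FALSE)
  N <- as.integer(counts[1L])
  stopIfNot(N >= 2L, "need >= 2 samples per class")
  classes <- names(counts)
  M <- length(classes)
  idx <- split(seq_along(labels), labels)
  U <- numeric(ncol(features)); Vm <- matrix(0, M, ncol(features))
  for (ci in seq_len(M)) {
    x <- features[idx[[classes[ci]]], , drop = FALSE]
    # mean over unordered within-class pairs of |x_u - x_v|, per feature
    s <- apply(x, 2L, function(col) {
      d <- abs(outer(col, col, "-"))
      sum(d) / (N * (N - 1))                  # mean over ordered pairs u != v
    })
    U <- U + s / M
    Vm[ci, ] <- colMeans(x)
  }
  V <- apply(Vm, 2L, function(mu) {
    d <- abs(outer(mu, mu, "-"))
    if (M < 2L) 0 else sum(d) / (M * (M - 1))
  })
  beta <- ifelse(V > 0, U / V, Inf)
  data.frame(feature = seq_len(ncol(features)), U = U, V = V, beta = beta)
}

#' Select the k most discriminative features
#'
#' Returns the indices of the k smallest evaluation factors beta, ties broken
#' by lower feature index; \code{Inf} sentinels rank last.
#'
#' @param scores data frame from \code{\link{evaluationFactors}}.
#' @param k number of features to keep.
#' @return integer vector of feature indices (ascending beta order).
#' @export
selectFeatures <- function(scores, k) {
  stopIfNot(k >= 1 && k <= nrow(scores), "k must lie in [1, feature count]")
  ord <- order(scores$beta, scores$feature)   # stable: ties by lower index
  sort(ord[seq_len(k)])
}

#' Export evaluation factors as CSV
#'
#' @param scores data frame from \code{\link{evaluationFactors}}.
#' @param path output CSV path.
#' @param k optionally mark the k selected features.
#' @export
writeFeatureScores <- function(scores, path, k = NULL) {
  out <- scores
  if (!is.null(k)) out$selected <- out$feature %in% selectFeatures(scores, k)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
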