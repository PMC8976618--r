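# Seeded synthetic data: multi-class gel-state grayscale images (pore
# texture on a smooth background, illumination drift, optional occlusion)
# and the four-source signal set for the blind-source-separation demo.
#
# The generator targets the statistical structure the recognition benchmarks
# need — a class-dependent texture signal (pore density rising with gel
# temperature), a within-class illumination nuisance, and an optional local
# occlusion nuisance — not photorealism.

# circulant separable Gaussian blur; sigma in pixels
gaussianBlurPeriodic <- function(m, sigma) {
  if (sigma <= 0) return(m)
  blur1 <- function(n) {
    half <- min(n %/% 2L, ceiling(4 * sigma))
    k <- stats::dnorm(-half:half, sd = sigma)
    k <- k / sum(k)
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      pos <- ((i - 1L + (-half:half)) %% n) + 1L
      for (j in seq_along(k)) B[i, pos[j]] <- B[i, pos[j]] + k[j]
    }
    B
  }
  Br <- blur1(nrow(m))
  Bc <- if (ncol(m) == nrow(m)) Br else blur1(ncol(m))
  Br %*% m %*% t(Bc)
}

# draw a Poisson pore configuration from a class spec
samplePoreLayout <- function(spec, size, seed) {
  withSeed(seed, {
    n <- rpois(1L, spec@poreDensity)
    data.frame(
      cy = runif(n, 1, size[1L]),
      cx = runif(n, 1, size[2L]),
      r = runif(n, spec@poreRadius[1L], spec@poreRadius[2L])
    )
  })
}

# subtract soft-edged dark disks at the layout's pore positions
renderPores <- function(img, layout, poreDepth) {
  if (!nrow(layout)) return(img)
  size <- dim(img)
  rowIdx <- matrix(seq_len(size[1L]), size[1L], size[2L])
  colIdx <- matrix(seq_len(size[2L]), size[1L], size[2L], byrow = TRUE)
  for (k in seq_len(nrow(layout))) {
    d2 <- (rowIdx - layout$cy[k])^2 + (colIdx - layout$cx[k])^2
    img <- img - poreDepth * exp(-(d2 / layout$r[k]^2)^2)
  }
  img
}

#' Generate one synthetic gel-state image
#'
#' A smooth correlated background at \code{baseIntensity}, darkened by
#' soft-edged circular pores, plus a random linear illumination gradient;
#' the result is clipped to [0,1]. By default the pore field is drawn fresh
#' (Poisson count, uniform positions, radii uniform in the spec's range).
#' If a \code{layout} is supplied, those pores are rendered with positional
#' jitter plus a small number of fresh extra pores — how
#' \code{\link{generateGelDataset}} emulates repeated photographs of
#' specimens sharing one gel state. Fully determined by its arguments.
#'
#' @param spec a \code{\link{gelClassSpec}}.
#' @param size integer(2) image size (default 128x128).
#' @param seed integer seed.
#' @param illuminationMax maximum amplitude of the linear shading field
#'   (default 0.1).
#' @param textureAmp amplitude of the smooth background texture
#'   (default 0.05).
#' @param poreDepth intensity drop at a pore center (default 0.35).
#' @param layout optional data.frame(cy, cx, r) of shared pore positions.
#' @param jitterSd positional jitter (pixels) applied to a shared layout.
#' @param extraPoreFrac fresh pores added per image, as a fraction of the
#'   spec's density, when a shared layout is used.
#' @param layoutKeep probability that each shared-layout pore is rendered in
#'   a given image (point-process thinning; specimens of one state share the
#'   configuration only partially). Ignored without a layout.
#' @return image matrix in [0,1].
#' @export
generateGelImage <- function(spec, size = c(128L, 128L), seed = 1L,
                             illuminationMax = 0.1, textureAmp = 0.05,
                             poreDepth = 0.35, layout = NULL,
                             jitterSd = 1.5, extraPoreFrac = 0.15,
                             layoutKeep = 0.8) {
  validObject(spec)
  size <- as.integer(size)
  withSeed(seed, {
    img <- matrix(spec@baseIntensity, size[1L], size[2L])
    if (textureAmp > 0 && spec@textureScale > 0) {
      noise <- gaussianBlurPeriodic(matrix(rnorm(prod(size)), size[1L], size[2L]),
                                    spec@textureScale)
      s <- stats::sd(noise)
      if (s > 0) img <- img + textureAmp * noise / s
    }
    pores <- if (is.null(layout)) {
      n <- rpois(1L, spec@poreDensity)
      data.frame(cy = runif(n, 1, size[1L]), cx = runif(n, 1, size[2L]),
                 r = runif(n, spec@poreRadius[1L], spec@poreRadius[2L]))
    } else {
      jit <- layout
      if (nrow(jit) && layoutKeep < 1)
        jit <- jit[runif(nrow(jit)) < layoutKeep, , drop = FALSE]
      if (nrow(jit)) {
        jit$cy <- jit$cy + rnorm(nrow(jit), sd = jitterSd)
        jit$cx <- jit$cx + rnorm(nrow(jit), sd = jitterSd)
      }
      nx <- rpois(1L, extraPoreFrac * spec@poreDensity)
      rbind(jit, data.frame(cy = runif(nx, 1, size[1L]),
                            cx = runif(nx, 1, size[2L]),
                            r = runif(nx, spec@poreRadius[1L],
                                      spec@poreRadius[2L])))
    }
    img <- renderPores(img, pores, poreDepth)
    if (illuminationMax > 0) {
      a <- runif(1, 0, illuminationMax)
      th <- runif(1, 0, 2 * pi)
      gx <- (seq_len(size[1L]) - (size[1L] + 1) / 2) / size[1L]
      gy <- (seq_len(size[2L]) - (size[2L] + 1) / 2) / size[2L]
      img <- img + a * (outer(gx, gy * 0, "+") * cos(th) +
                        outer(gx * 0, gy, "+") * sin(th)) * 2
    }
    clip01(img)
  })
}

#' Default ladder of gel-state class specifications
#'
#' Pore density and pore size both rise across classes — gel states at
#' increasing temperature grow more, larger pores — while background level
#' and texture are shared, so the pore structure is what distinguishes
#' classes. Each class uses a shared characteristic pore configuration
#' (\code{layout = "shared"}): images within a state are repeated
#' photographs of like specimens, not independent random fields.
#'
#' @param nClasses number of classes (default 10).
#' @param densityRange numeric(2), pore densities of the first and last class
#'   (default 5 to 50).
#' @param minRadiusRange numeric(2), minimum pore radius of the first and
#'   last class (default 2 to 5 pixels); each class's maximum radius is twice
#'   its minimum.
#' @param baseIntensity,textureScale shared \code{\link{gelClassSpec}}
#'   parameters.
#' @param layout "shared" (default) or "iid" pore placement.
#' @return list of \code{GelClassSpec}.
#' @export
defaultGelClasses <- function(nClasses = 10L, densityRange = c(5, 50),
                              minRadiusRange = c(2, 5), baseIntensity = 0.75,
                              textureScale = 3, layout = "shared") {
  dens <- seq(densityRange[1L], densityRange[2L], length.out = nClasses)
  rmin <- seq(minRadiusRange[1L], minRadiusRange[2L], length.out = nClasses)
  lapply(seq_len(nClasses), function(i)
    gelClassSpec(sprintf("state%02d", i), poreDensity = dens[i],
                 poreRadius = c(rmin[i], 2 * rmin[i]),
                 baseIntensity = baseIntensity,
                 textureScale = textureScale, layout = layout))
}

#' Configuration for a synthetic gel-state dataset
#'
#' @param classes list of \code{\link{gelClassSpec}} (default: the 10-state
#'   ladder of \code{\link{defaultGelClasses}}).
#' @param nClasses,perClass convenience: build \code{nClasses} default
#'   classes with \code{perClass} images each (perClass >= 2).
#' @param imageSize integer(2) (default 128x128).
#' @param illuminationMax illumination-gradient amplitude (default 0.1).
#' @param textureAmp background texture amplitude (default 0.05).
#' @param occlusion NULL, or list(region = c(row0, row1, col0, col1),
#'   fill = value, fraction = share of images affected).
#' @param seed integer master seed.
#' @return a config list (class "gelGenConfig") for
#'   \code{\link{generateGelDataset}}.
#' @export
gelGenConfig <- function(classes = NULL, nClasses = 10L, perClass = 10L,
                         imageSize = c(128L, 128L), illuminationMax = 0.1,
                         textureAmp = 0.05, occlusion = NULL, seed = 1L) {
  if (is.null(classes)) classes <- defaultGelClasses(nClasses)
  stopIfNot(perClass >= 2L, "perClass must be >= 2")
  stopIfNot(illuminationMax >= 0, "illuminationMax must be >= 0")
  structure(list(classes = classes, perClass = as.integer(perClass),
                 imageSize = as.integer(imageSize),
                 illuminationMax = illuminationMax, textureAmp = textureAmp,
                 occlusion = occlusion, seed = as.integer(seed)),
            class = "gelGenConfig")
}

#' Generate a balanced synthetic gel-state dataset
#'
#' @param config a \code{\link{gelGenConfig}}.
#' @return a \code{\link{GelImageSet}} with \code{length(classes)} classes x
#'   \code{perClass} images.
#' @examples
#' gs <- generateGelDataset(gelGenConfig(nClasses = 3, perClass = 4,
#'                                       imageSize = c(32, 32), seed = 7))
#' table(classLabels(gs))
#' @export
generateGelDataset <- function(config) {
  stopIfNot(inherits(config, "gelGenConfig"), "config must be a gelGenConfig")
  images <- list(); labels <- character(); ids <- character()
  for (ci in seq_along(config$classes)) {
    spec <- config$classes[[ci]]
    layout <- if (spec@layout == "shared")
      samplePoreLayout(spec, config$imageSize,
                       childSeed(config$seed, ci * 7757L)) else NULL
    for (j in seq_len(config$perClass)) {
      s <- childSeed(config$seed, ci * 10007L + j)
      images[[length(images) + 1L]] <-
        generateGelImage(spec, size = config$imageSize, seed = s,
                         illuminationMax = config$illuminationMax,
                         textureAmp = config$textureAmp, layout = layout)
      labels <- c(labels, spec@label)
      ids <- c(ids, sprintf("%s_%03d", spec@label, j))
    }
  }
  gs <- GelImageSet(images, labels = labels, ids = ids)
  occ <- config$occlusion
  if (!is.null(occ))
    gs <- occludeImages(gs, occ$region, fill = occ$fill %||% 0,
                        fraction = occ$fraction %||% 1,
                        seed = childSeed(config$seed, 424243L))
  gs
}

#' The canonical 10-state recognition benchmark
#'
#' The study conditions used throughout the package's benchmarks: the
#' 10-state class ladder of \code{\link{defaultGelClasses}} (rising pore
#' density and size, shared per-class pore configurations), 16 images per
#' state at 64x64, pronounced illumination variation (amplitude 0.3 — the
#' nuisance that makes training-set size matter), and per-image pore
#' thinning. Fully determined by \code{seed}.
#'
#' @param seed integer master seed.
#' @param perClass images per state (default 16).
#' @param imageSize integer(2) (default 64x64).
#' @return a \code{\link{GelImageSet}}.
#' @export
gelBenchmarkDataset <- function(seed, perClass = 16L, imageSize = c(64L, 64L)) {
  generateGelDataset(gelGenConfig(classes = defaultGelClasses(),
                                  perClass = perClass, imageSize = imageSize,
                                  illuminationMax = 0.3, seed = seed))
}

#' Four canonical source signals for the BSS demonstration
#'
#' Sine, square, sawtooth and uniform-noise signals at incommensurate
#' frequencies, each standardized to exactly zero mean and unit variance;
#' pairwise sample correlations stay near zero.
#'
#' @param nSamples number of samples (>= 512).
#' @param seed integer seed (for the noise channel).
#' @return 4 x nSamples matrix, rows named sine/square/sawtooth/noise.
#' @export
generateBssSignals <- function(nSamples = 2000L, seed = 1L) {
  stopIfNot(nSamples >= 512L, "nSamples must be >= 512")
  t <- seq_len(nSamples)
  S <- rbind(
    sine = sin(2 * pi * 0.0190 * t),
    square = sign(sin(2 * pi * 0.00731 * t)),
    sawtooth = 2 * ((0.00411 * t) %% 1) - 1,
    noise = withSeed(seed, runif(nSamples, -1, 1))
  )
  # standardize rows to exactly mean 0 and unit sample variance
  S <- t(scale(t(S)))
  attr(S, "scaled:center") <- NULL
  attr(S, "scaled:scale") <- NULL
  rownames(S) <- c("sine", "square", "sawtooth", "noise")
  S
}
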