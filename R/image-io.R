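# Dataset I/O: class-per-subdirectory image trees, PNG/TIFF/PGM files,
# preprocessing to a common square size, and seeded train/test splits.

# Rec.601 luma weights for colour -> grayscale
.LUMA <- c(0.299, 0.587, 0.114)

readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  stopIfNot(magic %in% c("P2", "P5"), paste0("not a PGM (P2/P5) file: ", path))
  # header tokens: width height maxval, '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    stopIfNot(length(ch) == 1L, paste0("truncated PGM header: ", path))
    if (ch == "#") {
      while (length(ch) == 1L && ch != "\n") ch <- readChar(con, 1L, useBytes = TRUE)
    } else if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
  } else {
    raw <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  stopIfNot(length(raw) == w * h, paste0("truncated PGM pixel data: ", path))
  matrix(raw / maxval, nrow = h, ncol = w, byrow = TRUE)
}

writePGM <- function(pixels, path, ascii = TRUE) {
  v <- as.integer(round(clip01(pixels) * 255))
  m <- matrix(v, nrow(pixels), ncol(pixels))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
    write(t(m), file = con, ncolumns = ncol(m))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0("P5\n", ncol(m), " ", nrow(m), "\n255\n"), con, eos = NULL)
    writeBin(as.raw(as.vector(t(m))), con)
  }
  invisible(path)
}

#' Read / write a single grayscale image file
#'
#' Supported formats (by extension): PNG, TIFF, PGM (P2/P5). 8-bit input is
#' scaled to [0,1]; colour input is converted to luminance (Rec.601 weights)
#' before scaling; an alpha channel is dropped.
#'
#' @param path file path; format inferred from the extension.
#' @return numeric matrix with values in [0,1].
#' @export
readImageFile <- function(path) {
  stopIfNot(file.exists(path), paste0("cannot read image file: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = readPGM(path),
    stop("unsupported image format '", ext, "' (supported: png, tif, tiff, pgm)",
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc >= 3L) {
      img <- .LUMA[1] * img[, , 1] + .LUMA[2] * img[, , 2] + .LUMA[3] * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  clip01(img)
}

#' @rdname readImageFile
#' @param pixels numeric matrix in [0,1].
#' @export
writeImageFile <- function(pixels, path) {
  ext <- tolower(tools::file_ext(path))
  pixels <- clip01(pixels)
  switch(ext,
    png = png::writePNG(pixels, path),
    tif = ,
    tiff = tiff::writeTIFF(pixels, path, bits.per.sample = 8L),
    pgm = writePGM(pixels, path),
    stop("unsupported image format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Crop and resize an image to a target square/rectangular size
#'
#' Non-target inputs are center-cropped to the largest sub-rectangle with the
#' target aspect ratio, then bilinearly resized.
#'
#' @param pixels numeric matrix.
#' @param targetSize integer(2) (rows, cols).
#' @return matrix of exactly \code{targetSize}.
#' @export
preprocessImage <- function(pixels, targetSize) {
  targetSize <- as.integer(targetSize)
  d <- dim(pixels)
  if (all(d == targetSize)) return(pixels)
  # center crop to target aspect ratio
  scale <- min(d / targetSize)
  cropDim <- floor(targetSize * scale)
  off <- floor((d - cropDim) / 2)
  cropped <- pixels[(off[1] + 1):(off[1] + cropDim[1]),
                    (off[2] + 1):(off[2] + cropDim[2]), drop = FALSE]
  if (all(dim(cropped) == targetSize)) return(cropped)
  out <- EBImage::resize(EBImage::Image(cropped), w = targetSize[1L],
                         h = targetSize[2L])
  clip01(matrix(EBImage::imageData(out), targetSize[1L], targetSize[2L]))
}

#' Load a class-structured image dataset
#'
#' Expects \code{root/<class_label>/<image files>}; every image is
#' preprocessed to \code{targetSize} (see \code{\link{preprocessImage}}).
#'
#' @param root dataset root directory.
#' @param targetSize integer(2) (rows, cols) all images are brought to.
#' @return a \code{\link{GelImageSet}}.
#' @export
loadDataset <- function(root, targetSize = c(128L, 128L)) {
  stopIfNot(dir.exists(root), paste0("dataset root not found: ", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  stopIfNot(length(classes) >= 1L, "dataset root contains no class directories")
  images <- list(); labels <- character(); ids <- character()
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|tif|tiff|pgm)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files))
      stop("class directory '", cl, "' contains no readable images", call. = FALSE)
    for (f in files) {
      images[[length(images) + 1L]] <- preprocessImage(readImageFile(f), targetSize)
      labels <- c(labels, cl)
      ids <- c(ids, paste0(cl, "/", basename(f)))
    }
  }
  GelImageSet(images, labels = labels, ids = ids)
}

#' Write a GelImageSet to a class-per-directory tree
#'
#' @param x a \code{GelImageSet}.
#' @param root output directory (created).
#' @param format "png", "tiff" or "pgm".
#' @return invisibly, the written file paths.
#' @export
writeDataset <- function(x, root, format = "png") {
  labs <- classLabels(x)
  paths <- character(ncol(x))
  for (i in seq_len(ncol(x))) {
    d <- file.path(root, labs[i])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(d, sprintf("%s_%04d.%s", labs[i], i, format))
    writeImageFile(getImage(x, i), paths[i])
  }
  invisible(paths)
}

#' @rdname writeDataset
#' @param path manifest CSV path (columns id, class, path, rows, cols).
#' @param filePaths optional file paths (as returned by \code{writeDataset}).
#' @export
writeManifest <- function(x, path, filePaths = NA_character_) {
  d <- imageDim(x)
  df <- data.frame(id = sampleIds(x), class = classLabels(x),
                   path = filePaths, rows = d[1L], cols = d[2L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Seeded per-class train/test split
#'
#' Draws exactly \code{trainPerClass} training images from every class; the
#' remainder forms the test set. The random stream is derived from
#' \code{(seed, repeatIndex)}, so each repeat of a multi-split protocol is
#' individually reproducible.
#'
#' @param x a \code{GelImageSet}.
#' @param trainPerClass integer P, training images per class (must be < class
#'   size for every class).
#' @param seed integer master seed.
#' @param repeatIndex integer repeat number (>= 1).
#' @return list(train =, test =) of \code{GelImageSet}.
#' @export
randomSplit <- function(x, trainPerClass, seed = 1L, repeatIndex = 1L) {
  labs <- classLabels(x)
  P <- as.integer(trainPerClass)
  counts <- table(labs)
  if (any(counts <= P))
    stop("trainPerClass = ", P, " must be smaller than every class size (min ",
         min(counts), ")", call. = FALSE)
  idx <- withSeed(childSeed(seed, repeatIndex), {
    unlist(lapply(split(seq_along(labs), labs), function(ii) sample(ii, P)))
  })
  idx <- sort(idx)
  list(train = x[, idx], test = x[, setdiff(seq_along(labs), idx)])
}
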