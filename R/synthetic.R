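#' Parameters of the synthetic tissue-image generator
#'
#' Bundles the knobs of the two-class synthetic histology emulator. The
#' generator reproduces the first/second-moment contrast the pipeline assumes
#' between benign (`N`) and adenocarcinoma (`ACA`) tissue: benign fields have a
#' lower mean intensity than malignant ones, and malignant fields carry darker,
#' denser nuclei. Defaults give a clearly separable two-class problem
#' (background means 0.3 vs 0.6, Gaussian texture sd 0.05).
#'
#' @param classMeanBenign background intensity of benign images, in \[0, 1\].
#' @param classMeanACA background intensity of adenocarcinoma images, in
#'   \[0, 1\]; larger than `classMeanBenign` by default.
#' @param nucleiDensityBenign,nucleiDensityACA expected nuclei blobs per 1e4
#'   pixels (nonnegative).
#' @param blobRadiusPx nucleus radius in pixels (> 0).
#' @param textureNoiseSD standard deviation of the additive Gaussian texture.
#' @param impulseNoiseP probability that a pixel is replaced by salt/pepper
#'   noise at generation time, in \[0, 1\].
#' @param seed default master seed.
#'
#' @return A validated list of class `SyntheticParams`.
#' @examples
#' p <- syntheticParams(textureNoiseSD = 0)
#' img <- generateTissueImage("N", p, seed = 1)
#' range(img)
#' @export
syntheticParams <- function(classMeanBenign = 0.3, classMeanACA = 0.6,
                            nucleiDensityBenign = 2, nucleiDensityACA = 6,
                            blobRadiusPx = 5, textureNoiseSD = 0.05,
                            impulseNoiseP = 0, seed = 1L) {
  .assertScalarNumeric(classMeanBenign, "classMeanBenign", 0, 1)
  .assertScalarNumeric(classMeanACA, "classMeanACA", 0, 1)
  .assertScalarNumeric(nucleiDensityBenign, "nucleiDensityBenign", 0)
  .assertScalarNumeric(nucleiDensityACA, "nucleiDensityACA", 0)
  .assertScalarNumeric(blobRadiusPx, "blobRadiusPx", 1e-6)
  .assertScalarNumeric(textureNoiseSD, "textureNoiseSD", 0)
  .assertScalarNumeric(impulseNoiseP, "impulseNoiseP", 0, 1)
  structure(list(classMeanBenign = classMeanBenign,
                 classMeanACA = classMeanACA,
                 nucleiDensityBenign = nucleiDensityBenign,
                 nucleiDensityACA = nucleiDensityACA,
                 blobRadiusPx = blobRadiusPx,
                 textureNoiseSD = textureNoiseSD,
                 impulseNoiseP = impulseNoiseP,
                 seed = as.integer(seed)),
            class = "SyntheticParams")
}

# Soft-edged dark disk: full depth inside the radius, Gaussian fall-off
# (sd = radius/3) outside, so segmentation boundaries stay nontrivial.
.stampBlob <- function(img, cy, cx, radius, depth) {
  side <- nrow(img)
  lo <- max(1L, floor(cy - 3 * radius)); hi <- min(side, ceiling(cy + 3 * radius))
  loj <- max(1L, floor(cx - 3 * radius)); hij <- min(side, ceiling(cx + 3 * radius))
  if (lo > hi || loj > hij) return(img)
  ii <- lo:hi; jj <- loj:hij
  r <- sqrt(outer((ii - cy)^2, (jj - cx)^2, "+"))
  excess <- pmax(0, r - radius)
  img[ii, jj] <- img[ii, jj] - depth * exp(-excess^2 / (2 * (radius / 3)^2))
  img
}

#' Generate one synthetic grayscale tissue image
#'
#' Deterministic given `(label, params, seed)`. The image is the class
#' background mean plus Gaussian texture, overlaid with dark soft-edged
#' circular "nuclei" at the class-specific density (adenocarcinoma nuclei are
#' darker and denser), then optionally corrupted with impulse noise and clipped
#' to \[0, 1\].
#'
#' @param label `"N"` or `"ACA"`.
#' @param params a [syntheticParams()] bundle.
#' @param seed integer seed for this image.
#' @param side image side in pixels (square output, 256 by default).
#' @return numeric `side x side` matrix of intensities in \[0, 1\].
#' @examples
#' img <- generateTissueImage("ACA", syntheticParams(), seed = 7, side = 64)
#' dim(img)
#' @export
generateTissueImage <- function(label, params = syntheticParams(), seed = 1L,
                                side = 256L) {
  if (!inherits(params, "SyntheticParams")) {
    stop("'params' must come from syntheticParams()", call. = FALSE)
  }
  label <- as.character(label)
  if (length(label) != 1L || !label %in% .classLevels) {
    stop("label must be \"N\" or \"ACA\"", call. = FALSE)
  }
  side <- as.integer(side)
  bgMean <- if (label == "N") params$classMeanBenign else params$classMeanACA
  density <- if (label == "N") params$nucleiDensityBenign else params$nucleiDensityACA
  depth <- if (label == "N") 0.25 else 0.35

  withr::with_seed(as.integer(seed), {
    img <- matrix(bgMean, side, side)
    if (params$textureNoiseSD > 0) {
      img <- img + matrix(stats::rnorm(side^2, 0, params$textureNoiseSD), side, side)
    }
    nBlobs <- stats::rpois(1, density * side^2 / 1e4)
    if (nBlobs > 0) {
      cy <- stats::runif(nBlobs, 1, side)
      cx <- stats::runif(nBlobs, 1, side)
      for (b in seq_len(nBlobs)) {
        img <- .stampBlob(img, cy[b], cx[b], params$blobRadiusPx, depth)
      }
    }
    img <- .clip01(img)
    if (params$impulseNoiseP > 0) {
      img <- addImpulseNoise(img, params$impulseNoiseP,
                             seed = deriveSeed(seed, 1L, 3L))
    }
    img
  })
}

#' Generate a balanced labeled synthetic dataset
#'
#' Produces `2 * nPerClass` images with per-image seeds derived
#' deterministically from the master seed and the image's index and label, so
#' regeneration does not depend on generation order.
#'
#' @param nPerClass images per class (>= 1).
#' @param params a [syntheticParams()] bundle.
#' @param seed master seed.
#' @param side image side in pixels.
#' @return A [LabeledImageSet-class] with labels interleaved `N, ACA, N, ...`.
#' @examples
#' ds <- generateDataset(2, syntheticParams(), seed = 1, side = 32)
#' table(labels(ds))
#' @export
generateDataset <- function(nPerClass, params = syntheticParams(), seed = 1L,
                            side = 256L) {
  nPerClass <- as.integer(nPerClass)
  if (is.na(nPerClass) || nPerClass < 1L) {
    stop("nPerClass must be >= 1", call. = FALSE)
  }
  labels <- rep(.classLevels, times = nPerClass)
  codes <- as.integer(labels == "ACA")
  seeds <- vapply(seq_along(labels), function(i) {
    deriveSeed(seed, i, codes[i])
  }, integer(1))
  imgs <- lapply(seq_along(labels), function(i) {
    generateTissueImage(labels[i], params, seed = seeds[i], side = side)
  })
  new("LabeledImageSet", images = imgs,
      labels = factor(labels, levels = .classLevels), seeds = seeds)
}

#' Corrupt an image with salt-and-pepper impulse noise
#'
#' Each pixel is independently replaced, with probability `p`, by 0 or 1 with
#' equal odds; remaining pixels are untouched.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param p corruption probability in \[0, 1\].
#' @param seed integer seed.
#' @return corrupted matrix of the same shape.
#' @examples
#' img <- matrix(0.5, 16, 16)
#' noisy <- addImpulseNoise(img, 0.2, seed = 1)
#' mean(noisy != img)
#' @export
addImpulseNoise <- function(image, p, seed = 1L) {
  .assertImage(image)
  .assertScalarNumeric(p, "p", 0, 1)
  if (p == 0) return(image)
  withr::with_seed(as.integer(seed), {
    hit <- stats::runif(length(image)) < p
    salt <- stats::runif(length(image)) < 0.5
    image[hit] <- as.numeric(salt[hit])
    image
  })
}

#' Write an image set to PNG files with a manifest
#'
#' Persists every image as an 8-bit grayscale PNG and writes a manifest CSV
#' with columns `image_path,label,seed`. Intensities are kept floating point
#' throughout the pipeline; quantization to 8 bits happens only here, at the
#' file boundary.
#'
#' @param imageSet a [LabeledImageSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
writeImageSet <- function(imageSet, dir) {
  stopifnot(is(imageSet, "LabeledImageSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(imageSet@images)
  paths <- file.path(dir, sprintf("img_%04d_%s.png", seq_len(n),
                                  as.character(imageSet@labels)))
  for (i in seq_len(n)) {
    png::writePNG(imageSet@images[[i]], paths[i])
  }
  manifest <- data.frame(image_path = paths,
                         label = as.character(imageSet@labels),
                         seed = imageSet@seeds)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
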