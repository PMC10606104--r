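#' Convert an RGB image to grayscale luminance
#'
#' Applies the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114). Inputs in
#' \[0, 255\] are rescaled to \[0, 1\] automatically; single-channel input
#' passes through unchanged.
#'
#' @param image either a numeric matrix (already grayscale) or an
#'   `h x w x 3` array.
#' @return numeric matrix of intensities in \[0, 1\].
#' @examples
#' rgb <- array(c(1, 0, 0), dim = c(1, 1, 3))
#' toGrayscale(rgb) # 0.299
#' @export
toGrayscale <- function(image) {
  if (is.matrix(image)) {
    if (max(image) > 1) image <- image / 255
    return(.clip01(image))
  }
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected a matrix or an h x w x 3 array", call. = FALSE)
  }
  if (max(image) > 1) image <- image / 255
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  dim(g) <- dim(image)[1:2]
  .clip01(g)
}

# 1-D bilinear sample positions for resizing n -> m (half-pixel alignment, the
# convention under which 2x downscale equals block means and identity resize
# is exact).
.bilinearCoords <- function(n, m) {
  pos <- (seq_len(m) - 0.5) * n / m + 0.5
  pos <- pmin(pmax(pos, 1), n)
  lo <- floor(pos)
  hi <- pmin(lo + 1, n)
  w <- pos - lo
  list(lo = as.integer(lo), hi = as.integer(hi), w = w)
}

#' Resize a grayscale image to a square side
#'
#' Bilinear interpolation with half-pixel alignment; output is clipped to
#' \[0, 1\]. Resizing to the current size returns the input exactly, and
#' constant images stay constant.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param side output side in pixels (>= 2); 256 by default.
#' @return `side x side` numeric matrix.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' dim(resizeSquare(img, 4))
#' @export
resizeSquare <- function(image, side = 256L) {
  .assertImage(image)
  side <- as.integer(side)
  if (is.na(side) || side < 2L) stop("side must be >= 2", call. = FALSE)
  if (nrow(image) == side && ncol(image) == side) return(image)
  rc <- .bilinearCoords(nrow(image), side)
  rows <- image[rc$lo, , drop = FALSE] * (1 - rc$w) +
          image[rc$hi, , drop = FALSE] * rc$w
  cc <- .bilinearCoords(ncol(image), side)
  out <- rows[, cc$lo, drop = FALSE] %*% diag(1 - cc$w, side) +
         rows[, cc$hi, drop = FALSE] %*% diag(cc$w, side)
  .clip01(out)
}

# Reflect-padded neighbourhood stack: returns an n_pixels x window^2 matrix of
# each pixel's window values (column-major pixel order).
.neighborStack <- function(image, window) {
  r <- (window - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  refl <- function(idx, n) {
    idx <- abs(idx - 1L) %% (2L * n - 2L)
    ifelse(idx >= n, 2L * n - 2L - idx, idx) + 1L
  }
  ri <- refl(seq(1L - r, h + r) - 1L + 1L, h)  # padded row indices
  ci <- refl(seq(1L - r, w + r) - 1L + 1L, w)
  padded <- image[ri, ci, drop = FALSE]
  offsets <- expand.grid(di = 0:(2L * r), dj = 0:(2L * r))
  out <- matrix(0, h * w, nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    out[, k] <- as.vector(padded[offsets$di[k] + seq_len(h),
                                 offsets$dj[k] + seq_len(w), drop = FALSE])
  }
  out
}

#' Two-stage adaptive median filter
#'
#' Classic adaptive median filtering for impulse noise. Stage A grows the
#' window (3, 5, ..., `maxWindow`) while the window median is itself an extreme
#' of the window; stage B replaces the centre pixel by the median only when the
#' centre is a window extreme. Impulse pixels are removed while edges are
#' preserved better than with a fixed-window median. Borders use reflect
#' padding.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param maxWindow odd maximum window side (>= 3), default 7.
#' @return filtered matrix of the same shape.
#' @examples
#' img <- matrix(0.5, 9, 9); img[5, 5] <- 1
#' adaptiveMedianFilter(img)[5, 5]
#' @export
adaptiveMedianFilter <- function(image, maxWindow = 7L) {
  .assertImage(image)
  maxWindow <- as.integer(maxWindow)
  if (is.na(maxWindow) || maxWindow < 3L || maxWindow %% 2L == 0L) {
    stop("maxWindow must be odd and >= 3", call. = FALSE)
  }
  n <- length(image)
  out <- as.vector(image)
  pending <- rep(TRUE, n)   # pixels whose window must still grow
  window <- 3L
  while (window <= maxWindow && any(pending)) {
    stack <- .neighborStack(image, window)[pending, , drop = FALSE]
    med <- apply(stack, 1, stats::median)
    mn <- do.call(pmin, as.data.frame(stack))
    mx <- do.call(pmax, as.data.frame(stack))
    px <- as.vector(image)[pending]
    resolved <- med > mn & med < mx
    # stage B: centre pixel kept unless it is itself an extreme
    isImpulse <- px <= mn | px >= mx
    idx <- which(pending)
    out[idx[resolved]] <- ifelse(isImpulse[resolved], med[resolved],
                                 px[resolved])
    if (window == maxWindow) {
      # window exhausted: fall back to the median
      out[idx[!resolved]] <- med[!resolved]
    }
    pending[idx[resolved]] <- FALSE
    window <- window + 2L
  }
  matrix(out, nrow(image), ncol(image))
}
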