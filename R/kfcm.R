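#' Control parameters for modified kernel fuzzy C-means
#'
#' @param c number of clusters (>= 2), default 2 (tissue vs background).
#' @param n fuzzifier exponent (> 1), default 2; larger values soften
#'   memberships, `n -> 1` approaches crisp k-means.
#' @param maxIter maximum alternating-update iterations.
#' @param tol centre-shift convergence threshold (nonnegative).
#' @param window odd side of the spatial neighbourhood feeding the fuzzy
#'   factor; `window = 1` disables the factor and recovers textbook FCM.
#' @param seed seed for centre jitter when `c > 2`.
#' @return validated list of class `KFCMControl`.
#' @seealso [runModifiedKFCM()]
#' @export
kfcmControl <- function(c = 2L, n = 2, maxIter = 100L, tol = 1e-4,
                        window = 3L, seed = 1L) {
  c <- as.integer(c)
  if (is.na(c) || c < 2L) stop("c must be >= 2", call. = FALSE)
  .assertScalarNumeric(n, "n")
  if (n <= 1) stop("fuzzifier n must be > 1", call. = FALSE)
  .assertScalarNumeric(tol, "tol", 0)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  structure(list(c = c, n = n, maxIter = as.integer(maxIter), tol = tol,
                 window = window, seed = as.integer(seed)),
            class = "KFCMControl")
}

#' Fuzzy membership update
#'
#' Computes the row-normalized membership matrix
#' `m_ij = 1 / sum_k (D_ij / D_ik)^(1/(n-1))` where `D_ij` is the squared
#' distance from pixel `i` to centre `j`, optionally augmented by a spatial
#' fuzzy-factor offset (`D = d^2 + F`). A pixel coinciding with one or more
#' centres gets a crisp assignment split equally over the coincident centres
#' rather than a division by zero.
#'
#' @param pixels numeric vector of pixel intensities.
#' @param centers numeric vector of cluster centres.
#' @param n fuzzifier (> 1).
#' @param offset optional nonnegative `length(pixels) x length(centers)`
#'   matrix added to the squared distances (the fuzzy factor).
#' @return membership matrix with rows summing to 1.
#' @examples
#' updateMembership(0.2, c(0, 1), n = 2) # ~ (0.941, 0.059)
#' @export
updateMembership <- function(pixels, centers, n = 2, offset = NULL) {
  if (length(pixels) < 1L) stop("need at least one pixel", call. = FALSE)
  D <- outer(pixels, centers, function(x, y) (x - y)^2)
  if (!is.null(offset)) {
    if (!all(dim(offset) == dim(D))) stop("offset shape mismatch", call. = FALSE)
    D <- D + offset
  }
  M <- D^(-1 / (n - 1))
  # crisp handling where some D is exactly zero
  zero <- !is.finite(M)
  zr <- rowSums(zero) > 0
  if (any(zr)) {
    M[zr, ] <- 0
    M[zr, ][zero[zr, , drop = FALSE]] <- 1
  }
  M / rowSums(M)
}

#' Cluster-centre update from memberships
#'
#' `y_j = sum_i m_ij^n x_i / sum_i m_ij^n`. A cluster whose membership column
#' is entirely zero keeps its previous centre (with a warning).
#'
#' @param pixels numeric vector of intensities.
#' @param M membership matrix (rows sum to 1).
#' @param n fuzzifier.
#' @param previous previous centres, used for empty clusters.
#' @return numeric vector of updated centres.
#' @export
updateCenters <- function(pixels, M, n = 2, previous = NULL) {
  W <- M^n
  denom <- colSums(W)
  num <- as.vector(crossprod(W, pixels))
  y <- num / denom
  empty <- denom == 0
  if (any(empty)) {
    warning("empty cluster(s) kept at previous centre")
    y[empty] <- if (!is.null(previous)) previous[empty] else mean(pixels)
  }
  y
}

#' Correlation distance between two intensity patches
#'
#' `1 - Pearson(a, b)`, clipped to \[0, 2\]. A constant patch carries no
#' correlation information, so the distance is defined as 1 (the midpoint)
#' rather than NaN.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return scalar in \[0, 2\].
#' @examples
#' correlationDistance(c(1, 2, 3), c(1, 3, 2)) # 0.5
#' @export
correlationDistance <- function(a, b) {
  if (length(a) != length(b)) stop("patch length mismatch", call. = FALSE)
  if (length(a) < 2L) stop("patches need >= 2 values", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1)
  min(2, max(0, 1 - stats::cor(a, b)))
}

# Full fuzzy-factor field: n_pixels x c matrix with
# F_ij = sum_{k in window(i), k != i} w_ik (1 - m_kj)^n,
# spatial weights w_ik = 1 / (1 + Chebyshev distance). Out-of-grid neighbours
# are skipped, so border pixels sum over fewer terms.
.fuzzyFactorField <- function(M, dims, window, n) {
  h <- dims[1]; w <- dims[2]
  r <- (window - 1L) %/% 2L
  cC <- ncol(M)
  F <- matrix(0, h * w, cC)
  if (r < 1L) return(F)
  for (j in seq_len(cC)) {
    G <- matrix((1 - M[, j])^n, h, w)
    acc <- matrix(0, h, w)
    for (di in -r:r) for (dj in -r:r) {
      if (di == 0L && dj == 0L) next
      wgt <- 1 / (1 + max(abs(di), abs(dj)))
      si <- seq_len(h) + di
      sj <- seq_len(w) + dj
      okI <- si >= 1L & si <= h
      okJ <- sj >= 1L & sj <= w
      acc[okI, okJ] <- acc[okI, okJ] + wgt * G[si[okI], sj[okJ], drop = FALSE]
    }
    F[, j] <- as.vector(acc)
  }
  F
}

#' Spatial fuzzy factor of one pixel and cluster
#'
#' `F'_ij = sum_{k in window(i), k != i} w_ik (1 - m_kj)^n` with spatial
#' weights `w_ik = 1 / (1 + Chebyshev pixel distance)`. The factor penalizes a
#' pixel's membership in cluster `j` when its neighbours do not belong to `j`,
#' which is what suppresses isolated (noise) pixels during clustering.
#'
#' @param M membership matrix (pixels x clusters, column-major pixel order).
#' @param pixelIndex 1-based pixel index into the image grid.
#' @param clusterIndex 1-based cluster index.
#' @param dims image dimensions `c(nrow, ncol)`.
#' @param window odd neighbourhood side (>= 3).
#' @param n fuzzifier.
#' @return nonnegative scalar.
#' @export
fuzzyFactor <- function(M, pixelIndex, clusterIndex, dims, window = 3L, n = 2) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be odd and >= 3", call. = FALSE)
  }
  if (pixelIndex < 1L || pixelIndex > prod(dims)) {
    stop("pixel index out of grid", call. = FALSE)
  }
  if (clusterIndex < 1L || clusterIndex > ncol(M)) {
    stop("cluster index out of range", call. = FALSE)
  }
  i0 <- ((pixelIndex - 1L) %% dims[1]) + 1L
  j0 <- ((pixelIndex - 1L) %/% dims[1]) + 1L
  r <- (window - 1L) %/% 2L
  total <- 0
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0L && dj == 0L) next
    i <- i0 + di; j <- j0 + dj
    if (i < 1L || i > dims[1] || j < 1L || j > dims[2]) next
    k <- (j - 1L) * dims[1] + i
    total <- total + (1 - M[k, clusterIndex])^n / (1 + max(abs(di), abs(dj)))
  }
  total
}

#' Modified kernel fuzzy C-means clustering of a grayscale image
#'
#' Alternates membership and centre updates until the maximum centre shift
#' drops below `tol` or `maxIter` is reached. The squared grayscale distance in
#' the membership update is augmented with the spatial fuzzy factor
#' ([fuzzyFactor()]) so that each pixel's assignment is pulled toward its
#' neighbourhood's, which suppresses impulse noise and speckle in the
#' segmentation. With `window = 1` the factor vanishes and the procedure is
#' textbook fuzzy C-means. Centres are initialized at evenly spaced intensity
#' percentiles (25th/75th for `c = 2`), with seeded jitter for `c > 2`.
#'
#' The per-iteration objective `sum_ij m_ij^n (d_ij^2 + F_ij)` is returned as a
#' trace.
#'
#' @param image numeric matrix in \[0, 1\] (a filtered grayscale image).
#' @param control a [kfcmControl()] bundle.
#' @return a [KFCMFit-class].
#' @examples
#' img <- matrix(c(rep(0.2, 32), rep(0.8, 32)), 8, 8)
#' fit <- runModifiedKFCM(img, kfcmControl(window = 1))
#' centers(fit)
#' @export
runModifiedKFCM <- function(image, control = kfcmControl()) {
  .assertImage(image)
  stopifnot(inherits(control, "KFCMControl"))
  x <- as.vector(image)
  cC <- control$c
  probs <- seq(1, 2 * cC - 1, by = 2) / (2 * cC)  # 25/75 percentiles for c=2
  y <- as.vector(stats::quantile(x, probs = probs, names = FALSE))
  if (cC > 2L) {
    y <- withr::with_seed(control$seed,
                          y + stats::runif(cC, -1e-3, 1e-3))
  }
  if (any(duplicated(y))) y <- y + seq(0, 1e-6, length.out = cC)
  dims <- dim(image)
  M <- updateMembership(x, y, control$n)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(control$maxIter)) {
    F <- if (control$window >= 3L) {
      .fuzzyFactorField(M, dims, control$window, control$n)
    } else NULL
    M <- updateMembership(x, y, control$n, offset = F)
    yNew <- updateCenters(x, M, control$n, previous = y)
    d2 <- outer(x, yNew, function(a, b) (a - b)^2)
    obj <- sum(M^control$n * (d2 + if (is.null(F)) 0 else F))
    objective <- c(objective, obj)
    shift <- max(abs(yNew - y))
    y <- yNew
    if (shift < control$tol) { converged <- TRUE; break }
  }
  new("KFCMFit", membership = M, centers = y, objective = objective,
      dims = as.integer(dims), iterations = iter, converged = converged)
}

#' Extract the segmented region-of-interest intensity vector
#'
#' The foreground is the cluster with the larger spatial support under
#' per-pixel argmax membership (ties go to the lower cluster index). Foreground
#' intensities are collected row-major; if more than `length` pixels are in the
#' foreground the lowest-membership ones are dropped, if fewer the vector is
#' padded with the foreground median, so the output always has exactly
#' `length` values. Swapping cluster labels does not change the output.
#'
#' @param image the clustered image.
#' @param fit a [KFCMFit-class] for that image.
#' @param length target ROI length; 36100 (a 190 x 190 region) at full scale.
#' @return a [SegmentedROI-class].
#' @export
extractROI <- function(image, fit, length = 36100L) {
  stopifnot(is(fit, "KFCMFit"))
  .assertImage(image)
  if (!all(dim(image) == fit@dims)) stop("image/fit dimension mismatch", call. = FALSE)
  length <- as.integer(length)
  assign <- max.col(fit@membership, ties.method = "first")
  support <- tabulate(assign, nbins = ncol(fit@membership))
  fg <- which.max(support)
  maskVec <- assign == fg
  if (!any(maskVec)) stop("empty foreground segment", call. = FALSE)
  # row-major ordering of foreground pixels
  h <- fit@dims[1]; w <- fit@dims[2]
  rowMajor <- order(((which(maskVec) - 1L) %% h), ((which(maskVec) - 1L) %/% h))
  fgIdx <- which(maskVec)[rowMajor]
  vals <- as.vector(image)[fgIdx]
  memb <- fit@membership[fgIdx, fg]
  if (base::length(vals) > length) {
    keep <- sort(order(memb, decreasing = TRUE)[seq_len(length)])
    vals <- vals[keep]
  } else if (base::length(vals) < length) {
    vals <- c(vals, rep(stats::median(vals), length - base::length(vals)))
  }
  new("SegmentedROI", values = vals,
      mask = matrix(maskVec, h, w))
}
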