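# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertScalarNumeric <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must lie in [%s, %s]", name, lower, upper), call. = FALSE)
  }
  invisible(x)
}

.assertImage <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
  if (length(img) == 0L) stop(sprintf("'%s' is empty", name), call. = FALSE)
  if (anyNA(img) || any(!is.finite(img))) {
    stop(sprintf("'%s' contains non-finite pixels", name), call. = FALSE)
  }
  invisible(img)
}

.clip01 <- function(x) {
  # pmin/pmax take attributes from their first argument; keep the shape
  d <- dim(x)
  out <- pmin(1, pmax(0, x))
  dim(out) <- d
  out
}

# Deterministic per-item seed derived from a master seed; stays within R's
# 32-bit integer range so downstream set.seed() is portable.
deriveSeed <- function(seed, index, labelCode = 0L) {
  s <- (as.numeric(seed) %% 2147483629) +
    10007 * as.numeric(index) +
    49999 * as.numeric(labelCode)
  as.integer(s %% 2147483629)
}

.classLevels <- c("N", "ACA")

.checkLabels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .classLevels)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected N or ACA)", call. = FALSE)
  }
  factor(labels, levels = .classLevels)
}

# Histogram probabilities over fixed [0,1] support with optional Laplace
# smoothing; values outside [0,1] are clamped into the end bins.
.histProbs <- function(x, bins = 32L, smooth = 0) {
  idx <- findInterval(x, seq(0, 1, length.out = bins + 1L),
                      rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins) + smooth
  counts / sum(counts)
}

# Jensen-Shannon divergence (natural log) between two probability vectors.
.jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# Content hash of an arbitrary R object (used for run manifests).
.objectHash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# Fisher separation score per feature column: (muN - muA)^2 / (varN + varA + eps)
.fisherScores <- function(x, labels, eps = 1e-12) {
  labels <- .checkLabels(labels)
  xn <- x[labels == "N", , drop = FALSE]
  xa <- x[labels == "ACA", , drop = FALSE]
  (colMeans(xn) - colMeans(xa))^2 /
    (apply(xn, 2, stats::var) + apply(xa, 2, stats::var) + eps)
}
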