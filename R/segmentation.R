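#' 2-D Gaussian smoothing of an image
#'
#' Spatial-domain convolution with a normalized, truncated Gaussian kernel
#' (default 5 x 5 support, sigma 1 px) using replicate padding at the edges.
#' Separable, deterministic.
#'
#' @param img numeric matrix.
#' @param size odd kernel side length in pixels.
#' @param sigma kernel standard deviation in pixels.
#' @return Smoothed matrix, same shape.
#' @export
gaussian_blur <- function(img, size = 5L, sigma = 1) {
  stopifnot(is.matrix(img), size %% 2L == 1L, sigma > 0)
  r <- (size - 1L) %/% 2L
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  # rows pass
  p <- img[pad_idx(nrow(img)), , drop = FALSE]
  tmp <- matrix(0, nrow(img), ncol(img))
  for (m in seq_len(size))
    tmp <- tmp + k[m] * p[seq_len(nrow(img)) + (m - 1L), , drop = FALSE]
  # cols pass
  p <- tmp[, pad_idx(ncol(img)), drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (m in seq_len(size))
    out <- out + k[m] * p[, seq_len(ncol(img)) + (m - 1L), drop = FALSE]
  out
}

#' Fused TWI + StO2 segmentation image
#'
#' The background-separation feature map: the scaled TWI and StO2 images are
#' each smoothed with a 5 x 5 Gaussian kernel, divided by their own maximum
#' and summed, giving values in [0, 2] -- near 0 for inert background, near
#' 2 for well-perfused, water-bearing tissue. Undefined StO2 pixels are set
#' to 0 before smoothing.
#'
#' @param cube a [hypercube].
#' @param bands,scaling see [index_bands()], [index_scaling()].
#' @param kernel_size,kernel_sigma Gaussian filter support (px) and sd (px).
#' @return Numeric matrix with values in [0, 2].
#' @export
fused_index_image <- function(cube, bands = index_bands(),
                              scaling = index_scaling(),
                              kernel_size = 5L, kernel_sigma = 1) {
  twi_img <- index_image(cube, "TWI", bands, scaling)
  sto2_img <- index_image(cube, "STO2", bands, scaling)
  sto2_img[is.na(sto2_img)] <- 0
  twi_img <- gaussian_blur(twi_img, kernel_size, kernel_sigma)
  sto2_img <- gaussian_blur(sto2_img, kernel_size, kernel_sigma)
  m1 <- max(twi_img); m2 <- max(sto2_img)
  if (m1 <= 0 || m2 <= 0)
    stop("cannot normalize: an index image is identically zero")
  twi_img / m1 + sto2_img / m2
}

#' Otsu threshold of a sample of values
#'
#' Histogram-based threshold maximizing the between-class variance
#' (equivalently minimizing within-class variance). Binning is fixed -- 256
#' uniform bins over `range` (default [0, 2], the range of the fused
#' segmentation image) -- so the result is deterministic. When the variance
#' is maximized on a plateau of cuts (an empty gap between two well-separated
#' classes), the plateau's midpoint is returned.
#'
#' @param values numeric vector with at least two distinct values.
#' @param bins number of histogram bins.
#' @param range `c(lo, hi)` histogram support; values outside are clamped
#'   into the end bins.
#' @return Threshold (upper edge of the optimal cut bin).
#' @export
otsu_threshold <- function(values, bins = 256L, range = c(0, 2)) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("Otsu threshold undefined for constant input")
  breaks <- seq(range[1L], range[2L], length.out = bins + 1L)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- tabulate(bin, nbins = bins)
  centers <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  w <- cumsum(counts)
  s <- cumsum(counts * centers)
  n <- w[bins]; total <- s[bins]
  k <- seq_len(bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, bins - 1L)
  mu0 <- s[k][valid] / w0[valid]
  mu1 <- (total - s[k][valid]) / w1[valid]
  bcv[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  top <- max(bcv)
  ties <- which(bcv >= top - abs(top) * 1e-12)
  mean(breaks[ties + 1L])
}

#' Histogram bimodality flag
#'
#' Decides whether a sample's histogram is bimodal: a 64-bin histogram over
#' `range` is smoothed with a short moving average and its local maxima are
#' extracted; the sample is called bimodal when two maxima, each at least
#' `min_peak` of the highest mode (so stray counts in a tail do not count
#' as modes), are separated by a valley that dips at least `prominence`
#' (fraction) below the smaller of the two peaks. Degenerate inputs (fewer
#' than 10 values, constant values) return `FALSE`.
#'
#' @param values numeric vector.
#' @param bins histogram bin count.
#' @param range histogram support; defaults to the data range.
#' @param smooth moving-average window (bins, odd).
#' @param prominence required relative valley depth in (0, 1).
#' @param min_peak minimum peak height as a fraction of the highest mode.
#' @return Logical flag.
#' @export
is_bimodal <- function(values, bins = 64L, range = NULL, smooth = 5L,
                       prominence = 0.2, min_peak = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 10L || length(unique(values)) < 2L) return(FALSE)
  if (is.null(range)) range <- base::range(values)
  breaks <- seq(range[1L], range[2L], length.out = bins + 1L)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- as.numeric(tabulate(bin, nbins = bins))
  # centered moving average, window truncated at the ends
  r <- (smooth - 1L) %/% 2L
  sm <- vapply(seq_len(bins), function(i)
    mean(counts[max(1L, i - r):min(bins, i + r)]), numeric(1))
  peaks <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) == -2)
  peaks <- peaks[sm[peaks] >= min_peak * max(sm)]
  if (length(peaks) < 2L) return(FALSE)
  peaks <- peaks[order(sm[peaks], decreasing = TRUE)]
  # accept the highest peak, then any peak separated from an accepted one
  # by a sufficiently deep valley
  accepted <- peaks[1L]
  for (p in peaks[-1L]) {
    ok <- all(vapply(accepted, function(a) {
      valley <- min(sm[min(a, p):max(a, p)])
      valley <= (1 - prominence) * min(sm[a], sm[p])
    }, logical(1)))
    if (ok) accepted <- c(accepted, p)
    if (length(accepted) >= 2L) return(TRUE)
  }
  FALSE
}

#' Segment the imaged body part from the background
#'
#' Computes the fused TWI + StO2 image and thresholds it: with Otsu's method
#' when the histogram of fused values is bimodal (the usual case -- one mode
#' for background, one for tissue), otherwise with the fixed fallback
#' threshold 1.0 (the midpoint of the [0, 2] fused range), which also
#' handles frames with no body part or with the body filling the frame. The
#' mask is the set of pixels strictly above the threshold.
#'
#' @param cube a [hypercube].
#' @param bands,scaling,kernel_size,kernel_sigma see [fused_index_image()].
#' @param roi_diameter diameter (px) of the central disk used to report
#'   `coverage_central`; clipped to the frame.
#' @param ... passed to [is_bimodal()].
#' @return A `body_mask` object: list with `mask` (logical matrix),
#'   `threshold`, `method` (`"otsu"` or `"fixed"`), `coverage_central`.
#' @export
body_mask <- function(cube, bands = index_bands(), scaling = index_scaling(),
                      kernel_size = 5L, kernel_sigma = 1,
                      roi_diameter = 100L, ...) {
  fused <- fused_index_image(cube, bands, scaling, kernel_size, kernel_sigma)
  bimodal <- is_bimodal(as.vector(fused), range = c(0, 2), ...)
  if (bimodal) {
    thr <- otsu_threshold(as.vector(fused), range = c(0, 2))
    method <- "otsu"
  } else {
    thr <- 1.0
    method <- "fixed"
  }
  mask <- fused > thr
  d <- min(roi_diameter, dim(fused))
  central <- central_roi_mask(dim(fused), d)
  structure(list(mask = mask, threshold = thr, method = method,
                 coverage_central = mean(mask[central])),
            class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("<body_mask> %d x %d, method=%s, threshold=%.4f, central coverage=%.3f, body fraction=%.3f\n",
              nrow(x$mask), ncol(x$mask), x$method, x$threshold,
              x$coverage_central, mean(x$mask)))
  invisible(x)
}

#' Select the best-framed repeat among replicate acquisitions
#'
#' Each site is imaged three times; the repeat whose body mask covers the
#' largest fraction of the central region is kept for analysis. Ties go to
#' the earliest repeat.
#'
#' @param masks list of `body_mask` objects (or logical matrices) of equal
#'   shape, one per repeat (normally three).
#' @param central logical matrix marking the central region; default the
#'   100 px central disk (clipped to the frame).
#' @return 1-based index of the selected repeat, with the coverages as
#'   attribute `coverage`.
#' @export
select_best_repeat <- function(masks, central = NULL) {
  get_mask <- function(m) if (inherits(m, "body_mask")) m$mask else m
  mats <- lapply(masks, get_mask)
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1L) stop("repeat masks differ in shape")
  if (is.null(central))
    central <- central_roi_mask(dims[[1L]], min(100L, dims[[1L]]))
  cov <- vapply(mats, function(m) mean(m[central]), numeric(1))
  structure(which.max(cov), coverage = cov)
}
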