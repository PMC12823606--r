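#' Central circular region-of-interest mask
#'
#' Boolean disk centered on the image: with 0-based pixel centers the image
#' center lies at `((H-1)/2, (W-1)/2)` (between pixels for even dimensions),
#' and a pixel belongs to the disk when its center is strictly within
#' `diameter/2` of that point. For the full 640 x 480 frame the default
#' 100 px diameter corresponds to about 4.6 cm of tissue at the standard
#' 50 cm capture distance.
#'
#' @param image_shape `c(height, width)` (a cube's spatial dims).
#' @param diameter_px disk diameter in pixels; must not exceed either
#'   dimension.
#' @return Logical matrix of shape `image_shape`.
#' @export
central_roi_mask <- function(image_shape, diameter_px = 100) {
  h <- image_shape[1L]; w <- image_shape[2L]
  if (diameter_px > min(h, w))
    stop("ROI diameter exceeds the image dimensions")
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  r2 <- (diameter_px / 2)^2
  dy2 <- (seq_len(h) - 1 - cy)^2
  dx2 <- (seq_len(w) - 1 - cx)^2
  outer(dy2, dx2, `+`) < r2
}

#' Representative ROI spectrum of a measurement
#'
#' Every pixel spectrum inside the body-and-ROI intersection is L1-normalized
#' (divided by its summed intensity) and the normalized spectra are averaged;
#' the result again sums to 1. Normalizing per pixel before averaging removes
#' pixel-level illumination differences; the order matters and is part of the
#' contract. An empty intersection yields an `NA` spectrum flagged missing,
#' never a zero spectrum.
#'
#' @param cube a [hypercube].
#' @param body logical matrix (or `body_mask`) of tissue pixels.
#' @param roi logical matrix, see [central_roi_mask()].
#' @return A normalized `spectrum` with attribute `n_pixels`; if the
#'   intersection is empty, an `NA` spectrum with attribute
#'   `missing = TRUE`.
#' @export
representative_spectrum <- function(cube, body, roi) {
  if (inherits(body, "body_mask")) body <- body$mask
  sel <- body & roi
  n <- sum(sel)
  if (n == 0L) {
    out <- structure(rep(NA_real_, length(cube$wavelengths)),
                     wavelengths = cube$wavelengths, normalized = FALSE,
                     missing = TRUE, n_pixels = 0L, class = "spectrum")
    return(out)
  }
  mat <- apply(cube$data, 3L, function(plane) plane[sel])  # n x bands
  if (n == 1L) mat <- matrix(mat, nrow = 1L)
  sums <- rowSums(mat)
  if (any(sums <= 0)) stop("ROI contains a pixel with non-positive summed intensity")
  avg <- colMeans(mat / sums)
  out <- spectrum(avg, cube$wavelengths, normalized = TRUE)
  attr(out, "n_pixels") <- n
  out
}

#' Indices of one side at one site
#'
#' Computes the full [index_set()] from the representative (average) ROI
#' spectrum. The contract is index-of-average, not average-of-pixel-indices:
#' the two differ on heterogeneous tissue.
#'
#' @param spec a normalized representative `spectrum`.
#' @param ... passed to [index_set()].
#' @return Named list of indices (see [index_set()]); `NULL` if the
#'   spectrum is flagged missing.
#' @export
side_indices <- function(spec, ...) {
  if (isTRUE(attr(spec, "missing"))) return(NULL)
  index_set(spec, ...)
}

#' Interlimb delta metrics at one site
#'
#' Componentwise affected minus unaffected difference of the raw
#' (unscaled) indices: `d_lwr`, `d_twi`, `d_tli`. Raw values are used so the
#' deltas are independent of the display-scaling constants; the result is
#' antisymmetric under swapping the sides. Edema deepens the water
#' absorption band (lowering the LWR denominator) and shallows the lipid
#' band (raising the numerator) on the affected side, so disease severity
#' drives `d_lwr` positive under this sign convention.
#'
#' @param affected,unaffected index sets (see [index_set()]) of the two
#'   sides at the same site.
#' @return Named list `d_lwr`, `d_twi`, `d_tli`; `NULL` when either side is
#'   missing.
#' @export
delta_metrics <- function(affected, unaffected) {
  if (is.null(affected) || is.null(unaffected)) return(NULL)
  list(
    d_lwr = affected$lwr - unaffected$lwr,
    d_twi = affected$twi_raw - unaffected$twi_raw,
    d_tli = affected$tli_raw - unaffected$tli_raw
  )
}
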