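#' Default acquisition wavelength grid
#'
#' Band centers of the imaging system's spectral axis: 100 bands from 500 to
#' 995 nm in uniform 5 nm steps. The device documentation quotes the range
#' loosely as "500 to 1000 nm"; with 100 stored planes the consistent reading
#' is 500--995 nm inclusive, which is what this grid encodes. Both the span
#' and the step are arguments so non-default instruments can be described.
#'
#' @param from,to first and last band center in nm.
#' @param by band spacing in nm.
#' @return Numeric vector of strictly increasing, uniformly spaced band
#'   centers in nm (length 100 for the defaults).
#' @examples
#' g <- make_default_grid()
#' length(g)     # 100
#' g[c(1, 100)]  # 500, 995
#' @export
make_default_grid <- function(from = 500, to = 995, by = 5) {
  g <- seq(from, to, by = by)
  validate_grid(g)
  g
}

validate_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L)
    stop("wavelength grid must be a numeric vector of length >= 2")
  d <- diff(grid)
  if (any(d <= 0))
    stop("wavelength grid must be strictly increasing")
  if (max(d) - min(d) > 1e-9)
    stop("wavelength grid must be uniformly spaced")
  invisible(grid)
}

grid_spacing <- function(grid) grid[2L] - grid[1L]

#' Construct a hypercube
#'
#' A hypercube is the unit of acquisition: a 3-D array of non-negative
#' reflectance intensities, dimensions (height, width, bands), with an
#' attached wavelength grid and free-form acquisition metadata (patient id,
#' side, site, repeat index, capture distance, ...). The default full-frame
#' acquisition is 640 x 480 x 100.
#'
#' @param data numeric array, dim (height, width, n_bands), finite, >= 0.
#' @param wavelengths wavelength grid; length must equal `dim(data)[3]`.
#' @param meta named list of acquisition metadata.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths = make_default_grid(), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (height, width, bands)")
  if (dim(data)[3L] != length(wavelengths))
    stop("number of bands (", dim(data)[3L], ") does not match wavelength grid (",
         length(wavelengths), ")")
  validate_grid(wavelengths)
  if (anyNA(data) || any(!is.finite(data)))
    stop("hypercube data must be finite")
  if (any(data < 0))
    stop("hypercube data must be non-negative")
  structure(list(data = data, wavelengths = wavelengths, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%g-%g nm, %g nm step)\n",
              d[1L], d[2L], d[3L], x$wavelengths[1L],
              x$wavelengths[length(x$wavelengths)], grid_spacing(x$wavelengths)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Construct a spectrum
#'
#' A 1-D reflectance vector aligned to a wavelength grid. `normalized` flags
#' L1 normalization (values sum to 1).
#'
#' @param values numeric vector of reflectance intensities.
#' @param wavelengths wavelength grid of equal length.
#' @param normalized logical; if `TRUE` the values must sum to 1 (within 1e-9).
#' @return Numeric vector of class `spectrum` with attributes `wavelengths`
#'   and `normalized`.
#' @export
spectrum <- function(values, wavelengths = make_default_grid(),
                     normalized = FALSE) {
  if (length(values) != length(wavelengths))
    stop("spectrum length does not match wavelength grid")
  validate_grid(wavelengths)
  if (isTRUE(normalized) && abs(sum(values) - 1) > 1e-9)
    stop("spectrum flagged normalized but values do not sum to 1")
  structure(as.numeric(values), wavelengths = as.numeric(wavelengths),
            normalized = isTRUE(normalized), class = "spectrum")
}

#' L1-normalize a spectrum
#'
#' Divides by the summed intensity across all bands so the result sums to 1.
#'
#' @param x a `spectrum` (or plain numeric vector on the default grid).
#' @return A normalized `spectrum`.
#' @export
normalize_l1 <- function(x) {
  w <- spectrum_wavelengths(x)
  s <- sum(x)
  if (s <= 0) stop("cannot L1-normalize a spectrum with non-positive sum")
  spectrum(as.numeric(x) / s, w, normalized = TRUE)
}

spectrum_wavelengths <- function(x) {
  w <- attr(x, "wavelengths")
  if (is.null(w)) {
    if (length(x) == 100L) w <- make_default_grid()
    else stop("spectrum has no wavelength grid attached")
  }
  w
}

#' Extract the spectrum at one pixel of a hypercube
#'
#' @param cube a `hypercube`.
#' @param row,col 1-based pixel indices.
#' @return A `spectrum`.
#' @export
pixel_spectrum <- function(cube, row, col) {
  spectrum(cube$data[row, col, ], cube$wavelengths)
}

band_index <- function(grid, band) {
  if (length(band) != 2L || band[1L] > band[2L])
    stop("band must be c(lo, hi) with lo <= hi")
  idx <- which(grid >= band[1L] & grid <= band[2L])
  if (length(idx) == 0L)
    stop(sprintf("band %g-%g nm contains no grid point", band[1L], band[2L]))
  idx
}

#' Mean reflectance over a wavelength band
#'
#' Arithmetic mean of the spectrum at all grid points lambda with
#' `lo <= lambda <= hi` (both ends inclusive). All band-ratio indices in the
#' package are built from this primitive.
#'
#' @param x a `spectrum` (or numeric vector on the default grid).
#' @param band `c(lo, hi)` in nm.
#' @return Scalar band mean.
#' @export
band_mean <- function(x, band) {
  grid <- spectrum_wavelengths(x)
  mean(as.numeric(x)[band_index(grid, band)])
}

#' Per-pixel band mean over a hypercube
#'
#' @param cube a `hypercube`.
#' @param band `c(lo, hi)` in nm.
#' @return Matrix (height x width) of band means.
#' @export
cube_band_mean <- function(cube, band) {
  idx <- band_index(cube$wavelengths, band)
  rowMeans(cube$data[, , idx, drop = FALSE], dims = 2L)
}

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D smoothing along the spectral axis with a truncated, renormalized
# Gaussian; edge windows are renormalized over the in-range support.
smooth_spectrum_values <- function(v, sigma) {
  if (sigma <= 0) return(v)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    kk <- k[j - i + r + 1L]
    out[i] <- sum(v[j] * kk) / sum(kk)
  }
  out
}

#' Mean central-difference second derivative over a band
#'
#' For each grid point lambda inside the band computes the central difference
#' `(f(lambda - h) - 2 f(lambda) + f(lambda + h)) / h^2` with `h` the grid
#' spacing (5 nm by default), then averages over the band. The band must be
#' interior to the grid (one grid point of margin on each side). An optional
#' Gaussian pre-smoothing along the spectral axis (`sigma` in band units) is
#' available for noisy spectra; it is off by default so the estimator is the
#' plain central difference.
#'
#' @param x a `spectrum` (or numeric vector on the default grid).
#' @param band `c(lo, hi)` in nm.
#' @param sigma spectral pre-smoothing standard deviation in bands; 0 = none.
#' @return Scalar mean second derivative (reflectance / nm^2).
#' @export
second_derivative_mean <- function(x, band, sigma = 0) {
  grid <- spectrum_wavelengths(x)
  idx <- band_index(grid, band)
  if (min(idx) <= 1L || max(idx) >= length(grid))
    stop("band touches the grid boundary; second derivative needs one interior margin point")
  h <- grid_spacing(grid)
  v <- smooth_spectrum_values(as.numeric(x), sigma)
  d2 <- (v[idx - 1L] - 2 * v[idx] + v[idx + 1L]) / h^2
  mean(d2)
}

#' Per-pixel mean second derivative over a hypercube
#'
#' @inheritParams second_derivative_mean
#' @param cube a `hypercube`.
#' @return Matrix (height x width).
#' @export
cube_second_derivative_mean <- function(cube, band, sigma = 0) {
  grid <- cube$wavelengths
  idx <- band_index(grid, band)
  if (min(idx) <= 1L || max(idx) >= length(grid))
    stop("band touches the grid boundary; second derivative needs one interior margin point")
  h <- grid_spacing(grid)
  dat <- cube$data
  if (sigma > 0) {
    k <- gaussian_kernel_1d(sigma)
    r <- (length(k) - 1L) %/% 2L
    n <- length(grid)
    sm <- array(0, dim(dat))
    for (b in seq_len(n)) {
      j <- max(1L, b - r):min(n, b + r)
      kk <- k[j - b + r + 1L]
      kk <- kk / sum(kk)
      plane <- matrix(0, dim(dat)[1L], dim(dat)[2L])
      for (m in seq_along(j)) plane <- plane + kk[m] * dat[, , j[m]]
      sm[, , b] <- plane
    }
    dat <- sm
  }
  acc <- matrix(0, dim(dat)[1L], dim(dat)[2L])
  for (b in idx)
    acc <- acc + (dat[, , b - 1L] - 2 * dat[, , b] + dat[, , b + 1L]) / h^2
  acc / length(idx)
}
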