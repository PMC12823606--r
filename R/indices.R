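#' Default absorption-band definitions for the tissue indices
#'
#' Band limits in nm, inclusive at both ends on the 5 nm grid:
#' \itemize{
#'   \item LWR: lipid 925--935 over water 965--985 (band-mean ratio).
#'   \item TWI: 875--895 over 950--975 (band-mean ratio; water absorption
#'     lowers the denominator, so TWI grows with tissue water).
#'   \item TLI: mean spectral second derivative over 925--935 (lipid band).
#'   \item StO2: ratio of mean second derivatives, 575--590 (hemoglobin) over
#'     740--780 (reference).
#' }
#' @return Named list of `c(lo, hi)` bands.
#' @export
index_bands <- function() {
  list(
    lwr_lipid = c(925, 935), lwr_water = c(965, 985),
    twi_num   = c(875, 895), twi_den   = c(950, 975),
    tli       = c(925, 935),
    sto2_num  = c(575, 590), sto2_den  = c(740, 780)
  )
}

#' Default affine scaling of raw index values onto 0--100
#'
#' The instrument vendor's scaling constants are proprietary; these defaults
#' map a documented plausible raw range linearly onto the display scale
#' [0, 100] (values outside are clamped). They exist for display and for the
#' background-segmentation fusion only: every scientific output of the
#' pipeline (interlimb deltas, spectral staging) is computed from raw,
#' unscaled values, so no conclusion depends on these constants. All entries
#' are overridable.
#'
#' For TWI and StO2 the lower anchor is the value a featureless (water- and
#' hemoglobin-free) reflectance spectrum produces (a band-mean ratio of ~1,
#' and a curvature ratio of ~1), so inert backgrounds score near 0. `lo > hi`
#' is permitted and reverses the direction of the map (used for StO2, whose
#' raw curvature ratio runs negative over hemoglobin-bearing tissue on this
#' grid).
#'
#' @return Named list of `c(lo, hi)` pairs: raw value `lo` maps to 0 and
#'   `hi` to 100.
#' @export
index_scaling <- function() {
  list(
    twi  = c(1.0, 2.0),
    tli  = c(0, 1e-3),
    sto2 = c(1, -400)
  )
}

scale_index <- function(raw, anchors) {
  scaled <- (raw - anchors[1L]) / (anchors[2L] - anchors[1L]) * 100
  pmin(pmax(scaled, 0), 100)
}

#' Lipid-to-water ratio (LWR)
#'
#' Ratio of the mean reflectance in the lipid absorption band (925--935 nm)
#' to that in the water absorption band (965--985 nm). Dimensionless,
#' invariant to global rescaling of the spectrum; fluid accumulation deepens
#' the water band and lowers LWR.
#'
#' @param x a `spectrum` (raw or L1-normalized).
#' @param bands band definitions, see [index_bands()].
#' @return Positive scalar ratio.
#' @export
lwr <- function(x, bands = index_bands()) {
  den <- band_mean(x, bands$lwr_water)
  if (den <= 0) stop("LWR undefined: non-positive water-band mean")
  band_mean(x, bands$lwr_lipid) / den
}

#' Tissue water index, raw ratio
#'
#' Band-mean ratio 875--895 / 950--975 nm. Water absorption around 970 nm
#' depresses the denominator, so the raw value increases with tissue water.
#'
#' @inheritParams lwr
#' @return Positive scalar ratio.
#' @export
twi_raw <- function(x, bands = index_bands()) {
  den <- band_mean(x, bands$twi_den)
  if (den <= 0) stop("TWI undefined: non-positive denominator band mean")
  band_mean(x, bands$twi_num) / den
}

#' Tissue water index, scaled 0--100
#' @inheritParams lwr
#' @param scaling affine anchors, see [index_scaling()].
#' @export
twi <- function(x, bands = index_bands(), scaling = index_scaling()) {
  scale_index(twi_raw(x, bands), scaling$twi)
}

#' Tissue lipid index, raw value
#'
#' Mean central-difference second derivative of the spectrum over the
#' 925--935 nm lipid band (units reflectance / nm^2).
#'
#' @inheritParams lwr
#' @param sigma optional spectral Gaussian pre-smoothing (bands); 0 = none.
#' @export
tli_raw <- function(x, bands = index_bands(), sigma = 0) {
  second_derivative_mean(x, bands$tli, sigma = sigma)
}

#' Tissue lipid index, scaled 0--100
#' @inheritParams tli_raw
#' @param scaling affine anchors, see [index_scaling()].
#' @export
tli <- function(x, bands = index_bands(), scaling = index_scaling(), sigma = 0) {
  scale_index(tli_raw(x, bands, sigma = sigma), scaling$tli)
}

#' Tissue oxygenation index, raw ratio
#'
#' Ratio of mean second derivatives over 575--590 nm (hemoglobin bands) and
#' 740--780 nm (reference). A vanishing reference curvature makes the ratio
#' undefined; that case returns `NA` (flagged, never silently 0).
#'
#' @inheritParams tli_raw
#' @return Scalar ratio, or `NA_real_` when the denominator vanishes.
#' @export
sto2_raw <- function(x, bands = index_bands(), sigma = 0) {
  num <- second_derivative_mean(x, bands$sto2_num, sigma = sigma)
  den <- second_derivative_mean(x, bands$sto2_den, sigma = sigma)
  if (abs(den) < 1e-300) return(NA_real_)
  num / den
}

#' Tissue oxygenation index, scaled 0--100
#' @inheritParams sto2_raw
#' @param scaling affine anchors, see [index_scaling()].
#' @export
sto2 <- function(x, bands = index_bands(), scaling = index_scaling(), sigma = 0) {
  raw <- sto2_raw(x, bands, sigma = sigma)
  if (is.na(raw)) return(NA_real_)
  scale_index(raw, scaling$sto2)
}

#' All indices of one spectrum
#'
#' Raw (unscaled) LWR, TWI, TLI, StO2 plus the 0--100 display-scaled
#' variants of the latter three. Raw values carry the science; scaled values
#' exist for display and segmentation.
#'
#' @inheritParams twi
#' @param sigma optional spectral pre-smoothing for the derivative indices.
#' @return Named list: `lwr`, `twi_raw`, `tli_raw`, `sto2_raw`, `twi`,
#'   `tli`, `sto2`.
#' @export
index_set <- function(x, bands = index_bands(), scaling = index_scaling(),
                      sigma = 0) {
  s2 <- sto2_raw(x, bands, sigma = sigma)
  list(
    lwr = lwr(x, bands),
    twi_raw = twi_raw(x, bands),
    tli_raw = tli_raw(x, bands, sigma = sigma),
    sto2_raw = s2,
    twi = twi(x, bands, scaling),
    tli = tli(x, bands, scaling, sigma = sigma),
    sto2 = if (is.na(s2)) NA_real_ else scale_index(s2, scaling$sto2)
  )
}

#' Per-pixel index map of a hypercube
#'
#' Applies the named index to every pixel spectrum; the result has the
#' cube's spatial shape. Names: `"LWR"`, `"TWI"`, `"TLI"`, `"STO2"` (scaled
#' variants) and `"TWI_RAW"`, `"TLI_RAW"`, `"STO2_RAW"`.
#'
#' @param cube a [hypercube].
#' @param index_name one of the names above.
#' @param bands,scaling see [index_bands()], [index_scaling()].
#' @param sigma optional spectral pre-smoothing for derivative indices.
#' @return Numeric matrix (height x width). Pixels where the index is
#'   undefined (StO2 with vanishing reference curvature) are `NA`.
#' @export
index_image <- function(cube, index_name, bands = index_bands(),
                        scaling = index_scaling(), sigma = 0) {
  stopifnot(inherits(cube, "hypercube"))
  switch(toupper(index_name),
    LWR = {
      den <- cube_band_mean(cube, bands$lwr_water)
      if (any(den <= 0)) stop("LWR undefined: non-positive water-band mean at some pixels")
      cube_band_mean(cube, bands$lwr_lipid) / den
    },
    TWI_RAW = {
      den <- cube_band_mean(cube, bands$twi_den)
      if (any(den <= 0)) stop("TWI undefined: non-positive denominator at some pixels")
      cube_band_mean(cube, bands$twi_num) / den
    },
    TWI = scale_index(index_image(cube, "TWI_RAW", bands, scaling, sigma), scaling$twi),
    TLI_RAW = cube_second_derivative_mean(cube, bands$tli, sigma = sigma),
    TLI = scale_index(index_image(cube, "TLI_RAW", bands, scaling, sigma), scaling$tli),
    STO2_RAW = {
      num <- cube_second_derivative_mean(cube, bands$sto2_num, sigma = sigma)
      den <- cube_second_derivative_mean(cube, bands$sto2_den, sigma = sigma)
      out <- num / den
      out[abs(den) < 1e-300] <- NA_real_
      out
    },
    STO2 = scale_index(index_image(cube, "STO2_RAW", bands, scaling, sigma), scaling$sto2),
    stop("unknown index name: ", index_name)
  )
}
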