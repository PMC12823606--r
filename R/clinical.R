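#' Percentage change between paired limb measurements
#'
#' Expresses an affected-side measurement relative to the unaffected side:
#' `affected / unaffected * 100`. Used for circumference and for the
#' ultrasound cutis/subcutis thicknesses, where it removes physiological
#' inter-individual size differences (100 = no change).
#'
#' @param affected,unaffected measurements in identical units;
#'   `unaffected` must be positive.
#' @return Percentage (vectorized).
#' @export
percent_change <- function(affected, unaffected) {
  if (any(unaffected <= 0)) stop("percent change needs a positive unaffected value")
  affected / unaffected * 100
}

#' Signed side difference between paired limb measurements
#'
#' `affected - unaffected`, in the measurement's own units; used where
#' absolute values are directly comparable (two-point discrimination in mm,
#' joint mobility in degrees).
#'
#' @param affected,unaffected measurements in identical units.
#' @return Signed difference (vectorized).
#' @export
side_difference <- function(affected, unaffected) affected - unaffected

#' Questionnaire category score
#'
#' Items are rated 1--4; the category score is the mean of the answered
#' items rescaled to 0--100 via `(mean - 1) / 3 * 100` (the unique affine
#' map sending the item-scale endpoints 1 and 4 to 0 and 100). Unanswered
#' items (`NA`) are excluded; a category with no answered item has no score
#' and returns `NA` with a warning.
#'
#' @param items numeric vector of item responses in `{1, 2, 3, 4}`, `NA`
#'   for unanswered.
#' @return Score in [0, 100], or `NA_real_` when no item was answered.
#' @export
questionnaire_score <- function(items) {
  ans <- items[!is.na(items)]
  if (length(ans) == 0L) {
    warning("questionnaire category with no answered items: score undefined")
    return(NA_real_)
  }
  if (any(ans < 1 | ans > 4)) stop("questionnaire items must lie in [1, 4]")
  (mean(ans) - 1) / 3 * 100
}
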