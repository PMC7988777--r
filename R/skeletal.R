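# Skeletal and histological quantifications that accompany the imaging
# pipeline: the 0-3 vertebral fusion/cleft severity rubric, two-phantom
# calibration of micro-CT grey values to tissue mineral density, and RGB
# channel means over a region of interest in stained sections.

#' Vertebral column severity rubric
#'
#' Maps an abnormality count n (fusions or clefts, or their sum) to a
#' severity score: n = 0 -> 0; 1 <= n <= 3 -> 1; n = 4 -> 2 (the integer
#' content of 3 < n < 5); n >= 5 -> 3. Vectorised.
#'
#' @param n nonnegative integer count(s).
#' @return integer score(s) in 0..3.
#' @export
severity_rubric <- function(n) {
  if (!is_count(n))
    nq_error("nq_value_error", "counts must be nonnegative integers")
  ifelse(n == 0, 0L, ifelse(n <= 3, 1L, ifelse(n < 5, 2L, 3L)))
}

#' Score fish from fusion and cleft counts
#'
#' Fusions and clefts are scored independently by the rubric; the default
#' per-fish score is the maximum of the two. Mode `"combined"` instead
#' applies the rubric to the summed count.
#'
#' @param counts data.frame with columns `fusions` and `clefts` (and
#'   optionally `fish_id`).
#' @param mode `"independent"` (default) or `"combined"`.
#' @return the input with `fusion_score`, `cleft_score` and `fish_score`
#'   columns appended (`"combined"` mode appends `fish_score` only).
#' @export
score_fish <- function(counts, mode = c("independent", "combined")) {
  stopifnot(is.data.frame(counts),
            all(c("fusions", "clefts") %in% names(counts)))
  mode <- match.arg(mode)
  if (mode == "independent") {
    counts$fusion_score <- severity_rubric(counts$fusions)
    counts$cleft_score <- severity_rubric(counts$clefts)
    counts$fish_score <- pmax(counts$fusion_score, counts$cleft_score)
  } else {
    counts$fish_score <- severity_rubric(counts$fusions + counts$clefts)
  }
  counts
}

#' Two-phantom tissue mineral density calibration
#'
#' Defines the affine map from mean grey value to density fitted through
#' two phantoms of known density (defaults 0.25 and 0.75 g/cm^3
#' hydroxyapatite): `d(g) = density_lo + (g - grey_lo) * (density_hi -
#' density_lo) / (grey_hi - grey_lo)`.
#'
#' @param grey_lo,grey_hi mean grey values of the low- and high-density
#'   phantoms (`grey_hi > grey_lo`).
#' @param density_lo,density_hi phantom densities in g/cm^3 HA.
#' @return object of class `nq_tmd_cal`.
#' @export
tmd_calibrate <- function(grey_lo, grey_hi, density_lo = 0.25,
                          density_hi = 0.75) {
  if (!(grey_hi > grey_lo))
    nq_error("nq_value_error", "grey_hi must exceed grey_lo")
  structure(list(grey_lo = grey_lo, grey_hi = grey_hi,
                 density_lo = density_lo, density_hi = density_hi,
                 slope = (density_hi - density_lo) / (grey_hi - grey_lo)),
            class = "nq_tmd_cal")
}

#' Convert mean grey values of segmented bone to density
#'
#' Applies the affine calibration. Values outside the phantom grey range
#' are extrapolated as-is (never clamped) and flagged; negative densities
#' are reported, flagged, so data problems stay visible.
#'
#' @param cal a [tmd_calibrate()].
#' @param grey mean grey value(s) of segmented bone.
#' @return data.frame (grey, density, extrapolated).
#' @export
tmd_apply <- function(cal, grey) {
  stopifnot(inherits(cal, "nq_tmd_cal"), is.numeric(grey))
  density <- cal$density_lo + (grey - cal$grey_lo) * cal$slope
  data.frame(grey = grey, density = density,
             extrapolated = grey < cal$grey_lo | grey > cal$grey_hi)
}

#' Per-channel mean intensities over a region of interest
#'
#' Arithmetic means of the red, green and blue channels over the ROI
#' pixels of an RGB raster; used for stain quantification (collagen fibre
#' colour and red-channel TRAP signal). Quantification operates on raw
#' channel values; display-time lookup-table transforms are ignored.
#'
#' @param image numeric array `height x width x 3`.
#' @param roi `NULL` (whole image), a length-4 vector `c(x0, x1, y0, y1)`
#'   (0-based, inclusive), or a logical `height x width` mask.
#' @return data.frame (mean_red, mean_green, mean_blue, n_pixels).
#' @export
channel_means <- function(image, roi = NULL) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  H <- dim(image)[1]; W <- dim(image)[2]
  sel <- matrix(TRUE, H, W)
  if (is.null(roi)) {
    # whole image
  } else if (is.matrix(roi) && is.logical(roi)) {
    stopifnot(all(dim(roi) == c(H, W)))
    sel <- roi
  } else if (is.numeric(roi) && length(roi) == 4) {
    if (roi[1] < 0 || roi[2] >= W || roi[3] < 0 || roi[4] >= H ||
        roi[1] > roi[2] || roi[3] > roi[4])
      nq_error("nq_value_error", "ROI rectangle out of bounds")
    sel[] <- FALSE
    sel[(roi[3]:roi[4]) + 1, (roi[1]:roi[2]) + 1] <- TRUE
  } else {
    nq_error("nq_value_error", "roi must be NULL, c(x0,x1,y0,y1) or a logical mask")
  }
  n <- sum(sel)
  if (n == 0) nq_error("nq_value_error", "empty ROI")
  data.frame(mean_red = mean(image[, , 1][sel]),
             mean_green = mean(image[, , 2][sel]),
             mean_blue = mean(image[, , 3][sel]),
             n_pixels = n)
}
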