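# Step three of the pipeline: the severity statistic (mean of the
# intensity profile) and lesion calling. Lesions show up on the profile as
# peaks of higher intensity and broader area; the caller makes that
# operational with a robust baseline (median), a dispersion-scaled height
# criterion (k * 1.4826 * MAD), a merge rule for nearby maxima, and a
# trapezoid area above baseline between flanking minima. All constants are
# configuration.

#' Severity of a notochord from its intensity profile
#'
#' The severity statistic is the arithmetic mean of the profile
#' intensities over the retained (in-bounds) samples.
#'
#' @param profile an `nq_profile`.
#' @return list (class `nq_severity`) with `mean_intensity`, `n_samples`,
#'   `n_dropped`.
#' @export
severity_score <- function(profile) {
  stopifnot(inherits(profile, "nq_profile"))
  if (!length(profile$intensities))
    nq_error("nq_value_error", "empty profile")
  structure(list(mean_intensity = mean(profile$intensities),
                 n_samples = length(profile$intensities),
                 n_dropped = profile$n_dropped),
            class = "nq_severity")
}

# strict local maxima with plateau handling: a run of equal values higher
# than the nearest differing neighbours on both sides counts once, at the
# run's center.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  if (k < 3) return(integer(0))
  i <- 2:(k - 1)
  is_max <- r$values[i] > r$values[i - 1] & r$values[i] > r$values[i + 1]
  runs <- i[is_max]
  as.integer(floor((starts[runs] + ends[runs]) / 2))
}

#' Call lesions as peaks on an intensity profile
#'
#' Baseline `b` is the profile median and dispersion `s = 1.4826 * MAD`.
#' Candidate peaks are local maxima with intensity at least `b + k * s`;
#' candidates closer than `min_separation` (arc-length pixels) are merged
#' keeping the higher; each surviving peak's area is the trapezoid
#' integral of the profile above `b` between its flanking minima (the
#' nearest return to baseline on each side, searching no further than the
#' neighbouring peak, with the window minimum as fallback), and calls with
#' area below `min_area` are dropped. Calls are returned sorted by
#' position.
#'
#' @param profile an `nq_profile` with at least 3 samples.
#' @param k height criterion in robust standard deviations (default 3).
#' @param min_separation merge radius in arc-length pixels (default 10).
#' @param min_area minimum area above baseline (grey value x pixels,
#'   default 0).
#' @return data.frame of lesion calls: `position`, `height` (grey value
#'   above baseline), `area`, `left`, `right` (arc-length bounds);
#'   zero-row when nothing qualifies.
#' @export
detect_peaks <- function(profile, k = 3, min_separation = 10, min_area = 0) {
  stopifnot(inherits(profile, "nq_profile"), k >= 0, min_separation >= 0)
  v <- profile$intensities
  pos <- profile$arc_positions
  if (length(v) < 3)
    nq_error("nq_value_error", "profile too short for peak detection")
  empty <- data.frame(position = numeric(0), height = numeric(0),
                      area = numeric(0), left = numeric(0), right = numeric(0))
  b <- median(v)
  s <- mad(v)  # 1.4826 * MAD by R's default constant
  cand <- local_maxima(v)
  cand <- cand[v[cand] >= b + k * s & v[cand] > b]
  if (!length(cand)) return(empty)
  # merge: accept in height order, reject candidates within min_separation
  ord <- cand[order(-v[cand], pos[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || min(abs(pos[kept] - pos[i])) >= min_separation)
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  # flanking minima: nearest return to baseline on each side (searching no
  # further than the neighbouring peak); if the profile never comes back
  # down to b in that window, the window's minimum is used instead
  bounds_left <- integer(length(kept))
  bounds_right <- integer(length(kept))
  for (j in seq_along(kept)) {
    lo <- if (j == 1) 1L else kept[j - 1]
    hi <- if (j == length(kept)) length(v) else kept[j + 1]
    lseg <- lo:kept[j]
    rseg <- kept[j]:hi
    lcross <- lseg[v[lseg] <= b]
    rcross <- rseg[v[rseg] <= b]
    bounds_left[j] <- if (length(lcross)) max(lcross) else lseg[which.min(v[lseg])]
    bounds_right[j] <- if (length(rcross)) min(rcross) else rseg[which.min(v[rseg])]
  }
  area <- vapply(seq_along(kept), function(j) {
    idx <- bounds_left[j]:bounds_right[j]
    if (length(idx) < 2) return(0)
    h <- pmax(v[idx] - b, 0)
    sum(diff(pos[idx]) * (h[-1] + h[-length(h)]) / 2)
  }, numeric(1))
  out <- data.frame(position = pos[kept], height = v[kept] - b,
                    area = area, left = pos[bounds_left],
                    right = pos[bounds_right])
  out <- out[out$area >= min_area & out$area > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classification thresholds for lesion counts
#'
#' Defaults follow the published rules: a fish is affected with more than
#' 3 lesions and severe (wounded) with more than 5.
#'
#' @param affected_if_more_than,severe_if_more_than integer lesion counts.
#' @export
lesion_thresholds <- function(affected_if_more_than = 3,
                              severe_if_more_than = 5) {
  stopifnot(severe_if_more_than >= affected_if_more_than)
  structure(list(affected_if_more_than = as.integer(affected_if_more_than),
                 severe_if_more_than = as.integer(severe_if_more_than)),
            class = "nq_thresholds")
}

#' Classify a fish by its lesion count
#'
#' @param calls a data.frame of lesion calls (from [detect_peaks()]) or a
#'   single nonnegative integer count.
#' @param thresholds a [lesion_thresholds()].
#' @return one of `"unaffected"`, `"affected"`, `"severe"`.
#' @export
classify_fish <- function(calls, thresholds = lesion_thresholds()) {
  stopifnot(inherits(thresholds, "nq_thresholds"))
  n <- if (is.data.frame(calls)) nrow(calls) else {
    if (!is_count(calls) || length(calls) != 1)
      nq_error("nq_value_error", "lesion count must be a nonnegative integer")
    as.integer(calls)
  }
  if (n > thresholds$severe_if_more_than) "severe"
  else if (n > thresholds$affected_if_more_than) "affected"
  else "unaffected"
}

#' Summarise per-fish results by group
#'
#' @param per_fish data.frame with columns `group`, `severity`, `status`.
#' @param groups optional vector of expected group labels; labels present
#'   in the data but not listed raise an error, and the summary rows
#'   follow the listed order.
#' @param digits decimal places for the percentage columns (default 2).
#' @return data.frame (group, n, mean_severity, pct_affected, pct_severe);
#'   `pct_affected` counts affected-or-severe fish (more than the affected
#'   threshold), `pct_severe` counts severe only.
#' @export
summarize_cohort <- function(per_fish, groups = NULL, digits = 2) {
  stopifnot(is.data.frame(per_fish),
            all(c("group", "severity", "status") %in% names(per_fish)))
  labs <- unique(per_fish$group)
  if (!is.null(groups)) {
    unknown <- setdiff(labs, groups)
    if (length(unknown))
      nq_error("nq_value_error",
               paste("unknown group label(s):", paste(unknown, collapse = ", ")))
    labs <- groups[groups %in% labs]
  }
  rows <- lapply(labs, function(g) {
    d <- per_fish[per_fish$group == g, ]
    sev <- d$severity[is.finite(d$severity)]
    if (!length(sev))
      nq_error("nq_value_error", sprintf("group '%s' has no severity values", g))
    data.frame(group = g, n = nrow(d),
               mean_severity = mean(sev),
               pct_affected = round(100 * mean(d$status %in% c("affected", "severe")),
                                    digits),
               pct_severe = round(100 * mean(d$status == "severe"), digits))
  })
  do.call(rbind, rows)
}
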