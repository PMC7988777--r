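# End-to-end pipeline entry points tying the modules together: simulate a
# cohort to disk, quantify a set of images into per-fish and per-lesion
# tables, run the group comparison, and score spine count tables. Each
# writer stamps its output directory with the configuration fingerprint
# and package version (run_info.json); no timestamps, so reruns with the
# same inputs are byte-identical. Per-fish failures never abort a cohort
# run: the fish is flagged and the run continues.

#' Pipeline configuration
#'
#' All tunable parameters of the quantification pipeline in one
#' serialisable object. Defaults match the synthetic study conditions
#' (16-bit grey scale); `threshold` and `min_area` are on the grey-value
#' scale of the input images and must be adapted to other data.
#'
#' @param threshold segmentation grey-value threshold (ignored when
#'   `auto_threshold = TRUE`).
#' @param auto_threshold use Otsu's method instead of the manual
#'   threshold (off by default; manual thresholding is the published
#'   procedure).
#' @param degree centerline polynomial degree (default 6).
#' @param step profile sampling step, arc-length pixels.
#' @param linewidth odd number of normal samples averaged per profile
#'   point.
#' @param peak_k peak height criterion in robust SDs.
#' @param min_separation peak merge radius, arc-length pixels.
#' @param min_area minimum lesion area above baseline (grey x pixels);
#'   the operational form of the "broader area under the peak" criterion,
#'   rejecting narrow noise spikes.
#' @param affected_gt,severe_gt classification thresholds: affected with
#'   more than `affected_gt` lesions, severe with more than `severe_gt`.
#' @param seed seed for any randomised stage.
#' @return object of class `nq_config`.
#' @export
pipeline_config <- function(threshold = 5000, auto_threshold = FALSE,
                            degree = 6, step = 1, linewidth = 1,
                            peak_k = 3, min_separation = 10,
                            min_area = 15000, affected_gt = 3,
                            severe_gt = 5, seed = 1L) {
  stopifnot(degree >= 1, step > 0, linewidth >= 1, linewidth %% 2 == 1,
            peak_k >= 0, min_separation >= 0, min_area >= 0,
            severe_gt >= affected_gt)
  structure(list(threshold = threshold,
                 auto_threshold = isTRUE(auto_threshold),
                 degree = as.integer(degree), step = step,
                 linewidth = as.integer(linewidth), peak_k = peak_k,
                 min_separation = min_separation, min_area = min_area,
                 affected_gt = as.integer(affected_gt),
                 severe_gt = as.integer(severe_gt),
                 seed = as.integer(seed)),
            class = "nq_config")
}

config_hash <- function(config) {
  fnv1a_hash(as.character(jsonlite::toJSON(unclass(config), digits = NA,
                                           auto_unbox = TRUE)))
}

write_run_info <- function(dir, config) {
  info <- list(package = "notoquant",
               version = as.character(packageVersion("notoquant")),
               config = unclass(config),
               config_hash = config_hash(config))
  writeLines(as.character(jsonlite::toJSON(info, digits = NA,
                                           auto_unbox = TRUE, pretty = TRUE)),
             file.path(dir, "run_info.json"))
}

#' Quantify one notochord image
#'
#' Runs the full per-fish pipeline: threshold segmentation (manual or
#' Otsu), largest 8-connected component, auto-transposition when the mask
#' bounding box is taller than wide (the fit assumes a roughly horizontal
#' notochord), degree-`degree` polynomial centerline fit, arc-length
#' intensity profile, mean-profile severity, peak-based lesion calls and
#' classification.
#'
#' @param image grey-value matrix.
#' @param config a [pipeline_config()].
#' @return list with `severity` (`nq_severity`), `lesions` (calls
#'   data.frame), `status`, `n_lesions`, `curve`, `profile`, and QC fields
#'   `mask_size`, `fit_rms`, `n_dropped`, `transposed`.
#' @export
quantify_image <- function(image, config = pipeline_config()) {
  stopifnot(is.matrix(image), inherits(config, "nq_config"))
  thr <- if (config$auto_threshold) auto_threshold(image) else config$threshold
  if (is.null(thr)) nq_error("nq_value_error", "no threshold configured")
  mask <- threshold_mask(image, thr)
  mask <- largest_component(mask)
  bbox_w <- diff(range(mask$coords$x)) + 1
  bbox_h <- diff(range(mask$coords$y)) + 1
  transposed <- FALSE
  if (bbox_h > bbox_w) {
    message("mask taller than wide: transposing image before centerline fit")
    image <- t(image)
    mask <- structure(list(coords = data.frame(x = mask$coords$y,
                                               y = mask$coords$x),
                           dim = rev(mask$dim)),
                      class = "nq_mask")
    transposed <- TRUE
  }
  curve <- fit_polynomial_centerline(mask, degree = config$degree)
  profile <- extract_profile(image, curve, step = config$step,
                             linewidth = config$linewidth)
  sev <- severity_score(profile)
  calls <- detect_peaks(profile, k = config$peak_k,
                        min_separation = config$min_separation,
                        min_area = config$min_area)
  thresholds <- lesion_thresholds(config$affected_gt, config$severe_gt)
  list(severity = sev, lesions = calls,
       n_lesions = nrow(calls),
       status = classify_fish(calls, thresholds),
       curve = curve, profile = profile,
       threshold_used = thr,
       mask_size = nrow(mask$coords),
       fit_rms = curve$rms_residual,
       n_dropped = profile$n_dropped,
       transposed = transposed)
}

#' Simulate a cohort to disk
#'
#' Generates the cohort, then writes one image per fish (TIFF by default),
#' one ground-truth JSON per fish, and a manifest CSV (fish_id, group,
#' image_path, truth_path). All fish are generated and validated before
#' anything is written, so an invalid spec leaves no partial manifest.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @param format `"tiff"` or `"png"` (PNG requires 8-bit specs).
#' @return the manifest data.frame, invisibly.
#' @export
nq_simulate <- function(spec, out_dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") ".tif" else ".png"
  cohort <- generate_cohort(spec)  # validates geometry before any write
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(fish) {
    img_path <- file.path(out_dir, paste0(fish$fish_id, ext))
    truth_path <- file.path(out_dir, paste0(fish$fish_id, "_truth.json"))
    write_image(fish$image, img_path)
    truth_to_json(fish$truth, truth_path)
    data.frame(fish_id = fish$fish_id, group = fish$group,
               image_path = basename(img_path),
               truth_path = basename(truth_path))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Quantify a cohort of images
#'
#' Accepts either a manifest CSV (as written by [nq_simulate()]) or a
#' vector of image paths with a parallel `groups` vector. Each fish is
#' quantified independently; failures (unreadable file, empty mask, fit
#' error) are flagged in the output and do not abort the run. Writes
#' `per_fish.csv`, `per_lesion.csv` and `run_info.json` when `out_dir` is
#' given.
#'
#' @param images manifest CSV path, or character vector of image paths.
#' @param config a [pipeline_config()].
#' @param groups group labels parallel to `images` (ignored when `images`
#'   is a manifest).
#' @param out_dir optional output directory.
#' @return list with `per_fish` and `per_lesion` data.frames.
#' @export
nq_quantify <- function(images, config = pipeline_config(), groups = NULL,
                        out_dir = NULL) {
  if (length(images) == 1 && grepl("\\.csv$", images, ignore.case = TRUE)) {
    manifest <- read.csv(images, stringsAsFactors = FALSE)
    base <- dirname(images)
    paths <- file.path(base, manifest$image_path)
    groups <- manifest$group
    ids <- manifest$fish_id
  } else {
    paths <- images
    if (is.null(groups)) groups <- rep("all", length(paths))
    ids <- tools::file_path_sans_ext(basename(paths))
  }
  per_fish <- list(); per_lesion <- list()
  n_failed <- 0L
  for (i in seq_along(paths)) {
    res <- tryCatch({
      img <- read_image(paths[i])
      q <- quantify_image(img, config)
      lf <- q$lesions
      if (nrow(lf)) {
        lf <- cbind(fish_id = ids[i], lf)
        per_lesion[[length(per_lesion) + 1]] <- lf
      }
      data.frame(fish_id = ids[i], group = groups[i],
                 severity = q$severity$mean_intensity,
                 n_lesions = q$n_lesions, status = q$status,
                 n_dropped_samples = q$n_dropped,
                 mask_size = q$mask_size, fit_rms = q$fit_rms,
                 failed = FALSE, message = "")
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      data.frame(fish_id = ids[i], group = groups[i],
                 severity = NA_real_, n_lesions = NA_integer_,
                 status = "failed", n_dropped_samples = NA_integer_,
                 mask_size = NA_integer_, fit_rms = NA_real_,
                 failed = TRUE, message = conditionMessage(e))
    })
    per_fish[[i]] <- res
  }
  per_fish <- do.call(rbind, per_fish)
  per_lesion <- if (length(per_lesion)) do.call(rbind, per_lesion)
  else data.frame(fish_id = character(0), position = numeric(0),
                  height = numeric(0), area = numeric(0),
                  left = numeric(0), right = numeric(0))
  if (n_failed > 0)
    message(sprintf("%d of %d fish failed quantification (flagged in output)",
                    n_failed, length(paths)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_fish, file.path(out_dir, "per_fish.csv"), row.names = FALSE)
    write.csv(per_lesion, file.path(out_dir, "per_lesion.csv"),
              row.names = FALSE)
    write_run_info(out_dir, config)
  }
  list(per_fish = per_fish, per_lesion = per_lesion)
}

#' Group comparison report for a quantified cohort
#'
#' Kruskal-Wallis omnibus on per-fish severities, Dunn's pairwise post hoc
#' with Bonferroni adjustment, and a per-group summary (n, mean severity,
#' percent affected / severe). Fish flagged as failed are excluded. Writes
#' `summary.csv`, `pairwise.csv` and `omnibus.json` when `out_dir` is
#' given.
#'
#' @param per_fish per-fish data.frame (from [nq_quantify()]) or a CSV
#'   path; needs `group`, `severity`, `status` columns.
#' @param out_dir optional output directory.
#' @param config optional [pipeline_config()] recorded in `run_info.json`.
#' @return list with `summary`, `omnibus`, `pairwise`.
#' @export
nq_cohort <- function(per_fish, out_dir = NULL, config = NULL) {
  if (is.character(per_fish)) per_fish <- read.csv(per_fish,
                                                   stringsAsFactors = FALSE)
  for (col in c("group", "severity", "status"))
    if (!col %in% names(per_fish))
      nq_error("nq_value_error", paste("missing column:", col))
  ok <- is.finite(per_fish$severity)
  d <- per_fish[ok, ]
  if (length(unique(d$group)) < 2)
    nq_error("nq_value_error", "need at least 2 groups with usable severities")
  omnibus <- kruskal_wallis(d$severity, d$group)
  pairwise <- dunn_posthoc(d$severity, d$group)
  summ <- summarize_cohort(d)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    write.csv(pairwise, file.path(out_dir, "pairwise.csv"), row.names = FALSE)
    writeLines(as.character(jsonlite::toJSON(
      list(statistic = omnibus$statistic, df = omnibus$df,
           p_value = omnibus$p_value),
      digits = NA, auto_unbox = TRUE)), file.path(out_dir, "omnibus.json"))
    if (!is.null(config)) write_run_info(out_dir, config)
  }
  list(summary = summ, omnibus = omnibus, pairwise = pairwise)
}

#' Score a spine count table
#'
#' Applies the vertebral severity rubric to a table of per-fish fusion and
#' cleft counts. Malformed rows (negative or non-integer counts) are
#' reported with their row numbers.
#'
#' @param counts data.frame or CSV path with `fusions` and `clefts`
#'   columns.
#' @param mode passed to [score_fish()].
#' @param out optional output CSV path.
#' @return the scored data.frame.
#' @export
nq_score_spine <- function(counts, mode = "independent", out = NULL) {
  if (is.character(counts)) {
    if (!file.exists(counts))
      nq_error("nq_io_error", paste("file not found:", counts))
    counts <- read.csv(counts, stringsAsFactors = FALSE)
  }
  if (!nrow(counts)) nq_error("nq_value_error", "empty count table")
  for (col in c("fusions", "clefts")) {
    v <- suppressWarnings(as.numeric(counts[[col]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      nq_error("nq_value_error", sprintf(
        "malformed %s at row(s): %s", col, paste(bad, collapse = ", ")))
    counts[[col]] <- as.integer(v)
  }
  scored <- score_fish(counts, mode = mode)
  if (!is.null(out)) write.csv(scored, out, row.names = FALSE)
  scored
}
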