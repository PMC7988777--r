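# Step one of the pipeline: detect notochord pixels by intensity
# thresholding. Inclusion uses ">= threshold"; component selection keeps
# the largest 8-connected component so stray bright debris cannot corrupt
# the centerline fit.

#' Threshold an image into a notochord mask
#'
#' Returns the set of pixels whose intensity is greater than or equal to
#' the threshold (the threshold itself is included). This is the manual
#' intensity threshold of the pipeline's first step.
#'
#' @param image numeric matrix (class `nq_image` or plain matrix).
#' @param threshold grey value.
#' @return object of class `nq_mask`: list with `coords` (data.frame x, y,
#'   0-based) and `dim` (c(height, width)).
#' @export
threshold_mask <- function(image, threshold) {
  stopifnot(is.matrix(image), length(image) > 0, is.numeric(threshold))
  idx <- which(image >= threshold, arr.ind = TRUE)
  rownames(idx) <- NULL
  if (nrow(idx) == 0)
    nq_error("nq_segmentation_error", sprintf(
      "no notochord detected: no pixel reaches threshold %g", threshold),
      threshold = threshold)
  structure(list(coords = data.frame(x = unname(idx[, 2] - 1L),
                                     y = unname(idx[, 1] - 1L)),
                 dim = dim(image)),
            class = "nq_mask")
}

#' Keep the largest 8-connected component of a mask
#'
#' Components are 8-connected (diagonal neighbours count, so a tube at a
#' shallow diagonal stays one piece). Ties on size are broken by smallest
#' minimum x, then smallest minimum y.
#'
#' @param mask an `nq_mask`.
#' @return an `nq_mask` containing only the winning component.
#' @export
largest_component <- function(mask) {
  stopifnot(inherits(mask, "nq_mask"))
  H <- mask$dim[1]; W <- mask$dim[2]
  lin <- mask$coords$y + 1L + H * mask$coords$x  # 1-based linear index
  inmask <- logical(H * W)
  inmask[lin] <- TRUE
  # edges to 4 of the 8 neighbours (the other 4 are the reverse direction)
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))  # (dy, dx)
  edges <- list()
  x <- mask$coords$x; y <- mask$coords$y
  for (o in offsets) {
    nx <- x + o[2]; ny <- y + o[1]
    ok <- nx >= 0 & nx < W & ny >= 0 & ny < H
    nlin <- ny + 1L + H * nx
    ok[ok] <- inmask[nlin[ok]]
    if (any(ok)) edges[[length(edges) + 1]] <- cbind(lin[ok], nlin[ok])
  }
  if (length(edges)) {
    em <- do.call(rbind, edges)
    # map linear indices to vertex ids 1..n
    vid <- integer(H * W)
    vid[lin] <- seq_along(lin)
    g <- igraph::graph_from_edgelist(cbind(vid[em[, 1]], vid[em[, 2]]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(lin) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(lin)  # all isolated pixels
  }
  comp_size <- tabulate(memb)
  comp_minx <- tapply(x, memb, min)
  comp_miny <- tapply(y, memb, min)
  ord <- order(-comp_size, comp_minx, comp_miny)
  win <- as.integer(names(comp_minx))[ord[1]]
  keep <- memb == win
  structure(list(coords = data.frame(x = x[keep], y = y[keep]),
                 dim = mask$dim),
            class = "nq_mask")
}

#' Otsu threshold for an intensity image
#'
#' Scans candidate grey values and returns the one that maximises the
#' between-class variance of the split `{I < t}` vs `{I >= t}` over the
#' integer histogram (the smallest maximiser on plateaus). Provided as an
#' optional fallback when no manual threshold is supplied; manual
#' thresholding remains the default behaviour of the pipeline.
#'
#' @param image numeric matrix with at least two distinct values.
#' @return grey value suitable for [threshold_mask()].
#' @export
auto_threshold <- function(image) {
  stopifnot(is.matrix(image))
  v <- as.vector(image)
  lev <- sort(unique(v))
  if (length(lev) < 2)
    nq_error("nq_value_error", "constant image: no threshold exists")
  counts <- tabulate(match(v, lev))
  n <- length(v)
  w <- cumsum(counts) / n                  # weight of {I < t} after level i
  mu <- cumsum(counts * lev) / n
  mu_t <- mu[length(mu)]
  # split after level i: class0 = levels 1..i, class1 = rest
  i <- seq_len(length(lev) - 1)
  w0 <- w[i]; w1 <- 1 - w0
  m0 <- mu[i] / w0; m1 <- (mu_t - mu[i]) / w1
  bcv <- w0 * w1 * (m0 - m1)^2
  best <- which.max(bcv)                   # which.max: first (smallest) maximiser
  # midpoint between the two classes' adjacent levels: same mask as any
  # threshold in the gap, and strictly between the class extremes
  (lev[best] + lev[best + 1]) / 2
}

#' Write a binary mask as a PNG or a CSV coordinate list
#'
#' @param mask an `nq_mask`.
#' @param path output path; `.png` writes a binary image, anything else a
#'   CSV with 0-based `x`, `y` columns.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "nq_mask"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- matrix(0, mask$dim[1], mask$dim[2])
    m[cbind(mask$coords$y + 1L, mask$coords$x + 1L)] <- 1
    png::writePNG(m, path)
  } else {
    write.csv(mask$coords, path, row.names = FALSE)
  }
  invisible(path)
}
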