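#' Segment nuclei from the smoothed reference-channel signal
#'
#' The diffuse intranuclear signal of the detector (reference) channel,
#' heavily smoothed, outlines each nucleus. The smoothed projection is
#' thresholded (Otsu by default on the image's own intensity range, which
#' makes the result invariant to constant offsets), holes are filled, small
#' and large objects are discarded, touching nuclei can optionally be split
#' by a watershed on the distance transform, and the remaining components
#' are labeled.
#'
#' @param reference_projection 2D matrix (max projection of the reference
#'   channel), nonnegative.
#' @param smooth_sigma Gaussian smoothing sigma, pixels.
#' @param min_area,max_area object area bounds, pixels.
#' @param threshold `"otsu"` or a numeric threshold on the smoothed image.
#' @param split_touching if `TRUE`, split touching nuclei by watershed on
#'   the distance transform.
#' @return an object of class `nucleus_map`: list with `labels` (integer
#'   matrix, 0 = background) and `cells` (data frame: `label`, `area`,
#'   `centroid_y`, `centroid_x`, `border`).
#' @export
segment_nuclei <- function(reference_projection, smooth_sigma = 5,
                           min_area = 500, max_area = Inf,
                           threshold = "otsu", split_touching = FALSE) {
  stopifnot(is.matrix(reference_projection), all(reference_projection >= 0),
            smooth_sigma > 0, min_area >= 0)
  g <- EBImage::gblur(reference_projection, sigma = smooth_sigma)
  rg <- range(g)
  if (diff(rg) < 1e-12) {
    warning("blank image: no nuclei found")
    return(.nucleus_map(matrix(0L, nrow(g), ncol(g))))
  }
  gs <- (g - rg[1]) / diff(rg)
  th <- if (identical(threshold, "otsu")) EBImage::otsu(EBImage::Image(gs))
        else (threshold - rg[1]) / diff(rg)
  bw <- gs > th
  bw <- EBImage::fillHull(bw)
  lab <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(bw), tolerance = 1)
  } else {
    EBImage::bwlabel(bw)
  }
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(bw), ncol(bw))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0L) {
    warning("no nucleus within area bounds")
    return(.nucleus_map(matrix(0L, nrow(lab), ncol(lab))))
  }
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  .nucleus_map(lab)
}

## build the per-nucleus table from a label matrix
.nucleus_map <- function(lab) {
  n <- max(lab)
  if (n == 0L) {
    cells <- data.frame(label = integer(0), area = integer(0),
                        centroid_y = numeric(0), centroid_x = numeric(0),
                        border = logical(0))
  } else {
    pos <- which(lab > 0L)
    l <- lab[pos]
    yy <- (pos - 1L) %% nrow(lab) + 1L
    xx <- (pos - 1L) %/% nrow(lab) + 1L
    cells <- data.frame(
      label = seq_len(n),
      area = tabulate(l, n),
      centroid_y = as.vector(tapply(yy, l, mean)),
      centroid_x = as.vector(tapply(xx, l, mean)),
      border = vapply(seq_len(n), function(i) {
        any(yy[l == i] %in% c(1L, nrow(lab))) ||
          any(xx[l == i] %in% c(1L, ncol(lab)))
      }, logical(1)))
  }
  structure(list(labels = lab, cells = cells), class = "nucleus_map")
}

#' @export
print.nucleus_map <- function(x, ...) {
  cat(sprintf("nucleus_map: %d nuclei (%d border-touching)\n",
              nrow(x$cells), sum(x$cells$border)))
  invisible(x)
}

#' Remove border-touching nuclei
#'
#' Nuclei cut by the frame edge cannot be measured completely; with
#' `exclude_border = TRUE` they are dropped and the remaining labels are
#' renumbered contiguously.
#'
#' @param map a [segment_nuclei()] result.
#' @param exclude_border drop border-touching nuclei (default `TRUE`).
#' @return a `nucleus_map`.
#' @export
filter_cells <- function(map, exclude_border = TRUE) {
  stopifnot(inherits(map, "nucleus_map"))
  if (!exclude_border || nrow(map$cells) == 0L || !any(map$cells$border))
    return(map)
  keep <- map$cells$label[!map$cells$border]
  lab <- map$labels
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  .nucleus_map(lab)
}
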