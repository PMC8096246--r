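#' Detect diffraction-limited spots with a Laplacian-of-Gaussian filter
#'
#' Convolves the projection with a scale-normalized (negated) LoG kernel at
#' `sigma = expected_diameter / (2 * sqrt(2))`, the scale at which the LoG
#' response of a Gaussian blob of that diameter peaks. Local maxima of the
#' response exceeding `min_snr` times the robust noise level (median
#' absolute deviation of the response map, floored at 2% of the peak
#' response so the threshold stays defined on noise-free images) become
#' spot candidates; each
#' candidate's mask is the connected response region above half its peak.
#' The kernel is zero-mean, so detection is exactly invariant to constant
#' intensity offsets.
#'
#' @param channel_projection 2D matrix.
#' @param expected_diameter expected spot diameter, pixels (>= 3).
#' @param min_snr detection threshold in robust-noise units.
#' @param channel channel name recorded in the candidates (metadata).
#' @return list of spot candidates; each is a list with `channel`, `center`
#'   (`c(y, x)`, integer pixel), `scale` (sigma), `response` and `mask`
#'   (linear pixel indices). The list carries attributes `frame_dim` and
#'   `threshold`.
#' @export
detect_spots <- function(channel_projection, expected_diameter = 5,
                         min_snr = 5, channel = NA_character_) {
  stopifnot(is.matrix(channel_projection), expected_diameter >= 3)
  s <- expected_diameter / (2 * sqrt(2))
  resp <- .log_response(channel_projection, s)
  ## robust noise from the response map; the floor at 2% of the peak keeps
  ## the threshold defined on noise-free images (where the MAD vanishes and
  ## smooth background texture would otherwise pass)
  noise <- max(mad(resp), 0.02 * max(resp), 1e-12)
  thr <- min_snr * noise
  ny <- nrow(resp); nx <- ncol(resp)

  ## 8-neighborhood local maxima above threshold
  inner <- matrix(FALSE, ny, nx)
  ys <- 2:(ny - 1); xs <- 2:(nx - 1)
  r0 <- resp[ys, xs]
  ismax <- r0 > thr
  for (o in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
    if (!any(ismax)) break
    ismax <- ismax & (r0 >= resp[ys + o[1], xs + o[2]])
  }
  inner[ys, xs] <- ismax
  peaks <- which(inner)
  if (length(peaks) == 0L)
    return(structure(list(), frame_dim = c(ny, nx), threshold = thr))

  py <- (peaks - 1L) %% ny + 1L
  px <- (peaks - 1L) %/% ny + 1L
  pr <- resp[peaks]
  ## non-maximum suppression: plateaus and shoulder maxima within ~a spot
  ## radius collapse onto the strongest peak (ties broken by index order)
  ord <- order(-pr, peaks)
  sep <- max(2, 1.5 * s)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) > 0 &&
        any((py[i] - py[sel])^2 + (px[i] - px[sel])^2 < sep^2)) next
    sel <- c(sel, i)
  }
  sel <- sel[order(peaks[sel])]

  w <- ceiling(3 * s) + 1L
  spots <- lapply(sel, function(i) {
    yy <- max(1L, py[i] - w):min(ny, py[i] + w)
    xx <- max(1L, px[i] - w):min(nx, px[i] + w)
    sub <- resp[yy, xx, drop = FALSE] >= 0.5 * pr[i]
    lab <- EBImage::bwlabel(sub)
    comp <- lab[match(py[i], yy), match(px[i], xx)]
    m <- which(lab == comp)
    ly <- (m - 1L) %% nrow(lab) + 1L
    lx <- (m - 1L) %/% nrow(lab) + 1L
    mask <- (yy[ly] - 1L) + (xx[lx] - 1L) * ny + 1L
    list(channel = channel, center = c(y = py[i], x = px[i]),
         scale = s, response = pr[i], mask = as.integer(mask))
  })
  structure(spots, frame_dim = c(ny, nx), threshold = thr)
}

## scale-normalized negated LoG response (bright blobs -> positive peaks)
.log_response <- function(img, s) {
  k <- as.integer(2 * ceiling(4 * s) + 1)
  h <- (k - 1L) / 2L
  d <- (-h):h
  r2 <- outer(d^2, d^2, `+`)
  ## -sigma^2 * LoG, i.e. sigma-normalized blob response
  kern <- (1 - r2 / (2 * s^2)) * exp(-r2 / (2 * s^2))
  kern <- kern - mean(kern)            # flat regions -> exactly zero
  EBImage::filter2(img, kern, boundary = "replicate")
}

#' Pair detector and sensor spots into loci
#'
#' Greedy nearest-neighbor matching of sensor spots to detector spots
#' within `match_radius` (channels must already be registered). The
#' detector channel is authoritative for locus existence: unmatched
#' detector spots are kept with status `detector_only` (their sensor
#' intensity is later measured on the detector-defined mask, which is what
#' makes loci with no visible sensor signal quantifiable), while unmatched
#' sensor spots are discarded and counted.
#'
#' @param detector_spots,sensor_spots [detect_spots()] results.
#' @param match_radius maximum pairing distance, pixels.
#' @return list of loci (`locus_id`, `detector_spot`, `sensor_spot` or
#'   `NULL`, `unified_mask`, `status`, `pair_distance`), with attribute
#'   `n_sensor_dropped`.
#' @export
match_loci <- function(detector_spots, sensor_spots, match_radius = 3) {
  nd <- length(detector_spots); ns <- length(sensor_spots)
  pair <- rep(NA_integer_, nd)
  pdist <- rep(NA_real_, nd)
  if (nd > 0 && ns > 0) {
    dc <- t(vapply(detector_spots, `[[`, numeric(2), "center"))
    sc <- t(vapply(sensor_spots, `[[`, numeric(2), "center"))
    dm <- outer(dc[, 1], sc[, 1], `-`)^2 + outer(dc[, 2], sc[, 2], `-`)^2
    cand <- which(dm <= match_radius^2, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ## smallest distance first; ties by detector index, then sensor index
      ord <- order(dm[cand], cand[, 1], cand[, 2])
      used_s <- logical(ns)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!is.na(pair[i]) || used_s[j]) next
        pair[i] <- j; used_s[j] <- TRUE
        pdist[i] <- sqrt(dm[i, j])
      }
    }
  }
  loci <- lapply(seq_len(nd), function(i) {
    sp <- if (!is.na(pair[i])) sensor_spots[[pair[i]]] else NULL
    mask <- if (is.null(sp)) detector_spots[[i]]$mask
            else sort(union(detector_spots[[i]]$mask, sp$mask))
    list(locus_id = i, detector_spot = detector_spots[[i]],
         sensor_spot = sp, unified_mask = as.integer(mask),
         status = if (is.null(sp)) "detector_only" else "paired",
         pair_distance = pdist[i])
  })
  structure(loci, n_sensor_dropped = ns - sum(!is.na(pair)),
            frame_dim = attr(detector_spots, "frame_dim"))
}

#' Assign loci to nuclei
#'
#' Each locus takes the nucleus label under its detector-spot center; loci
#' on background (label 0) are discarded and counted. The unified mask is
#' clipped to the nucleus.
#'
#' @param loci a [match_loci()] result.
#' @param map a [segment_nuclei()] `nucleus_map` of the same frame.
#' @return the loci that fall inside nuclei, each with a `nucleus_id`
#'   field; attribute `n_background_dropped` counts the discarded ones.
#' @export
assign_to_nuclei <- function(loci, map) {
  stopifnot(inherits(map, "nucleus_map"))
  lab <- map$labels
  out <- list()
  dropped <- 0L
  for (lc in loci) {
    ctr <- lc$detector_spot$center
    id <- lab[ctr[1], ctr[2]]
    if (id == 0L) { dropped <- dropped + 1L; next }
    lc$nucleus_id <- id
    lc$unified_mask <- lc$unified_mask[lab[lc$unified_mask] == id]
    out[[length(out) + 1L]] <- lc
  }
  structure(out, n_background_dropped = dropped, frame_dim = dim(lab))
}
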