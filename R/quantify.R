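#' Build the concentric background rim of a locus
#'
#' The local background around a locus is estimated on a concentric band
#' ("rim", default width 5 pixels) obtained by dilating the locus mask with
#' a disc of radius `width` and removing the locus itself. The rim is
#' clipped to the nucleus and excludes the pixels of all other loci
#' (each dilated by 1 px), so neighbouring signals never contaminate the
#' background estimate.
#'
#' @param locus_mask integer linear pixel indices of the locus.
#' @param width rim width, pixels (>= 1; default 5).
#' @param nucleus_mask linear indices of the locus's nucleus.
#' @param other_loci_masks list of linear-index masks of the other loci in
#'   the frame (only those near the locus matter).
#' @param dim `c(ny, nx)` frame shape.
#' @return integer linear indices of the rim; `integer(0)` when the
#'   exclusions leave nothing (the caller marks the locus invalid).
#' @export
make_rim <- function(locus_mask, width = 5, nucleus_mask, other_loci_masks,
                     dim) {
  stopifnot(width >= 1, length(locus_mask) > 0, length(dim) == 2L)
  ny <- dim[1]; nx <- dim[2]
  ly <- (locus_mask - 1L) %% ny + 1L
  lx <- (locus_mask - 1L) %/% ny + 1L
  pad <- as.integer(width) + 2L
  y0 <- max(1L, min(ly) - pad); y1 <- min(ny, max(ly) + pad)
  x0 <- max(1L, min(lx) - pad); x1 <- min(nx, max(lx) + pad)
  wy <- y1 - y0 + 1L; wx <- x1 - x0 + 1L
  to_local <- function(idx) {
    yy <- (idx - 1L) %% ny + 1L
    xx <- (idx - 1L) %/% ny + 1L
    ok <- yy >= y0 & yy <= y1 & xx >= x0 & xx <= x1
    (yy[ok] - y0 + 1L) + (xx[ok] - x0) * wy
  }
  loc <- matrix(FALSE, wy, wx)
  loc[to_local(locus_mask)] <- TRUE
  brush <- EBImage::makeBrush(2L * as.integer(width) + 1L, shape = "disc")
  dil <- EBImage::dilate(loc, brush) > 0
  rim <- dil & !loc
  nuc <- matrix(FALSE, wy, wx)
  nuc[to_local(nucleus_mask)] <- TRUE
  rim <- rim & nuc
  if (length(other_loci_masks) > 0) {
    oth <- matrix(FALSE, wy, wx)
    for (om in other_loci_masks) oth[to_local(om)] <- TRUE
    if (any(oth)) {
      oth <- EBImage::dilate(oth, EBImage::makeBrush(3L, "box")) > 0
      rim <- rim & !oth
    }
  }
  li <- which(rim)
  yy <- (li - 1L) %% wy + y0
  xx <- (li - 1L) %/% wy + x0
  as.integer(yy + (xx - 1L) * ny)
}

#' Compute the rim-corrected sensor/detector ratio
#'
#' The assay readout per locus is
#' `G/R = (I_Locus_Ch2 - I_Rim_Ch2) / (I_Locus_Ch1 - I_Rim_Ch1)`,
#' where Ch1 is the detector (reference) channel, Ch2 the sensor channel,
#' and `I_Locus` / `I_Rim` are mean intensities over the locus and rim
#' masks. The corrected sensor signal is floored at zero (a locus cannot
#' carry a negative mark density); a corrected detector signal at or below
#' `epsilon` leaves the ratio undefined (`valid = FALSE`), since the
#' detector signal is what defines the locus.
#'
#' @param m a data frame (or one-row list) with columns `I_Locus_Ch1`,
#'   `I_Rim_Ch1`, `I_Locus_Ch2`, `I_Rim_Ch2`.
#' @param epsilon positive validity floor for the corrected detector
#'   signal.
#' @return `m` with columns `ratio_GR` and `valid` replaced/added.
#' @export
compute_ratio <- function(m, epsilon = 1e-9) {
  den <- m$I_Locus_Ch1 - m$I_Rim_Ch1
  num <- pmax(m$I_Locus_Ch2 - m$I_Rim_Ch2, 0)
  valid <- den > epsilon
  m$ratio_GR <- ifelse(valid, num / den, NA_real_)
  m$valid <- valid
  m
}

#' Measure one locus in all channels
#'
#' Mean intensities over the unified locus mask and its rim are taken per
#' channel, either on the maximum-intensity z-projection (`z_mode =
#' "projection"`) or on each of the `k_slices` brightest slices with the
#' per-slice ratios averaged, weighted by each slice's corrected detector
#' signal (`z_mode = "per_slice"`, the remedy for z-axis chromatic jitter:
#' more slices, less measurement variation).
#'
#' @param stack registered [image_stack()] with `detector` and `sensor`
#'   channels.
#' @param locus a locus from [assign_to_nuclei()].
#' @param rim rim pixel indices from [make_rim()].
#' @param z_mode `"projection"` or `"per_slice"`.
#' @param k_slices number of brightest slices used in `per_slice` mode.
#' @param epsilon denominator validity floor; `NULL` (default) uses 3x the
#'   standard error of the detector rim.
#' @return one-row data frame (a `LocusMeasurement`): locus / nucleus ids,
#'   the four mean intensities, `ratio_GR`, `valid`, `reason`,
#'   `n_slices_used`.
#' @export
measure_locus <- function(stack, locus, rim,
                          z_mode = c("projection", "per_slice"),
                          k_slices = 3L, epsilon = NULL) {
  z_mode <- match.arg(z_mode)
  mask <- locus$unified_mask
  row <- data.frame(locus_id = locus$locus_id,
                    nucleus_id = locus$nucleus_id %||% NA_integer_,
                    I_Locus_Ch1 = NA_real_, I_Rim_Ch1 = NA_real_,
                    I_Locus_Ch2 = NA_real_, I_Rim_Ch2 = NA_real_,
                    ratio_GR = NA_real_, valid = FALSE, reason = "",
                    n_slices_used = 0L, status = locus$status)
  if (length(rim) == 0L) { row$reason <- "empty_rim"; return(row) }
  if (length(mask) == 0L) { row$reason <- "empty_mask"; return(row) }
  ## masks overlapping resampled-invalid pixels cannot be trusted
  for (v in stack$valid) {
    if (!all(v[mask]) || !all(v[rim])) {
      row$reason <- "out_of_frame"; return(row)
    }
  }
  det <- stack_channel(stack, "detector")
  sen <- stack_channel(stack, "sensor")
  nz <- dim(det)[3]
  plane_means <- function(a, z) {
    p <- a[, , z]
    c(locus = mean(p[mask]), rim = mean(p[rim]))
  }
  if (z_mode == "projection" || nz == 1L) {
    dp <- project_max(det); sp <- project_max(sen)
    row$I_Locus_Ch1 <- mean(dp[mask]); row$I_Rim_Ch1 <- mean(dp[rim])
    row$I_Locus_Ch2 <- mean(sp[mask]); row$I_Rim_Ch2 <- mean(sp[rim])
    row$n_slices_used <- nz
    if (is.null(epsilon))
      epsilon <- max(3 * sd(dp[rim]) / sqrt(length(rim)), 1e-9)
    row <- compute_ratio(row, epsilon)
  } else {
    k <- min(k_slices, nz)
    bright <- order(vapply(seq_len(nz),
                           function(z) mean(det[, , z][mask]),
                           numeric(1)), decreasing = TRUE)[seq_len(k)]
    per <- lapply(bright, function(z) {
      d <- plane_means(det, z); s <- plane_means(sen, z)
      data.frame(I_Locus_Ch1 = d["locus"], I_Rim_Ch1 = d["rim"],
                 I_Locus_Ch2 = s["locus"], I_Rim_Ch2 = s["rim"])
    })
    per <- do.call(rbind, per)
    if (is.null(epsilon))
      epsilon <- max(3 * sd(det[, , bright[1]][rim]) / sqrt(length(rim)), 1e-9)
    per <- compute_ratio(per, epsilon)
    row$I_Locus_Ch1 <- mean(per$I_Locus_Ch1)
    row$I_Rim_Ch1 <- mean(per$I_Rim_Ch1)
    row$I_Locus_Ch2 <- mean(per$I_Locus_Ch2)
    row$I_Rim_Ch2 <- mean(per$I_Rim_Ch2)
    row$n_slices_used <- k
    if (any(per$valid)) {
      ## average of per-slice ratios weighted by the slice's corrected
      ## detector signal: out-of-focus slices carry little weight, so using
      ## more slices cannot inflate the variance of the estimate
      w <- (per$I_Locus_Ch1 - per$I_Rim_Ch1)[per$valid]
      row$ratio_GR <- sum(w * per$ratio_GR[per$valid]) / sum(w)
      row$valid <- TRUE
    } else row$reason <- "denominator_below_epsilon"
  }
  if (!row$valid && row$reason == "") row$reason <- "denominator_below_epsilon"
  row
}

#' Run the full per-image measurement chain
#'
#' Registers the sensor channel to the detector channel, segments nuclei
#' from the smoothed detector projection, detects spots in both channels,
#' pairs them, assigns them to nuclei, builds rims and measures every
#' locus. This is the programmatic equivalent of processing one microscopy
#' field.
#'
#' @param stack an [image_stack()] with `detector` and `sensor` channels
#'   (and optionally `aux` for RNA positivity).
#' @param config a configuration list as returned by [default_config()].
#' @return list with `measurements` (per-locus data frame, including an
#'   `rna_positive` column when an `aux` channel is present), `nuclei` (the
#'   `nucleus_map` used), `shift` (the estimated chromatic shift) and
#'   `log` (named counts of dropped objects).
#' @export
quantify_stack <- function(stack, config = default_config()) {
  stopifnot(inherits(stack, "image_stack"))
  cfg <- config
  det_proj <- project_channel(stack, "detector")
  sen_proj <- project_channel(stack, "sensor")

  shift <- estimate_shift(det_proj, sen_proj,
                          max_shift = cfg$registration$max_shift)
  stack <- apply_shift(stack, "sensor", shift,
                       max_shift = cfg$registration$max_shift)
  sen_proj <- project_channel(stack, "sensor")

  map <- segment_nuclei(det_proj,
                        smooth_sigma = cfg$segmentation$smooth_sigma,
                        min_area = cfg$segmentation$min_area,
                        max_area = cfg$segmentation$max_area,
                        split_touching = cfg$segmentation$split_touching)
  n_border <- sum(map$cells$border)
  map <- filter_cells(map, exclude_border = cfg$segmentation$exclude_border)

  dspots <- detect_spots(det_proj, cfg$detection$expected_diameter,
                         cfg$detection$min_snr, channel = "detector")
  sspots <- detect_spots(sen_proj, cfg$detection$expected_diameter,
                         cfg$detection$min_snr, channel = "sensor")
  loci <- match_loci(dspots, sspots, cfg$detection$match_radius)
  n_sensor_dropped <- attr(loci, "n_sensor_dropped")
  loci <- assign_to_nuclei(loci, map)
  n_bg <- attr(loci, "n_background_dropped")

  d <- dim(map$labels)
  nuc_masks <- lapply(map$cells$label, function(l) which(map$labels == l))
  names(nuc_masks) <- map$cells$label
  all_masks <- lapply(loci, `[[`, "unified_mask")
  rows <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    lc <- loci[[i]]
    rim <- make_rim(lc$unified_mask, width = cfg$quantification$rim_width,
                    nucleus_mask = nuc_masks[[as.character(lc$nucleus_id)]],
                    other_loci_masks = all_masks[-i], dim = d)
    m <- measure_locus(stack, lc, rim,
                       z_mode = cfg$quantification$z_mode,
                       k_slices = cfg$quantification$k_slices)
    m$center_y <- lc$detector_spot$center[1]
    m$center_x <- lc$detector_spot$center[2]
    m$shift_dy <- shift$dy
    m$shift_dx <- shift$dx
    rows[[i]] <- m
  }
  meas <- if (length(rows)) do.call(rbind, rows) else
    cbind(measure_locus(stack,
                        list(locus_id = integer(0)), integer(0))[0, ],
          center_y = numeric(0), center_x = numeric(0),
          shift_dy = numeric(0), shift_dx = numeric(0))

  if ("aux" %in% names(stack$channels) && nrow(meas) > 0) {
    aux_proj <- project_channel(stack, "aux")
    aux_mask <- aux_proj > median(aux_proj) + 3 * mad(aux_proj)
    frac <- vapply(loci, function(lc)
      mean(aux_mask[lc$unified_mask]), numeric(1))
    meas$rna_positive <- frac > cfg$stats$rna_overlap
  }
  list(measurements = meas, nuclei = map, shift = shift,
       log = c(n_border_nuclei = n_border,
               n_sensor_only_dropped = n_sensor_dropped,
               n_background_loci_dropped = n_bg,
               n_invalid = sum(!meas$valid)))
}

#' Aggregate locus measurements into per-cell records
#'
#' `population` mode keeps every valid locus. `allelic` mode keeps only
#' nuclei with exactly two valid loci: nuclei with more (e.g. replicated
#' loci) or fewer are excluded from allelic analysis.
#'
#' @param measurements per-locus data frame from [quantify_stack()].
#' @param mode `"population"` or `"allelic"`.
#' @return list with `loci` (kept measurements) and `cells` (per-nucleus
#'   summary: `nucleus_id`, `n_loci`, `ratio1`, `ratio2` (allelic mode),
#'   `mean_GR`); attributes `n_excluded_gt2` / `n_excluded_lt2` count the
#'   nuclei dropped in allelic mode.
#' @export
aggregate_cells <- function(measurements,
                            mode = c("population", "allelic")) {
  mode <- match.arg(mode)
  ok <- measurements[measurements$valid, , drop = FALSE]
  if (mode == "population") {
    cells <- if (nrow(ok)) {
      agg <- split(ok$ratio_GR, ok$nucleus_id)
      data.frame(nucleus_id = as.integer(names(agg)),
                 n_loci = lengths(agg),
                 mean_GR = vapply(agg, mean, numeric(1)),
                 row.names = NULL)
    } else data.frame(nucleus_id = integer(0), n_loci = integer(0),
                      mean_GR = numeric(0))
    return(structure(list(loci = ok, cells = cells), mode = mode))
  }
  counts <- table(ok$nucleus_id)
  keep_ids <- as.integer(names(counts)[counts == 2L])
  kept <- ok[ok$nucleus_id %in% keep_ids, , drop = FALSE]
  cells <- if (length(keep_ids)) {
    do.call(rbind, lapply(keep_ids, function(id) {
      sub <- kept[kept$nucleus_id == id, ]
      data.frame(nucleus_id = id, n_loci = 2L,
                 ratio1 = sub$ratio_GR[1], ratio2 = sub$ratio_GR[2],
                 locus_id1 = sub$locus_id[1], locus_id2 = sub$locus_id[2],
                 rna_positive1 = if ("rna_positive" %in% names(sub))
                   sub$rna_positive[1] else NA,
                 rna_positive2 = if ("rna_positive" %in% names(sub))
                   sub$rna_positive[2] else NA,
                 mean_GR = mean(sub$ratio_GR))
    }))
  } else data.frame(nucleus_id = integer(0), n_loci = integer(0),
                    ratio1 = numeric(0), ratio2 = numeric(0),
                    locus_id1 = integer(0), locus_id2 = integer(0),
                    rna_positive1 = logical(0), rna_positive2 = logical(0),
                    mean_GR = numeric(0))
  structure(list(loci = kept, cells = cells), mode = mode,
            n_excluded_gt2 = sum(counts > 2L),
            n_excluded_lt2 = sum(counts < 2L))
}
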