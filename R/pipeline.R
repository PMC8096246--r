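#' Default pipeline configuration
#'
#' All tunable parameters of the measurement chain in one nested list.
#' Every value can be overridden in a YAML config file ([read_config()]) or
#' programmatically.
#'
#' @return nested named list with sections `channels`, `registration`,
#'   `segmentation`, `detection`, `quantification`, `stats`.
#' @export
default_config <- function() {
  list(
    channels = list(detector = 1L, sensor = 2L, aux = 3L),
    registration = list(max_shift = 10),
    segmentation = list(smooth_sigma = 5, min_area = 500, max_area = Inf,
                        exclude_border = TRUE, split_touching = FALSE),
    detection = list(expected_diameter = 5, min_snr = 5, match_radius = 3),
    quantification = list(rim_width = 5, z_mode = "projection",
                          k_slices = 3L),
    stats = list(positivity_threshold = NULL, rna_overlap = 0.5,
                 min_cells = 25L)
  )
}

#' Read a YAML config, merged over the defaults
#'
#' @param path YAML file; keys mirror [default_config()]. Missing keys keep
#'   their defaults.
#' @return the merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_rec <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_rec(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_rec(default_config(), user)
}

.known_roles <- c("test", "no_antibody_control", "no_exonuclease_control")

#' Read a specimen manifest
#'
#' The manifest is a CSV with columns `path` (TIFF file), `role` and
#' `specimen` (free-text label). Valid roles are `test`,
#' `no_antibody_control`, `no_exonuclease_control` and
#' `calibration:<fraction>` (e.g. `calibration:0.33`).
#'
#' @param path CSV path.
#' @param base_dir directory against which relative image paths are
#'   resolved; defaults to the manifest's directory.
#' @return data frame with columns `path`, `role`, `specimen` and the
#'   parsed `calibration_fraction` (NA for non-calibration rows).
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  mf <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "role", "specimen")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  is_cal <- grepl("^calibration:", mf$role)
  bad <- !is_cal & !(mf$role %in% .known_roles)
  if (any(bad))
    stop("unknown manifest role(s): ", paste(unique(mf$role[bad]),
                                             collapse = ", "))
  mf$calibration_fraction <- ifelse(
    is_cal, suppressWarnings(as.numeric(sub("^calibration:", "", mf$role))),
    NA_real_)
  if (any(is_cal & is.na(mf$calibration_fraction)))
    stop("calibration roles must be 'calibration:<fraction>'")
  rel <- !grepl("^(/|[A-Za-z]:)", mf$path)
  mf$path[rel] <- file.path(base_dir, mf$path[rel])
  mf
}

## quantify one image file (or in-memory specimen) into per-locus rows
.quantify_one <- function(path_or_stack, config, channel_names) {
  stack <- if (inherits(path_or_stack, "image_stack")) path_or_stack
           else read_stack(path_or_stack, channel_names = channel_names)
  quantify_stack(stack, config)
}

#' Quantify every specimen in a manifest
#'
#' Runs the full measurement chain on every image, pools loci per
#' specimen, and (by default) normalizes ratios by the mean G/R of the
#' `no_exonuclease_control` specimens so the control mean is exactly 1.
#' Specimens with fewer analyzed cells than `config$stats$min_cells`
#' trigger a warning, mirroring the assay's minimum-cell guideline.
#'
#' @param manifest a [read_manifest()] data frame, or a named list of
#'   in-memory `eva_specimen` / [image_stack()] objects paired with a
#'   `roles` attribute.
#' @param config pipeline configuration ([default_config()]).
#' @param normalize divide ratios by the no-exonuclease control mean
#'   (default `TRUE`; requires such a control in the manifest).
#' @param channel_names channel names for TIFFs without a sidecar.
#' @return list with `loci` (pooled per-locus data frame with `specimen`,
#'   `role`, `normalized_GR` columns), `summary` (per-specimen data
#'   frame) and `shifts`.
#' @export
run_quantify <- function(manifest, config = default_config(),
                         normalize = TRUE,
                         channel_names = c("detector", "sensor")) {
  stopifnot(is.data.frame(manifest))
  rows <- list(); shifts <- list()
  for (i in seq_len(nrow(manifest))) {
    q <- .quantify_one(manifest$path[i], config, channel_names)
    m <- q$measurements
    if (nrow(m)) {
      m$specimen <- manifest$specimen[i]
      m$role <- manifest$role[i]
      rows[[length(rows) + 1L]] <- m
    }
    shifts[[manifest$specimen[i]]] <- q$shift
  }
  if (length(rows) == 0L) stop("no loci measured in any specimen")
  loci <- do.call(rbind, rows)

  if (normalize) {
    ctrl <- loci$ratio_GR[loci$role == "no_exonuclease_control" & loci$valid]
    if (length(ctrl) == 0L)
      stop("normalization requested but no no_exonuclease_control loci; ",
           "use normalize = FALSE for raw ratios")
    loci$normalized_GR <- normalize_to_control(loci$ratio_GR, ctrl)
  } else {
    loci$normalized_GR <- NA_real_
  }

  summ <- do.call(rbind, lapply(split(loci, loci$specimen), function(s) {
    ok <- s[s$valid, ]
    n_cells <- length(unique(ok$nucleus_id))
    data.frame(specimen = s$specimen[1], role = s$role[1],
               n_loci = nrow(ok), n_cells = n_cells,
               mean_GR = mean(ok$ratio_GR),
               median_GR = median(ok$ratio_GR),
               mean_normalized_GR = mean(ok$normalized_GR),
               cv = if (nrow(ok) >= 2 && mean(ok$ratio_GR) != 0)
                 coefficient_of_variation(ok$ratio_GR) else NA_real_)
  }))
  rownames(summ) <- NULL
  low <- summ$n_cells < (config$stats$min_cells %||% 25L)
  if (any(low))
    warning("specimen(s) below the minimum analyzed-cell guideline: ",
            paste(sprintf("%s (%d cells)", summ$specimen[low],
                          summ$n_cells[low]), collapse = ", "))
  list(loci = loci, summary = summ, shifts = shifts)
}

#' Run the dynamic-range calibration workflow
#'
#' Quantifies every `calibration:<fraction>` specimen, collapses loci to
#' per-cell mean G/R values per condition, and fits the dynamic range with
#' [calibrate_dynamic_range()].
#'
#' @param manifest [read_manifest()] data frame containing calibration
#'   rows for at least fractions 0 and 1.
#' @param config pipeline configuration.
#' @param channel_names channel names for TIFFs without a sidecar.
#' @return a [calibrate_dynamic_range()] result.
#' @export
run_calibrate <- function(manifest, config = default_config(),
                          channel_names = c("detector", "sensor")) {
  cal <- manifest[!is.na(manifest$calibration_fraction), , drop = FALSE]
  if (nrow(cal) == 0L) stop("manifest has no calibration specimens")
  fr <- sort(unique(cal$calibration_fraction))
  if (!any(fr == 0) || !any(fr == 1))
    stop("calibration requires both fraction 0 and fraction 1 specimens")
  cond <- list()
  for (f in fr) {
    sub <- cal[cal$calibration_fraction == f, , drop = FALSE]
    vals <- numeric(0)
    for (i in seq_len(nrow(sub))) {
      q <- .quantify_one(sub$path[i], config, channel_names)
      agg <- aggregate_cells(q$measurements, mode = "population")
      vals <- c(vals, agg$cells$mean_GR)
    }
    cond[[sprintf("%g", f)]] <- vals
  }
  calibrate_dynamic_range(cond)
}

#' Per-cell mean G/R values of an in-memory specimen
#'
#' Convenience wrapper used by the calibration and recovery workflows:
#' quantifies a specimen's stack and returns one mean valid G/R per
#' nucleus.
#'
#' @param specimen an `eva_specimen` (or bare [image_stack()]).
#' @param config pipeline configuration.
#' @return numeric vector of per-cell mean ratios.
#' @export
cell_mean_ratios <- function(specimen, config = default_config()) {
  stack <- if (inherits(specimen, "eva_specimen")) specimen$stack
           else specimen
  q <- quantify_stack(stack, config)
  aggregate_cells(q$measurements, mode = "population")$cells$mean_GR
}
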