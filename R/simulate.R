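#' Parameters for synthetic EVA specimens
#'
#' Bundles and validates every knob of the synthetic specimen generator.
#' The generator emulates the specimen classes of an EVA experiment: fields
#' of elliptical nuclei with textured diffuse signal, 0-4 diffraction-limited
#' foci per nucleus rendered as isotropic Gaussians, a linear additive
#' background gradient, a global chromatic translation of the sensor channel,
#' and shot + read noise.
#'
#' @param image_shape `c(ny, nx)` frame size in pixels.
#' @param n_z_slices number of optical slices (>= 1).
#' @param n_nuclei nuclei per field.
#' @param nucleus_axes `c(min, max)` range of ellipse semi-axes (pixels).
#' @param foci_per_nucleus foci count per nucleus: a scalar or a `c(lo, hi)`
#'   range sampled uniformly per nucleus.
#' @param true_ratio ground-truth sensor/detector ratio per focus: a scalar
#'   (all foci) or a vector sampled uniformly per focus.
#' @param detector_amplitude peak detector-focus amplitude (counts above the
#'   local diffuse signal).
#' @param psf_sigma lateral Gaussian PSF sigma (pixels).
#' @param psf_sigma_z axial Gaussian sigma (slices); ignored for single-plane
#'   stacks.
#' @param background_level extracellular background (counts).
#' @param background_gradient `c(gy, gx)` additive slope (counts/pixel).
#' @param nucleus_level mean diffuse intranuclear signal above background
#'   (counts, detector channel).
#' @param sensor_background_frac diffuse sensor signal as a fraction of the
#'   detector's diffuse signal.
#' @param texture_amp relative amplitude of the smooth multiplicative
#'   intranuclear texture.
#' @param chromatic_shift `c(dy, dx)` translation (pixels) applied to the
#'   sensor channel only.
#' @param noise `"shot_read"` (Poisson shot noise plus Gaussian read noise,
#'   clipped at zero) or `"none"`.
#' @param read_sigma read-noise standard deviation (counts).
#' @param min_separation minimum focus-focus distance within a nucleus
#'   (pixels); default `6 * psf_sigma` keeps rims free of neighbour signal.
#' @param seed RNG seed; fully determines the specimen.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(image_shape = c(512L, 512L), n_z_slices = 5L,
                       n_nuclei = 8L, nucleus_axes = c(18, 30),
                       foci_per_nucleus = 2L, true_ratio = 0.8,
                       detector_amplitude = 3000, psf_sigma = 1.7,
                       psf_sigma_z = 1.0, background_level = 100,
                       background_gradient = c(0.05, 0.08),
                       nucleus_level = 300, sensor_background_frac = 0.3,
                       texture_amp = 0.15, chromatic_shift = c(2, -3),
                       noise = c("shot_read", "none"), read_sigma = 10,
                       min_separation = NULL, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 64),
            is_count(n_z_slices), n_z_slices >= 1,
            is_count(n_nuclei),
            length(nucleus_axes) == 2L, all(nucleus_axes > 0),
            nucleus_axes[1] <= nucleus_axes[2],
            length(foci_per_nucleus) %in% 1:2, all(foci_per_nucleus >= 0),
            all(foci_per_nucleus == round(foci_per_nucleus)),
            all(true_ratio >= 0), detector_amplitude >= 0, psf_sigma > 0,
            psf_sigma_z > 0, background_level >= 0,
            length(background_gradient) == 2L,
            nucleus_level >= 0, sensor_background_frac >= 0,
            texture_amp >= 0, length(chromatic_shift) == 2L,
            all(is.finite(chromatic_shift)), read_sigma >= 0,
            is.numeric(seed), length(seed) == 1L)
  if (is.null(min_separation)) min_separation <- 6 * psf_sigma
  structure(list(image_shape = as.integer(image_shape),
                 n_z_slices = as.integer(n_z_slices),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_axes = nucleus_axes,
                 foci_per_nucleus = foci_per_nucleus,
                 true_ratio = true_ratio,
                 detector_amplitude = detector_amplitude,
                 psf_sigma = psf_sigma, psf_sigma_z = psf_sigma_z,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 nucleus_level = nucleus_level,
                 sensor_background_frac = sensor_background_frac,
                 texture_amp = texture_amp,
                 chromatic_shift = chromatic_shift,
                 noise = noise, read_sigma = read_sigma,
                 min_separation = min_separation,
                 seed = as.integer(seed)),
            class = "sim_params")
}

## rasterize a rotated ellipse into logical matrix coordinates
.ellipse_mask_indices <- function(cy, cx, a, b, theta, ny, nx) {
  r <- ceiling(max(a, b)) + 1L
  ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(y = rep(ys, times = length(xs))[as.vector(inside)],
        x = rep(xs, each = length(ys))[as.vector(inside)])
}

## add a Gaussian focus (amplitude amp, sigma s laterally, sz axially,
## centered at fractional (cy, cx, cz)) into a (y,x,z) array
.render_focus <- function(a, cy, cx, cz, amp, s, sz) {
  d <- dim(a)
  w <- ceiling(4 * s)
  ys <- max(1L, floor(cy - w)):min(d[1], ceiling(cy + w))
  xs <- max(1L, floor(cx - w)):min(d[2], ceiling(cx + w))
  g <- amp * outer(exp(-(ys - cy)^2 / (2 * s^2)),
                   exp(-(xs - cx)^2 / (2 * s^2)))
  if (d[3] == 1L) {
    a[ys, xs, 1L] <- a[ys, xs, 1L] + g
  } else {
    for (z in seq_len(d[3])) {
      wz <- exp(-(z - cz)^2 / (2 * sz^2))
      if (wz > 1e-6) a[ys, xs, z] <- a[ys, xs, z] + wz * g
    }
  }
  a
}

## core generator; `allelic` is NULL or
## list(fold, base_ratio, aux_amplitude, aux_sigma)
.render_specimen <- function(params, condition_label, allelic = NULL) {
  p <- params
  ny <- p$image_shape[1]; nx <- p$image_shape[2]; nz <- p$n_z_slices
  with_seed(p$seed, {
    ## --- nucleus placement (rejection sampling on bounding circles)
    margin <- p$nucleus_axes[2] + 4
    centers <- matrix(NA_real_, 0, 2)
    axes <- matrix(NA_real_, 0, 2); thetas <- numeric(0)
    tries <- 0L
    while (nrow(centers) < p$n_nuclei) {
      tries <- tries + 1L
      if (tries > 400L * max(1L, p$n_nuclei))
        stop("could not place ", p$n_nuclei, " non-overlapping nuclei in a ",
             ny, "x", nx, " frame")
      a <- runif(1, p$nucleus_axes[1], p$nucleus_axes[2])
      b <- runif(1, p$nucleus_axes[1], min(a, p$nucleus_axes[2]))
      cy <- runif(1, margin, ny - margin); cx <- runif(1, margin, nx - margin)
      if (nrow(centers) > 0) {
        dmin <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        if (any(dmin < apply(axes, 1, max) + a + 12)) next
      }
      centers <- rbind(centers, c(cy, cx))
      axes <- rbind(axes, c(a, b)); thetas <- c(thetas, runif(1, 0, pi))
    }

    labels <- matrix(0L, ny, nx)
    for (i in seq_len(p$n_nuclei)) {
      px <- .ellipse_mask_indices(centers[i, 1], centers[i, 2],
                                  axes[i, 1], axes[i, 2], thetas[i], ny, nx)
      labels[px] <- i
    }

    ## --- diffuse scenes: background + gradient + textured nuclear signal
    grad <- outer(seq_len(ny) * p$background_gradient[1],
                  rep(1, nx)) +
            outer(rep(1, ny), seq_len(nx) * p$background_gradient[2])
    texture <- EBImage::gblur(matrix(rnorm(ny * nx), ny, nx), sigma = 12)
    texture <- texture / max(sd(texture), 1e-12)
    interior <- labels > 0
    det_plane <- p$background_level + grad
    det_plane[interior] <- det_plane[interior] +
      p$nucleus_level * pmax(0.2, 1 + p$texture_amp * texture[interior])
    sen_plane <- p$sensor_background_frac * det_plane

    det <- array(rep(det_plane, nz), dim = c(ny, nx, nz))
    sen <- array(rep(sen_plane, nz), dim = c(ny, nx, nz))
    aux <- if (!is.null(allelic)) array(0, dim = c(ny, nx, nz)) else NULL

    ## --- foci
    truth <- list()
    fid <- 0L
    for (i in seq_len(p$n_nuclei)) {
      nf <- if (!is.null(allelic)) 2L
            else if (length(p$foci_per_nucleus) == 1L) p$foci_per_nucleus
            else sample(p$foci_per_nucleus[1]:p$foci_per_nucleus[2], 1L)
      if (nf == 0L) next
      pos <- matrix(NA_real_, 0, 2)
      ft <- 0L
      while (nrow(pos) < nf) {
        ft <- ft + 1L
        if (ft > 2000L)
          stop("focus placement impossible: nucleus ", i,
               " too small for ", nf, " foci at min separation ",
               signif(p$min_separation, 3))
        ## an unlucky early placement can block the rest; restart the set
        if (ft %% 150L == 0L) pos <- matrix(NA_real_, 0, 2)
        phi <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * 0.65
        u <- rr * axes[i, 1] * cos(phi); v <- rr * axes[i, 2] * sin(phi)
        fy <- centers[i, 1] + u * cos(thetas[i]) - v * sin(thetas[i])
        fx <- centers[i, 2] + u * sin(thetas[i]) + v * cos(thetas[i])
        if (labels[round(fy), round(fx)] != i) next
        if (nrow(pos) > 0 &&
            any(sqrt((pos[, 1] - fy)^2 + (pos[, 2] - fx)^2) <
                p$min_separation)) next
        pos <- rbind(pos, c(fy, fx))
      }
      if (!is.null(allelic)) rna_pos_idx <- sample(1:2, 1L)
      for (j in seq_len(nf)) {
        fid <- fid + 1L
        fz <- if (nz > 1L) runif(1, 1.5, nz - 0.5) else 1
        if (!is.null(allelic)) {
          rna <- (j == rna_pos_idx)
          ratio <- if (rna) allelic$base_ratio / allelic$fold
                   else allelic$base_ratio
        } else {
          rna <- NA
          ratio <- if (length(p$true_ratio) == 1L) p$true_ratio
                   else sample(p$true_ratio, 1L)
        }
        det <- .render_focus(det, pos[j, 1], pos[j, 2], fz,
                             p$detector_amplitude, p$psf_sigma, p$psf_sigma_z)
        sen <- .render_focus(sen, pos[j, 1], pos[j, 2], fz,
                             ratio * p$detector_amplitude,
                             p$psf_sigma, p$psf_sigma_z)
        if (!is.null(allelic) && rna)
          aux <- .render_focus(aux, pos[j, 1], pos[j, 2], fz,
                               allelic$aux_amplitude, allelic$aux_sigma,
                               p$psf_sigma_z)
        truth[[fid]] <- data.frame(
          focus_id = fid, nucleus_id = i, z = fz,
          y = pos[j, 1], x = pos[j, 2], true_ratio = ratio,
          detector_amplitude = p$detector_amplitude,
          condition_label = condition_label, rna_positive = rna)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(focus_id = integer(0), nucleus_id = integer(0),
                             z = numeric(0), y = numeric(0), x = numeric(0),
                             true_ratio = numeric(0),
                             detector_amplitude = numeric(0),
                             condition_label = character(0),
                             rna_positive = logical(0))

    ## --- chromatic shift: sensor content moves by +(dy, dx)
    cs <- p$chromatic_shift
    if (any(cs != 0)) {
      fill <- p$sensor_background_frac * p$background_level
      for (z in seq_len(nz)) {
        sh <- shift_plane(sen[, , z], -cs[1], -cs[2], fill = fill)
        attr(sh, "valid") <- NULL
        sen[, , z] <- sh
      }
    }

    ## --- noise, applied last
    if (p$noise == "shot_read") {
      noisify <- function(a) {
        n <- length(a)
        v <- rpois(n, lambda = as.vector(a)) + rnorm(n, 0, p$read_sigma)
        array(pmax(v, 0), dim = dim(a))
      }
      det <- noisify(det); sen <- noisify(sen)
      if (!is.null(aux)) aux <- noisify(aux)
    }

    chans <- list(detector = det, sensor = sen)
    if (!is.null(aux)) chans$aux <- aux
    structure(list(stack = image_stack(chans), nuclei = labels,
                   truth = truth, params = p,
                   condition_label = condition_label),
              class = "eva_specimen")
  })
}

#' Generate a synthetic EVA specimen with ground truth
#'
#' Renders one field of view: the detector channel carries Gaussian foci of
#' amplitude `detector_amplitude` on a textured nuclear background; the
#' sensor channel carries the same foci scaled by `true_ratio` and is then
#' translated by `chromatic_shift`; noise is applied last. The returned
#' truth table has exactly one row per rendered focus.
#'
#' @param params a [sim_params()] object.
#' @param condition_label free-text label copied into the truth table.
#' @return an object of class `eva_specimen`: a list with elements `stack`
#'   (an [image_stack()]), `nuclei` (the ground-truth integer label map),
#'   `truth` (a data frame with one row per focus) and `params`.
#' @export
generate_specimen <- function(params = sim_params(),
                              condition_label = "test") {
  stopifnot(inherits(params, "sim_params"))
  .render_specimen(params, condition_label)
}

#' @export
print.eva_specimen <- function(x, ...) {
  cat(sprintf("eva_specimen '%s': %d nuclei, %d foci\n",
              x$condition_label, x$params$n_nuclei, nrow(x$truth)))
  invisible(x)
}

#' Generate a labeled-fraction mixing series
#'
#' Emulates the dynamic-range calibration experiment: the labeled sensor
#' oligo is mixed with unlabeled oligo at several fractions, so the true
#' sensor/detector ratio of every focus in a condition is
#' `fraction * ratio_scale`. One specimen is generated per fraction, with
#' the fraction recorded as the condition label.
#'
#' @param fractions labeled-oligo fractions in `[0, 1]`; must be nonempty.
#' @param n_nuclei_per_condition nuclei per condition specimen.
#' @param params base [sim_params()]; `true_ratio`, `n_nuclei` and `seed`
#'   are overridden per condition (seeds are derived from `params$seed`).
#' @param ratio_scale G/R ratio of the fully labeled (fraction 1) condition.
#' @return a named list of `eva_specimen` objects (names are the fractions),
#'   with attributes `fractions` and `ratio_scale`.
#' @export
generate_mixing_series <- function(fractions, n_nuclei_per_condition = 25L,
                                   params = sim_params(),
                                   ratio_scale = 0.9) {
  if (length(fractions) == 0L) stop("fractions must be a nonempty vector")
  stopifnot(all(fractions >= 0 & fractions <= 1), ratio_scale > 0,
            inherits(params, "sim_params"))
  out <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    p <- params
    p$true_ratio <- fractions[i] * ratio_scale
    p$n_nuclei <- as.integer(n_nuclei_per_condition)
    p$seed <- params$seed + 1009L * i
    out[[i]] <- .render_specimen(p, sprintf("%.2f", fractions[i]))
  }
  names(out) <- sprintf("%.2f", fractions)
  attr(out, "fractions") <- fractions
  attr(out, "ratio_scale") <- ratio_scale
  out
}

#' Generate a heterozygous (allelic) specimen with an RNA-positivity channel
#'
#' Emulates a cell population in which each nucleus carries exactly two
#' copies of the probed gene, one transcribed (RNA+) and one silent (RNA-).
#' The RNA+ focus has true ratio `base_ratio / fold_difference` and is
#' marked by a diffuse blob in an auxiliary channel (the RNA FISH signal);
#' the RNA- focus has ratio `base_ratio`.
#'
#' @param fold_difference true RNA-/RNA+ ratio fold difference (> 0).
#' @param n_nuclei number of nuclei.
#' @param params base [sim_params()]; `n_nuclei` is overridden and every
#'   nucleus gets exactly two foci.
#' @param base_ratio G/R truth at the RNA- (methylated) focus.
#' @param aux_amplitude,aux_sigma amplitude (counts) and lateral sigma
#'   (pixels) of the RNA FISH blob in the auxiliary channel.
#' @return an `eva_specimen` whose stack has an `aux` channel and whose
#'   truth table has a logical `rna_positive` column.
#' @export
generate_allelic_specimen <- function(fold_difference, n_nuclei = 25L,
                                      params = sim_params(),
                                      base_ratio = 0.8,
                                      aux_amplitude = 2000,
                                      aux_sigma = 2.5) {
  if (!is.numeric(fold_difference) || length(fold_difference) != 1L ||
      fold_difference <= 0)
    stop("fold_difference must be a single positive number")
  stopifnot(inherits(params, "sim_params"), base_ratio > 0)
  p <- params
  p$n_nuclei <- as.integer(n_nuclei)
  p$foci_per_nucleus <- 2L
  .render_specimen(p, "allelic",
                   allelic = list(fold = fold_difference,
                                  base_ratio = base_ratio,
                                  aux_amplitude = aux_amplitude,
                                  aux_sigma = aux_sigma))
}
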