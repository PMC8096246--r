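#' Estimate the inter-channel translation (chromatic shift)
#'
#' Finds the translation `(dy, dx)` that maximizes the normalized
#' cross-correlation between a reference plane and a moving plane, i.e. the
#' offset by which the moving plane's content is displaced relative to the
#' reference. The search is restricted to `|dy|, |dx| <= max_shift`; the
#' integer peak is refined to subpixel precision by a separable quadratic
#' fit.
#'
#' Chromatic aberration displaces one color channel relative to the other by
#' a field-wide translation, so the shift is estimated once per field of
#' view (on maximum-intensity projections) and not per locus.
#'
#' @param reference_plane 2D matrix (the detector/reference channel).
#' @param moving_plane 2D matrix of the same shape (the sensor channel).
#' @param max_shift maximum allowed |shift| per axis, pixels (default 10).
#' @return an object of class `eva_shift`: list with numeric `dy`, `dx`.
#' @export
estimate_shift <- function(reference_plane, moving_plane, max_shift = 10) {
  stopifnot(is.matrix(reference_plane), is.matrix(moving_plane),
            all(dim(reference_plane) == dim(moving_plane)),
            length(reference_plane) > 0, max_shift >= 0)
  if (sd(reference_plane) == 0 || sd(moving_plane) == 0)
    stop("no registration signal: a plane has zero variance")
  ny <- nrow(reference_plane); nx <- ncol(reference_plane)
  a <- reference_plane - mean(reference_plane)
  b <- moving_plane - mean(moving_plane)
  ## circular cross-correlation C(dy,dx) = sum_y a(y) * b(y - d)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / length(a)
  ## C[wrap(-d)] holds the correlation at displacement d of b relative to a;
  ## index arithmetic below maps displacement d in [-max_shift, max_shift]
  ## to the wrapped array index.
  m <- as.integer(min(max_shift, floor((ny - 1) / 2), floor((nx - 1) / 2)))
  ds <- (-m):m
  idx <- function(d, n) ((n - d) %% n) + 1L
  sub <- cc[idx(ds, ny), idx(ds, nx), drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  dy <- ds[pk[1]]; dx <- ds[pk[2]]

  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) return(0)            # not a proper local max
    max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  at <- function(d1, d2) cc[idx(d1, ny), idx(d2, nx)]
  sy <- if (abs(dy) < m) refine(at(dy - 1, dx), at(dy, dx), at(dy + 1, dx)) else 0
  sx <- if (abs(dx) < m) refine(at(dy, dx - 1), at(dy, dx), at(dy, dx + 1)) else 0
  structure(list(dy = dy + sy, dx = dx + sx), class = "eva_shift")
}

#' @export
print.eva_shift <- function(x, ...) {
  cat(sprintf("shift: dy = %.3f, dx = %.3f px\n", x$dy, x$dx))
  invisible(x)
}

#' Resample a channel to undo an estimated shift
#'
#' Translates the named channel by the inverse of `shift` (linear
#' interpolation for fractional shifts, pure integer roll otherwise) so that
#' it aligns with the reference channel. Pixels whose source falls outside
#' the frame are filled with the channel's median and flagged invalid; rim
#' and locus masks touching invalid pixels are rejected downstream.
#'
#' @param stack an [image_stack()].
#' @param channel channel name to resample.
#' @param shift an `eva_shift` (or list with `dy`, `dx`).
#' @param max_shift sanity bound; larger shifts indicate an acquisition
#'   problem and raise an error.
#' @return the stack with the channel replaced and a validity mask stored in
#'   `stack$valid[[channel]]`.
#' @export
apply_shift <- function(stack, channel, shift, max_shift = 10) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack_channel(stack, channel)
  if (abs(shift$dy) > max_shift || abs(shift$dx) > max_shift)
    stop(sprintf("shift (%.2f, %.2f) exceeds max_shift = %g",
                 shift$dy, shift$dx, max_shift))
  if (shift$dy == 0 && shift$dx == 0) {
    stack$valid[[channel]] <- matrix(TRUE, dim(a)[1], dim(a)[2])
    return(stack)
  }
  fill <- median(a)
  valid <- NULL
  for (z in seq_len(dim(a)[3])) {
    ## content sits at +shift; sampling at (y + dy, x + dx) moves it back
    sh <- shift_plane(a[, , z], shift$dy, shift$dx, fill = fill)
    valid <- attr(sh, "valid")
    attr(sh, "valid") <- NULL
    a[, , z] <- sh
  }
  stack$channels[[channel]] <- a
  stack$valid[[channel]] <- valid
  stack
}
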