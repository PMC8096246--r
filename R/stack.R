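#' Multi-channel image stack
#'
#' Container for one field of view: a named list of channels, each a
#' `(y, x, z)` array of nonnegative intensities (counts). Channel names are
#' free, but the pipeline expects `detector` (Ch1, red, reference) and
#' `sensor` (Ch2, green, measurement); an optional `aux` channel carries an
#' RNA FISH positivity signal.
#'
#' @param channels named list of numeric arrays, all the same `(y, x, z)`
#'   shape (matrices are promoted to single-slice arrays).
#' @param pixel_size optional physical pixel size (microns), metadata only.
#' @param z_step optional z spacing (microns), metadata only.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size = NA_real_, z_step = NA_real_) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    stopifnot(is.array(a), length(dim(a)) == 3L)
    if (any(a < 0)) stop("image_stack: negative intensities")
    a
  })
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) stop("image_stack: channels differ in shape")
  structure(list(channels = channels, pixel_size = pixel_size,
                 z_step = z_step, valid = list()),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d x %d px, %d z-slice(s), channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

stack_channel <- function(stack, name) {
  a <- stack$channels[[name]]
  if (is.null(a)) stop(sprintf("channel '%s' not present (have: %s)",
                               name, paste(names(stack$channels), collapse = ", ")))
  a
}

#' Maximum-intensity projection of one channel
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return a `(y, x)` matrix.
#' @export
project_channel <- function(stack, channel) {
  project_max(stack_channel(stack, channel))
}

#' Write an image stack to multi-page TIFF
#'
#' Pages are written in Z-major, channel-fastest order (axis order Z,C,Y,X);
#' intensities are stored as 32-bit floats scaled by 1/65535 (the nominal
#' 16-bit full scale). A JSON sidecar `<path>.json` records channel names,
#' slice count and the scale factor so [read_stack()] can restore the exact
#' array layout.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$channels[[1]])
  cn <- names(stack$channels)
  pages <- list()
  for (z in seq_len(d[3])) for (ch in cn)
    pages[[length(pages) + 1L]] <- stack$channels[[ch]][, , z] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channels = cn, n_z = d[3], scale = 65535,
               axis_order = "ZCYX", pixel_size = stack$pixel_size,
               z_step = stack$z_step)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Reads a multi-page TIFF written by [write_stack()] (using its JSON
#' sidecar), or a generic 2-4 channel TIFF given explicit `channel_names`.
#' Pages may be grayscale planes in Z,C order or RGB(A)-interleaved planes
#' (one page per z, channels in the third array dimension); both dialects
#' are normalized to the internal `(y, x, z)` per-channel layout.
#'
#' @param path TIFF path.
#' @param channel_names channel names in file order; required when no
#'   sidecar is present. Its length must match the file's channel count.
#' @param scale multiplier applied to stored values (ignored when a sidecar
#'   provides one). Default 65535 restores nominal 16-bit counts.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, channel_names = NULL, scale = 65535) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  interleaved <- length(dim(pages[[1]])) == 3L
  if (!is.null(meta)) {
    cn <- unlist(meta$channels); nz <- meta$n_z; scale <- meta$scale
  } else {
    if (interleaved) {
      nch <- dim(pages[[1]])[3]
      nz <- length(pages)
    } else {
      if (is.null(channel_names))
        stop("read_stack: no sidecar metadata; supply channel_names")
      nch <- length(channel_names)
      if (length(pages) %% nch != 0L)
        stop(sprintf("read_stack: %d pages not divisible by %d channels (%s)",
                     length(pages), nch, paste(channel_names, collapse = ", ")))
      nz <- length(pages) %/% nch
    }
    cn <- channel_names
    if (is.null(cn)) stop("read_stack: supply channel_names")
    if (interleaved && length(cn) != dim(pages[[1]])[3])
      stop(sprintf("read_stack: file has %d interleaved channels, manifest names %d (%s)",
                   dim(pages[[1]])[3], length(cn), paste(cn, collapse = ", ")))
  }
  ny <- dim(pages[[1]])[1]; nx <- dim(pages[[1]])[2]
  chans <- setNames(vector("list", length(cn)), cn)
  for (ci in seq_along(cn)) {
    a <- array(0, dim = c(ny, nx, nz))
    for (z in seq_len(nz)) {
      a[, , z] <- if (interleaved) pages[[z]][, , ci]
                  else pages[[(z - 1L) * length(cn) + ci]]
    }
    chans[[ci]] <- a * scale
  }
  image_stack(chans,
              pixel_size = if (!is.null(meta)) meta$pixel_size %||% NA_real_ else NA_real_,
              z_step = if (!is.null(meta)) meta$z_step %||% NA_real_ else NA_real_)
}
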