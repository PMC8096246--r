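`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a private RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are reproducible without disturbing the global
#' stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

## max-intensity projection of a (y, x, z) array
project_max <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  nz <- dim(a)[3]
  if (nz == 1L) return(a[, , 1L])
  out <- a[, , 1L]
  for (k in 2L:nz) out <- pmax(out, a[, , k])
  out
}

## Sample a plane at (y + dy, x + dx) with bilinear interpolation.
## Out-of-frame samples take `fill`; attribute "valid" marks in-frame pixels.
shift_plane <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  if (dy == round(dy) && dx == round(dx)) {
    dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
    out <- matrix(fill, ny, nx)
    valid <- matrix(FALSE, ny, nx)
    ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
    oky <- ys >= 1L & ys <= ny; okx <- xs >= 1L & xs <= nx
    out[oky, okx] <- m[ys[oky], xs[okx]]
    valid[oky, okx] <- TRUE
    attr(out, "valid") <- valid
    return(out)
  }
  ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  ## pad so the four gather indices always land in frame
  pad <- matrix(fill, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  gi <- function(yi, xi) {
    yi <- pmin(pmax(yi + 1L, 1L), ny + 2L)
    xi <- pmin(pmax(xi + 1L, 1L), nx + 2L)
    pad[yi, xi, drop = FALSE]
  }
  w00 <- outer(1 - fy, 1 - fx); w01 <- outer(1 - fy, fx)
  w10 <- outer(fy, 1 - fx);     w11 <- outer(fy, fx)
  out <- w00 * gi(y0, x0) + w01 * gi(y0, x0 + 1L) +
         w10 * gi(y0 + 1L, x0) + w11 * gi(y0 + 1L, x0 + 1L)
  valid <- outer(y0 >= 1L & (y0 + 1L) <= ny, x0 >= 1L & (x0 + 1L) <= nx, `&`)
  out[!valid] <- fill
  attr(out, "valid") <- valid
  out
}

## linear pixel indices of the bounding box [y0:y1] x [x0:x1], clipped to frame
box_indices <- function(y0, y1, x0, x1, ny, nx) {
  ys <- max(1L, y0):min(ny, y1)
  xs <- max(1L, x0):min(nx, x1)
  as.vector(outer(ys, (xs - 1L) * ny, `+`))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 0
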