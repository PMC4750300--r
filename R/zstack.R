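#' Calibrated confocal Z-stack
#'
#' A `zstack` is a light container for a single-channel 8-bit confocal
#' volume together with its voxel calibration: `voxels`, a 3D integer array
#' indexed `[z, y, x]` with values in 0--255; `dxy`, the in-plane pixel
#' size in micrometres per pixel (isotropic in x and y); and `dz`, the
#' axial step in micrometres per slice. All length measurements in the
#' package are expressed in micrometres through these two numbers.
#'
#' Coordinate conventions: indices are 0-based in user-facing coordinates,
#' `(x, y)` positions are continuous and measured at pixel centres, z
#' indices are integers. Slice `k` samples the plane at height `k * dz`.
#'
#' @param voxels 3D numeric array indexed `[z, y, x]`, values in 0--255.
#' @param dxy In-plane pixel size, um/pixel (> 0).
#' @param dz Z-step, um/slice (> 0).
#'
#' @return An object of class `zstack`.
#' @export
#' @examples
#' st <- zstack(array(0L, c(3, 8, 8)), dxy = 0.1, dz = 0.25)
#' dim(st$voxels)
zstack <- function(voxels, dxy, dz) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, c(1L, nrow(voxels), ncol(voxels)))
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!is.numeric(dxy) || length(dxy) != 1L || !is.finite(dxy) || dxy <= 0) {
    stop("`dxy` must be a single positive number (um/pixel)", call. = FALSE)
  }
  if (!is.numeric(dz) || length(dz) != 1L || !is.finite(dz) || dz <= 0) {
    stop("`dz` must be a single positive number (um/slice)", call. = FALSE)
  }
  if (dim(voxels)[1] < 1L) stop("stack must contain at least one slice", call. = FALSE)
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("voxel intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(voxels = voxels, dxy = as.numeric(dxy), dz = as.numeric(dz)),
    class = "zstack"
  )
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<zstack> %d slices x %d x %d px | dxy = %g um/px, dz = %g um/slice | range [%d, %d]\n",
    d[1], d[2], d[3], x$dxy, x$dz, as.integer(min(x$voxels)), as.integer(max(x$voxels))
  ))
  invisible(x)
}

#' Number of slices in a Z-stack
#' @param stack A [zstack()].
#' @return Integer slice count.
#' @export
n_slices <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  dim(stack$voxels)[1]
}

#' Resample a Z-stack onto a coarser axial grid
#'
#' Emulates acquiring the same field with a larger Z-step: slices are
#' linearly interpolated along z onto a grid of spacing `new_dz` starting
#' at the position of the first original slice, covering the same axial
#' range. In-plane content is untouched; output intensities are rounded
#' back to 8-bit. Only downsampling is supported (`new_dz >= dz`).
#'
#' @param stack A [zstack()].
#' @param new_dz New Z-step in um, `>= stack$dz`.
#' @return A [zstack()] with `dz = new_dz`.
#' @export
#' @examples
#' st <- zstack(array(rep(0:12, each = 4) * 10, c(13, 2, 2)), dxy = 0.1, dz = 0.25)
#' n_slices(resample_z(st, 0.5))
resample_z <- function(stack, new_dz) {
  stopifnot(inherits(stack, "zstack"))
  if (!is.numeric(new_dz) || length(new_dz) != 1L || new_dz <= 0) {
    stop("`new_dz` must be a single positive number", call. = FALSE)
  }
  tol <- 1e-9
  if (new_dz < stack$dz - tol) {
    stop(sprintf(
      "cannot resample to a finer grid: new_dz = %g < dz = %g", new_dz, stack$dz
    ), call. = FALSE)
  }
  d <- dim(stack$voxels)
  z_range <- (d[1] - 1L) * stack$dz
  n_new <- floor(z_range / new_dz + tol) + 1L
  out <- array(0L, c(n_new, d[2], d[3]))
  for (k in seq_len(n_new)) {
    z_um <- (k - 1L) * new_dz
    pos <- z_um / stack$dz            # position on the old grid, 0-based
    i0 <- floor(pos + tol)
    w <- pos - i0
    if (w < tol || i0 + 1L >= d[1]) {
      sl <- stack$voxels[i0 + 1L, , ]
    } else {
      sl <- (1 - w) * stack$voxels[i0 + 1L, , ] + w * stack$voxels[i0 + 2L, , ]
    }
    out[k, , ] <- as.integer(pmin(255, pmax(0, round(sl))))
  }
  zstack(out, dxy = stack$dxy, dz = new_dz)
}

#' Maximum intensity projection of a Z-stack
#'
#' Collapses the volume along z: output pixel `(y, x)` is the maximum of
#' voxel `(z, y, x)` over all slices. This is the substrate of the MIP
#' measurement method and the "top view" used to choose the DAAS reslice
#' direction.
#'
#' @param stack A [zstack()].
#' @return A matrix `(y, x)` with attribute `dxy` (um/pixel).
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  d <- dim(stack$voxels)
  proj <- stack$voxels[1, , , drop = TRUE]
  if (is.null(dim(proj))) proj <- matrix(proj, d[2], d[3])
  if (d[1] > 1L) {
    for (k in 2:d[1]) {
      proj <- pmax(proj, matrix(stack$voxels[k, , ], d[2], d[3]))
    }
  }
  attr(proj, "dxy") <- stack$dxy
  proj
}
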