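#' Reslice a Z-stack along an in-plane vector
#'
#' Builds the DAAS "side view": a vertical plane through the volume,
#' spanned by the direction `p1 -> p2` (in the x-y plane) and the z-axis.
#' Columns are sampled at the in-plane pixel spacing (one original pixel
#' per column, so the plane has the same resolution as the original data);
#' rows are the original z-slices. Each sample is the bilinear
#' interpolation of the four neighbouring pixels within its z-slice -- the
#' slicing plane contains the z-axis, so sample z-coordinates coincide
#' with slice positions and no interpolation across z is needed. The
#' sampled segment is extended by `margin_px` pixels beyond `p1` and `p2`,
#' clipped to the image bounds.
#'
#' @param stack A [zstack()].
#' @param p1_xy,p2_xy Distinct `(x, y)` pixel coordinates inside the image.
#' @param margin_px Extension beyond the selected segment, pixels.
#' @return An object of class `resliced_plane`: list with `pixels`
#'   (matrix indexed `[z, s]`), `ds` (= `dxy`, um/column), `dz`
#'   (um/row), and the sampling geometry (`origin_xy`, `direction`,
#'   `s_offset`).
#' @export
reslice <- function(stack, p1_xy, p2_xy, margin_px = 3) {
  stopifnot(inherits(stack, "zstack"))
  p1 <- as.numeric(p1_xy)[1:2]
  p2 <- as.numeric(p2_xy)[1:2]
  d <- dim(stack$voxels)
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  for (p in list(p1, p2)) {
    if (p[1] < 0 || p[1] > nx - 1 || p[2] < 0 || p[2] > ny - 1) {
      stop("reslice endpoints must lie inside the image bounds", call. = FALSE)
    }
  }
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  if (len < 1e-12) stop("zero-length reslice vector", call. = FALSE)
  u <- v / len

  # feasible parameter interval keeping samples inside the image
  t_lo <- -Inf; t_hi <- Inf
  for (ax in 1:2) {
    hi_bound <- if (ax == 1) nx - 1 else ny - 1
    if (abs(u[ax]) < 1e-12) next
    tt <- sort(c((0 - p1[ax]) / u[ax], (hi_bound - p1[ax]) / u[ax]))
    t_lo <- max(t_lo, tt[1]); t_hi <- min(t_hi, tt[2])
  }
  t0 <- max(-margin_px, t_lo)
  t1 <- min(len + margin_px, t_hi)
  ncol_out <- floor(t1 - t0 + 1e-9) + 1L
  ts <- t0 + seq_len(ncol_out) - 1
  xs <- p1[1] + ts * u[1]
  ys <- p1[2] + ts * u[2]

  px <- matrix(0, nz, ncol_out)
  for (k in seq_len(nz)) {
    sl <- matrix(stack$voxels[k, , ], ny, nx)
    px[k, ] <- bilinear_sample(sl, xs, ys)
  }
  structure(
    list(
      pixels = px, ds = stack$dxy, dz = stack$dz,
      origin_xy = p1, direction = u, s_offset = t0
    ),
    class = "resliced_plane"
  )
}

#' @export
print.resliced_plane <- function(x, ...) {
  cat(sprintf(
    "<resliced_plane> %d z-rows x %d columns | ds = %g um, dz = %g um\n",
    nrow(x$pixels), ncol(x$pixels), x$ds, x$dz
  ))
  invisible(x)
}

# Bilinear interpolation within one image. img is (y, x); xs/ys are
# 0-based continuous pixel coordinates (pixel centres at integers).
# Exact at grid points. Coordinates are clamped to the valid domain.
bilinear_sample <- function(img, xs, ys) {
  ny <- nrow(img); nx <- ncol(img)
  xs <- pmin(pmax(xs, 0), nx - 1)
  ys <- pmin(pmax(ys, 0), ny - 1)
  x0 <- if (nx == 1) rep(0, length(xs)) else pmin(floor(xs), nx - 2)
  y0 <- if (ny == 1) rep(0, length(ys)) else pmin(floor(ys), ny - 2)
  fx <- xs - x0
  fy <- ys - y0
  x1 <- pmin(x0 + 1, nx - 1)
  y1 <- pmin(y0 + 1, ny - 1)
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' DAAS polyline length on a resliced plane
#'
#' Anisotropy-aware length of an ordered set of `(s, z)` picks on the
#' side view: `sum(sqrt((ds*delta_s)^2 + (dz*delta_z)^2))` in um, where
#' `s` is the column and `z` the row coordinate in (possibly fractional)
#' pixel units.
#'
#' @param plane A `resliced_plane` from [reslice()].
#' @param points_sz Two-column matrix/data frame of ordered `(s, z)` picks,
#'   at least 2 points.
#' @return Length in um.
#' @export
#' @examples
#' pl <- structure(list(pixels = matrix(0, 4, 8), ds = 0.25, dz = 1),
#'   class = "resliced_plane")
#' measure_daas(pl, rbind(c(0, 0), c(4, 0))) # 1 um
measure_daas <- function(plane, points_sz) {
  stopifnot(inherits(plane, "resliced_plane"))
  pts <- as.matrix(points_sz)
  if (nrow(pts) < 2L) stop("need at least 2 picks", call. = FALSE)
  sum(sqrt((diff(pts[, 1]) * plane$ds)^2 + (diff(pts[, 2]) * plane$dz)^2))
}

#' Automatic endpoint detection on a plane or projection
#'
#' Replaces the operator's clicks: locates the two ends of the brightest
#' elongated structure at sub-pixel precision. The image is thresholded at
#' `cfg$intensity_lo`; within the largest connected component the signal's
#' intensity-weighted principal axis is determined, the intensity profile
#' along that axis is sampled by bilinear interpolation, and each end is
#' placed where the profile crosses half of the background-corrected peak
#' (never below `intensity_lo`), linearly interpolated between samples.
#' Half-maximum edge localisation recovers the true tip of a
#' Gaussian-blurred segment to first order independently of the PSF
#' width, which a raw threshold boundary does not.
#'
#' @param img A `resliced_plane` from [reslice()], or a matrix such as a
#'   [max_projection()] (with an optional `dxy` attribute; rows and
#'   columns are then assumed isotropic).
#' @param cfg A [measure_config()].
#' @return A 2x2 matrix of ordered endpoints, columns `s` (column index)
#'   and `z` (row index), 0-based fractional pixel units; the first row is
#'   the lexicographically smaller `(s, z)` pair. Attribute `length_um`
#'   carries the endpoint separation in um.
#' @export
auto_endpoints <- function(img, cfg = measure_config()) {
  if (inherits(img, "resliced_plane")) {
    px <- img$pixels; ds <- img$ds; dr <- img$dz
  } else {
    px <- as.matrix(img)
    ds <- attr(img, "dxy") %||% 1
    dr <- ds
  }
  mask <- px >= cfg$intensity_lo
  if (!any(mask)) {
    stop("no pixel at or above intensity_lo = ", cfg$intensity_lo,
      call. = FALSE)
  }
  comp <- largest_component(mask)
  bg <- if (all(mask)) 0 else stats::median(px[!mask])

  rows0 <- comp$rows - 1L   # 0-based
  cols0 <- comp$cols - 1L
  if (length(rows0) == 1L) {
    ends <- rbind(c(cols0, rows0), c(cols0, rows0))
    colnames(ends) <- c("s", "z")
    attr(ends, "length_um") <- 0
    return(ends)
  }

  # Axis estimate from intensity centroids. The transverse centroid of a
  # Gaussian-blurred line within one row (or column) lies exactly on the
  # line's axis, so per-row / per-column centroids are unbiased by the
  # PSF anisotropy (unlike a principal axis of the blurred blob, which
  # tilts toward the more blurred direction). Rows/columns near the tips,
  # where the end-cap skews the transverse profile, are excluded by a
  # mass criterion.
  vals <- px[cbind(comp$rows, comp$cols)]
  w <- pmax(vals - bg, 0)
  sx <- cols0 * ds
  sy <- rows0 * dr
  s_extent <- diff(range(sx[vals >= max(vals) / 2]))
  z_extent <- diff(range(sy[vals >= max(vals) / 2]))
  if (z_extent <= 2 * s_extent) {
    # prefer per-column centroids (columns sample at the finer in-plane
    # spacing); fall back to rows only for strongly vertical streaks
    m <- tapply(w, cols0, sum)
    cen <- tapply(w * sy, cols0, sum) / pmax(m, 1e-12)
    coord <- as.numeric(names(m)) * ds
    swap <- FALSE
  } else {
    m <- tapply(w, rows0, sum)
    cen <- tapply(w * sx, rows0, sum) / pmax(m, 1e-12)
    coord <- as.numeric(names(m)) * dr
    swap <- TRUE
  }
  m <- as.numeric(m)
  cen <- as.numeric(cen)
  keep <- m >= 0.75 * max(m)
  if (sum(keep) >= 2) {
    fit <- stats::lm.wfit(cbind(1, coord[keep]), cen[keep], m[keep])
    slope <- fit$coefficients[2]
    if (!is.finite(slope)) slope <- 0
    t_mid <- stats::weighted.mean(coord[keep], m[keep])
    c_mid <- fit$coefficients[1] + slope * t_mid
  } else {
    slope <- 0
    t_mid <- stats::weighted.mean(coord, m)
    c_mid <- stats::weighted.mean(cen, m)
  }
  if (swap) {
    centre <- c(c_mid, t_mid)
    ax <- c(slope, 1) / sqrt(1 + slope^2)
  } else {
    centre <- c(t_mid, c_mid)
    ax <- c(1, slope) / sqrt(1 + slope^2)
  }

  # Endpoints: half-maximum crossings of the interpolated on-axis
  # intensity profile. The on-axis intensity of a blurred segment drops
  # to half its plateau exactly at the true tips, so the crossing
  # localises the tip independently of the PSF width (a raw intensity_lo
  # boundary does not).
  ext <- 2 * max(ds, dr)
  h <- min(ds, dr) / 2
  half_range <- max(diff(range(sx)), diff(range(sy)))
  tgrid <- seq(-half_range - ext, half_range + ext, by = h)
  prof_x <- (centre[1] + tgrid * ax[1]) / ds
  prof_y <- (centre[2] + tgrid * ax[2]) / dr
  inside <- prof_x >= 0 & prof_x <= ncol(px) - 1 &
    prof_y >= 0 & prof_y <= nrow(px) - 1
  prof <- rep(bg, length(tgrid))
  prof[inside] <- bilinear_sample(px, prof_x[inside], prof_y[inside])
  peak_i <- which.max(prof)
  cutoff <- max(cfg$intensity_lo, bg + (prof[peak_i] - bg) / 2)
  t_end <- function(step) {
    i <- peak_i
    repeat {
      j <- i + step
      if (j < 1 || j > length(prof)) return(tgrid[i])
      if (prof[j] < cutoff) {
        f <- (prof[i] - cutoff) / (prof[i] - prof[j])
        return(tgrid[i] + f * (tgrid[j] - tgrid[i]))
      }
      i <- j
    }
  }
  tt <- c(t_end(-1L), t_end(1L))
  ends_um <- rbind(centre + tt[1] * ax, centre + tt[2] * ax)
  ends <- cbind(s = ends_um[, 1] / ds, z = ends_um[, 2] / dr)
  ord <- order(ends[, 1], ends[, 2])
  ends <- ends[ord, , drop = FALSE]
  attr(ends, "length_um") <- sqrt(sum((ends_um[1, ] - ends_um[2, ])^2))
  ends
}

# Largest 8-connected component of a logical mask. Returns 1-based row/col
# indices of its pixels. Ties broken by first occurrence in column-major
# scan order (deterministic).
largest_component <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  lab <- 0L
  best <- NULL
  best_n <- -1L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- integer(length(idx))
    queue[1] <- start
    labels[start] <- lab
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      r <- (cur - 1L) %% ny + 1L
      cc <- (cur - 1L) %/% ny + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > ny || c2 < 1L || c2 > nx) next
        j <- (c2 - 1L) * ny + r2
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- lab
          tail <- tail + 1L
          queue[tail] <- j
        }
      }
    }
    members <- queue[seq_len(tail)]
    if (length(members) > best_n) {
      best_n <- length(members)
      best <- members
    }
  }
  best <- sort(best)
  list(
    rows = (best - 1L) %% ny + 1L,
    cols = (best - 1L) %/% ny + 1L
  )
}
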