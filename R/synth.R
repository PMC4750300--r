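#' Ground-truth cilia for synthetic rendering
#'
#' Builds a tibble of straight-cilium ground truths. Each cilium is a 3D
#' line segment of length `length_um` starting at `base_*` (um), pointing
#' along `azimuth_deg` in the x-y plane and rising out of it by
#' `elevation_deg` (0 deg = lying flat in the imaging plane, 90 deg =
#' perpendicular to the coverslip). `amplitude` is the peak 8-bit
#' intensity of the rendered signal above background.
#'
#' @param cilium_id Identifier(s).
#' @param base_x,base_y,base_z Base position, um.
#' @param length_um True length L, um (> 0).
#' @param elevation_deg Angle between the cilium axis and the x-y plane,
#'   in `[0, 90]`.
#' @param azimuth_deg In-plane direction, degrees.
#' @param amplitude Peak intensity in `(0, 255]`.
#' @return A tibble, one row per cilium.
#' @export
#' @examples
#' ground_truth_cilia("c1", 2, 2, 0.5, length_um = 3, elevation_deg = 45)
ground_truth_cilia <- function(cilium_id, base_x, base_y, base_z,
                               length_um, elevation_deg, azimuth_deg = 0,
                               amplitude = 180) {
  gt <- tibble::tibble(
    cilium_id = as.character(cilium_id),
    base_x = base_x, base_y = base_y, base_z = base_z,
    length_um = length_um,
    elevation_deg = elevation_deg,
    azimuth_deg = azimuth_deg,
    amplitude = amplitude
  )
  if (any(gt$length_um <= 0)) stop("length_um must be > 0", call. = FALSE)
  if (any(gt$elevation_deg < 0 | gt$elevation_deg > 90)) {
    stop("elevation_deg must lie in [0, 90]", call. = FALSE)
  }
  if (any(gt$amplitude <= 0 | gt$amplitude > 255)) {
    stop("amplitude must lie in (0, 255]", call. = FALSE)
  }
  gt
}

#' Rendering configuration for synthetic Z-stacks
#'
#' Defaults model an 8-bit confocal export at high in-plane resolution:
#' dxy = 0.1 um/px, dz = 0.25 um (the step size used throughout the
#' package), a separable anisotropic Gaussian PSF with sigma_xy = 0.1 um
#' and sigma_z = 0.3 um, background level 10 and additive Gaussian noise
#' with sd 8 (set `noise_sd = 0` for noise-free geometry tests).
#'
#' @param shape Integer vector `c(nz, ny, nx)`.
#' @param dxy,dz Voxel calibration, um.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas, um
#'   (`psf_sigma_z >= psf_sigma_xy > 0`).
#' @param background_level Constant background intensity.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed Integer seed for the noise draw.
#' @param allow_saturation If `FALSE` (default), refuse configurations
#'   where `amplitude + background_level > 255`.
#' @return A list of class `render_config`.
#' @export
render_config <- function(shape = c(16L, 64L, 64L), dxy = 0.1, dz = 0.25,
                          psf_sigma_xy = 0.1, psf_sigma_z = 0.3,
                          background_level = 10, noise_sd = 8,
                          seed = 1L, allow_saturation = FALSE) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (!(psf_sigma_z >= psf_sigma_xy && psf_sigma_xy > 0)) {
    stop("require psf_sigma_z >= psf_sigma_xy > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (dxy <= 0 || dz <= 0) stop("dxy and dz must be > 0", call. = FALSE)
  structure(
    list(
      shape = as.integer(shape), dxy = dxy, dz = dz,
      psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
      background_level = background_level, noise_sd = noise_sd,
      seed = as.integer(seed), allow_saturation = isTRUE(allow_saturation)
    ),
    class = "render_config"
  )
}

# Unit direction vector (x, y, z) of a cilium axis.
cilium_direction <- function(elevation_deg, azimuth_deg) {
  el <- elevation_deg * pi / 180
  az <- azimuth_deg * pi / 180
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

#' Inclusive slice span of a line segment along z
#'
#' A slice at height `k * dz` represents the slab
#' `[k*dz - dz/2, k*dz + dz/2)`: the segment "appears in" slice `k` iff its
#' z-interval intersects that slab (nearest-plane assignment). This is the
#' span an annotation records and the source of the PyT axial term
#' `b = (z_last - z_first) * dz`.
#'
#' @param z0,z1 Segment z endpoints, um (any order).
#' @param dz Slice spacing, um.
#' @param n_slices Optional slice count for clipping/validation.
#' @return Integer vector `c(z_first, z_last)` (0-based, inclusive).
#' @export
#' @examples
#' cilium_slice_span(0.5, 0.5 + 3, dz = 0.25) # vertical 3 um -> 13 slices
cilium_slice_span <- function(z0, z1, dz, n_slices = NULL) {
  eps <- 1e-9
  lo <- min(z0, z1)
  hi <- max(z0, z1)
  zf <- as.integer(ceiling((lo - dz / 2) / dz - eps))
  zl <- as.integer(floor(hi / dz + 0.5 + eps))
  if (!is.null(n_slices)) {
    if (zl < 0 || zf > n_slices - 1L) {
      stop("segment lies outside the stack's z-range", call. = FALSE)
    }
    zf <- max(zf, 0L)
    zl <- min(zl, n_slices - 1L)
  }
  if (zf < 0L) zf <- 0L
  c(z_first = zf, z_last = zl)
}

#' Analytic annotations for ground-truth cilia on a given grid
#'
#' Returns the annotation an ideal operator would produce: the exact
#' projected endpoints of the (pre-blur) segment in pixel units and the
#' inclusive slice span of its z-interval. Ground truth is independent of
#' any detection step.
#'
#' @param cilia Ground-truth tibble (see [ground_truth_cilia()]).
#' @param dxy,dz Grid calibration, um.
#' @param n_slices Optional slice count for span clipping.
#' @return An annotation tibble (two points per cilium).
#' @export
analytic_annotations <- function(cilia, dxy, dz, n_slices = NULL) {
  rows <- purrr::pmap(cilia, function(cilium_id, base_x, base_y, base_z,
                                      length_um, elevation_deg, azimuth_deg,
                                      amplitude, ...) {
    d <- cilium_direction(elevation_deg, azimuth_deg)
    tip <- c(base_x, base_y, base_z) + length_um * d
    span <- cilium_slice_span(base_z, tip[3], dz, n_slices)
    tibble::tibble(
      cilium_id = cilium_id,
      point_index = c(0L, 1L),
      x = c(base_x, tip[1]) / dxy,
      y = c(base_y, tip[2]) / dxy,
      z_first = span[["z_first"]],
      z_last = span[["z_last"]]
    )
  })
  dplyr::bind_rows(rows)
}

#' Render ground-truth cilia into a synthetic Z-stack
#'
#' Each cilium is modelled as a line segment of constant linear intensity
#' density convolved with a separable anisotropic Gaussian PSF
#' (`sigma_x = sigma_y = psf_sigma_xy`, `sigma_z = psf_sigma_z`); the
#' convolution has a closed form (Gaussian in the perpendicular offset
#' times an erf difference along the axis) and is normalised so that the
#' mid-segment on-axis intensity equals the cilium's `amplitude`. The
#' background level is added, Gaussian noise of sd `noise_sd` is drawn
#' (deterministically for a fixed `cfg$seed`), and the result is clipped
#' to `[0, 255]` and quantised to 8-bit.
#'
#' @param cilia Ground-truth tibble (see [ground_truth_cilia()]).
#' @param cfg A [render_config()].
#' @return A list with elements `stack` (a [zstack()]) and `annotations`
#'   (the analytic annotation tibble for the rendered grid).
#' @export
render_stack <- function(cilia, cfg) {
  stopifnot(inherits(cfg, "render_config"))
  nz <- cfg$shape[1]; ny <- cfg$shape[2]; nx <- cfg$shape[3]
  if (!cfg$allow_saturation &&
      any(cilia$amplitude + cfg$background_level > 255)) {
    stop("amplitude + background exceeds 255 (would saturate); ",
      "set allow_saturation = TRUE to force", call. = FALSE)
  }
  sig <- c(cfg$psf_sigma_xy, cfg$psf_sigma_xy, cfg$psf_sigma_z)
  pad <- 3 * sig
  ext_hi <- c((nx - 1) * cfg$dxy, (ny - 1) * cfg$dxy, (nz - 1) * cfg$dz)

  vol <- array(0, c(nz, ny, nx))
  for (i in seq_len(nrow(cilia))) {
    ci <- cilia[i, ]
    d <- cilium_direction(ci$elevation_deg, ci$azimuth_deg)
    p0 <- c(ci$base_x, ci$base_y, ci$base_z)
    p1 <- p0 + ci$length_um * d
    lo <- pmin(p0, p1)[c(1, 2, 3)]
    hi <- pmax(p0, p1)[c(1, 2, 3)]
    if (any(lo - pad[c(1, 2, 3)] < -1e-9) ||
        any(hi + pad[c(1, 2, 3)] > ext_hi[c(1, 2, 3)] + 1e-9)) {
      stop("cilium ", ci$cilium_id,
        " does not fit inside the volume after PSF padding", call. = FALSE)
    }
    vol <- vol + render_segment(p0, d, ci$length_um, ci$amplitude, sig,
      nz, ny, nx, cfg$dxy, cfg$dz)
  }
  vol <- vol + cfg$background_level
  if (cfg$noise_sd > 0) {
    noise <- withr::with_seed(cfg$seed,
      stats::rnorm(length(vol), mean = 0, sd = cfg$noise_sd))
    vol <- vol + noise
  }
  vox <- array(as.integer(pmin(255, pmax(0, round(vol)))), dim(vol))
  stack <- zstack(vox, dxy = cfg$dxy, dz = cfg$dz)
  ann <- analytic_annotations(cilia, cfg$dxy, cfg$dz, n_slices = nz)
  list(stack = stack, annotations = ann)
}

# Closed-form render of one segment over a bounding sub-volume.
# p0: base (um), d: unit direction, L: length (um), A: peak amplitude,
# sig: PSF sigmas (x, y, z). Returns full-size (nz, ny, nx) array.
render_segment <- function(p0, d, L, A, sig, nz, ny, nx, dxy, dz) {
  p1 <- p0 + L * d
  # bounding box in voxel indices (0-based), +/- 4 sigma
  xr <- range(p0[1], p1[1]) + c(-1, 1) * 4 * sig[1]
  yr <- range(p0[2], p1[2]) + c(-1, 1) * 4 * sig[2]
  zr <- range(p0[3], p1[3]) + c(-1, 1) * 4 * sig[3]
  ix <- max(0L, floor(xr[1] / dxy)):min(nx - 1L, ceiling(xr[2] / dxy))
  iy <- max(0L, floor(yr[1] / dxy)):min(ny - 1L, ceiling(yr[2] / dxy))
  iz <- max(0L, floor(zr[1] / dz)):min(nz - 1L, ceiling(zr[2] / dz))

  # separable quadratic-form pieces: gamma = sum p_i^2 / s_i^2,
  # beta = sum p_i d_i / s_i^2 with p = voxel - base
  px <- ix * dxy - p0[1]; py <- iy * dxy - p0[2]; pz <- iz * dz - p0[3]
  gx <- px^2 / sig[1]^2; gy <- py^2 / sig[2]^2; gz <- pz^2 / sig[3]^2
  bx <- px * d[1] / sig[1]^2; by <- py * d[2] / sig[2]^2; bz <- pz * d[3] / sig[3]^2
  alpha <- sum((d / sig)^2)

  gam <- outer(outer(gz, gy, "+"), gx, "+")
  bet <- outer(outer(bz, by, "+"), bx, "+")
  q <- gam - bet^2 / alpha
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  s <- sqrt(2 * alpha)
  # segment point at parameter u is base + u*d; integrating the Gaussian
  # over u in [0, L] gives an erf difference around the foot point bet/alpha
  intensity <- A * exp(-q / 2) * (erf((alpha * L - bet) / s) + erf(bet / s)) / 2

  out <- array(0, c(nz, ny, nx))
  out[iz + 1L, iy + 1L, ix + 1L] <- intensity
  out
}

#' Simulate a cohort of flat and angled cilia
#'
#' Generates ground truths and per-cilium synthetic stacks emulating the
#' two cilium populations seen in a confluent monolayer: "flat" cilia
#' lying close to the imaging plane (elevation drawn from
#' `flat_elevation_range`) and "angled" cilia tilted out of it
#' (`angled_elevation_range`). Ranges are chosen so that, at dz = 0.25 um,
#' the slice-span classifier reproduces the intended population of every
#' cilium. True lengths are drawn from a truncated normal; with
#' `paired_lengths = TRUE` the identical length vector is used for both
#' populations, so any apparent length difference between the populations
#' is attributable to the measurement method alone.
#'
#' @param n_flat,n_angled Cilia per population.
#' @param length_mean,length_sd,length_range True length distribution, um.
#' @param flat_elevation_range,angled_elevation_range Elevation ranges,
#'   degrees.
#' @param paired_lengths Use the same true lengths for both populations.
#' @param cfg_template A [render_config()]; its shape is overridden
#'   per cilium to fit the geometry.
#' @param seed Integer seed (geometry and per-stack noise).
#' @return A list: `truth` (ground-truth tibble with `population`),
#'   `stacks` (named list of [zstack()]), `annotations` (annotation tibble
#'   across all cilia, spans on each cilium's own stack).
#' @export
simulate_cohort <- function(n_flat = 31, n_angled = 31,
                            length_mean = 3.2, length_sd = 0.7,
                            length_range = c(1.8, 5),
                            flat_elevation_range = c(0, 8),
                            angled_elevation_range = c(35, 70),
                            paired_lengths = FALSE,
                            cfg_template = render_config(),
                            seed = 1L) {
  n <- n_flat + n_angled
  draws <- withr::with_seed(as.integer(seed), {
    rtrunc_norm <- function(m) {
      x <- stats::rnorm(m, length_mean, length_sd)
      while (any(bad <- x < length_range[1] | x > length_range[2])) {
        x[bad] <- stats::rnorm(sum(bad), length_mean, length_sd)
      }
      x
    }
    len_flat <- rtrunc_norm(n_flat)
    len_angled <- if (paired_lengths && n_angled == n_flat) {
      len_flat
    } else {
      rtrunc_norm(n_angled)
    }
    list(
      lengths = c(len_flat, len_angled),
      elev = c(
        stats::runif(n_flat, flat_elevation_range[1], flat_elevation_range[2]),
        stats::runif(n_angled, angled_elevation_range[1], angled_elevation_range[2])
      ),
      azim = stats::runif(n, 0, 360),
      noise_seeds = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  truth <- tibble::tibble(
    cilium_id = sprintf("cil%03d", seq_len(n)),
    population = rep(c("FLAT", "ANGLED"), c(n_flat, n_angled)),
    length_um = draws$lengths,
    elevation_deg = draws$elev,
    azimuth_deg = draws$azim
  )

  stacks <- vector("list", n)
  anns <- vector("list", n)
  for (i in seq_len(n)) {
    one <- render_cilium_stack(
      truth$cilium_id[i], truth$length_um[i], truth$elevation_deg[i],
      truth$azimuth_deg[i], cfg_template, noise_seed = draws$noise_seeds[i]
    )
    stacks[[i]] <- one$stack
    anns[[i]] <- one$annotations
  }
  names(stacks) <- truth$cilium_id
  list(truth = truth, stacks = stacks, annotations = dplyr::bind_rows(anns))
}

#' Render a single cilium into an auto-sized stack
#'
#' Convenience wrapper around [render_stack()]: places the cilium base at
#' `base_z` (on a slice plane by default) with enough lateral and axial
#' margin for the PSF, and sizes the volume to fit.
#'
#' @param cilium_id Identifier.
#' @param length_um,elevation_deg,azimuth_deg Geometry (see
#'   [ground_truth_cilia()]).
#' @param cfg A [render_config()] supplying calibration, PSF, noise and
#'   amplitude context; `shape` is recomputed.
#' @param amplitude Peak intensity.
#' @param base_z Base height, um.
#' @param noise_seed Seed for this stack's noise.
#' @return As [render_stack()].
#' @export
render_cilium_stack <- function(cilium_id, length_um, elevation_deg,
                                azimuth_deg = 30, cfg = render_config(),
                                amplitude = 180, base_z = 1,
                                noise_seed = cfg$seed) {
  d <- cilium_direction(elevation_deg, azimuth_deg)
  margin_xy <- 4 * cfg$psf_sigma_xy + 3 * cfg$dxy
  margin_z <- 4 * cfg$psf_sigma_z + 2 * cfg$dz
  dx <- length_um * d[1]; dy <- length_um * d[2]; dzext <- length_um * d[3]
  nx <- ceiling((abs(dx) + 2 * margin_xy) / cfg$dxy) + 1L
  ny <- ceiling((abs(dy) + 2 * margin_xy) / cfg$dxy) + 1L
  nz <- ceiling((base_z + dzext + margin_z) / cfg$dz) + 1L
  base_x <- margin_xy + max(0, -dx)
  base_y <- margin_xy + max(0, -dy)
  cfg2 <- cfg
  cfg2$shape <- as.integer(c(nz, ny, nx))
  cfg2$seed <- as.integer(noise_seed)
  cilia <- ground_truth_cilia(cilium_id, base_x, base_y, base_z,
    length_um, elevation_deg, azimuth_deg, amplitude)
  render_stack(cilia, cfg2)
}
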