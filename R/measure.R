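#' Measurement configuration
#'
#' `intensity_lo`/`intensity_hi` define the grayscale window in which
#' cilium signal is considered (defaults 55--255, the usual window for
#' 8-bit confocal exports of acetylated-alpha-tubulin staining);
#' `flat_max_slices` is the largest slice span still classified FLAT
#' (default 4: a flat cilium shows its entire length in at most four
#' Z-slices, an angled one in more than four).
#'
#' @param intensity_lo Lower intensity threshold (mask cut), `[0, 255)`.
#' @param intensity_hi Intensity ceiling, `(intensity_lo, 255]`.
#' @param flat_max_slices Maximum slice span counted as FLAT (>= 1).
#' @return A list of class `measure_config`.
#' @export
measure_config <- function(intensity_lo = 55, intensity_hi = 255,
                           flat_max_slices = 4L) {
  if (!(intensity_lo >= 0 && intensity_lo < intensity_hi && intensity_hi <= 255)) {
    stop("require 0 <= intensity_lo < intensity_hi <= 255", call. = FALSE)
  }
  if (flat_max_slices < 1) stop("flat_max_slices must be >= 1", call. = FALSE)
  structure(
    list(
      intensity_lo = intensity_lo, intensity_hi = intensity_hi,
      flat_max_slices = as.integer(flat_max_slices)
    ),
    class = "measure_config"
  )
}

#' Euclidean length of a 2D polyline
#'
#' The projected length `a`: the sum of Euclidean segment lengths of an
#' operator-traced polyline on the maximum intensity projection, converted
#' to micrometres by the pixel size.
#'
#' @param points_xy Two-column matrix or data frame of `(x, y)` pixel
#'   coordinates, at least 2 points.
#' @param dxy Pixel size, um/pixel.
#' @return Length in um.
#' @export
#' @examples
#' polyline_length_2d(rbind(c(0, 0), c(3, 4)), dxy = 1) # 5
polyline_length_2d <- function(points_xy, dxy) {
  pts <- as.matrix(points_xy)
  if (nrow(pts) < 2L) stop("a polyline needs at least 2 points", call. = FALSE)
  stopifnot(ncol(pts) >= 2L, dxy > 0)
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)) * dxy
}

#' Axial extent of an annotated cilium
#'
#' The PyT axial term `b = (z_last - z_first) * dz`: the interval count
#' between the first and last slice showing signal, times the Z-step. A
#' cilium visible in a single slice has zero axial extent.
#'
#' @param annotation One-cilium annotation tibble (or any object with
#'   `z_first`/`z_last`).
#' @param dz Z-step, um/slice.
#' @return Extent in um.
#' @export
z_extent <- function(annotation, dz) {
  stopifnot(dz > 0)
  zf <- annotation$z_first[1]
  zl <- annotation$z_last[1]
  if (is.na(zf) || is.na(zl) || zl < zf) {
    stop("invalid z span", call. = FALSE)
  }
  (zl - zf) * dz
}

#' MIP length of one annotated cilium
#'
#' Projected polyline length only; no axial term. Systematically
#' underestimates cilia tilted out of the imaging plane by a factor of
#' about `cos(elevation)`.
#'
#' @param annotation One-cilium annotation tibble.
#' @param dxy Pixel size, um/pixel.
#' @return Length in um.
#' @export
measure_mip <- function(annotation, dxy) {
  polyline_length_2d(annotation[, c("x", "y")], dxy)
}

#' PyT length of one annotated cilium
#'
#' Pythagorean estimate `c = sqrt(a^2 + b^2)` with `a` the projected
#' polyline length ([polyline_length_2d()]) and `b` the axial slice extent
#' ([z_extent()]). For a single-slice cilium `b = 0` and PyT reduces
#' exactly to MIP. Valid for straight cilia (continuous slope along the
#' full length).
#'
#' @inheritParams measure_mip
#' @param dz Z-step, um/slice.
#' @return Length in um.
#' @export
measure_pyt <- function(annotation, dxy, dz) {
  a <- polyline_length_2d(annotation[, c("x", "y")], dxy)
  b <- z_extent(annotation, dz)
  sqrt(a^2 + b^2)
}

#' Classify cilia as flat or angled from their slice span
#'
#' FLAT iff the inclusive slice span `z_last - z_first + 1` is at most
#' `flat_max_slices` (default 4); otherwise ANGLED. A pure function of the
#' span: the polyline plays no role.
#'
#' @param annotations Annotation tibble (any number of cilia).
#' @param cfg A [measure_config()].
#' @return Tibble with `cilium_id`, `span_slices`, `classification`.
#' @export
classify_cilia <- function(annotations, cfg = measure_config()) {
  stopifnot(inherits(cfg, "measure_config"))
  ann <- dplyr::distinct(
    tibble::as_tibble(annotations),
    .data$cilium_id, .data$z_first, .data$z_last
  )
  dplyr::transmute(ann,
    cilium_id = .data$cilium_id,
    span_slices = as.integer(.data$z_last - .data$z_first + 1L),
    classification = ifelse(.data$span_slices <= cfg$flat_max_slices,
      "FLAT", "ANGLED")
  )
}

#' Average replicate measurements per cilium and method
#'
#' Collapses repeated measurements (the standard protocol takes three per
#' cilium) to their arithmetic mean, and reports the replicate range
#' (max - min) as a technical-quality check: repeated measurements of the
#' same cilium are expected to agree within about 0.3 um.
#'
#' @param measurements Tibble with `cilium_id`, `method`, `replicate`,
#'   `length_um` (and optionally `classification`).
#' @return Tibble with one row per cilium x method: `length_um` (mean) and
#'   `length_range_um` (max - min over replicates).
#' @export
average_replicates <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  required <- c("cilium_id", "method", "length_um")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    stop("measurements lack columns: ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  keep_class <- "classification" %in% names(m)
  grp <- dplyr::group_by(m, .data$cilium_id, .data$method)
  out <- dplyr::summarise(grp,
    n_replicates = dplyr::n(),
    length_range_um = max(.data$length_um) - min(.data$length_um),
    classification = if (keep_class) .data$classification[1] else NA_character_,
    length_um = mean(.data$length_um),
    .groups = "drop"
  )
  dplyr::select(out, "cilium_id", "method", "length_um",
    "length_range_um", "n_replicates", "classification")
}

#' Measure annotated cilia in a Z-stack with the three methods
#'
#' Runs any subset of the three measurement methods on every annotated
#' cilium:
#'
#' * `MIP`: projected polyline length on the maximum intensity projection.
#' * `PYT`: `sqrt(a^2 + b^2)` combining the projected length with the
#'   axial slice extent.
#' * `DAAS`: the stack is resliced along the cilium's in-plane direction
#'   ([reslice()]) and the length is measured on the resulting vertical
#'   plane between automatically located endpoints ([auto_endpoints()]).
#'
#' Replicates repeat the measurement; with `operator_sd = 0` (default)
#' they are identical (the pipeline is deterministic). A positive
#' `operator_sd` jitters the annotation endpoints by that amount (um) per
#' replicate to emulate operator variability.
#'
#' @param stack A [zstack()].
#' @param annotations Annotation tibble for this stack.
#' @param methods Character subset of `c("MIP", "PYT", "DAAS")`.
#' @param cfg A [measure_config()].
#' @param replicates Measurements per cilium and method (default 3).
#' @param operator_sd Per-replicate endpoint jitter, um (default 0).
#' @param seed Seed for the jitter draw.
#' @return Tibble with `cilium_id`, `method`, `replicate`, `length_um`,
#'   `span_slices`, `classification`.
#' @export
measure_cilia <- function(stack, annotations,
                          methods = c("MIP", "PYT", "DAAS"),
                          cfg = measure_config(), replicates = 3L,
                          operator_sd = 0, seed = 1L) {
  stopifnot(inherits(stack, "zstack"))
  methods <- match.arg(toupper(methods), c("MIP", "PYT", "DAAS"),
    several.ok = TRUE)
  ann <- validate_annotations(annotations, n_slices = n_slices(stack))
  cls <- classify_cilia(ann, cfg)
  ids <- unique(ann$cilium_id)
  jitters <- if (operator_sd > 0) {
    withr::with_seed(as.integer(seed),
      stats::rnorm(length(ids) * replicates * 4L, 0, operator_sd / stack$dxy))
  } else {
    numeric(0)
  }
  ji <- 0L
  out <- list()
  for (id in ids) {
    a1 <- ann[ann$cilium_id == id, ]
    cl <- cls$classification[cls$cilium_id == id]
    sp <- cls$span_slices[cls$cilium_id == id]
    for (r in seq_len(replicates)) {
      ar <- a1
      if (operator_sd > 0) {
        k <- nrow(ar)
        idx <- ji + seq_len(2L * k)
        ji <- ji + 2L * k
        ar$x <- ar$x + jitters[idx[seq_len(k)]]
        ar$y <- ar$y + jitters[idx[k + seq_len(k)]]
      }
      for (m in methods) {
        len <- switch(m,
          MIP = measure_mip(ar, stack$dxy),
          PYT = measure_pyt(ar, stack$dxy, stack$dz),
          DAAS = daas_length(stack, ar, cfg)
        )
        out[[length(out) + 1L]] <- tibble::tibble(
          cilium_id = id, method = m, replicate = r,
          length_um = len, span_slices = sp, classification = cl
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# Full DAAS measurement for one annotated cilium: reslice along the
# polyline's end-to-end direction, auto-locate endpoints, measure.
daas_length <- function(stack, annotation, cfg) {
  pts <- as.matrix(annotation[, c("x", "y")])
  p1 <- pts[1, ]
  p2 <- pts[nrow(pts), ]
  if (sqrt(sum((p2 - p1)^2)) < 1e-12) {
    stop("DAAS needs a non-degenerate in-plane direction", call. = FALSE)
  }
  plane <- reslice(stack, p1, p2)
  ends <- auto_endpoints(plane, cfg)
  measure_daas(plane, ends)
}
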