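#' Read a calibrated Z-stack from a multi-page TIFF / OME-TIFF
#'
#' Reads a single-channel 8-bit stack. Voxel calibration is resolved with
#' the precedence: explicit `dxy`/`dz` arguments, then OME-XML metadata
#' (`PhysicalSizeX` / `PhysicalSizeZ` in the ImageDescription tag). If a
#' calibration value is available from neither source the function fails:
#' lengths in micrometres are meaningless without it and are never guessed.
#'
#' @param path Path to the TIFF file.
#' @param dxy Optional in-plane pixel size override, um/pixel.
#' @param dz Optional Z-step override, um/slice.
#' @return A [zstack()].
#' @export
read_stack <- function(path, dxy = NULL, dz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  first <- pages[[1]]
  spp <- attr(first, "samples.per.pixel")
  if (length(dim(first)) == 3L || (!is.null(spp) && spp > 1L)) {
    stop("multi-channel TIFF not supported; supply a single-channel stack",
      call. = FALSE
    )
  }
  ome <- parse_ome_calibration(attr(first, "description"))
  dxy <- dxy %||% ome$dxy
  dz <- dz %||% ome$dz
  if (is.null(dxy)) {
    stop("no in-plane calibration: pass `dxy` or use an OME-TIFF with PhysicalSizeX",
      call. = FALSE
    )
  }
  if (is.null(dz)) {
    stop("no axial calibration: pass `dz` or use an OME-TIFF with PhysicalSizeZ",
      call. = FALSE
    )
  }
  vox <- array(0L, c(length(pages), nrow(first), ncol(first)))
  for (k in seq_along(pages)) {
    m <- pages[[k]]
    if (max(m) <= 1 && is.double(m)) m <- round(m * 255) # defensive: rescaled read
    vox[k, , ] <- as.integer(m)
  }
  zstack(vox, dxy = dxy, dz = dz)
}

# Pull PhysicalSizeX / PhysicalSizeZ (um) out of an OME-XML ImageDescription.
# Returns list(dxy = NULL-or-number, dz = NULL-or-number); tolerant of
# non-OME descriptions.
parse_ome_calibration <- function(desc) {
  out <- list(dxy = NULL, dz = NULL)
  if (is.null(desc) || !nzchar(desc) || !grepl("<", desc, fixed = TRUE)) {
    return(out)
  }
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(out)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(out)
  sx <- xml2::xml_attr(px, "PhysicalSizeX")
  sz <- xml2::xml_attr(px, "PhysicalSizeZ")
  if (!is.na(sx)) out$dxy <- as.numeric(sx)
  if (!is.na(sz)) out$dz <- as.numeric(sz)
  out
}

#' Write a Z-stack as a multi-page 8-bit TIFF
#'
#' Voxel values are written losslessly (8-bit, LZW). The installed TIFF
#' writer cannot embed an ImageDescription, so calibration is not stored
#' in the file; keep it alongside (e.g. in the run configuration) and pass
#' it back to [read_stack()].
#'
#' @param stack A [zstack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  d <- dim(stack$voxels)
  pages <- lapply(seq_len(d[1]), function(k) {
    matrix(stack$voxels[k, , ], d[2], d[3]) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read per-cilium annotations from CSV
#'
#' An annotation records, for one cilium, the operator-traced polyline on
#' the maximum intensity projection plus the first and last Z-slice in
#' which the cilium signal appears. The CSV has one row per polyline point
#' with columns `cilium_id`, `point_index`, `x`, `y`, `z_first`, `z_last`
#' (coordinates in pixels, 0-based, sub-pixel allowed; z indices integer,
#' inclusive). Lines starting with `#` are ignored.
#'
#' @param path CSV path.
#' @return A tibble with one row per point, ordered by `cilium_id` then
#'   `point_index`, validated: `0 <= z_first <= z_last`, at least two
#'   distinct consecutive points per cilium.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
    progress = FALSE)
  validate_annotations(ann)
}

#' Validate an annotation table
#'
#' @param ann Data frame with columns `cilium_id`, `point_index`, `x`, `y`,
#'   `z_first`, `z_last` (one row per polyline point).
#' @param n_slices Optional slice count; when given, z spans are checked
#'   against it.
#' @return The validated annotations as a tibble, points ordered within
#'   cilium.
#' @export
validate_annotations <- function(ann, n_slices = NULL) {
  required <- c("cilium_id", "point_index", "x", "y", "z_first", "z_last")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  num_cols <- c("point_index", "x", "y", "z_first", "z_last")
  for (cl in num_cols) {
    if (!is.numeric(ann[[cl]])) {
      stop("annotation column `", cl, "` must be numeric", call. = FALSE)
    }
    if (any(!is.finite(ann[[cl]]))) {
      stop("annotation column `", cl, "` contains non-finite values", call. = FALSE)
    }
  }
  ann <- dplyr::arrange(tibble::as_tibble(ann), .data$cilium_id, .data$point_index)
  by_cil <- dplyr::group_by(ann, .data$cilium_id)
  chk <- dplyr::summarise(by_cil,
    n_pts = dplyr::n(),
    zf = .data$z_first[1],
    zl = .data$z_last[1],
    z_const = all(.data$z_first == .data$z_first[1]) &&
      all(.data$z_last == .data$z_last[1]),
    dup = any(diff(.data$x) == 0 & diff(.data$y) == 0),
    .groups = "drop"
  )
  bad <- chk$n_pts < 2L
  if (any(bad)) {
    stop("cilium ", paste(chk$cilium_id[bad], collapse = ", "),
      ": an annotation needs at least 2 points", call. = FALSE)
  }
  if (!all(chk$z_const)) {
    stop("z_first/z_last must be constant within a cilium", call. = FALSE)
  }
  bad <- chk$zl < chk$zf | chk$zf < 0
  if (any(bad)) {
    stop("cilium ", paste(chk$cilium_id[bad], collapse = ", "),
      ": requires 0 <= z_first <= z_last", call. = FALSE)
  }
  if (any(chk$dup)) {
    stop("cilium ", paste(chk$cilium_id[chk$dup], collapse = ", "),
      ": consecutive polyline points must be distinct", call. = FALSE)
  }
  if (!is.null(n_slices)) {
    if (any(chk$zl >= n_slices)) {
      stop("z_last exceeds the stack's slice count", call. = FALSE)
    }
  }
  ann
}

#' Write annotations to CSV
#'
#' @param ann Annotation tibble (see [read_annotations()]).
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, header = NULL) {
  ann <- validate_annotations(ann)
  write_csv_commented(ann, path, header)
}

#' Write length measurements to CSV
#'
#' Records carry `cilium_id`, `method`, `replicate`, `length_um` and
#' `classification`; lengths are serialized at full precision so the file
#' round-trips losslessly through [read_measurements()]. An empty record
#' set produces a header-only file.
#'
#' @param records Measurement tibble.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path, header = NULL) {
  required <- c("cilium_id", "method", "replicate", "length_um", "classification")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("measurement records lack columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  write_csv_commented(tibble::as_tibble(records), path, header)
}

#' Read length measurements from CSV
#'
#' @param path CSV path, as written by [write_measurements()]; `#` comment
#'   lines are skipped.
#' @return A tibble.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

# CSV writer with optional '#' comment header; full double precision
# (readr serializes doubles with enough digits to round-trip exactly).
write_csv_commented <- function(df, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header) && length(header) > 0) {
    writeLines(paste0("# ", sub("^#\\s*", "", header)), con)
  }
  body <- readr::format_csv(df)
  writeLines(sub("\n$", "", body), con, sep = "\n")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
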