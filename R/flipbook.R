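# Flipbook mosaics: tile axial slices of co-registered volumetric series
# into one 2D frame per time point, for rapid serial visual inspection.
# Registration, skull stripping and bias correction are upstream concerns
# (FSL flirt/bet2/fast); this module only renders already co-registered
# volumes and warns when affine headers disagree.

#' Mosaic layout specification
#'
#' @param columns,rows Tile grid (default 6 x 4).
#' @param slice_spacing Distance between displayed axial slices, mm.
#' @param intensity_window Percentile pair for display normalization.
#' @return Object of class `mosaic_spec`.
#' @export
mosaic_spec <- function(columns = 6L, rows = 4L, slice_spacing = 3,
                        intensity_window = c(2, 98)) {
  if (columns < 1L || rows < 1L) {
    stop("mosaic needs at least a 1 x 1 grid", call. = FALSE)
  }
  if (slice_spacing <= 0) stop("slice_spacing must be > 0", call. = FALSE)
  if (length(intensity_window) != 2L ||
      intensity_window[1L] >= intensity_window[2L] ||
      any(intensity_window < 0) || any(intensity_window > 100)) {
    stop("intensity_window must be an increasing percentile pair in [0, 100]",
         call. = FALSE)
  }
  structure(list(columns = as.integer(columns), rows = as.integer(rows),
                 slice_spacing = slice_spacing,
                 intensity_window = intensity_window),
            class = "mosaic_spec")
}

#' Read a NIfTI volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return List with `data` (3D array), `spacing` (voxel sizes, mm) and
#'   `xform` (4x4 affine), ready for [make_mosaic()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = as.array(img), spacing = pd[seq_len(3L)],
       xform = RNifti::xform(img))
}

#' Warn unless volumes share an affine (co-registration check)
#'
#' @param volumes List of volumes from [read_volume()] (or with `xform`
#'   entries).
#' @param tol Maximum absolute affine-element difference tolerated.
#' @return `TRUE` (invisibly) when all affines agree, else `FALSE` with a
#'   warning.
#' @export
check_coregistration <- function(volumes, tol = 1e-4) {
  xf <- lapply(volumes, function(v) v$xform)
  xf <- xf[!vapply(xf, is.null, logical(1))]
  if (length(xf) < 2L) return(invisible(TRUE))
  ok <- all(vapply(xf[-1L], function(m) {
    max(abs(m - xf[[1L]])) <= tol
  }, logical(1)))
  if (!ok) {
    warning("volumes do not share an affine header: they do not appear ",
            "co-registered; register them (e.g. FSL flirt, 6 dof) before ",
            "building a flipbook", call. = FALSE)
  }
  invisible(ok)
}

#' Tile axial slices of a volume into a mosaic frame
#'
#' Selects `rows * columns` axial slices at `slice_spacing` mm intervals
#' from inferior to superior, normalizes intensities to `[0, 1]` by the
#' spec's percentile window (a degenerate window falls back to the full
#' data range; a constant volume renders as a constant frame), and tiles
#' the slices row-major. Slice positions beyond the volume render black.
#'
#' @param volume 3D array, or a list from [read_volume()].
#' @param spec A [mosaic_spec()].
#' @param spacing Voxel sizes in mm (length 3); taken from `volume$spacing`
#'   when the volume comes from [read_volume()].
#' @param label Optional label stored on the frame (burned in on export).
#' @return Matrix of class `mosaic_frame` in `[0, 1]`, with attributes
#'   `tile_dim`, `grid`, `slice_indices`, `label`.
#' @export
make_mosaic <- function(volume, spec = mosaic_spec(), spacing = c(1, 1, 1),
                        label = NULL) {
  if (is.list(volume) && !is.null(volume$data)) {
    if (!is.null(volume$spacing)) spacing <- volume$spacing
    volume <- volume$data
  }
  if (!is.array(volume) || length(dim(volume)) != 3L) {
    stop("make_mosaic needs a 3D volume", call. = FALSE)
  }
  stopifnot(inherits(spec, "mosaic_spec"))
  dz <- spacing[3L]
  if (!is.finite(dz) || dz <= 0) dz <- 1
  step <- max(1L, as.integer(round(spec$slice_spacing / dz)))
  n_tiles <- spec$rows * spec$columns
  idx <- seq(1L, by = step, length.out = n_tiles)

  q <- stats::quantile(volume, probs = spec$intensity_window / 100,
                       na.rm = TRUE, names = FALSE)
  if (q[2L] <= q[1L]) q <- range(volume, na.rm = TRUE) # degenerate window
  windowed <- if (q[2L] > q[1L]) {
    pmin(pmax((volume - q[1L]) / (q[2L] - q[1L]), 0), 1)
  } else {
    array(0, dim(volume)) # constant volume
  }

  nx <- dim(volume)[1L]
  ny <- dim(volume)[2L]
  nz <- dim(volume)[3L]
  frame <- matrix(0, nrow = spec$rows * nx, ncol = spec$columns * ny)
  for (k in seq_len(n_tiles)) {
    r <- (k - 1L) %/% spec$columns
    c0 <- (k - 1L) %% spec$columns
    if (idx[k] <= nz) {
      frame[r * nx + seq_len(nx), c0 * ny + seq_len(ny)] <-
        windowed[, , idx[k]]
    } # else: slice beyond the volume stays black
  }
  structure(frame,
            tile_dim = c(nx, ny),
            grid = c(rows = spec$rows, columns = spec$columns),
            slice_indices = idx,
            label = label,
            class = c("mosaic_frame", "matrix", "array"))
}

plot_frame <- function(frame, index) {
  graphics::par(mar = c(0, 0, 0, 0), bg = "black")
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = ncol(frame) / nrow(frame))
  graphics::rasterImage(grDevices::as.raster(unclass(frame)), 0, 0, 1, 1,
                        interpolate = FALSE)
  lab <- attr(frame, "label")
  txt <- if (is.null(lab)) sprintf("frame %d", index) else
    sprintf("frame %d: %s", index, lab)
  graphics::text(0.01, 0.02, txt, adj = c(0, 0), col = "white", cex = 0.9)
}

#' Export mosaic frames as a flipbook
#'
#' Writes one page (or image) per time point in order, with the frame index
#' and its label burned into the lower-left corner.
#'
#' @param frames List of [make_mosaic()] frames with identical dimensions.
#' @param path Output PDF path, or output directory for
#'   `format = "image-directory"`.
#' @param format `"multipage-pdf"` or `"image-directory"` (numbered PNGs).
#' @param width,height Page size in inches for the PDF device.
#' @return Character vector of files written, invisibly.
#' @export
export_flipbook <- function(frames, path,
                            format = c("multipage-pdf", "image-directory"),
                            width = 10, height = 7) {
  format <- match.arg(format)
  if (!length(frames)) stop("no frames to export", call. = FALSE)
  if (inherits(frames, "mosaic_frame")) frames <- list(frames)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  if (format == "multipage-pdf") {
    grDevices::pdf(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    for (i in seq_along(frames)) plot_frame(frames[[i]], i)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(frames))
  for (i in seq_along(frames)) {
    files[i] <- file.path(path, sprintf("frame_%03d.png", i))
    grDevices::png(files[i], width = 120 * width, height = 120 * height)
    plot_frame(frames[[i]], i)
    grDevices::dev.off()
  }
  invisible(files)
}
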