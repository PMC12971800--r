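#' CT slice and volume containers
#'
#' A `ct_slice` is the unit of segmentation work: a 2-D matrix of calibrated
#' Hounsfield units (HU) plus the in-plane pixel spacing in millimetres.
#' A `ct_volume` stacks slices that share a pixel grid, with slice positions
#' along the scanner axis. The in-memory orientation convention is
#' Left-Anterior-Superior (LAS): increasing column index points to the
#' patient's left, increasing row index to anterior, increasing slice index
#' to superior. The `orientation` tag records the actual axis directions of
#' the stored array as a three-letter code (column, row, slice axis), e.g.
#' `"LAS"`, `"RPS"`; [normalize_orientation()] reorders arbitrary tags to LAS.
#'
#' @param hu numeric matrix of Hounsfield units (rows x cols).
#' @param pixel_spacing length-2 numeric, mm per pixel (row, col); both > 0.
#' @param orientation three-letter axis code, one letter from each of
#'   \{L,R\}, \{A,P\}, \{S,I\} in any order, or `NA` if unknown.
#' @param provenance optional list of acquisition metadata (source path etc.).
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(hu, pixel_spacing, orientation = "LAS", provenance = NULL) {
  hu <- as.matrix(hu)
  storage.mode(hu) <- "double"
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    invalid_spec("pixel_spacing must be two positive finite numbers (mm)")
  }
  if (any(!is.finite(hu))) invalid_spec("HU image contains non-finite values")
  structure(
    list(hu = hu, pixel_spacing = pixel_spacing,
         orientation = orientation, provenance = provenance),
    class = "ct_slice"
  )
}

#' @rdname ct_slice
#' @param slices 3-D numeric array (rows x cols x n_slices) of HU values.
#' @param slice_positions numeric vector of slice positions (mm), strictly
#'   monotone, one per slice.
#' @export
ct_volume <- function(slices, pixel_spacing, slice_positions,
                      orientation = "LAS", provenance = NULL) {
  slices <- as.array(slices)
  if (length(dim(slices)) != 3) invalid_spec("volume must be a 3-D array")
  n <- dim(slices)[3]
  slice_positions <- as.numeric(slice_positions)
  if (length(slice_positions) != n) {
    invalid_spec("need one slice position per slice")
  }
  d <- diff(slice_positions)
  if (n > 1 && !(all(d > 0) || all(d < 0))) {
    invalid_spec("slice positions must be strictly monotone")
  }
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  structure(
    list(slices = slices, pixel_spacing = pixel_spacing,
         slice_positions = slice_positions, orientation = orientation,
         provenance = provenance),
    class = "ct_volume"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, spacing %.3g x %.3g mm, HU [%.0f, %.0f], orientation %s\n",
              nrow(x$hu), ncol(x$hu), x$pixel_spacing[1], x$pixel_spacing[2],
              min(x$hu), max(x$hu), x$orientation %||% "NA"))
  invisible(x)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %d x %d px x %d slices, spacing %.3g x %.3g mm, positions [%.1f, %.1f] mm\n",
              dim(x$slices)[1], dim(x$slices)[2], dim(x$slices)[3],
              x$pixel_spacing[1], x$pixel_spacing[2],
              min(x$slice_positions), max(x$slice_positions)))
  invisible(x)
}

# Extract slice i of a volume as a ct_slice.
volume_slice <- function(vol, i) {
  ct_slice(vol$slices[, , i], vol$pixel_spacing, vol$orientation, vol$provenance)
}
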