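#' Normalize patient orientation to Left-Anterior-Superior ordering
#'
#' Reorders the voxel array of a CT volume so that increasing column index
#' points to the patient's left, increasing row index to anterior, and
#' increasing slice index to superior (LAS). The stored orientation tag is a
#' three-letter code giving the anatomical direction of increasing (column,
#' row, slice) index; any permutation/flip of \{L,R\} x \{A,P\} x \{S,I\}
#' is handled. The operation is a pure axis permutation plus flips, so the
#' multiset of HU values is preserved exactly and the operation is
#' idempotent. Optional companion masks (ground truth) are transformed
#' alongside so they stay aligned.
#'
#' @param volume a [ct_volume()].
#' @param masks optional named list of arrays with the same dimensions as
#'   the volume, transformed identically.
#' @return The volume in LAS order; if `masks` were given, a list with
#'   `volume` and `masks`.
#' @export
normalize_orientation <- function(volume, masks = NULL) {
  tag <- volume$orientation
  if (is.null(tag) || is.na(tag) || !nzchar(tag)) {
    adipoct_error("volume has no orientation metadata; refusing to guess",
                  "adipoct_orientation_error")
  }
  tag <- toupper(tag)
  letters3 <- strsplit(tag, "")[[1]]
  axis_of <- function(ch) switch(ch, L = , R = 1L, A = , P = 2L, S = , I = 3L,
                                 adipoct_error(sprintf("bad orientation letter '%s'", ch),
                                               "adipoct_orientation_error"))
  axes <- vapply(letters3, axis_of, integer(1))
  if (length(letters3) != 3 || anyDuplicated(axes)) {
    adipoct_error(sprintf("ambiguous orientation tag '%s'", tag),
                  "adipoct_orientation_error")
  }
  flip <- letters3 %in% c("R", "P", "I")

  arr <- volume$slices
  # current array dims: (row, col, slice); tag letters refer to (col, row, slice)
  dim_of_letter <- c(2L, 1L, 3L)  # letter position -> array dimension
  # apply flips first
  for (i in 1:3) {
    if (flip[i]) {
      d <- dim_of_letter[i]
      idx <- rev(seq_len(dim(arr)[d]))
      arr <- switch(d, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
      if (!is.null(masks)) masks <- lapply(masks, function(m)
        switch(d, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
               m[, , idx, drop = FALSE]))
    }
  }
  # then permute axes so letter order becomes (LR, AP, SI) on (col, row, slice)
  # target: anatomical axis 1 (LR) on array dim 2, axis 2 (AP) on dim 1,
  # axis 3 (SI) on dim 3.
  cur_dim_of_axis <- integer(3)       # anatomical axis -> current array dim
  cur_dim_of_axis[axes] <- dim_of_letter
  perm <- cur_dim_of_axis[c(2L, 1L, 3L)]   # new (row, col, slice)
  if (!identical(perm, 1:3)) {
    arr <- aperm(arr, perm)
    if (!is.null(masks)) masks <- lapply(masks, aperm, perm = perm)
  }
  spacing <- volume$pixel_spacing
  if (!identical(perm[1:2], 1:2)) spacing <- spacing[perm[1:2]]
  out <- ct_volume(arr, spacing, volume$slice_positions, orientation = "LAS",
                   provenance = volume$provenance)
  if (is.null(masks)) out else list(volume = out, masks = masks)
}

#' Resample a CT volume to contiguous slices of a target thickness
#'
#' Linearly interpolates along the slice axis onto a grid of evenly spaced
#' positions (default 3 mm) spanning the input range; the in-plane grid is
#' untouched. Linear interpolation cannot overshoot, so the output HU range
#' is bounded by the input range. A single-slice volume is passed through
#' with a warning since a slice-level pipeline needs no resampling.
#'
#' @param volume a [ct_volume()].
#' @param target_thickness output slice spacing in mm.
#' @return A [ct_volume()] at the target spacing.
#' @export
resample_slices <- function(volume, target_thickness = 3.0) {
  pos <- volume$slice_positions
  n <- length(pos)
  if (n < 2) {
    warning("single-slice volume: resampling skipped")
    return(volume)
  }
  if (pos[1] > pos[n]) {  # enforce increasing positions
    volume$slices <- volume$slices[, , n:1, drop = FALSE]
    pos <- rev(pos)
  }
  new_pos <- seq(pos[1], pos[n], by = target_thickness)
  d <- dim(volume$slices)
  out <- array(0, c(d[1], d[2], length(new_pos)))
  idx <- findInterval(new_pos, pos, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n - 1L)
  w <- (new_pos - pos[idx]) / (pos[idx + 1L] - pos[idx])
  for (k in seq_along(new_pos)) {
    out[, , k] <- (1 - w[k]) * volume$slices[, , idx[k]] +
                  w[k] * volume$slices[, , idx[k] + 1L]
  }
  ct_volume(out, volume$pixel_spacing, new_pos, volume$orientation,
            volume$provenance)
}

#' Remove the vendor Hounsfield-unit offset by anchoring on background air
#'
#' Scanners may export CT numbers shifted by a constant vendor offset. The
#' offset is estimated from background air: pixels below `air_threshold`
#' (applied after subtracting a robust provisional shift, so even large
#' offsets are caught) whose connected component touches the image border.
#' The mean HU of that region should be -1000; the difference is subtracted
#' from the whole image. Applying the operation twice is a no-op up to the
#' re-estimated residual (about 0 HU).
#'
#' @param slice a [ct_slice()].
#' @param air_threshold HU threshold under which a pixel is considered air
#'   candidate, before correction (default -700).
#' @return The corrected [ct_slice()], with the estimated offset stored in
#'   `provenance$hu_offset_removed`.
#' @export
normalize_hu <- function(slice, air_threshold = -700) {
  hu <- slice$hu
  # an image needs air/tissue contrast before an air anchor means anything
  if (diff(stats::quantile(hu, c(0.05, 0.95), names = FALSE)) < 200) {
    adipoct_error("no air/tissue contrast: cannot anchor HU offset on border air",
                  "adipoct_hu_error")
  }
  # provisional shift: the most common extreme-low value tracks air even
  # when the vendor offset moves the whole histogram
  prov <- stats::quantile(hu, 0.05, names = FALSE)
  shift0 <- if (prov > air_threshold || prov < -1500) prov + 1000 else 0
  cand <- (hu - shift0) < air_threshold
  lab <- EBImage::bwlabel(cand)
  border_labels <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ],
                                    lab[, 1], lab[, ncol(lab)])), 0)
  if (length(border_labels) == 0) {
    adipoct_error("no border-connected air region found; cannot anchor HU offset",
                  "adipoct_hu_error")
  }
  air <- lab %in% border_labels
  offset <- mean(hu[air]) - (-1000)
  out <- slice
  out$hu <- hu - offset
  out$provenance <- c(slice$provenance, list(hu_offset_removed = offset))
  out
}
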