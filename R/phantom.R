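#' Specification of a synthetic abdominal CT phantom
#'
#' Builds the parametric geometry of a single axial abdominal cross-section
#' at the L3 level: an elliptical body with a subcutaneous fat ring of
#' (optionally angularly varying) thickness, an abdominal-wall muscle ring,
#' a visceral cavity holding elliptical fat blobs, soft-tissue organ blobs
#' and a vertebral-body surrogate, and a CT table slab separated from the
#' body by an air gap. Tissue HU means default to textbook values: fat lies
#' strictly inside the adipose band [-274, -49] HU, muscle and organs above
#' it, air far below. A vendor HU offset can be injected to exercise HU
#' normalization.
#'
#' @param image_size integer length-2, image size in pixels (rows, cols).
#' @param pixel_spacing mm per pixel (row, col).
#' @param body_center_mm ellipse centre in mm relative to the image centre.
#' @param body_semiaxes_mm ellipse semi-axes in mm (x = columns, y = rows).
#' @param sat_ring_thickness mm; may be 0 (no subcutaneous fat).
#' @param sat_ring_perturb relative amplitude of a smooth angular variation
#'   of the SAT ring thickness (0 = perfectly concentric ring).
#' @param muscle_ring_thickness mm.
#' @param visceral_fat_fraction target fraction of the visceral-cavity area
#'   occupied by fat blobs, in [0, 1].
#' @param n_fat_blobs maximum number of fat blobs painted.
#' @param organ_blobs list of lists with `center` (mm, relative to body
#'   centre), `semiaxes` (mm) and `hu`; pass `list()` for none.
#' @param hu_means named list of per-tissue mean HU.
#' @param hu_noise_sd additive Gaussian noise sd in HU.
#' @param include_table paint a CT table slab below the body.
#' @param vendor_hu_offset HU added to every pixel after noise.
#' @param seed integer; the full phantom is deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(256L, 256L),
                         pixel_spacing = c(1.75, 1.75),
                         body_center_mm = c(0, -20),
                         body_semiaxes_mm = c(150, 100),
                         sat_ring_thickness = 25,
                         sat_ring_perturb = 0.15,
                         muscle_ring_thickness = 12,
                         visceral_fat_fraction = 0.30,
                         n_fat_blobs = 40,
                         organ_blobs = default_organ_blobs(),
                         hu_means = default_hu_means(),
                         hu_noise_sd = 10,
                         include_table = TRUE,
                         vendor_hu_offset = 0,
                         seed = 1L) {
  spec <- structure(
    list(image_size = as.integer(image_size),
         pixel_spacing = as.numeric(pixel_spacing),
         body_center_mm = as.numeric(body_center_mm),
         body_semiaxes_mm = as.numeric(body_semiaxes_mm),
         sat_ring_thickness = sat_ring_thickness,
         sat_ring_perturb = sat_ring_perturb,
         muscle_ring_thickness = muscle_ring_thickness,
         visceral_fat_fraction = visceral_fat_fraction,
         n_fat_blobs = as.integer(n_fat_blobs),
         organ_blobs = organ_blobs,
         hu_means = hu_means,
         hu_noise_sd = hu_noise_sd,
         include_table = include_table,
         vendor_hu_offset = vendor_hu_offset,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @export
default_hu_means <- function() {
  list(air = -1000, sat_fat = -100, vat_fat = -90, muscle = 40,
       organ = 50, bone = 700, table = 300)
}

#' @rdname phantom_spec
#' @export
default_organ_blobs <- function() {
  list(
    list(center = c(45, -15), semiaxes = c(38, 28), hu = 50),
    list(center = c(-48, -5), semiaxes = c(32, 24), hu = 55),
    list(center = c(0, 52), semiaxes = c(16, 16), hu = 700)  # vertebral body
  )
}

validate_phantom_spec <- function(spec) {
  hm <- spec$hu_means
  if (hm$sat_fat < -274 || hm$sat_fat > -49 || hm$vat_fat < -274 || hm$vat_fat > -49)
    invalid_spec("fat HU means must lie inside [-274, -49]")
  if (hm$muscle <= -49 || hm$organ <= -49)
    invalid_spec("muscle and organ HU means must lie above -49")
  if (hm$air >= -274) invalid_spec("air HU mean must lie below -274")
  if (spec$sat_ring_thickness < 0 || spec$muscle_ring_thickness <= 0)
    invalid_spec("ring thicknesses must be non-negative (SAT) / positive (muscle)")
  if (spec$visceral_fat_fraction < 0 || spec$visceral_fat_fraction > 1)
    invalid_spec("visceral_fat_fraction must be in [0, 1]")
  fov <- spec$image_size * spec$pixel_spacing   # (rows=y, cols=x) extent, mm
  cx <- spec$body_center_mm[1]; cy <- spec$body_center_mm[2]
  a <- spec$body_semiaxes_mm[1]; b <- spec$body_semiaxes_mm[2]
  # ring thickness varies inward only, so the body extent is the ellipse itself
  if (abs(cx) + a > fov[2] / 2 - 2 * spec$pixel_spacing[2] ||
      abs(cy) + b > fov[1] / 2 - 2 * spec$pixel_spacing[1])
    invalid_spec("body ellipse exceeds image bounds")
  if (spec$include_table) {
    # slab: 5 mm air gap + 18 mm of table below the body
    if (cy + b + 5 + 18 > fov[1] / 2 - 2 * spec$pixel_spacing[1])
      invalid_spec("body ellipse plus table exceeds image bounds")
  }
  invisible(spec)
}

# Label codes used while painting
.LBL <- c(air = 0L, table = 1L, soft = 2L, sat = 3L, muscle = 4L,
          vat = 5L, organ = 6L, bone = 7L)

#' Generate a synthetic abdominal CT slice with ground truth
#'
#' Paints, in order: air background, CT table, body soft tissue, SAT ring,
#' muscle ring, then visceral-cavity organ blobs and fat blobs; adds
#' Gaussian HU noise and finally the vendor HU offset. Ground-truth masks
#' are the noise-free painted labels and ground-truth areas are pixel
#' counts times pixel area, so the truth is exact for the painted geometry.
#' The same seed yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `slice` (a [ct_slice()]) and `truth`, a list holding
#'   logical masks (`body_mask`, `sat_mask`, `vat_mask`, `muscle_mask`),
#'   `sat_area_mm2`, `vat_area_mm2`, `vsr_true` (NA when SAT area is 0) and
#'   the label matrix.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  sp <- spec$pixel_spacing
  # mm coordinates of pixel centres, origin at image centre
  y <- (seq_len(nr) - (nr + 1) / 2) * sp[1]
  x <- (seq_len(nc) - (nc + 1) / 2) * sp[2]
  X <- matrix(x, nr, nc, byrow = TRUE) - spec$body_center_mm[1]
  Y <- matrix(y, nr, nc) - spec$body_center_mm[2]
  a <- spec$body_semiaxes_mm[1]; b <- spec$body_semiaxes_mm[2]

  # elliptical radius e (1 on the skin) and radial depth below the skin (mm)
  e <- sqrt((X / a)^2 + (Y / b)^2)
  theta <- atan2(Y, X)
  R <- 1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)
  depth <- (1 - e) * R

  t_sat <- spec$sat_ring_thickness *
    (1 + spec$sat_ring_perturb * sin(2 * theta + 0.7))
  t_mus <- spec$muscle_ring_thickness

  lbl <- matrix(.LBL[["air"]], nr, nc)
  if (spec$include_table) {
    y_tab <- spec$body_center_mm[2] + b + 5          # 5 mm air gap
    tab <- matrix(y, nr, nc) >= y_tab &
           matrix(y, nr, nc) <= y_tab + 18 &
           abs(matrix(x, nr, nc, byrow = TRUE)) <= 0.42 * nc * sp[2]
    lbl[tab] <- .LBL[["table"]]
  }
  body <- e <= 1
  lbl[body] <- .LBL[["soft"]]
  lbl[body & depth < t_sat] <- .LBL[["sat"]]
  lbl[body & depth >= t_sat & depth < t_sat + t_mus] <- .LBL[["muscle"]]
  cavity <- body & depth >= t_sat + t_mus

  for (ob in spec$organ_blobs) {
    inb <- ((X - ob$center[1]) / ob$semiaxes[1])^2 +
           ((Y - ob$center[2]) / ob$semiaxes[2])^2 <= 1
    lbl[inb & cavity] <- if (ob$hu >= 200) .LBL[["bone"]] else .LBL[["organ"]]
  }

  # Fat blobs: deterministic candidate stream, painted until the target
  # cavity fraction is reached (monotone in visceral_fat_fraction).
  n_cavity <- sum(cavity)
  target_px <- spec$visceral_fat_fraction * n_cavity
  lbl <- with_seed(derive_seed(spec$seed, 1L), {
    painted <- 0L; placed <- 0L; tries <- 0L
    while (painted < target_px && placed < spec$n_fat_blobs && tries < 50L * spec$n_fat_blobs) {
      tries <- tries + 1L
      cx <- runif(1, -0.9, 0.9) * (a - t_sat[1] - t_mus)
      cy <- runif(1, -0.9, 0.9) * (b - t_sat[1] - t_mus)
      ra <- runif(1, 5, 14); rb <- runif(1, 5, 14)
      inb <- ((X - cx) / ra)^2 + ((Y - cy) / rb)^2 <= 1
      paintable <- inb & cavity & lbl != .LBL[["organ"]] & lbl != .LBL[["bone"]]
      if (sum(paintable) < 4) next
      lbl[paintable] <- .LBL[["vat"]]
      placed <- placed + 1L
      painted <- sum(lbl == .LBL[["vat"]])
    }
    lbl
  })

  hu_for <- c(spec$hu_means$air, spec$hu_means$table, spec$hu_means$organ - 10,
              spec$hu_means$sat_fat, spec$hu_means$muscle, spec$hu_means$vat_fat,
              spec$hu_means$organ, spec$hu_means$bone)
  hu <- matrix(hu_for[lbl + 1L], nr, nc)
  if (spec$hu_noise_sd > 0) {
    hu <- hu + with_seed(derive_seed(spec$seed, 2L),
                         matrix(rnorm(nr * nc, 0, spec$hu_noise_sd), nr, nc))
  }
  hu <- hu + spec$vendor_hu_offset

  pixel_area <- sp[1] * sp[2]
  sat_mask <- lbl == .LBL[["sat"]]
  vat_mask <- lbl == .LBL[["vat"]]
  sat_area <- sum(sat_mask) * pixel_area
  vat_area <- sum(vat_mask) * pixel_area
  truth <- list(
    body_mask = body,
    sat_mask = sat_mask,
    vat_mask = vat_mask,
    muscle_mask = lbl == .LBL[["muscle"]],
    labels = lbl,
    sat_area_mm2 = sat_area,
    vat_area_mm2 = vat_area,
    vsr_true = if (sat_area > 0) vat_area / sat_area else NA_real_
  )
  list(
    slice = ct_slice(hu, sp, orientation = "LAS",
                     provenance = list(source = "phantom", seed = spec$seed)),
    truth = truth
  )
}

#' Stack a phantom into a thin volume
#'
#' Replicates a phantom slice into a short contiguous stack with independent
#' per-slice noise, for exercising orientation and slice-resampling
#' preprocessing. Geometry is constant along the stack.
#'
#' @param spec a [phantom_spec()].
#' @param n_slices number of slices.
#' @param slice_thickness slice spacing in mm.
#' @return A [ct_volume()].
#' @export
generate_phantom_volume <- function(spec, n_slices = 3L, slice_thickness = 3) {
  base <- generate_phantom(phantom_spec_update(spec, hu_noise_sd = 0,
                                               vendor_hu_offset = 0))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  arr <- array(0, c(nr, nc, n_slices))
  noise <- with_seed(derive_seed(spec$seed, 3L),
                     array(rnorm(nr * nc * n_slices, 0, spec$hu_noise_sd),
                           c(nr, nc, n_slices)))
  for (k in seq_len(n_slices)) arr[, , k] <- base$slice$hu + noise[, , k]
  arr <- arr + spec$vendor_hu_offset
  ct_volume(arr, spec$pixel_spacing,
            slice_positions = (seq_len(n_slices) - 1) * slice_thickness,
            orientation = "LAS",
            provenance = list(source = "phantom_volume", seed = spec$seed))
}

# Return a copy of a phantom_spec with fields replaced.
phantom_spec_update <- function(spec, ...) {
  upd <- list(...)
  spec[names(upd)] <- upd
  validate_phantom_spec(spec)
  spec
}

#' Write and read CT slices as NIfTI or DICOM
#'
#' `write_ct_slice()` stores a slice so that HU values and pixel spacing
#' survive a round trip: NIfTI-1 via the voxel dimensions, DICOM via
#' RescaleSlope/RescaleIntercept (slope 1, intercept -1024, the CT
#' convention; HU are quantized to integers). `read_ct_slice()` dispatches
#' on the file extension (`.nii`/`.nii.gz` vs `.dcm`).
#'
#' @param slice a [ct_slice()].
#' @param path output file path.
#' @param format `"nifti"` or `"dicom"`; default inferred from `path`.
#' @return `write_ct_slice()` returns `path` invisibly; `read_ct_slice()`
#'   returns a [ct_slice()].
#' @export
write_ct_slice <- function(slice, path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_ct_format(path)
  if (format == "nifti") {
    arr <- array(slice$hu, c(dim(slice$hu), 1L))
    attr(arr, "pixdim") <- c(slice$pixel_spacing, 1)
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  } else {
    write_dicom_slice(slice, path)
  }
  invisible(path)
}

#' @rdname write_ct_slice
#' @export
read_ct_slice <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_ct_format(path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    hu <- as.array(img)
    if (length(dim(hu)) == 3) hu <- hu[, , 1]
    ct_slice(hu, RNifti::pixdim(img)[1:2], orientation = NA_character_,
             provenance = list(source = path))
  } else {
    read_dicom_slice(path)
  }
}

guess_ct_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.dcm$", path, ignore.case = TRUE)) "dicom"
  else invalid_spec(sprintf("cannot infer CT format from '%s'", path))
}

#' Save phantom ground truth as plain files
#'
#' Writes the compartment masks as a PNG label image (0 = background,
#' distinct gray levels per compartment) and the analytic areas as JSON.
#'
#' @param truth the `truth` element of [generate_phantom()].
#' @param prefix path prefix; writes `<prefix>_labels.png` and
#'   `<prefix>_areas.json`.
#' @return Invisibly, the two paths written.
#' @export
write_ground_truth <- function(truth, prefix) {
  lab_path <- paste0(prefix, "_labels.png")
  png::writePNG(truth$labels / max(7, max(truth$labels)), lab_path)
  js_path <- paste0(prefix, "_areas.json")
  jsonlite::write_json(
    list(sat_area_mm2 = truth$sat_area_mm2, vat_area_mm2 = truth$vat_area_mm2,
         vsr_true = truth$vsr_true),
    js_path, auto_unbox = TRUE, digits = NA)
  invisible(c(lab_path, js_path))
}
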