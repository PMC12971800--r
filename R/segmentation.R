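#' Tunable parameters of the adipose segmentation pipeline
#'
#' All thresholds and iteration controls of the five segmentation stages
#' live in one place so every choice is visible and overridable.
#'
#' @param air_hu region-growing air threshold for the body mask (HU).
#' @param hu_low,hu_high adipose band bounds (HU), closed interval.
#' @param kappa anisotropic-diffusion conductance scale (HU).
#' @param n_iter diffusion iterations.
#' @param dt diffusion time step (stable for dt <= 0.25 with 4 neighbours).
#' @param erosion_radius_mm initial inward erosion used to seed the internal
#'   contour past the subcutaneous fat ring.
#' @param tol convergence tolerance for contour evolution: mean boundary
#'   displacement per iteration, in pixels.
#' @param max_iter contour evolution iteration cap.
#' @param min_internal_area_frac contour-collapse guard: the internal region
#'   must keep at least this fraction of the body area.
#' @return A named list of class `segment_config`.
#' @export
segment_config <- function(air_hu = -400, hu_low = -274, hu_high = -49,
                           kappa = 50, n_iter = 5, dt = 0.125,
                           erosion_radius_mm = 30, tol = 0.1, max_iter = 200,
                           min_internal_area_frac = 0.05) {
  structure(list(air_hu = air_hu, hu_low = hu_low, hu_high = hu_high,
                 kappa = kappa, n_iter = n_iter, dt = dt,
                 erosion_radius_mm = erosion_radius_mm, tol = tol,
                 max_iter = max_iter,
                 min_internal_area_frac = min_internal_area_frac),
            class = "segment_config")
}

# Morphological helpers built on the distance transform: erosion/dilation of
# a binary mask by a Euclidean radius in pixels (fast and radius-exact).
erode_by <- function(mask, r) {
  if (r <= 0) return(mask)
  EBImage::distmap(mask * 1) > r
}
dilate_by <- function(mask, r) {
  if (r <= 0) return(mask)
  !(EBImage::distmap(!mask * 1) > r)
}

#' Step 1: body mask by region growing with CT-table removal
#'
#' Air is grown from every border pixel across 8-connected neighbours below
#' the air threshold; the complement splits into candidate objects, of which
#' the largest connected component is the body, discarding the CT table and
#' cables. Internal holes (e.g. bowel gas) are filled so the mask is simply
#' connected.
#'
#' @param slice an HU-normalized [ct_slice()].
#' @param air_hu air threshold in HU.
#' @return A list of class `body_mask`: `mask` (logical matrix),
#'   `table_removed`, `largest_component_only`.
#' @export
make_body_mask <- function(slice, air_hu = -400) {
  hu <- slice$hu
  low <- hu < air_hu
  lab_low <- EBImage::bwlabel(low * 1)
  border_labels <- setdiff(unique(c(lab_low[1, ], lab_low[nrow(hu), ],
                                    lab_low[, 1], lab_low[, ncol(hu)])), 0)
  outside_air <- matrix(lab_low %in% border_labels, nrow(hu))
  objects <- !outside_air
  lab_obj <- EBImage::bwlabel(objects * 1)
  if (max(lab_obj) == 0) seg_failure("no object found in slice", "body_mask")
  sizes <- tabulate(lab_obj[lab_obj > 0])
  body <- lab_obj == which.max(sizes)
  body <- EBImage::fillHull(body) > 0
  touches <- c(any(body[1, ]), any(body[nrow(body), ]),
               any(body[, 1]), any(body[, ncol(body)]))
  if (all(touches)) {
    seg_failure("body mask touches all four image borders", "body_mask")
  }
  structure(list(mask = body, table_removed = TRUE,
                 largest_component_only = TRUE),
            class = "body_mask")
}

#' Step 2: anisotropic diffusion denoising (Perona-Malik)
#'
#' Four-neighbour Perona-Malik diffusion with the exponential conductance
#' g(s) = exp(-(s/kappa)^2): gradients well below kappa are smoothed like a
#' heat equation, while edges with contrast much larger than kappa (the
#' roughly 140 HU fat/muscle interface at the default kappa = 50) conduct
#' almost nothing and are preserved. The symmetric flux form conserves the
#' image mean up to boundary effects.
#'
#' @param slice a [ct_slice()].
#' @param kappa conductance scale in HU.
#' @param n_iter number of iterations (0 returns the input unchanged).
#' @param dt time step; stability requires dt <= 0.25.
#' @return The denoised [ct_slice()].
#' @export
denoise <- function(slice, kappa = 50, n_iter = 5, dt = 0.125) {
  if (n_iter < 0 || dt <= 0) {
    adipoct_error("n_iter must be >= 0 and dt > 0", "adipoct_parameter_error")
  }
  if (n_iter == 0) return(slice)
  u <- slice$hu
  nr <- nrow(u); nc <- ncol(u)
  for (it in seq_len(n_iter)) {
    # neighbour differences with replicated (Neumann) boundaries
    dN <- rbind(u[1, , drop = FALSE], u[-nr, , drop = FALSE]) - u
    dS <- rbind(u[-1, , drop = FALSE], u[nr, , drop = FALSE]) - u
    dW <- cbind(u[, 1, drop = FALSE], u[, -nc, drop = FALSE]) - u
    dE <- cbind(u[, -1, drop = FALSE], u[, nc, drop = FALSE]) - u
    u <- u + dt * (exp(-(dN / kappa)^2) * dN + exp(-(dS / kappa)^2) * dS +
                   exp(-(dW / kappa)^2) * dW + exp(-(dE / kappa)^2) * dE)
  }
  out <- slice
  out$hu <- u
  out
}

#' Step 3: label adipose tissue by Hounsfield-unit band
#'
#' A pixel is labeled adipose iff its (denoised) HU lies in the closed
#' interval [-274, -49] and it is inside the body mask.
#'
#' @param slice a denoised, HU-normalized [ct_slice()].
#' @param mask a [make_body_mask()] result (or logical matrix).
#' @param hu_low,hu_high band bounds, inclusive at both ends.
#' @return Logical matrix of class `adipose_labels`, with the band stored
#'   in attributes `hu_low`/`hu_high`.
#' @export
label_adipose <- function(slice, mask, hu_low = -274, hu_high = -49) {
  m <- if (inherits(mask, "body_mask")) mask$mask else mask
  lab <- slice$hu >= hu_low & slice$hu <= hu_high & m
  structure(lab, class = c("adipose_labels", class(lab)),
            hu_low = hu_low, hu_high = hu_high)
}

#' Step 4: external and internal body contours
#'
#' The external contour is taken from the body-mask boundary (the skin
#' surface). The internal contour is found by a morphological active
#' contour: a seed region, obtained by eroding the body mask inward past
#' the subcutaneous fat ring, is evolved outward by unit geodesic dilation
#' steps constrained to non-adipose tissue that is not connected to the
#' skin, so the front locks onto the outer surface of the abdominal-wall
#' musculature. Iteration stops when the mean boundary displacement per
#' iteration falls below `tol` pixels or at `max_iter`.
#'
#' The erosion radius adapts: starting from `erosion_radius_mm`, it shrinks
#' until the seed is non-empty, and grows while the HU band under the seed
#' boundary is still adipose (i.e. the seed has not yet passed the SAT
#' ring).
#'
#' @param slice a denoised, HU-normalized [ct_slice()].
#' @param mask a [make_body_mask()] result.
#' @param config a [segment_config()].
#' @return A list of class `contour_pair`: `external_contour` and
#'   `internal_contour` (closed counter-clockwise polygons, 0-based pixel
#'   coordinates as (row, col) matrices), the corresponding filled masks
#'   `external_mask`/`internal_mask`, `iterations_used`, `converged`.
#' @export
fit_contours <- function(slice, mask, config = segment_config()) {
  body <- if (inherits(mask, "body_mask")) mask$mask else mask
  n_body <- sum(body)
  if (n_body < 50) seg_failure("body mask too small to contour", "contours")
  px_mm <- mean(slice$pixel_spacing)
  adipose <- slice$hu >= config$hu_low & slice$hu <= config$hu_high & body

  # adipose connected to the skin surface: candidate subcutaneous ring
  boundary_band <- body & !erode_by(body, 2)
  lab_fat <- EBImage::bwlabel(adipose * 1)
  skin_labels <- setdiff(unique(lab_fat[boundary_band]), 0)
  sat_cand <- matrix(lab_fat %in% skin_labels, nrow(body))
  core_target <- body & !sat_cand

  # adaptive erosion seed
  r <- config$erosion_radius_mm / px_mm
  seed <- erode_by(body, r)
  while (r > 1 && sum(seed) < 0.02 * n_body) {
    r <- r / 1.5
    seed <- erode_by(body, r)
  }
  # push deeper while the seed boundary still sits in subcutaneous fat
  while (r < 0.45 * sqrt(n_body)) {
    band <- seed & !erode_by(seed, 2)
    if (sum(band) == 0 || mean(slice$hu[band]) > config$hu_high) break
    r <- r + 2 / px_mm
    seed2 <- erode_by(body, r)
    if (sum(seed2) < 0.02 * n_body) break
    seed <- seed2
  }
  seed <- seed & core_target
  lab_seed <- EBImage::bwlabel(seed * 1)
  if (max(lab_seed) == 0) seg_failure("internal contour seed collapsed", "contours")
  seed <- lab_seed == which.max(tabulate(lab_seed[lab_seed > 0]))

  # geodesic dilation of the seed inside the non-SAT tissue web
  cur <- seed
  iterations <- 0L
  converged <- FALSE
  perim <- max(1, sum(cur & !erode_by(cur, 1.5)))
  for (it in seq_len(config$max_iter)) {
    nxt <- dilate_by(cur, 1.5) & core_target
    iterations <- it
    grown <- sum(nxt & !cur)
    cur <- cur | nxt
    perim <- max(1, sum(cur & !erode_by(cur, 1.5)))
    if (grown / perim < config$tol) { converged <- TRUE; break }
  }
  internal <- EBImage::fillHull(cur) > 0
  if (sum(internal) < config$min_internal_area_frac * n_body) {
    seg_failure("internal contour collapsed", "contours")
  }
  external <- body

  structure(list(
    external_contour = mask_contour(external),
    internal_contour = mask_contour(internal),
    external_mask = external,
    internal_mask = internal,
    iterations_used = iterations,
    converged = converged
  ), class = "contour_pair")
}

# Closed counter-clockwise polygon (0-based (row, col)) tracing a mask.
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(mask * 1L)
  if (length(oc) == 0) return(matrix(numeric(0), ncol = 2))
  poly <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # EBImage returns 0-based (x, y) on its column-major grid; report (row, col)
  poly <- poly[, c(2, 1), drop = FALSE]
  colnames(poly) <- c("row", "col")
  if (polygon_area_signed(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  poly
}

polygon_area_signed <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

#' Step 5: quantify SAT and VAT areas and the VSR
#'
#' Subcutaneous adipose tissue (SAT) is any adipose-labeled pixel between
#' the external and internal contours; visceral adipose tissue (VAT) is any
#' adipose-labeled pixel inside the internal contour. Areas are pixel
#' counts times the pixel area.
#'
#' @param labels a [label_adipose()] result.
#' @param contours a [fit_contours()] result.
#' @param pixel_spacing mm per pixel (row, col).
#' @return An `adipose_measures` object; see [adipose_measures()].
#' @export
quantify <- function(labels, contours, pixel_spacing) {
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (any(pixel_spacing <= 0)) invalid_spec("pixel_spacing must be positive")
  lab <- unclass(labels)
  sat_px <- sum(lab & contours$external_mask & !contours$internal_mask)
  vat_px <- sum(lab & contours$internal_mask)
  pa <- pixel_spacing[1] * pixel_spacing[2]
  adipose_measures(sat_area_mm2 = sat_px * pa, vat_area_mm2 = vat_px * pa,
                   pixel_area_mm2 = pa)
}

#' Adipose-tissue area measures
#'
#' The three biomarkers of the pipeline: SAT area, VAT area (reported in
#' both mm^2 and cm^2) and the visceral-to-subcutaneous area ratio
#' VSR = VAT / SAT. When the SAT area is zero the VSR is undefined and
#' reported as `NA` with `vsr_defined = FALSE`, never as infinity.
#'
#' @param sat_area_mm2,vat_area_mm2 areas in mm^2.
#' @param pixel_area_mm2 area of one pixel in mm^2 (metadata).
#' @param qa_image_path optional path of the QA rendering.
#' @return A list of class `adipose_measures` with mm^2 and cm^2 fields,
#'   `vsr` and `vsr_defined`.
#' @export
adipose_measures <- function(sat_area_mm2, vat_area_mm2,
                             pixel_area_mm2 = NA_real_,
                             qa_image_path = NULL) {
  if (sat_area_mm2 < 0 || vat_area_mm2 < 0) {
    invalid_spec("areas must be non-negative")
  }
  vsr_defined <- sat_area_mm2 > 0
  structure(list(
    sat_area_mm2 = sat_area_mm2,
    vat_area_mm2 = vat_area_mm2,
    sat_area_cm2 = sat_area_mm2 / 100,
    vat_area_cm2 = vat_area_mm2 / 100,
    vsr = if (vsr_defined) vat_area_mm2 / sat_area_mm2 else NA_real_,
    vsr_defined = vsr_defined,
    pixel_area_mm2 = pixel_area_mm2,
    qa_image_path = qa_image_path
  ), class = "adipose_measures")
}

#' @export
print.adipose_measures <- function(x, ...) {
  cat(sprintf("SAT area: %.1f cm^2\nVAT area: %.1f cm^2\nVSR: %s\n",
              x$sat_area_cm2, x$vat_area_cm2,
              if (x$vsr_defined) sprintf("%.2f", x$vsr) else "undefined (SAT = 0)"))
  invisible(x)
}

#' Run the full five-step segmentation on one slice
#'
#' Composes body-mask creation, anisotropic diffusion, HU-band adipose
#' labeling, contour fitting and quantification; records per-stage wall
#' times. Deterministic for a fixed input and configuration. Any stage
#' failure is returned as a tool-failure result naming the failing stage
#' rather than an R error, matching the batch-processing contract.
#'
#' @param slice an HU-normalized L3 [ct_slice()].
#' @param config a [segment_config()].
#' @param qa_path optional path: write a QA rendering on success.
#' @return A list: `measures` (an `adipose_measures` or `NULL`), `status`
#'   (`"ok"` or `"tool_failure"`), `failed_stage`, `timings_s` (named
#'   numeric), plus the intermediate `mask`, `labels`, `contours` when
#'   successful.
#' @export
segment_slice <- function(slice, config = segment_config(), qa_path = NULL) {
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }
  res <- tryCatch({
    mask <- stage("body_mask", make_body_mask(slice, config$air_hu))
    den <- stage("denoise", denoise(slice, config$kappa, config$n_iter, config$dt))
    labels <- stage("label_adipose",
                    label_adipose(den, mask, config$hu_low, config$hu_high))
    contours <- stage("fit_contours", fit_contours(den, mask, config))
    measures <- stage("quantify", quantify(labels, contours, slice$pixel_spacing))
    if (!is.null(qa_path)) {
      render_qa(slice, labels, contours, measures, qa_path)
      measures$qa_image_path <- qa_path
    }
    list(measures = measures, status = "ok", failed_stage = NA_character_,
         timings_s = timings, mask = mask, labels = labels, contours = contours)
  }, adipoct_segmentation_failure = function(e) {
    list(measures = NULL, status = "tool_failure",
         failed_stage = if (!is.null(e$stage)) e$stage else NA_character_,
         timings_s = timings, message = conditionMessage(e))
  })
  res
}
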