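# Color-coded quality-assurance rendering: grayscale soft-tissue-windowed
# CT underlay, VAT overlaid in gold, SAT in blue, contours drawn, and an
# annotation strip printing the SAT/VAT areas (cm^2) and the VSR.

# 5x7 bitmap glyphs for the annotation strip (1 = lit).
.QA_FONT <- local({
  g <- list(
    "0" = c("01110","10001","10011","10101","11001","10001","01110"),
    "1" = c("00100","01100","00100","00100","00100","00100","01110"),
    "2" = c("01110","10001","00001","00010","00100","01000","11111"),
    "3" = c("11110","00001","00001","01110","00001","00001","11110"),
    "4" = c("00010","00110","01010","10010","11111","00010","00010"),
    "5" = c("11111","10000","11110","00001","00001","10001","01110"),
    "6" = c("00110","01000","10000","11110","10001","10001","01110"),
    "7" = c("11111","00001","00010","00100","01000","01000","01000"),
    "8" = c("01110","10001","10001","01110","10001","10001","01110"),
    "9" = c("01110","10001","10001","01111","00001","00010","01100"),
    "." = c("00000","00000","00000","00000","00000","01100","01100"),
    ":" = c("00000","01100","01100","00000","01100","01100","00000"),
    " " = c("00000","00000","00000","00000","00000","00000","00000"),
    "-" = c("00000","00000","00000","11111","00000","00000","00000"),
    "S" = c("01111","10000","10000","01110","00001","00001","11110"),
    "A" = c("01110","10001","10001","11111","10001","10001","10001"),
    "T" = c("11111","00100","00100","00100","00100","00100","00100"),
    "V" = c("10001","10001","10001","10001","01010","01010","00100"),
    "R" = c("11110","10001","10001","11110","10100","10010","10001"),
    "N" = c("10001","11001","10101","10011","10001","10001","10001"),
    "D" = c("11110","10001","10001","10001","10001","10001","11110"),
    "E" = c("11111","10000","10000","11110","10000","10000","11111"),
    "F" = c("11111","10000","10000","11110","10000","10000","10000"),
    "U" = c("10001","10001","10001","10001","10001","10001","01110")
  )
  lapply(g, function(rows) {
    do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  })
})

draw_text <- function(canvas, text, row0, col0, value = 1) {
  chars <- strsplit(toupper(text), "")[[1]]
  col <- col0
  for (ch in chars) {
    glyph <- .QA_FONT[[ch]]
    if (is.null(glyph)) glyph <- .QA_FONT[[" "]]
    rr <- row0 + seq_len(7) - 1
    cc <- col + seq_len(5) - 1
    if (max(rr) <= nrow(canvas) && max(cc) <= ncol(canvas)) {
      seg <- canvas[rr, cc]
      seg[glyph == 1] <- value
      canvas[rr, cc] <- seg
    }
    col <- col + 6
  }
  canvas
}

#' Render the color-coded quality-assurance image
#'
#' Writes a PNG with a soft-tissue-windowed grayscale underlay of the CT
#' slice, the VAT pixels in gold and the SAT pixels in blue (defaults
#' configurable), the external and internal contours drawn, and an
#' annotation strip printing the SAT and VAT areas in cm^2 and the VSR.
#'
#' @param slice the [ct_slice()] that was segmented.
#' @param labels a [label_adipose()] result.
#' @param contours a [fit_contours()] result.
#' @param measures the [quantify()] result (used for the annotation strip).
#' @param path output PNG path.
#' @param vat_color,sat_color overlay colors as RGB triplets in [0, 1];
#'   defaults gold and blue.
#' @param window HU display window (center, width) for the underlay.
#' @return `path`, invisibly.
#' @export
render_qa <- function(slice, labels, contours, measures, path,
                      vat_color = c(1.0, 0.84, 0.0),
                      sat_color = c(0.12, 0.35, 0.95),
                      window = c(40, 400)) {
  hu <- slice$hu
  lo <- window[1] - window[2] / 2
  gray <- pmin(pmax((hu - lo) / window[2], 0), 1)
  nr <- nrow(hu); nc <- ncol(hu)
  rgb <- array(rep(gray, 3), c(nr, nc, 3))

  draw_mask_outline <- function(rgb, mask, color) {
    edge <- mask & !erode_by(mask, 1.5)
    for (k in 1:3) { ch <- rgb[, , k]; ch[edge] <- color[k]; rgb[, , k] <- ch }
    rgb
  }
  rgb <- draw_mask_outline(rgb, contours$external_mask, c(0.9, 0.1, 0.1))
  rgb <- draw_mask_outline(rgb, contours$internal_mask, c(0.1, 0.9, 0.1))

  lab <- unclass(labels)
  sat_px <- lab & contours$external_mask & !contours$internal_mask
  vat_px <- lab & contours$internal_mask
  for (k in 1:3) {
    ch <- rgb[, , k]
    ch[sat_px] <- sat_color[k]
    ch[vat_px] <- vat_color[k]
    rgb[, , k] <- ch
  }

  strip_h <- 14L
  strip <- matrix(0, strip_h, nc)
  note <- if (isTRUE(measures$vsr_defined)) {
    sprintf("SAT %.1f  VAT %.1f  VSR %.2f",
            measures$sat_area_cm2, measures$vat_area_cm2, measures$vsr)
  } else {
    sprintf("SAT %.1f  VAT %.1f  VSR UNDEF",
            measures$sat_area_cm2, measures$vat_area_cm2)
  }
  strip <- draw_text(strip, note, 4, 4)
  out <- array(0, c(nr + strip_h, nc, 3))
  out[seq_len(nr), , ] <- rgb
  for (k in 1:3) out[nr + seq_len(strip_h), , k] <- strip
  png::writePNG(out, path)
  invisible(path)
}
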