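# Minimal single-frame CT DICOM I/O (Explicit VR Little Endian).
#
# Scope: just enough of PS3.10 to round-trip one axial CT slice — Rows,
# Columns, PixelSpacing, RescaleSlope/Intercept, ImageOrientationPatient and
# 16-bit signed PixelData. Not a general DICOM implementation: one frame,
# one transfer syntax, no sequences.

.DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.DCM_CT_SOP <- "1.2.840.10008.5.1.4.1.1.2"

dcm_uid <- function() {
  paste0("2.25.", paste0(sample(0:9, 30, replace = TRUE), collapse = ""))
}

dcm_elem <- function(group, element, vr, value) {
  tag <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                  endian = "little")
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    body <- value
    len <- writeBin(length(body), raw(), size = 4, endian = "little")
    c(tag, charToRaw(vr), as.raw(c(0, 0)), len, body)
  } else if (vr %in% c("US", "UL", "SS", "SL", "FL", "FD")) {
    size <- switch(vr, US = 2, SS = 2, UL = 4, SL = 4, FL = 4, FD = 8)
    body <- if (vr %in% c("FL", "FD")) {
      writeBin(as.double(value), raw(), size = size, endian = "little")
    } else {
      writeBin(as.integer(value), raw(), size = size, endian = "little")
    }
    len <- writeBin(length(body), raw(), size = 2, endian = "little")
    c(tag, charToRaw(vr), len, body)
  } else {  # string VRs: CS, DS, IS, LO, SH, UI, DA, TM, PN ...
    s <- paste(value, collapse = "\\")
    body <- charToRaw(s)
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    if (length(body) %% 2 == 1) body <- c(body, pad)
    len <- writeBin(length(body), raw(), size = 2, endian = "little")
    c(tag, charToRaw(vr), len, body)
  }
}

write_dicom_slice <- function(slice, path) {
  intercept <- -1024
  stored <- round(slice$hu) - intercept         # slope 1
  if (any(stored < -32768 | stored > 32767)) {
    invalid_spec("HU values out of range for 16-bit DICOM storage")
  }
  nr <- nrow(slice$hu); nc <- ncol(slice$hu)
  # PixelData is row-major within DICOM (fastest across columns)
  px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")

  sop_uid <- with_seed(derive_seed(sum(slice$hu[1, ]) %% 1e6, 9L), dcm_uid())
  meta <- c(
    dcm_elem(0x0002, 0x0002, "UI", .DCM_CT_SOP),
    dcm_elem(0x0002, 0x0003, "UI", sop_uid),
    dcm_elem(0x0002, 0x0010, "UI", .DCM_EXPLICIT_LE)
  )
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", length(meta)), meta)

  orient <- slice$orientation %||% "LAS"
  # row direction = second letter axis, col direction = first; LAS default
  iop <- c(1, 0, 0, 0, 1, 0)
  ds_fmt <- function(x) sub("0+$", "", sub("\\.$", "", sprintf("%.8f", x)))

  dataset <- c(
    dcm_elem(0x0008, 0x0016, "UI", .DCM_CT_SOP),
    dcm_elem(0x0008, 0x0018, "UI", sop_uid),
    dcm_elem(0x0008, 0x0060, "CS", "CT"),
    dcm_elem(0x0020, 0x0037, "DS", ds_fmt(iop)),
    dcm_elem(0x0028, 0x0002, "US", 1L),
    dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_elem(0x0028, 0x0010, "US", nr),
    dcm_elem(0x0028, 0x0011, "US", nc),
    dcm_elem(0x0028, 0x0030, "DS", ds_fmt(slice$pixel_spacing)),
    dcm_elem(0x0028, 0x0100, "US", 16L),
    dcm_elem(0x0028, 0x0101, "US", 16L),
    dcm_elem(0x0028, 0x0102, "US", 15L),
    dcm_elem(0x0028, 0x0103, "US", 1L),
    dcm_elem(0x0028, 0x1052, "DS", ds_fmt(intercept)),
    dcm_elem(0x0028, 0x1053, "DS", "1"),
    dcm_elem(0x7FE0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

read_dicom_slice <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM") {
    adipoct_error(sprintf("'%s' is not a DICOM part-10 file", path),
                  "adipoct_io_error")
  }
  pos <- 133L
  elems <- list()
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  while (pos + 8 <= length(bytes) + 1) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- u32(pos + 8L); body_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); body_at <- pos + 8L
    }
    body <- if (len > 0) bytes[body_at:(body_at + len - 1L)] else raw(0)
    elems[[sprintf("%04x,%04x", group, element)]] <- list(vr = vr, body = body)
    pos <- body_at + len
  }
  gets <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    trimws(rawToChar(e$body[e$body != as.raw(0)]))
  }
  getn <- function(key) as.numeric(strsplit(gets(key), "\\\\")[[1]])
  getus <- function(key) {
    e <- elems[[key]]
    readBin(e$body, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  nr <- getus("0028,0010"); nc <- getus("0028,0011")
  spacing <- getn("0028,0030")
  slope <- getn("0028,1053") %||% 1
  intercept <- getn("0028,1052") %||% 0
  px <- elems[["7fe0,0010"]]
  stored <- readBin(px$body, "integer", nr * nc, size = 2, signed = TRUE,
                    endian = "little")
  hu <- t(matrix(stored, nc, nr)) * slope + intercept
  ct_slice(hu, spacing, orientation = NA_character_,
           provenance = list(source = path, modality = gets("0008,0060")))
}
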