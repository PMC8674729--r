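# Minimal DICOM part-10 support: just enough to read the pixel-spacing tags
# (and pixel array) from little-endian files and to write the package's own
# synthetic radiographs. Not a general DICOM implementation.

.vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.vr_known <- c(.vr_long, "AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD",
               "IS", "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI",
               "UL", "US")

.u16 <- function(raw) sum(as.integer(raw) * c(1L, 256L))
.u32 <- function(raw) sum(as.numeric(raw) * c(1, 256, 65536, 16777216))

# Walk the element stream of a little-endian DICOM file, collecting the few
# tags we care about. Handles both explicit and implicit VR.
readDicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(raw) >= 132 && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  out <- list()
  want <- c("0028,0030", "0018,1164", "0028,0010", "0028,0011",
            "0028,0100", "7fe0,0010")
  while (pos + 8 <= length(raw)) {
    grp <- .u16(raw[pos:(pos + 1)]); ele <- .u16(raw[(pos + 2):(pos + 3)])
    tag <- sprintf("%04x,%04x", grp, ele)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% .vr_known) {
      if (vr %in% .vr_long) {
        len <- .u32(raw[(pos + 8):(pos + 11)]); hdr <- 12L
      } else {
        len <- .u16(raw[(pos + 6):(pos + 7)]); hdr <- 8L
      }
    } else { # implicit VR
      len <- .u32(raw[(pos + 4):(pos + 7)]); hdr <- 8L
      vr <- NA_character_
    }
    if (!is.finite(len) || pos + hdr + len - 1L > length(raw)) break
    if (tag %in% want) {
      val <- raw[(pos + hdr):(pos + hdr + len - 1L)]
      out[[tag]] <- switch(tag,
        "0028,0030" = , "0018,1164" =
          as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
        "0028,0010" = , "0028,0011" = , "0028,0100" = .u16(val[1:2]),
        val)
    }
    pos <- pos + hdr + as.integer(len)
    if (tag == "7fe0,0010") break
  }
  out
}

#' Read pixel spacing from a DICOM header
#'
#' Prefers PixelSpacing (0028,0030) and falls back to ImagerPixelSpacing
#' (0018,1164). Measurements in mm require this spacing; when both tags are
#' absent the caller must supply an override.
#'
#' @param path DICOM file.
#' @return numeric length-2 (row, col) spacing in mm/px.
#' @export
readPixelSpacing <- function(path) {
  d <- readDicom(path)
  sp <- d[["0028,0030"]] %||% d[["0018,1164"]]
  if (is.null(sp)) {
    fmStop("fm_missing_spacing",
           "%s: neither PixelSpacing nor ImagerPixelSpacing present", path)
  }
  if (length(sp) == 1L) sp <- c(sp, sp)
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    fmStop("fm_invalid_header", "%s: non-positive pixel spacing", path)
  }
  sp
}

#' Read the pixel array of a (package-written) DICOM file
#'
#' Supports the 8-bit single-frame files produced by \code{writeDicom}.
#'
#' @param path DICOM file.
#' @return numeric matrix in [0, 1], rows = image rows.
#' @export
readDicomImage <- function(path) {
  d <- readDicom(path)
  if (is.null(d[["7fe0,0010"]])) fmStop("fm_parse_error", "%s: no pixel data", path)
  rows <- d[["0028,0010"]]; cols <- d[["0028,0011"]]
  px <- as.integer(d[["7fe0,0010"]])[seq_len(rows * cols)]
  matrix(px, nrow = rows, ncol = cols, byrow = TRUE) / 255
}

.dcm_element <- function(grp, ele, vr, value) {
  if (vr %in% c("DS", "UI", "CS", "LO", "SH")) {
    v <- charToRaw(value)
    if (length(v) %% 2 == 1) v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  } else if (vr == "US") {
    v <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "UL") {
    v <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "OB") {
    v <- value
    if (length(v) %% 2 == 1) v <- c(v, as.raw(0))
  } else stop("unsupported VR ", vr)
  hdr <- c(writeBin(c(grp, ele), raw(), size = 2, endian = "little"),
           charToRaw(vr))
  if (vr %in% .vr_long) {
    c(hdr, as.raw(c(0, 0)),
      writeBin(length(v), raw(), size = 4, endian = "little"), v)
  } else {
    c(hdr, writeBin(length(v), raw(), size = 2, endian = "little"), v)
  }
}

#' Write a minimal grayscale DICOM file
#'
#' Explicit-VR little-endian, 8-bit single-frame secondary capture carrying
#' the image matrix and its pixel spacing. Used for the package's synthetic
#' pseudo-radiographs and for round-trip tests of the header reader.
#'
#' @param image numeric matrix in [0, 1] (rows = image rows).
#' @param path output file.
#' @param spacing mm-per-pixel (single number or (row, col) pair) written to
#'   PixelSpacing; NULL to omit.
#' @param imagerSpacing optional ImagerPixelSpacing value; NULL to omit.
#' @return \code{path}, invisibly.
#' @export
writeDicom <- function(image, path, spacing = NULL, imagerSpacing = NULL) {
  img8 <- as.integer(pmin(pmax(round(image * 255), 0), 255))
  px <- as.raw(as.integer(t(matrix(img8, nrow(image), ncol(image)))))
  ds <- function(sp) {
    if (length(sp) == 1L) sp <- c(sp, sp)
    sprintf("%g\\%g", sp[1], sp[2])
  }
  meta <- c(
    .dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
    .dcm_element(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1")
  )
  body <- c(
    .dcm_element(0x0008L, 0x0060L, "CS", "OT"),
    if (!is.null(imagerSpacing)) .dcm_element(0x0018L, 0x1164L, "DS", ds(imagerSpacing)),
    .dcm_element(0x0028L, 0x0002L, "US", 1L),
    .dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    .dcm_element(0x0028L, 0x0010L, "US", nrow(image)),
    .dcm_element(0x0028L, 0x0011L, "US", ncol(image)),
    if (!is.null(spacing)) .dcm_element(0x0028L, 0x0030L, "DS", ds(spacing)),
    .dcm_element(0x0028L, 0x0100L, "US", 8L),
    .dcm_element(0x0028L, 0x0101L, "US", 8L),
    .dcm_element(0x0028L, 0x0102L, "US", 7L),
    .dcm_element(0x0028L, 0x0103L, "US", 0L),
    .dcm_element(0x7fe0L, 0x0010L, "OB", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(.dcm_element(0x0002L, 0x0000L, "UL", length(meta)), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}
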