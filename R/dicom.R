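# Minimal single-frame DICOM support.
#
# Scope: uncompressed, explicit-VR little-endian, monochrome, single-frame
# files -- the shape in which individual scapular Y-view exports arrive.
# Compressed transfer syntaxes, sequences with undefined length, and
# multi-frame objects are out of scope and raise errors.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

#' Read a single-frame grayscale DICOM file
#'
#' Minimal reader for uncompressed explicit-VR little-endian monochrome
#' DICOM, returning the raw stored pixel values (no rescale slope/intercept
#' is applied; windowing is deliberately ignored because quantification
#' runs on the package's own 8-bit normalization).
#'
#' @param path file path.
#' @return list with `pixels` (numeric matrix, row-major as stored),
#'   `bits_allocated`, `bits_stored`.
#' @export
read_dicom_gray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 132) {
    stop(sprintf("cannot read DICOM '%s': file truncated", path),
         call. = FALSE)
  }
  seek(con, 128)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "DICM")) {
    stop(sprintf("'%s' is not a DICOM file (missing DICM magic)", path),
         call. = FALSE)
  }
  elems <- list()
  repeat {
    hdr <- dicom_read_element(con, path)
    if (is.null(hdr)) break
    elems[[sprintf("%04x,%04x", hdr$group, hdr$element)]] <- hdr
  }
  ts <- dicom_string(elems[["0002,0010"]])
  if (!is.null(ts) && ts != DICOM_EXPLICIT_LE) {
    stop(sprintf("unsupported DICOM transfer syntax '%s' in '%s'", ts, path),
         call. = FALSE)
  }
  rows <- dicom_us(elems[["0028,0010"]], path, "Rows")
  cols <- dicom_us(elems[["0028,0011"]], path, "Columns")
  ba <- dicom_us(elems[["0028,0100"]], path, "BitsAllocated")
  bs <- elems[["0028,0101"]]
  bs <- if (is.null(bs)) ba else dicom_us(bs, path, "BitsStored")
  pix <- elems[["7fe0,0010"]]
  if (is.null(pix)) {
    stop(sprintf("DICOM '%s' has no PixelData", path), call. = FALSE)
  }
  n <- rows * cols
  bytes <- pix$value
  if (ba == 8) {
    if (length(bytes) < n) {
      stop(sprintf("DICOM '%s': PixelData truncated", path), call. = FALSE)
    }
    vals <- as.integer(bytes[seq_len(n)])
  } else if (ba == 16) {
    if (length(bytes) < 2L * n) {
      stop(sprintf("DICOM '%s': PixelData truncated", path), call. = FALSE)
    }
    v <- as.integer(bytes)
    vals <- v[seq(1L, 2L * n, by = 2L)] + 256L * v[seq(2L, 2L * n, by = 2L)]
  } else {
    stop(sprintf("unsupported BitsAllocated %d in '%s'", ba, path),
         call. = FALSE)
  }
  list(pixels = matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
       bits_allocated = ba, bits_stored = bs)
}

dicom_read_element <- function(con, path) {
  gb <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  if (length(gb) == 0L) return(NULL)
  if (length(gb) < 2L) {
    stop(sprintf("DICOM '%s': truncated element header", path),
         call. = FALSE)
  }
  group <- gb[1L] + 256L * gb[2L]
  eb <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  if (length(eb) < 2L) {
    stop(sprintf("DICOM '%s': truncated element header", path),
         call. = FALSE)
  }
  element <- eb[1L] + 256L * eb[2L]
  vr <- readChar(con, 2L, useBytes = TRUE)
  if (nchar(vr) < 2L) {
    stop(sprintf("DICOM '%s': truncated element header", path),
         call. = FALSE)
  }
  if (vr %in% LONG_VRS) {
    seek(con, 2L, origin = "current") # reserved
    len <- readBin(con, "integer", 1L, size = 4L)
  } else {
    len <- readBin(con, "integer", 1L, size = 2L, signed = FALSE)
  }
  if (length(len) == 0L || is.na(len) || len < 0L) {
    stop(sprintf("DICOM '%s': undefined-length element (%04x,%04x) unsupported",
                 path, group, element), call. = FALSE)
  }
  value <- readBin(con, "integer", len, size = 1L, signed = FALSE)
  if (length(value) < len) {
    stop(sprintf("DICOM '%s': element (%04x,%04x) truncated", path,
                 group, element), call. = FALSE)
  }
  list(group = group, element = element, vr = vr, value = value)
}

dicom_string <- function(el) {
  if (is.null(el)) return(NULL)
  sub("[\\x00 ]+$", "", rawToChar(as.raw(el$value)), perl = TRUE)
}

dicom_us <- function(el, path, what) {
  if (is.null(el) || length(el$value) < 2L) {
    stop(sprintf("DICOM '%s': missing %s", path, what), call. = FALSE)
  }
  el$value[1L] + 256L * el$value[2L]
}

#' Write a single-frame grayscale DICOM file
#'
#' Minimal explicit-VR little-endian writer, the counterpart of
#' [read_dicom_gray()]; used for fixtures and round-trip testing.
#'
#' @param pixels integer matrix of non-negative pixel values.
#' @param path output path.
#' @param bits_allocated 8 or 16.
#' @return `path`, invisibly.
#' @export
write_dicom_gray <- function(pixels, path, bits_allocated = 16L) {
  stopifnot(is.matrix(pixels), all(pixels >= 0),
            bits_allocated %in% c(8L, 16L))
  if (max(pixels) >= 2^bits_allocated) {
    stop("pixel values exceed the allocated bit depth", call. = FALSE)
  }
  u16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
  u32 <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L,
                              (x %/% 65536L) %% 256L, x %/% 16777216L))
  even_pad <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2L == 1L) r <- c(r, as.raw(0L))
    r
  }
  short_el <- function(group, element, vr, value_raw) {
    c(u16(group), u16(element), charToRaw(vr),
      u16(length(value_raw)), value_raw)
  }
  long_el <- function(group, element, vr, value_raw) {
    c(u16(group), u16(element), charToRaw(vr), as.raw(c(0L, 0L)),
      u32(length(value_raw)), value_raw)
  }

  ts <- even_pad(DICOM_EXPLICIT_LE)
  meta <- c(
    long_el(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    short_el(0x0002L, 0x0010L, "UI", ts)
  )
  meta <- c(short_el(0x0002L, 0x0000L, "UL", u32(length(meta))), meta)

  vals <- as.integer(t(pixels)) # row-major storage
  if (bits_allocated == 8L) {
    pdata <- as.raw(vals)
  } else {
    pdata <- as.raw(as.vector(rbind(vals %% 256L, vals %/% 256L)))
  }
  if (length(pdata) %% 2L == 1L) pdata <- c(pdata, as.raw(0L))
  body <- c(
    short_el(0x0008L, 0x0060L, "CS", even_pad("MR")),
    short_el(0x0028L, 0x0002L, "US", u16(1L)),
    short_el(0x0028L, 0x0004L, "CS", even_pad("MONOCHROME2")),
    short_el(0x0028L, 0x0010L, "US", u16(nrow(pixels))),
    short_el(0x0028L, 0x0011L, "US", u16(ncol(pixels))),
    short_el(0x0028L, 0x0100L, "US", u16(bits_allocated)),
    short_el(0x0028L, 0x0101L, "US", u16(bits_allocated)),
    short_el(0x0028L, 0x0102L, "US", u16(bits_allocated - 1L)),
    short_el(0x0028L, 0x0103L, "US", u16(0L)),
    long_el(0x7fe0L, 0x0010L, "OW", pdata)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0L), 128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}
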