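# Minimal single-frame DICOM support: Explicit VR Little Endian, uncompressed
# 16-bit grayscale. Enough of the standard to round-trip micro-CT slice
# stacks and to read the attributes that fix stack geometry (pixel spacing,
# slice spacing/position, instance number, rescale slope/intercept). Not a
# general DICOM implementation; compressed transfer syntaxes, multi-frame
# and non-axial acquisitions are out of scope.

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad_str <- function(s, pad = charToRaw(" ")) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad)
  r
}

# one data element, explicit VR little endian
dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- dcm_pad_str(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  stopifnot(is.raw(value), length(value) %% 2 == 0)
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), dcm_u32(length(value)), value)
  } else {
    if (length(value) > 65534) stop("element value too long for short VR")
    c(head, dcm_u16(length(value)), value)
  }
}

dcm_ds <- function(x) paste(sprintf("%.16g", x), collapse = "\\")

#' Write a volume as a stack of single-frame DICOM slice files
#'
#' One uncompressed Explicit-VR-little-endian DICOM file per z-slice, with
#' consistent Rows/Columns, PixelSpacing, ImagePositionPatient,
#' SpacingBetweenSlices and InstanceNumber attributes so that
#' [read_dicom_stack()] recovers the grid exactly regardless of file order.
#' Intensities are quantized to signed 16-bit integers (the phantom
#' generator emits integer-valued grids, for which the round trip is
#' lossless). Test/fixture writer only — not for clinical use.
#'
#' @param v a volume with intensities in the signed 16-bit range.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; files are named `<prefix>_<k>.dcm`.
#' @return character vector of the written file paths, invisibly.
#' @export
write_dicom_fixture <- function(v, dir, prefix = "slice") {
  stopifnot(is_volume(v))
  if (any(abs(v$data) > 32766) || any(v$data != round(v$data))) {
    rounded <- round(v$data)
    if (any(abs(rounded) > 32766)) {
      stop("intensities exceed the signed 16-bit range of the fixture writer",
           call. = FALSE)
    }
    warning("intensities quantized to integers for DICOM fixture")
    v$data <- rounded
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- v$dims
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    pix <- as.integer(as.vector(v$data[, , k]))  # x fastest = DICOM row-major
    pixraw <- writeBin(pix, raw(), size = 2, endian = "little")
    pos <- v$origin + c(0, 0, (k - 1) * v$spacing[3])
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_element(0x0008, 0x0018, "UI", sprintf("1.2.826.0.1.3680043.9.7435.1.%d", k)),
      dcm_element(0x0018, 0x0050, "DS", dcm_ds(v$spacing[3])),
      dcm_element(0x0018, 0x0088, "DS", dcm_ds(v$spacing[3])),
      dcm_element(0x0020, 0x0013, "IS", sprintf("%d", k)),
      dcm_element(0x0020, 0x0032, "DS", dcm_ds(pos)),
      dcm_element(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0028, 0x0002, "US", dcm_u16(1)),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", dcm_u16(d[2])),   # Rows = ny
      dcm_element(0x0028, 0x0011, "US", dcm_u16(d[1])),   # Columns = nx
      dcm_element(0x0028, 0x0030, "DS", dcm_ds(c(v$spacing[2], v$spacing[1]))),
      dcm_element(0x0028, 0x0100, "US", dcm_u16(16)),
      dcm_element(0x0028, 0x0101, "US", dcm_u16(16)),
      dcm_element(0x0028, 0x0102, "US", dcm_u16(15)),
      dcm_element(0x0028, 0x0103, "US", dcm_u16(1)),
      dcm_element(0x0028, 0x1052, "DS", "0"),
      dcm_element(0x0028, 0x1053, "DS", "1"),
      dcm_element(0x7FE0, 0x0010, "OW", pixraw)
    )
    meta <- c(
      dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_element(0x0002, 0x0003, "UI", sprintf("1.2.826.0.1.3680043.9.7435.1.%d", k)),
      dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_u32(length(meta))), meta)
    path <- file.path(dir, sprintf("%s_%04d.dcm", prefix, k))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

# parse one DICOM file into the attributes the stack reader needs
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM marker): ", path, call. = FALSE)
  }
  pos <- 133L
  att <- list()
  getu16 <- function(r) sum(as.integer(r) * c(1L, 256L))
  getu32 <- function(r) sum(as.numeric(r) * c(1, 256, 65536, 16777216))
  while (pos + 7 <= length(raw)) {
    group <- getu16(raw[pos:(pos + 1)])
    elem <- getu16(raw[(pos + 2):(pos + 3)])
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- getu32(raw[(pos + 8):(pos + 11)])
      vstart <- pos + 12L
    } else {
      len <- getu16(raw[(pos + 6):(pos + 7)])
      vstart <- pos + 8L
    }
    if (vstart + len - 1 > length(raw)) {
      stop("truncated DICOM element in ", path, call. = FALSE)
    }
    val <- raw[seq.int(vstart, length.out = len)]
    tag <- sprintf("%04X,%04X", group, elem)
    keep <- c("0018,0050", "0018,0088", "0020,0013", "0020,0032",
              "0028,0010", "0028,0011", "0028,0030", "0028,0100",
              "0028,0103", "0028,1052", "0028,1053", "7FE0,0010")
    if (tag %in% keep) {
      att[[tag]] <- switch(vr,
        US = getu16(val[1:2]),
        UL = getu32(val[1:4]),
        DS = as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
        IS = as.integer(trimws(rawToChar(val))),
        OW = val,
        OB = val,
        trimws(rawToChar(val)))
    }
    pos <- vstart + len
    if (tag == "7FE0,0010") break
  }
  rows <- att[["0028,0010"]]; cols <- att[["0028,0011"]]
  if (is.null(rows) || is.null(cols)) {
    stop("DICOM file lacks Rows/Columns: ", path, call. = FALSE)
  }
  bits <- att[["0028,0100"]] %||% 16
  if (bits != 16) stop("only 16-bit DICOM pixel data supported: ", path, call. = FALSE)
  signed <- (att[["0028,0103"]] %||% 0) == 1
  pixraw <- att[["7FE0,0010"]]
  if (is.null(pixraw)) stop("DICOM file lacks PixelData: ", path, call. = FALSE)
  if (length(pixraw) < 2 * rows * cols) {
    stop("truncated PixelData in ", path, call. = FALSE)
  }
  pix <- readBin(pixraw, "integer", n = rows * cols, size = 2,
                 signed = signed, endian = "little")
  slope <- att[["0028,1053"]] %||% 1
  intercept <- att[["0028,1052"]] %||% 0
  m <- matrix(pix * slope + intercept, nrow = cols, ncol = rows)  # (x, y)
  list(
    pixels = m,
    rows = rows, cols = cols,
    pixel_spacing = att[["0028,0030"]],      # (row, col) = (sy, sx)
    slice_spacing = att[["0018,0088"]] %||% att[["0018,0050"]],
    position = att[["0020,0032"]],
    instance = att[["0020,0013"]],
    path = path
  )
}

#' Read a stack of single-frame DICOM slice files into a volume
#'
#' Slices are sorted into anatomical order by InstanceNumber when present,
#' else by the z component of ImagePositionPatient, else by file name, so
#' shuffled directory listings load identically. Rescale slope/intercept are
#' applied and intensities stored as doubles.
#'
#' @param file_paths character vector of DICOM slice files (any order).
#' @param subset optional integer vector of 1-based slice indices into the
#'   *sorted* stack (e.g. `5:12` for slices 5 through 12).
#' @param spacing_override optional length-3 numeric `(sx, sy, sz)` used
#'   when the files lack spacing attributes.
#' @return a [new_volume()] with dims `(cols, rows, n_selected)`.
#' @export
read_dicom_stack <- function(file_paths, subset = NULL, spacing_override = NULL) {
  if (length(file_paths) == 0) stop("no DICOM files given", call. = FALSE)
  missing <- file_paths[!file.exists(file_paths)]
  if (length(missing)) {
    stop("DICOM file not found: ", missing[1], call. = FALSE)
  }
  slices <- lapply(file_paths, read_dicom_slice)
  r0 <- slices[[1]]
  for (s in slices) {
    if (s$rows != r0$rows || s$cols != r0$cols) {
      stop(sprintf("inconsistent in-plane dims in %s: %dx%d vs %dx%d in %s",
                   s$path, s$rows, s$cols, r0$rows, r0$cols, r0$path),
           call. = FALSE)
    }
    if (!is.null(s$pixel_spacing) && !is.null(r0$pixel_spacing) &&
        any(abs(s$pixel_spacing - r0$pixel_spacing) > 1e-9)) {
      stop("inconsistent pixel spacing in ", s$path, call. = FALSE)
    }
  }
  inst <- vapply(slices, function(s) s$instance %||% NA_integer_, integer(1))
  posz <- vapply(slices, function(s) if (is.null(s$position)) NA_real_ else s$position[3],
                 numeric(1))
  ord <- if (!anyNA(inst)) {
    order(inst)
  } else if (!anyNA(posz)) {
    order(posz)
  } else {
    order(vapply(slices, function(s) basename(s$path), character(1)))
  }
  slices <- slices[ord]
  if (!is.null(subset)) {
    subset <- as.integer(subset)
    if (length(subset) == 0) stop("empty slice subset", call. = FALSE)
    if (any(subset < 1) || any(subset > length(slices))) {
      stop("slice subset out of range 1..", length(slices), call. = FALSE)
    }
    slices <- slices[subset]
  }
  n <- length(slices)
  if (!is.null(spacing_override)) {
    spacing <- as.numeric(spacing_override)
  } else {
    ps <- slices[[1]]$pixel_spacing
    if (is.null(ps)) {
      stop("DICOM files lack PixelSpacing; supply spacing_override = c(sx, sy, sz)",
           call. = FALSE)
    }
    sz <- slices[[1]]$slice_spacing
    if (is.null(sz) && n > 1 && !anyNA(posz)) {
      zz <- sort(posz[ord])
      sz <- abs(zz[2] - zz[1])
    }
    if (is.null(sz) || !isTRUE(sz > 0)) {
      if (n == 1) sz <- 1 else {
        stop("cannot determine slice spacing; supply spacing_override",
             call. = FALSE)
      }
    }
    spacing <- c(ps[2], ps[1], sz)  # PixelSpacing is (row, col) = (sy, sx)
  }
  origin <- if (!is.null(slices[[1]]$position)) slices[[1]]$position else c(0, 0, 0)
  data <- array(0, dim = c(r0$cols, r0$rows, n))
  for (k in seq_len(n)) data[, , k] <- slices[[k]]$pixels
  new_volume(data, spacing = spacing, origin = origin)
}
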