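# Minimal DICOM reader: just enough of the little-endian encodings to recover
# the geometry tags the volume/fat pipeline needs (Pixel Spacing, Slice
# Thickness, rescale slope/intercept) plus the pixel data. Sequences and
# compressed transfer syntaxes are out of scope.

.dcm_uint16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
.dcm_uint32 <- function(raw, at) {
  sum(as.numeric(raw[at + 0:3]) * 256^(0:3))
}

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one explicit- or implicit-VR little-endian DICOM file into a tag list.
.dcm_parse <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 200 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  explicit <- TRUE
  in_meta <- TRUE
  tags <- list()
  want <- c(
    "0018,0050", "0028,0030", "0028,0010", "0028,0011", "0028,0100",
    "0028,0103", "0028,1052", "0028,1053", "0020,0013", "7fe0,0010",
    "0002,0010"
  )
  while (pos + 7L <= length(raw)) {
    group <- .dcm_uint16(raw, pos)
    elem <- .dcm_uint16(raw, pos + 2L)
    pos <- pos + 4L
    if (in_meta && group != 2L) {
      # file meta group ended; switch to the negotiated transfer syntax
      in_meta <- FALSE
      ts <- tags[["0002,0010"]]
      if (!is.null(ts)) {
        ts <- sub("\\s+$", "", rawToChar(ts))
        if (ts == "1.2.840.10008.1.2") {
          explicit <- FALSE
        } else if (ts != "1.2.840.10008.1.2.1") {
          stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
        }
      }
    }
    use_explicit <- in_meta || explicit
    if (use_explicit) {
      vr <- rawToChar(raw[pos + 0:1])
      if (vr %in% .dcm_long_vrs) {
        len <- .dcm_uint32(raw, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- .dcm_uint16(raw, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      len <- .dcm_uint32(raw, pos)
      pos <- pos + 4L
    }
    if (len == 4294967295) # undefined length (sequences): unsupported
      stop("unsupported DICOM element with undefined length in ", path, call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% want) tags[[key]] <- raw[pos + seq_len(len) - 1L]
    pos <- pos + len
  }
  tags
}

.dcm_str <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v))
}
.dcm_num <- function(tags, key) {
  s <- .dcm_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcm_us <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  .dcm_uint16(v, 1L)
}

# Decode one parsed file into (slice matrix in HU, geometry metadata).
.dcm_slice <- function(path) {
  tags <- .dcm_parse(path)
  rows <- .dcm_us(tags, "0028,0010")
  cols <- .dcm_us(tags, "0028,0011")
  ps <- .dcm_num(tags, "0028,0030")
  st <- .dcm_num(tags, "0018,0050")
  if (is.null(rows) || is.null(cols) || is.null(ps) || is.null(st))
    stop("DICOM file lacks Rows/Columns/Pixel Spacing/Slice Thickness: ", path,
         call. = FALSE)
  bits <- .dcm_us(tags, "0028,0100")
  if (!is.null(bits) && bits != 16L)
    stop("only 16-bit DICOM pixel data is supported", call. = FALSE)
  signed <- identical(.dcm_us(tags, "0028,0103"), 1L)
  slope <- .dcm_num(tags, "0028,1053")
  icept <- .dcm_num(tags, "0028,1052")
  inst <- .dcm_num(tags, "0020,0013")
  px <- tags[["7fe0,0010"]]
  if (is.null(px)) stop("DICOM file has no pixel data: ", path, call. = FALSE)
  v <- readBin(px, integer(), n = rows * cols, size = 2L,
               signed = signed, endian = "little")
  # DICOM pixel data is row-major: first row left-to-right, then next row
  img <- t(matrix(v, nrow = cols, ncol = rows))
  hu <- img * (if (is.null(slope)) 1 else slope[1]) +
    (if (is.null(icept)) 0 else icept[1])
  list(
    image = hu,
    slice_thickness = st[1],
    pixel_spacing = ps, # (row spacing, column spacing) mm
    instance = if (is.null(inst)) NA_real_ else inst[1]
  )
}

#' Read a DICOM series as a CT volume
#'
#' Reads every `.dcm` file in a directory (uncompressed little-endian
#' encodings only), applies the rescale slope/intercept so values are in
#' Hounsfield units, orders slices by Instance Number, and recovers the voxel
#' spacing from the Slice Thickness and Pixel Spacing tags.
#'
#' @param dir directory containing one DICOM series.
#' @param pattern file-name filter passed to [list.files()].
#' @return A [volume_image] in HU.
#' @export
read_dicom_series <- function(dir, pattern = "\\.dcm$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) stop("no DICOM files found in ", dir, call. = FALSE)
  slices <- lapply(files, .dcm_slice)
  inst <- vapply(slices, function(s) s$instance, numeric(1))
  if (!anyNA(inst)) slices <- slices[order(inst)]
  dims <- vapply(slices, function(s) dim(s$image), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions across the DICOM series", call. = FALSE)
  vox <- array(0, c(length(slices), dims[1, 1], dims[2, 1]))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$image
  s1 <- slices[[1]]
  volume_image(vox, spacing = c(s1$slice_thickness, s1$pixel_spacing[1],
                                s1$pixel_spacing[2]))
}

#' @rdname read_dicom_series
#' @return `read_dicom_spacing()` returns the length-3 spacing vector
#'   `(slice thickness, pixel height, pixel width)` in mm.
#' @export
read_dicom_spacing <- function(dir, pattern = "\\.dcm$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) stop("no DICOM files found in ", dir, call. = FALSE)
  s <- .dcm_slice(files[[1]])
  c(s$slice_thickness, s$pixel_spacing[1], s$pixel_spacing[2])
}
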