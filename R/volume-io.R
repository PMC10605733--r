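#' MRI sequence volume
#'
#' Container for one MRI sequence: a 3-D scalar grid plus the physical
#' geometry read from (or destined for) an image header.
#'
#' @section Coordinate convention:
#' This is the single place the package's indexing convention is defined.
#' Voxel data are stored as a 1-based R array indexed `[row, col, slice]`.
#' `spacing` and `origin` follow the MetaImage/NIfTI header order
#' `(x, y, z)` where x runs along columns, y along rows and z along
#' slices, all in millimetres.  The physical position of voxel
#' `[r, c, k]` is `origin + (c - 1, r - 1, k - 1) * spacing`.
#'
#' @param data numeric 3-D array `[row, col, slice]` of intensities.
#' @param spacing numeric length-3 voxel spacing `(dx, dy, dz)` in mm,
#'   all strictly positive.
#' @param origin numeric length-3 physical position `(x, y, z)` in mm of
#'   voxel `[1, 1, 1]`.
#' @param label sequence label, conventionally one of `"ADC"`, `"HBV"`,
#'   `"T2"` (or `"mask"` for masks).
#' @return An object of class `sequence_volume`.
#' @export
sequence_volume <- function(data, spacing, origin = c(0, 0, 0),
                            label = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [row, col, slice]")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (dx, dy, dz) in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (x, y, z) in mm")
  if (any(!is.finite(data)))
    stop("volume intensities must all be finite")
  structure(
    list(data = data, spacing = spacing, origin = origin,
         label = as.character(label)),
    class = "sequence_volume")
}

#' @export
print.sequence_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sequence_volume %s: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, origin (%.3g, %.3g, %.3g) mm>\n",
    x$label, d[1], d[2], d[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.sequence_volume <- function(x) dim(x$data)

#' Voxel volume in millilitres
#'
#' @param spacing length-3 voxel spacing in mm, or a `sequence_volume`.
#' @return Voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_mL <- function(spacing) {
  if (inherits(spacing, "sequence_volume")) spacing <- spacing$spacing
  prod(spacing) / 1000
}

## In-plane voxel area (mm^2); "resolution" comparisons use this.
in_plane_area <- function(vol) vol$spacing[1] * vol$spacing[2]

# ---------------------------------------------------------------------------
# MetaImage (.mha, local uncompressed payload)
# ---------------------------------------------------------------------------

.met_types <- data.frame(
  met = c("MET_UCHAR", "MET_CHAR", "MET_SHORT", "MET_USHORT",
          "MET_INT", "MET_UINT", "MET_FLOAT", "MET_DOUBLE"),
  what = c("integer", "integer", "integer", "integer",
           "integer", "integer", "double", "double"),
  size = c(1L, 1L, 2L, 2L, 4L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

#' Write a volume as MetaImage
#'
#' Writes an uncompressed single-file MetaImage (`ElementDataFile = LOCAL`)
#' with spacing and offset taken from the volume's geometry.
#'
#' @param vol a [sequence_volume()].
#' @param path output file path (conventionally `.mha`).
#' @param element_type on-disk scalar type; `MET_DOUBLE` (default) round
#'   trips exactly, `MET_UCHAR` suits binary masks.
#' @return `path`, invisibly.
#' @export
write_mha <- function(vol, path, element_type = "MET_DOUBLE") {
  stopifnot(inherits(vol, "sequence_volume"))
  ti <- match(element_type, .met_types$met)
  if (is.na(ti)) stop("unsupported MetaImage element type: ", element_type)
  d <- dim(vol$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(vol$origin, trim = TRUE), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    paste("ElementSpacing =",
          paste(format(vol$spacing, trim = TRUE), collapse = " ")),
    paste("DimSize =", d[2], d[1], d[3]),
    paste("ElementType =", element_type),
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  # header order is x-fastest: permute [row, col, slice] -> [col, row, slice]
  v <- as.vector(aperm(vol$data, c(2, 1, 3)))
  if (.met_types$what[ti] == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = .met_types$size[ti], endian = "little")
  invisible(path)
}

#' Read a MetaImage volume
#'
#' Supports 3-D, uncompressed, little-endian, single-file (`LOCAL`)
#' MetaImage, which is what [write_mha()] and the common medical-imaging
#' toolkits emit for scalar volumes.
#'
#' @param path file path.
#' @param label sequence label to attach.
#' @return A [sequence_volume()].
#' @export
read_mha <- function(path, label = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("not a valid MetaImage header (no ElementDataFile): ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    fields[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  need <- function(key) {
    if (is.null(fields[[key]]))
      stop("MetaImage header missing required field '", key, "': ", path)
    fields[[key]]
  }
  if (need("ElementDataFile") != "LOCAL")
    stop("only ElementDataFile = LOCAL MetaImage files are supported")
  if (!is.null(fields$CompressedData) &&
      tolower(fields$CompressedData) == "true")
    stop("compressed MetaImage payloads are not supported")
  if (!is.null(fields$BinaryDataByteOrderMSB) &&
      tolower(fields$BinaryDataByteOrderMSB) == "true")
    stop("big-endian MetaImage payloads are not supported")
  dimsize <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  if (length(dimsize) != 3L) stop("only 3-D MetaImage volumes are supported")
  spacing <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  origin <- if (is.null(fields$Offset)) c(0, 0, 0) else
    as.numeric(strsplit(fields$Offset, "\\s+")[[1]])
  ti <- match(need("ElementType"), .met_types$met)
  if (is.na(ti)) stop("unsupported ElementType: ", fields$ElementType)
  n <- prod(dimsize)
  v <- readBin(con, what = .met_types$what[ti], n = n,
               size = .met_types$size[ti], signed = .met_types$signed[ti],
               endian = "little")
  if (length(v) != n) stop("truncated MetaImage payload: ", path)
  a <- aperm(array(as.numeric(v), dim = dimsize), c(2, 1, 3))
  sequence_volume(a, spacing = spacing, origin = origin, label = label)
}

# ---------------------------------------------------------------------------
# NIfTI-1 (.nii, single-file uncompressed)
# ---------------------------------------------------------------------------

.nii_types <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L, 512L),
  what = c("integer", "integer", "integer", "double", "double", "integer"),
  size = c(1L, 2L, 4L, 4L, 8L, 2L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE)

#' Write a volume as NIfTI-1
#'
#' Emits a minimal single-file uncompressed `.nii` with identity rotation
#' (qform code 1, zero quaternion), spacing in `pixdim` and the origin in
#' the q-offset fields.
#'
#' @inheritParams write_mha
#' @param datatype NIfTI datatype code: 64 (float64, default, exact round
#'   trip), 16 (float32) or 2 (uint8 for masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = 64L) {
  stopifnot(inherits(vol, "sequence_volume"))
  ti <- match(as.integer(datatype), .nii_types$code)
  if (is.na(ti)) stop("unsupported NIfTI datatype code: ", datatype)
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wi32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  zero <- function(n) writeBin(raw(n), con)
  wi32(348L)                                   # sizeof_hdr
  zero(36L)                                    # data_type..dim_info
  wi16(c(3L, d[2], d[1], d[3], 1L, 1L, 1L, 1L)) # dim[8]
  wf32(c(0, 0, 0))                             # intent_p1..p3
  wi16(0L)                                     # intent_code
  wi16(.nii_types$code[ti])                    # datatype
  wi16(.nii_types$size[ti] * 8L)               # bitpix
  wi16(0L)                                     # slice_start
  wf32(c(1, vol$spacing, 0, 0, 0, 0))          # pixdim[8], qfac = 1
  wf32(352)                                    # vox_offset
  wf32(c(1, 0))                                # scl_slope, scl_inter
  wi16(0L)                                     # slice_end
  writeBin(as.raw(c(0L, 2L)), con)             # slice_code, xyzt_units = mm
  wf32(c(0, 0, 0, 0))                          # cal_max..toffset
  wi32(c(0L, 0L))                              # glmax, glmin
  zero(104L)                                   # descrip[80] + aux_file[24]
  wi16(c(1L, 0L))                              # qform_code = 1, sform_code = 0
  wf32(c(0, 0, 0))                             # quaternion b, c, d (identity)
  wf32(vol$origin)                             # qoffset x, y, z
  wf32(c(vol$spacing[1], 0, 0, vol$origin[1],  # srow (informational)
         0, vol$spacing[2], 0, vol$origin[2],
         0, 0, vol$spacing[3], vol$origin[3]))
  zero(16L)                                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  zero(4L)                                     # extension flag
  v <- as.vector(aperm(vol$data, c(2, 1, 3)))
  if (.nii_types$what[ti] == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = .nii_types$size[ti], endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file uncompressed little-endian `.nii` volumes with an
#' axis-aligned grid (zero/identity rotation); scaling slope/intercept are
#' applied when present.
#'
#' @inheritParams read_mha
#' @return A [sequence_volume()].
#' @export
read_nifti <- function(path, label = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path)
  ri16 <- function(off, n) readBin(hdr[(off + 1L):(off + 2L * n)], "integer",
                                   n = n, size = 2, endian = "little")
  ri32 <- function(off, n) readBin(hdr[(off + 1L):(off + 4L * n)], "integer",
                                   n = n, size = 4, endian = "little")
  rf32 <- function(off, n) readBin(hdr[(off + 1L):(off + 4L * n)], "double",
                                   n = n, size = 4, endian = "little")
  if (ri32(0L, 1L) != 348L)
    stop("not a little-endian NIfTI-1 file (sizeof_hdr != 348): ", path)
  dims <- ri16(40L, 8L)
  if (dims[1] < 3L || any(dims[5:8] > 1L))
    stop("only 3-D NIfTI volumes are supported: ", path)
  d <- dims[2:4]
  datatype <- ri16(70L, 1L)
  ti <- match(datatype, .nii_types$code)
  if (is.na(ti)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rf32(76L, 8L)
  spacing <- pixdim[2:4]
  if (any(spacing <= 0))
    stop("NIfTI header has non-positive pixdim spacing: ", path)
  vox_offset <- rf32(108L, 1L)
  scl <- rf32(112L, 2L)
  quat <- rf32(256L, 3L)
  if (any(abs(quat) > 1e-6))
    stop("rotated NIfTI grids are not supported (non-zero quaternion)")
  origin <- rf32(268L, 3L)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(d)
  v <- readBin(con, what = .nii_types$what[ti], n = n,
               size = .nii_types$size[ti], signed = .nii_types$signed[ti],
               endian = "little")
  if (length(v) != n) stop("truncated NIfTI payload: ", path)
  v <- as.numeric(v)
  if (is.finite(scl[1]) && scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    v <- v * scl[1] + scl[2]
  a <- aperm(array(v, dim = d), c(2, 1, 3))
  sequence_volume(a, spacing = spacing, origin = origin, label = label)
}

# ---------------------------------------------------------------------------
# Format-dispatching front ends
# ---------------------------------------------------------------------------

#' Read an MRI sequence volume
#'
#' Dispatches on the file extension: `.mha`/`.mhd` are read as MetaImage,
#' `.nii` as NIfTI-1.  Spacing and origin come from the header; voxel
#' intensities are returned unchanged.
#'
#' @param path path to a MetaImage or NIfTI file.
#' @param label sequence label (`"ADC"`, `"HBV"`, `"T2"`, ...).
#' @return A [sequence_volume()].
#' @export
read_sequence <- function(path, label = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mha = ,
         mhd = read_mha(path, label),
         nii = read_nifti(path, label),
         stop("unrecognized volume format '.", ext,
              "' (expected .mha or .nii): ", path))
}

#' Write an MRI sequence volume
#'
#' Counterpart of [read_sequence()]; the format follows the extension.
#'
#' @param vol a [sequence_volume()].
#' @param path output path ending in `.mha` or `.nii`.
#' @param mask logical; if `TRUE` write as unsigned bytes (binary masks).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(vol, path, mask = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mha = write_mha(vol, path,
                         element_type = if (mask) "MET_UCHAR" else "MET_DOUBLE"),
         nii = write_nifti(vol, path, datatype = if (mask) 2L else 64L),
         stop("unrecognized volume format '.", ext,
              "' (expected .mha or .nii): ", path))
}
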