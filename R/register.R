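#' @title Spatial registration of BP-MRI sequences
#' @description Helpers that bring the ADC, HBV and T2 sequences onto one
#'   common grid: resample to the coarsest in-plane resolution, translate
#'   by header offsets (plus an optional manual tweak), crop to the shared
#'   field of view and stitch slices into the 2-D mosaic the detection and
#'   blobbing stages operate on.
#' @name registration
NULL

## Bilinear in-plane resampling of one slice.  `xq`, `yq` are physical
## query coordinates; source voxel centres are origin + (i-1)*spacing.
resample_slice_bilinear <- function(sl, spacing, origin, xq, yq) {
  fx <- (xq - origin[1]) / spacing[1] + 1
  fy <- (yq - origin[2]) / spacing[2] + 1
  nx <- ncol(sl); ny <- nrow(sl)
  fx <- pmin(pmax(fx, 1), nx)
  fy <- pmin(pmax(fy, 1), ny)
  x0 <- pmin(floor(fx), nx - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(fy), ny - 1L); y1 <- y0 + 1
  if (nx == 1L) { x0 <- x1 <- rep(1L, length(fx)) }
  if (ny == 1L) { y0 <- y1 <- rep(1L, length(fy)) }
  wx <- fx - x0
  wy <- fy - y0
  WX <- outer(rep(1, length(fy)), wx)
  WY <- outer(wy, rep(1, length(fx)))
  sl[y0, x0, drop = FALSE] * (1 - WX) * (1 - WY) +
    sl[y0, x1, drop = FALSE] * WX * (1 - WY) +
    sl[y1, x0, drop = FALSE] * (1 - WX) * WY +
    sl[y1, x1, drop = FALSE] * WX * WY
}

## Nearest-neighbour variant for masks/labels.
resample_slice_nearest <- function(sl, spacing, origin, xq, yq) {
  ix <- round((xq - origin[1]) / spacing[1]) + 1
  iy <- round((yq - origin[2]) / spacing[2]) + 1
  ix <- pmin(pmax(ix, 1), ncol(sl))
  iy <- pmin(pmax(iy, 1), nrow(sl))
  sl[iy, ix, drop = FALSE]
}

## Pick the target sequence: largest in-plane voxel area; ties prefer ADC
## (the stated reference), then first in list order.
pick_reference <- function(sequences) {
  areas <- vapply(sequences, in_plane_area, numeric(1))
  best <- max(areas)
  cand <- which(abs(areas - best) < 1e-9)
  labels <- vapply(sequences[cand], function(v) v$label, character(1))
  if ("ADC" %in% labels) cand[match("ADC", labels)] else cand[1]
}

#' Resample sequences to the lowest in-plane resolution
#'
#' The target grid is the sequence with the largest in-plane voxel size
#' (ties broken in favour of ADC).  Every other sequence is resampled
#' in-plane onto a grid with the target's dimensions and spacing, within
#' its own physical frame; slice count and thickness must already agree
#' across sequences and are left untouched.  Intensities are interpolated
#' bilinearly, masks with nearest neighbour.
#'
#' @param sequences named list of [sequence_volume()]s (>= 2).
#' @param masks optional named list of mask volumes to carry along.
#' @return List with `sequences` (all on the common grid), `masks`,
#'   and `reference` (name of the target sequence).
#' @export
resample_to_lowest_resolution <- function(sequences, masks = NULL) {
  stopifnot(length(sequences) >= 2)
  nsl <- vapply(sequences, function(v) dim(v$data)[3], integer(1))
  if (length(unique(nsl)) != 1L)
    stop("inconsistent slice counts across sequences: ",
         paste(sprintf("%s=%d", names(sequences), nsl), collapse = ", "))
  ri <- pick_reference(sequences)
  ref <- sequences[[ri]]
  nx <- dim(ref$data)[2]; ny <- dim(ref$data)[1]

  resample_one <- function(vol, nearest = FALSE) {
    same <- all(dim(vol$data)[1:2] == c(ny, nx)) &&
      all(abs(vol$spacing[1:2] - ref$spacing[1:2]) < 1e-9)
    if (same) return(vol)
    # target voxel-centre offsets within the volume's own frame
    xq <- vol$origin[1] + (seq_len(nx) - 1) * ref$spacing[1]
    yq <- vol$origin[2] + (seq_len(ny) - 1) * ref$spacing[2]
    out <- array(0, dim = c(ny, nx, dim(vol$data)[3]))
    fn <- if (nearest) resample_slice_nearest else resample_slice_bilinear
    for (k in seq_len(dim(vol$data)[3]))
      out[, , k] <- fn(vol$data[, , k], vol$spacing, vol$origin, xq, yq)
    sequence_volume(out,
                    spacing = c(ref$spacing[1:2], vol$spacing[3]),
                    origin = vol$origin, label = vol$label)
  }

  list(sequences = lapply(sequences, resample_one),
       masks = if (is.null(masks)) NULL else
         lapply(masks, resample_one, nearest = TRUE),
       reference = names(sequences)[ri])
}

#' Translate a sequence onto a reference by header offsets
#'
#' Shifts `moving` in-plane by the voxel-rounded difference between its
#' header origin and the reference's, plus an optional manual
#' `extra_shift` (the stand-in for visual fine alignment).  Voxels
#' shifted in from outside the field are zero-filled; the valid index
#' range is recorded for [crop_to_common_fov()].  A non-integer computed
#' shift is rounded to the nearest voxel and the residual reported.
#'
#' @param moving,reference [sequence_volume()]s on the common grid.
#' @param extra_shift integer `(x, y)` voxel tweak, default `c(0, 0)`.
#' @return The aligned `moving` volume, with origin set to the
#'   reference's and a `valid` attribute giving the in-field index
#'   ranges.
#' @export
translate_align <- function(moving, reference, extra_shift = c(0L, 0L)) {
  stopifnot(inherits(moving, "sequence_volume"),
            inherits(reference, "sequence_volume"))
  if (any(abs(moving$spacing[1:2] - reference$spacing[1:2]) > 1e-9))
    stop("sequences must share the common grid before translation")
  off_vox <- (reference$origin[1:2] - moving$origin[1:2]) /
    moving$spacing[1:2]
  shift <- round(off_vox) + as.integer(round(extra_shift))
  resid <- off_vox - round(off_vox)
  if (any(abs(resid) > 1e-6))
    message(sprintf(
      "translate_align(%s): rounding header shift (%.4f, %.4f) voxels; residual (%.4f, %.4f)",
      moving$label, off_vox[1], off_vox[2], resid[1], resid[2]))
  d <- dim(moving$data)
  out <- shift_plane(moving$data, shift[2], shift[1])
  vol <- sequence_volume(out, spacing = moving$spacing,
                         origin = c(reference$origin[1:2], moving$origin[3]),
                         label = moving$label)
  attr(vol, "valid") <- list(
    rows = c(max(1L, 1L + shift[2]), min(d[1], d[1] + shift[2])),
    cols = c(max(1L, 1L + shift[1]), min(d[2], d[2] + shift[1])))
  vol
}

#' Crop sequences (and masks) to the common field of view
#'
#' Intersects the valid in-plane index ranges recorded by
#' [translate_align()] (full range when absent) and crops every sequence
#' and mask identically, preserving voxel correspondence.
#'
#' @param sequences named list of aligned [sequence_volume()]s.
#' @param masks optional named list of masks on the same grid.
#' @return List with cropped `sequences` and `masks`.
#' @export
crop_to_common_fov <- function(sequences, masks = NULL) {
  d <- dim(sequences[[1]]$data)
  rows <- c(1L, d[1]); cols <- c(1L, d[2])
  for (v in sequences) {
    if (any(dim(v$data) != d)) stop("sequences are not on one grid")
    val <- attr(v, "valid")
    if (!is.null(val)) {
      rows <- c(max(rows[1], val$rows[1]), min(rows[2], val$rows[2]))
      cols <- c(max(cols[1], val$cols[1]), min(cols[2], val$cols[2]))
    }
  }
  if (rows[1] > rows[2] || cols[1] > cols[2])
    stop("empty common field of view after alignment")
  crop <- function(v) {
    out <- sequence_volume(
      v$data[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE],
      spacing = v$spacing,
      origin = v$origin + c((cols[1] - 1) * v$spacing[1],
                            (rows[1] - 1) * v$spacing[2], 0),
      label = v$label)
    out
  }
  list(sequences = lapply(sequences, crop),
       masks = if (is.null(masks)) NULL else lapply(masks, crop))
}

#' Assemble the registered three-channel hypercube
#'
#' Runs the full registration chain — resample to the coarsest in-plane
#' grid, translate by header offsets (plus per-sequence extra shifts),
#' crop to the shared field of view — and stacks the ADC, HBV and T2
#' channels into one registered cube with its stitched mosaic view.
#'
#' @param adc,hbv,t2 [sequence_volume()]s of the three sequences.
#' @param masks optional named list of mask volumes on the reference
#'   sequence's grid (e.g. `normal_mask`, `tumor_mask`).
#' @param extra_shift named list of integer `(x, y)` manual tweaks per
#'   sequence label, default none.
#' @return A `hypercube` object; see [stitch()] for the mosaic fields.
#' @export
build_hypercube <- function(adc, hbv, t2, masks = NULL,
                            extra_shift = list()) {
  seqs <- list(ADC = adc, HBV = hbv, T2 = t2)
  res <- resample_to_lowest_resolution(seqs, masks)
  ref <- res$sequences[[res$reference]]
  aligned <- lapply(res$sequences, function(v) {
    es <- extra_shift[[v$label]]
    translate_align(v, ref, extra_shift = if (is.null(es)) c(0L, 0L) else es)
  })
  cropped <- crop_to_common_fov(aligned, res$masks)
  ch <- cropped$sequences
  d <- dim(ch$ADC$data)
  cube <- array(0, dim = c(d, 3L),
                dimnames = list(NULL, NULL, NULL, c("ADC", "HBV", "T2")))
  cube[, , , 1] <- ch$ADC$data
  cube[, , , 2] <- ch$HBV$data
  cube[, , , 3] <- ch$T2$data
  stitch(cube, spacing = c(ref$spacing[1:2], ch$ADC$spacing[3]),
         origin = ch$ADC$origin, masks = cropped$masks)
}

#' Stitch a registered cube into a hypercube mosaic
#'
#' Abuts slices horizontally: the mosaic has the cube's rows and
#' `slices * cols` columns per channel, with a per-column slice-index
#' map so downstream blobbing never bridges tile seams.  The mapping to
#' `(row, col, slice)` is exactly invertible via [unstitch()].
#'
#' @param cube 4-D array `[row, col, slice, channel]`.
#' @param spacing,origin common-grid geometry (mm).
#' @param masks optional named list of [sequence_volume()] masks on the
#'   same grid.
#' @return An object of class `hypercube` with fields `cube`, `mosaic`
#'   (`[row, slices*cols, channel]`), `slice_map` (slice index per
#'   mosaic column), `spacing`, `origin`, `voxel_volume_mL` and `masks`.
#' @export
stitch <- function(cube, spacing, origin = c(0, 0, 0), masks = NULL) {
  stopifnot(length(dim(cube)) == 4L)
  d <- dim(cube)
  # column-major reshape groups (col, slice): slice k fills mosaic
  # columns (k-1)*cols + 1 .. k*cols, i.e. slices abut horizontally
  mosaic <- array(cube, dim = c(d[1], d[2] * d[3], d[4]))
  slice_map <- rep(seq_len(d[3]), each = d[2])
  structure(
    list(cube = cube, mosaic = mosaic, slice_map = slice_map,
         spacing = as.numeric(spacing), origin = as.numeric(origin),
         voxel_volume_mL = voxel_volume_mL(spacing), masks = masks),
    class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf(
    "<hypercube: %d x %d x %d voxels x %d channels, mosaic %d x %d, voxel %.4g mL>\n",
    d[1], d[2], d[3], d[4], dim(x$mosaic)[1], dim(x$mosaic)[2],
    x$voxel_volume_mL))
  invisible(x)
}

#' Invert the mosaic back to the registered cube
#'
#' @param hc a `hypercube`.
#' @return The 4-D cube array; `unstitch(stitch(x)) == x`.
#' @export
unstitch <- function(hc) {
  stopifnot(inherits(hc, "hypercube"))
  array(hc$mosaic, dim = dim(hc$cube), dimnames = dimnames(hc$cube))
}

## Mosaic view of a 3-D scalar volume on the hypercube grid.
mosaic_of <- function(a3) {
  d <- dim(a3)
  array(a3, dim = c(d[1], d[2] * d[3]))
}

#' Extract the channel matrix of selected voxels
#'
#' @param hc a `hypercube`.
#' @param mask logical/numeric 3-D array on the cube grid; voxels where
#'   `mask > 0` are returned.
#' @return An `n x 3` matrix of (ADC, HBV, T2) vectors.
#' @export
hypercube_vectors <- function(hc, mask) {
  stopifnot(inherits(hc, "hypercube"))
  if (inherits(mask, "sequence_volume")) mask <- mask$data
  idx <- which(mask > 0)
  n <- prod(dim(hc$cube)[1:3])
  cbind(ADC = hc$cube[idx], HBV = hc$cube[idx + n], T2 = hc$cube[idx + 2 * n])
}

#' Write a color composite PNG of the stitched mosaic
#'
#' Assigns red, green and blue to the ADC, HBV and T2 channels after
#' robust (2nd-98th percentile) per-channel scaling.
#'
#' @param hc a `hypercube`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_composite_png <- function(hc, path) {
  stopifnot(inherits(hc, "hypercube"))
  scale01 <- function(m) {
    q <- stats::quantile(m, c(0.02, 0.98), names = FALSE)
    if (q[2] <= q[1]) q[2] <- q[1] + 1
    pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
  }
  r <- scale01(hc$mosaic[, , 1])
  g <- scale01(hc$mosaic[, , 2])
  b <- scale01(hc$mosaic[, , 3])
  img <- array(c(r, g, b), dim = c(dim(r), 3))
  grDevices::png(path, width = ncol(r), height = nrow(r))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
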