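#' Label 8-connected blobs on the stitched mosaic
#'
#' Groups above-threshold voxels into in-plane 8-connected components
#' ("blobs").  Connectivity is evaluated on the stitched mosaic but never
#' across tile seams: two mosaic columns only connect when the slice-index
#' map assigns them to the same slice, so a blob always lives in a single
#' slice tile.  Labels are assigned in raster order (first pixel reached
#' scanning rows top-to-bottom, left-to-right).
#'
#' @param mask a [threshold_map()] `binary_mask`, a logical 3-D array on
#'   the cube grid, or a logical mosaic matrix (then `slice_map` is
#'   required).
#' @param slice_map integer slice index per mosaic column (only when
#'   `mask` is a matrix).
#' @return A list of `blob` objects (possibly empty), each with fields
#'   `label`, `coords` (matrix with columns `row`, `col` = mosaic
#'   column, `slice`, `tile_col` = column within the slice tile) and
#'   `n_voxels`.  The integer label mosaic is attached as attribute
#'   `label_mosaic`.
#' @export
label_blobs <- function(mask, slice_map = NULL) {
  if (inherits(mask, "binary_mask")) mask <- mask$mask
  if (is.array(mask) && length(dim(mask)) == 3L) {
    d <- dim(mask)
    slice_map <- rep(seq_len(d[3]), each = d[2])
    mask <- array(mask, dim = c(d[1], d[2] * d[3]))
  }
  if (!is.matrix(mask)) stop("mask must be a matrix, 3-D array or binary_mask")
  if (is.null(slice_map) || length(slice_map) != ncol(mask))
    stop("slice_map must give one slice index per mosaic column")
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  # first pass, raster order; prior neighbours under 8-connectivity
  for (r in seq_len(nr)) {
    for (cc in which(mask[r, ])) {
      neigh <- integer(0)
      if (cc > 1L && slice_map[cc - 1L] == slice_map[cc]) {
        if (lab[r, cc - 1L]) neigh <- c(neigh, lab[r, cc - 1L])
        if (r > 1L && lab[r - 1L, cc - 1L])
          neigh <- c(neigh, lab[r - 1L, cc - 1L])
      }
      if (r > 1L) {
        if (lab[r - 1L, cc]) neigh <- c(neigh, lab[r - 1L, cc])
        if (cc < nc && slice_map[cc + 1L] == slice_map[cc] &&
            lab[r - 1L, cc + 1L])
          neigh <- c(neigh, lab[r - 1L, cc + 1L])
      }
      if (length(neigh) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[r, cc] <- nxt
      } else {
        roots <- unique(vapply(neigh, find, integer(1)))
        keep <- min(roots)
        for (rt in roots) parent[rt] <- keep
        lab[r, cc] <- keep
      }
    }
  }
  if (nxt == 0L) {
    out <- list()
    attr(out, "label_mosaic") <- lab
    return(out)
  }
  # second pass: resolve to roots, then relabel in raster order of the
  # component's first pixel
  idx <- which(t(mask))                     # raster (row-major) order
  rows <- (idx - 1L) %/% nc + 1L
  cols <- (idx - 1L) %% nc + 1L
  roots <- vapply(seq_along(idx), function(i) find(lab[rows[i], cols[i]]),
                  integer(1))
  final <- match(roots, unique(roots))      # unique() preserves first-seen order
  lab[] <- 0L
  lab[cbind(rows, cols)] <- final
  tile_w <- sum(slice_map == slice_map[1])
  blobs <- lapply(seq_len(max(final)), function(k) {
    sel <- final == k
    coords <- cbind(row = rows[sel], col = cols[sel],
                    slice = slice_map[cols[sel]],
                    tile_col = (cols[sel] - 1L) %% tile_w + 1L)
    structure(list(label = k, coords = coords, n_voxels = sum(sel)),
              class = "blob")
  })
  attr(blobs, "label_mosaic") <- lab
  blobs
}

#' Filter out undersized blobs
#'
#' Removes blobs with fewer than `min_voxels` member voxels (default 5,
#' about 0.01 mL at typical BP-MRI resolution); survivors are unchanged.
#'
#' @param blobs list of blobs from [label_blobs()].
#' @param min_voxels minimum voxel count a blob must reach to survive.
#' @return The filtered blob list (labels preserved).
#' @export
filter_blobs <- function(blobs, min_voxels = 5L) {
  out <- Filter(function(b) b$n_voxels >= min_voxels, blobs)
  attr(out, "label_mosaic") <- attr(blobs, "label_mosaic")
  out
}

#' Blob volume in millilitres
#'
#' @param blob a `blob`.
#' @param voxel_volume_mL volume of one voxel in mL (> 0).
#' @return `n_voxels * voxel_volume_mL`.
#' @export
blob_volume <- function(blob, voxel_volume_mL) {
  stopifnot(voxel_volume_mL > 0)
  blob$n_voxels * voxel_volume_mL
}

#' Blob inertia matrix and eigenvalues
#'
#' Second central moments of the in-plane member coordinates
#' (tile column, row): `I = [[var_x, cov_xy], [cov_xy, var_y]]` with
#' population (1/n) normalization.  Eigenvalues are returned sorted
#' `l >= s`; they are proportional to the squared semi-axis lengths of
#' the equivalent ellipse.
#'
#' @param blob a `blob`.
#' @return List with `I` (2x2), `l` and `s`.
#' @export
blob_inertia <- function(blob) {
  x <- blob$coords[, "tile_col"]
  y <- blob$coords[, "row"]
  dx <- x - mean(x); dy <- y - mean(y)
  I <- matrix(c(mean(dx * dx), mean(dx * dy),
                mean(dx * dy), mean(dy * dy)), 2, 2)
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  list(I = I, l = max(ev), s = min(ev))
}

#' Blob eccentricity from inertia eigenvalues
#'
#' The default is the normalized eigenvalue difference
#' `E = (l - s) / (l + s)`, ranging from 0 (round) to 1 (line); for a
#' dense ellipse with semi-axes `a >= b` it converges to
#' `(a^2 - b^2) / (a^2 + b^2)`.  The classical conic eccentricity
#' `sqrt(1 - s/l)` is available as an option.  Translation, rotation and
#' scale invariant.  A single-voxel blob (zero inertia) is defined to
#' have eccentricity 0.
#'
#' @param blob a `blob`.
#' @param method `"moment_ratio"` (default) or `"classical"`.
#' @return Eccentricity in `[0, 1]`.
#' @export
blob_eccentricity <- function(blob, method = c("moment_ratio", "classical")) {
  method <- match.arg(method)
  ei <- blob_inertia(blob)
  if (ei$l + ei$s <= 0) return(0)
  if (method == "moment_ratio") {
    (ei$l - ei$s) / (ei$l + ei$s)
  } else {
    sqrt(1 - ei$s / ei$l)
  }
}

#' Per-blob summary table
#'
#' @param blobs list of blobs.
#' @param voxel_volume_mL voxel volume in mL.
#' @return Data frame with one row per blob: `label`, `slice` (of the
#'   blob's tile), `n_voxels`, `volume_mL`, `l`, `s`, `eccentricity`.
#' @export
blob_table <- function(blobs, voxel_volume_mL) {
  if (length(blobs) == 0L)
    return(data.frame(label = integer(), slice = integer(),
                      n_voxels = integer(), volume_mL = numeric(),
                      l = numeric(), s = numeric(), eccentricity = numeric()))
  do.call(rbind, lapply(blobs, function(b) {
    ei <- blob_inertia(b)
    data.frame(label = b$label, slice = b$coords[1, "slice"],
               n_voxels = b$n_voxels,
               volume_mL = blob_volume(b, voxel_volume_mL),
               l = ei$l, s = ei$s,
               eccentricity = blob_eccentricity(b))
  }))
}

#' Morphology features of a blob list
#'
#' The three per-patient, per-threshold features the statistics stage
#' consumes: the largest blob's volume, the mean blob volume, and the
#' eccentricity of the largest (maximum-volume) blob.  Ties in volume go
#' to the lowest label, which makes the choice deterministic.  An empty
#' blob list yields all-zero features with `empty = TRUE`.
#'
#' @param blobs list of (already filtered) blobs.
#' @param voxel_volume_mL voxel volume in mL.
#' @return One-row data frame: `max_blob_volume`, `avg_blob_volume`,
#'   `max_blob_eccentricity`, `n_blobs`, `empty`.
#' @export
extract_features <- function(blobs, voxel_volume_mL) {
  if (length(blobs) == 0L)
    return(data.frame(max_blob_volume = 0, avg_blob_volume = 0,
                      max_blob_eccentricity = 0, n_blobs = 0L, empty = TRUE))
  vols <- vapply(blobs, blob_volume, numeric(1),
                 voxel_volume_mL = voxel_volume_mL)
  j <- which.max(vols)                      # first max = lowest label
  data.frame(max_blob_volume = vols[j],
             avg_blob_volume = mean(vols),
             max_blob_eccentricity = blob_eccentricity(blobs[[j]]),
             n_blobs = length(blobs), empty = FALSE)
}
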