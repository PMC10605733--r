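test_that("8-connectivity joins diagonals but not gaps", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- m[3, 3] <- TRUE                 # diagonal touch -> one blob
  blobs <- label_blobs(m, slice_map = rep(1L, 5))
  expect_length(blobs, 1L)
  expect_equal(blobs[[1]]$n_voxels, 2L)
  m2 <- matrix(FALSE, 5, 5)
  m2[2, 2] <- m2[2, 4] <- TRUE               # one-voxel gap -> two blobs
  expect_length(label_blobs(m2, slice_map = rep(1L, 5)), 2L)
})

test_that("labels never bridge stitched-tile seams", {
  # two tiles of width 3; voxels adjacent across the seam stay separate
  m <- matrix(FALSE, 4, 6)
  m[2, 3] <- TRUE; m[2, 4] <- TRUE
  blobs <- label_blobs(m, slice_map = rep(1:2, each = 3))
  expect_length(blobs, 2L)
  expect_equal(vapply(blobs, function(b) b$coords[1, "slice"], integer(1)),
               c(1L, 2L))
  # same mask on a single tile merges
  expect_length(label_blobs(m, slice_map = rep(1L, 6)), 1L)
})

test_that("labeling matches the BFS flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:40) {
    nr <- sample(5:16, 1); tiles <- sample(1:3, 1); w <- sample(4:9, 1)
    slice_map <- rep(seq_len(tiles), each = w)
    m <- matrix(runif(nr * tiles * w) < 0.4, nr, tiles * w)
    blobs <- label_blobs(m, slice_map)
    lab <- attr(blobs, "label_mosaic")
    expect_identical(lab, bfs_label_oracle(m, slice_map))
    expect_equal(sum(vapply(blobs, function(b) b$n_voxels, integer(1))),
                 sum(m))
  }
})

test_that("the size filter removes exactly the undersized components", {
  # constructed components of sizes 3, 5 and 12 in separate corners
  m <- matrix(FALSE, 12, 12)
  m[1, 1:3] <- TRUE                                  # 3 voxels
  m[4:5, 6:8] <- TRUE; m[4, 9] <- FALSE              # 6 -> make it 5
  m[5, 8] <- FALSE
  m[9:12, 1:3] <- TRUE                               # 12 voxels
  blobs <- label_blobs(m, slice_map = rep(1L, 12))
  sizes <- sort(vapply(blobs, function(b) b$n_voxels, integer(1)))
  expect_equal(sizes, c(3L, 5L, 12L))
  kept <- filter_blobs(blobs, min_voxels = 5L)
  expect_length(kept, 2L)
  expect_equal(sort(vapply(kept, function(b) b$n_voxels, integer(1))),
               c(5L, 12L))
  # 4 removed, 5 kept at the default threshold
  m4 <- matrix(FALSE, 4, 10)
  m4[1, 1:4] <- TRUE; m4[3, 6:10] <- TRUE
  kept4 <- filter_blobs(label_blobs(m4, rep(1L, 10)))
  expect_length(kept4, 1L)
  expect_equal(kept4[[1]]$n_voxels, 5L)
  # identity on lists with no undersized blobs
  expect_length(filter_blobs(kept), 2L)
})

test_that("blob volume is count times voxel volume", {
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE
  b <- label_blobs(m, rep(1L, 3))[[1]]
  expect_equal(blob_volume(b, voxel_volume_mL(c(2, 2, 3))), 0.012)
  expect_error(blob_volume(b, 0), "voxel_volume_mL > 0")
})

test_that("eccentricity closed forms: line 1, square/disk 0, 2:1 ellipse 0.6", {
  # straight line of N collinear voxels
  for (N in c(2L, 7L)) {
    m <- matrix(FALSE, 10, 10); m[4, seq_len(N)] <- TRUE
    b <- label_blobs(m, rep(1L, 10))[[1]]
    expect_equal(blob_eccentricity(b), 1)
  }
  # filled symmetric square
  m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
  expect_equal(blob_eccentricity(label_blobs(m, rep(1L, 9))[[1]]), 0,
               tolerance = 1e-12)
  # digital disk
  expect_lt(blob_eccentricity(ellipse_blob(8, 8)), 1e-12)
  # dense 2:1 ellipse converges to (4 - 1) / (4 + 1) = 0.6
  expect_equal(blob_eccentricity(ellipse_blob(40, 20)), 0.6,
               tolerance = 0.02)
  # single-voxel convention
  m1 <- matrix(FALSE, 3, 3); m1[2, 2] <- TRUE
  expect_equal(blob_eccentricity(label_blobs(m1, rep(1L, 3))[[1]]), 0)
})

test_that("eccentricity is invariant to rotation, reflection and scale", {
  b0 <- ellipse_blob(30, 12)
  e0 <- blob_eccentricity(b0)
  # axis-aligned 90-degree rotation and reflection are exact
  rot <- b0
  rot$coords[, c("row", "tile_col")] <- rot$coords[, c("tile_col", "row")]
  expect_equal(blob_eccentricity(rot), e0, tolerance = 1e-12)
  refl <- b0
  refl$coords[, "tile_col"] <- -refl$coords[, "tile_col"] + 100
  expect_equal(blob_eccentricity(refl), e0, tolerance = 1e-12)
  # arbitrary-angle re-rasterization moves E by < 0.02
  e37 <- blob_eccentricity(ellipse_blob(30, 12, theta = 37 * pi / 180))
  expect_lt(abs(e37 - e0), 0.02)
  # doubling the scale leaves the limit value (discretization aside)
  expect_lt(abs(blob_eccentricity(ellipse_blob(60, 24)) - e0), 0.01)
  # classical variant maps the same geometry to sqrt(1 - b^2/a^2)
  expect_equal(blob_eccentricity(ellipse_blob(40, 20), method = "classical"),
               sqrt(1 - 0.25), tolerance = 0.02)
})

test_that("inertia eigenvalues are ordered and match brute-force moments", {
  b <- ellipse_blob(20, 9, theta = 0.3)
  ei <- blob_inertia(b)
  expect_gte(ei$l, ei$s)
  x <- b$coords[, "tile_col"]; y <- b$coords[, "row"]
  I_brute <- matrix(c(mean((x - mean(x))^2), mean((x - mean(x)) * (y - mean(y))),
                      mean((x - mean(x)) * (y - mean(y))), mean((y - mean(y))^2)),
                    2, 2)
  expect_equal(ei$I, I_brute)
  expect_equal(sort(eigen(I_brute)$values), sort(c(ei$l, ei$s)))
})

test_that("feature extraction summarizes the blob list deterministically", {
  vox <- voxel_volume_mL(c(2, 2, 3))
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE                       # 9 voxels
  m[10:12, 10:18] <- TRUE                   # 27 voxels
  blobs <- label_blobs(m, rep(1L, 20))
  f <- extract_features(blobs, vox)
  expect_equal(f$max_blob_volume, 27 * vox)
  expect_equal(f$avg_blob_volume, (9 + 27) / 2 * vox)
  expect_equal(f$max_blob_eccentricity,
               blob_eccentricity(blobs[[which.max(
                 vapply(blobs, function(b) b$n_voxels, integer(1)))]]))
  expect_false(f$empty)
  # single blob: max = average
  f1 <- extract_features(blobs[1], vox)
  expect_equal(f1$max_blob_volume, f1$avg_blob_volume)
  # volume tie: the lowest label wins
  m2 <- matrix(FALSE, 10, 20)
  m2[2, 1:5] <- TRUE                        # label 1, a line (E = 1)
  m2[6:10, 10:10] <- TRUE                   # label 2, 5 voxels vertical line
  blobs2 <- label_blobs(m2, rep(1L, 20))
  f2 <- extract_features(blobs2, vox)
  expect_equal(f2$max_blob_eccentricity, blob_eccentricity(blobs2[[1]]))
  # empty input yields zero features and the flag
  fe <- extract_features(list(), vox)
  expect_true(fe$empty)
  expect_equal(fe$max_blob_volume, 0)
  expect_equal(fe$n_blobs, 0L)
})

test_that("rasterized phantom disk volume approaches the analytic value", {
  # digital disk of radius r voxels: area within 15% of pi r^2 for r >= 3
  for (r in c(3, 5, 9)) {
    b <- ellipse_blob(r, r)
    expect_lt(abs(b$n_voxels - pi * r^2) / (pi * r^2), 0.15)
  }
})
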