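# Independent oracles and shared fixtures.  Each oracle is deliberately a
# different algorithm from the implementation it checks.

# ACE oracle: explicitly whiten with the Cholesky factor, then take the
# squared cosine of the whitened, centered vectors.
ace_oracle <- function(x, m, cm, s) {
  U <- chol(cm)                       # cm = t(U) %*% U
  whiten <- function(v) forwardsolve(t(U), v)
  tw <- whiten(s - m)
  apply(as.matrix(x), 1, function(xi) {
    dw <- whiten(xi - m)
    nd <- sqrt(sum(dw^2))
    if (nd == 0) return(0)
    (sum(dw * tw) / (nd * sqrt(sum(tw^2))))^2
  })
}

# Random symmetric positive definite matrix.
random_spd <- function(p) {
  a <- matrix(rnorm(p * p), p, p)
  crossprod(a) + diag(p) * 0.1
}

# Blob-labeling oracle: BFS flood fill, 8-connected, never crossing
# slice-map seams.  Returns an integer label matrix with labels in
# raster order of each component's first pixel.
bfs_label_oracle <- function(mask, slice_map) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[r, cc] || lab[r, cc] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, cc))
    lab[r, cc] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- p[1] + dr; c2 <- p[2] + dc
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        if (slice_map[c2] != slice_map[p[2]]) next
        if (mask[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- nxt
          queue[[length(queue) + 1]] <- c(rr, c2)
        }
      }
    }
  }
  lab
}

# AUC oracle: exhaustive positive/negative pair counting, ties worth 1/2.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Small, fast phantom fixtures ------------------------------------------------

test_phantom_spec <- function(tumors = NULL, seed = 7L, tumor_sd = 40,
                              t2_offset_vox = c(0L, 0L),
                              t2_mm = 0.5, ...) {
  phantom_spec(fov_mm = c(64, 64), n_slices = 6L, slice_mm = 3,
               spacing = list(ADC = c(2, 2), HBV = c(2, 2),
                              T2 = c(t2_mm, t2_mm)),
               prostate_center = c(32, 32, 9),
               prostate_semiaxes = c(22, 18, 9),
               tumors = tumors, tumor_sd = tumor_sd,
               t2_offset_vox = t2_offset_vox, seed = seed, ...)
}

one_tumor <- function(cx = 34, cy = 30, a = 7, b = 4, theta = 0.4,
                      slice_first = 3L, slice_count = 1L) {
  data.frame(cx = cx, cy = cy, a = a, b = b, theta = theta,
             slice_first = slice_first, slice_count = slice_count)
}

# Cohort base spec used by statistics-layer tests; T2 at 1 mm keeps the
# many-patient runs fast while staying finer than the 2 mm reference.
test_cohort_base <- function(seed = 0L) test_phantom_spec(seed = seed, t2_mm = 1)

# Dense digital ellipse blob (single tile) for eccentricity checks.
ellipse_blob <- function(a, b, theta = 0, n = NULL) {
  lim <- ceiling(max(a, b)) + 2
  xs <- seq(-lim, lim)
  grid <- expand.grid(x = xs, y = xs)
  u <- grid$x * cos(theta) + grid$y * sin(theta)
  v <- -grid$x * sin(theta) + grid$y * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  coords <- cbind(row = grid$y[keep] + lim + 1, col = grid$x[keep] + lim + 1,
                  slice = 1L, tile_col = grid$x[keep] + lim + 1)
  structure(list(label = 1L, coords = coords, n_voxels = sum(keep)),
            class = "blob")
}

mask_from_coords <- function(nr, nc, coords) {
  m <- matrix(FALSE, nr, nc)
  m[coords] <- TRUE
  m
}
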