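#' Background second-order statistics
#'
#' Sample mean and sample covariance (denominator `n - 1`) of the
#' three-channel vectors under the normal-prostate mask; these whiten the
#' scene for the Adaptive Cosine Estimator.  No covariance regularization
#' or principal-component removal is applied: a singular covariance is an
#' error asking for more mask voxels.
#'
#' @param hc a `hypercube`.
#' @param mask normal-prostate mask ([sequence_volume()] or array) on
#'   the hypercube grid.
#' @param min_voxels minimum mask size accepted (default 30).
#' @return An object of class `background_stats` with fields `m` (mean
#'   vector), `cm` (3x3 covariance) and `n` (voxel count).
#' @export
compute_background_stats <- function(hc, mask, min_voxels = 30L) {
  x <- hypercube_vectors(hc, mask)
  if (nrow(x) == 0L) stop("normal-prostate mask selects no voxels")
  if (nrow(x) < min_voxels)
    stop("only ", nrow(x), " background voxels; at least ", min_voxels,
         " are required for a stable covariance")
  m <- colMeans(x)
  cm <- stats::cov(x)
  ok <- tryCatch({ chol(cm); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("background covariance is singular; enlarge the normal-prostate ",
         "mask (regularization is deliberately not applied)")
  structure(list(m = m, cm = cm, n = nrow(x)), class = "background_stats")
}

#' Derive an in-scene tumor signature
#'
#' The signature is the mean three-channel vector over a seed region of
#' the hypercube (typically a few voxels inside a suspected lesion).
#'
#' @param hc a `hypercube`.
#' @param seed_region mask (volume or array) on the hypercube grid, or an
#'   `n x 3` matrix of `(row, col, slice)` voxel indices.
#' @param stats optional [compute_background_stats()] result; when given,
#'   a signature indistinguishable from the background mean is rejected.
#' @param tol relative tolerance for the degeneracy check.
#' @return An object of class `ace_signature` with fields `s` and
#'   `provenance`.
#' @export
derive_signature <- function(hc, seed_region, stats = NULL, tol = 1e-8) {
  if (is.matrix(seed_region) && ncol(seed_region) == 3L &&
      !inherits(seed_region, "sequence_volume")) {
    d <- dim(hc$cube)[1:3]
    mask <- array(FALSE, dim = d)
    mask[seed_region] <- TRUE
    prov <- sprintf("%d seed voxels (index list)", nrow(seed_region))
  } else {
    mask <- if (inherits(seed_region, "sequence_volume")) seed_region$data
            else seed_region
    prov <- sprintf("%d seed voxels (mask)", sum(mask > 0))
  }
  x <- hypercube_vectors(hc, mask)
  if (nrow(x) == 0L) stop("signature seed region is empty")
  s <- colMeans(x)
  if (!is.null(stats)) check_signature(s, stats, tol)
  structure(list(s = s, provenance = prov), class = "ace_signature")
}

check_signature <- function(s, stats, tol = 1e-8) {
  scale <- max(1, sqrt(sum(stats$m^2)))
  if (sqrt(sum((s - stats$m)^2)) <= tol * scale)
    stop("degenerate signature: S coincides with the background mean")
  invisible(TRUE)
}

#' Adaptive Cosine Estimator detection map
#'
#' Scores every voxel of the hypercube against an in-scene signature.
#' With `d = x - m`, `t = S - m` and background covariance `CM`, the
#' squared form is
#' \deqn{ACE(x) = \frac{(t^\top CM^{-1} d)^2}
#'                     {(t^\top CM^{-1} t)\,(d^\top CM^{-1} d)}}
#' the squared cosine between the whitened test vector and whitened
#' signature, in `[0, 1]`; its decision surface is a cone around the
#' signature.  The signed form returns the cosine itself in `[-1, 1]`.
#' A voxel equal to the background mean (`d = 0`) scores 0 by the limit
#' convention.  Scores are invariant to positive scaling of `d` and `t`
#' and to any invertible affine recoloring applied consistently to the
#' scene, mean, covariance and signature.
#'
#' @param hc a `hypercube`.
#' @param stats a [compute_background_stats()] result.
#' @param signature an [derive_signature()] result (or length-3 vector).
#' @param form `"squared"` (default) or `"signed"`.
#' @return An object of class `detection_map`: list with `scores` (3-D
#'   array on the cube grid), `form`, `signature`, `stats`.
#' @export
ace_score <- function(hc, stats, signature, form = c("squared", "signed")) {
  form <- match.arg(form)
  stopifnot(inherits(hc, "hypercube"), inherits(stats, "background_stats"))
  s <- if (inherits(signature, "ace_signature")) signature$s
       else as.numeric(signature)
  check_signature(s, stats)
  d3 <- dim(hc$cube)[1:3]
  x <- matrix(hc$cube, ncol = 3L)           # all voxels, channels as columns
  scores <- ace_statistic(x, stats$m, stats$cm, s, form)
  structure(list(scores = array(scores, dim = d3), form = form,
                 signature = s, stats = stats),
            class = "detection_map")
}

#' ACE statistic on raw vectors
#'
#' Vectorized workhorse behind [ace_score()], exposed for direct use on
#' `n x p` matrices (any dimension `p`).
#'
#' @param x `n x p` matrix of test vectors.
#' @param m background mean (length p).
#' @param cm background covariance (`p x p`, positive definite).
#' @param s signature vector (length p).
#' @param form `"squared"` or `"signed"`.
#' @return Numeric vector of n scores.
#' @export
ace_statistic <- function(x, m, cm, s, form = c("squared", "signed")) {
  form <- match.arg(form)
  x <- as.matrix(x)
  ci <- chol2inv(chol(cm))
  t_ <- as.numeric(s) - as.numeric(m)
  d <- sweep(x, 2, as.numeric(m))
  dci <- d %*% ci
  num <- as.numeric(dci %*% t_)
  dd <- rowSums(dci * d)
  tt <- as.numeric(t_ %*% ci %*% t_)
  out <- numeric(nrow(x))
  nz <- dd > 0
  if (form == "squared") {
    out[nz] <- pmin(pmax(num[nz]^2 / (tt * dd[nz]), 0), 1)
  } else {
    out[nz] <- pmin(pmax(num[nz] / sqrt(tt * dd[nz]), -1), 1)
  }
  out
}

#' Threshold a detection map into a binary tumor mask
#'
#' Voxels with score strictly above the threshold are tumor candidates;
#' an optional scene mask (e.g. the prostate extent) excludes everything
#' else.  Masks are nested: a higher threshold always yields a subset.
#'
#' @param map a `detection_map`.
#' @param threshold scalar in `[0, 1]`.
#' @param scene_mask optional mask (volume or array) on the same grid.
#' @return An object of class `binary_mask`: list with logical 3-D
#'   `mask` and the `threshold`.
#' @export
threshold_map <- function(map, threshold, scene_mask = NULL) {
  stopifnot(inherits(map, "detection_map"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single number in [0, 1]")
  keep <- map$scores > threshold
  if (!is.null(scene_mask)) {
    if (inherits(scene_mask, "sequence_volume")) scene_mask <- scene_mask$data
    keep <- keep & (scene_mask > 0)
  }
  structure(list(mask = keep, threshold = threshold), class = "binary_mask")
}
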