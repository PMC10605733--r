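hc_from_matrix <- function(x) {
  # wrap an n x 3 matrix as a 1-row hypercube for API-level calls
  n <- nrow(x)
  cube <- array(0, dim = c(1, n, 1, 3))
  for (ch in 1:3) cube[1, , 1, ch] <- x[, ch]
  stitch(cube, spacing = c(2, 2, 3))
}

test_that("background stats are the sample mean and n-1 covariance", {
  set.seed(1)
  x <- matrix(rnorm(300), 100, 3)
  hc <- hc_from_matrix(x)
  mask <- array(TRUE, dim = c(1, 100, 1))
  st <- compute_background_stats(hc, mask)
  expect_equal(st$m, c(ADC = mean(x[, 1]), HBV = mean(x[, 2]),
                       T2 = mean(x[, 3])))
  expect_equal(unname(st$cm), unname(cov(x)))
  expect_equal(st$n, 100L)
  # order invariance
  perm <- sample(100)
  st2 <- compute_background_stats(hc_from_matrix(x[perm, ]), mask)
  expect_equal(st2$m, st$m)
  expect_equal(st2$cm, st$cm)
})

test_that("degenerate masks and singular covariances are rejected", {
  x <- matrix(rep(c(1, 2, 3), each = 50), 50, 3)
  hc <- hc_from_matrix(x)
  mask <- array(TRUE, dim = c(1, 50, 1))
  expect_error(compute_background_stats(hc, mask), "singular")
  expect_error(compute_background_stats(hc, array(FALSE, c(1, 50, 1))),
               "no voxels")
  expect_error(compute_background_stats(hc, mask, min_voxels = 60),
               "at least 60")
})

test_that("covariance estimate converges on synthetic background", {
  spec <- test_phantom_spec(seed = 33)
  ph <- generate_phantom(spec)
  hc <- build_hypercube(ph$volumes$ADC, ph$volumes$HBV, ph$volumes$T2,
                        masks = list(normal = ph$normal_mask))
  st <- compute_background_stats(hc, hc$masks$normal)
  rel <- norm(st$cm - spec$sigma_bg, "F") / norm(spec$sigma_bg, "F")
  expect_lt(rel, 5 * sqrt(2 / st$n))
  expect_lt(max(abs(st$m - spec$m_bg) /
                  (sqrt(diag(spec$sigma_bg)) / sqrt(st$n))), 4)
})

test_that("signature derivation follows the seed region mean", {
  ph <- generate_phantom(test_phantom_spec(tumors = one_tumor(),
                                           tumor_sd = 0))
  hc <- build_hypercube(ph$volumes$ADC, ph$volumes$HBV, ph$volumes$T2,
                        masks = list(tumor = ph$tumor_mask))
  # noiseless tumor: signature equals the generator tumor mean exactly
  sig <- derive_signature(hc, hc$masks$tumor)
  expect_equal(unname(sig$s), c(650, 420, 180))
  # single-voxel seed equals that voxel's vector
  idx <- which(hc$masks$tumor$data > 0, arr.ind = TRUE)[1, , drop = FALSE]
  sig1 <- derive_signature(hc, unname(idx))
  expect_equal(unname(sig1$s),
               unname(c(hc$cube[idx[1], idx[2], idx[3], 1],
                        hc$cube[idx[1], idx[2], idx[3], 2],
                        hc$cube[idx[1], idx[2], idx[3], 3])))
  expect_error(derive_signature(hc, array(FALSE, dim(hc$cube)[1:3])),
               "empty")
})

test_that("noisy seed signature is within the CLT bound of m_tum", {
  spec <- test_phantom_spec(tumors = one_tumor(a = 9, b = 7,
                                               slice_count = 3L),
                            tumor_sd = 30, seed = 17)
  ph <- generate_phantom(spec)
  hc <- build_hypercube(ph$volumes$ADC, ph$volumes$HBV, ph$volumes$T2,
                        masks = list(tumor = ph$tumor_mask))
  sig <- derive_signature(hc, hc$masks$tumor)
  n <- sum(hc$masks$tumor$data > 0)
  expect_true(all(abs(sig$s - spec$m_tum) < 3 * 30 / sqrt(n) + 1e-9))
})

test_that("ACE trivial geometry: collinear 1, orthogonal 0, 45 degrees 0.5", {
  m <- c(0, 0, 0); cm <- diag(3); s <- c(1, 0, 0)
  expect_equal(ace_statistic(rbind(c(2, 0, 0), c(0.3, 0, 0)), m, cm, s),
               c(1, 1))
  expect_equal(ace_statistic(rbind(c(0, 1, 0), c(0, 0, 5)), m, cm, s),
               c(0, 0))
  expect_equal(ace_statistic(rbind(c(1, 1, 0)), m, cm, s), 0.5)
  # background-mean voxel scores 0 by convention
  expect_equal(ace_statistic(rbind(m), m, cm, s), 0)
})

test_that("ACE agrees with the whiten-then-cosine oracle", {
  set.seed(99)
  for (rep in 1:25) {
    cm <- random_spd(3)
    m <- rnorm(3)
    s <- m + rnorm(3)
    x <- matrix(rnorm(60, sd = 2), 20, 3)
    expect_equal(ace_statistic(x, m, cm, s), ace_oracle(x, m, cm, s),
                 tolerance = 1e-10)
  }
})

test_that("ACE is invariant to scaling and affine recoloring", {
  set.seed(5)
  cm <- random_spd(3); m <- rnorm(3); s <- m + rnorm(3)
  x <- matrix(rnorm(30), 10, 3)
  base <- ace_statistic(x, m, cm, s)
  # positive scaling of d and t
  x_scaled <- sweep(sweep(x, 2, m), 1, runif(10, 0.1, 5), `*`)
  x_scaled <- sweep(x_scaled, 2, m, `+`)
  expect_equal(ace_statistic(x_scaled, m, cm, s), base, tolerance = 1e-9)
  s_scaled <- m + 3.7 * (s - m)
  expect_equal(ace_statistic(x, m, cm, s_scaled), base, tolerance = 1e-9)
  # invertible affine recoloring applied consistently (CFAR invariance)
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  b <- rnorm(3)
  xt <- sweep(x %*% t(A), 2, b, `+`)
  expect_equal(
    ace_statistic(xt, as.numeric(A %*% m + b), A %*% cm %*% t(A),
                  as.numeric(A %*% s + b)),
    base, tolerance = 1e-8)
})

test_that("signed form is the cosine and squares to the squared form", {
  set.seed(7)
  cm <- random_spd(3); m <- rnorm(3); s <- m + rnorm(3)
  x <- matrix(rnorm(45), 15, 3)
  sq <- ace_statistic(x, m, cm, s, form = "squared")
  sg <- ace_statistic(x, m, cm, s, form = "signed")
  expect_equal(sg^2, sq, tolerance = 1e-12)
  expect_true(all(sg >= -1 & sg <= 1))
})

test_that("noiseless phantom tumor voxels all score 1", {
  ph <- generate_phantom(test_phantom_spec(tumors = one_tumor(),
                                           tumor_sd = 0))
  hc <- build_hypercube(ph$volumes$ADC, ph$volumes$HBV, ph$volumes$T2,
                        masks = list(normal = ph$normal_mask,
                                     tumor = ph$tumor_mask))
  st <- compute_background_stats(hc, hc$masks$normal)
  dmap <- ace_score(hc, st, derive_signature(hc, hc$masks$tumor))
  expect_true(all(dmap$scores >= 0 & dmap$scores <= 1))
  expect_equal(unname(dmap$scores[hc$masks$tumor$data > 0]),
               rep(1, sum(hc$masks$tumor$data > 0)))
})

test_that("thresholded masks are nested and respect the scene", {
  ph <- generate_phantom(test_phantom_spec(tumors = one_tumor(), seed = 3))
  res <- run_patient(ph, run_config(thresholds = c(0.5, 0.9)))
  m_lo <- threshold_map(res$detection, 0.90)
  m_hi <- threshold_map(res$detection, 0.94)
  expect_true(all(m_lo$mask[m_hi$mask]))           # mask(0.94) subset of mask(0.90)
  m_all <- threshold_map(res$detection, 0)
  expect_equal(sum(m_all$mask), sum(res$detection$scores > 0))
  m_one <- threshold_map(res$detection, 1)
  expect_equal(sum(m_one$mask), 0L)                # nothing exceeds 1 strictly
  scoped <- threshold_map(res$detection, 0.5,
                          scene_mask = res$hypercube$masks$prostate)
  expect_true(all(res$hypercube$masks$prostate$data[scoped$mask] > 0))
  expect_error(threshold_map(res$detection, 1.5), "\\[0, 1\\]")
})

test_that("background false-alarm fraction decreases with the threshold", {
  ph <- generate_phantom(test_phantom_spec(seed = 19))
  hc <- build_hypercube(ph$volumes$ADC, ph$volumes$HBV, ph$volumes$T2,
                        masks = list(normal = ph$normal_mask))
  st <- compute_background_stats(hc, hc$masks$normal)
  dmap <- ace_score(hc, st, c(650, 420, 180))
  bg <- dmap$scores[hc$masks$normal$data > 0]
  fr <- vapply(c(0.5, 0.7, 0.9, 0.96), function(t) mean(bg > t), numeric(1))
  expect_true(all(diff(fr) < 0))
  expect_lt(fr[3], 0.15)  # scores concentrate away from 1 on pure background
})
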