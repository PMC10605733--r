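#' Phantom study specification
#'
#' Describes a synthetic bi-parametric MRI study: three co-localized
#' sequences (ADC, HBV, T2) on grids of different in-plane resolution
#' sharing one slice stack, a prostate ellipsoid filled with correlated
#' multivariate-Gaussian background, and elliptical-cylinder tumors with
#' known geometry.  Default channel means give the tumor the
#' characteristic contrast sign pattern (low ADC, high HBV, low T2);
#' magnitudes are configuration, not physiology.
#'
#' Tumors are elliptical cylinders: an in-plane ellipse with semi-axes
#' `a >= b` (mm) rotated by `theta`, extruded over `slice_count`
#' contiguous slices.  Their true volume is `pi * a * b * h` with
#' `h = slice_count * slice_mm`, and their true in-plane eccentricity is
#' `(a^2 - b^2) / (a^2 + b^2)`.
#'
#' @param fov_mm in-plane physical field of view `(x, y)` in mm.
#' @param n_slices number of axial slices (shared by all sequences).
#' @param slice_mm slice thickness in mm (shared by all sequences).
#' @param spacing named list of in-plane spacings `(dx, dy)` in mm for
#'   `ADC`, `HBV` and `T2`; T2 is conventionally the finest.
#' @param prostate_center ellipsoid centre `(x, y, z)` in mm; default is
#'   the middle of the field of view.
#' @param prostate_semiaxes ellipsoid semi-axes `(x, y, z)` in mm.
#' @param m_bg length-3 mean intensity of normal prostate per channel
#'   `(ADC, HBV, T2)`.
#' @param sigma_bg 3x3 symmetric positive-definite channel covariance of
#'   the normal-prostate background.
#' @param tumors data frame with one row per tumor and columns `cx`,
#'   `cy` (centre, mm), `a`, `b` (in-plane semi-axes, mm, `a >= b > 0`),
#'   `theta` (radians), `slice_first`, `slice_count` (1-based slice
#'   extent).  Use `NULL` for a tumor-free phantom.
#' @param m_tum length-3 mean tumor intensity per channel.
#' @param tumor_sd isotropic tumor noise standard deviation.
#' @param exterior_sd noise level of the near-zero exterior.
#' @param t2_offset_vox integer T2 acquisition offset `(x, y)` in T2
#'   voxels; the voxel content is shifted and the compensating offset is
#'   recorded in the T2 header, as in real acquisitions.
#' @param seed RNG seed fixing all randomness of the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(fov_mm = c(96, 96),
                         n_slices = 8L,
                         slice_mm = 3,
                         spacing = list(ADC = c(2, 2), HBV = c(2, 2),
                                        T2 = c(0.5, 0.5)),
                         prostate_center = NULL,
                         prostate_semiaxes = c(28, 24, 11),
                         m_bg = c(1200, 150, 400),
                         sigma_bg = default_sigma_bg(),
                         tumors = NULL,
                         m_tum = c(650, 420, 180),
                         tumor_sd = 40,
                         exterior_sd = 5,
                         t2_offset_vox = c(0L, 0L),
                         seed = 1L) {
  if (is.null(prostate_center))
    prostate_center <- c(fov_mm / 2, n_slices * slice_mm / 2)
  if (is.null(tumors))
    tumors <- data.frame(cx = numeric(), cy = numeric(), a = numeric(),
                         b = numeric(), theta = numeric(),
                         slice_first = integer(), slice_count = integer())
  tumors <- as.data.frame(tumors)
  spec <- structure(
    list(fov_mm = as.numeric(fov_mm), n_slices = as.integer(n_slices),
         slice_mm = as.numeric(slice_mm), spacing = spacing,
         prostate_center = as.numeric(prostate_center),
         prostate_semiaxes = as.numeric(prostate_semiaxes),
         m_bg = as.numeric(m_bg), sigma_bg = as.matrix(sigma_bg),
         tumors = tumors, m_tum = as.numeric(m_tum),
         tumor_sd = as.numeric(tumor_sd),
         exterior_sd = as.numeric(exterior_sd),
         t2_offset_vox = as.integer(round(t2_offset_vox)),
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Default background channel covariance
#'
#' Channel standard deviations (120, 30, 60) for (ADC, HBV, T2) with mild
#' cross-channel correlation, a plausibly structured but illustrative
#' second-order model of normal prostate.
#'
#' @return A 3x3 symmetric positive-definite matrix.
#' @export
default_sigma_bg <- function() {
  sd <- c(120, 30, 60)
  corr <- matrix(c(1, -0.3, 0.4,
                   -0.3, 1, -0.2,
                   0.4, -0.2, 1), 3, 3)
  diag(sd) %*% corr %*% diag(sd)
}

validate_phantom_spec <- function(spec) {
  s <- spec$sigma_bg
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-8)))
    stop("sigma_bg must be symmetric")
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("sigma_bg must be positive definite")
  tu <- spec$tumors
  need <- c("cx", "cy", "a", "b", "theta", "slice_first", "slice_count")
  if (!all(need %in% names(tu)))
    stop("tumors data frame needs columns: ", paste(need, collapse = ", "))
  if (nrow(tu) > 0) {
    if (any(tu$b <= 0) || any(tu$a < tu$b))
      stop("tumor semi-axes must satisfy a >= b > 0")
    if (any(tu$slice_first < 1) ||
        any(tu$slice_first + tu$slice_count - 1 > spec$n_slices))
      stop("tumor slice extent outside the volume")
    # analytic containment: extreme points of each tumor must lie inside
    # the prostate ellipsoid at both end slices
    for (i in seq_len(nrow(tu))) {
      th <- seq(0, 2 * pi, length.out = 33)[-33]
      ex <- tu$cx[i] + tu$a[i] * cos(th) * cos(tu$theta[i]) -
        tu$b[i] * sin(th) * sin(tu$theta[i])
      ey <- tu$cy[i] + tu$a[i] * cos(th) * sin(tu$theta[i]) +
        tu$b[i] * sin(th) * cos(tu$theta[i])
      zc <- (c(tu$slice_first[i], tu$slice_first[i] + tu$slice_count[i] - 1) -
               0.5) * spec$slice_mm
      pc <- spec$prostate_center
      ps <- spec$prostate_semiaxes
      r2 <- outer(((ex - pc[1]) / ps[1])^2 + ((ey - pc[2]) / ps[2])^2,
                  ((zc - pc[3]) / ps[3])^2, `+`)
      if (any(r2 > 1))
        stop("tumor ", i, " extends outside the prostate ellipsoid")
    }
  }
  invisible(spec)
}

## Grid of voxel-centre coordinates for one sequence; origin places the
## first voxel centre half a voxel into the FOV so all grids tile the
## same physical extent.
phantom_grid <- function(spec, which) {
  sp <- c(spec$spacing[[which]], spec$slice_mm)
  n <- c(round(spec$fov_mm[1] / sp[1]), round(spec$fov_mm[2] / sp[2]),
         spec$n_slices)
  list(spacing = sp, origin = sp / 2, nx = n[1], ny = n[2], nz = n[3],
       x = sp[1] / 2 + (seq_len(n[1]) - 1) * sp[1],
       y = sp[2] / 2 + (seq_len(n[2]) - 1) * sp[2],
       z = sp[3] / 2 + (seq_len(n[3]) - 1) * sp[3])
}

## Tumor label per voxel (0 = none) for voxel-centre coordinate vectors.
rasterize_tumors <- function(spec, x, y, nz) {
  lab2d <- matrix(0L, length(y), length(x))
  per_slice <- vector("list", nz)
  for (k in seq_len(nz)) per_slice[[k]] <- lab2d
  tu <- spec$tumors
  for (i in seq_len(nrow(tu))) {
    dx <- outer(rep(1, length(y)), x - tu$cx[i])
    dy <- outer(y - tu$cy[i], rep(1, length(x)))
    u <- dx * cos(tu$theta[i]) + dy * sin(tu$theta[i])
    v <- -dx * sin(tu$theta[i]) + dy * cos(tu$theta[i])
    inside <- (u / tu$a[i])^2 + (v / tu$b[i])^2 <= 1
    ks <- tu$slice_first[i]:(tu$slice_first[i] + tu$slice_count[i] - 1)
    for (k in ks) per_slice[[k]][inside] <- i
  }
  lab <- array(0L, dim = c(length(y), length(x), nz))
  for (k in seq_len(nz)) lab[, , k] <- per_slice[[k]]
  lab
}

## Multivariate normal draws, n x d, via Cholesky.
rmvn <- function(n, mean, sigma) {
  d <- length(mean)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% chol(sigma), 2, mean, `+`)
}

#' Generate a phantom BP-MRI study
#'
#' Draws one synthetic study from a [phantom_spec()]: an underlying
#' three-channel field is sampled once on the coarsest grid
#' (exterior near zero, prostate background multivariate Gaussian around
#' `m_bg` with covariance `sigma_bg`, tumor voxels around `m_tum`), then
#' each sequence observes one channel of that field on its own grid, so
#' cross-channel correlation survives registration.  The T2 volume is
#' additionally shifted by the configured acquisition offset with the
#' compensating origin recorded in its header.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_study` with elements
#'   \describe{
#'     \item{volumes}{named list of ADC, HBV, T2 [sequence_volume()]s.}
#'     \item{prostate_mask}{whole-prostate mask on the reference grid.}
#'     \item{normal_mask}{prostate-minus-tumor mask (ACE background).}
#'     \item{tumor_mask}{integer tumor-label volume (0 = none).}
#'     \item{truth}{data frame of per-tumor true volume (mL), true
#'       eccentricity and rasterized voxel count.}
#'     \item{spec}{the input specification.}
#'   }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  seeded <- local_seed(spec$seed)
  on.exit(seeded())

  areas <- vapply(spec$spacing, prod, numeric(1))
  ref_name <- names(areas)[which.max(areas)]  # coarsest grid carries the field
  ref <- phantom_grid(spec, ref_name)

  pc <- spec$prostate_center
  ps <- spec$prostate_semiaxes
  r2xy <- outer(((ref$y - pc[2]) / ps[2])^2, ((ref$x - pc[1]) / ps[1])^2, `+`)
  prostate <- array(FALSE, dim = c(ref$ny, ref$nx, ref$nz))
  for (k in seq_len(ref$nz))
    prostate[, , k] <- r2xy + ((ref$z[k] - pc[3]) / ps[3])^2 <= 1
  tumor_lab <- rasterize_tumors(spec, ref$x, ref$y, ref$nz)
  if (any(tumor_lab > 0 & !prostate))
    stop("rasterized tumor voxels fall outside the prostate ellipsoid")

  n_vox <- length(prostate)
  field <- if (spec$exterior_sd > 0)
    matrix(stats::rnorm(n_vox * 3, 0, spec$exterior_sd), n_vox, 3)
  else matrix(0, n_vox, 3)
  idx_bg <- which(prostate & tumor_lab == 0)
  idx_tum <- which(tumor_lab > 0)
  if (length(idx_bg))
    field[idx_bg, ] <- rmvn(length(idx_bg), spec$m_bg, spec$sigma_bg)
  if (length(idx_tum))
    field[idx_tum, ] <- if (spec$tumor_sd > 0)
      rmvn(length(idx_tum), spec$m_tum, diag(spec$tumor_sd^2, 3))
    else matrix(spec$m_tum, length(idx_tum), 3, byrow = TRUE)

  channel_vol <- function(ch, grid) {
    # nearest-neighbour lookup of the reference-grid field
    ix <- pmin(pmax(round((grid$x - ref$origin[1]) / ref$spacing[1]) + 1, 1),
               ref$nx)
    iy <- pmin(pmax(round((grid$y - ref$origin[2]) / ref$spacing[2]) + 1, 1),
               ref$ny)
    vol <- array(0, dim = c(grid$ny, grid$nx, grid$nz))
    f <- array(field[, ch], dim = dim(prostate))
    for (k in seq_len(grid$nz)) vol[, , k] <- f[iy, ix, k]
    vol
  }

  vols <- list()
  for (nm in c("ADC", "HBV", "T2")) {
    g <- phantom_grid(spec, nm)
    a <- channel_vol(match(nm, c("ADC", "HBV", "T2")), g)
    origin <- g$origin
    if (nm == "T2" && any(spec$t2_offset_vox != 0L)) {
      off <- spec$t2_offset_vox           # (x, y) voxels
      a <- shift_plane(a, off[2], off[1]) # content moves +off; header records it
      origin <- origin - c(off * g$spacing[1:2], 0)
    }
    vols[[nm]] <- sequence_volume(a, spacing = g$spacing, origin = origin,
                                  label = nm)
  }

  as_mask_vol <- function(m)
    sequence_volume(array(as.numeric(m), dim = dim(prostate)),
                    spacing = ref$spacing, origin = ref$origin, label = "mask")
  tu <- spec$tumors
  truth <- data.frame(
    tumor = seq_len(nrow(tu)),
    cx = tu$cx, cy = tu$cy, a_mm = tu$a, b_mm = tu$b, theta = tu$theta,
    slice_first = tu$slice_first, slice_count = tu$slice_count,
    volume_mL = pi * tu$a * tu$b * (tu$slice_count * spec$slice_mm) / 1000,
    eccentricity = ifelse(tu$a^2 + tu$b^2 > 0,
                          (tu$a^2 - tu$b^2) / (tu$a^2 + tu$b^2), 0),
    n_voxels = vapply(seq_len(nrow(tu)),
                      function(i) sum(tumor_lab == i), integer(1)))

  structure(
    list(volumes = vols,
         prostate_mask = as_mask_vol(prostate),
         normal_mask = as_mask_vol(prostate & tumor_lab == 0),
         tumor_mask = as_mask_vol(tumor_lab),
         truth = truth, spec = spec),
    class = "phantom_study")
}

## Shift a 3-D array in-plane by integer voxels (rows dy, cols dx),
## zero-filling; used for the synthetic T2 acquisition offset and for
## header-driven realignment.
shift_plane <- function(a, dy, dx) {
  d <- dim(a)
  out <- array(0, dim = d)
  src_r <- seq_len(d[1]) - dy
  src_c <- seq_len(d[2]) - dx
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c), ] <- a[src_r[ok_r], src_c[ok_c], , drop = FALSE]
  out
}

## Run expr with a locally fixed seed, restoring the caller's RNG state.
local_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
    invisible(NULL)
  }
}

#' Cohort specification
#'
#' Describes a synthetic patient cohort: per-patient tumor burden, a
#' latent ISUP-grade model driven positively by tumor volume and
#' negatively by eccentricity, and clinical covariate distributions.
#' The latent grade is
#' `clamp(round(beta0 + beta_v * V + beta_e * E + eps), 0, 5)` with
#' `eps ~ N(0, sigma)`, where `V` is the largest tumor's true volume
#' (mL) and `E` that tumor's true eccentricity (both 0 for tumor-free
#' patients).  Clinically significant cancer is `ISUP >= 2`.
#'
#' @param n number of patients (>= 2).
#' @param tumor_count_probs probabilities of 0, 1, 2, ... tumors.
#' @param a_range range of the major in-plane semi-axis a (mm).
#' @param b_ratio_range range of the axis ratio b/a in (0, 1].
#' @param slice_count_range integer range of tumor slice extents.
#' @param beta0,beta_v,beta_e,sigma latent-grade model parameters;
#'   `beta_v > 0`, `beta_e < 0` reproduce the qualitative finding that
#'   volume raises and eccentricity lowers aggressiveness.
#' @param age_mean,age_sd,age_range patient age model (normal, clipped).
#' @param psa_meanlog,psa_sdlog PSA model (log-normal, ng/mL).
#' @param pvol_meanlog,pvol_sdlog prostate volume model (log-normal, mL).
#' @param base_spec tumor-free [phantom_spec()] template each patient's
#'   study is built from.
#' @param seed RNG seed fixing the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 42L,
                        tumor_count_probs = c(0.25, 0.55, 0.20),
                        a_range = c(4, 12),
                        b_ratio_range = c(0.4, 1),
                        slice_count_range = c(1L, 3L),
                        beta0 = 0.4, beta_v = 1.2, beta_e = -1.5,
                        sigma = 0.6,
                        age_mean = 65, age_sd = 7, age_range = c(50, 78),
                        psa_meanlog = log(10), psa_sdlog = 0.7,
                        pvol_meanlog = log(55), pvol_sdlog = 0.45,
                        base_spec = NULL,
                        seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("a cohort needs at least 2 patients")
  if (beta_v <= 0) stop("beta_v must be positive (volume raises grade)")
  if (beta_e >= 0) stop("beta_e must be negative (eccentricity lowers grade)")
  if (is.null(base_spec)) base_spec <- phantom_spec(seed = 0L)
  stopifnot(inherits(base_spec, "phantom_spec"))
  structure(
    list(n = n, tumor_count_probs = tumor_count_probs / sum(tumor_count_probs),
         a_range = as.numeric(a_range),
         b_ratio_range = as.numeric(b_ratio_range),
         slice_count_range = as.integer(slice_count_range),
         beta0 = beta0, beta_v = beta_v, beta_e = beta_e, sigma = sigma,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         psa_meanlog = psa_meanlog, psa_sdlog = psa_sdlog,
         pvol_meanlog = pvol_meanlog, pvol_sdlog = pvol_sdlog,
         base_spec = base_spec, seed = as.integer(seed)),
    class = "cohort_spec")
}

## sample() treats a scalar as 1:x; this keeps length-1 vectors literal.
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

## Draw a geometrically valid tumor table for one patient by rejection
## against the analytic containment check.
draw_tumors <- function(cspec, n_tumors) {
  bs <- cspec$base_spec
  out <- NULL
  attempts <- 0L
  while (n_tumors > 0L && attempts < 200L) {
    attempts <- attempts + 1L
    a <- stats::runif(1, cspec$a_range[1], cspec$a_range[2])
    b <- a * stats::runif(1, cspec$b_ratio_range[1], cspec$b_ratio_range[2])
    theta <- stats::runif(1, 0, pi)
    sc <- resample(cspec$slice_count_range[1]:cspec$slice_count_range[2])
    mid <- round(bs$prostate_center[3] / bs$slice_mm)
    sf <- mid - resample(0:(sc - 1L))
    sf <- max(1L, min(sf, bs$n_slices - sc + 1L))
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * 0.35
    cand <- data.frame(
      cx = bs$prostate_center[1] + rad * cos(ang) * bs$prostate_semiaxes[1],
      cy = bs$prostate_center[2] + rad * sin(ang) * bs$prostate_semiaxes[2],
      a = a, b = b, theta = theta, slice_first = sf, slice_count = sc)
    trial <- rbind(if (is.null(out)) cand[0, ] else out, cand)
    ok <- tryCatch({
      spec <- bs
      spec$tumors <- trial
      validate_phantom_spec(spec)
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      out <- trial
      n_tumors <- n_tumors - 1L
    }
  }
  if (is.null(out)) cspec$base_spec$tumors[0, ] else out
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` phantom studies plus a clinical table with ISUP grade,
#' CsPCa flag and covariates under the latent-grade model of
#' [cohort_spec()].  The same seed reproduces the cohort exactly.
#'
#' @param cspec a [cohort_spec()].
#' @param imaging logical; if `FALSE`, skip generating the voxel data and
#'   return only the clinical table and per-patient truth geometry
#'   (useful for fast statistics-only simulations).
#' @return A list of class `phantom_cohort` with elements `clinical`
#'   (data frame: `patient_id`, `isup`, `cspca`, `psa`, `age`,
#'   `prostate_volume`, `true_volume_mL`, `true_eccentricity`,
#'   `n_tumors`), `studies` (list of `phantom_study` or per-patient
#'   specs when `imaging = FALSE`) and `spec`.
#' @export
generate_cohort <- function(cspec, imaging = TRUE) {
  stopifnot(inherits(cspec, "cohort_spec"))
  seeded <- local_seed(cspec$seed)
  on.exit(seeded())

  n <- cspec$n
  counts <- sample(seq_along(cspec$tumor_count_probs) - 1L, n, replace = TRUE,
                   prob = cspec$tumor_count_probs)
  studies <- vector("list", n)
  clinical <- vector("list", n)
  for (i in seq_len(n)) {
    tumors <- draw_tumors(cspec, counts[i])
    V <- E <- 0
    if (nrow(tumors) > 0) {
      vols <- pi * tumors$a * tumors$b *
        (tumors$slice_count * cspec$base_spec$slice_mm) / 1000
      j <- which.max(vols)
      V <- vols[j]
      E <- (tumors$a[j]^2 - tumors$b[j]^2) / (tumors$a[j]^2 + tumors$b[j]^2)
    }
    grade <- cspec$beta0 + cspec$beta_v * V + cspec$beta_e * E +
      stats::rnorm(1, 0, cspec$sigma)
    grade <- min(max(round(grade), 0L), 5L)
    age <- min(max(round(stats::rnorm(1, cspec$age_mean, cspec$age_sd)),
                   cspec$age_range[1]), cspec$age_range[2])
    psa <- round(stats::rlnorm(1, cspec$psa_meanlog, cspec$psa_sdlog), 2)
    pvol <- round(stats::rlnorm(1, cspec$pvol_meanlog, cspec$pvol_sdlog), 1)

    pspec <- cspec$base_spec
    pspec$tumors <- tumors
    # per-patient sub-seed, kept within 32-bit integer range
    pspec$seed <- (cspec$seed * 1000L + i) %% .Machine$integer.max
    studies[[i]] <- if (imaging) generate_phantom(pspec) else pspec
    clinical[[i]] <- data.frame(
      patient_id = sprintf("P%03d", i), isup = grade, cspca = grade >= 2L,
      psa = psa, age = age, prostate_volume = pvol,
      true_volume_mL = V, true_eccentricity = E, n_tumors = nrow(tumors))
  }
  structure(list(clinical = do.call(rbind, clinical), studies = studies,
                 spec = cspec),
            class = "phantom_cohort")
}

#' Write a cohort to disk
#'
#' Writes each patient's sequences and masks as volumes plus
#' `cohort.csv` and per-patient `truth.csv` tables; layout is one
#' directory per patient.  Deterministic: the same cohort writes
#' byte-identical CSVs.
#'
#' @param cohort a `phantom_cohort` generated with `imaging = TRUE`.
#' @param dir output directory (created if needed).
#' @param format `"mha"` or `"nii"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("mha", "nii")) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  for (i in seq_along(cohort$studies)) {
    st <- cohort$studies[[i]]
    if (!inherits(st, "phantom_study"))
      stop("cohort was generated with imaging = FALSE; nothing to write")
    pdir <- file.path(dir, cohort$clinical$patient_id[i])
    dir.create(pdir, showWarnings = FALSE)
    for (nm in names(st$volumes))
      write_sequence(st$volumes[[nm]],
                     file.path(pdir, paste0(tolower(nm), ".", format)))
    write_sequence(st$normal_mask,
                   file.path(pdir, paste0("normal_mask.", format)), mask = TRUE)
    write_sequence(st$tumor_mask,
                   file.path(pdir, paste0("tumor_mask.", format)), mask = TRUE)
    utils::write.csv(st$truth, file.path(pdir, "truth.csv"), row.names = FALSE)
    # generator tumor mean: signature fallback for tumor-free studies
    utils::write.csv(data.frame(channel = c("ADC", "HBV", "T2"),
                                value = st$spec$m_tum),
                     file.path(pdir, "signature.csv"), row.names = FALSE)
  }
  invisible(dir)
}
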