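#' Pipeline run configuration
#'
#' Bundles the tunables of an end-to-end run: the ACE threshold grid,
#' the minimum blob size, how the tumor signature is obtained, manual
#' per-sequence alignment tweaks, the RNG seed for the statistics stage
#' and an optional output directory.
#'
#' @param thresholds ACE thresholds in (0, 1), sorted unique; default
#'   `c(0.90, 0.92, 0.94, 0.96)`.
#' @param min_blob_voxels blobs below this voxel count are discarded
#'   (default 5).
#' @param signature either `NULL` (derive in scene from the tumor-truth
#'   mask, phantom runs) or an explicit length-3 `(ADC, HBV, T2)` vector.
#' @param extra_shift named list of integer `(x, y)` manual shifts per
#'   sequence label (the stand-in for visual fine alignment).
#' @param reps repetitions for the repeated-split logistic AUC.
#' @param seed RNG seed for the statistics stage.
#' @param out_dir optional directory for CSV/PNG artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(thresholds = c(0.90, 0.92, 0.94, 0.96),
                       min_blob_voxels = 5L,
                       signature = NULL,
                       extra_shift = list(),
                       reps = 1000L,
                       seed = 1L,
                       out_dir = NULL) {
  thresholds <- as.numeric(thresholds)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  if (anyDuplicated(thresholds)) stop("thresholds must be unique")
  if (min_blob_voxels < 1L) stop("min_blob_voxels must be >= 1")
  structure(
    list(thresholds = sort(thresholds),
         min_blob_voxels = as.integer(min_blob_voxels),
         signature = signature, extra_shift = extra_shift,
         reps = as.integer(reps), seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config")
}

## Stable short hash of a configuration for run provenance stamps.
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 100000000L
}

## Load one patient's volumes + masks from a directory written by
## write_cohort() (or following the same layout).
read_patient_dir <- function(dir, format = NULL) {
  find <- function(stem) {
    for (ext in if (is.null(format)) c("mha", "nii") else format) {
      p <- file.path(dir, paste0(stem, ".", ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }
  paths <- vapply(c("adc", "hbv", "t2", "normal_mask", "tumor_mask"),
                  find, character(1))
  if (any(is.na(paths[1:4])))
    stop("patient directory ", dir,
         " must contain adc, hbv, t2 and normal_mask volumes")
  vols <- list(ADC = read_sequence(paths[["adc"]], "ADC"),
               HBV = read_sequence(paths[["hbv"]], "HBV"),
               T2 = read_sequence(paths[["t2"]], "T2"))
  masks <- list(normal = read_sequence(paths[["normal_mask"]], "mask"))
  if (!is.na(paths[["tumor_mask"]]))
    masks$tumor <- read_sequence(paths[["tumor_mask"]], "mask")
  sig_path <- file.path(dir, "signature.csv")
  list(volumes = vols, masks = masks,
       signature = if (file.exists(sig_path))
         utils::read.csv(sig_path)$value else NULL,
       truth = if (file.exists(file.path(dir, "truth.csv")))
         utils::read.csv(file.path(dir, "truth.csv")) else NULL)
}

#' Run the detection pipeline for one patient
#'
#' Registers the three sequences into a hypercube, estimates background
#' statistics on the normal-prostate mask, derives (or takes) the tumor
#' signature, scores the scene with the Adaptive Cosine Estimator and,
#' for every configured threshold, labels blobs, filters the undersized
#' ones and extracts the morphology features.
#'
#' @param patient a `phantom_study`, a list with `volumes` (named ADC,
#'   HBV, T2) and `masks` (named `normal`, optional `tumor`,
#'   `prostate`), or a patient directory path.
#' @param config a [run_config()].
#' @return List of class `patient_result` with `features` (one row per
#'   threshold), `blob_tables` (per threshold), `detection` (the
#'   `detection_map`), `hypercube`, `stats`, `signature`.
#' @export
run_patient <- function(patient, config = run_config()) {
  if (is.character(patient)) patient <- read_patient_dir(patient)
  sig_fallback <- NULL
  if (inherits(patient, "phantom_study")) {
    masks <- list(normal = patient$normal_mask,
                  prostate = patient$prostate_mask,
                  tumor = patient$tumor_mask)
    vols <- patient$volumes
    sig_fallback <- patient$spec$m_tum  # tumor-free studies have no seed
  } else {
    vols <- patient$volumes
    masks <- patient$masks
    sig_fallback <- patient$signature
  }
  hc <- build_hypercube(vols$ADC, vols$HBV, vols$T2, masks = masks,
                        extra_shift = config$extra_shift)
  stats <- compute_background_stats(hc, hc$masks$normal)
  sig <- if (!is.null(config$signature)) {
    structure(list(s = as.numeric(config$signature),
                   provenance = "explicit configuration vector"),
              class = "ace_signature")
  } else if (!is.null(hc$masks$tumor) && any(hc$masks$tumor$data > 0)) {
    derive_signature(hc, hc$masks$tumor, stats = stats)
  } else if (!is.null(sig_fallback)) {
    structure(list(s = as.numeric(sig_fallback),
                   provenance = "generator tumor mean (no in-scene seed)"),
              class = "ace_signature")
  } else {
    stop("no signature: supply config$signature or a non-empty tumor ",
         "seed mask")
  }
  dmap <- ace_score(hc, stats, sig)
  scene <- if (!is.null(hc$masks$prostate)) hc$masks$prostate else NULL

  feats <- list(); btabs <- list()
  for (th in config$thresholds) {
    bm <- threshold_map(dmap, th, scene_mask = scene)
    blobs <- filter_blobs(label_blobs(bm), config$min_blob_voxels)
    f <- extract_features(blobs, hc$voxel_volume_mL)
    f$threshold <- th
    feats[[length(feats) + 1L]] <- f
    btabs[[sprintf("%.2f", th)]] <- blob_table(blobs, hc$voxel_volume_mL)
  }
  structure(
    list(features = do.call(rbind, feats), blob_tables = btabs,
         detection = dmap, hypercube = hc, stats = stats, signature = sig),
    class = "patient_result")
}

#' Run the full cohort analysis
#'
#' Applies [run_patient()] to every study (one failure never aborts the
#' cohort: errors are collected per patient), joins the per-threshold
#' morphology features with the clinical table and produces the
#' univariate threshold sweep, the clinical-covariate fits and the
#' two-feature (eccentricity + volume) fits with repeated-split
#' logistic AUCs.  When all patients fall in one CsPCa class the
#' logistic stage is skipped with a message.
#'
#' @param cohort a `phantom_cohort` (from [generate_cohort()]) or a
#'   directory written by [write_cohort()].
#' @param config a [run_config()].
#' @return List of class `cohort_result` with `features` (long table),
#'   `univariate` (sweep rows), `clinical` (covariate fits),
#'   `multivariate` (paired fits), `errors`, `log`.
#' @export
run_cohort <- function(cohort, config = run_config()) {
  t0 <- Sys.time()
  if (is.character(cohort)) {
    dir <- cohort
    clin <- utils::read.csv(file.path(dir, "cohort.csv"))
    studies <- file.path(dir, clin$patient_id)
  } else {
    stopifnot(inherits(cohort, "phantom_cohort"))
    clin <- cohort$clinical
    studies <- cohort$studies
  }
  if (nrow(clin) < 2L) stop("a cohort run needs at least 2 patients")

  rows <- list(); errors <- list()
  for (i in seq_len(nrow(clin))) {
    pid <- clin$patient_id[i]
    res <- tryCatch(run_patient(studies[[i]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[pid]] <- conditionMessage(res)
      next
    }
    f <- res$features
    f$patient_id <- pid
    rows[[pid]] <- f
  }
  if (length(rows) == 0L)
    stop("every patient failed; first error: ", errors[[1]])
  features <- merge(do.call(rbind, rows), clin, by = "patient_id")
  features <- features[order(features$threshold, features$patient_id), ]
  rownames(features) <- NULL

  two_class <- length(unique(features$cspca)) == 2L
  if (!two_class)
    message("cohort has a single CsPCa class; logistic/AUC stage skipped")

  uni <- threshold_sweep(features, reps = config$reps, seed = config$seed,
                         auc = two_class)

  # clinical covariates: threshold-free univariate fits + AUCs
  clin_rows <- list()
  for (fn in c("age", "psa", "prostate_volume")) {
    sub <- features[features$threshold == config$thresholds[1], ]
    r <- p <- a <- lo <- hi <- NA_real_
    fit <- if (stats::sd(sub[[fn]]) > 0)
      tryCatch(fit_univariate(sub[[fn]], sub$isup), error = function(e) NULL)
    else NULL
    if (!is.null(fit)) {
      r <- fit$r; p <- fit$p
      if (two_class) {
        rr <- tryCatch(
          logistic_split_auc(sub[[fn]], sub$cspca, reps = config$reps,
                             seed = config$seed),
          error = function(e) NULL)
        if (!is.null(rr)) {
          a <- rr$mean_auc; lo <- rr$ci[1]; hi <- rr$ci[2]
        }
      }
    }
    clin_rows[[fn]] <- data.frame(feature = fn, r = r, p = p, auc = a,
                                  ci_lo = lo, ci_hi = hi)
  }
  clinical_fits <- do.call(rbind, clin_rows)
  rownames(clinical_fits) <- NULL

  # eccentricity + volume paired fits per threshold
  multi_rows <- list()
  for (th in config$thresholds) {
    sub <- features[features$threshold == th, ]
    for (vf in c("avg_blob_volume", "max_blob_volume")) {
      if (stats::sd(sub$max_blob_eccentricity) == 0 ||
          stats::sd(sub[[vf]]) == 0) next
      fit <- tryCatch(
        fit_multivariate(sub$max_blob_eccentricity, sub[[vf]], sub$isup),
        error = function(e) NULL)
      if (is.null(fit)) next
      a <- lo <- hi <- NA_real_
      if (two_class) {
        rr <- tryCatch(
          logistic_split_auc(
            cbind(ecc = sub$max_blob_eccentricity, vol = sub[[vf]]),
            sub$cspca, reps = config$reps, seed = config$seed),
          error = function(e) NULL)
        if (!is.null(rr)) {
          a <- rr$mean_auc; lo <- rr$ci[1]; hi <- rr$ci[2]
        }
      }
      multi_rows[[length(multi_rows) + 1L]] <- data.frame(
        threshold = th, variable1 = "max_blob_eccentricity",
        r1 = fit$r1, p1 = fit$p1, variable2 = vf, r2 = fit$r2, p2 = fit$p2,
        r12 = fit$r12, f_probability = fit$f_probability,
        auc = a, ci_lo = lo, ci_hi = hi)
    }
  }
  multivariate <- if (length(multi_rows)) do.call(rbind, multi_rows) else NULL

  log <- data.frame(
    seed = config$seed, reps = config$reps,
    config_hash = config_hash(config),
    n_patients = nrow(clin), n_processed = length(rows),
    n_failed = length(errors),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- structure(
    list(features = features, univariate = uni, clinical = clinical_fits,
         multivariate = multivariate, errors = errors, log = log),
    class = "cohort_result")
  if (!is.null(config$out_dir)) write_cohort_result(out, config$out_dir)
  out
}

#' Write cohort-result tables as CSV
#'
#' @param result a `cohort_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(result$univariate, file.path(dir, "univariate_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(result$clinical, file.path(dir, "clinical_fits.csv"),
                   row.names = FALSE)
  if (!is.null(result$multivariate))
    utils::write.csv(result$multivariate,
                     file.path(dir, "multivariate_fits.csv"),
                     row.names = FALSE)
  utils::write.csv(result$log, file.path(dir, "run_log.csv"),
                   row.names = FALSE)
  if (length(result$errors))
    writeLines(paste(names(result$errors), unlist(result$errors), sep = ": "),
               file.path(dir, "errors.txt"))
  invisible(dir)
}
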