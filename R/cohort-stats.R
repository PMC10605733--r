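#' Univariate linear fit of a feature to grade
#'
#' Ordinary least squares of `y` on `x` with the summaries the morphology
#' analysis reports: the signed Pearson correlation R, the two-sided
#' t-test p-value of the slope, 95% confidence intervals for both
#' coefficients and the overall F probability (identical to the slope p
#' in the univariate case).
#'
#' @param x numeric predictor (not constant).
#' @param y numeric response (e.g. ISUP grade).
#' @return An object of class `fit_result`: list with `coefficients`,
#'   `conf_int`, `r`, `p`, `f_probability`, `r_squared`, `n`, `model`.
#' @export
fit_univariate <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("univariate fit needs at least 3 observations")
  if (stats::sd(x) == 0) stop("predictor is constant; no fit possible")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p_slope <- sm$coefficients["x", "Pr(>|t|)"]
  fstat <- sm$fstatistic
  structure(
    list(coefficients = stats::coef(fit),
         conf_int = stats::confint(fit),
         r = stats::cor(x, y),
         p = p_slope,
         f_probability = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                          lower.tail = FALSE)),
         r_squared = sm$r.squared,
         n = length(x), model = fit),
    class = "fit_result")
}

#' Two-predictor linear fit of features to grade
#'
#' Joint OLS of `y` on `x1` and `x2`.  `r1`, `r2` are the signed
#' univariate Pearson correlations of each predictor with `y`, while the
#' parenthesized `p1`, `p2` come from the joint fit's coefficient
#' t-tests; `r12` is the multiple correlation (square root of the joint
#' R-squared) and `f_probability` the overall F-test p-value.
#'
#' @param x1,x2 numeric predictors (jointly full rank).
#' @param y numeric response.
#' @return A `fit_result` with fields `r1`, `r2`, `r12`, `p1`, `p2`,
#'   `f_probability`, plus coefficients, intervals and `n`.
#' @export
fit_multivariate <- function(x1, x2, y) {
  stopifnot(length(x1) == length(y), length(x2) == length(y))
  ok <- is.finite(x1) & is.finite(x2) & is.finite(y)
  x1 <- x1[ok]; x2 <- x2[ok]; y <- y[ok]
  if (length(y) < 4L) stop("two-predictor fit needs at least 4 observations")
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3L)
    stop("design matrix is rank deficient (collinear predictors)")
  fit <- stats::lm(y ~ x1 + x2)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(
    list(coefficients = stats::coef(fit),
         conf_int = stats::confint(fit),
         r1 = stats::cor(x1, y), r2 = stats::cor(x2, y),
         r12 = sqrt(sm$r.squared),
         p1 = sm$coefficients["x1", "Pr(>|t|)"],
         p2 = sm$coefficients["x2", "Pr(>|t|)"],
         f_probability = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                          lower.tail = FALSE)),
         r_squared = sm$r.squared,
         n = length(y), model = fit),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!is.null(x$r12)) {
    cat(sprintf("<fit_result: R1 = %.3f (p = %.3g), R2 = %.3f (p = %.3g), R12 = %.3f (F prob = %.3g), n = %d>\n",
                x$r1, x$p1, x$r2, x$p2, x$r12, x$f_probability, x$n))
  } else {
    cat(sprintf("<fit_result: R = %.3f (p = %.3g), n = %d>\n", x$r, x$p, x$n))
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve swept over the distinct
#' score values, which (ties counted half) equals the Mann-Whitney
#' probability that a random positive outranks a random negative.
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels logical or 0/1 class labels; both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("ROC needs both classes present")
  curve <- roc_curve(scores, labels)
  # trapezoid over the (fpr, tpr) polyline
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame of `threshold`, `fpr`, `tpr`, starting at (0, 0)
#'   and ending at (1, 1), one step per distinct score.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  np <- sum(l); nn <- sum(!l)
  last <- cumsum(rep(1, length(s)))[!duplicated(s, fromLast = TRUE)]
  # cumulative counts evaluated at the end of each tie group
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp / nn),
             tpr = c(0, tp / np))
}

#' Repeated-split logistic AUC distribution
#'
#' Repeatedly splits the cohort into a 70%/30% train/test partition,
#' fits a logistic regression of the binary outcome on the feature(s) on
#' the training set, scores the held-out set and records the test AUC.
#' Splits whose training or test portion lacks one of the classes are
#' redrawn (and counted).  The distribution of AUCs is summarized by its
#' mean and the 2.5/97.5 percentile interval.
#'
#' @param features numeric vector or matrix (rows = patients).
#' @param labels logical/0-1 outcome (e.g. CsPCa); both classes present.
#' @param train_frac training fraction, default 0.7.
#' @param reps number of random splits, default 1000.
#' @param seed RNG seed making the whole procedure reproducible.
#' @return An object of class `roc_result`: list with `aucs`,
#'   `mean_auc`, `ci` (2.5/97.5 percentiles), `reps`, `redraws`, `seed`.
#' @export
logistic_split_auc <- function(features, labels, train_frac = 0.7,
                               reps = 1000L, seed = 1L) {
  X <- as.matrix(features)
  labels <- as.logical(labels)
  n <- nrow(X)
  stopifnot(length(labels) == n, reps >= 1L,
            train_frac > 0, train_frac < 1)
  if (!any(labels) || all(labels))
    stop("both classes must be present in the cohort")
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("repeated splits need at least 2 patients of each class ",
         "(one for training, one for testing)")
  seeded <- local_seed(seed)
  on.exit(seeded())
  n_train <- round(train_frac * n)
  if (n_train < 2L || n_train > n - 1L)
    stop("training fraction leaves an unusable split")
  df <- data.frame(y = labels, X)
  xnames <- setdiff(names(df), "y")
  form <- stats::as.formula(paste("y ~", paste(xnames, collapse = " + ")))
  aucs <- numeric(reps)
  redraws <- 0L
  for (i in seq_len(reps)) {
    repeat {
      tr <- sample.int(n, n_train)
      te <- setdiff(seq_len(n), tr)
      if (length(unique(labels[tr])) == 2L &&
          length(unique(labels[te])) == 2L) break
      redraws <- redraws + 1L
      if (redraws > 10000L * reps)
        stop("could not draw class-balanced splits")
    }
    fit <- suppressWarnings(
      stats::glm(form, family = stats::binomial(), data = df[tr, ]))
    # perfect separation gives huge but finite ML coefficients; the AUC
    # of the induced ranking is still well defined, so no special-casing
    p <- suppressWarnings(
      stats::predict(fit, newdata = df[te, , drop = FALSE], type = "link"))
    aucs[i] <- roc_auc(p, labels[te])
  }
  structure(
    list(aucs = aucs, mean_auc = mean(aucs),
         ci = unname(stats::quantile(aucs, c(0.025, 0.975))),
         reps = reps, redraws = redraws, seed = seed),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: mean AUC %.3f [%.3f-%.3f], %d splits (%d redraws)>\n",
              x$mean_auc, x$ci[1], x$ci[2], x$reps, x$redraws))
  invisible(x)
}

#' Feature-vs-grade sweep over ACE thresholds
#'
#' For every (threshold, feature) pair, fits the feature linearly to the
#' ISUP grade (R, p) and, when both outcome classes are present,
#' evaluates the repeated-split logistic AUC against CsPCa.  The
#' threshold maximizing R defines the optimal threshold per feature.
#'
#' @param features data frame with columns `threshold`, `isup`, `cspca`
#'   and the feature columns (one row per patient and threshold), as
#'   produced by [run_cohort()].
#' @param feature_names feature columns to sweep; defaults to the three
#'   morphology features.
#' @param reps,seed passed to [logistic_split_auc()].
#' @param auc logical; set `FALSE` to skip the (slower) logistic stage.
#' @return Data frame with one row per (threshold, feature): `threshold`,
#'   `feature`, `r`, `p`, `auc`, `ci_lo`, `ci_hi`; the per-feature
#'   optimal thresholds are attached as attribute `optimal`.
#' @export
threshold_sweep <- function(features,
                            feature_names = c("max_blob_volume",
                                              "avg_blob_volume",
                                              "max_blob_eccentricity"),
                            reps = 1000L, seed = 1L, auc = TRUE) {
  stopifnot(all(c("threshold", "isup", "cspca") %in% names(features)),
            all(feature_names %in% names(features)))
  thresholds <- sort(unique(features$threshold))
  rows <- list()
  for (th in thresholds) {
    sub <- features[features$threshold == th, ]
    for (fn in feature_names) {
      x <- sub[[fn]]
      r <- p <- a <- lo <- hi <- NA_real_
      fit <- if (stats::sd(x) > 0 && stats::sd(sub$isup) > 0)
        tryCatch(fit_univariate(x, sub$isup), error = function(e) NULL)
      else NULL
      if (!is.null(fit)) {
        r <- fit$r; p <- fit$p
        if (auc) {
          rr <- tryCatch(
            logistic_split_auc(x, sub$cspca, reps = reps, seed = seed),
            error = function(e) NULL)  # infeasible class balance -> NA
          if (!is.null(rr)) {
            a <- rr$mean_auc; lo <- rr$ci[1]; hi <- rr$ci[2]
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = th, feature = fn, r = r, p = p,
        auc = a, ci_lo = lo, ci_hi = hi)
    }
  }
  out <- do.call(rbind, rows)
  opt <- vapply(feature_names, function(fn) {
    sub <- out[out$feature == fn & is.finite(out$r), ]
    if (nrow(sub) == 0L) NA_real_ else sub$threshold[which.max(sub$r)]
  }, numeric(1))
  attr(out, "optimal") <- opt
  out
}
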