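test_that("univariate fit recovers exact linear relations", {
  x <- c(1, 2, 3, 4, 5)
  fit <- fit_univariate(x, 2 * x)
  expect_equal(fit$r, 1)
  expect_lt(fit$p, 1e-10)
  expect_equal(unname(fit$coefficients), c(0, 2), tolerance = 1e-10)
  # R^2 identity against an independent Pearson computation
  set.seed(1)
  y <- 2 * x + rnorm(5)
  fit2 <- fit_univariate(x, y)
  expect_equal(fit2$r_squared, cor(x, y)^2)
  expect_equal(fit2$r, cor(x, y))
  expect_error(fit_univariate(rep(1, 5), y), "constant")
  expect_error(fit_univariate(1:2, 1:2), "at least 3")
})

test_that("null univariate p-values are calibrated at the 5% level", {
  set.seed(2024)
  n_reps <- 400
  p <- replicate(n_reps, {
    x <- rnorm(42); y <- rnorm(42)
    fit_univariate(x, y)$p
  })
  rate <- mean(p < 0.05)
  # binomial 3 sigma band around 0.05
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_reps))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 1e-4)
})

test_that("two-predictor fit reports R1, R2, R12 and the F probability", {
  set.seed(3)
  x1 <- rnorm(40); x2 <- rnorm(40)
  y <- x1 + x2
  fit <- fit_multivariate(x1, x2, y)
  expect_equal(fit$r12, 1, tolerance = 1e-7)
  expect_lt(fit$f_probability, 1e-12)
  expect_equal(fit$r1, cor(x1, y))
  expect_equal(fit$r2, cor(x2, y))
  # pure-noise second predictor: R12 ~ |R1|
  y2 <- 2 * x1 + rnorm(40, sd = 0.3)
  fitn <- fit_multivariate(x1, x2, y2)
  expect_lt(abs(fitn$r12 - abs(cor(x1, y2))), 0.03)
  # permuting patients leaves the fit unchanged
  perm <- sample(40)
  fitp <- fit_multivariate(x1[perm], x2[perm], y2[perm])
  expect_equal(fitp$r12, fitn$r12)
  expect_equal(fitp$coefficients, fitn$coefficients)
  expect_error(fit_multivariate(x1, 2 * x1, y), "rank")
})

test_that("trapezoid AUC equals the pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(8)
  for (i in 1:20) {
    n <- 50
    scores <- sample(round(rnorm(n), 2))      # rounding forces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), auc_pair_oracle(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("roc_curve is a valid monotone curve from (0,0) to (1,1)", {
  set.seed(9)
  scores <- rnorm(30); labels <- runif(30) < 0.5
  cur <- roc_curve(scores, labels)
  expect_equal(cur$fpr[1], 0); expect_equal(cur$tpr[1], 0)
  expect_equal(cur$fpr[nrow(cur)], 1); expect_equal(cur$tpr[nrow(cur)], 1)
  expect_true(all(diff(cur$fpr) >= 0))
  expect_true(all(diff(cur$tpr) >= 0))
})

test_that("repeated-split logistic AUC behaves on canonical inputs", {
  set.seed(10)
  n <- 40
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  # perfectly separating feature: every split AUC is 1
  sep <- ifelse(labels, 1, 0) + runif(n, 0, 0.01)
  rs <- logistic_split_auc(sep, labels, reps = 50, seed = 1)
  expect_equal(rs$aucs, rep(1, 50))
  expect_equal(rs$ci, c(1, 1))
  # determinism and seed sensitivity
  rs2 <- logistic_split_auc(sep, labels, reps = 50, seed = 1)
  expect_identical(rs$aucs, rs2$aucs)
  expect_error(logistic_split_auc(sep, rep(TRUE, n)), "both classes")
})

test_that("label-independent features give chance-level mean AUC", {
  set.seed(11)
  n <- 42
  labels <- rep(c(TRUE, FALSE), c(18, 24))
  # the dominant Monte-Carlo error is the cohort draw itself (null
  # sample-AUC sd ~ 0.09 at n = 42), so average over independent cohorts
  means <- vapply(1:8, function(k) {
    logistic_split_auc(rnorm(n), labels, reps = 50, seed = k)$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.1)
  # different split seed: same mean within the percentile interval
  noise <- rnorm(n)
  rs <- logistic_split_auc(noise, labels, reps = 200, seed = 2)
  rs_b <- logistic_split_auc(noise, labels, reps = 200, seed = 3)
  expect_gt(rs_b$mean_auc, rs$ci[1])
  expect_lt(rs_b$mean_auc, rs$ci[2])
})

test_that("degenerate splits are redrawn, not scored", {
  set.seed(12)
  labels <- c(rep(FALSE, 38), rep(TRUE, 4))  # rare positives force redraws
  x <- rnorm(42) + 2 * labels
  rs <- logistic_split_auc(x, labels, reps = 100, seed = 4)
  expect_gt(rs$redraws, 0)
  expect_true(all(rs$aucs >= 0 & rs$aucs <= 1))
})

test_that("threshold sweep emits one row per threshold and feature", {
  set.seed(13)
  n <- 30
  thresholds <- c(0.90, 0.92, 0.94, 0.96)
  grid <- expand.grid(patient = seq_len(n), threshold = thresholds)
  isup <- sample(0:5, n, replace = TRUE, prob = c(17, 14, 5, 3, 1, 2))
  feats <- data.frame(
    threshold = grid$threshold,
    isup = isup[grid$patient],
    cspca = isup[grid$patient] >= 2,
    max_blob_volume = rnorm(nrow(grid), 1),
    avg_blob_volume = rnorm(nrow(grid), 1),
    max_blob_eccentricity = runif(nrow(grid)))
  sw <- threshold_sweep(feats, reps = 25, seed = 1)
  expect_equal(nrow(sw), 12L)   # 3 features x 4 thresholds
  expect_setequal(unique(sw$threshold), thresholds)
  opt <- attr(sw, "optimal")
  expect_length(opt, 3L)
  for (fn in names(opt)) {
    sub <- sw[sw$feature == fn, ]
    expect_equal(unname(opt[fn]), sub$threshold[which.max(sub$r)])
  }
  # threshold-independent features give a flat sweep
  flat <- feats
  for (cn in c("max_blob_volume", "avg_blob_volume", "max_blob_eccentricity"))
    flat[[cn]] <- rep(flat[[cn]][flat$threshold == 0.90], 4)
  swf <- threshold_sweep(flat, reps = 10, seed = 1, auc = FALSE)
  expect_equal(swf$r, rep(swf$r[1:3], 4), tolerance = 1e-12)
})
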