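test_that("complexity and oblique communality reproduce the published per-metal values", {
  ref <- fa_reference_solution()
  com <- hoffman_complexity(ref$loadings)
  expect_equal(round(com[["Zn"]], 1), 1.0)
  expect_equal(round(com[["Pb"]], 1), 2.2)
  expect_true(all(com >= 1))
  h2 <- communalities_oblique(ref$loadings, ref$factor_corr)
  expect_equal(round(h2[["Zn"]], 2), 0.91)
  # orthogonal single-loading row: closed form
  expect_equal(unname(communalities_oblique(c(0.8, 0, 0), diag(3))), 0.64)
  expect_equal(unname(hoffman_complexity(c(0.8, 0, 0))), 1)
})

test_that("ML extraction with oblimin rotation recovers a planted orthogonal pattern", {
  # population correlation from a clean 3-factor model, entries >= 0.7
  L <- matrix(0, 9, 3)
  L[1:3, 1] <- c(0.8, 0.75, 0.7); L[4:6, 2] <- c(0.85, 0.8, 0.7); L[7:9, 3] <- c(0.8, 0.7, 0.75)
  R <- L %*% t(L); diag(R) <- 1
  dimnames(R) <- list(paste0("V", 1:9), paste0("V", 1:9))
  fit <- fa_fit(R, 3, n = 1000)
  # match fitted factors to planted ones by dominant block, up to sign
  recovered <- abs(fit$loadings)
  err <- sapply(1:3, function(j) {
    best <- which.max(colSums(recovered[which(L[, j] > 0), , drop = FALSE]))
    max(abs(recovered[, best] - abs(L[, j])))
  })
  expect_lt(max(err), 0.1)
  expect_equal(fit$h2 + fit$u2, rep(1, 9), tolerance = 0.02, ignore_attr = TRUE)
  expect_true(all(fit$com >= 1 - 1e-9))
  expect_equal(diag(fit$factor_corr), rep(1, 3), ignore_attr = TRUE)
  expect_equal(fit$factor_corr, t(fit$factor_corr))
  expect_true(all(diff(fit$cumulative_var) >= -1e-12))
  # near-perfect model: tiny discrepancy and residuals
  expect_lt(fit$fit$objective, 1e-4)
  expect_lt(fit$fit$RMSR, 0.01)
})

test_that("oblimin rotation is invariant to orthogonal re-expression of the extraction", {
  set.seed(3)
  A <- matrix(0, 8, 2); A[1:4, 1] <- runif(4, 0.6, 0.9); A[5:8, 2] <- runif(4, 0.6, 0.9)
  A <- A + matrix(rnorm(16, 0, 0.05), 8, 2)
  Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  r1 <- dustrisk:::oblimin_rotate(A)
  r2 <- dustrisk:::oblimin_rotate(A %*% Q)
  expect_equal(r1$criterion, r2$criterion, tolerance = 1e-6)
  h1 <- communalities_oblique(r1$loadings, r1$Phi)
  h2 <- communalities_oblique(r2$loadings, r2$Phi)
  expect_equal(unname(h1), unname(h2), tolerance = 1e-5)
  # pattern matrices agree up to column permutation/sign (ordering is canonical)
  expect_equal(abs(unname(r1$loadings)), abs(unname(r2$loadings)), tolerance = 1e-4)
})

test_that("fit statistics obey their defining identities", {
  z <- standardize(log(generate_dataset(factor_only_config(6, n = 200))$concentrations))
  R <- stats::cor(z)
  fit <- fa_fit(R, 3, n = 200)
  st <- fit$fit
  expect_equal(st$df, ((10 - 3)^2 - 13) / 2)  # 18
  expect_equal(st$AIC - st$BIC, 4 * st$df)
  expect_equal(st$AIC, st$chi_square + 2 * st$df)
  expect_equal(st$BIC, st$chi_square - 2 * st$df)
  expect_gte(st$chi_square, 0)
  expect_gte(st$RMSR, 0)
  expect_equal(st$p_value, stats::pchisq(st$chi_square, st$df, lower.tail = FALSE))
  expect_error(fa_fit(R, 7, 200), "degrees of freedom")
})

test_that("parallel analysis separates structure from noise", {
  # planted two-factor data
  metals <- paste0("M", 1:10)
  L <- matrix(0, 10, 2, dimnames = list(metals, NULL))
  L[1:5, 1] <- 0.8; L[6:10, 2] <- 0.8
  hits <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(n_sites = 200, metals = metals, m_true = 2,
                            loadings_true = L, factor_corr_true = diag(2),
                            cluster_labels_true = rep(1L, 200),
                            cluster_shifts = matrix(0, 1, 10, dimnames = list("C1", metals)),
                            base_log_mean = stats::setNames(rep(0, 10), metals),
                            lognormal = FALSE, seed = s)
    x <- generate_dataset(cfg)$concentrations
    pa <- parallel_analysis(x, reps = 50, seed = s)
    if (pa$pa_retained == 2) hits <- hits + 1
    expect_true(all(diff(pa$random_eigen_means) < 0))  # strictly decreasing
  }
  expect_gte(hits, 9)
  # pure noise: the mean-eigenvalue comparison retains few factors on average
  # (a chance crossing of the first random eigenvalue keeps 2+ in a minority
  # of draws; the percentile variant would suppress those, but the mean rule
  # is the one implemented)
  pa_noise <- vapply(1:20, function(s) {
    set.seed(s + 100)
    parallel_analysis(matrix(rnorm(200 * 10), 200, 10), reps = 50, seed = s)$pa_retained
  }, numeric(1))
  expect_lte(mean(pa_noise), 1.5)
  expect_lte(stats::median(pa_noise), 1)
  expect_error(parallel_analysis(matrix(rnorm(50), 10, 5), reps = 5), "reps")
})

test_that("VSS scores a clean one-factor structure near 1 and is monotone in complexity", {
  lam <- c(0.9, 0.85, 0.8, 0.75, 0.9)
  R <- lam %*% t(lam); diag(R) <- 1
  v <- vss(R, n = 300, m_max = 3)
  expect_gt(v["c1", "m1"], 0.98)
  ok <- !is.na(v["c1", ]) & !is.na(v["c2", ])
  expect_true(all(v["c2", ok] >= v["c1", ok] - 1e-9))
  expect_true(all(v[!is.na(v)] <= 1 + 1e-9))
})

test_that("retention rules are reported consistently by select_m", {
  z <- standardize(log(generate_dataset(factor_only_config(12, n = 250))$concentrations))
  sel <- select_m(data = z, n = nrow(z), m_max = 5, reps = 50, seed = 2)
  expect_identical(unname(sel$selected_m$bic), which.min(sel$bic_curve))
  expect_identical(unname(sel$selected_m$aic), which.min(sel$aic_curve))
  expect_identical(sel$default_m, unname(sel$selected_m$bic))
  expect_identical(unname(sel$selected_m$vss_c1), unname(which.max(sel$vss_curve["c1", ])))
  expect_true(sel$selected_m$parallel >= 0 && sel$selected_m$parallel <= 10)
})

test_that("regression factor scores track the factors they estimate", {
  # near-noiseless single factor: adequacy approaches its ceiling
  lam <- rep(0.995, 6)
  R <- lam %*% t(lam); diag(R) <- 1
  fit <- suppressWarnings(fa_fit(R, 1, n = 500))
  expect_gt(fit$score_adequacy$R2[1], 0.98)
  expect_gt(fit$score_adequacy$min_correlation[1], 0.96)

  # simulation: scores correlate with the true factors they target
  cfg <- factor_only_config(21, n = 400)
  ds <- generate_dataset(cfg)
  z <- standardize(log(ds$concentrations))
  fit3 <- suppressWarnings(fa_fit(stats::cor(z), 3, n = 400))
  sc <- factor_scores(z, fit3)
  expect_true(all(sc$adequacy$R2 >= 0 & sc$adequacy$R2 <= 1))
  cors <- abs(stats::cor(sc$scores, ds$factors_true))
  # each fitted factor matches exactly one planted factor strongly
  expect_true(all(apply(cors, 1, max) > 0.8))
})
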