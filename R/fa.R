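#' Maximum-likelihood factor analysis with oblimin rotation
#'
#' Fits an m-factor model to a correlation matrix by maximum likelihood
#' (minimizing the discrepancy `F = log|Sigma| - log|R| + tr(R Sigma^-1) - p`
#' with `Sigma = Lambda Lambda' + Psi`), then applies an oblique (oblimin)
#' rotation yielding a pattern matrix `Lambda` and factor correlation matrix
#' `Phi`. Per-variable diagnostics follow the conventions of the oblique
#' model: communality `h2 = diag(Lambda Phi Lambda')`, uniqueness
#' `u2 = 1 - h2`, Hoffman complexity `com = (sum lambda^2)^2 / sum lambda^4`
#' over the pattern row, and SS loadings per factor from the structure-matrix
#' convention `diag(Lambda' Lambda Phi)`. Uniquenesses below 0.001 (Heywood
#' cases) are floored there and recorded as a warning flag rather than
#' aborting, since small-sample fits produce them routinely.
#'
#' @param R correlation matrix (positive definite)
#' @param m number of factors; must leave non-negative model degrees of freedom
#' @param n sample count used for fit statistics
#' @return An object of class `fa_model`: `m`, `loadings` (pattern), `factor_corr`,
#'   `structure`, `h2`, `u2`, `com`, `ss_loadings`, `proportion_var`,
#'   `cumulative_var`, `unrotated`, `uniquenesses`, `heywood`, `fit`
#'   (an `fa_fit_stats`, see [fa_fit_statistics()]), `score_adequacy`, `n`.
#' @examples
#' ref <- fa_reference_solution()
#' communalities_oblique(ref$loadings, ref$factor_corr)["Zn"]  # 0.91
#' @export
fa_fit <- function(R, m, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop_dustrisk("correlation matrix is not positive definite")
  df <- fa_df(p, m)
  if (m < 1 || df < 0)
    stop_dustrisk("m = %d leaves negative degrees of freedom for p = %d", m, p)
  if (is.null(colnames(R))) dimnames(R) <- list(paste0("V", 1:p), paste0("V", 1:p))

  fit0 <- stats::factanal(covmat = R, factors = m, n.obs = n,
                          rotation = "none", control = list(lower = 0.001))
  A <- matrix(stats::loadings(fit0), p, m, dimnames = list(colnames(R), NULL))
  uniq <- fit0$uniquenesses
  heywood <- names(uniq)[uniq <= 0.001 + 1e-8]
  if (length(heywood))
    warning(sprintf("Heywood case: uniqueness floored at 0.001 for %s",
                    paste(heywood, collapse = ", ")), call. = FALSE)

  rot <- oblimin_rotate(A)
  L <- rot$loadings; Phi <- rot$Phi
  Smat <- L %*% Phi                       # structure matrix
  h2 <- rowSums((L %*% Phi) * L)          # diag(L Phi L')
  u2 <- 1 - h2
  com <- hoffman_complexity(L)
  ss <- diag(t(L) %*% L %*% Phi)
  ss <- stats::setNames(as.numeric(ss), colnames(L))
  prop <- ss / p
  fit_stats <- fa_fit_statistics(R, list(loadings_unrotated = A, uniquenesses = uniq, m = m), n)
  adequacy <- score_adequacy(R, L, Phi)
  structure(list(m = m, loadings = L, factor_corr = Phi, structure = Smat,
                 h2 = h2, u2 = u2, com = com,
                 ss_loadings = ss, proportion_var = prop,
                 cumulative_var = cumsum(prop),
                 unrotated = A, uniquenesses = uniq, heywood = heywood,
                 fit = fit_stats, score_adequacy = adequacy, n = n, p = p),
            class = "fa_model")
}

fa_df <- function(p, m) ((p - m)^2 - (p + m)) / 2

#' Hoffman complexity of loading rows
#'
#' `(sum_f lambda^2)^2 / sum_f lambda^4` per variable: 1 when a variable
#' loads on a single factor, approaching the factor count for perfectly even
#' loading.
#'
#' @param loadings variable x factor pattern matrix (or a single row)
#' @return numeric vector, one value per variable
#' @export
hoffman_complexity <- function(loadings) {
  L <- rbind(loadings)
  s2 <- rowSums(L^2)
  s4 <- rowSums(L^4)
  out <- ifelse(s4 > 0, s2^2 / s4, NA_real_)
  stats::setNames(as.numeric(out), rownames(L))
}

#' Communalities under an oblique factor model
#'
#' `h2 = diag(Lambda Phi Lambda')` — the share of each variable's variance
#' reproduced by correlated factors.
#'
#' @param loadings variable x factor pattern matrix
#' @param factor_corr factor correlation matrix `Phi`
#' @return numeric vector of communalities
#' @export
communalities_oblique <- function(loadings, factor_corr) {
  L <- rbind(loadings)
  stats::setNames(as.numeric(rowSums((L %*% factor_corr) * L)), rownames(L))
}

#' Fit statistics for a maximum-likelihood factor model
#'
#' Computes the Bartlett-corrected chi-square
#' `chi2 = (n - 1 - (2p + 5)/6 - 2m/3) * F_min`, model degrees of freedom
#' `df = ((p - m)^2 - (p + m)) / 2`, its upper-tail p-value, the root mean
#' square of off-diagonal residual correlations (RMSR), the Tucker-Lewis
#' index against the independence model, and two information-criterion pairs:
#' the degrees-of-freedom forms `BIC = chi2 - 2 df` and `AIC = chi2 + 2 df`
#' used by this package's selection rule, plus the conventional
#' sample-size-penalized variants `bic_ln_n = chi2 - df log(n)` and
#' `aic_2df = chi2 - 2 df` reported for comparison.
#'
#' @param R correlation matrix the model was fitted to
#' @param model an `fa_model`, or a list with `loadings_unrotated`,
#'   `uniquenesses` and `m`
#' @param n sample count
#' @return An object of class `fa_fit_stats`.
#' @export
fa_fit_statistics <- function(R, model, n) {
  A <- if (inherits(model, "fa_model")) model$unrotated else model$loadings_unrotated
  uniq <- model$uniquenesses
  m <- if (inherits(model, "fa_model")) model$m else model$m
  p <- ncol(R)
  df <- fa_df(p, m)
  if (df < 1) stop_dustrisk("saturated model: df = %g < 1", df)
  Sigma <- A %*% t(A) + diag(as.numeric(uniq), p)
  Fmin <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) -
    as.numeric(determinant(R, logarithm = TRUE)$modulus) +
    sum(diag(solve(Sigma, R))) - p
  Fmin <- max(Fmin, 0)
  bart <- n - 1 - (2 * p + 5) / 6 - 2 * m / 3
  chi2 <- bart * Fmin
  pval <- stats::pchisq(chi2, df, lower.tail = FALSE)
  resid <- R - Sigma
  off <- resid[lower.tri(resid)]
  rmsr <- sqrt(mean(off^2))
  # independence (null) model: Sigma0 = I, F0 = -log|R|
  F0 <- -as.numeric(determinant(R, logarithm = TRUE)$modulus)
  df0 <- p * (p - 1) / 2
  chi0 <- (n - 1 - (2 * p + 5) / 6) * F0
  tli <- ((chi0 / df0) - (chi2 / df)) / ((chi0 / df0) - 1)
  structure(list(chi_square = chi2, df = df, p_value = pval, RMSR = rmsr,
                 TLI = tli, BIC = chi2 - 2 * df, AIC = chi2 + 2 * df,
                 bic_ln_n = chi2 - df * log(n), aic_2df = chi2 - 2 * df,
                 objective = Fmin, null_chi_square = chi0, null_df = df0),
            class = "fa_fit_stats")
}

#' @export
print.fa_fit_stats <- function(x, ...) {
  cat(sprintf("chi2 = %.3f on df = %g (p = %.3f); RMSR = %.3f; TLI = %.3f\n",
              x$chi_square, x$df, x$p_value, x$RMSR, x$TLI))
  cat(sprintf("BIC (chi2 - 2df) = %.2f; AIC (chi2 + 2df) = %.2f; chi2 - df*ln(n) = %.2f\n",
              x$BIC, x$AIC, x$bic_ln_n))
  invisible(x)
}

#' @export
print.fa_model <- function(x, ...) {
  cat(sprintf("ML factor model: %d factors, %d variables (n = %d)\n", x$m, x$p, x$n))
  tab <- cbind(round(x$loadings, 2), h2 = round(x$h2, 2),
               u2 = round(x$u2, 3), com = round(x$com, 1))
  print(tab)
  cat("Factor correlations:\n"); print(round(x$factor_corr, 2))
  print(x$fit)
  invisible(x)
}

#' Parallel analysis for factor retention
#'
#' Compares the eigenvalues of the observed correlation matrix with the mean
#' eigenvalues of correlation matrices computed from standard-normal data of
#' the same dimensions. The retained count is the longest initial run of
#' observed eigenvalues exceeding their random counterparts.
#'
#' @param data site x variable matrix
#' @param reps number of random replicates (>= 20)
#' @param seed RNG seed
#' @return list with `pa_retained`, `observed_eigen`, `random_eigen_means`
#' @export
parallel_analysis <- function(data, reps = 100, seed = 1) {
  x <- as_concentration_matrix_lax(data)
  if (reps < 20) stop_dustrisk("parallel analysis needs reps >= 20")
  n <- nrow(x); p <- ncol(x)
  obs <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  rand <- with_seed(seed, {
    acc <- matrix(0, reps, p)
    for (r in seq_len(reps)) {
      z <- matrix(stats::rnorm(n * p), n, p)
      acc[r, ] <- eigen(stats::cor(z), symmetric = TRUE, only.values = TRUE)$values
    }
    acc
  })
  means <- colMeans(rand)
  k <- 0
  while (k < p && obs[k + 1] > means[k + 1]) k <- k + 1
  list(pa_retained = k, observed_eigen = obs, random_eigen_means = means)
}

#' Very simple structure (VSS) curves
#'
#' For each candidate factor count m, refits the ML model, simplifies the
#' oblique pattern matrix to its c largest-magnitude loadings per row
#' (c = 1, 2), and scores how well the simplified model reproduces the
#' off-diagonal correlations:
#' `VSS = 1 - sum offdiag((R - Ls Phi Ls')^2) / sum offdiag(R^2)`.
#' The m = 0 baseline is 0 by convention.
#'
#' @param R correlation matrix
#' @param n sample count
#' @param m_max largest factor count to evaluate (df-admissible)
#' @return matrix with rows `c1`, `c2` and one column per m
#' @export
vss <- function(R, n, m_max) {
  p <- ncol(R)
  denom <- sum(R[lower.tri(R)]^2) * 2
  out <- matrix(NA_real_, 2, m_max,
                dimnames = list(c("c1", "c2"), paste0("m", seq_len(m_max))))
  for (m in seq_len(m_max)) {
    fit <- fa_fit_quiet(R, m, n)
    if (is.null(fit)) next
    for (cc in 1:2) {
      c_eff <- min(cc, m)
      Ls <- simplify_loadings(fit$loadings, c_eff)
      res <- R - Ls %*% fit$factor_corr %*% t(Ls)
      out[cc, m] <- 1 - sum(res[lower.tri(res)]^2) * 2 / denom
    }
  }
  out
}

simplify_loadings <- function(L, c_keep) {
  Ls <- L * 0
  for (i in seq_len(nrow(L))) {
    keep <- order(abs(L[i, ]), decreasing = TRUE)[seq_len(c_keep)]
    Ls[i, keep] <- L[i, keep]
  }
  Ls
}

fa_fit_quiet <- function(R, m, n) {
  tryCatch(suppressWarnings(fa_fit(R, m, n)), error = function(e) NULL)
}

#' Factor-count selection across retention rules
#'
#' Fits models for m = 1..m_max and reports the choice of each rule: argmin
#' of `BIC = chi2 - 2 df`, argmin of `AIC = chi2 + 2 df`, parallel analysis,
#' and argmax of the VSS curves at complexity 1 and 2. The pipeline default
#' is the BIC rule.
#'
#' @param data site x variable matrix (used for parallel analysis), or `NULL`
#'   to skip the parallel-analysis rule
#' @param R correlation matrix (computed from `data` when omitted)
#' @param n sample count
#' @param m_max largest factor count to consider
#' @param reps,seed parallel-analysis settings
#' @return An object of class `fa_selection`: curves plus `selected_m` per rule
#'   and `default_m` (the BIC choice).
#' @export
select_m <- function(data = NULL, R = if (!is.null(data)) stats::cor(as_concentration_matrix_lax(data)) else NULL,
                     n, m_max = NULL, reps = 100, seed = 1) {
  if (is.null(R)) stop_dustrisk("either data or R must be supplied")
  p <- ncol(R)
  if (is.null(m_max)) m_max <- max(1, max(which(vapply(1:p, function(m) fa_df(p, m) >= 1, logical(1)))))
  aic <- bic <- rep(NA_real_, m_max)
  for (m in seq_len(m_max)) {
    fit <- fa_fit_quiet(R, m, n)
    if (!is.null(fit)) { aic[m] <- fit$fit$AIC; bic[m] <- fit$fit$BIC }
  }
  vss_curve <- vss(R, n, m_max)
  pa <- if (!is.null(data)) parallel_analysis(data, reps = reps, seed = seed) else NULL
  sel <- list(bic = which.min(bic), aic = which.min(aic),
              vss_c1 = which.max(vss_curve["c1", ]),
              vss_c2 = which.max(vss_curve["c2", ]))
  if (!is.null(pa)) sel$parallel <- pa$pa_retained
  structure(list(aic_curve = aic, bic_curve = bic, vss_curve = vss_curve,
                 parallel = pa, selected_m = sel,
                 default_m = unname(sel$bic), m_max = m_max),
            class = "fa_selection")
}

#' Regression factor scores and their adequacy
#'
#' Regression-method scores `z W` with weights `W = R^{-1} Lambda Phi`
#' (the inverse correlation matrix applied to the structure matrix). Score
#' adequacy per factor: squared multiple correlation
#' `R2 = diag(Phi Lambda' R^{-1} Lambda Phi)`, its square root (correlation
#' of scores with factors), and the minimum correlation of equally valid
#' score sets, `2 R2 - 1`.
#'
#' @param z standardized site x variable matrix
#' @param model an `fa_model` fitted on the same variables
#' @return list with `scores` (site x factor) and `adequacy` (data.frame with
#'   `correlation`, `R2`, `min_correlation` per factor)
#' @export
factor_scores <- function(z, model) {
  stopifnot(inherits(model, "fa_model"))
  z <- as_concentration_matrix_lax(z)
  R <- stats::cor(z)
  adequacy <- score_adequacy(R, model$loadings, model$factor_corr)
  W <- solve(R, model$loadings %*% model$factor_corr)
  scores <- z %*% W
  colnames(scores) <- colnames(model$loadings)
  list(scores = scores, adequacy = adequacy)
}

score_adequacy <- function(R, L, Phi) {
  Smat <- L %*% Phi
  ok <- tryCatch({ Ri_S <- solve(R, Smat); TRUE }, error = function(e) FALSE)
  if (!ok) stop_dustrisk("correlation matrix is singular; cannot compute factor scores")
  R2 <- pmin(pmax(diag(t(Smat) %*% Ri_S), 0), 1)
  data.frame(factor = colnames(L), correlation = sqrt(R2), R2 = R2,
             min_correlation = 2 * R2 - 1, row.names = NULL,
             stringsAsFactors = FALSE)
}
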