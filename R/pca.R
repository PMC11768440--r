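#' Column-standardize a concentration table
#'
#' Centers each metal column to mean zero and scales it to unit sample
#' standard deviation (n - 1 denominator). Standardization puts metals
#' measured on very different scales (percent-level Fe versus trace Cd) on a
#' common footing before any distance- or correlation-based analysis.
#'
#' @param table site x metal numeric matrix or data.frame
#' @return standardized numeric matrix with the input dimnames
#' @export
standardize <- function(table) {
  x <- as_concentration_matrix_lax(table)
  if (nrow(x) < 2L) stop_dustrisk("standardization needs at least 2 sites")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop_dustrisk("constant column(s): %s",
                  paste(colnames(x)[sds == 0], collapse = ", "))
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

# like as_concentration_matrix but without the positivity requirement
as_concentration_matrix_lax <- function(x) {
  if (is.data.frame(x)) {
    if ("site_id" %in% names(x)) {
      rn <- as.character(x$site_id)
      x <- as.matrix(x[setdiff(names(x), "site_id")])
      rownames(x) <- rn
    } else x <- as.matrix(x)
  }
  check_numeric_matrix(x, "data table")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("D", seq_len(nrow(x)))
  x
}

#' Principal component analysis on the correlation matrix
#'
#' Eigendecomposition of the sample correlation matrix of the standardized
#' variables. Scores are the projections `y = z E`; the variance fraction of
#' component j is `t_j = lambda_j / sum(lambda)`. Variable cos2 on component
#' j is the squared correlation between the variable and the j-th score
#' (`lambda_j * e_vj^2` for standardized input); individual cos2 is the
#' squared cosine of the site against its total distance from the centroid;
#' variable contributions are `100 * e_vj^2`, summing to 100 within each
#' component. The sign of each eigenvector is fixed so that its entry of
#' largest magnitude is positive.
#'
#' @param z standardized site x variable matrix (see [standardize()])
#' @return An object of class `pca_model` with elements `S` (correlation
#'   matrix), `eigenvalues`, `eigenvectors`, `scores`, `variance_fraction`,
#'   `cos2_variables`, `cos2_individuals`, `contributions`, `n`, `p`.
#' @export
pca_fit <- function(z) {
  z <- as_concentration_matrix_lax(z)
  n <- nrow(z); p <- ncol(z)
  if (n < 2L) stop_dustrisk("PCA needs at least 2 sites")
  S <- stats::cor(z)
  e <- eigen(S, symmetric = TRUE)
  E <- e$vectors
  # sign convention: dominant entry of each eigenvector positive
  for (j in seq_len(p)) {
    i <- which.max(abs(E[, j]))
    if (E[i, j] < 0) E[, j] <- -E[, j]
  }
  lambda <- pmax(e$values, 0)
  comp <- paste0("PC", seq_len(p))
  dimnames(E) <- list(colnames(z), comp)
  scores <- z %*% E
  tfrac <- lambda / sum(lambda)
  loadings <- sweep(E, 2, sqrt(lambda), "*")          # variable-score correlations
  cos2_var <- loadings^2
  row_d2 <- rowSums(scores^2)
  cos2_ind <- sweep(scores^2, 1, ifelse(row_d2 > 0, row_d2, 1), "/")
  contrib <- 100 * E^2
  structure(list(S = S, eigenvalues = stats::setNames(lambda, comp),
                 eigenvectors = E, scores = scores,
                 variance_fraction = stats::setNames(tfrac, comp),
                 cos2_variables = cos2_var, cos2_individuals = cos2_ind,
                 contributions = contrib, n = n, p = p),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA on %d x %d correlation matrix\n", x$p, x$p))
  tab <- data.frame(eigenvalue = round(x$eigenvalues, 3),
                    pct = round(100 * x$variance_fraction, 2),
                    cum_pct = round(100 * cumsum(x$variance_fraction), 2))
  print(utils::head(tab, 6))
  invisible(x)
}

#' Profile log-likelihood of a k-component PCA model
#'
#' Gaussian log-likelihood of n standardized observations under the
#' probabilistic-PCA covariance that keeps the top k eigencomponents exactly
#' and replaces the remaining p - k eigenvalues by their mean (isotropic
#' residual). With eigenvalues `l_1 >= ... >= l_p` of the correlation matrix,
#' `L_k = -(n/2) * (p*log(2*pi) + sum_{j<=k} log l_j + (p-k)*log(mean of the rest) + p)`.
#' This is the likelihood under which adding one more component is worthwhile
#' (per-component AIC) roughly when its eigenvalue exceeds `exp(-2/n)`.
#'
#' @param eigenvalues descending eigenvalues of the correlation matrix
#' @param k number of retained components, `1 <= k < p`
#' @param n sample count
#' @return scalar log-likelihood
#' @export
pca_log_likelihood <- function(eigenvalues, k, n) {
  p <- length(eigenvalues)
  if (!is_count(k) || k < 1 || k >= p) stop_dustrisk("k must satisfy 1 <= k < p")
  lam <- sort(eigenvalues, decreasing = TRUE)
  if (any(lam <= 0)) stop_dustrisk("eigenvalues must be positive for the likelihood")
  sigma2 <- mean(lam[(k + 1):p])
  -(n / 2) * (p * log(2 * pi) + sum(log(lam[seq_len(k)])) + (p - k) * log(sigma2) + p)
}

#' Component-count selection by four rules
#'
#' Applies the Kaiser rule (eigenvalue > 1, strict), the cumulative explained
#' variance rule, AIC/BIC minimization over the profile log-likelihood
#' `L_k` (`AIC_k = -2 L_k + 2k`, `BIC_k = -2 L_k + k log n`), and the
#' sequential eigenvalue-threshold forms of those criteria: keep adding
#' component k+1 while `lambda_{k+1} > exp(-2/n)` (AIC form) or
#' `lambda_{k+1} > n^(1/n)` (BIC form).
#'
#' @param model a [pca_fit()] result
#' @param n sample count (defaults to the model's)
#' @param cumvar_threshold retained cumulative variance fraction (default 0.8)
#' @return An object of class `component_selection`: list with `kaiser_k`,
#'   `cumvar_k`, `aic_curve`, `bic_curve`, `aic_k`, `bic_k`,
#'   `aic_threshold`, `bic_threshold`, `aic_threshold_k`, `bic_threshold_k`,
#'   `cumvar_threshold`, `n`.
#' @export
select_components <- function(model, n = model$n, cumvar_threshold = 0.8) {
  stopifnot(inherits(model, "pca_model"))
  if (cumvar_threshold <= 0 || cumvar_threshold > 1)
    stop_dustrisk("cumvar_threshold must be in (0, 1]")
  lam <- as.numeric(model$eigenvalues)
  p <- length(lam)
  kaiser_k <- sum(lam > 1)
  cum <- cumsum(model$variance_fraction)
  cumvar_k <- which(cum >= cumvar_threshold - 1e-12)[1]
  ks <- seq_len(p - 1)
  ll <- vapply(ks, function(k) pca_log_likelihood(lam, k, n), numeric(1))
  aic_curve <- stats::setNames(-2 * ll + 2 * ks, ks)
  bic_curve <- stats::setNames(-2 * ll + ks * log(n), ks)
  aic_thr <- exp(-2 / n)
  bic_thr <- n^(1 / n)
  seq_count <- function(thr) {
    k <- 0L
    while (k < p && lam[k + 1] > thr) k <- k + 1L
    k
  }
  structure(list(n = n, kaiser_k = kaiser_k, cumvar_k = unname(cumvar_k),
                 cumvar_threshold = cumvar_threshold,
                 aic_curve = aic_curve, bic_curve = bic_curve,
                 aic_k = ks[which.min(aic_curve)], bic_k = ks[which.min(bic_curve)],
                 aic_threshold = aic_thr, bic_threshold = bic_thr,
                 aic_threshold_k = seq_count(aic_thr),
                 bic_threshold_k = seq_count(bic_thr)),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat("Component selection:\n")
  cat(sprintf("  Kaiser (lambda > 1): %d\n", x$kaiser_k))
  cat(sprintf("  cumulative variance >= %.0f%%: %d\n", 100 * x$cumvar_threshold, x$cumvar_k))
  cat(sprintf("  AIC argmin: %d; BIC argmin: %d\n", x$aic_k, x$bic_k))
  cat(sprintf("  eigenvalue thresholds: AIC form exp(-2/n)=%.4f -> %d; BIC form n^(1/n)=%.4f -> %d\n",
              x$aic_threshold, x$aic_threshold_k, x$bic_threshold, x$bic_threshold_k))
  invisible(x)
}

#' Scree table for a fitted PCA
#'
#' @param model a [pca_fit()] result
#' @return data.frame with columns `component`, `eigenvalue`, `pct`, `cum_pct`
#' @export
scree_table <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  data.frame(component = seq_along(model$eigenvalues),
             eigenvalue = as.numeric(model$eigenvalues),
             pct = 100 * as.numeric(model$variance_fraction),
             cum_pct = 100 * cumsum(as.numeric(model$variance_fraction)))
}
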