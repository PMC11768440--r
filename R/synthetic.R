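#' Configuration for the synthetic concentration generator
#'
#' Describes a site x metal concentration matrix with the statistical
#' structure the downstream analyses assume: latent factors inducing
#' metal-metal correlations on the log scale, site clusters inducing mean
#' offsets, and independent unique noise. The default configuration mirrors
#' a 14-site, 10-metal urban-dust survey with three latent source factors
#' (a traffic/industry block Zn-Fe-Cu-Pb, a crustal block Cr-Mn-Ba, and a
#' Co-Cd-Ni block) and three site clusters of differing overall pollution
#' level.
#'
#' @param n_sites number of sites (>= 3)
#' @param metals character vector of metal names
#' @param m_true number of latent factors (1..length(metals))
#' @param loadings_true metal x factor loading matrix (log scale)
#' @param factor_corr_true factor x factor correlation matrix (symmetric,
#'   unit diagonal, positive semi-definite)
#' @param cluster_labels_true integer cluster id per site
#' @param cluster_shifts cluster x metal matrix of log-scale mean offsets
#' @param base_log_mean named log-concentration location per metal
#' @param noise_sd unique-variance standard deviation per metal (log scale,
#'   strictly positive)
#' @param lognormal if `TRUE` (default) the latent structure lives on the log
#'   scale and concentrations are exponentiated, guaranteeing positivity
#' @param seed integer seed driving the single generator stream
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 14,
                             metals = c("Ba", "Cd", "Co", "Cr", "Cu",
                                        "Fe", "Mn", "Ni", "Pb", "Zn"),
                             m_true = 3,
                             loadings_true = default_loadings(metals, m_true),
                             factor_corr_true = default_factor_corr(m_true),
                             cluster_labels_true = rep(seq_len(3), length.out = n_sites),
                             cluster_shifts = default_cluster_shifts(cluster_labels_true, metals),
                             base_log_mean = default_base_log_mean(metals),
                             noise_sd = stats::setNames(rep(0.6, length(metals)), metals),
                             lognormal = TRUE,
                             seed = 1L) {
  cfg <- list(n_sites = n_sites, metals = metals, m_true = m_true,
              loadings_true = loadings_true, factor_corr_true = factor_corr_true,
              cluster_labels_true = cluster_labels_true,
              cluster_shifts = cluster_shifts, base_log_mean = base_log_mean,
              noise_sd = noise_sd, lognormal = isTRUE(lognormal),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  p <- length(cfg$metals)
  if (!is_count(cfg$n_sites) || cfg$n_sites < 3) stop_dustrisk("n_sites must be >= 3")
  if (!is_count(cfg$m_true) || cfg$m_true < 1 || cfg$m_true > p)
    stop_dustrisk("m_true must be between 1 and the number of metals")
  L <- cfg$loadings_true
  if (!is.matrix(L) || nrow(L) != p || ncol(L) != cfg$m_true)
    stop_dustrisk("loadings_true must be a %d x %d matrix", p, cfg$m_true)
  Phi <- cfg$factor_corr_true
  if (!is.matrix(Phi) || nrow(Phi) != cfg$m_true || ncol(Phi) != cfg$m_true ||
      max(abs(Phi - t(Phi))) > 1e-10 || max(abs(diag(Phi) - 1)) > 1e-10)
    stop_dustrisk("factor_corr_true must be symmetric with unit diagonal")
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_dustrisk("factor_corr_true is not positive semi-definite (min eigenvalue %.3g)", min(ev))
  if (length(cfg$cluster_labels_true) != cfg$n_sites)
    stop_dustrisk("cluster_labels_true must have one label per site")
  k <- length(unique(cfg$cluster_labels_true))
  if (!is.matrix(cfg$cluster_shifts) || nrow(cfg$cluster_shifts) < k ||
      ncol(cfg$cluster_shifts) != p)
    stop_dustrisk("cluster_shifts must be a cluster x metal matrix")
  if (length(cfg$base_log_mean) != p) stop_dustrisk("base_log_mean must cover every metal")
  if (length(cfg$noise_sd) != p || any(!is.finite(cfg$noise_sd)) || any(cfg$noise_sd <= 0))
    stop_dustrisk("noise_sd must be strictly positive for every metal")
  invisible(cfg)
}

#' @rdname synthetic_config
#' @export
default_loadings <- function(metals, m_true = 3, strength = 0.8) {
  blocks <- list(c("Zn", "Fe", "Cu", "Pb"), c("Cr", "Mn", "Ba"), c("Co", "Cd", "Ni"))
  L <- matrix(0, length(metals), m_true, dimnames = list(metals, NULL))
  for (j in seq_len(m_true)) {
    members <- if (j <= length(blocks)) intersect(blocks[[j]], metals) else character()
    L[members, j] <- strength
  }
  # metals outside the named blocks load on factor 1 so no row is all-zero
  orphan <- rowSums(abs(L)) == 0
  L[orphan, 1] <- strength
  L
}

#' @rdname synthetic_config
#' @export
default_factor_corr <- function(m_true = 3) {
  Phi <- diag(m_true)
  if (m_true >= 2) Phi[1, 2] <- Phi[2, 1] <- 0.5
  Phi
}

#' @rdname synthetic_config
#' @export
default_cluster_shifts <- function(cluster_labels, metals, scale = 0.6) {
  k <- length(unique(cluster_labels))
  lev <- scale * rev(seq_len(k) - (k + 1) / 2)  # cluster 1 highest, equal spacing
  matrix(rep(lev, length(metals)), nrow = k,
         dimnames = list(paste0("C", seq_len(k)), metals))
}

#' @rdname synthetic_config
#' @export
default_base_log_mean <- function(metals) {
  typical <- c(Ba = 15, Cd = 0.3, Co = 2, Cr = 25, Cu = 10,
               Fe = 75, Mn = 40, Ni = 12, Pb = 8, Zn = 90)
  out <- log(ifelse(metals %in% names(typical), typical[metals], 10))
  stats::setNames(as.numeric(out), metals)
}

#' Generate a synthetic concentration dataset
#'
#' Draws site factor scores from `N(0, factor_corr_true)`, builds the
#' log-concentration of site i, metal j as
#' `base_log_mean[j] + cluster_shifts[label(i), j] + (factor_i %*% t(loadings_true))[j] + noise`,
#' and exponentiates when `lognormal` is on. Deterministic given
#' `config$seed`: the same configuration regenerates bit-identical values.
#'
#' @param config a [synthetic_config()]
#' @return An object of class `synthetic_dataset`: list with `concentrations`
#'   (site x metal matrix, mg/kg), `factors_true` (site x factor scores),
#'   `cluster_labels_true`, and the `config` echo.
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_sites; p <- length(config$metals); m <- config$m_true
  with_seed(config$seed, {
    U <- chol_psd(config$factor_corr_true)
    Fscores <- matrix(stats::rnorm(n * m), n, m) %*% U
    E <- matrix(stats::rnorm(n * p), n, p) %*% diag(config$noise_sd, p)
    logc <- matrix(rep(config$base_log_mean, each = n), n, p) +
      config$cluster_shifts[config$cluster_labels_true, , drop = FALSE] +
      Fscores %*% t(config$loadings_true) + E
    conc <- if (config$lognormal) exp(logc) else logc
    dimnames(conc) <- list(paste0("D", seq_len(n)), config$metals)
    structure(list(concentrations = conc, factors_true = Fscores,
                   cluster_labels_true = config$cluster_labels_true,
                   config = config),
              class = "synthetic_dataset")
  })
}

# Cholesky-like factor tolerating semi-definite correlation matrices.
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(v), length(v)) %*% t(e$vectors))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dust dataset: %d sites x %d metals, %d latent factors, %d clusters\n",
              nrow(x$concentrations), ncol(x$concentrations),
              x$config$m_true, length(unique(x$cluster_labels_true))))
  invisible(x)
}

#' Write a concentration table to CSV
#'
#' Emits the schema the pipeline reader expects: header `site_id,<metal1>,...`,
#' one row per site, decimal-point notation, UTF-8. Values are written at 15
#' significant digits so a write/read cycle is lossless well beyond 12
#' significant digits. Metal names containing delimiters are quoted by the
#' CSV writer.
#'
#' @param dataset a `synthetic_dataset` or a site x metal matrix
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_concentration_csv <- function(dataset, path) {
  conc <- if (inherits(dataset, "synthetic_dataset")) dataset$concentrations else dataset
  conc <- as_concentration_matrix(conc)
  if (nrow(conc) == 0L) stop_dustrisk("refusing to write an empty site list")
  df <- data.frame(site_id = rownames(conc),
                   signif(conc, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
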