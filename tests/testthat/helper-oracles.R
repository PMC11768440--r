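# Independent brute-force oracles (plain double loops) used to cross-check
# the vectorized implementations, plus small data generators.

bf_dist <- function(A, i, j) sqrt(sum((A[i, ] - A[j, ])^2))

bf_silhouette <- function(Y, labels) {
  n <- nrow(Y)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0) { s[i] <- 0; next }
    a <- mean(sapply(mates, function(j) bf_dist(Y, i, j)))
    b <- Inf
    for (g in setdiff(unique(labels), own)) {
      others <- which(labels == g)
      b <- min(b, mean(sapply(others, function(j) bf_dist(Y, i, j))))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(mean = mean(s), s = s)
}

bf_sammon <- function(X, Y) {
  n <- nrow(X)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ds <- bf_dist(X, i, j); d <- bf_dist(Y, i, j)
    num <- num + (ds - d)^2 / ds
    den <- den + ds
  }
  num / den
}

bf_kl <- function(P, Q) {
  out <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    if (P[i, j] > 0) out <- out + P[i, j] * log(P[i, j] / Q[i, j])
  out
}

bf_intra_inter <- function(Y, labels) {
  cl <- sort(unique(labels))
  intra <- sapply(cl, function(g) {
    idx <- which(labels == g)
    if (length(idx) < 2) return(0)
    v <- c()
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx))
      v <- c(v, bf_dist(Y, idx[a], idx[b]))
    mean(v)
  })
  v <- c()
  n <- nrow(Y)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (labels[i] != labels[j]) v <- c(v, bf_dist(Y, i, j))
  list(intra = stats::setNames(intra, cl), inter = if (length(v)) mean(v) else 0)
}

# Entropy (bits) of the conditional affinity row at bandwidth sigma.
bf_row_entropy <- function(d2, sigma) {
  w <- exp(-d2 / (2 * sigma^2))
  p <- w / sum(w)
  p <- p[p > 0]
  -sum(p * log2(p))
}

metals10 <- c("Ba", "Cd", "Co", "Cr", "Cu", "Fe", "Mn", "Ni", "Pb", "Zn")

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# Generator config with planted factors only (no cluster structure).
factor_only_config <- function(seed, n = 300, strength = 0.8) {
  synthetic_config(
    n_sites = n, m_true = 3,
    loadings_true = default_loadings(metals10, 3, strength),
    factor_corr_true = diag(3),
    cluster_labels_true = rep(1L, n),
    cluster_shifts = matrix(0, 1, 10, dimnames = list("C1", metals10)),
    seed = seed)
}

# Generator config with 3 planted clusters shifted by `shift_sd` noise SDs.
# Factor loadings are kept weak (0.3) so within-cluster variability is
# noise-dominated: the clusters are the structure under test here.
clustered_config <- function(seed, n = 30, shift_sd = 3, noise = 0.6) {
  labels <- rep(1:3, length.out = n)
  synthetic_config(
    n_sites = n, m_true = 3,
    loadings_true = default_loadings(metals10, 3, strength = 0.3),
    cluster_labels_true = labels,
    cluster_shifts = default_cluster_shifts(labels, metals10, scale = shift_sd * noise),
    noise_sd = stats::setNames(rep(noise, 10), metals10),
    seed = seed)
}

random_labeled_points <- function(seed, n = 10, d = 2, k = 3) {
  set.seed(seed)
  list(Y = matrix(rnorm(n * d), n, d),
       labels = sample(rep(seq_len(k), length.out = n)))
}
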