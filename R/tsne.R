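#' t-SNE hyperparameters
#'
#' @param out_dims embedding dimension (default 2)
#' @param perplexity target perplexity `Perp`, the effective neighbor count;
#'   must satisfy `1 < Perp < n`
#' @param eta learning rate of the gradient descent (default 50)
#' @param alpha momentum coefficient, in `[0, 1)`, conventionally 0.5-0.9
#' @param max_iter gradient-descent iterations (default 500)
#' @param seed RNG seed for the embedding initialization
#' @param sigma_tol bandwidth-calibration tolerance on the entropy, in bits
#' @param sigma_max_iter bisection iterations for the bandwidth search
#' @param exaggeration early-exaggeration factor applied to P for the first
#'   `exaggeration_iter` iterations; default 1 (off)
#' @param exaggeration_iter iterations under exaggeration
#' @return An object of class `tsne_params`.
#' @export
tsne_params <- function(out_dims = 2, perplexity = 3, eta = 50, alpha = 0.5,
                        max_iter = 500, seed = 1, sigma_tol = 1e-5,
                        sigma_max_iter = 200, exaggeration = 1,
                        exaggeration_iter = 0) {
  if (eta <= 0) stop_dustrisk("learning rate eta must be positive")
  if (alpha < 0 || alpha >= 1) stop_dustrisk("momentum alpha must be in [0, 1)")
  if (perplexity <= 1) stop_dustrisk("perplexity must exceed 1")
  structure(list(out_dims = out_dims, perplexity = perplexity, eta = eta,
                 alpha = alpha, max_iter = max_iter, seed = as.integer(seed),
                 sigma_tol = sigma_tol, sigma_max_iter = sigma_max_iter,
                 exaggeration = exaggeration,
                 exaggeration_iter = exaggeration_iter),
            class = "tsne_params")
}

#' Gaussian conditional affinities with perplexity calibration
#'
#' For each point i, finds the Gaussian bandwidth `sigma_i` by bisection so
#' that the Shannon entropy (bits) of the conditional distribution
#' `p_{j|i} = exp(-||x_i - x_j||^2 / (2 sigma_i^2)) / sum_k ...`
#' equals `log2(Perp)` within `sigma_tol`, i.e. the perplexity `2^H` of every
#' row equals the target.
#'
#' @param X site x variable data matrix (n >= 3)
#' @param perplexity target perplexity, `< n`
#' @param sigma_tol entropy tolerance in bits
#' @param max_iter bisection iterations per point
#' @return list with `P_conditional` (rows sum to 1, zero diagonal), `sigma`
#'   (per-point bandwidths), `entropy_bits` (achieved per-point entropies)
#' @export
conditional_affinities <- function(X, perplexity, sigma_tol = 1e-5, max_iter = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop_dustrisk("need at least 3 points")
  if (perplexity >= n) stop_dustrisk("perplexity (%g) must be below the number of samples (%d)", perplexity, n)
  D2 <- dist_matrix(X)^2
  dup <- which(D2 == 0 & upper.tri(D2), arr.ind = TRUE)
  if (nrow(dup) > 0)
    stop_dustrisk("duplicate points: rows %d and %d coincide, bandwidth calibration is impossible",
                  dup[1, 1], dup[1, 2])
  target <- log2(perplexity)
  P <- matrix(0, n, n, dimnames = dimnames(D2))
  sigma <- numeric(n)
  Hs <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    # bisection on the precision beta = 1 / (2 sigma^2)
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    for (it in seq_len(max_iter)) {
      H <- row_entropy_bits(d2, beta)
      if (abs(H - target) < sigma_tol) break
      if (H > target) {           # too spread out: increase precision
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    w <- exp(-(d2 - min(d2)) * beta)
    P[i, -i] <- w / sum(w)
    sigma[i] <- sqrt(1 / (2 * beta))
    Hs[i] <- row_entropy_bits(d2, beta)
  }
  list(P_conditional = P, sigma = sigma, entropy_bits = Hs)
}

row_entropy_bits <- function(d2, beta) {
  w <- exp(-(d2 - min(d2)) * beta)
  p <- w / sum(w)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Symmetrized joint affinities
#'
#' `P_ij = (p_{j|i} + p_{i|j}) / (2n)` — the canonical symmetric-SNE joint
#' distribution; symmetric, non-negative, summing to 1.
#'
#' @param affinities result of [conditional_affinities()], or a conditional
#'   matrix
#' @return joint probability matrix
#' @export
joint_p <- function(affinities) {
  Pc <- if (is.list(affinities)) affinities$P_conditional else affinities
  (Pc + t(Pc)) / (2 * nrow(Pc))
}

#' Low-dimensional similarities under the Cauchy kernel
#'
#' `q_ij = (1 + ||y_i - y_j||^2)^-1 / sum_{k != l} (1 + ||y_k - y_l||^2)^-1`,
#' zero diagonal. The heavy tail gives moderately distant pairs room in the
#' embedding, countering the crowding problem.
#'
#' @param Y n x d embedding coordinates
#' @return joint similarity matrix Q
#' @export
low_dim_q <- function(Y) {
  W <- 1 / (1 + dist_matrix(Y)^2)
  diag(W) <- 0
  W / sum(W)
}

#' Kullback-Leibler divergence between affinity matrices
#'
#' `sum_{i != j} P_ij log(P_ij / Q_ij)` with the convention `0 log 0 = 0`.
#' Errors when Q vanishes where P is positive.
#'
#' @param P,Q matrices of identical shape; off-diagonal entries are compared
#' @return non-negative scalar (natural log)
#' @export
kl_divergence <- function(P, Q) {
  if (!all(dim(P) == dim(Q))) stop_dustrisk("P and Q must have the same shape")
  mask <- P > 0
  if (any(Q[mask] <= 0)) stop_dustrisk("Q is zero where P is positive; KL undefined")
  sum(P[mask] * log(P[mask] / Q[mask]))
}

#' Run t-SNE by momentum gradient descent
#'
#' Embeds `X` into `out_dims` dimensions by minimizing the KL divergence
#' between the perplexity-calibrated joint affinities P and the Cauchy-kernel
#' similarities Q of the embedding. The embedding is initialized from a
#' seeded standard normal scaled by 1e-4 and updated as
#' `Y(t) = Y(t-1) - eta * grad + alpha * (Y(t-1) - Y(t-2))` with the exact
#' gradient `4 sum_j (P_ij - Q_ij) (1 + ||y_i - y_j||^2)^-1 (y_i - y_j)`.
#' Deterministic given `params$seed`.
#'
#' @param X site x variable data matrix
#' @param params a [tsne_params()] object
#' @return An object of class `tsne_embedding`: `Y` (coordinates), `kl_trace`
#'   (KL per iteration), `final_kl`, `affinities`, `params`.
#' @export
tsne_run <- function(X, params = tsne_params()) {
  stopifnot(inherits(params, "tsne_params"))
  X <- as.matrix(X)
  n <- nrow(X)
  aff <- conditional_affinities(X, params$perplexity,
                                sigma_tol = params$sigma_tol,
                                max_iter = params$sigma_max_iter)
  P <- joint_p(aff)
  Y <- with_seed(params$seed,
                 matrix(stats::rnorm(n * params$out_dims), n, params$out_dims) * 1e-4)
  Y_prev <- Y
  kl_trace <- numeric(params$max_iter)
  for (iter in seq_len(params$max_iter)) {
    Pit <- if (iter <= params$exaggeration_iter) P * params$exaggeration else P
    g <- tsne_gradient(Pit, Y)
    Y_new <- Y - params$eta * g$grad + params$alpha * (Y - Y_prev)
    Y_prev <- Y
    Y <- Y_new
    kl <- kl_divergence(P, g$Q)
    if (!is.finite(kl))
      stop_dustrisk("t-SNE diverged at iteration %d (non-finite KL)", iter)
    kl_trace[iter] <- kl
  }
  final_kl <- kl_divergence(P, low_dim_q(Y))
  rownames(Y) <- rownames(X)
  colnames(Y) <- paste0("dim", seq_len(params$out_dims))
  structure(list(Y = Y, kl_trace = kl_trace, final_kl = final_kl,
                 affinities = aff, P = P, params = params),
            class = "tsne_embedding")
}

# Exact KL gradient at Y: 4 * sum_j (P_ij - Q_ij) w_ij (y_i - y_j) with
# w_ij the Cauchy kernel. Returns the Q used so callers can reuse it.
tsne_gradient <- function(P, Y) {
  n <- nrow(Y)
  W <- 1 / (1 + dist_matrix(Y)^2)
  diag(W) <- 0
  Q <- W / sum(W)
  M <- 4 * (P - Q) * W
  grad <- diag(rowSums(M), n) %*% Y - M %*% Y
  list(grad = grad, Q = Q)
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("t-SNE embedding: %d points -> %d dims; Perp = %g; final KL = %.4f\n",
              nrow(x$Y), ncol(x$Y), x$params$perplexity, x$final_kl))
  invisible(x)
}
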