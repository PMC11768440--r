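# Gaussian-process surrogate with expected improvement, used to tune the
# t-SNE hyperparameters. Small-n BO: dense GP, anisotropic squared-exponential
# kernel on inputs rescaled to [0,1]^d, hyperparameters by marginal likelihood.

gp_kernel <- function(X1, X2, ls, sf2) {
  d <- ncol(X1)
  K <- matrix(0, nrow(X1), nrow(X2))
  for (j in seq_len(d)) K <- K + (outer(X1[, j], X2[, j], "-") / ls[j])^2
  sf2 * exp(-0.5 * K)
}

gp_fit <- function(X, y, jitter = 1e-6) {
  d <- ncol(X)
  mu <- mean(y); sdy <- stats::sd(y); if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  nll <- function(theta) {
    ls <- exp(theta[seq_len(d)]); sf2 <- exp(theta[d + 1]); sn2 <- exp(theta[d + 2])
    K <- gp_kernel(X, X, ls, sf2) + diag(sn2 + jitter, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    as.numeric(0.5 * sum(ys * alpha) + sum(log(diag(ch))))
  }
  init <- c(rep(log(0.3), d), log(1), log(1e-4))
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = c(rep(log(0.02), d), log(1e-3), log(1e-8)),
                      upper = c(rep(log(3), d), log(100), log(1)),
                      control = list(maxit = 100))
  theta <- opt$par
  ls <- exp(theta[seq_len(d)]); sf2 <- exp(theta[d + 1]); sn2 <- exp(theta[d + 2])
  K <- gp_kernel(X, X, ls, sf2) + diag(sn2 + jitter, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(X = X, mu = mu, sdy = sdy, ls = ls, sf2 = sf2, sn2 = sn2,
       chol = ch, alpha = alpha)
}

gp_predict <- function(fit, Xnew) {
  Ks <- gp_kernel(Xnew, fit$X, fit$ls, fit$sf2)
  m <- as.numeric(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(Ks))
  var <- pmax(fit$sf2 + fit$sn2 - colSums(v^2), 1e-12)
  list(mean = m * fit$sdy + fit$mu, sd = sqrt(var) * fit$sdy)
}

expected_improvement <- function(pred, incumbent, jitter = 1e-6) {
  imp <- incumbent - pred$mean - jitter
  z <- imp / pred$sd
  imp * stats::pnorm(z) + pred$sd * stats::dnorm(z)
}

#' Bayesian minimization of a black-box function
#'
#' Gaussian-process surrogate (squared-exponential kernel, marginal-likelihood
#' hyperparameters) with expected-improvement acquisition, maximized over a
#' seeded Latin-hypercube candidate set. The initial design is a space-filling
#' Latin hypercube; `init_points` rows may be supplied to force specific
#' configurations (e.g. a default setting) into the design. Deterministic
#' given `seed`.
#'
#' @param fn objective returning a finite scalar to minimize; called as
#'   `fn(x, eval_index)` where `x` is a parameter vector
#' @param lower,upper numeric bounds per dimension
#' @param budget total number of objective evaluations (>= initial design)
#' @param seed RNG seed
#' @param n_init initial-design size (default 8)
#' @param init_points optional matrix of rows to include in the initial design
#' @param n_candidates acquisition candidate count per iteration
#' @return An object of class `bayes_opt`: `best_x`, `best_objective`,
#'   `trace` (data.frame of evaluated points, objectives and evaluation
#'   seeds), `incumbent_trace`.
#' @export
bayes_optimize <- function(fn, lower, upper, budget = 30, seed = 1,
                           n_init = 8, init_points = NULL, n_candidates = 500) {
  d <- length(lower)
  if (length(upper) != d || any(upper <= lower)) stop_dustrisk("invalid bounds")
  if (budget < n_init) stop_dustrisk("budget (%d) below the initial design size (%d)", budget, n_init)
  span <- upper - lower
  n_forced <- if (is.null(init_points)) 0L else nrow(init_points)
  design <- with_seed(seed, lhs::maximinLHS(max(1, n_init - n_forced), d))
  X <- sweep(sweep(design, 2, span, "*"), 2, lower, "+")
  if (n_forced > 0) X <- rbind(matrix(init_points, ncol = d), X)[seq_len(n_init), , drop = FALSE]
  y <- numeric(0)
  for (i in seq_len(nrow(X))) y[i] <- fn(X[i, ], i)
  while (length(y) < budget) {
    i <- length(y) + 1L
    Xu <- sweep(sweep(X, 2, lower, "-"), 2, span, "/")
    cand_u <- with_seed(derive_seed(seed, i), matrix(stats::runif(n_candidates * d), ncol = d))
    fit <- tryCatch(gp_fit(Xu, y), error = function(e) NULL)
    if (is.null(fit)) {
      xu_new <- cand_u[1, ]
    } else {
      pred <- gp_predict(fit, cand_u)
      ei <- expected_improvement(pred, min(y))
      xu_new <- cand_u[which.max(ei), ]
    }
    x_new <- lower + xu_new * span
    X <- rbind(X, x_new)
    y[i] <- fn(x_new, i)
  }
  best <- which.min(y)
  trace <- data.frame(eval = seq_along(y), X, objective = y)
  names(trace)[1 + seq_len(d)] <- paste0("x", seq_len(d))
  structure(list(best_x = X[best, ], best_objective = y[best], trace = trace,
                 incumbent_trace = cummin(y), budget = budget, seed = seed,
                 lower = lower, upper = upper),
            class = "bayes_opt")
}

#' Tune t-SNE hyperparameters by Bayesian optimization
#'
#' Optimizes (perplexity, learning rate, momentum) under one of three
#' embedding-quality objectives: the final KL divergence (minimized), the
#' mean silhouette of the clustered embedding (maximized; internally
#' negated), or the Sammon mapping error (minimized). Every candidate is
#' evaluated by a full t-SNE run whose seed is derived deterministically from
#' the master seed and the evaluation index, so the objective is a
#' deterministic function of the parameters. The default t-SNE configuration
#' is included as the first point of the initial design, so the returned
#' incumbent can never be worse than the default setting under the same seed
#' policy.
#'
#' @param X data matrix to embed (standardize first for mixed-scale metals)
#' @param objective one of `"kl"`, `"silhouette"`, `"sammon"`
#' @param bounds list with elements `perplexity`, `eta`, `alpha`, each a
#'   length-2 numeric range; perplexity defaults to `[2, n-2]`, eta to
#'   `[10, 1000]`, alpha to `[0.5, 0.9]`
#' @param budget evaluation budget (default 30)
#' @param seed master seed
#' @param max_iter t-SNE iterations per evaluation
#' @param defaults a [tsne_params()] object seeding the initial design
#' @param k cluster count for the silhouette objective (`"auto"` allowed)
#' @return An object of class `tsne_opt`: fields of [bayes_optimize()] plus
#'   `best_params` (a `tsne_params`), `objective`, `eval_seeds`.
#' @export
optimize_tsne <- function(X, objective = c("kl", "silhouette", "sammon"),
                          bounds = NULL, budget = 30, seed = 1,
                          max_iter = 300, defaults = tsne_params(max_iter = max_iter),
                          k = "auto") {
  objective <- match.arg(objective)
  X <- as.matrix(X)
  n <- nrow(X)
  b <- list(perplexity = c(2, n - 2), eta = c(10, 1000), alpha = c(0.5, 0.9))
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  lower <- c(b$perplexity[1], b$eta[1], b$alpha[1])
  upper <- c(b$perplexity[2], b$eta[2], b$alpha[2])
  eval_seeds <- integer(0)
  score <- function(x, i) {
    s <- derive_seed(seed, i)
    eval_seeds[i] <<- s
    emb <- tsne_run(X, tsne_params(perplexity = x[1], eta = x[2], alpha = x[3],
                                   max_iter = max_iter, seed = s))
    switch(objective,
           kl = emb$final_kl,
           silhouette = {
             cl <- assign_clusters(emb$Y, k = k, seed = s)
             -silhouette_score(emb$Y, cl$labels)$mean
           },
           sammon = sammon_error(X, emb$Y))
  }
  default_x <- pmin(pmax(c(defaults$perplexity, defaults$eta, defaults$alpha), lower), upper)
  res <- bayes_optimize(score, lower, upper, budget = budget, seed = seed,
                        init_points = matrix(default_x, nrow = 1))
  res$best_params <- tsne_params(perplexity = res$best_x[1], eta = res$best_x[2],
                                 alpha = res$best_x[3], max_iter = max_iter,
                                 seed = eval_seeds[which.min(res$trace$objective)])
  res$objective <- objective
  res$eval_seeds <- eval_seeds
  names(res$trace)[2:4] <- c("perplexity", "eta", "alpha")
  class(res) <- c("tsne_opt", class(res))
  res
}

#' @export
print.bayes_opt <- function(x, ...) {
  cat(sprintf("Bayesian optimization: %d evaluations; best objective %.6g\n",
              nrow(x$trace), x$best_objective))
  cat("  best x:", paste(signif(x$best_x, 5), collapse = ", "), "\n")
  invisible(x)
}
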