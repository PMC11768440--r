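# Oblique rotation by the gradient-projection algorithm (quartimin / oblimin
# with gamma = 0). Works directly on the unrotated loading matrix; returns the
# pattern matrix and the factor correlation matrix Phi = T'T.

quartimin_criterion <- function(L) {
  m <- ncol(L)
  L2 <- L^2
  N <- matrix(1, m, m) - diag(m)
  list(f = sum(L2 * (L2 %*% N)) / 4, Gq = L * (L2 %*% N))
}

# A: p x m unrotated loadings. Random restarts guard against local optima;
# restarts use seeded random orthogonal starts so the rotation is deterministic.
oblimin_rotate <- function(A, eps = 1e-6, maxit = 1000, n_starts = 10, seed = 42) {
  m <- ncol(A)
  if (m == 1L) {
    L1 <- A
    if (L1[which.max(abs(L1)), 1] < 0) L1 <- -L1
    dimnames(L1) <- list(rownames(A), "F1")
    return(list(loadings = L1, Phi = matrix(1, 1, 1, dimnames = list("F1", "F1")),
                converged = TRUE, criterion = 0))
  }
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      T0 <- if (s == 1L) diag(m) else {
        Q <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
        # normalize columns so diag(T'T) = 1 (oblique constraint)
        sweep(Q, 2, sqrt(colSums(Q^2)), "/")
      }
      res <- gpa_oblq(A, T0, eps = eps, maxit = maxit)
      if (is.null(best) || res$f < best$f) best <- res
    }
  })
  L <- best$loadings
  Phi <- best$Phi
  # order factors by sum-of-squares of pattern loadings, descending
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  # sign convention: dominant loading of each factor positive
  for (j in seq_len(m)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]
      Phi[, j] <- -Phi[, j]
    }
  }
  dimnames(Phi) <- list(paste0("F", seq_len(m)), paste0("F", seq_len(m)))
  dimnames(L) <- list(rownames(A), paste0("F", seq_len(m)))
  list(loadings = L, Phi = Phi, converged = best$converged, criterion = best$f)
}

gpa_oblq <- function(A, Tmat, eps = 1e-6, maxit = 1000) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- quartimin_criterion(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (i in 0:20) {
      X <- Tmat - al * Gp
      Tt <- sweep(X, 2, sqrt(colSums(X^2)), "/")
      Ti_t <- solve(Tt)
      Lt <- A %*% t(Ti_t)
      vgt <- quartimin_criterion(Lt)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt; Ti <- Ti_t; L <- Lt; f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% Ti)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, f = f, converged = converged)
}
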