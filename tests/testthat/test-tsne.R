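test_that("perplexity calibration hits the target entropy", {
  # equilateral triangle: both neighbors equidistant, Perp = 2 forces 0.5/0.5
  X <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  aff <- conditional_affinities(X, perplexity = 2)
  expect_equal(unname(aff$P_conditional[1, 2:3]), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(unname(diag(aff$P_conditional)), rep(0, 3))
  expect_equal(rowSums(aff$P_conditional), rep(1, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(aff$entropy_bits, rep(1, 3), tolerance = 1e-5)  # 2^H = 2

  # asymmetric 1-D instance: achieved entropies equal log2(Perp) = 1 bit
  X2 <- matrix(c(0, 1, 3), 3, 1)
  a2 <- conditional_affinities(X2, perplexity = 2)
  expect_equal(a2$entropy_bits, rep(1, 3), tolerance = 1e-5)

  # bisection agrees with a brute-force bandwidth grid search
  set.seed(5)
  X3 <- matrix(rnorm(20), 10, 2)
  a3 <- conditional_affinities(X3, perplexity = 4)
  D2 <- as.matrix(dist(X3))^2
  for (i in 1:10) {
    grid <- exp(seq(log(1e-3), log(1e3), length.out = 20000))
    H <- vapply(grid, function(s) bf_row_entropy(D2[i, -i], s), numeric(1))
    s_star <- grid[which.min(abs(H - log2(4)))]
    expect_equal(a3$sigma[i], s_star, tolerance = 1e-3)
    expect_equal(bf_row_entropy(D2[i, -i], a3$sigma[i]), log2(4), tolerance = 1e-4)
  }
  expect_error(conditional_affinities(X3, perplexity = 10), "perplexity")
  expect_error(conditional_affinities(rbind(c(0, 0), c(0, 0), c(1, 1)), 2),
               "rows 1 and 2")
})

test_that("joint affinities are the symmetrized conditionals", {
  # symmetric conditional (equilateral) collapses to conditional / n
  X <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  aff <- conditional_affinities(X, 2)
  P <- joint_p(aff)
  expect_equal(P, aff$P_conditional / 3, tolerance = 1e-8)
  expect_equal(sum(P), 1, tolerance = 1e-10)
  expect_equal(P, t(P))
  # hand-computed asymmetric case
  Pc <- rbind(c(0, 0.7, 0.3), c(0.2, 0, 0.8), c(0.5, 0.5, 0))
  expect_equal(joint_p(Pc), (Pc + t(Pc)) / 6, tolerance = 1e-15)
})

test_that("the Cauchy kernel similarities follow the closed form", {
  Yc <- matrix(1, 3, 2)
  Q <- low_dim_q(Yc)
  expect_equal(Q[upper.tri(Q) | lower.tri(Q)], rep(1 / 6, 6), tolerance = 1e-15)
  expect_equal(unname(diag(Q)), rep(0, 3))

  Y <- matrix(c(0, 1, 3), 3, 1)
  W <- 1 / (1 + as.matrix(dist(Y))^2); diag(W) <- 0
  expect_equal(low_dim_q(Y), W / sum(W), tolerance = 1e-12)
  # shrinking all distances raises every kernel term
  expect_true(all(low_dim_q(Y / 2)[upper.tri(W)] * 0 + (1 / (1 + as.matrix(dist(Y / 2))^2))[upper.tri(W)]
                  > (1 / (1 + as.matrix(dist(Y))^2))[upper.tri(W)]))
})

test_that("KL divergence satisfies Gibbs' inequality and the hand example", {
  P <- matrix(c(0, .5, .5, 0), 2, 2)
  expect_equal(kl_divergence(P, P), 0)
  Q <- matrix(c(0, .9, .1, 0), 2, 2)
  expect_equal(kl_divergence(P, Q), 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-12)
  expect_equal(kl_divergence(P, Q), 0.5108, tolerance = 1e-4)
  set.seed(7)
  for (r in 1:100) {
    n <- sample(3:6, 1)
    p <- matrix(rexp(n * n), n, n); diag(p) <- 0; p <- p / sum(p)
    q <- matrix(rexp(n * n), n, n); diag(q) <- 0; q <- q / sum(q)
    expect_gte(kl_divergence(p, q), -1e-12)
    expect_equal(kl_divergence(p, q), bf_kl(p, q), tolerance = 1e-12)
  }
  expect_error(kl_divergence(P, matrix(c(0, 1, 0, 0), 2, 2)), "zero")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(11)
  for (r in 1:5) {
    X <- matrix(rnorm(6 * 3), 6, 3)
    P <- joint_p(conditional_affinities(X, 3))
    Y <- matrix(rnorm(12, sd = 0.5), 6, 2)
    g <- dustrisk:::tsne_gradient(P, Y)$grad
    eps <- 1e-6
    num <- Y * 0
    for (i in 1:6) for (d in 1:2) {
      Yp <- Y; Yp[i, d] <- Y[i, d] + eps
      Ym <- Y; Ym[i, d] <- Y[i, d] - eps
      num[i, d] <- (kl_divergence(P, low_dim_q(Yp)) -
                    kl_divergence(P, low_dim_q(Ym))) / (2 * eps)
    }
    expect_equal(g, num, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("momentum descent is deterministic, decreases KL, and respects geometry", {
  z <- standardize(generate_dataset(synthetic_config(seed = 14))$concentrations)
  p1 <- tsne_params(max_iter = 300, seed = 5)
  e1 <- tsne_run(z, p1)
  e2 <- tsne_run(z, p1)
  expect_identical(e1$Y, e2$Y)
  expect_true(all(is.finite(e1$kl_trace)))
  expect_gte(e1$final_kl, 0)

  # descent from the initial configuration across several datasets
  for (s in 1:5) {
    zz <- standardize(generate_dataset(synthetic_config(seed = 100 + s))$concentrations)
    e <- tsne_run(zz, tsne_params(max_iter = 500, eta = 50, alpha = 0.5, seed = s))
    expect_lte(e$final_kl, e$kl_trace[1])
  }

  # rigid rotation of the input: the affinities are exactly equivariant, and
  # the KL trace matches over a horizon short enough that floating-point
  # noise has not been amplified by the momentum dynamics
  set.seed(2); Q <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  PA <- joint_p(conditional_affinities(z, 3))
  PB <- joint_p(conditional_affinities(z %*% Q, 3))
  expect_equal(PA, PB, tolerance = 1e-10, ignore_attr = TRUE)
  eA <- tsne_run(z, tsne_params(max_iter = 30, seed = 5))
  eB <- tsne_run(z %*% Q, tsne_params(max_iter = 30, seed = 5))
  expect_lt(max(abs(eA$kl_trace - eB$kl_trace)), 1e-8)

  # two well-separated groups stay separated in the embedding
  set.seed(9)
  X <- rbind(matrix(rnorm(7 * 3, 0, 0.5), 7, 3),
             matrix(rnorm(7 * 3, 20, 0.5), 7, 3))
  emb <- tsne_run(X, tsne_params(perplexity = 4, max_iter = 500, seed = 1))
  lab <- rep(1:2, each = 7)
  dd <- bf_intra_inter(emb$Y, lab)
  expect_lt(mean(dd$intra), dd$inter)
})
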