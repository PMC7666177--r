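test_that("objective evaluates hand-computed cases", {
  # two centers at distance 1, samples sitting exactly on their centers,
  # perfect reconstruction: only the tree term is nonzero and the symmetric
  # double-count cancels the 1/2
  W <- diag(4)[, 1:2]
  Y <- rbind(c(0, 1), c(0, 0))
  Z <- Y
  X <- W %*% Z
  R <- diag(2)
  B <- matrix(c(0, 1, 1, 0), 2)
  params <- ddrtree_params(lambda = 1, gamma = 3, sigma = 0.5)
  model <- list(W = W, Z = Z, Y = Y, B = B, R = R)
  expect_equal(ddrtree_objective(X, model, params), 1)
  # lambda = gamma = 0 isolates the reconstruction term (gamma must stay
  # positive in the constructor, so evaluate the term directly)
  set.seed(1)
  X2 <- matrix(rnorm(8), 4, 2)
  model2 <- list(W = W, Z = crossprod(W, X2), Y = Y, B = B, R = R)
  p0 <- ddrtree_params(lambda = 0, gamma = 1e-12, sigma = 0.5)
  expect_equal(ddrtree_objective(X2, model2, p0),
               sum((X2 - W %*% crossprod(W, X2))^2), tolerance = 1e-6)
  # uniform soft assignment: entropy term is gamma * sigma * N * log(1/K)
  K <- 4; N <- 3
  Yk <- matrix(0, 2, K)
  Zu <- matrix(0, 2, N)
  Ru <- matrix(1 / K, N, K)
  Bu <- update_B(matrix(rnorm(2 * K), 2, K))
  pu <- ddrtree_params(lambda = 0, gamma = 2, sigma = 0.3)
  Xu <- W %*% Zu
  expect_equal(ddrtree_objective(Xu, list(W = W, Z = Zu, Y = Yk, B = Bu,
                                          R = Ru), pu),
               2 * 0.3 * N * log(1 / K))
})

test_that("soft assignment matches its closed form and limits", {
  Z <- matrix(c(0, 0), 2, 1)
  Y <- rbind(c(-1, 1), c(0, 0))
  expect_equal(unname(update_R(Z, Y, sigma = 0.7)[1, ]), c(0.5, 0.5))
  # squared distances (0, 2 sigma) give (1, e^-2) normalized
  s <- 0.37
  Y2 <- rbind(c(0, sqrt(2 * s)), c(0, 0))
  r <- update_R(Z, Y2, s)[1, ]
  expect_equal(unname(r), c(1, exp(-2)) / (1 + exp(-2)), tolerance = 1e-12)
  # tiny bandwidth: one-hot at the nearest center
  Y3 <- rbind(c(0.5, 2), c(0, 0))
  expect_equal(unname(update_R(Z, Y3, 1e-8)[1, ]), c(1, 0))
  # rows always sum to one, even for extreme distances
  set.seed(2)
  Rbig <- update_R(matrix(rnorm(20) * 100, 2, 10),
                   matrix(rnorm(12) * 100, 2, 6), 1e-3)
  expect_equal(rowSums(Rbig), rep(1, 10), tolerance = 1e-12)
  expect_true(all(Rbig >= 0))
})

test_that("spanning-tree update is the exact MST with deterministic ties", {
  # collinear centers: nearest-neighbour chain
  Y <- rbind(c(0, 1, 2.5), c(0, 0, 0))
  B <- update_B(Y)
  expect_equal(B[1, 2], 1)
  expect_equal(B[2, 3], 1)
  expect_equal(B[1, 3], 0)
  expect_equal(sum(B) / 2, 2)
  expect_equal(update_B(matrix(0, 2, 1)), matrix(0, 1, 1))
  # exhaustive enumeration oracle over all labelled spanning trees on K = 6
  for (s in 1:5) {
    set.seed(s)
    Y6 <- matrix(rnorm(12), 2, 6)
    B6 <- update_B(Y6)
    d2 <- as.matrix(dist(t(Y6)))^2
    expect_equal(sum(B6 * d2) / 2, enumerate_mst_weight(Y6), tolerance = 1e-10)
    # independent library cross-check
    g <- igraph::graph_from_adjacency_matrix(d2, mode = "undirected",
                                             weighted = TRUE)
    ig <- igraph::mst(g)
    expect_equal(sum(B6 * d2) / 2, sum(igraph::E(ig)$weight),
                 tolerance = 1e-10)
  }
})

test_that("center update solves its stationarity system exactly", {
  # K = 1: the single center is the mean of the latent points
  set.seed(3)
  Z <- matrix(rnorm(20), 2, 10)
  R1 <- matrix(1, 10, 1)
  Y1 <- update_Y(Z, R1, matrix(0, 1, 1), lambda = 4, gamma = 2)
  expect_equal(as.numeric(Y1), rowMeans(Z), tolerance = 1e-10)
  # lambda = 0: decoupled soft-weighted means
  R <- exp(matrix(rnorm(40), 10, 4)); R <- R / rowSums(R)
  B <- update_B(matrix(rnorm(8), 2, 4))
  Y0 <- update_Y(Z, R, B, lambda = 0, gamma = 5)
  expected <- sweep(Z %*% R, 2, colSums(R), `/`)
  expect_equal(Y0, expected, tolerance = 1e-10)
  # random case: residual of the linear system vanishes
  lambda <- 3; gamma <- 1.5
  Yr <- update_Y(Z, R, B, lambda, gamma)
  L <- diag(rowSums(B)) - B
  resid <- Yr %*% (lambda * L + gamma * diag(colSums(R))) - gamma * Z %*% R
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("latent update matches its closed form and limits", {
  set.seed(4)
  D <- 12; N <- 6; K <- 3
  X <- matrix(rnorm(D * N), D, N)
  W <- qr.Q(qr(matrix(rnorm(D * 2), D, 2)))
  Y <- matrix(rnorm(2 * K), 2, K)
  R <- exp(matrix(rnorm(N * K), N, K)); R <- R / rowSums(R)
  expect_equal(update_Z(X, W, Y, R, gamma = 1),
               (crossprod(W, X) + Y %*% t(R)) / 2, tolerance = 1e-12)
  expect_equal(update_Z(X, W, Y, R, gamma = 1e-12), crossprod(W, X),
               tolerance = 1e-8)
  expect_equal(update_Z(X, W, Y, R, gamma = 1e12), Y %*% t(R),
               tolerance = 1e-8)
})

test_that("Procrustes loading update maximizes the trace objective", {
  set.seed(5)
  D <- 20; N <- 8; d <- 3
  Z <- matrix(rnorm(d * N), d, N)
  Q <- qr.Q(qr(matrix(rnorm(D * d), D, d)))
  # exact factorization: W recovers Q on the span of Z
  X <- Q %*% Z
  W <- update_W(X, Z, d)
  expect_equal(W %*% Z, X, tolerance = 1e-10)
  # random case: no random orthonormal frame does better, and the
  # reconstruction term does not increase
  X2 <- matrix(rnorm(D * N), D, N)
  W2 <- update_W(X2, Z, d)
  expect_equal(crossprod(W2), diag(d), tolerance = 1e-10)
  tr_opt <- sum(diag(crossprod(W2, X2 %*% t(Z))))
  worse <- vapply(1:500, function(i) {
    Wr <- qr.Q(qr(matrix(rnorm(D * d), D, d)))
    sum(diag(crossprod(Wr, X2 %*% t(Z))))
  }, numeric(1))
  expect_true(all(worse <= tr_opt + 1e-8))
  before <- sum((X2 - Q %*% Z)^2)
  after <- sum((X2 - W2 %*% Z)^2)
  expect_lte(after, before + 1e-8)
})

test_that("initialization is deterministic and rotation equivariant", {
  co <- fixture_path_cohort()
  X <- co$log_expression
  p <- ddrtree_params(seed = 3)
  m1 <- ddrtree_initialize(X, p)
  m2 <- ddrtree_initialize(X, p)
  expect_identical(m1$Z, m2$Z)
  expect_identical(m1$Y, m2$Y)
  # rank-2 noiseless input reconstructs exactly at initialization
  tr <- generate_tree_topology("path")
  lat <- sample_latent_positions(tr, 40, seed = 8)
  noiseless <- generate_expression(lat$positions, lat$truth, n_genes = 80,
                                   frac_increasing = 0, frac_decreasing = 0,
                                   frac_branch_specific = 0,
                                   noise_sd = 1e-12, seed = 8)
  X0 <- noiseless$log_expression
  m0 <- ddrtree_initialize(X0, ddrtree_params(seed = 1))
  Xc <- X0 - rowMeans(X0)
  expect_lt(sum((Xc - m0$W %*% m0$Z)^2), 1e-12 * sum(Xc^2) + 1e-8)
  # rotating the gene space leaves the latent geometry unchanged
  set.seed(9)
  Q <- qr.Q(qr(matrix(rnorm(nrow(X)^2), nrow(X))))
  mrot <- ddrtree_initialize(Q %*% X, p)
  # Z is identified up to sign of the singular vectors
  align <- sign(diag(cor(t(m1$Z), t(mrot$Z))))
  expect_equal(mrot$Z * align, m1$Z, tolerance = 1e-6)
  expect_error(ddrtree_initialize(X, ddrtree_params(K = ncol(X) + 1)),
               "exceeds")
})

test_that("fitting is monotone, convergent and respects the stopping rule", {
  co <- fixture_path_cohort()
  fit <- fixture_path_fit()
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  expect_true(fit$converged)
  # infinite tolerance stops after exactly one sweep
  one <- ddrtree_fit(co$log_expression, ddrtree_params(tol = Inf, seed = 42))
  expect_equal(one$n_iter, 1L)
  expect_length(one$objective_trace, 2L)
  # same seed reproduces the fit bit for bit
  again <- ddrtree_fit(co$log_expression, ddrtree_params(seed = 42))
  expect_identical(fit$Z, again$Z)
  expect_identical(fit$B, again$B)
})

test_that("fitted models satisfy every structural constraint", {
  fit <- fixture_path_fit()
  K <- ncol(fit$Y)
  expect_lt(max(abs(crossprod(fit$W) - diag(2))), 1e-8)
  expect_lt(max(abs(rowSums(fit$R) - 1)), 1e-10)
  expect_true(all(fit$R >= 0))
  expect_equal(sum(fit$B) / 2, K - 1)
  g <- igraph::graph_from_adjacency_matrix(fit$B != 0, mode = "undirected")
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::gsize(g), K - 1)   # connected + K-1 edges = acyclic
})

test_that("rescaling the data reproduces the latent geometry up to scale", {
  co <- fixture_path_cohort()
  X <- co$log_expression
  c0 <- 2
  # every quadratic term scales as c^2; rescaling the entropy bandwidth by
  # c^2 makes the whole objective scale exactly, so the latent geometry is
  # reproduced up to the factor c
  base <- ddrtree_fit(X, ddrtree_params(lambda = 100, gamma = 10,
                                        sigma = 1e-3, seed = 1,
                                        max_iter = 15, tol = 1e-12))
  scaled <- ddrtree_fit(c0 * X, ddrtree_params(lambda = 100, gamma = 10,
                                               sigma = c0^2 * 1e-3, seed = 1,
                                               max_iter = 15, tol = 1e-12))
  expect_equal(scaled$Z, c0 * base$Z, tolerance = 1e-6)
  expect_equal(scaled$objective_trace, c0^2 * base$objective_trace,
               tolerance = 1e-6)
})
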