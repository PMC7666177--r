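# Shared fixtures, built in code and memoized per test run.

memo <- local({
  cache <- new.env(parent = emptyenv())
  function(key, fn) {
    if (!exists(key, envir = cache)) assign(key, fn(), envir = cache)
    get(key, envir = cache)
  }
})

# small path-topology cohort for fast fit-based tests
fixture_path_cohort <- function() memo("path_cohort", function() {
  simulate_cohort(n_samples = 80, n_genes = 150, topology = "path",
                  plant_resistant = FALSE, seed = 42)
})

fixture_path_fit <- function() memo("path_fit", function() {
  co <- fixture_path_cohort()
  ddrtree_fit(co$log_expression, ddrtree_params(seed = 42))
})

# toy principal graph: path of centers at x = 0, 1, 2 (unit edges)
toy_path_graph <- function(xs = c(0, 1, 2)) {
  K <- length(xs)
  B <- matrix(0, K, K)
  for (k in seq_len(K - 1)) B[k, k + 1] <- B[k + 1, k] <- 1
  build_principal_graph(list(Y = rbind(xs, rep(0, K)), B = B))
}

# star graph: hub at origin, arms along given angles with given lengths,
# n vertices per arm (hub shared)
toy_star_graph <- function(arm_lengths, n_per_arm = 3) {
  tree <- NULL
  angs <- seq(0, 2 * pi, length.out = length(arm_lengths) + 1)[-1]
  verts <- matrix(c(0, 0), 1, 2)
  edges <- NULL
  for (a in seq_along(arm_lengths)) {
    step <- arm_lengths[a] / (n_per_arm - 1)
    prev <- 1L
    for (i in seq_len(n_per_arm - 1)) {
      verts <- rbind(verts, i * step * c(cos(angs[a]), sin(angs[a])))
      edges <- rbind(edges, c(prev, nrow(verts)))
      prev <- nrow(verts)
    }
  }
  K <- nrow(verts)
  B <- matrix(0, K, K)
  B[edges] <- 1
  B <- B + t(B)
  build_principal_graph(list(Y = t(verts), B = (B > 0) * 1))
}

# random valid optimizer state for block-monotonicity checks
random_model_state <- function(seed, D = 30, N = 15, K = 5, d = 2) {
  set.seed(seed)
  X <- matrix(rnorm(D * N), D, N)
  X <- X - rowMeans(X)
  W <- qr.Q(qr(matrix(rnorm(D * d), D, d)))
  Z <- matrix(rnorm(d * N), d, N)
  Y <- matrix(rnorm(d * K), d, K)
  R <- exp(matrix(rnorm(N * K), N, K))
  R <- R / rowSums(R)
  B <- update_B(Y + matrix(rnorm(d * K), d, K))  # a valid but non-optimal tree
  list(X = X, model = list(W = W, Z = Z, Y = Y, B = B, R = R))
}

# exhaustive minimum spanning-tree weight by Pruefer-sequence enumeration
enumerate_mst_weight <- function(Y) {
  K <- ncol(Y)
  stopifnot(K >= 3, K <= 7)
  d2 <- as.matrix(dist(t(Y)))^2
  seqs <- expand.grid(rep(list(seq_len(K)), K - 2))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    prf <- as.integer(seqs[r, ])
    degree <- rep(1L, K) + tabulate(prf, K)
    w <- 0
    pr <- prf
    for (v in pr) {
      leaf <- which(degree == 1L)[1]
      w <- w + d2[leaf, v]
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    w <- w + d2[last[1], last[2]]
    best <- min(best, w)
  }
  best
}

# brute-force Benjamini-Hochberg step-up on a p-vector
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}
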