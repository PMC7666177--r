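# Reverse graph embedding with a spanning-tree constraint, fitted by exact
# block-coordinate descent.
#
# The objective over W (genes x d, orthonormal columns), Z (d x N latent
# coordinates), Y (d x K centers), B (K x K spanning-tree adjacency) and R
# (N x K soft assignments, rows on the simplex) is
#
#   J = sum_i ||x_i - W z_i||^2
#     + (lambda/2) sum_{k,k'} b_{kk'} ||W y_k - W y_k'||^2
#     + gamma [ sum_{i,k} r_{ik} ||z_i - y_k||^2 + sigma r_{ik} log r_{ik} ]
#
# subject to B a spanning tree, W'W = I, R row-stochastic. Each block has a
# closed-form exact minimizer, so the sweep (R, B, Y, Z, W) is monotone.

#' Hyperparameters for the principal-tree fit
#'
#' @param d latent dimension (default 2: the tree is embedded in the plane).
#' @param K number of cluster centers; default one center per sample
#'   (`K = N`, chosen at fit time when `NULL`), the reference convention
#'   for this family of algorithms — fewer centers coarsen the tree and
#'   pile samples onto leaf vertices.
#' @param lambda tree-smoothness weight; default `5 * N` chosen at fit time
#'   when `NULL`.
#' @param gamma clustering weight (> 0).
#' @param sigma entropy bandwidth of the soft assignment (> 0).
#' @param max_iter maximum number of block sweeps.
#' @param tol relative objective-change stopping tolerance.
#' @param seed integer seed (center initialization).
#' @return a validated `ddrtree_params` list.
#' @export
ddrtree_params <- function(d = 2L, K = NULL, lambda = NULL, gamma = 10,
                           sigma = 1e-3, max_iter = 100L, tol = 1e-5,
                           seed = 1L) {
  if (d < 1) stop_config("d must be >= 1")
  if (!is.null(K) && K < 1) stop_config("K must be >= 1")
  if (!is.null(lambda) && lambda < 0) stop_config("lambda must be >= 0")
  if (gamma <= 0) stop_config("gamma must be > 0")
  if (sigma <= 0) stop_config("sigma must be > 0")
  if (tol <= 0) stop_config("tol must be > 0")
  structure(list(d = as.integer(d), K = K, lambda = lambda, gamma = gamma,
                 sigma = sigma, max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "ddrtree_params")
}

resolve_params <- function(params, N) {
  if (is.null(params$K)) params$K <- N
  params$K <- as.integer(params$K)
  if (is.null(params$lambda)) params$lambda <- 5 * N
  params
}

# squared Euclidean distances between columns of A (d x n) and B (d x m)
cross_dist2 <- function(A, B) {
  d2 <- outer(colSums(A^2), colSums(B^2), `+`) - 2 * crossprod(A, B)
  pmax(d2, 0)
}

#' Objective value of the principal-tree fit
#'
#' Evaluates the reverse-graph-embedding objective at a model state, with
#' the `0 * log 0 = 0` convention in the entropy term.
#'
#' @param X genes x samples matrix (gene-centered, as fitted).
#' @param model a `latent_tree_model` (or any list with W, Z, Y, B, R).
#' @param params a `ddrtree_params` with `lambda`, `gamma`, `sigma` set.
#' @return the scalar objective J.
#' @export
ddrtree_objective <- function(X, model, params) {
  W <- model$W; Z <- model$Z; Y <- model$Y; B <- model$B; R <- model$R
  check_model_constraints(model)
  term1 <- sum((X - W %*% Z)^2)
  dy2 <- cross_dist2(Y, Y)              # ||Wy_k - Wy_k'||^2 = ||y_k - y_k'||^2
  term2 <- params$lambda / 2 * sum(B * dy2)
  dzy2 <- cross_dist2(Z, Y)
  term3 <- params$gamma * (sum(R * dzy2) + params$sigma * sum(xlogx(R)))
  term1 + term2 + term3
}

check_model_constraints <- function(model, tol_orth = 1e-8, tol_row = 1e-10) {
  W <- model$W; R <- model$R; B <- model$B
  if (max(abs(crossprod(W) - diag(ncol(W)))) > tol_orth)
    stop_config("W columns are not orthonormal")
  if (any(R < 0) || max(abs(rowSums(R) - 1)) > tol_row)
    stop_config("R rows must be nonnegative and sum to 1")
  check_spanning_tree(B)
  invisible(TRUE)
}

check_spanning_tree <- function(B) {
  K <- nrow(B)
  if (!isTRUE(all.equal(B, t(B)))) stop_config("B must be symmetric")
  n_edges <- sum(B[upper.tri(B)] != 0)
  if (K == 1L) {
    if (n_edges != 0) stop_config("B for K = 1 must be empty")
    return(invisible(TRUE))
  }
  if (n_edges != K - 1L) stop_config("B must have exactly K - 1 edges")
  g <- igraph::graph_from_adjacency_matrix(B != 0, mode = "undirected")
  if (!igraph::is_connected(g)) stop_config("B must be connected")
  invisible(TRUE)
}

#' Soft-assignment update
#'
#' Exact minimizer of the clustering-plus-entropy term in R:
#' `r_ik = exp(-||z_i - y_k||^2 / sigma)`, row-normalized (computed with a
#' row-max shift for overflow safety).
#'
#' @param Z d x N latent coordinates.
#' @param Y d x K centers.
#' @param sigma entropy bandwidth (> 0).
#' @return N x K row-stochastic matrix.
#' @export
update_R <- function(Z, Y, sigma) {
  stopifnot(sigma > 0)
  logits <- -cross_dist2(Z, Y) / sigma
  shifted <- logits - apply(logits, 1, max)
  E <- exp(shifted)
  E / rowSums(E)
}

#' Spanning-tree update
#'
#' Exact minimizer of the tree term over spanning trees: the minimum
#' spanning tree of the complete graph on centers with squared Euclidean
#' edge weights. Prim's algorithm with deterministic lexicographic
#' tie-breaking (lowest vertex index first).
#'
#' @param Y d x K centers.
#' @return K x K symmetric binary adjacency with K - 1 edges.
#' @export
update_B <- function(Y) {
  K <- ncol(Y)
  B <- matrix(0, K, K)
  if (K <= 1L) return(B)
  d2 <- cross_dist2(Y, Y)
  in_tree <- c(TRUE, rep(FALSE, K - 1))
  # best[v]: cheapest known connection cost of v into the tree; via[v]: by whom
  best <- d2[1, ]
  via <- rep(1L, K)
  for (step in seq_len(K - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]   # which.min: first minimum = lowest index
    B[v, via[v]] <- B[via[v], v] <- 1
    in_tree[v] <- TRUE
    upd <- !in_tree & d2[v, ] < best
    best[upd] <- d2[v, upd]
    via[upd] <- v
  }
  B
}

#' Center update
#'
#' Exact minimizer of the objective in Y given the rest: solves
#' `Y (lambda L + gamma Gamma) = gamma Z R` where `L = diag(B 1) - B` is the
#' tree Laplacian and `Gamma = diag(R^T 1)`; the system matrix is symmetric
#' positive definite.
#'
#' @param Z d x N latent coordinates.
#' @param R N x K soft assignments.
#' @param B K x K spanning-tree adjacency.
#' @param lambda,gamma objective weights.
#' @return d x K center matrix.
#' @export
update_Y <- function(Z, R, B, lambda, gamma) {
  L <- diag(rowSums(B), nrow(B)) - B
  M <- lambda * L + gamma * diag(colSums(R), ncol(R))
  rhs <- gamma * (Z %*% R)              # d x K
  t(solve(M, t(rhs)))
}

#' Latent-coordinate update
#'
#' Exact minimizer in Z given orthonormal W:
#' `Z = (W^T X + gamma Y R^T) / (1 + gamma)`.
#'
#' @param X genes x samples matrix.
#' @param W genes x d orthonormal-column matrix.
#' @param Y d x K centers.
#' @param R N x K soft assignments.
#' @param gamma clustering weight.
#' @return d x N latent coordinates.
#' @export
update_Z <- function(X, W, Y, R, gamma) {
  (crossprod(W, X) + gamma * Y %*% t(R)) / (1 + gamma)
}

#' Loading update (orthogonal Procrustes)
#'
#' Exact Stiefel-constrained minimizer of the reconstruction term in W given
#' Z: with thin SVD `X Z^T = U S V^T`, `W = U V^T` maximizes
#' `tr(W^T X Z^T)` over orthonormal-column W. The tree and clustering terms
#' do not depend on W when `W^T W = I`.
#'
#' @param X genes x samples matrix.
#' @param Z d x N latent coordinates.
#' @param d latent dimension.
#' @return genes x d orthonormal-column matrix.
#' @export
update_W <- function(X, Z, d = nrow(Z)) {
  s <- svd(X %*% t(Z), nu = d, nv = d)
  s$u %*% t(s$v)
}

# deterministic k-means++-style center seeding on columns of Z
kmeanspp_centers <- function(Z, K) {
  N <- ncol(Z)
  idx <- integer(K)
  idx[1] <- sample.int(N, 1)
  d2 <- cross_dist2(Z, Z[, idx[1], drop = FALSE])[, 1]
  if (K > 1) for (k in 2:K) {
    p <- d2 / sum(d2)
    idx[k] <- if (all(d2 == 0)) sample.int(N, 1) else
      sample.int(N, 1, prob = p)
    d2 <- pmin(d2, cross_dist2(Z, Z[, idx[k], drop = FALSE])[, 1])
  }
  Z[, idx, drop = FALSE]
}

#' Initialize a principal-tree model
#'
#' Gene-centers X; takes W as the top-d left singular vectors (column signs
#' fixed so the largest-magnitude entry of each column is positive),
#' Z = W^T X, Y from a seeded k-means (k-means++-style seeding) on the
#' latent coordinates, then R and B by their exact updates.
#'
#' @param X genes x samples matrix.
#' @param params a `ddrtree_params`.
#' @return a `latent_tree_model` (objective trace holds the initial J).
#' @export
ddrtree_initialize <- function(X, params = ddrtree_params()) {
  N <- ncol(X)
  params <- resolve_params(params, N)
  if (params$K > N) stop_config("K (%d) exceeds sample count (%d)",
                                params$K, N)
  gene_means <- rowMeans(X)
  Xc <- X - gene_means
  sv <- svd(Xc, nu = params$d, nv = 0)
  W <- sv$u
  for (j in seq_len(ncol(W))) {
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  Z <- crossprod(W, Xc)
  set.seed(substream_seed(params$seed, "centers"))
  Y <- if (params$K >= N) Z else {
    init <- kmeanspp_centers(Z, params$K)
    km <- tryCatch(
      suppressWarnings(kmeans(t(Z), centers = t(init), iter.max = 50)),
      error = function(e) NULL)   # degenerate seeding: keep seeded centers
    if (is.null(km)) init else t(km$centers)
  }
  R <- update_R(Z, Y, params$sigma)
  B <- update_B(Y)
  model <- structure(list(W = W, Z = Z, Y = Y, B = B, R = R,
                          gene_means = gene_means,
                          params = params,
                          sample_ids = colnames(X),
                          gene_ids = rownames(X),
                          objective_trace = numeric(0),
                          converged = FALSE, n_iter = 0L),
                     class = "latent_tree_model")
  model$objective_trace <- ddrtree_objective(Xc, model, params)
  model
}

#' Fit the principal tree by block-coordinate descent
#'
#' Repeats exact block sweeps in the order (R, B, Y, Z, W) until the
#' relative objective change drops below `tol` or `max_iter` sweeps; the
#' objective trace is non-increasing by construction.
#'
#' @param X genes x samples matrix (log-scale expression; gene-centering is
#'   applied internally).
#' @param params a `ddrtree_params`.
#' @param diagnostics logical; record per-sweep constraint diagnostics
#'   (orthonormality and row-sum deviations, spanning-tree check).
#' @return a fitted `latent_tree_model`.
#' @export
ddrtree_fit <- function(X, params = ddrtree_params(), diagnostics = FALSE) {
  if (!all(is.finite(X))) stop_config("X must be finite")
  model <- ddrtree_initialize(X, params)
  params <- model$params
  Xc <- X - model$gene_means
  trace <- model$objective_trace
  diag_rows <- list()
  J_prev <- trace[1]
  for (it in seq_len(params$max_iter)) {
    model$R <- update_R(model$Z, model$Y, params$sigma)
    model$B <- update_B(model$Y)
    model$Y <- update_Y(model$Z, model$R, model$B, params$lambda,
                        params$gamma)
    model$Z <- update_Z(Xc, model$W, model$Y, model$R, params$gamma)
    model$W <- update_W(Xc, model$Z, params$d)
    J <- ddrtree_objective(Xc, model, params)
    if (!is.finite(J))
      stop_config("non-finite objective after sweep %d", it)
    trace <- c(trace, J)
    if (diagnostics) {
      diag_rows[[it]] <- data.frame(
        sweep = it,
        orth_dev = max(abs(crossprod(model$W) - diag(params$d))),
        rowsum_dev = max(abs(rowSums(model$R) - 1)),
        tree_ok = isTRUE(tryCatch(check_spanning_tree(model$B),
                                  error = function(e) FALSE)),
        objective = J)
    }
    model$n_iter <- it
    if (abs(J - J_prev) / max(abs(J_prev), .Machine$double.eps) < params$tol) {
      model$converged <- TRUE
      break
    }
    J_prev <- J
  }
  model$objective_trace <- trace
  if (diagnostics) model$diagnostics <- do.call(rbind, diag_rows)
  model
}

#' @export
print.latent_tree_model <- function(x, ...) {
  cat(sprintf(
    "latent_tree_model: %d genes, %d samples, d = %d, K = %d\n",
    nrow(x$W), ncol(x$Z), x$params$d, ncol(x$Y)))
  cat(sprintf("  %d sweep(s), converged: %s, objective %.4g -> %.4g\n",
              x$n_iter, x$converged,
              x$objective_trace[1], tail(x$objective_trace, 1)))
  invisible(x)
}
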