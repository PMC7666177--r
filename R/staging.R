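# From a fitted latent tree to pseudotimes and branch labels: principal
# graph construction, sample projection onto edges, root selection on the
# diameter path, geodesic distance, [0,1] scaling, branch decomposition and
# leave-one-out stability.

#' Build the principal tree graph from a fitted model
#'
#' Realizes the spanning tree B geometrically: vertices are the latent
#' centers, edges carry Euclidean lengths `||y_k - y_k'||`, and branches are
#' the maximal paths whose internal vertices have degree 2 (cut at every
#' vertex of degree != 2), numbered by their smallest vertex index.
#'
#' @param model a `latent_tree_model`.
#' @return a `principal_tree_graph`: `vertices` (K x d), `edges`
#'   (data.frame `from`, `to`, `length`, `branch`), `leaves`, `n_branches`.
#' @export
build_principal_graph <- function(model) {
  Y <- model$Y
  B <- model$B
  K <- ncol(Y)
  check_spanning_tree(B)
  idx <- which(B != 0 & upper.tri(B), arr.ind = TRUE)
  edges <- data.frame(from = idx[, 1], to = idx[, 2])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  edges$length <- sqrt(colSums((Y[, edges$from, drop = FALSE] -
                                Y[, edges$to, drop = FALSE])^2))
  edges$branch <- branch_decompose_edges(edges$from, edges$to, K)
  deg <- tabulate(c(edges$from, edges$to), nbins = K)
  structure(list(vertices = t(Y), edges = edges,
                 leaves = which(deg == 1L),
                 degree = deg,
                 n_branches = if (nrow(edges)) max(edges$branch) else 0L),
            class = "principal_tree_graph")
}

graph_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$vertices))))
}

# all-vertex distances from a set of source vertices (edge-length metric)
graph_distances <- function(graph, from = NULL) {
  g <- graph_igraph(graph)
  igraph::distances(g, v = if (is.null(from)) igraph::V(g) else from,
                    weights = graph$edges$length)
}

#' Project samples onto the principal tree
#'
#' Each latent sample is mapped to its closest point over all tree edges,
#' with the along-edge parameter clamped to `[0, 1]`; ties go to the lowest
#' edge id. Zero-length edges are treated as points (with a warning).
#'
#' @param Z d x N latent coordinates (columns are samples).
#' @param graph a `principal_tree_graph`.
#' @return data.frame per sample: `edge`, `offset` (position along the
#'   edge), `dist` (Euclidean distance to the projection).
#' @export
project_samples <- function(Z, graph) {
  ed <- graph$edges
  if (nrow(ed) == 0L) stop_config("principal graph has no edges")
  V <- t(graph$vertices)                       # d x K
  if (any(ed$length == 0))
    warning("zero-length edge(s) treated as points")
  N <- ncol(Z)
  E <- nrow(ed)
  A <- V[, ed$from, drop = FALSE]              # d x E
  Dir <- V[, ed$to, drop = FALSE] - A          # d x E
  len2 <- pmax(colSums(Dir^2), .Machine$double.eps)
  # t_mat[i, e] = clamp(<z_i - a_e, dir_e> / |dir_e|^2)
  t_mat <- (crossprod(Z, Dir) - matrix(colSums(A * Dir), N, E, byrow = TRUE)) /
    matrix(len2, N, E, byrow = TRUE)
  t_mat <- pmin(pmax(t_mat, 0), 1)
  # squared distance ||z - (a + t dir)||^2
  z2 <- colSums(Z^2)
  a2 <- colSums(A^2)
  za <- crossprod(Z, A)                        # N x E
  zd <- crossprod(Z, Dir)
  ad <- matrix(colSums(A * Dir), N, E, byrow = TRUE)
  d2 <- z2 + matrix(a2, N, E, byrow = TRUE) - 2 * za +
    t_mat^2 * matrix(len2, N, E, byrow = TRUE) - 2 * t_mat * (zd - ad)
  best <- apply(d2, 1, which.min)              # first minimum: lowest edge id
  data.frame(edge = best,
             offset = t_mat[cbind(seq_len(N), best)],
             dist = sqrt(pmax(d2[cbind(seq_len(N), best)], 0)))
}

#' Choose the root on the diameter path
#'
#' Finds the leaf pair at maximal tree distance (the diameter path). When
#' per-sample orientation labels are supplied (e.g. case indicators), each
#' sample is attached to the nearer endpoint of its projection and the
#' endpoint with the lower fraction of label-positive samples becomes the
#' root (disease-late orientation); otherwise the endpoint with the smaller
#' vertex index is used. `root_override` bypasses the rule entirely.
#'
#' @param graph a `principal_tree_graph`.
#' @param orientation_labels optional per-sample binary labels (1 = late).
#' @param projections optional projections (required with labels).
#' @param root_override optional vertex index.
#' @return list `root`, `diameter_endpoints`.
#' @export
find_root <- function(graph, orientation_labels = NULL, projections = NULL,
                      root_override = NULL) {
  K <- nrow(graph$vertices)
  if (!is.null(root_override)) {
    if (!(root_override %in% seq_len(K)))
      stop_config("root_override %s is not a vertex", root_override)
  }
  leaves <- graph$leaves
  if (length(leaves) < 1L) stop_config("graph has no leaves")
  dmat <- graph_distances(graph)
  sub <- dmat[leaves, leaves, drop = FALSE]
  best <- which(sub == max(sub), arr.ind = TRUE)
  # deterministic: smallest vertex pair
  pair <- sort(c(leaves[best[1, 1]], leaves[best[1, 2]]))
  if (!is.null(root_override))
    return(list(root = as.integer(root_override),
                diameter_endpoints = pair))
  root <- pair[1]
  if (!is.null(orientation_labels)) {
    if (is.null(projections))
      stop_config("projections are required with orientation_labels")
    lab <- as.numeric(orientation_labels)
    g_ends <- lapply(pair, function(v)
      sample_geodesics(projections, graph, v))
    nearer_first <- g_ends[[1]] <= g_ends[[2]]
    f1 <- mean(lab[nearer_first])
    f2 <- mean(lab[!nearer_first])
    if (!is.nan(f1) && !is.nan(f2))
      root <- if (f1 <= f2) pair[1] else pair[2]
  }
  list(root = as.integer(root), diameter_endpoints = pair)
}

# geodesic distance from `root` to each projected sample point
sample_geodesics <- function(projections, graph, root) {
  dv <- as.numeric(graph_distances(graph, from = root))
  ed <- graph$edges[projections$edge, , drop = FALSE]
  pmin(dv[ed$from] + projections$offset * ed$length,
       dv[ed$to] + (1 - projections$offset) * ed$length)
}

#' Geodesic pseudotime from a root vertex
#'
#' Pseudotime is the geodesic distance along the tree from the root to each
#' sample's projected point, min-max scaled to `[0, 1]`.
#'
#' @param projections output of [project_samples()].
#' @param graph a `principal_tree_graph`.
#' @param root root vertex index.
#' @return data.frame per sample: `edge`, `offset`, `raw_distance`,
#'   `pseudotime`, `branch`.
#' @export
compute_pseudotime <- function(projections, graph, root) {
  g <- sample_geodesics(projections, graph, root)
  if (max(g) == min(g))
    stop_config("degenerate staging: all samples project to one point")
  data.frame(edge = projections$edge,
             offset = projections$offset,
             raw_distance = g,
             pseudotime = (g - min(g)) / (max(g) - min(g)),
             branch = assign_branches(projections, graph))
}

#' Branch labels for projected samples
#'
#' Samples inherit the branch of the edge they project onto; a sample
#' projecting exactly onto a vertex of degree != 2 takes the smallest
#' incident branch id.
#'
#' @param projections output of [project_samples()].
#' @param graph a `principal_tree_graph`.
#' @return integer branch labels.
#' @export
assign_branches <- function(projections, graph) {
  ed <- graph$edges
  br <- ed$branch[projections$edge]
  at0 <- projections$offset == 0
  at1 <- projections$offset == 1
  vtx <- ifelse(at0, ed$from[projections$edge],
                ifelse(at1, ed$to[projections$edge], NA_integer_))
  hit <- which(!is.na(vtx) & graph$degree[vtx] != 2L)
  for (i in hit) {
    inc <- ed$branch[ed$from == vtx[i] | ed$to == vtx[i]]
    br[i] <- min(inc)
  }
  br
}

#' Stage samples on a fitted principal tree
#'
#' Convenience wrapper: builds the principal graph, projects the fitted
#' latent coordinates, chooses the root on the diameter path and returns
#' per-sample pseudotime and branch.
#'
#' @param model a `latent_tree_model`.
#' @param orientation_labels optional per-sample binary labels; the diameter
#'   endpoint with the lower positive fraction becomes the root.
#' @param root_override optional vertex index.
#' @return a `staging_result`: data.frame (`sample_id`, `edge`, `offset`,
#'   `raw_distance`, `pseudotime`, `branch`) with attributes `root`,
#'   `diameter_endpoints`, `graph`.
#' @export
stage_samples <- function(model, orientation_labels = NULL,
                          root_override = NULL) {
  graph <- build_principal_graph(model)
  proj <- project_samples(model$Z, graph)
  rt <- find_root(graph, orientation_labels, proj, root_override)
  res <- compute_pseudotime(proj, graph, rt$root)
  res <- cbind(sample_id = model$sample_ids %||% seq_len(nrow(res)), res)
  attr(res, "root") <- rt$root
  attr(res, "diameter_endpoints") <- rt$diameter_endpoints
  attr(res, "graph") <- graph
  class(res) <- c("staging_result", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-out pseudotime stability
#'
#' Drops one sample at a time, refits the principal tree with the same
#' parameters, restages, and reports the absolute Pearson correlation
#' between the reduced-fit and full-fit pseudotimes over the shared
#' samples. Refit failures are recorded as `NA` with a warning.
#'
#' @param X genes x samples matrix.
#' @param params a `ddrtree_params`.
#' @param orientation_labels optional labels forwarded to staging.
#' @return numeric vector (one value per left-out sample).
#' @export
loo_stability <- function(X, params = ddrtree_params(),
                          orientation_labels = NULL) {
  N <- ncol(X)
  if (N < 3L) stop_config("leave-one-out needs at least 3 samples")
  full <- stage_samples(ddrtree_fit(X, params), orientation_labels)
  out <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    r <- tryCatch({
      lab_i <- if (is.null(orientation_labels)) NULL else
        orientation_labels[-i]
      st <- stage_samples(ddrtree_fit(X[, -i, drop = FALSE], params), lab_i)
      abs(cor(st$pseudotime, full$pseudotime[-i]))
    }, error = function(e) {
      warning(sprintf("leave-one-out refit failed for sample %d: %s",
                      i, conditionMessage(e)))
      NA_real_
    })
    out[i] <- r
  }
  names(out) <- colnames(X)
  out
}
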