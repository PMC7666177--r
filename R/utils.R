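#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov coef cor cutree dist fitted glm hclust kmeans lm
#'   logLik p.adjust pchisq pf phyper plogis pnorm predict pt ptukey qnorm
#'   quantile rbinom rlnorm rnbinom rnorm runif sd setNames smooth.spline
#'   var binomial vcov complete.cases
#' @importFrom utils head tail read.delim write.table
NULL

# Derive a named pseudo-random sub-stream seed from a master seed so that
# generator stages can be regenerated independently. Stays below 2^31.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 1000003
  as.integer(((abs(seed) %% 1000003) * 1009 + h) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two labelings of the same samples, corrected
#' for chance; 1 is perfect agreement, 0 is the expectation under random
#' labeling. Used to score recovery of planted branch structure.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return a single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Decompose a tree (edge list on vertices 1..n_vertices) into branches:
# maximal paths whose internal vertices have degree 2. Returns an integer
# branch id per edge; ids ordered by the smallest vertex index in the branch.
branch_decompose_edges <- function(from, to, n_vertices) {
  m <- length(from)
  if (m == 0L) return(integer(0))
  deg <- tabulate(c(from, to), nbins = n_vertices)
  # union edges sharing a degree-2 vertex
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  incident <- vector("list", n_vertices)
  for (e in seq_len(m)) {
    incident[[from[e]]] <- c(incident[[from[e]]], e)
    incident[[to[e]]] <- c(incident[[to[e]]], e)
  }
  for (v in seq_len(n_vertices)) {
    if (deg[v] == 2L) {
      es <- incident[[v]]
      r1 <- find(es[1L]); r2 <- find(es[2L])
      if (r1 != r2) parent[r2] <- r1
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  # order branch ids by smallest vertex index occurring in the branch
  min_vertex <- tapply(pmin(from, to), roots, min)
  ord <- order(min_vertex)
  id_map <- setNames(seq_along(ord), names(min_vertex)[ord])
  as.integer(id_map[as.character(roots)])
}

# 0 * log(0) == 0 convention for entropy-like sums
xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
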