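# Branch-specific differential expression (one-way ANOVA + Tukey HSD
# against a reference branch), direction-stratified gene sets, Fisher-exact
# gene-set enrichment, branch-mean biclustering and the resistant-control
# analysis.

#' Reference branch selection
#'
#' The branch with the highest proportion of controls is the reference for
#' all branch contrasts; ties are broken by larger branch size, then by
#' smaller branch id.
#'
#' @param branch per-sample branch labels.
#' @param control per-sample control indicator (logical or 0/1).
#' @return the reference branch id.
#' @export
select_reference_branch <- function(branch, control) {
  control <- as.logical(control)
  if (!any(control)) stop_config("no control samples present")
  tab <- tapply(control, branch, mean)
  size <- tapply(control, branch, length)
  ids <- names(tab)
  ord <- order(-tab, -size, as.numeric(ids))
  out <- ids[ord[1]]
  if (!is.na(suppressWarnings(as.numeric(out)))) out <- as.numeric(out)
  out
}

#' Branch-specific differential expression (ANOVA + Tukey HSD)
#'
#' Per gene: one-way ANOVA across branches, then for every non-reference
#' branch a Tukey honest-significant-difference contrast against the
#' reference: `q = |m_b - m_ref| / sqrt(MSE/2 * (1/n_b + 1/n_ref))`, with
#' the two-sided p from the studentized-range distribution with
#' `(n_branches, N - n_branches)` parameters. BH adjustment is applied
#' within each branch contrast across genes. Branches with fewer than two
#' samples are excluded with a warning. Genes with zero within-branch
#' variance get the degenerate rule: p = 0 if the contrasted means differ,
#' 1 otherwise (flagged).
#'
#' @param expr genes x samples matrix.
#' @param branch per-sample branch labels.
#' @param reference reference branch id (see [select_reference_branch()]).
#' @param fdr BH-adjusted significance threshold recorded in the table.
#' @return a data.frame (class `branch_de_table`): `gene`, `branch`,
#'   `mean_diff`, `anova_f`, `anova_p`, `tukey_q`, `tukey_p`, `adjusted_p`,
#'   `direction`, `significant`, `degenerate`.
#' @export
branch_anova_tukey <- function(expr, branch, reference, fdr = 0.05) {
  branch <- as.vector(branch)
  stopifnot(ncol(expr) == length(branch))
  sizes <- table(branch)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning(sprintf("excluding branch(es) with < 2 samples: %s",
                    paste(small, collapse = ", ")))
    keep <- !(branch %in% small)
    expr <- expr[, keep, drop = FALSE]
    branch <- branch[keep]
  }
  labs <- sort(unique(branch))
  if (!(reference %in% labs)) stop_config("reference branch not present")
  if (length(labs) < 2L) stop_config("need >= 2 branches")
  Bn <- length(labs)
  N <- ncol(expr)
  idx <- lapply(labs, function(b) which(branch == b))
  nb <- vapply(idx, length, integer(1))
  means <- matrix(unlist(lapply(idx, function(ix)
    rowMeans(expr[, ix, drop = FALSE]))), nrow = nrow(expr),
    dimnames = list(rownames(expr), as.character(labs)))
  grand <- rowMeans(expr)
  ssb <- rowSums(sweep((means - grand)^2, 2, nb, `*`))
  sst <- rowSums((expr - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df_b <- Bn - 1
  df_w <- N - Bn
  mse <- ssw / df_w
  f <- (ssb / df_b) / mse
  anova_p <- pf(f, df_b, df_w, lower.tail = FALSE)
  ref_chr <- as.character(reference)
  non_ref <- setdiff(as.character(labs), ref_chr)
  n_ref <- nb[match(ref_chr, as.character(labs))]
  rows <- lapply(non_ref, function(b) {
    n_b <- nb[match(b, as.character(labs))]
    diff <- means[, b] - means[, ref_chr]
    se <- sqrt(mse / 2 * (1 / n_b + 1 / n_ref))
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = Bn, df = df_w, lower.tail = FALSE)
    degenerate <- mse == 0
    p[degenerate] <- ifelse(diff[degenerate] != 0, 0, 1)
    data.frame(gene = rownames(expr), branch = b, mean_diff = unname(diff),
               anova_f = unname(f), anova_p = unname(anova_p),
               tukey_q = unname(q), tukey_p = unname(p),
               adjusted_p = p.adjust(p, "BH"),
               direction = ifelse(diff >= 0, "up", "down"),
               degenerate = unname(degenerate),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$adjusted_p < fdr
  attr(out, "reference") <- reference
  attr(out, "fdr") <- fdr
  class(out) <- c("branch_de_table", "data.frame")
  out
}

#' Direction-stratified significant gene sets
#'
#' Groups significant genes by branch contrast and direction of change; a
#' gene may appear in several branch contrasts.
#'
#' @param de_table a `branch_de_table`.
#' @param fdr adjusted-p threshold.
#' @return named list `"<branch>_<up|down>"` of gene-id vectors (empty
#'   groups omitted).
#' @export
direction_gene_sets <- function(de_table, fdr = 0.05) {
  sig <- de_table[de_table$adjusted_p < fdr, , drop = FALSE]
  if (nrow(sig) == 0L) return(list())
  split(sig$gene, paste(sig$branch, sig$direction, sep = "_"))
}

#' Fisher-exact gene-set enrichment
#'
#' For each set: 2x2 table of query membership by set membership over the
#' universe; one-sided (enrichment) hypergeometric p, sample odds ratio
#' `ad/bc` (0.5 added to every cell for display only when some cell is 0),
#' BH adjustment across sets.
#'
#' @param query character vector of gene ids (genes outside the universe
#'   are dropped with a warning).
#' @param gene_sets named list of gene-id vectors (e.g. from
#'   [read_gene_sets()]).
#' @param universe character vector of all analyzed genes.
#' @param fdr adjusted-p threshold for the `significant` flag.
#' @return data.frame: `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `odds_ratio`, `p`, `adjusted_p`, `significant`.
#' @export
fisher_enrichment <- function(query, gene_sets, universe, fdr = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_config("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  query <- unique(query)
  U <- length(universe)
  q <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    a <- length(intersect(query, s))
    b <- q - a
    cc <- length(s) - a
    d <- U - a - b - cc
    p <- phyper(a - 1, length(s), U - length(s), q, lower.tail = FALSE)
    or <- if (a * d == 0 || b * cc == 0) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else (a * d) / (b * cc)
    data.frame(set = nm, overlap = a, set_size = length(s), query_size = q,
               universe_size = U, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$p, "BH")
  out$significant <- out$adjusted_p < fdr
  out[order(out$p), , drop = FALSE]
}

#' Branch-mean expression matrix
#'
#' Normalizes each gene across samples (z-score by default; min-max
#' optionally) and averages within branch. Constant genes are set to
#' all-zero rows and flagged in the `degenerate_genes` attribute.
#'
#' @param expr genes x samples matrix.
#' @param branch per-sample branch labels.
#' @param normalization `"zscore"` or `"minmax"`.
#' @return genes x branches matrix.
#' @export
branch_mean_matrix <- function(expr, branch,
                               normalization = c("zscore", "minmax")) {
  normalization <- match.arg(normalization)
  stopifnot(ncol(expr) == length(branch))
  m <- rowMeans(expr)
  s <- apply(expr, 1, sd)
  norm <- if (normalization == "zscore") {
    out <- (expr - m) / ifelse(s == 0, 1, s)
    out[s == 0, ] <- 0
    out
  } else {
    lo <- apply(expr, 1, min); hi <- apply(expr, 1, max)
    out <- (expr - lo) / ifelse(hi == lo, 1, hi - lo)
    out[hi == lo, ] <- 0
    out
  }
  labs <- sort(unique(branch))
  res <- vapply(labs, function(b)
    rowMeans(norm[, branch == b, drop = FALSE]), numeric(nrow(expr)))
  colnames(res) <- as.character(labs)
  rownames(res) <- rownames(expr)
  attr(res, "degenerate_genes") <- rownames(expr)[s == 0]
  res
}

#' Bicluster a branch-mean matrix
#'
#' Agglomerative hierarchical clustering on both rows (genes) and columns
#' (branches); gene clusters come from cutting the row dendrogram.
#'
#' @param mat genes x branches matrix (see [branch_mean_matrix()]).
#' @param n_gene_clusters number of gene clusters to cut.
#' @param linkage hclust agglomeration method.
#' @param distance `"euclidean"` (passed to [stats::dist()]).
#' @return list: `gene_clusters` (named integer vector), `gene_order`,
#'   `branch_order`, `gene_tree`, `branch_tree`.
#' @export
bicluster <- function(mat, n_gene_clusters = 6, linkage = "complete",
                      distance = "euclidean") {
  if (!all(is.finite(mat))) stop_config("matrix must be finite")
  ht_g <- hclust(dist(mat, method = distance), method = linkage)
  ht_b <- if (ncol(mat) > 1L)
    hclust(dist(t(mat), method = distance), method = linkage) else NULL
  k <- min(n_gene_clusters, nrow(mat))
  cl <- cutree(ht_g, k = k)
  list(gene_clusters = cl,
       gene_order = ht_g$order,
       branch_order = if (is.null(ht_b)) 1L else ht_b$order,
       gene_tree = ht_g, branch_tree = ht_b)
}

#' Resistant individuals: high-pseudotime controls
#'
#' Controls whose pseudotime lies strictly above the empirical `quantile`
#' of all pseudotimes (type-7 quantile); the default 0.8 selects the top
#' quintile.
#'
#' @param pseudotime numeric per-sample pseudotime in `[0, 1]`.
#' @param control per-sample control indicator.
#' @param quantile_cut quantile threshold (default 0.8).
#' @param sample_ids optional ids to return (default indices).
#' @return vector of resistant sample ids (empty with a warning if none).
#' @export
resistant_individuals <- function(pseudotime, control, quantile_cut = 0.8,
                                  sample_ids = NULL) {
  control <- as.logical(control)
  thr <- quantile(pseudotime, quantile_cut, type = 7)
  hit <- which(control & pseudotime > thr)
  ids <- (sample_ids %||% seq_along(pseudotime))[hit]
  if (length(ids) == 0L)
    warning("no controls above the pseudotime quantile; empty resistant set")
  ids
}

#' Differential expression between resistant and non-resistant samples
#'
#' Per-gene two-group linear-model t-test with BH adjustment, split by
#' direction. Zero-variance genes are dropped with a warning.
#'
#' @param expr genes x samples matrix.
#' @param resistant per-sample logical flag.
#' @param fdr adjusted-p threshold.
#' @return list: `up`, `down` (gene ids), `table`.
#' @export
resistant_de <- function(expr, resistant, fdr = 0.05) {
  resistant <- as.logical(resistant)
  if (sum(resistant) < 2L || sum(!resistant) < 2L)
    stop_config("need >= 2 samples in each group")
  tab <- two_group_t(expr, resistant)
  degenerate <- tab$pooled_var == 0 | !is.finite(tab$statistic)
  if (any(degenerate)) {
    warning(sprintf("%d zero-variance gene(s) dropped", sum(degenerate)))
    tab <- tab[!degenerate, , drop = FALSE]
  }
  tab$adjusted_p <- p.adjust(tab$p, "BH")
  sig <- tab[tab$adjusted_p < fdr, , drop = FALSE]
  list(up = sig$gene[sig$diff > 0], down = sig$gene[sig$diff < 0],
       table = tab)
}

#' Pairwise overlap tests and exclusive intersections of gene lists
#'
#' For every pair of named lists: one-sided Fisher enrichment p and sample
#' odds ratio over the universe. Also counts every nonempty exclusive
#' intersection (the UpSet decomposition).
#'
#' @param lists named list of gene-id vectors (subsets of `universe`).
#' @param universe character vector of all genes.
#' @return list: `pairwise` (data.frame a, b, overlap, odds_ratio, p),
#'   `exclusive` (data.frame pattern, count).
#' @export
overlap_upset <- function(lists, universe) {
  stopifnot(!is.null(names(lists)))
  universe <- unique(universe)
  lists <- lapply(lists, function(x) intersect(unique(x), universe))
  nm <- names(lists)
  pairs <- if (length(nm) >= 2) utils::combn(nm, 2, simplify = FALSE) else
    list()
  pw <- do.call(rbind, lapply(pairs, function(p2) {
    A <- lists[[p2[1]]]; Bl <- lists[[p2[2]]]
    a <- length(intersect(A, Bl))
    b <- length(A) - a
    cc <- length(Bl) - a
    d <- length(universe) - a - b - cc
    pval <- phyper(a - 1, length(Bl), length(universe) - length(Bl),
                   length(A), lower.tail = FALSE)
    or <- if (a * d == 0 || b * cc == 0)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)) else
      (a * d) / (b * cc)
    data.frame(a = p2[1], b = p2[2], overlap = a, odds_ratio = or, p = pval,
               stringsAsFactors = FALSE)
  }))
  members <- unique(unlist(lists))
  excl <- if (length(members)) {
    memb <- vapply(lists, function(l) members %in% l, logical(length(members)))
    if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(members))
    pattern <- apply(memb, 1, function(z) paste(nm[z], collapse = "&"))
    as.data.frame(table(pattern), stringsAsFactors = FALSE,
                  responseName = "count")
  } else data.frame(pattern = character(0), count = integer(0))
  list(pairwise = pw, exclusive = excl)
}
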