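# Gene filtering, normalization and covariate adjustment feeding the
# manifold learner.

as_expression_matrix <- function(values, scale = c("counts", "log_cpm",
                                                   "adjusted", "log")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (anyNA(values)) stop_config("expression matrix contains missing values")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_config("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop_config("duplicate gene ids: %s",
                paste(unique(rownames(values)[duplicated(rownames(values))]),
                      collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_config("duplicate sample ids")
  attr(values, "scale") <- scale
  values
}

#' Filter genes by counts-per-million expression prevalence
#'
#' Keeps genes whose CPM exceeds `cpm_threshold` in at least
#' `sample_fraction` of samples within every group (all samples when
#' `groups` is absent). `CPM_gi = counts_gi / library_size_i * 1e6`.
#'
#' @param counts genes x samples nonnegative count matrix with dimnames.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param sample_fraction required fraction of samples above the cutoff
#'   (default 0.5).
#' @param groups optional per-sample group labels; the prevalence rule must
#'   hold within every group.
#' @return the filtered count matrix.
#' @export
cpm_filter <- function(counts, cpm_threshold = 1, sample_fraction = 0.5,
                       groups = NULL) {
  counts <- as_expression_matrix(counts, "counts")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_config("zero library size for sample(s): %s",
                paste(colnames(counts)[lib == 0], collapse = ", "))
  cpm <- sweep(counts, 2, lib, `/`) * 1e6
  ok_in <- function(cols) {
    rowMeans(cpm[, cols, drop = FALSE] > cpm_threshold) >= sample_fraction
  }
  keep <- if (is.null(groups)) {
    ok_in(seq_len(ncol(counts)))
  } else {
    stopifnot(length(groups) == ncol(counts))
    Reduce(`&`, lapply(split(seq_len(ncol(counts)), groups), ok_in))
  }
  counts[keep, , drop = FALSE]
}

#' Log2 counts-per-million normalization
#'
#' Deterministic `log2(CPM + 1)` transform.
#'
#' @param counts genes x samples nonnegative count matrix.
#' @return genes x samples log2-CPM matrix (scale attribute `log_cpm`).
#' @export
log_normalize <- function(counts) {
  counts <- as_expression_matrix(counts, "counts")
  if (any(counts < 0)) stop_config("negative entries in count matrix")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_config("zero library size for sample(s): %s",
                paste(colnames(counts)[lib == 0], collapse = ", "))
  out <- log2(sweep(counts, 2, lib, `/`) * 1e6 + 1)
  attr(out, "scale") <- "log_cpm"
  out
}

# vectorized equal-variance two-group t-test per gene (rows of expr)
two_group_t <- function(expr, is_a) {
  n1 <- sum(is_a); n2 <- sum(!is_a)
  m1 <- rowMeans(expr[, is_a, drop = FALSE])
  m2 <- rowMeans(expr[, !is_a, drop = FALSE])
  v1 <- apply(expr[, is_a, drop = FALSE], 1, var)
  v2 <- apply(expr[, !is_a, drop = FALSE], 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  stat <- (m1 - m2) / se
  df <- n1 + n2 - 2
  data.frame(gene = rownames(expr), diff = m1 - m2, statistic = stat,
             p = 2 * pt(-abs(stat), df), pooled_var = sp2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential-expression gene selection
#'
#' Per-gene two-group linear-model t-test (equal-variance pooled t) on
#' log-scale values, Benjamini-Hochberg adjustment across genes; genes with
#' adjusted p below `fdr_threshold` are kept. Genes with zero pooled
#' variance are dropped with a warning (their statistic is undefined).
#'
#' @param expr genes x samples log-scale matrix.
#' @param labels per-sample binary labels (factor, logical, or two values).
#' @param fdr_threshold adjusted-p cutoff (default 0.10).
#' @return a `gene_selection` list: `method`, `kept_gene_ids`, `table`
#'   (gene, statistic, p, adjusted_p, kept), `fdr_threshold`.
#' @export
de_gene_selection <- function(expr, labels, fdr_threshold = 0.10) {
  stopifnot(ncol(expr) == length(labels))
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop_config("labels must contain exactly two classes")
  labels <- droplevels(labels)
  if (any(table(labels) < 2L))
    stop_config("each label class needs >= 2 samples")
  tab <- two_group_t(expr, labels == levels(labels)[1])
  degenerate <- tab$pooled_var == 0 | !is.finite(tab$statistic)
  if (any(degenerate)) {
    warning(sprintf("%d zero-variance gene(s) dropped from selection",
                    sum(degenerate)))
    tab <- tab[!degenerate, , drop = FALSE]
  }
  tab$adjusted_p <- p.adjust(tab$p, method = "BH")
  tab$kept <- tab$adjusted_p < fdr_threshold
  structure(list(method = "de",
                 kept_gene_ids = tab$gene[tab$kept],
                 table = tab[, c("gene", "statistic", "p", "adjusted_p",
                                 "kept")],
                 fdr_threshold = fdr_threshold),
            class = "gene_selection")
}

#' High-variance gene selection
#'
#' Keeps the `top_n` genes by across-sample variance; ties broken by gene id
#' lexicographic order.
#'
#' @param expr genes x samples matrix.
#' @param top_n number of genes to keep.
#' @return a `gene_selection` list (statistic column holds the variance).
#' @export
variance_gene_selection <- function(expr, top_n) {
  if (top_n <= 0) stop_config("top_n must be positive")
  if (top_n > nrow(expr)) stop_config("top_n exceeds gene count")
  v <- apply(expr, 1, var)
  ord <- order(-v, rownames(expr))
  kept <- rownames(expr)[ord[seq_len(top_n)]]
  tab <- data.frame(gene = rownames(expr), statistic = v,
                    p = NA_real_, adjusted_p = NA_real_,
                    kept = rownames(expr) %in% kept,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(method = "variance", kept_gene_ids = kept, table = tab,
                 fdr_threshold = NA_real_),
            class = "gene_selection")
}

#' Regress known covariates out of each gene
#'
#' Replaces every gene by its least-squares residual (on an
#' intercept-plus-covariates design) plus its original mean, so adjusted
#' values stay on the original scale while being orthogonal to every
#' covariate column.
#'
#' @param expr genes x samples matrix.
#' @param covariates samples x p data.frame or matrix, row-aligned to the
#'   columns of `expr`.
#' @return adjusted genes x samples matrix (scale attribute `adjusted`).
#' @export
covariate_adjust <- function(expr, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == ncol(expr))
  mm <- stats::model.matrix(~ ., data = covariates)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[setdiff(seq_len(ncol(mm)), qr_mm$pivot[seq_len(qr_mm$rank)])]
    stop_config("rank-deficient covariate design; collinear column(s): %s",
                paste(bad, collapse = ", "))
  }
  fitted <- t(qr.fitted(qr_mm, t(expr)))
  resid <- expr - fitted
  out <- resid + rowMeans(expr)
  dimnames(out) <- dimnames(expr)
  attr(out, "scale") <- "adjusted"
  out
}
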