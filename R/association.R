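# Association statistics between pseudotime and outcomes: binary logistic
# and ordinal proportional-odds models, gene-set correlation shift, and
# cell-type marker trajectories.

association_result <- function(model, term, fit_coef, se, stat, p, n,
                               converged, covariates = character(0)) {
  structure(list(model = model, term = term, coefficient = fit_coef,
                 se = se, statistic = stat, p = p, n = n,
                 converged = converged, covariates = covariates),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s association: coef = %.4g (se %.3g), %s = %.3g, p = %.3g, n = %d\n",
              x$model, x$coefficient, x$se,
              if (x$model == "ordinal") "LR chi-sq" else "z",
              x$statistic, x$p, x$n))
  invisible(x)
}

detect_separation <- function(fit) {
  probs <- fitted(fit)
  max(abs(coef(fit))) > 15 &&
    (any(probs < 1e-10) || any(probs > 1 - 1e-10))
}

#' Logistic association of an outcome with pseudotime
#'
#' Maximum-likelihood logistic regression of a binary outcome on
#' pseudotime (plus optional covariates); Wald z-test for the pseudotime
#' coefficient. Complete or quasi-complete separation is reported as an
#' explicit error.
#'
#' @param pseudotime numeric per-sample pseudotime.
#' @param outcome binary outcome (0/1, logical, or two-level factor).
#' @param covariates optional data.frame of adjustment covariates.
#' @return an `association_result`.
#' @export
logistic_assoc <- function(pseudotime, outcome, covariates = NULL) {
  y <- if (is.factor(outcome) || is.character(outcome)) {
    vals <- as.character(outcome)
    if (setequal(unique(vals), c("case", "control"))) {
      as.integer(vals == "case")
    } else {
      f <- droplevels(as.factor(outcome))
      if (nlevels(f) != 2L) stop_config("outcome must have two levels")
      as.integer(f) - 1L                     # second level is the event
    }
  } else {
    as.integer(outcome)
  }
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) != 2L)
    stop_config("outcome must be binary with both classes present")
  dat <- data.frame(.y = y, .pt = pseudotime)
  form <- .y ~ .pt
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c(".pt", colnames(covariates)),
                               response = ".y")
  }
  fit <- suppressWarnings(glm(form, family = binomial(), data = dat,
                              control = list(maxit = 100, epsilon = 1e-10)))
  if (detect_separation(fit))
    stop_config("separation detected: logistic MLE does not exist")
  sm <- summary(fit)$coefficients
  association_result("logistic", "pseudotime",
                     fit_coef = sm[".pt", 1], se = sm[".pt", 2],
                     stat = sm[".pt", 3], p = sm[".pt", 4],
                     n = length(y), converged = fit$converged,
                     covariates = if (is.null(covariates)) character(0)
                                  else colnames(covariates))
}

#' Ordinal (proportional-odds) association with pseudotime
#'
#' Proportional-odds maximum likelihood with the convention
#' `P(Y <= j) = plogis(theta_j - beta * x)`; likelihood-ratio test of
#' `beta = 0`. Unobserved levels are collapsed with a warning.
#'
#' @param pseudotime numeric per-sample pseudotime.
#' @param outcome ordered outcome (integer levels or ordered factor).
#' @return an `association_result` (statistic is the LR chi-square).
#' @export
ordinal_assoc <- function(pseudotime, outcome) {
  y <- if (is.ordered(outcome)) outcome else
    factor(outcome, ordered = TRUE)
  observed <- table(y)
  if (any(observed == 0)) {
    warning("collapsing unobserved outcome level(s)")
    y <- droplevels(y)
  }
  if (nlevels(y) < 2L) stop_config("outcome needs >= 2 observed levels")
  dat <- data.frame(.y = y, .pt = pseudotime)
  if (nlevels(y) == 2L) {
    # the proportional-odds model with one cutpoint IS binary logistic:
    # P(Y = 2) = plogis(beta x - theta)
    fit <- suppressWarnings(glm(I(as.integer(.y) - 1L) ~ .pt,
                                family = binomial(), data = dat,
                                control = list(maxit = 100,
                                               epsilon = 1e-12)))
    if (detect_separation(fit))
      stop_config("separation detected: ordinal MLE does not exist")
    null2 <- suppressWarnings(glm(I(as.integer(.y) - 1L) ~ 1,
                                  family = binomial(), data = dat))
    lr <- as.numeric(2 * (logLik(fit) - logLik(null2)))
    sm <- summary(fit)$coefficients
    return(association_result("ordinal", "pseudotime",
                              fit_coef = sm[".pt", 1], se = sm[".pt", 2],
                              stat = lr,
                              p = pchisq(lr, 1, lower.tail = FALSE),
                              n = length(y), converged = fit$converged))
  }
  full <- tryCatch(
    suppressWarnings(MASS::polr(.y ~ .pt, data = dat, Hess = TRUE,
                                method = "logistic")),
    error = function(e) stop_config("ordinal fit failed: %s",
                                    conditionMessage(e)))
  if (abs(coef(full)[".pt"]) > 30)
    stop_config("separation detected: ordinal MLE does not exist")
  null <- suppressWarnings(MASS::polr(.y ~ 1, data = dat,
                                      method = "logistic"))
  lr <- as.numeric(2 * (logLik(full) - logLik(null)))
  p <- pchisq(lr, df = 1, lower.tail = FALSE)
  se <- sqrt(diag(vcov(full))[".pt"])
  association_result("ordinal", "pseudotime",
                     fit_coef = unname(coef(full)[".pt"]), se = unname(se),
                     stat = lr, p = p, n = length(y),
                     converged = full$convergence == 0)
}

#' Gene-set shift in correlation with pseudotime
#'
#' Computes each gene's Spearman correlation with pseudotime (average ranks
#' at ties) and tests whether a gene set's correlations are shifted against
#' the background of all other analyzed genes with a two-group linear model
#' (t-test on set membership).
#'
#' @param expr genes x samples matrix.
#' @param pseudotime numeric per-sample pseudotime.
#' @param gene_set character vector of gene ids.
#' @param background optional character vector restricting the background
#'   genes (default: all other rows of `expr`).
#' @return list: `table` (gene, rho, in_set), `shift` (mean in-set minus
#'   background correlation), `statistic`, `p`.
#' @export
geneset_correlation_shift <- function(expr, pseudotime, gene_set,
                                      background = NULL) {
  gene_set <- intersect(gene_set, rownames(expr))
  if (length(gene_set) == 0L)
    stop_config("gene_set shares no genes with the expression matrix")
  bg <- setdiff(background %||% rownames(expr), gene_set)
  genes <- c(gene_set, intersect(bg, rownames(expr)))
  # Spearman with average ranks, vectorized over genes
  ranked <- t(apply(expr[genes, , drop = FALSE], 1, rank))
  rho <- as.numeric(cor(t(ranked), rank(pseudotime)))
  names(rho) <- genes
  in_set <- genes %in% gene_set
  fit <- lm(rho ~ in_set)
  sm <- summary(fit)$coefficients
  list(table = data.frame(gene = genes, rho = unname(rho), in_set = in_set,
                          stringsAsFactors = FALSE),
       shift = unname(coef(fit)["in_setTRUE"]),
       statistic = sm["in_setTRUE", 3],
       p = sm["in_setTRUE", 4])
}

#' Cell-type marker trajectories along pseudotime
#'
#' For each marker set: each member gene's expression is smoothed along
#' pseudotime with a cubic smoothing spline tuned to the requested
#' effective degrees of freedom, min-max normalized to `[0, 1]` (constant
#' fits map to 0.5), and the per-sample normalized values are averaged
#' across the set. The set average is regressed on pseudotime (ordinary
#' least squares) for a slope and p-value, and evaluated on a uniform
#' pseudotime grid for plotting.
#'
#' @param expr genes x samples matrix.
#' @param pseudotime numeric per-sample pseudotime.
#' @param marker_sets named list of gene-id vectors (one per cell type).
#' @param spline_df effective degrees of freedom of the smoother
#'   (default 3).
#' @param grid_size number of grid points for the returned curve.
#' @return named list of `trajectory_summary` lists: `cell_type`, `genes`,
#'   `grid`, `curve` (values in `[0, 1]`), `slope`, `p`.
#' @export
celltype_trajectory <- function(expr, pseudotime, marker_sets,
                                spline_df = 3, grid_size = 100) {
  stopifnot(is.list(marker_sets), !is.null(names(marker_sets)))
  grid <- seq(min(pseudotime), max(pseudotime), length.out = grid_size)
  lapply(setNames(names(marker_sets), names(marker_sets)), function(ct) {
    genes <- intersect(marker_sets[[ct]], rownames(expr))
    if (length(genes) == 0L)
      stop_config("marker set '%s' absent from expression matrix (missing: %s)",
                  ct, paste(head(marker_sets[[ct]], 5), collapse = ", "))
    smooth_one <- function(g) {
      y <- expr[g, ]
      fit <- tryCatch(
        smooth.spline(pseudotime, y, df = spline_df, cv = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) {                     # too few unique points: linear
        lfit <- lm(y ~ pseudotime)
        list(at = unname(predict(lfit)),
             on_grid = unname(predict(lfit,
                                      newdata = data.frame(pseudotime = grid))))
      } else {
        list(at = predict(fit, pseudotime)$y,
             on_grid = predict(fit, grid)$y)
      }
    }
    sm <- lapply(genes, smooth_one)
    norm01 <- function(v, ref) {
      rng <- range(ref)
      if (rng[2] - rng[1] < 1e-8 * max(1, abs(rng[1])))
        rep(0.5, length(v)) else
        pmin(pmax((v - rng[1]) / (rng[2] - rng[1]), 0), 1)
    }
    at_mat <- vapply(sm, function(s) norm01(s$at, s$at), numeric(length(pseudotime)))
    grid_mat <- vapply(sm, function(s) norm01(s$on_grid, s$at), numeric(grid_size))
    avg_at <- rowMeans(at_mat)
    fit <- lm(avg_at ~ pseudotime)
    smc <- summary(fit)$coefficients
    list(cell_type = ct, genes = genes, grid = grid,
         curve = rowMeans(grid_mat),
         slope = unname(coef(fit)["pseudotime"]),
         p = smc["pseudotime", 4])
  })
}
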