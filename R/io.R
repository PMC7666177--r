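# Readers and writers for the tabular formats the pipeline exchanges
# (expression TSV/CSV, MatrixMarket triplets, metadata TSV, GMT gene sets,
# YAML configuration) plus the staged pipeline runner.

#' Read an expression matrix
#'
#' Genes are rows; the first column holds gene ids, remaining columns are
#' samples. MatrixMarket triplet input takes companion row/column name
#' files (one id per line).
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"mtx_triplet"`.
#' @param row_names,col_names companion id files (mtx_triplet only;
#'   defaults `<path>.rownames` / `<path>.colnames`).
#' @return numeric genes x samples matrix with dimnames.
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx_triplet"),
                            row_names = paste0(path, ".rownames"),
                            col_names = paste0(path, ".colnames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("file not found: %s", path)
  if (format == "mtx_triplet") {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(row_names)
    cn <- readLines(col_names)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop_config("row/column name files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
    if (anyDuplicated(rn))
      stop_config("duplicate gene id(s): %s",
                  paste(unique(rn[duplicated(rn)]), collapse = ", "))
    return(m)
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_config("duplicate gene id(s): %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad))
    stop_config("non-numeric expression column(s): %s",
                paste(colnames(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr genes x samples matrix with dimnames.
#' @param path output path.
#' @param id_column name of the gene-id column (default `gene_id`).
#' @export
write_expression <- function(expr, path, id_column = "gene_id") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV
#'
#' @param path file path (tab-separated, header row).
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then one or more gene ids,
#' tab-separated. Order is preserved; duplicate genes within a set are
#' removed with a warning.
#'
#' @param path GMT file path.
#' @return named list of gene-id vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty gene-set file")
    return(list())
  }
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop_config("line %d of %s has fewer than 3 tab-separated fields",
                  i, path)
    genes <- parts[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("set '%s' (line %d): %d duplicate gene(s) removed",
                      parts[1], i, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    out[[parts[1]]] <- genes
  }
  out
}

#' Write gene sets as GMT
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a staging result as TSV
#' @param staging a `staging_result`.
#' @param path output path.
#' @export
write_staging <- function(staging, path) {
  write_tsv(as.data.frame(staging)[, c("sample_id", "branch",
                                       "raw_distance", "pseudotime")], path)
}

#' Read a pipeline configuration from YAML
#'
#' Validates the file before any compute: known stage blocks, a writable
#' output directory and an integer seed.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' Validate (and default-fill) a pipeline configuration
#' @param cfg a named list (see the vignette for the schema).
#' @return the validated `pipeline_config`.
#' @export
validate_pipeline_config <- function(cfg) {
  defaults <- list(
    output_dir = "pseudostage_out",
    seed = 1L,
    verbosity = 1L,
    simulate = list(n_samples = 300L, n_genes = 1000L, topology = "y",
                    plant_resistant = TRUE),
    preprocess = list(selection = "variance", top_n = 1000L,
                      fdr_threshold = 0.10),
    fit = list(),
    stage = list(orientation_column = "diagnosis", root_override = NULL),
    associate = list(score_column = "score"),
    branches = list(fdr = 0.05),
    resistance = list(quantile_cut = 0.8, fdr = 0.05))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]]))
        if (is.null(cfg[[nm]][[sub]])) cfg[[nm]][[sub]] <- defaults[[nm]][[sub]]
    }
  }
  unknown <- setdiff(names(cfg), c(names(defaults), "expression", "metadata",
                                   "gene_sets"))
  if (length(unknown))
    stop_config("unknown config block(s): %s", paste(unknown, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbosity >= 1))
    message(sprintf(paste0("[pseudostage] ", fmt), ...))
}

artifact_manifest <- function(cfg, dir) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        "manifest.json"))
  hashes <- as.character(tools::md5sum(file.path(dir, files)))
  manifest <- list(seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg), "verbosity")],
                   files = as.list(setNames(hashes, files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the staging pipeline
#'
#' Executes the named stages in order on a validated configuration:
#' `simulate` (synthetic cohort with ground truth), `preprocess` (gene
#' selection), `fit` (principal tree), `stage` (pseudotime + branches),
#' `associate` (logistic / ordinal / correlation-shift / trajectories),
#' `branches` (ANOVA + Tukey DE, gene sets, biclustering), `enrich`
#' (Fisher enrichment of branch sets against supplied GMT collections) and
#' `resistance` (quantile rule, DE, overlap with planted/derived sets).
#' `"all"` runs everything. Artifacts are written under
#' `cfg$output_dir` together with a manifest (inputs, parameters, seed,
#' content hashes); a fixed config and seed reproduce the manifest exactly.
#'
#' @param cfg a `pipeline_config` (see [read_pipeline_config()]).
#' @param stages character vector of stage names or `"all"`.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(cfg, stages = "all") {
  cfg <- validate_pipeline_config(unclass(cfg))
  all_stages <- c("simulate", "preprocess", "fit", "stage", "associate",
                  "branches", "enrich", "resistance")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_config("unknown stage(s): %s", paste(bad, collapse = ", "))
  # every stage needs its upstream results: run the chain up to the last
  # requested stage
  stages <- all_stages[seq_len(max(match(stages, all_stages)))]
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, body) {
    pipeline_log(cfg, "stage %s", name)
    tryCatch(body(), error = function(e)
      stop_config("stage %s failed: %s", name, conditionMessage(e)))
  }

  load_inputs <- function() {
    if (!is.null(cfg$expression)) {
      state$expr <- read_expression(cfg$expression)
      state$meta <- read_metadata(cfg$metadata)
    } else {
      sim <- cfg$simulate
      state$cohort <- simulate_cohort(
        n_samples = sim$n_samples, n_genes = sim$n_genes,
        topology = sim$topology, plant_resistant = sim$plant_resistant,
        seed = cfg$seed)
      state$expr <- state$cohort$log_expression
      state$meta <- state$cohort$metadata
    }
    cols <- unique(c(cfg$stage$orientation_column, cfg$associate$score_column))
    missing_cols <- setdiff(cols, colnames(state$meta))
    if (length(missing_cols))
      stop_config("metadata lacks configured column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    load_inputs()
    if (!is.null(state$cohort)) {
      write_expression(state$expr, file.path(cfg$output_dir, "expression.tsv"))
      write_tsv(state$meta, file.path(cfg$output_dir, "metadata.tsv"))
      write_gene_sets(c(state$cohort$marker_sets,
                        list(gwas = state$cohort$gwas_set)),
                      file.path(cfg$output_dir, "gene_sets.gmt"))
      truth <- state$cohort$truth
      write_tsv(data.frame(sample_id = colnames(state$expr),
                           true_pseudotime = truth$true_pseudotime,
                           true_branch = truth$true_branch),
                file.path(cfg$output_dir, "truth.tsv"))
      yaml::write_yaml(list(seed = cfg$seed, simulate = cfg$simulate),
                       file.path(cfg$output_dir, "generator_params.yaml"))
    }
  })
  if (is.null(state$expr) && any(stages != "simulate")) load_inputs()

  if ("preprocess" %in% stages) run_stage("preprocess", function() {
    pp <- cfg$preprocess
    sel <- if (identical(pp$selection, "de")) {
      de_gene_selection(state$expr, state$meta$diagnosis,
                        fdr_threshold = pp$fdr_threshold)
    } else {
      variance_gene_selection(state$expr,
                              min(pp$top_n, nrow(state$expr)))
    }
    state$selection <- sel
    state$expr_fit <- state$expr[sel$kept_gene_ids, , drop = FALSE]
    write_tsv(sel$table, file.path(cfg$output_dir, "gene_selection.tsv"))
  })
  if (is.null(state$expr_fit)) state$expr_fit <- state$expr

  if ("fit" %in% stages) run_stage("fit", function() {
    state$model <- ddrtree_fit(state$expr_fit,
                               do.call(ddrtree_params,
                                       c(cfg$fit, list(seed = cfg$seed))))
    write_tsv(data.frame(sweep = seq_along(state$model$objective_trace) - 1,
                         objective = state$model$objective_trace),
              file.path(cfg$output_dir, "objective_trace.tsv"))
  })

  if ("stage" %in% stages) run_stage("stage", function() {
    orient <- state$meta[[cfg$stage$orientation_column]]
    if (!is.null(orient) && !is.numeric(orient))
      orient <- as.integer(orient == "case")
    state$staging <- stage_samples(state$model, orient,
                                   cfg$stage$root_override)
    write_staging(state$staging, file.path(cfg$output_dir, "pseudotime.tsv"))
    graph <- attr(state$staging, "graph")
    write_tsv(cbind(vertex = seq_len(nrow(graph$vertices)),
                    as.data.frame(graph$vertices)),
              file.path(cfg$output_dir, "graph_vertices.tsv"))
    write_tsv(graph$edges, file.path(cfg$output_dir, "graph_edges.tsv"))
  })

  if ("associate" %in% stages) run_stage("associate", function() {
    pt <- state$staging$pseudotime
    res <- list(
      logistic = logistic_assoc(pt, state$meta$diagnosis),
      ordinal = ordinal_assoc(pt, state$meta[[cfg$associate$score_column]]))
    tab <- do.call(rbind, lapply(names(res), function(nm) {
      r <- res[[nm]]
      data.frame(model = nm, coefficient = r$coefficient, se = r$se,
                 statistic = r$statistic, p = r$p, n = r$n)
    }))
    write_tsv(tab, file.path(cfg$output_dir, "associations.tsv"))
    if (!is.null(state$cohort)) {
      shift <- geneset_correlation_shift(state$expr, pt,
                                         state$cohort$gwas_set)
      write_tsv(data.frame(shift = shift$shift, statistic = shift$statistic,
                           p = shift$p),
                file.path(cfg$output_dir, "gwas_shift.tsv"))
      traj <- celltype_trajectory(state$expr, pt, state$cohort$marker_sets)
      write_tsv(do.call(rbind, lapply(traj, function(tr)
        data.frame(cell_type = tr$cell_type, slope = tr$slope, p = tr$p))),
        file.path(cfg$output_dir, "trajectories.tsv"))
      state$trajectories <- traj
    }
    state$associations <- res
  })

  if ("branches" %in% stages) run_stage("branches", function() {
    br <- state$staging$branch
    ref <- select_reference_branch(br, state$meta$diagnosis == "control")
    de <- branch_anova_tukey(state$expr, br, ref, fdr = cfg$branches$fdr)
    state$branch_de <- de
    state$branch_sets <- direction_gene_sets(de, fdr = cfg$branches$fdr)
    write_tsv(as.data.frame(de), file.path(cfg$output_dir, "branch_de.tsv"))
    bm <- branch_mean_matrix(state$expr, br)
    bic <- bicluster(bm)
    state$biclusters <- split(names(bic$gene_clusters), bic$gene_clusters)
    names(state$biclusters) <- paste0("cluster", names(state$biclusters))
    write_gene_sets(c(state$branch_sets, state$biclusters),
                    file.path(cfg$output_dir, "branch_gene_sets.gmt"))
  })

  if ("enrich" %in% stages) run_stage("enrich", function() {
    sets <- if (!is.null(cfg$gene_sets)) read_gene_sets(cfg$gene_sets) else
      c(state$cohort$marker_sets, list(gwas = state$cohort$gwas_set))
    universe <- rownames(state$expr)
    enr <- do.call(rbind, lapply(names(state$branch_sets), function(nm) {
      e <- fisher_enrichment(state$branch_sets[[nm]], sets, universe,
                             fdr = cfg$branches$fdr)
      cbind(query = nm, e)
    }))
    if (is.null(enr)) enr <- data.frame()
    write_tsv(enr, file.path(cfg$output_dir, "enrichment.tsv"))
    state$enrichment <- enr
  })

  if ("resistance" %in% stages) run_stage("resistance", function() {
    pt <- state$staging$pseudotime
    ctrl <- state$meta$diagnosis == "control"
    res_ids <- resistant_individuals(pt, ctrl, cfg$resistance$quantile_cut,
                                     sample_ids = state$staging$sample_id)
    flag <- state$staging$sample_id %in% res_ids
    out <- list(resistant = res_ids)
    if (sum(flag) >= 2L) {
      de <- resistant_de(state$expr, flag, fdr = cfg$resistance$fdr)
      out$de <- de
      sets_for_overlap <- state$biclusters %||% list()
      planted <- state$cohort$truth$resistant_genes
      if (!is.null(planted))
        sets_for_overlap <- c(sets_for_overlap, list(planted = planted))
      out$overlap <- overlap_upset(c(list(resistant_up = de$up),
                                     sets_for_overlap),
                                   rownames(state$expr))
      write_tsv(out$overlap$pairwise,
                file.path(cfg$output_dir, "resistance_overlap.tsv"))
    }
    write_tsv(data.frame(sample_id = res_ids),
              file.path(cfg$output_dir, "resistant_samples.tsv"))
    state$resistance <- out
  })

  artifact_manifest(cfg, cfg$output_dir)
  invisible(as.list(state))
}
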