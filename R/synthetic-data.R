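# Synthetic cohorts with a known branching trajectory.
#
# The generator emulates the structure a bulk-brain staging analysis assumes:
# expression driven by a latent tree embedded in the plane, binary diagnosis
# and ordinal neuropathology scores that are stochastically monotone in the
# latent stage, designated cell-type marker and GWAS gene programs, and a
# minority of high-stage control samples carrying a distinct upregulated
# cluster. Every cohort ships with its full ground truth so recovery can be
# scored exactly.

#' Build a latent tree topology
#'
#' Constructs a small tree embedded in the plane on which latent sample
#' positions are drawn. Supported topologies: a simple path, a "y" (three
#' arms joined at one hub) and a "double_y" (a central segment with two arms
#' at each end).
#'
#' @param topology_name one of `"path"`, `"y"`, `"double_y"`.
#' @param arm_length positive arm length, or a vector with one length per
#'   arm in construction order (path: 1; y: trunk, upper, lower; double_y:
#'   central segment, then the four outer arms). A trunk longer than the
#'   fork arms makes the maximum-diameter path traverse it, mirroring a
#'   disease tree whose shared early trajectory dominates the diameter.
#' @param n_vertices_per_arm vertices per arm, hub included (>= 2).
#' @param seed integer; kept for interface symmetry (construction is
#'   deterministic).
#' @return an object of class `true_tree`: `vertices` (V x 2 matrix),
#'   `edges` (data.frame `from`, `to`, `length`), `root_vertex`,
#'   `topology_name`.
#' @export
generate_tree_topology <- function(topology_name, arm_length = NULL,
                                   n_vertices_per_arm = 6, seed = 1L) {
  if (n_vertices_per_arm < 2) stop_config("n_vertices_per_arm must be >= 2")
  n_arms <- switch(topology_name, path = 1L, y = 3L, double_y = 5L,
                   stop_config("unknown topology_name '%s'", topology_name))
  if (is.null(arm_length))
    arm_length <- if (topology_name == "y") c(7, 5, 5) else 5
  if (any(arm_length <= 0)) stop_config("arm_length must be positive")
  arm_length <- rep_len(arm_length, n_arms)
  # an arm is a chain of n_vertices_per_arm vertices starting at `origin`
  # heading in direction `ang`; the origin vertex is shared (index `hub`)
  arm_coords <- function(origin, ang, step) {
    t(sapply(seq_len(n_vertices_per_arm - 1), function(i)
      origin + i * step * c(cos(ang), sin(ang))))
  }
  verts <- NULL
  edges <- NULL
  arm_no <- 0L
  add_arm <- function(hub_idx, ang) {
    arm_no <<- arm_no + 1L
    step <- arm_length[arm_no] / (n_vertices_per_arm - 1)
    new <- arm_coords(verts[hub_idx, ], ang, step)
    start <- nrow(verts)
    verts <<- rbind(verts, new)
    idx <- c(hub_idx, start + seq_len(nrow(new)))
    edges <<- rbind(edges, data.frame(from = idx[-length(idx)], to = idx[-1]))
  }
  if (topology_name == "path") {
    step <- arm_length[1] / (n_vertices_per_arm - 1)
    verts <- cbind(step * (seq_len(n_vertices_per_arm) - 1), 0)
    edges <- data.frame(from = seq_len(n_vertices_per_arm - 1),
                        to = seq_len(n_vertices_per_arm - 1) + 1)
  } else if (topology_name == "y") {
    verts <- matrix(c(0, 0), 1, 2)
    add_arm(1L, pi)          # trunk arm (root at its far tip)
    add_arm(1L, pi / 5)      # upper branch
    add_arm(1L, -pi / 5)     # lower branch
  } else {
    verts <- matrix(c(0, 0), 1, 2)
    add_arm(1L, 0)           # central segment; far end is the second hub
    hub2 <- nrow(verts)
    add_arm(1L, pi - pi / 5)
    add_arm(1L, pi + pi / 5)
    add_arm(hub2, pi / 5)
    add_arm(hub2, -pi / 5)
  }
  verts <- unname(as.matrix(verts))
  edges$length <- sqrt(rowSums((verts[edges$from, , drop = FALSE] -
                                verts[edges$to, , drop = FALSE])^2))
  root <- if (topology_name == "path") 1L else
    if (topology_name == "y") 1L + (n_vertices_per_arm - 1L) else
      1L + 2L * (n_vertices_per_arm - 1L)  # tip of an outer arm
  structure(list(vertices = verts, edges = edges,
                 root_vertex = as.integer(root),
                 topology_name = topology_name),
            class = "true_tree")
}

tree_igraph <- function(tree) {
  igraph::graph_from_data_frame(
    data.frame(from = tree$edges$from, to = tree$edges$to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(tree$vertices))))
}

#' Sample latent positions uniformly along a tree
#'
#' Positions are drawn uniformly by arc length over the whole tree (edges
#' chosen with probability proportional to length, offset uniform). The true
#' pseudotime is the geodesic distance from the root, min-max scaled to
#' `[0, 1]`; the true branch is taken from the degree-not-2 decomposition of
#' the tree.
#'
#' @param tree a `true_tree`.
#' @param n_samples number of samples (>= 2).
#' @param seed integer seed.
#' @return list with `positions` (n x 2 matrix), and `truth` (class
#'   `synthetic_truth`) holding `true_pseudotime`, `raw_distance`,
#'   `true_branch`, `edge`, `offset`, `seed`.
#' @export
sample_latent_positions <- function(tree, n_samples, seed = 1L) {
  if (nrow(tree$vertices) < 2L) stop_config("degenerate tree: single vertex")
  if (n_samples < 2L) stop_config("n_samples must be >= 2")
  set.seed(substream_seed(seed, "latent_positions"))
  ed <- tree$edges
  eidx <- sample.int(nrow(ed), n_samples, replace = TRUE, prob = ed$length)
  offs <- runif(n_samples)
  a <- tree$vertices[ed$from[eidx], , drop = FALSE]
  b <- tree$vertices[ed$to[eidx], , drop = FALSE]
  pos <- a + offs * (b - a)
  g <- tree_igraph(tree)
  dv <- as.numeric(igraph::distances(g, v = tree$root_vertex,
                                     weights = tree$edges$length))
  raw <- pmin(dv[ed$from[eidx]] + offs * ed$length[eidx],
              dv[ed$to[eidx]] + (1 - offs) * ed$length[eidx])
  if (max(raw) == min(raw)) stop_config("all samples coincide on the tree")
  pt <- (raw - min(raw)) / (max(raw) - min(raw))
  branch_of_edge <- branch_decompose_edges(ed$from, ed$to,
                                           nrow(tree$vertices))
  truth <- structure(list(
    true_pseudotime = pt,
    raw_distance = raw,
    true_branch = branch_of_edge[eidx],
    edge = eidx,
    offset = offs,
    tree = tree,
    seed = as.integer(seed)), class = "synthetic_truth")
  list(positions = unname(pos), truth = truth)
}

# monotone logistic program profile on [0,1]
program_profile <- function(t, amplitude, steepness = 8, midpoint = 0.5) {
  amplitude * plogis(steepness * (t - midpoint))
}

# noiseless planted effect for one gene across samples
program_effect <- function(program, branch_target, t, branch, amplitude,
                           branch_effect) {
  switch(program,
    flat = rep(0, length(t)),
    increasing = program_profile(t, amplitude),
    decreasing = amplitude - program_profile(t, amplitude),
    branch_specific = ifelse(branch == branch_target, branch_effect, 0),
    resistant_cluster = rep(0, length(t)),
    stop_config("unknown gene program '%s'", program))
}

#' Generate expression for sampled latent positions
#'
#' Two generative modes. `linear_gaussian` produces log-scale values
#' `x_i = s * W_true z_i + f_g(t_i, branch_i) + noise` where `W_true` has
#' orthonormal columns, `z_i` is the latent planar position and `f_g` is the
#' gene's planted program (zero for flat genes). `negbin_counts` produces
#' counts with per-gene mean `exp(b0_g + f_g(t_i, branch_i))` times a
#' log-normal library-size factor, sampled negative-binomially.
#'
#' Planted programs: `increasing` / `decreasing` are monotone logistic
#' functions of true pseudotime; `branch_specific` programs are nonzero only
#' on their branch; remaining genes are flat nulls.
#'
#' @param positions n x 2 matrix of latent positions.
#' @param truth `synthetic_truth` from [sample_latent_positions()].
#' @param n_genes number of genes.
#' @param frac_increasing,frac_decreasing,frac_branch_specific program
#'   fractions; must sum to <= 1.
#' @param noise_sd Gaussian noise sd (linear_gaussian mode), > 0.
#' @param nb_dispersion negative-binomial size parameter (larger is closer
#'   to Poisson), > 0.
#' @param mean_library_size expected library size in counts mode.
#' @param mode `"linear_gaussian"` or `"negbin_counts"`.
#' @param signal_scale scalar `s` multiplying the planar signal.
#' @param amplitude log-scale amplitude of increasing/decreasing programs.
#' @param branch_effect log-scale amplitude of branch-specific programs.
#' @param seed integer seed.
#' @return a `generated_cohort`: `log_expression` (genes x samples),
#'   `counts` (counts mode only), `metadata` skeleton, and the updated
#'   `truth` carrying `gene_programs` and `program_branch`.
#' @export
generate_expression <- function(positions, truth, n_genes = 1000,
                                frac_increasing = 0.1, frac_decreasing = 0.1,
                                frac_branch_specific = 0.1,
                                noise_sd = 1, nb_dispersion = 10,
                                mean_library_size = 1e6,
                                mode = c("linear_gaussian", "negbin_counts"),
                                signal_scale = 10, amplitude = 2,
                                branch_effect = 1.5, seed = 1L) {
  mode <- match.arg(mode)
  if (noise_sd <= 0) stop_config("noise_sd must be positive")
  if (nb_dispersion <= 0) stop_config("nb_dispersion must be positive")
  fr <- c(frac_increasing, frac_decreasing, frac_branch_specific)
  if (any(fr < 0) || sum(fr) > 1) stop_config("program fractions must be in [0,1] and sum to <= 1")
  n <- nrow(positions)
  t_true <- truth$true_pseudotime
  br <- truth$true_branch
  set.seed(substream_seed(seed, "expression"))

  counts_of <- function(x) as.integer(round(n_genes * x))
  n_inc <- counts_of(frac_increasing)
  n_dec <- counts_of(frac_decreasing)
  n_bs <- counts_of(frac_branch_specific)
  programs <- rep("flat", n_genes)
  programs[seq_len(n_inc)] <- "increasing"
  if (n_dec > 0) programs[n_inc + seq_len(n_dec)] <- "decreasing"
  if (n_bs > 0) programs[n_inc + n_dec + seq_len(n_bs)] <- "branch_specific"
  branches <- sort(unique(br))
  target <- rep(NA_integer_, n_genes)
  if (n_bs > 0) {
    nonroot <- if (length(branches) > 1) branches[-1] else branches
    target[programs == "branch_specific"] <-
      rep_len(nonroot, n_bs)
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- sprintf("s%03d", seq_len(n))

  planted <- matrix(0, n_genes, n)
  for (gi in which(programs != "flat")) {
    planted[gi, ] <- program_effect(programs[gi], target[gi], t_true, br,
                                    amplitude, branch_effect)
  }

  if (mode == "linear_gaussian") {
    w_raw <- matrix(rnorm(n_genes * 2), n_genes, 2)
    w_true <- qr.Q(qr(w_raw))          # orthonormal columns
    log_expr <- signal_scale * (w_true %*% t(positions)) + planted +
      matrix(rnorm(n_genes * n, sd = noise_sd), n_genes, n)
    counts <- NULL
  } else {
    b0 <- rnorm(n_genes, mean = 0, sd = 1)
    rel <- sweep(exp(planted), 1, exp(b0), `*`)   # unnormalized gene weights
    lib <- mean_library_size * rlnorm(n, meanlog = 0, sdlog = 0.3)
    mu <- sweep(rel, 2, lib / colSums(rel), `*`)
    counts <- matrix(rnbinom(n_genes * n, size = nb_dispersion, mu = mu),
                     n_genes, n)
    log_expr <- log2(sweep(counts, 2, pmax(colSums(counts), 1), `/`) * 1e6 + 1)
  }
  dimnames(log_expr) <- list(gene_ids, sample_ids)
  if (!is.null(counts)) dimnames(counts) <- list(gene_ids, sample_ids)

  truth$gene_programs <- setNames(programs, gene_ids)
  truth$program_branch <- setNames(target, gene_ids)
  truth$w_true <- if (mode == "linear_gaussian") w_true else NULL

  structure(list(
    log_expression = log_expr,
    counts = counts,
    metadata = data.frame(sample_id = sample_ids,
                          stringsAsFactors = FALSE),
    marker_sets = list(),
    gwas_set = character(0),
    truth = truth), class = "generated_cohort")
}

#' Generate clinical labels from the latent stage
#'
#' Case status follows a logistic model in true pseudotime `t`:
#' `P(case) = plogis(logistic_a + logistic_b * t)`. The ordinal score follows
#' a proportional-odds model `P(Y <= j) = plogis(theta_j - ordinal_beta * t)`
#' and the allele dosage is `Binomial(2, plogis(dosage_a + dosage_b * t))`.
#'
#' @param truth a `synthetic_truth`.
#' @param logistic_a,logistic_b intercept/slope of the case model.
#' @param ordinal_cutpoints strictly increasing cutpoints `theta_j`
#'   (J - 1 values for J levels).
#' @param ordinal_beta slope of the proportional-odds model.
#' @param dosage_a,dosage_b intercept/slope of the dosage model.
#' @param seed integer seed.
#' @return data.frame with `sample_id` absent (join by position): `diagnosis`
#'   (`case`/`control`), `score` (ordered 1..J), `dosage` (0/1/2).
#' @export
generate_clinical_labels <- function(truth, logistic_a = -2, logistic_b = 4,
                                     ordinal_cutpoints = c(0.4, 1.0, 1.6),
                                     ordinal_beta = 2,
                                     dosage_a = -1, dosage_b = 1, seed = 1L) {
  if (is.unsorted(ordinal_cutpoints, strictly = TRUE))
    stop_config("ordinal_cutpoints must be strictly increasing")
  t <- truth$true_pseudotime
  n <- length(t)
  set.seed(substream_seed(seed, "clinical_labels"))
  case <- rbinom(n, 1, plogis(logistic_a + logistic_b * t))
  # proportional odds: P(Y <= j) = plogis(theta_j - beta t)
  cum <- vapply(ordinal_cutpoints, function(th) plogis(th - ordinal_beta * t),
                numeric(n))
  cum <- cbind(cum, 1)
  u <- runif(n)
  score <- apply(cum >= u, 1, function(z) which(z)[1])
  dosage <- rbinom(n, 2, plogis(dosage_a + dosage_b * t))
  data.frame(diagnosis = ifelse(case == 1, "case", "control"),
             score = as.integer(score),
             dosage = as.integer(dosage),
             stringsAsFactors = FALSE)
}

#' Plant a resistant-control gene cluster
#'
#' Flags `n_resistant` control samples whose true pseudotime lies strictly
#' above the `quantile_floor` quantile of all pseudotimes and adds `effect`
#' (log scale) to a designated cluster of flat genes in those samples only,
#' emulating controls whose transcriptome places them at late disease stage
#' with a distinct upregulated module.
#'
#' @param cohort a `generated_cohort` whose `metadata` has a `diagnosis`
#'   column.
#' @param quantile_floor quantile (type 7) of all pseudotimes above which
#'   controls are eligible.
#' @param n_resistant number of controls to flag.
#' @param cluster_size number of flat genes receiving the effect.
#' @param effect log-scale shift added in resistant samples (>= 0).
#' @param seed integer seed.
#' @return the modified cohort; its `truth` gains `resistant_samples`
#'   (sample ids) and `resistant_genes` (gene ids, program
#'   `resistant_cluster`).
#' @export
plant_resistant_controls <- function(cohort, quantile_floor = 0.8,
                                     n_resistant = 9, cluster_size = 50,
                                     effect = 2, seed = 1L) {
  if (effect < 0) stop_config("effect must be nonnegative")
  truth <- cohort$truth
  if (is.null(cohort$metadata$diagnosis))
    stop_config("cohort metadata lacks a diagnosis column; generate labels first")
  t <- truth$true_pseudotime
  thr <- quantile(t, quantile_floor, type = 7)
  eligible <- which(cohort$metadata$diagnosis == "control" & t > thr)
  if (length(eligible) < n_resistant)
    stop_config("only %d eligible controls above the %.2f quantile (need %d)",
                length(eligible), quantile_floor, n_resistant)
  set.seed(substream_seed(seed, "resistant"))
  res_idx <- sort(sample(eligible, n_resistant))
  flat <- which(truth$gene_programs == "flat")
  if (length(flat) < cluster_size)
    stop_config("only %d flat genes available for a cluster of %d",
                length(flat), cluster_size)
  genes <- sort(sample(flat, cluster_size))
  cohort$log_expression[genes, res_idx] <-
    cohort$log_expression[genes, res_idx] + effect
  if (!is.null(cohort$counts)) {
    cohort$counts[genes, res_idx] <-
      as.integer(round(cohort$counts[genes, res_idx] * 2^effect))
  }
  truth$gene_programs[genes] <- "resistant_cluster"
  truth$resistant_samples <- colnames(cohort$log_expression)[res_idx]
  truth$resistant_genes <- rownames(cohort$log_expression)[genes]
  cohort$truth <- truth
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper wiring tree construction, latent positions,
#' expression, clinical labels, marker/GWAS set designation and (optionally)
#' resistant-control planting, all from one master seed with independent
#' named sub-streams.
#'
#' The marker sets emulate brain cell-type signatures: the planted
#' `decreasing` genes are split into a "neuron" set and the `increasing`
#' genes into "microglia" and "astrocyte" sets; the GWAS set is a subset of
#' increasing genes (disease-correlated loci).
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param topology tree topology name (see [generate_tree_topology()]).
#' @param plant_resistant logical; plant the resistant-control cluster
#'   (requires enough eligible controls).
#' @param n_resistant,resistant_effect,resistant_cluster_size forwarded to
#'   [plant_resistant_controls()].
#' @param seed master integer seed.
#' @param ... forwarded to [generate_expression()].
#' @inheritParams generate_clinical_labels
#' @return a `generated_cohort` with populated `metadata`, `marker_sets`,
#'   `gwas_set` and `truth`.
#' @export
simulate_cohort <- function(n_samples = 300, n_genes = 1000,
                            topology = "y",
                            logistic_a = -2, logistic_b = 4,
                            ordinal_cutpoints = c(0.4, 1.0, 1.6),
                            ordinal_beta = 2,
                            plant_resistant = FALSE, n_resistant = 9,
                            resistant_effect = 2,
                            resistant_cluster_size = 50,
                            seed = 1L, ...) {
  tree <- generate_tree_topology(topology, seed = seed)
  lat <- sample_latent_positions(tree, n_samples, seed = seed)
  cohort <- generate_expression(lat$positions, lat$truth, n_genes = n_genes,
                                seed = seed, ...)
  labs <- generate_clinical_labels(cohort$truth,
                                   logistic_a = logistic_a,
                                   logistic_b = logistic_b,
                                   ordinal_cutpoints = ordinal_cutpoints,
                                   ordinal_beta = ordinal_beta, seed = seed)
  cohort$metadata <- cbind(cohort$metadata, labs)
  progs <- cohort$truth$gene_programs
  inc <- names(progs)[progs == "increasing"]
  dec <- names(progs)[progs == "decreasing"]
  half <- ceiling(length(inc) / 2)
  cohort$marker_sets <- list(
    neuron = dec,
    microglia = inc[seq_len(half)],
    astrocyte = inc[setdiff(seq_along(inc), seq_len(half))])
  cohort$marker_sets <- Filter(function(x) length(x) > 0, cohort$marker_sets)
  set.seed(substream_seed(seed, "gwas_set"))
  n_gwas <- min(60L, length(inc))
  cohort$gwas_set <- sort(sample(inc, n_gwas))
  if (plant_resistant) {
    # resistant individuals are controls by definition (disease-free despite a
    # late-stage transcriptome): if the label draw left too few controls above
    # the pseudotime floor, relabel high-stage cases as controls first
    t <- cohort$truth$true_pseudotime
    thr <- quantile(t, 0.8, type = 7)
    elig <- cohort$metadata$diagnosis == "control" & t > thr
    need <- n_resistant - sum(elig)
    if (need > 0) {
      cand <- which(cohort$metadata$diagnosis == "case" & t > thr)
      if (length(cand) < need)
        stop_config("cannot place %d resistant controls above the 0.8 quantile",
                    n_resistant)
      set.seed(substream_seed(seed, "resistant_relabel"))
      cohort$metadata$diagnosis[sample(cand, need)] <- "control"
    }
    cohort <- plant_resistant_controls(
      cohort, n_resistant = n_resistant,
      cluster_size = resistant_cluster_size,
      effect = resistant_effect, seed = seed)
  }
  cohort
}
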