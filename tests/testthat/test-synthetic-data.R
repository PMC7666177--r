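test_that("tree topologies have the promised leaf and hub structure", {
  cases <- list(
    list(name = "path", n = 5, leaves = 2, hubs = 0, vertices = 5),
    list(name = "y", n = 3, leaves = 3, hubs = 1, vertices = 7),
    list(name = "double_y", n = 3, leaves = 4, hubs = 2, vertices = NA))
  for (cs in cases) {
    tr <- generate_tree_topology(cs$name, arm_length = 1,
                                 n_vertices_per_arm = cs$n, seed = 7)
    deg <- tabulate(c(tr$edges$from, tr$edges$to), nbins = nrow(tr$vertices))
    expect_equal(nrow(tr$edges), nrow(tr$vertices) - 1)
    expect_equal(sum(deg == 1), cs$leaves)
    expect_equal(sum(deg == 3), cs$hubs)
    if (!is.na(cs$vertices)) expect_equal(nrow(tr$vertices), cs$vertices)
    expect_true(all(tr$edges$length > 0))
    g <- igraph::graph_from_data_frame(tr$edges[, 1:2], directed = FALSE)
    expect_true(igraph::is_connected(g))
  }
  expect_error(generate_tree_topology("ring"), "unknown topology")
  expect_error(generate_tree_topology("path", n_vertices_per_arm = 1), ">= 2")
})

test_that("latent positions scale geodesic distance to [0, 1] exactly", {
  tr <- generate_tree_topology("path", arm_length = 4, n_vertices_per_arm = 5)
  lat <- sample_latent_positions(tr, 400, seed = 9)
  t <- lat$truth$true_pseudotime
  expect_equal(min(t), 0)
  expect_equal(max(t), 1)
  expect_true(all(t >= 0 & t <= 1))
  # scaled pseudotime is an affine map of arc length: a sample at arc 1 of a
  # length-4 path whose samples span the full path maps near 0.25
  raw <- lat$truth$raw_distance
  expect_equal(t, (raw - min(raw)) / (max(raw) - min(raw)))
  expect_error(sample_latent_positions(tr, 1), ">= 2")
})

test_that("hand geodesic: arc length 1 from the root of a length-4 path", {
  tr <- generate_tree_topology("path", arm_length = 4, n_vertices_per_arm = 5)
  # edge 1 runs from the root (x = 0) to x = 1; offset 0.5 sits at arc 0.5
  lat <- sample_latent_positions(tr, 2, seed = 1)
  ed <- tr$edges
  d_root <- lat$truth$raw_distance
  # recompute one sample's raw distance by hand
  i <- 1
  a <- tr$vertices[ed$from[lat$truth$edge[i]], ]
  hand <- sqrt(sum((lat$positions[i, ] - tr$vertices[tr$root_vertex, ])^2))
  # on a straight path the geodesic equals the Euclidean distance to the root
  expect_equal(d_root[i], hand, tolerance = 1e-10)
})

test_that("noiseless planar mode is rank 2 after gene centering", {
  tr <- generate_tree_topology("y")
  lat <- sample_latent_positions(tr, 60, seed = 2)
  co <- generate_expression(lat$positions, lat$truth, n_genes = 120,
                            frac_increasing = 0, frac_decreasing = 0,
                            frac_branch_specific = 0, noise_sd = 1e-12,
                            seed = 2)
  Xc <- co$log_expression - rowMeans(co$log_expression)
  sv <- svd(Xc, nu = 0, nv = 0)$d
  expect_lt(sv[3] / sv[1], 1e-8)
})

test_that("negative-binomial mode approaches Poisson at large dispersion", {
  tr <- generate_tree_topology("path")
  lat <- sample_latent_positions(tr, 100, seed = 3)
  set.seed(31)
  # direct Monte-Carlo on the sampling distribution used by the generator
  mu <- 50
  draws <- rnbinom(1e4, size = 1e6, mu = mu)
  expect_equal(var(draws) / mean(draws), 1, tolerance = 0.05)
  co <- generate_expression(lat$positions, lat$truth, n_genes = 50,
                            mode = "negbin_counts", nb_dispersion = 1e6,
                            seed = 3)
  expect_true(all(co$counts >= 0))
  expect_true(all(co$counts == round(co$counts)))
  expect_error(generate_expression(lat$positions, lat$truth, n_genes = 10,
                                   noise_sd = 0), "positive")
  expect_error(generate_expression(lat$positions, lat$truth, n_genes = 10,
                                   nb_dispersion = -1), "positive")
})

test_that("flat null genes carry no trajectory signal in counts mode", {
  # in counts mode only planted programs couple genes to the trajectory, so
  # a flat gene's log expression is uncorrelated with pseudotime
  tr <- generate_tree_topology("path")
  ok <- vapply(1:20, function(s) {
    lat <- sample_latent_positions(tr, 300, seed = s)
    co <- generate_expression(lat$positions, lat$truth, n_genes = 20,
                              frac_increasing = 0, frac_decreasing = 0,
                              frac_branch_specific = 0,
                              mode = "negbin_counts", seed = s)
    rho <- cor(co$log_expression[20, ], lat$truth$true_pseudotime,
               method = "spearman")
    abs(rho) < 0.15
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("clinical labels follow their stated sampling models", {
  tr <- generate_tree_topology("path")
  lat <- sample_latent_positions(tr, 1000, seed = 4)
  # zero slope: case fraction matches the intercept within 3 binomial SEs
  md <- generate_clinical_labels(lat$truth, logistic_a = -0.5, logistic_b = 0,
                                 seed = 4)
  p0 <- plogis(-0.5)
  se <- sqrt(p0 * (1 - p0) / 1000)
  expect_lt(abs(mean(md$diagnosis == "case") - p0), 3 * se)
  # strong positive slope: cases are later than controls
  md2 <- generate_clinical_labels(lat$truth, logistic_a = -2, logistic_b = 4,
                                  seed = 4)
  t <- lat$truth$true_pseudotime
  expect_gt(mean(t[md2$diagnosis == "case"]), mean(t[md2$diagnosis == "control"]))
  # two ordinal levels collapse to a Bernoulli with the stated convention:
  # P(Y = 2) = plogis(beta t - theta)
  md3 <- generate_clinical_labels(lat$truth, ordinal_cutpoints = 0.7,
                                  ordinal_beta = 2, seed = 77)
  emp <- mean(md3$score == 2)
  expect_equal(emp, mean(plogis(2 * t - 0.7)), tolerance = 0.05)
  expect_error(generate_clinical_labels(lat$truth,
                                        ordinal_cutpoints = c(1, 0.5)),
               "strictly increasing")
})

test_that("resistant planting shifts exactly the designated block", {
  # balanced label model so plenty of controls sit at late stage
  co <- simulate_cohort(n_samples = 150, n_genes = 300, topology = "path",
                        logistic_a = 0, logistic_b = 0,
                        plant_resistant = FALSE, seed = 6)
  base <- co
  planted <- plant_resistant_controls(co, n_resistant = 5, cluster_size = 20,
                                      effect = 2, seed = 6)
  genes <- planted$truth$resistant_genes
  samples <- planted$truth$resistant_samples
  expect_length(genes, 20)
  expect_length(samples, 5)
  # resistant samples are controls above the 0.8 quantile of pseudotime
  idx <- match(samples, colnames(co$log_expression))
  expect_true(all(planted$metadata$diagnosis[idx] == "control"))
  thr <- quantile(planted$truth$true_pseudotime, 0.8, type = 7)
  expect_true(all(planted$truth$true_pseudotime[idx] > thr))
  # effect lands only on the block
  diffm <- planted$log_expression - base$log_expression
  expect_equal(unname(diffm[genes, idx]), matrix(2, 20, 5))
  diffm[genes, idx] <- 0
  expect_true(all(diffm == 0))
  # zero effect is the identity
  same <- plant_resistant_controls(base, n_resistant = 5, cluster_size = 20,
                                   effect = 0, seed = 6)
  expect_equal(same$log_expression, base$log_expression)
  # shortfall errors name the count
  expect_error(plant_resistant_controls(base, n_resistant = 500),
               "eligible controls")
})

test_that("generation is bit-identical under a fixed seed", {
  a <- simulate_cohort(n_samples = 60, n_genes = 80, seed = 10,
                       plant_resistant = FALSE)
  b <- simulate_cohort(n_samples = 60, n_genes = 80, seed = 10,
                       plant_resistant = FALSE)
  expect_identical(a$log_expression, b$log_expression)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$true_pseudotime, b$truth$true_pseudotime)
  c <- simulate_cohort(n_samples = 60, n_genes = 80, seed = 11,
                       plant_resistant = FALSE)
  expect_false(identical(a$log_expression, c$log_expression))
})

test_that("branch-specific programs are exactly zero off-branch", {
  tr <- generate_tree_topology("y")
  lat <- sample_latent_positions(tr, 100, seed = 12)
  co <- generate_expression(lat$positions, lat$truth, n_genes = 60,
                            frac_increasing = 0, frac_decreasing = 0,
                            frac_branch_specific = 0.2, noise_sd = 1e-12,
                            signal_scale = 0, seed = 12)
  progs <- co$truth$gene_programs
  bs <- names(progs)[progs == "branch_specific"]
  for (g in bs) {
    tgt <- co$truth$program_branch[g]
    off <- lat$truth$true_branch != tgt
    expect_true(all(abs(co$log_expression[g, off]) < 1e-9))
    expect_true(all(abs(co$log_expression[g, !off] - 1.5) < 1e-9))
  }
})
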