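test_that("generate_network delivers exact counts, near-spanning connectivity and self-loops", {
  tree <- generate_network(10, 9, seed = 1)
  expect_length(tree$nodes, 10L)
  expect_equal(nrow(tree$edges), 9L)
  expect_equal(igraph::components(phasenet:::as_igraph(tree))$no, 1L)

  for (model in c("duplication-divergence", "configuration")) {
    net <- generate_network(200, 1060, model = model, self_loop_rate = 0.05,
                            seed = 2)
    expect_length(net$nodes, 200L)
    expect_equal(nrow(net$edges), 1060L)
    expect_length(net$self_loops, 10L)
    comp <- igraph::components(phasenet:::as_igraph(net))
    expect_gte(max(comp$csize), 0.95 * 200)
  }
  expect_identical(generate_network(50, 120, seed = 5),
                   generate_network(50, 120, seed = 5))
  expect_error(generate_network(10, 5, seed = 1), "infeasible")
  expect_error(generate_network(10, 60, seed = 1), "infeasible")
})

test_that("network generation reaches the scale of a curated disease interactome", {
  net <- generate_network(1100, 5827, seed = 3)
  expect_length(net$nodes, 1100L)
  expect_equal(nrow(net$edges), 5827L)
})

test_that("planted modules are connected supersets of a shared core", {
  net <- generate_network(150, 800, seed = 4)
  truth <- plant_modules(net, sizes = c(30, 30, 40), core_size = 15, seed = 4)
  adj <- phasenet:::adjacency_list(net)
  expect_length(truth$core, 15L)
  expect_equal(lengths(truth$modules), c(`early-middle` = 30L,
                                         `middle-late` = 30L,
                                         `early-late` = 40L))
  for (m in truth$modules) {
    expect_true(all(truth$core %in% m))
    expect_true(phasenet:::is_connected_set(adj, m))
  }
  expect_gte(length(Reduce(intersect, truth$modules)), 15L)
  same <- plant_modules(net, sizes = c(12, 12, 12), core_size = 12, seed = 5)
  expect_equal(same$modules[[1]], same$modules[[2]])
  expect_equal(same$modules[[3]], same$core)
  expect_error(plant_modules(net, sizes = c(200, 30, 30), core_size = 5),
               "exceed")
})

test_that("generated profiles respect coverage, label and finiteness invariants", {
  net <- generate_network(120, 640, seed = 6)
  truth <- plant_modules(net, sizes = c(20, 20, 20), core_size = 8, seed = 6)
  prs <- generate_profiles(net, truth, n_profiles = 3, samples_per_phase = 4,
                           coverage = 0.8, seed = 6)
  truth_genes <- unique(unlist(truth$modules))
  for (pr in prs) {
    expect_s3_class(pr, "expression_profile")
    expect_true(all(is.finite(pr$values)))
    expect_equal(unname(table(pr$sample_phases)[c("early", "middle", "late",
                                                  "control")]),
                 rep(4L, 4), ignore_attr = TRUE)
    expect_gte(mean(truth_genes %in% rownames(pr$values)), 0.9)
  }
  full <- generate_profiles(net, truth, n_profiles = 2, samples_per_phase = 3,
                            coverage = 1, seed = 7)
  expect_setequal(rownames(full[[1]]$values), net$nodes)
  expect_setequal(rownames(full[[2]]$values), net$nodes)
})

test_that("a zero effect size produces null differential signal on planted genes", {
  net <- generate_network(100, 530, seed = 8)
  truth <- plant_modules(net, sizes = c(20, 20, 20), core_size = 8, seed = 8)
  prs <- generate_profiles(net, truth, n_profiles = 1, samples_per_phase = 8,
                           delta = 0, coverage = 1, seed = 8)
  de <- moderated_t_test(prs[[1]], "early-late")
  planted <- de$p_raw[de$gene %in% truth$modules[["early-late"]]]
  expect_gt(suppressWarnings(stats::ks.test(de$p_raw, "punif"))$p.value, 0.01)
  expect_lte(mean(planted < 0.05), 0.25)
})

test_that("a strong effect size gives near-complete power on planted genes", {
  net <- generate_network(150, 800, seed = 9)
  truth <- plant_modules(net, sizes = c(25, 25, 25), core_size = 10, seed = 9)
  prs <- generate_profiles(net, truth, n_profiles = 1, samples_per_phase = 10,
                           delta = 5, sigma = 1, coverage = 1, seed = 9)
  de <- moderated_t_test(prs[[1]], "early-middle")
  planted <- de$p_adj[de$gene %in% truth$modules[["early-middle"]]]
  expect_gte(mean(planted < 0.01), 0.95)
})

test_that("known lists mix the requested fraction of core genes", {
  net <- generate_network(100, 530, seed = 10)
  truth <- plant_modules(net, sizes = c(20, 20, 20), core_size = 10, seed = 10)
  kl <- make_known_list(truth, net, size = 30, core_fraction = 0.5, seed = 10)
  expect_length(kl, 30L)
  expect_equal(sum(kl %in% truth$core), 10L)  # capped by the core size
  kl2 <- make_known_list(truth, net, size = 16, core_fraction = 0.5, seed = 10)
  expect_equal(sum(kl2 %in% truth$core), 8L)
})

test_that("recovery metrics follow the precision/recall arithmetic", {
  truth <- list(core = sprintf("c%02d", 1:10))
  class(truth) <- "synthetic_truth"
  expect_equal(recovery_metrics(truth, truth$core),
               c(precision = 1, recall = 1, f1 = 1))
  expect_equal(recovery_metrics(truth, c("x", "y")),
               c(precision = 0, recall = 0, f1 = 0))
  found <- c(truth$core[1:8], sprintf("x%02d", 1:8))
  m <- recovery_metrics(truth, found)
  expect_equal(unname(m["precision"]), 0.5)
  expect_equal(unname(m["recall"]), 0.8)
  expect_equal(unname(m["f1"]), 2 * 0.5 * 0.8 / 1.3, tolerance = 1e-12)
  expect_message(m0 <- recovery_metrics(truth, character()), "empty")
  expect_equal(unname(m0["f1"]), 0)
})

test_that("the synthetic bundle is fully reproducible under a master seed", {
  b1 <- synthetic_bundle(n_nodes = 80, n_edges = 420, sizes = c(12, 12, 12),
                         core_size = 6, samples_per_phase = 3, seed = 11)
  b2 <- synthetic_bundle(n_nodes = 80, n_edges = 420, sizes = c(12, 12, 12),
                         core_size = 6, samples_per_phase = 3, seed = 11)
  expect_identical(b1$network, b2$network)
  expect_identical(b1$truth, b2$truth)
  expect_identical(lapply(b1$profiles, `[[`, "values"),
                   lapply(b2$profiles, `[[`, "values"))
  expect_identical(b1$known_lists, b2$known_lists)
})
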