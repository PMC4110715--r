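test_that("score_subnetwork evaluates the aggregate z formula", {
  z <- c(a = 2, b = 1, c = 1, d = 1, e = 1, f = 0)
  expect_equal(score_subnetwork(z, "a"), 2)
  expect_equal(score_subnetwork(z, c("b", "c", "d", "e")), 2)
  expect_equal(score_subnetwork(c(x = 0, y = 0), c("x", "y")), 0)
  expect_error(score_subnetwork(z, character()), "empty")
  expect_error(score_subnetwork(z, "zz"), "zz")
  # relabeling invariance
  z2 <- stats::setNames(z, paste0("r_", names(z)))
  expect_equal(score_subnetwork(z2, c("r_b", "r_c")),
               score_subnetwork(z, c("b", "c")))
  # adding a zero-score gene dilutes by sqrt(k / (k + 1))
  s4 <- score_subnetwork(z, c("b", "c", "d", "e"))
  s5 <- score_subnetwork(z, c("b", "c", "d", "e", "f"))
  expect_equal(s5, s4 * sqrt(4 / 5))
})

test_that("Monte-Carlo calibration matches sampling theory and exact moments", {
  set.seed(201)
  z <- stats::setNames(rnorm(500), sprintf("g%03d", 1:500))
  cs <- calibrate_scores(z, k = 10, reps = 1000, seed = 4)
  expect_lt(abs(cs[["mean"]]), 4 / sqrt(1000))
  nm <- null_moments(z, 10)
  expect_lt(abs(cs[["mean"]] - nm[["mean"]]), 4 * nm[["sd"]] / sqrt(1000))
  expect_lt(abs(cs[["sd"]] - nm[["sd"]]) / nm[["sd"]], 0.15)
})

test_that("degenerate null score distributions are rejected", {
  z <- stats::setNames(rep(2, 6), letters[1:6])
  expect_error(calibrate_scores(z, k = 3, seed = 1), "sd = 0")
  z2 <- stats::setNames(rnorm(6), letters[1:6])
  expect_error(calibrate_scores(z2, k = 6, seed = 1), "sd = 0")
  expect_error(null_moments(z, 3), "sd = 0")
})

test_that("greedy search is exact on the path fixture", {
  net <- build_network(data.frame(source = c("a", "b"), target = c("b", "c")))
  z <- c(a = 3, b = 3, c = -5)
  mods <- greedy_search(net, z, calibrated = FALSE)
  expect_equal(mods[[1]]$genes, c("a", "b"))
  expect_equal(mods[[1]]$z_agg, 6 / sqrt(2))
  expect_equal(mods[[1]]$z_agg, enum_connected_best(net, z, calibrated = FALSE))
})

test_that("greedy search attains the enumerated optimum on the star fixture", {
  net <- build_network(data.frame(source = rep("hub", 5),
                                  target = paste0("leaf", 1:5)))
  z <- c(hub = -1, stats::setNames(rep(2, 5), paste0("leaf", 1:5)))
  mods <- greedy_search(net, z, calibrated = FALSE)
  opt <- enum_connected_best(net, z, calibrated = FALSE)
  expect_equal(mods[[1]]$z_agg, opt)                 # 9 / sqrt(6)
  expect_gte(mods[[1]]$z_agg, max(z))                # beats any single seed
})

test_that("greedy search warns and returns nothing without positive scores", {
  net <- build_network(data.frame(source = "a", target = "b"))
  expect_warning(mods <- greedy_search(net, c(a = 0, b = 0)), "positive")
  expect_length(mods, 0L)
  expect_error(greedy_search(net, c(a = 1, b = 0), seed_genes = "zz"), "zz")
})

test_that("greedy modules are connected, deduplicated, ranked and reproducible", {
  set.seed(202)
  net <- random_connected_net(25, 0.15)
  z <- stats::setNames(rnorm(25, sd = 1.5), net$nodes)
  mods <- greedy_search(net, z, seed = 9)
  expect_gt(length(mods), 0L)
  adj <- phasenet:::adjacency_list(net)
  keys <- character()
  last <- Inf
  for (m in mods) {
    expect_true(phasenet:::is_connected_set(adj, m$genes))
    expect_equal(m$z_agg, sum(z[m$genes]) / sqrt(length(m$genes)))
    expect_lte(m$score_cal, last)
    last <- m$score_cal
    keys <- c(keys, paste(m$genes, collapse = "+"))
  }
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(vapply(mods, `[[`, numeric(1), "rank"), seq_along(mods))
  mods2 <- greedy_search(net, z, seed = 9)
  expect_identical(mods, mods2)
})

test_that("merge_top unions gene sets and attaches induced edges", {
  net <- random_connected_net(10, 0.5)
  mk <- function(genes, rank) structure(
    list(genes = sort(genes), z_agg = 1, score_cal = 1, rank = rank),
    class = "scored_subnetwork")
  g <- net$nodes
  one <- structure(list(mk(g[1:3], 1)), class = "active_module_list")
  core1 <- merge_top(one, net)
  expect_setequal(core1$genes, g[1:3])
  expect_true(all(core1$edges[, 1] %in% g[1:3] & core1$edges[, 2] %in% g[1:3]))

  disjoint <- structure(list(mk(g[1:3], 1), mk(g[4:7], 2)),
                        class = "active_module_list")
  expect_length(merge_top(disjoint, net)$genes, 7L)

  shared <- structure(list(mk(g[1:5], 1), mk(g[4:7], 2)),
                      class = "active_module_list")
  core3 <- merge_top(shared, net)
  expect_length(core3$genes, 7L)
  expect_equal(core3$provenance$ranks[core3$provenance$gene == g[4]], "1,2")

  expect_warning(empty <- merge_top(structure(list(),
                                              class = "active_module_list"),
                                    net), "no modules")
  expect_length(empty$genes, 0L)
})
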