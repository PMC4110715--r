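test_that("overlap_percentage implements the Jaccard-style overlap formula", {
  expect_equal(overlap_percentage(c("a", "b"), c("a", "b")), 100)
  expect_equal(overlap_percentage(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_percentage(c("a", "b", "c"), c("b", "c", "d")), 50)
  expect_error(overlap_percentage(character(), character()), "empty")
  # symmetry, and 100 only for equal sets
  expect_equal(overlap_percentage(letters[1:4], letters[3:8]),
               overlap_percentage(letters[3:8], letters[1:4]))
  expect_lt(overlap_percentage(letters[1:4], letters[1:5]), 100)
  # monotone in the intersection at fixed union
  expect_lt(overlap_percentage(c("a", "b", "x"), c("c", "d", "x")),
            overlap_percentage(c("a", "b", "x"), c("a", "b", "c", "d", "x")) + 100)
})

fake_core <- function(genes, measured = NULL, id = "p") {
  structure(list(profile_id = id, contrast = "early-middle",
                 genes = sort(genes), measured = measured),
            class = "core_subnetwork")
}

test_that("consensus_genes applies the shared-by-all rule with coverage awareness", {
  cores <- list(fake_core(c("a", "b"), id = "p1"),
                fake_core(c("a", "b", "c"), id = "p2"),
                fake_core(c("a", "c"), id = "p3"))
  expect_equal(consensus_genes(cores), "a")
  # b is in 2 of 3 while covered by all three platforms: excluded at tau = 1
  expect_false("b" %in% consensus_genes(cores))
  expect_setequal(consensus_genes(cores, tau = 2 / 3), c("a", "b", "c"))
  # unmeasured platforms are not counted against a gene
  cores2 <- list(fake_core(c("a", "b"), measured = c("a", "b", "c"), id = "p1"),
                 fake_core(c("a", "b"), measured = c("a", "b", "c"), id = "p2"),
                 fake_core("a", measured = "a", id = "p3"))
  expect_setequal(consensus_genes(cores2, respect_coverage = TRUE), c("a", "b"))
  expect_equal(consensus_genes(cores2, respect_coverage = FALSE), "a")
  expect_error(consensus_genes(cores, tau = 1.5), "tau")
  expect_error(consensus_genes(cores[1]), ">= 2")
  # order invariance
  expect_equal(consensus_genes(cores[c(3, 1, 2)]), consensus_genes(cores))
})

test_that("build_module attaches the exact induced interactions", {
  net <- build_network(data.frame(
    source = c("a", "b", "c", "c", "d", "e"),
    target = c("b", "c", "a", "d", "e", "f")))
  tri <- build_module(c("a", "b", "c"), net, "early-middle")
  expect_equal(nrow(tri$edges), 3L)
  expect_equal(nrow(build_module(c("a", "e"), net, "middle-late")$edges), 0L)
  expect_equal(nrow(build_module(c("a", "b", "c", "d", "e", "f"), net,
                                 "early-late")$edges), 6L)
  expect_error(build_module("zz", net, "early-late"), "zz")
})

test_that("unique signatures and common candidates partition as set arithmetic dictates", {
  net <- build_network(data.frame(
    source = c("a", "a", "a", "a", "a", "a"),
    target = c("b", "c", "d", "x", "e", "f")))
  mk <- function(genes, ct) build_module(genes, net, ct)
  same <- unique_and_common(list(mk(c("a", "b"), "early-middle"),
                                 mk(c("a", "b"), "middle-late"),
                                 mk(c("a", "b"), "early-late")))
  expect_true(all(lengths(same$unique) == 0))
  expect_equal(as.character(same$common), c("a", "b"))

  disj <- unique_and_common(list(mk("b", "early-middle"),
                                 mk("c", "middle-late"),
                                 mk("d", "early-late")))
  expect_length(disj$common, 0L)
  expect_equal(disj$unique$`early-middle`, "b")

  mix <- unique_and_common(list(mk(c("a", "b", "c", "x"), "early-middle"),
                                mk(c("a", "b", "d", "x"), "middle-late"),
                                mk(c("a", "c", "d", "x"), "early-late")))
  expect_equal(as.character(mix$common), c("a", "x"))
  expect_true(all(lengths(mix$unique) == 0))
  expect_length(intersect(unlist(mix$unique), mix$common), 0L)

  expect_error(unique_and_common(list(mk("a", "early-middle"),
                                      mk("b", "early-middle"),
                                      mk("c", "early-late"))), "duplicate")
  expect_error(unique_and_common(list(mk("a", "early-middle"))), "three")
})

test_that("common candidates never exceed the smallest module", {
  set.seed(301)
  net <- random_connected_net(15, 0.3)
  mods <- lapply(c("early-middle", "middle-late", "early-late"), function(ct)
    build_module(sample(net$nodes, sample(3:8, 1)), net, ct))
  uc <- unique_and_common(mods)
  expect_lte(length(uc$common), min(lengths(lapply(mods, `[[`, "genes"))))
})
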