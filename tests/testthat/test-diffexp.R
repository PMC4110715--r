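test_that("moderated t with d0 = 0 reproduces the ordinary pooled t-test", {
  set.seed(101)
  pr <- two_phase_profile(25, n = 5, delta = 1.5, shifted = 1:5)
  res <- moderated_t_test(pr, "early-middle", d0 = 0)
  grp <- pr$sample_phases
  for (i in c(1, 7, 25)) {
    tt <- t.test(pr$values[i, grp == "middle"], pr$values[i, grp == "early"],
                 var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_raw[i], tt$p.value, tolerance = 1e-10)
  }
  expect_true(all(res$p_adj >= res$p_raw))
})

test_that("moderated t with d0 = Inf uses the prior variance for every gene", {
  set.seed(102)
  pr <- two_phase_profile(12, n = 4)
  s02 <- 0.7
  res <- moderated_t_test(pr, "early-middle", d0 = Inf, s02 = s02)
  grp <- pr$sample_phases
  eff <- rowMeans(pr$values[, grp == "middle"]) -
    rowMeans(pr$values[, grp == "early"])
  expect_equal(res$t_mod, unname(eff / sqrt(s02 * (1 / 4 + 1 / 4))),
               tolerance = 1e-12)
  expect_true(all(is.infinite(res$df_total)))
})

test_that("empirical-Bayes moderated t agrees with limma on a shared fixture", {
  set.seed(103)
  pr <- two_phase_profile(200, n = 4, delta = 2, shifted = 1:20)
  res <- moderated_t_test(pr, "early-middle")
  expect_gt(attr(res, "d0"), 0)
  grp <- factor(pr$sample_phases, levels = c("early", "middle"))
  design <- stats::model.matrix(~grp)
  fit <- limma::eBayes(limma::lmFit(pr$values, design))
  expect_gt(stats::cor(res$t_mod, fit$t[, 2]), 0.99)
  expect_true(all(sign(res$t_mod) == sign(fit$t[, 2])))
})

test_that("degenerate and undersized inputs are rejected with informative errors", {
  vals <- matrix(1:12, nrow = 2,
                 dimnames = list(c("g1", "g2"), sprintf("s%d", 1:6)))
  ph <- stats::setNames(c("early", "early", "middle", "middle", "late", "late"),
                        colnames(vals))
  pr <- expression_profile("p", vals, ph)
  # constant within-group values: zero residual variance everywhere
  vals2 <- matrix(rep(c(1, 2), each = 2, times = 2), nrow = 2, byrow = TRUE,
                  dimnames = dimnames(vals[, 1:4]))
  expect_error(
    moderated_t_test(expression_profile("p", vals2, ph[1:4]), "early-middle"),
    "zero residual variance")
  ph3 <- ph; ph3[3] <- "early"           # leaves one middle sample
  expect_error(
    moderated_t_test(expression_profile("p", vals, ph3), "early-middle"),
    "middle")
})

test_that("raw p-values are uniform under the two-group null", {
  set.seed(104)
  pr <- two_phase_profile(1000, n = 8)
  res <- moderated_t_test(pr, "early-middle")
  ks <- suppressWarnings(stats::ks.test(res$p_raw, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("bh_adjust applies the step-up rule and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_error(bh_adjust(c(0.5, 0)), "index 2")
  expect_error(bh_adjust(c(1.2)), "index 1")
  set.seed(105)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(!is.unsorted(bh_adjust(sort(p))))
})

test_that("p_to_z maps p-values to finite significance z-scores", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.0228), 2.0, tolerance = 1e-3)
  expect_equal(p_to_z(1), qnorm(1e-16), tolerance = 0.005)  # clamped, about -8.2
  expect_true(is.finite(p_to_z(1)))
  expect_error(p_to_z(0), "outside")
  expect_error(p_to_z(1.01), "outside")
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(p_to_z(p)) < 0))   # strictly decreasing
})

test_that("node_scores assigns z = 0 to unmeasured network genes and flags coverage", {
  set.seed(106)
  pr <- two_phase_profile(6, n = 3)
  net <- build_network(data.frame(source = c("gene001", "gene002", "extra1"),
                                  target = c("gene002", "extra1", "gene003")))
  de <- moderated_t_test(pr, "early-middle")
  z <- node_scores(de, net)
  expect_setequal(names(z), net$nodes)
  expect_equal(unname(z["extra1"]), 0)
  expect_setequal(attr(z, "measured"), c("gene001", "gene002", "gene003"))
  expect_true(all(is.finite(z)))
})
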