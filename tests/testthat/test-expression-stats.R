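# Reporter metabolites, greedy subnetwork, Welch/BH, and DE merging.

test_that("reporter z_raw follows the quantile transform exactly", {
  m <- make_pathway_model(5)  # M1..M5 chain, one gene per reaction
  # all neighbour genes at p = 0.5 -> z_raw 0
  pv <- stats::setNames(rep(0.5, 4), sprintf("g%02d", 1:4))
  rs <- reporter_metabolites(m, pv, n_background = 500, seed = 1)
  expect_equal(rs$z_raw, rep(0, nrow(rs)), tolerance = 1e-12)
  # single neighbour gene at p = 0.0228 -> z_raw ~ 2.00
  pv2 <- stats::setNames(0.0228, "g01")
  rs2 <- reporter_metabolites(m, pv2, n_background = 500, seed = 1)
  expect_equal(rs2$z_raw[rs2$metabolite == "M01[c]"],
               stats::qnorm(1 - 0.0228), tolerance = 1e-9)
  expect_equal(rs2$z_raw[rs2$metabolite == "M01[c]"], 2.0, tolerance = 0.01)
  expect_error(reporter_metabolites(m, c(offmodel = 0.1)), "no overlap")
})

test_that("null reporter scores are approximately standard normal after correction", {
  m <- make_genes_model(n_mets = 60, n_genes = 50, seed = 4)
  set.seed(8)
  pv <- stats::setNames(runif(50), sprintf("g%02d", 1:50))
  rs <- reporter_metabolites(m, pv, n_background = 2000, seed = 2)
  zc <- rs$z_corrected[rs$k >= 3]
  expect_gte(length(zc), 10)
  expect_lt(abs(mean(zc)), 0.1)
  expect_gt(sd(zc), 0.8)
  expect_lt(sd(zc), 1.2)
})

test_that("greedy subnetwork recovers a planted stretch and matches exhaustive search", {
  m <- make_pathway_model(10)
  planted_genes <- sprintf("g%02d", 2:7)   # makes M03..M07 doubly planted
  pv <- stats::setNames(rep(0.5, 9), sprintf("g%02d", 1:9))
  pv[planted_genes] <- 1e-6
  rs <- reporter_metabolites(m, pv, n_background = 2000, seed = 3)
  sub <- greedy_reporter_subnetwork(m, rs, size_limit = 5)
  planted_mets <- sprintf("M%02d[c]", 3:7)
  expect_setequal(sub$metabolites, planted_mets)
  scores <- stats::setNames(rs$z_corrected, rs$metabolite)
  oracle <- oracle_best_subnetwork(m, scores, 5)
  expect_equal(sub$mean_z, oracle$mean, tolerance = 1e-9)
  expect_setequal(sub$metabolites, oracle$metabolites)
})

test_that("subnetwork stops at a single scored metabolite among nulls", {
  m <- make_pathway_model(6)
  pv <- stats::setNames(rep(0.9, 5), sprintf("g%02d", 1:5))
  pv["g03"] <- 1e-8
  rs <- reporter_metabolites(m, pv, n_background = 2000, seed = 5)
  sub <- greedy_reporter_subnetwork(m, rs, size_limit = 4)
  best <- rs$metabolite[which.max(rs$z_corrected)]
  expect_true(best %in% sub$metabolites)
  expect_lte(length(sub$metabolites), 2)  # only the planted neighbourhood
})

test_that("welch_test matches the closed-form statistic and edge cases", {
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  w <- welch_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
  # hand computation: means 2.5/4.5, var 5/3 each, se = sqrt(2*5/12)
  t_hand <- (2.5 - 4.5) / sqrt(5 / 3 / 4 + 5 / 3 / 4)
  expect_equal(w$t, t_hand, tolerance = 1e-9)
  expect_equal(w$t, -2.1909, tolerance = 1e-4)
  expect_equal(w$df, 6, tolerance = 1e-9)
  # scale invariance
  w10 <- welch_test(10 * c(1, 2, 3, 4), 10 * c(3, 4, 5, 6))
  expect_equal(w10$t, w$t, tolerance = 1e-9)
  expect_equal(w10$p_value, w$p_value, tolerance = 1e-12)
  # degenerate: both constant
  expect_equal(welch_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(welch_test(c(2, 2), c(3, 3)), "constant")
  # equal variance and size: identical t to the pooled test, different df
  a <- c(1, 2, 3, 4, 6); b <- c(2, 3, 4, 5, 7)
  pooled <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(welch_test(a, b)$t, unname(pooled$statistic), tolerance = 1e-9)
})

test_that("BH adjustment matches step-up arithmetic and is order invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  q <- bh_fdr(p)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p[perm]), q[perm])
  # q >= p and monotone in rank order
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(numeric()), "empty")
})

test_that("segment merge keeps the lowest Q and drops direction conflicts", {
  t1 <- data.frame(gene_id = c("gA", "gB", "gC"), log2fc = c(1, 2, -1),
                   q_value = c(0.01, 0.01, 0.2), stringsAsFactors = FALSE)
  t2 <- data.frame(gene_id = c("gA", "gB", "gD"), log2fc = c(1.5, -2, 1),
                   q_value = c(0.04, 0.01, 0.03), stringsAsFactors = FALSE)
  merged <- merge_segment_de(list(t1, t2))
  # gA significant up twice: kept at its lowest Q
  expect_equal(merged$q_value[merged$gene_id == "gA"], 0.01)
  expect_equal(merged$log2fc[merged$gene_id == "gA"], 1)
  # gB significantly up and down: excluded entirely
  expect_false("gB" %in% merged$gene_id)
  expect_equal(attr(merged, "dropped"), "gB")
  # disjoint genes pass through
  expect_true(all(c("gC", "gD") %in% merged$gene_id))
})

test_that("compare_groups detects planted log-normal effects and controls the null", {
  sim <- make_metabolomics(n_analytes = 40, n_per_group = 6,
                           effect_sizes = c(rep(2, 20), rep(0, 20)), seed = 10)
  res <- compare_groups(sim$data)
  eff <- sim$truth$effect[match(res$analyte, sim$truth$analyte)]
  expect_gte(mean(res$q_value[eff == 2] < 0.05), 0.95)
})
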