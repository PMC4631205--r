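# Diet partitioning and the round-robin cross-feeding simulation.

test_that("diet grams split by class fractions with protein expanded to amino acids", {
  aa <- data.frame(aa = c("gly", "leu"), weight_fraction = c(0.5, 0.5),
                   molar_mass = c(0.075, 0.131))
  diet <- diet_composition(data.frame(
    name = c("casein", "starch"),
    class = c("protein", "digestible_carb"),
    grams_per_day = c(100, 18),
    molar_mass = c(NA, 0.18), stringsAsFactors = FALSE), aa_profile = aa)
  pools <- partition_diet(diet, partition_config(
    list(digestible_carb = c(bacteria = 0.4, colon = 0))))
  grams <- attr(pools, "grams")
  # protein: bacteria cap 40 g, colon 5 g, host the remaining 55 g
  expect_equal(grams$bacteria[grams$class == "protein"], 40)
  expect_equal(grams$colon[grams$class == "protein"], 5)
  expect_equal(grams$small_intestine[grams$class == "protein"], 55)
  # 18 g of a 0.18 g/mmol sugar at bacteria fraction 0.4 -> 40 mmol
  expect_equal(pools$bacteria[["starch"]], 40)
  # amino-acid expansion via the weight profile
  expect_equal(pools$bacteria[["gly"]], 40 * 0.5 / 0.075)
  expect_equal(pools$bacteria[["leu"]], 40 * 0.5 / 0.131)
})

test_that("zero diet gives empty pools; missing molar mass is an error", {
  diet <- diet_composition(data.frame(
    name = "starch", class = "digestible_carb", grams_per_day = 0,
    molar_mass = 0.18, stringsAsFactors = FALSE))
  pools <- partition_diet(diet)
  expect_equal(sum(unlist(pools)), 0)
  bad <- diet_composition(data.frame(
    name = "mystery", class = "fat", grams_per_day = 5,
    molar_mass = NA, stringsAsFactors = FALSE))
  expect_error(partition_diet(bad, partition_config(
    list(fat = c(bacteria = 0.5, colon = 0)))), "mystery")
})

test_that("cross-feeding: the consumer grows only via the producer's acetate", {
  pair <- make_crossfeed_pair()
  pools <- partition_diet(pair$diet)
  res <- simulate_community(list(pair$producer, pair$consumer),
                            pools$bacteria)
  expect_true(res$converged)
  expect_gt(res$growth[["producer"]], 0)
  expect_gt(res$growth[["consumer"]], 0)
  expect_gt(res$ledger$cross_fed[res$ledger$metabolite == "acetate"], 0)
  expect_gt(res$ledger$cross_fed[res$ledger$metabolite == "butyrate"], 0)
  # producer removed, sugar-only pool: consumer cannot grow
  solo <- simulate_community(list(pair$consumer), pools$bacteria["starch"])
  expect_equal(unname(solo$growth), 0)
  expect_equal(solo$rounds, 1)
  # solo growth bounds community growth from above (resources are shared);
  # on an uncontested pool (starch only) the two coincide, and the consumer
  # does at least as well in community as alone on the same pool
  solo_p <- simulate_community(list(pair$producer), pools$bacteria)
  expect_gte(solo_p$growth[["producer"]], res$growth[["producer"]] - 1e-6)
  starch_only <- pools$bacteria["starch"]
  both_s <- simulate_community(list(pair$producer, pair$consumer), starch_only)
  solo_s <- simulate_community(list(pair$producer), starch_only)
  expect_equal(both_s$growth[["producer"]], solo_s$growth[["producer"]],
               tolerance = 1e-6)
  solo_c <- simulate_community(list(pair$consumer), pools$bacteria)
  expect_gte(res$growth[["consumer"]], solo_c$growth[["consumer"]] - 1e-6)
})

test_that("the mass ledger closes per shared metabolite", {
  pair <- make_crossfeed_pair()
  pools <- partition_diet(pair$diet)
  res <- simulate_community(list(pair$producer, pair$consumer),
                            pools$bacteria)
  led <- res$ledger
  expect_true(all(led$consumed <= led$allocated + led$cross_fed + 1e-6))
  expect_true(all(led$residual >= -1e-6))
  expect_equal(led$residual, led$pool + led$cross_fed - led$consumed,
               tolerance = 1e-9)
  # empty pool: nothing moves, single round
  empty <- simulate_community(list(pair$producer, pair$consumer), numeric())
  expect_equal(unname(empty$growth), c(0, 0))
  expect_true(empty$converged)
})

test_that("doubling the pool doubles growth (LP homogeneity)", {
  pair <- make_crossfeed_pair(glucose_uptake_cap = 1000)
  pools <- partition_diet(pair$diet)
  r1 <- simulate_community(list(pair$producer, pair$consumer), pools$bacteria)
  r2 <- simulate_community(list(pair$producer, pair$consumer),
                           2 * pools$bacteria)
  expect_equal(unname(r2$growth), 2 * unname(r1$growth), tolerance = 1e-6)
})

test_that("a contested metabolite splits in proportion to probed demand", {
  # two identical consumers demanding the full pool each: a 10-unit pool
  # splits 5/5
  pair <- make_crossfeed_pair()
  c1 <- pair$consumer; c2 <- pair$consumer
  c2$model$id <- "consumer2"
  res <- simulate_community(list(c1, c2), c(acetate = 10))
  expect_equal(res$uptake[["consumer"]][["acetate"]], 5, tolerance = 1e-6)
  expect_equal(res$uptake[["consumer2"]][["acetate"]], 5, tolerance = 1e-6)
  # capacity-limited demand 10 vs 5 on a pool of 12 splits 8/4
  c3 <- pair$consumer
  c3$model <- set_bounds(c3$model, "EX_ac", lb = -10)
  c4 <- pair$consumer; c4$model$id <- "consumer2"
  c4$model <- set_bounds(c4$model, "EX_ac", lb = -5)
  res2 <- simulate_community(list(c3, c4), c(acetate = 12))
  expect_equal(res2$uptake[["consumer"]][["acetate"]], 8, tolerance = 1e-6)
  expect_equal(res2$uptake[["consumer2"]][["acetate"]], 4, tolerance = 1e-6)
})

test_that("amino-acid consumption is attributed structurally and exhaustion flagged", {
  pair <- make_crossfeed_pair()
  # remove the producer's glycine pathway so only the consumer can take it
  prod <- pair$producer
  prod$model <- set_bounds(prod$model, "R_gly_bio", ub = 0)
  res <- simulate_community(list(prod, pair$consumer),
                            c(starch = 10, gly = 5))
  rep <- consumption_report(res, "gly")
  expect_equal(rep$producer, 0, tolerance = 1e-9)
  expect_equal(rep$consumer, 5, tolerance = 1e-6)
  expect_true(rep$exhausted)
  expect_error(consumption_report(res, "nosuchacid"), "nosuchacid")
})
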