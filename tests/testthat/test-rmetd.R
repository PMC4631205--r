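# The relative-expression integration contract: mapped-gene rule, 20%
# product floors, +/-20% bound scaling, sensitivity, and invariants.

de_row <- function(gene, lfc, q) {
  data.frame(gene_id = gene, log2fc = lfc, q_value = q,
             stringsAsFactors = FALSE)
}

epithelium_cfg <- function(...) {
  rmetd_config(objective_products = c("EX_chylo", "EX_hdl"),
               cap_at_model_bounds = FALSE, ...)
}

test_that("mapped-gene rule: concordant, mixed and sub-threshold genes", {
  m <- make_toy_gem("chain")
  m$reactions$gpr[m$reactions$id == "R_conv"] <- "g1 or g2"
  up2 <- rbind(de_row("g1", 1, 0.01), de_row("g2", 2, 0.02))
  map <- map_de_to_reactions(m, up2)
  expect_equal(map$direction[map$reaction == "R_conv"], "up")
  expect_equal(map$reason[map$reaction == "R_conv"], "all-concordant")
  m$reactions$gpr[m$reactions$id == "R_conv"] <- "g1 and g2"
  mixed <- rbind(de_row("g1", 1, 0.01), de_row("g2", -1, 0.01))
  map2 <- map_de_to_reactions(m, mixed)
  expect_equal(map2$direction[map2$reaction == "R_conv"], "unchanged")
  expect_equal(map2$reason[map2$reaction == "R_conv"], "mixed-directions")
  map3 <- map_de_to_reactions(m, de_row("g1", 1, 0.20), q_threshold = 0.05)
  expect_false("R_conv" %in% map3$reaction)
  # off-model genes are ignored but counted
  map4 <- map_de_to_reactions(m, de_row("nosuch", 1, 0.01))
  expect_equal(nrow(map4), 0)
  expect_equal(attr(map4, "coverage")$unmatched, "nosuch")
})

test_that("product secretion floor is 20% of the individually maximised production", {
  # toy secretory model where the product maximum is 5
  ep <- make_toy_gem("epithelium")
  m <- set_bounds(ep, "EX_fat", lb = -5, ub = 0)   # relax windows
  m <- set_bounds(m, "EX_glc", lb = -10, ub = 0)
  pmax_ <- fba(m, objective = "EX_chylo")$objective_value
  cfg <- rmetd_config(objective_products = "EX_chylo")
  res <- run_rmetd(m, de_row("g_glyc", -1, 0.5), config = cfg)  # not significant
  floor_set <- res$reference_model$reactions$lb[
    res$reference_model$reactions$id == "EX_chylo"]
  expect_equal(floor_set, 0.2 * pmax_, tolerance = 1e-9)
  expect_equal(res$product_floors[["EX_chylo"]], 0.2 * pmax_, tolerance = 1e-9)
})

test_that("up/down scaling multiplies the reference FVA range by 1 +/- alpha", {
  ep <- make_toy_gem("epithelium")
  de <- rbind(de_row("g_fabp", 1, 0.01),
              de_row("g_gclc", -1, 0.01), de_row("g_gss", -1, 0.01))
  res <- run_rmetd(ep, de, config = epithelium_cfg())
  rb <- res$reference_bounds; cb <- res$condition_bounds
  up <- cb$reaction[cb$direction == "up"]; dn <- cb$reaction[cb$direction == "down"]
  expect_setequal(up, "R_lipid"); expect_setequal(dn, "R_gsh")
  i <- match("R_lipid", rb$reaction)
  expect_equal(cb$lb[i], rb$lb[i] * 1.2, tolerance = 1e-9)
  expect_equal(cb$ub[i], rb$ub[i] * 1.2, tolerance = 1e-9)
  j <- match("R_gsh", rb$reaction)
  expect_equal(cb$lb[j], rb$lb[j] * 0.8, tolerance = 1e-9)
  expect_equal(cb$ub[j], rb$ub[j] * 0.8, tolerance = 1e-9)
})

test_that("a known scaled interval: [2,4] goes to [2.4,4.8] up and [1.6,3.2] down", {
  expect_equal(gutflux:::scale_interval(2, 4, 1.2), c(2.4, 4.8))
  expect_equal(gutflux:::scale_interval(2, 4, 0.8), c(1.6, 3.2))
  # signed interval scales away from / toward zero on both sides
  expect_equal(gutflux:::scale_interval(-5, 10, 1.2), c(-6, 12))
})

test_that("empty DE table leaves reference and condition identical (ratios 1)", {
  ep <- make_toy_gem("epithelium")
  empty <- de_row(character(), numeric(), numeric())
  res <- run_rmetd(ep, empty, config = epithelium_cfg())
  expect_equal(res$product_comparison$ratio, c(1, 1), tolerance = 1e-6)
  expect_equal(res$reference_solution$objective_value,
               res$condition_solution$objective_value, tolerance = 1e-6)
  scan <- sensitivity_scan(ep, empty, config = epithelium_cfg())
  expect_true(all(abs(scan$ratio - 1) < 1e-6))
})

test_that("down-regulated lipid route lowers chylomicron secretion, stably in alpha", {
  ep <- make_toy_gem("epithelium")
  de <- make_toy_gem("epithelium") |> make_de_table(fraction_up = 0,
                                                    fraction_down = 1, seed = 3)
  res <- run_rmetd(ep, de$de, config = epithelium_cfg())
  cmp <- res$product_comparison
  expect_lt(cmp$condition[cmp$product == "EX_chylo"],
            cmp$reference[cmp$product == "EX_chylo"])
  scan <- sensitivity_scan(ep, de$de, config = epithelium_cfg(),
                           alphas = c(0.1, 0.2, 0.3))
  expect_true(attr(scan, "stable"))
  expect_true(all(scan$status == "optimal"))
  # singleton scan equals run_rmetd
  one <- sensitivity_scan(ep, de$de, config = epithelium_cfg(), alphas = 0.2)
  expect_equal(one$condition, unname(cmp$condition), tolerance = 1e-9)
})

test_that("all-down DE never increases the achievable primary product maximum", {
  ep <- make_toy_gem("epithelium")
  base_max <- fba(ep)$objective_value
  for (seed in 1:3) {
    de <- make_de_table(ep, fraction_up = 0, fraction_down = 1, seed = seed)
    res <- run_rmetd(ep, de$de, config = epithelium_cfg())
    cond_max <- fba(res$condition_model, objective = "EX_chylo")$objective_value
    expect_lte(cond_max, base_max + 1e-6)
  }
})

test_that("scaling depends only on range and direction, not iteration order", {
  ep <- make_toy_gem("epithelium")
  de <- make_de_table(ep, fraction_up = 0.3, fraction_down = 0.3, seed = 5)$de
  res1 <- run_rmetd(ep, de, config = epithelium_cfg())
  res2 <- run_rmetd(ep, de[rev(seq_len(nrow(de))), ], config = epithelium_cfg())
  b1 <- res1$condition_bounds[order(res1$condition_bounds$reaction), ]
  b2 <- res2$condition_bounds[order(res2$condition_bounds$reaction), ]
  expect_equal(b1$lb, b2$lb, tolerance = 1e-12)
  expect_equal(b1$ub, b2$ub, tolerance = 1e-12)
})

test_that("raising the product floor cannot shrink the parsimonious total flux", {
  ep <- make_toy_gem("epithelium")
  de <- de_row("g_apoa1", -1, 0.01)
  total <- vapply(c(0.1, 0.2, 0.4), function(f) {
    cfg <- rmetd_config(objective_products = c("EX_chylo", "EX_hdl"),
                        product_floor_fraction = f,
                        cap_at_model_bounds = FALSE)
    run_rmetd(ep, de, config = cfg)$reference_solution$total_flux
  }, numeric(1))
  expect_true(all(diff(total) > -1e-6))
})

test_that("infeasible scaled bounds produce an elastic diagnosis, not silence", {
  ep <- make_toy_gem("epithelium")
  # cap at the forced uptake windows: down-scaled windows clash with them
  cfg <- rmetd_config(objective_products = c("EX_chylo", "EX_hdl"),
                      cap_at_model_bounds = TRUE)
  de <- make_de_table(ep, fraction_up = 0, fraction_down = 1, seed = 3)
  res <- run_rmetd(ep, de$de, config = cfg)
  if (res$condition_solution$status != "optimal") {
    expect_gt(length(res$diagnostics), 0)
  } else {
    succeed("capped run stayed feasible")
  }
})
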