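test_that("toy_tsv round-trips explicit fields", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlb\tub\tgpr\tobjective",
               "EX_A\tA[e] =>\t-10\t0\t\t",
               "R1\tA[e] => B[c]\t0\t1000\tg1 and g2\t",
               "EX_B\tB[c] =>\t0\t1000\t\tmax"), tsv)
  m <- load_model(tsv, format = "toy_tsv")
  expect_equal(nrow(m$reactions), 3)
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(m$reactions$lb[m$reactions$id == "EX_A"], -10)
  expect_equal(m$objective$reaction, "EX_B")
  expect_equal(sort(model_genes(m)), c("g1", "g2"))
  expect_equal(m$stoichiometry$R1, c("A[e]" = -1, "B[c]" = 1))
})

test_that("equation parser handles coefficients, reversibility and exchanges", {
  eq <- parse_equation("2 A[c] + B[c] => C[e]")
  expect_equal(eq$stoich, c("A[c]" = -2, "B[c]" = -1, "C[e]" = 1))
  expect_false(eq$reversible)
  expect_true(parse_equation("A[c] <=> B[c]")$reversible)
  expect_equal(parse_equation("A[e] =>")$stoich, c("A[e]" = -1))
  expect_error(parse_equation("A[c] B[c]"), "no '=>'")
})

test_that("SBML save/load preserves element sets, bounds, objective and GPR truth tables", {
  for (template in c("chain", "diamond", "epithelium")) {
    m <- make_toy_gem(template)
    path <- tempfile(fileext = ".xml")
    save_model(m, path)
    m2 <- load_model(path)
    expect_equal(element_sets(m2)$reaction_ids, element_sets(m)$reaction_ids)
    expect_equal(element_sets(m2)$metabolite_ids, element_sets(m)$metabolite_ids)
    expect_equal(element_sets(m2)$gene_ids, element_sets(m)$gene_ids)
    i <- match(m$reactions$id, m2$reactions$id)
    expect_equal(m2$reactions$lb[i], m$reactions$lb, tolerance = 1e-9)
    expect_equal(m2$reactions$ub[i], m$reactions$ub, tolerance = 1e-9)
    expect_equal(m2$objective$reaction, m$objective$reaction)
    # GPR logical equivalence over all gene on/off assignments
    for (j in seq_len(nrow(m$reactions))) {
      g <- gpr_genes(m$reactions$gpr[j])
      if (!length(g) || length(g) > 4) next
      for (mask in 0:(2^length(g) - 1)) {
        act <- stats::setNames(as.logical(bitwAnd(mask, 2^(seq_along(g) - 1))), g)
        expect_equal(gpr_eval(m2$reactions$gpr[i[j]], act),
                     gpr_eval(m$reactions$gpr[j], act))
      }
    }
  }
})

test_that("nested AND/OR GPR survives the SBML round trip logically intact", {
  m <- make_toy_gem("chain")
  m$reactions$gpr[2] <- "g1 and (g2 or g3)"
  path <- tempfile(fileext = ".xml")
  save_model(m, path)
  m2 <- load_model(path)
  g <- c("g1", "g2", "g3")
  for (mask in 0:7) {
    act <- stats::setNames(as.logical(bitwAnd(mask, c(1, 2, 4))), g)
    expect_equal(gpr_eval(m2$reactions$gpr[m2$reactions$id == "R_conv"], act),
                 gpr_eval("g1 and (g2 or g3)", act))
  }
})

test_that("models with no GPRs write SBML without gene-association blocks", {
  m <- make_toy_gem("chain")
  path <- tempfile(fileext = ".xml")
  save_model(m, path)
  txt <- readLines(path)
  expect_false(any(grepl("geneProductAssociation", txt)))
  expect_false(any(grepl("listOfGeneProducts", txt)))
  expect_length(element_sets(load_model(path))$gene_ids, 0)
})

test_that("a reaction referencing an undeclared metabolite fails validation", {
  expect_error(
    make_model("bad",
               metabolites = data.frame(id = "A[c]", name = "A", compartment = "c"),
               reactions = data.frame(id = "R1", lb = 0, ub = 10),
               stoichiometry = list(R1 = c("A[c]" = -1, "ghost[c]" = 1))),
    "R1.*ghost")
  m <- make_toy_gem("chain")
  m$stoichiometry$R_conv <- c("A[e]" = -1, "ghost[c]" = 1)
  report <- validate_model(m, stop_on_error = FALSE)
  expect_true(any(grepl("R_conv", report)))
})

test_that("bound violations and bad objectives are reported", {
  m <- make_toy_gem("chain")
  m$reactions$lb[1] <- 5  # above ub = 0
  expect_match(validate_model(m, stop_on_error = FALSE), "lb > ub",
               all = FALSE)
  m2 <- make_toy_gem("chain")
  m2$objective$reaction <- "nope"
  expect_match(validate_model(m2, stop_on_error = FALSE), "objective",
               all = FALSE)
})

test_that("element sets are deterministic and exchange detection ignores order", {
  p <- tempfile(fileext = ".xml")
  save_model(make_toy_gem("epithelium"), p)
  a <- load_model(p); b <- load_model(p)
  expect_identical(element_sets(a), element_sets(b))
  m <- make_toy_gem("diamond")
  ex1 <- exchange_reactions(m)
  perm <- m
  perm$metabolites <- perm$metabolites[rev(seq_len(nrow(perm$metabolites))), ]
  expect_setequal(exchange_reactions(perm), ex1)
  expect_setequal(ex1, c("EX_A", "EX_P"))
})

test_that("diet bounds only touch the named exchanges", {
  m <- make_toy_gem("chain")
  m2 <- apply_diet_bounds(m, c(EX_A = 4))
  expect_equal(m2$reactions$lb[m2$reactions$id == "EX_A"], -4)
  expect_equal(m2$reactions$lb[m2$reactions$id == "R_conv"], 0)
  expect_error(apply_diet_bounds(m, c(EX_A = -1)), "non-negative")
})
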