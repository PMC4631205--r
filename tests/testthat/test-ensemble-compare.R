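# Hamming distances, heterogeneity degree, and core/unique statistics.

sets_of <- function(id, rxns = character(), mets = character(),
                    genes = character()) {
  structure(list(model_id = id, reaction_ids = sort(rxns),
                 metabolite_ids = sort(mets), gene_ids = sort(genes)),
            class = "element_sets")
}

test_that("presence matrix spans the union with correct row sums", {
  M <- presence_matrix(list(sets_of("m1", c("a", "b", "c")),
                            sets_of("m2", c("b", "c", "d"))), "reaction")
  expect_equal(dim(M), c(2, 4))
  expect_equal(unname(rowSums(M)), c(3, 3))
  # identical sets give identical rows
  M2 <- presence_matrix(list(sets_of("x", c("a", "b")),
                             sets_of("y", c("a", "b"))), "reaction")
  expect_equal(unname(M2[1, ]), unname(M2[2, ]))
  expect_error(presence_matrix(list(sets_of("m", "a"), sets_of("m", "b")),
                               "reaction"), "duplicate")
})

test_that("presence matrix columns equal the independent set union on generated models", {
  models <- list(make_toy_gem("chain"), make_toy_gem("diamond"),
                 make_toy_gem("futile_cycle"))
  sets <- lapply(models, element_sets)
  M <- presence_matrix(sets, "reaction")
  oracle_union <- Reduce(union, lapply(sets, `[[`, "reaction_ids"))
  expect_setequal(colnames(M), oracle_union)
})

test_that("Hamming totals decompose into directed counts and average rows", {
  M <- presence_matrix(list(sets_of("m1", c("a", "b", "c")),
                            sets_of("m2", c("b", "c", "d"))), "reaction")
  d <- pairwise_distances(M)
  expect_equal(d$pairs$a_minus_b, 1)
  expect_equal(d$pairs$b_minus_a, 1)
  expect_equal(d$pairs$total, 2)
  # directed decomposition: 401 one way + 77 the other = 478 total
  lung <- sprintf("core%03d", 1:200)
  stomach <- c(lung[1:123], sprintf("sto%02d", 1:77))
  lung_full <- c(lung, sprintf("lun%03d", 1:324))
  A <- sets_of("lung", genes = c(lung_full))
  B <- sets_of("stomach", genes = stomach)
  dg <- pairwise_distances(presence_matrix(list(A, B), "gene"))
  expect_equal(dg$pairs$a_minus_b, 401)
  expect_equal(dg$pairs$b_minus_a, 77)
  expect_equal(dg$pairs$total, 478)
  # identical sets: zero everywhere
  d0 <- pairwise_distances(presence_matrix(
    list(sets_of("x", "a"), sets_of("y", "a")), "reaction"))
  expect_equal(d0$pairs$total, 0)
})

test_that("heterogeneity degree is mean over max, with the stated edge cases", {
  same <- presence_matrix(list(sets_of("x", c("a", "b")),
                               sets_of("y", c("a", "b")),
                               sets_of("z", c("a", "b"))), "reaction")
  expect_equal(heterogeneity(same)$heterogeneity_degree, 0)
  two <- presence_matrix(list(sets_of("x", c("a", "b")),
                              sets_of("y", c("c", "d"))), "reaction")
  expect_equal(heterogeneity(two)$heterogeneity_degree, 1)
  # hand-enumerated pairwise distances 2, 2, 4 -> (8/3)/4
  tri <- presence_matrix(list(sets_of("x", c("a", "b")),
                              sets_of("y", c("a", "c")),
                              sets_of("z", c("d", "e"))), "reaction")
  # x~y: {b,c}=2; x~z: {a,b,d,e}=4; y~z: {a,c,d,e}=4 -- adjust to 2,2,4:
  tri2 <- presence_matrix(list(sets_of("x", c("a", "b")),
                               sets_of("y", c("a", "c")),
                               sets_of("z", c("b", "c", "d", "e"))), "reaction")
  d <- pairwise_distances(tri2)$pairs$total
  expect_setequal(d, c(2, 4, 4))
  h <- heterogeneity(tri2)
  expect_equal(h$heterogeneity_degree, mean(d) / max(d))
})

test_that("core statistics match set arithmetic and column sums", {
  sets <- list(sets_of("m1", c("a", "b", "c", "d")),
               sets_of("m2", c("a", "b", "d")),
               sets_of("m3", c("a", "b", "e")))
  M <- presence_matrix(sets, "reaction")
  cs <- core_statistics(M)
  # independent oracle by set operations
  ids <- lapply(sets, `[[`, "reaction_ids")
  expect_equal(cs$union_count, length(Reduce(union, ids)))
  expect_equal(cs$core_count, length(Reduce(intersect, ids)))
  tally <- table(unlist(ids))
  expect_equal(cs$unique_count, sum(tally == 1))
  expect_equal(cs$core_percentage, round(100 * 2 / 5, 1))
  # all elements everywhere -> 100%
  full <- presence_matrix(list(sets_of("x", c("a", "b")),
                               sets_of("y", c("a", "b"))), "reaction")
  expect_equal(core_statistics(full)$core_percentage, 100.0)
})

test_that("triangle inequality and permutation invariance hold on generated ensembles", {
  set.seed(7)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(i) {
      sets_of(paste0("m", i),
              sample(letters, sample(5:15, 1)))
    })
    M <- presence_matrix(sets, "reaction")
    tot <- pairwise_distances(M)$totals
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      expect_lte(tot[i, j], tot[i, k] + tot[k, j] + 1e-12)
    }
    perm <- sample(4)
    Mp <- presence_matrix(sets[perm], "reaction")
    expect_equal(heterogeneity(Mp)$heterogeneity_degree,
                 heterogeneity(M)$heterogeneity_degree)
    expect_equal(core_statistics(Mp), core_statistics(M))
    expect_equal(pairwise_distances(Mp)$average[rownames(M)],
                 pairwise_distances(M)$average)
  }
})
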