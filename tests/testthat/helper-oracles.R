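# Independent oracles used across the suite.
#
# oracle_lp(): brute-force vertex enumeration for tiny LPs over
# {Sv = 0, lb <= v <= ub}. A vertex fixes n - rank(S) variables at one of
# their bounds and solves the equality system for the rest; the optimum is
# the best objective value over all feasible candidates. Exponential, so
# only ever applied to models with a handful of reactions — by design it
# shares no code with the simplex under test.

oracle_lp <- function(model, objective, maximize = TRUE) {
  S <- stoichiometric_matrix(model)
  n <- nrow(model$reactions)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  cc <- numeric(n); cc[match(objective, model$reactions$id)] <- 1
  r <- if (nrow(S)) qr(S)$rank else 0
  k <- n - r
  best <- NULL; best_v <- NULL
  fix_sets <- utils::combn(n, k, simplify = FALSE)
  for (fix in fix_sets) {
    free <- setdiff(seq_len(n), fix)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(fix)))
    for (ci in seq_len(nrow(combos))) {
      v <- numeric(n)
      v[fix] <- ifelse(unlist(combos[ci, ]), ub[fix], lb[fix])
      if (length(free)) {
        A <- S[, free, drop = FALSE]
        rhs <- -as.vector(S[, fix, drop = FALSE] %*% v[fix])
        sol <- tryCatch(qr.solve(A, rhs, tol = 1e-10), error = function(e) NULL)
        if (is.null(sol)) next
        v[free] <- sol
        if (max(abs(S %*% v)) > 1e-8) next
      }
      if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) next
      val <- sum(cc * v)
      if (is.null(best) || (maximize && val > best) ||
          (!maximize && val < best)) {
        best <- val; best_v <- v
      }
    }
  }
  list(value = best, v = stats::setNames(best_v, model$reactions$id))
}

# Exhaustive best connected metabolite subset of a given size by mean score
# (bipartite adjacency through shared reactions).
oracle_best_subnetwork <- function(model, scores, size) {
  mets <- names(scores)
  adj <- function(a, b) {
    any(vapply(model$stoichiometry, function(st)
      a %in% names(st) && b %in% names(st), logical(1)))
  }
  connected <- function(set) {
    if (length(set) == 1) return(TRUE)
    seen <- set[1]; frontier <- set[1]
    while (length(frontier)) {
      nxt <- setdiff(set[vapply(set, function(m)
        any(vapply(frontier, adj, logical(1), a = m)), logical(1))], seen)
      seen <- union(seen, nxt); frontier <- nxt
    }
    length(seen) == length(set)
  }
  best <- NULL; best_mean <- -Inf
  for (set in utils::combn(mets, size, simplify = FALSE)) {
    if (!connected(set)) next
    m <- mean(scores[set])
    if (m > best_mean) { best_mean <- m; best <- set }
  }
  list(metabolites = sort(best), mean = best_mean)
}

# A linear pathway model: M1 -R1-> M2 -R2-> ... with one gene per internal
# reaction, used by reporter-metabolite tests.
make_pathway_model <- function(n_mets = 10) {
  rows <- list(list(id = "EX_in", eq = "M01[c] =>", lb = -10, ub = 0))
  gprs <- c()
  for (i in seq_len(n_mets - 1)) {
    id <- sprintf("R%02d", i)
    rows[[length(rows) + 1]] <- list(
      id = id,
      eq = sprintf("M%02d[c] => M%02d[c]", i, i + 1), lb = 0, ub = 1000)
    gprs[id] <- sprintf("g%02d", i)
  }
  rows[[length(rows) + 1]] <- list(
    id = "EX_out", eq = sprintf("M%02d[c] =>", n_mets), lb = 0, ub = 1000)
  gutflux:::toy_from_rows("pathway", rows, objective = "EX_out",
                          optimum = 10, gprs = gprs)
}

# Random many-gene network for null reporter calibration: a chain of
# reactions whose GPRs draw 2-4 genes from a fixed pool.
make_genes_model <- function(n_mets = 40, n_genes = 50, seed = 1) {
  set.seed(seed)
  rows <- list(list(id = "EX_in", eq = "N01[c] =>", lb = -10, ub = 0))
  gprs <- c()
  pool <- sprintf("g%02d", seq_len(n_genes))
  for (i in seq_len(n_mets - 1)) {
    id <- sprintf("R%02d", i)
    rows[[length(rows) + 1]] <- list(
      id = id, eq = sprintf("N%02d[c] => N%02d[c]", i, i + 1),
      lb = 0, ub = 1000)
    gg <- sample(pool, sample(2:4, 1))
    gprs[id] <- paste(gg, collapse = " or ")
  }
  rows[[length(rows) + 1]] <- list(
    id = "EX_out", eq = sprintf("N%02d[c] =>", n_mets), lb = 0, ub = 1000)
  gutflux:::toy_from_rows("genenet", rows, objective = "EX_out",
                          optimum = 10, gprs = gprs)
}

expect_fluxes_feasible <- function(model, fluxes, tol = 1e-6) {
  expect_lt(steady_state_residual(model, fluxes), tol)
  i <- match(names(fluxes), model$reactions$id)
  expect_true(all(fluxes >= model$reactions$lb[i] - tol))
  expect_true(all(fluxes <= model$reactions$ub[i] + tol))
}
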