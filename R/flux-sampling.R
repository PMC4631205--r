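# Uniform-style sampling of the feasible flux polytope and concordance
# calls for transcriptionally regulated reactions.
#
# The sampler is artificial-centering hit-and-run (ACHR): warmup points are
# LP vertices of the polytope (coordinate extrema first, then random
# objective directions); the chain walks along directions through the
# running centre, which concentrates steps along the polytope's long axes.
# All movement happens inside the null space of S, so every sample satisfies
# the steady-state constraint by construction; the walk is periodically
# re-projected to cancel numeric drift.

#' Sample the feasible flux region
#'
#' @param model A feasible, bounded `metabolic_model`.
#' @param n Number of samples to keep (default 5000).
#' @param seed Integer seed; identical seeds give bitwise-identical sample
#'   matrices.
#' @param warmup Number of warmup LP vertices (default 200).
#' @param thinning Keep every `thinning`-th point of the walk (default 10).
#' @return A `sample_set`: `samples` (n x reactions matrix), `reactions`,
#'   `seed`, `warmup`, `thinning`.
#' @export
sample_fluxes <- function(model, n = 5000, seed = 1, warmup = 200,
                          thinning = 10) {
  rxns <- model$reactions$id
  k <- length(rxns)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  S <- stoichiometric_matrix(model)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  # null-space basis of S (identity when there are no metabolites)
  N <- if (nrow(S)) {
    sv <- svd(S, nu = 0, nv = k)
    r <- sum(sv$d > 1e-10 * max(sv$d, 1))
    if (r == k) matrix(0, k, 0) else sv$v[, (r + 1):k, drop = FALSE]
  } else diag(k)
  # warmup vertices: per-coordinate min/max, then random directions
  dirs <- list()
  for (i in seq_len(min(k, ceiling(warmup / 2)))) {
    e <- numeric(k); e[i] <- 1
    dirs <- c(dirs, list(e, -e))
  }
  while (length(dirs) < warmup) {
    d <- stats::rnorm(k)
    dirs <- c(dirs, list(d))
  }
  dirs <- dirs[seq_len(max(warmup, 2))]
  W <- matrix(NA_real_, length(dirs), k)
  for (j in seq_along(dirs)) {
    sol <- lp_solve(dirs[[j]], Aeq = S, beq = numeric(nrow(S)),
                    lb = lb, ub = ub, maximize = TRUE)
    if (sol$status != "optimal") stop("model infeasible during warmup")
    W[j, ] <- sol$v
  }
  center <- colMeans(W)
  x <- center
  if (ncol(N) == 0) {
    # fully determined flux space: every sample is the unique point
    samples <- matrix(rep(W[1, ], each = n), nrow = n)
    colnames(samples) <- rxns
    return(structure(list(samples = samples, reactions = rxns, seed = seed,
                          warmup = warmup, thinning = thinning),
                     class = "sample_set"))
  }
  # a polytope that is a single point (all warmup vertices coincide) has
  # nothing to walk over: every sample is that point
  if (max(apply(W, 2, function(col) diff(range(col)))) < 1e-9) {
    samples <- matrix(rep(W[1, ], each = n), nrow = n)
    colnames(samples) <- rxns
    return(structure(list(samples = samples, reactions = rxns, seed = seed,
                          warmup = warmup, thinning = thinning),
                     class = "sample_set"))
  }
  samples <- matrix(NA_real_, n, k)
  kept <- 0L; step <- 0L; total_accepted <- nrow(W); failed <- 0L
  while (kept < n) {
    step <- step + 1L
    ref <- W[sample.int(nrow(W), 1L), ]
    u <- ref - center
    u <- u - project_complement(u, N)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) {
      failed <- failed + 1L
      if (failed > 10000L) stop("sampler cannot find a feasible direction")
      next
    }
    u <- u / nu
    # step-size interval from the box constraints
    amin <- -Inf; amax <- Inf
    for (i in seq_len(k)) {
      if (abs(u[i]) < 1e-12) next
      a1 <- (lb[i] - x[i]) / u[i]; a2 <- (ub[i] - x[i]) / u[i]
      lo <- min(a1, a2); hi <- max(a1, a2)
      amin <- max(amin, lo); amax <- min(amax, hi)
    }
    if (!is.finite(amin) || !is.finite(amax) || amax - amin < 1e-12) {
      failed <- failed + 1L
      if (failed > 10000L) stop("sampler cannot find a feasible direction")
      next
    }
    failed <- 0L
    lambda <- stats::runif(1, amin, amax)
    x <- x + lambda * u
    x <- pmin(pmax(x, lb), ub)
    total_accepted <- total_accepted + 1L
    center <- center + (x - center) / total_accepted
    if (step %% 200L == 0L && nrow(S)) {
      # cancel accumulated numeric drift off the steady-state subspace
      x0 <- W[1, ]
      x <- x0 + as.vector(N %*% crossprod(N, x - x0))
      x <- pmin(pmax(x, lb), ub)
    }
    if (step %% thinning == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- x
    }
  }
  colnames(samples) <- rxns
  structure(list(samples = samples, reactions = rxns, seed = seed,
                 warmup = warmup, thinning = thinning),
            class = "sample_set")
}

# component of v orthogonal to the column space of N
project_complement <- function(v, N) {
  if (ncol(N) == 0) return(v)
  v - as.vector(N %*% crossprod(N, v))
}

#' Call transcriptionally regulated reactions
#'
#' Compares per-reaction flux sample statistics between two conditions: the
#' flux direction is `up`/`down` when the means are separated by more than
#' `separation` times the sum of the standard deviations, `none` otherwise.
#' A reaction is called regulated when its flux direction is non-null and
#' concordant with the expression direction of its genes.
#'
#' @param samples_ref,samples_cond `sample_set`s over the same reactions.
#' @param directions Data frame `reaction`, `direction` from
#'   [map_de_to_reactions()] (reactions absent from it count as
#'   `unchanged`).
#' @param separation Separation multiple (default 1.0).
#' @return Data frame `reaction`, `mean_ref`, `sd_ref`, `mean_cond`,
#'   `sd_cond`, `flux_direction`, `expression_direction`, `regulated`.
#' @export
call_regulated <- function(samples_ref, samples_cond, directions,
                           separation = 1.0) {
  if (!identical(samples_ref$reactions, samples_cond$reactions)) {
    only_ref <- setdiff(samples_ref$reactions, samples_cond$reactions)
    only_cond <- setdiff(samples_cond$reactions, samples_ref$reactions)
    stop("sample sets disagree on reactions; only in reference: ",
         paste(only_ref, collapse = ", "), "; only in condition: ",
         paste(only_cond, collapse = ", "))
  }
  rxns <- samples_ref$reactions
  m_ref <- colMeans(samples_ref$samples)
  s_ref <- apply(samples_ref$samples, 2, stats::sd)
  m_cond <- colMeans(samples_cond$samples)
  s_cond <- apply(samples_cond$samples, 2, stats::sd)
  # activity is the flux magnitude: an uptake (negative flux) that becomes
  # less negative carries less flux and counts as down
  delta <- abs(m_cond) - abs(m_ref)
  sep_ok <- abs(m_cond - m_ref) > separation * (s_ref + s_cond)
  flux_dir <- ifelse(sep_ok, ifelse(delta > 0, "up", "down"), "none")
  expr_dir <- stats::setNames(rep("unchanged", length(rxns)), rxns)
  hit <- intersect(directions$reaction, rxns)
  expr_dir[hit] <- directions$direction[match(hit, directions$reaction)]
  data.frame(reaction = rxns, mean_ref = unname(m_ref), sd_ref = unname(s_ref),
             mean_cond = unname(m_cond), sd_cond = unname(s_cond),
             flux_direction = flux_dir,
             expression_direction = unname(expr_dir),
             regulated = flux_dir != "none" & flux_dir == expr_dir,
             stringsAsFactors = FALSE, row.names = NULL)
}
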