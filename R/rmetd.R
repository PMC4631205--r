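# RMetD: relative metabolic differences.
#
# Integrates relative (not absolute) differential gene expression between a
# reference and a perturbed condition into a genome-scale model: reactions
# associated with significantly changed genes have their reference FVA
# ranges scaled by +alpha (up-regulated) or -alpha (down-regulated), after
# which the secretion of the objective products (chylomicrons, HDL in the
# small-intestine application) is compared between the two constrained
# models.

#' RMetD configuration
#'
#' @param alpha Bound scaling fraction in (0, 1); up-regulated reactions get
#'   their FVA bounds multiplied by `1 + alpha`, down-regulated by
#'   `1 - alpha`. Default 0.20.
#' @param q_threshold Q-value significance cutoff for differential
#'   expression (default 0.05).
#' @param objective_products Ordered character vector of exchange reaction
#'   ids; the first is the primary optimisation target, the rest are read
#'   out from its parsimonious solution.
#' @param product_floor_fraction Each product's secretion lower bound is set
#'   to this fraction of its individually maximised production (default
#'   0.20).
#' @param cap_at_model_bounds Clamp scaled bounds back inside the original
#'   model bounds (default `TRUE`).
#' @return An `rmetd_config` list.
#' @export
rmetd_config <- function(alpha = 0.20, q_threshold = 0.05,
                         objective_products = character(),
                         product_floor_fraction = 0.20,
                         cap_at_model_bounds = TRUE) {
  stopifnot(alpha > 0, alpha < 1,
            product_floor_fraction > 0, product_floor_fraction < 1)
  structure(list(alpha = alpha, q_threshold = q_threshold,
                 objective_products = objective_products,
                 product_floor_fraction = product_floor_fraction,
                 cap_at_model_bounds = cap_at_model_bounds),
            class = "rmetd_config")
}

#' Project differential expression onto reactions
#'
#' A reaction whose GPR mentions at least one significantly changed gene
#' (Q-value below `q_threshold`) is called `up` if all its significant
#' genes are up-regulated, `down` if all are down-regulated, and
#' `unchanged` when they disagree (mixed trends are treated as no
#' significant change). Reactions with no significant gene are absent from
#' the map. DE genes absent from the model are ignored but counted in the
#' coverage attribute.
#'
#' @param model A `metabolic_model`.
#' @param de Data frame with columns `gene_id`, `log2fc`, `q_value` (or a
#'   `direction` column with `"up"`/`"down"`).
#' @param q_threshold Significance cutoff.
#' @return Data frame `reaction`, `direction`, `genes` (comma-joined
#'   contributing gene ids), `reason` (`all-concordant`, `mixed-directions`);
#'   attribute `coverage` = list(n_de, n_in_model, unmatched).
#' @export
map_de_to_reactions <- function(model, de, q_threshold = 0.05) {
  if (anyDuplicated(de$gene_id)) stop("duplicate gene ids in DE table")
  if (is.null(de$direction)) {
    de$direction <- ifelse(de$log2fc > 0, "up", "down")
  }
  model_gene_set <- model_genes(model)
  unmatched <- setdiff(de$gene_id, model_gene_set)
  sig <- de[de$q_value < q_threshold & de$gene_id %in% model_gene_set, ]
  dir_of <- stats::setNames(sig$direction, sig$gene_id)
  rows <- lapply(seq_len(nrow(model$reactions)), function(i) {
    gg <- intersect(gpr_genes(model$reactions$gpr[i]), names(dir_of))
    if (!length(gg)) return(NULL)
    dirs <- unique(dir_of[gg])
    data.frame(
      reaction = model$reactions$id[i],
      direction = if (length(dirs) == 1) dirs else "unchanged",
      genes = paste(gg, collapse = ","),
      reason = if (length(dirs) == 1) "all-concordant" else "mixed-directions",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(reaction = character(), direction = character(),
                      genes = character(), reason = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "coverage") <- list(n_de = nrow(de),
                                n_in_model = sum(de$gene_id %in% model_gene_set),
                                unmatched = unmatched)
  out
}

scale_interval <- function(lb, ub, factor) c(lb * factor, ub * factor)

# Elastic re-solve: minimise total violation of the imposed RMetD bounds to
# diagnose which constraints make the model infeasible.
elastic_diagnosis <- function(model, imposed) {
  n <- nrow(model$reactions)
  k <- nrow(imposed)
  S <- stoichiometric_matrix(model)
  idx <- match(imposed$reaction, model$reactions$id)
  # variables: v (free within original bounds, with imposed rows relaxed),
  # s (lb slack), t (ub slack)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  lb[idx] <- pmin(lb[idx], imposed$lb); ub[idx] <- pmax(ub[idx], imposed$ub)
  Aeq <- cbind(S, matrix(0, nrow(S), 2 * k))
  # v_i + s_i >= imposed lb_i ; -v_i + t_i >= -imposed ub_i
  Age <- matrix(0, 2 * k, n + 2 * k)
  bge <- numeric(2 * k)
  for (j in seq_len(k)) {
    Age[j, idx[j]] <- 1; Age[j, n + j] <- 1; bge[j] <- imposed$lb[j]
    Age[k + j, idx[j]] <- -1; Age[k + j, n + k + j] <- 1
    bge[k + j] <- -imposed$ub[j]
  }
  big <- max(abs(c(lb, ub))) + 1
  sol <- lp_solve(c(numeric(n), rep(1, 2 * k)),
                  Aeq = Aeq, beq = numeric(nrow(S)), Age = Age, bge = bge,
                  lb = c(lb, numeric(2 * k)), ub = c(ub, rep(big, 2 * k)),
                  maximize = FALSE)
  if (sol$status != "optimal") return(list(feasible = FALSE, violated = imposed$reaction))
  slack <- sol$v[n + seq_len(2 * k)]
  viol <- unique(imposed$reaction[c(which(slack[seq_len(k)] > 1e-6),
                                    which(slack[k + seq_len(k)] > 1e-6))])
  list(feasible = length(viol) == 0, violated = viol,
       total_slack = sum(slack))
}

#' Run the RMetD procedure
#'
#' Steps, in order: (1) apply the diet uptake limits to a reference and a
#' condition copy of the model; (2) maximise each objective product alone
#' and set its secretion lower bound to `product_floor_fraction` times that
#' maximum in both copies; (3) project the DE table onto reactions; (4) run
#' FVA over the mapped reactions in the reference copy with the product
#' floors active (the primary objective is deliberately not fixed at its
#' optimum, which would collapse the ranges the scaling acts on); (5) impose
#' the FVA ranges as hard bounds on the reference copy, and the scaled
#' ranges (`x (1 + alpha)` for up, `x (1 - alpha)` for down, unscaled for
#' mixed) on the condition copy; (6) optionally cap the scaled bounds at
#' the original model bounds; (7) solve both copies by parsimonious FBA
#' maximising the primary product; (8) compare per-product secretions.
#'
#' Infeasibility at step (7) is never silently relaxed: an elastic re-solve
#' reports the minimal set of imposed bounds that must be violated, and the
#' result carries the diagnostic.
#'
#' @param reference_model A feasible `metabolic_model` (the reference
#'   condition, e.g. germ-free).
#' @param de DE table (see [map_de_to_reactions()]); the condition copy
#'   represents the state the DE directions point towards (e.g.
#'   conventionally raised).
#' @param diet_bounds Named numeric vector, exchange id -> max uptake.
#' @param config An [rmetd_config()].
#' @return An `rmetd_result`: `direction_map`, `reference_bounds`,
#'   `condition_bounds`, `reference_solution`, `condition_solution`,
#'   `product_comparison` (data frame `product`, `reference`, `condition`,
#'   `ratio`), `alpha`, and `diagnostics` when a copy was infeasible.
#' @export
run_rmetd <- function(reference_model, de, diet_bounds = numeric(),
                      config = rmetd_config()) {
  products <- config$objective_products
  if (!length(products)) stop("config$objective_products must name at least one exchange")
  base <- apply_diet_bounds(reference_model, diet_bounds)
  # step 2: product floors from individual maxima
  floors <- vapply(products, function(p) {
    sol <- fba(base, objective = p, sense = "max")
    if (sol$status != "optimal") {
      stop("cannot maximise product ", p, ": ", sol$status)
    }
    config$product_floor_fraction * sol$objective_value
  }, numeric(1))
  floored <- base
  for (p in products) floored <- set_bounds(floored, p, lb = floors[[p]])
  # step 3-4
  dmap <- map_de_to_reactions(reference_model, de, config$q_threshold)
  ref <- cond <- floored
  ref_bounds <- cond_bounds <- NULL
  if (nrow(dmap)) {
    ranges <- fva(floored, dmap$reaction)$ranges
    fac <- ifelse(dmap$direction == "up", 1 + config$alpha,
                  ifelse(dmap$direction == "down", 1 - config$alpha, 1))
    cond_lb <- ranges$min * fac
    cond_ub <- ranges$max * fac
    if (config$cap_at_model_bounds) {
      orig <- reference_model$reactions[match(dmap$reaction,
                                              reference_model$reactions$id), ]
      cond_lb <- pmax(cond_lb, orig$lb); cond_ub <- pmin(cond_ub, orig$ub)
      bad <- cond_lb > cond_ub
      cond_lb[bad] <- pmin(cond_lb[bad], cond_ub[bad])
    }
    ref <- set_bounds(ref, dmap$reaction, lb = ranges$min, ub = ranges$max)
    cond <- set_bounds(cond, dmap$reaction, lb = cond_lb, ub = cond_ub)
    ref_bounds <- data.frame(reaction = dmap$reaction, lb = ranges$min,
                             ub = ranges$max, stringsAsFactors = FALSE)
    cond_bounds <- data.frame(reaction = dmap$reaction, lb = cond_lb,
                              ub = cond_ub, direction = dmap$direction,
                              stringsAsFactors = FALSE)
  }
  # step 7: parsimonious FBA on the primary product
  primary <- products[1]
  solve_copy <- function(model, bounds) {
    sol <- pfba(model, objective = primary, sense = "max")
    diag <- NULL
    if (sol$status != "optimal" && !is.null(bounds)) {
      diag <- elastic_diagnosis(floored, bounds)
    }
    list(sol = sol, diag = diag)
  }
  ref_out <- solve_copy(ref, ref_bounds)
  cond_out <- solve_copy(cond, cond_bounds)
  cmp <- data.frame(product = products,
                    reference = NA_real_, condition = NA_real_,
                    ratio = NA_real_, stringsAsFactors = FALSE)
  if (ref_out$sol$status == "optimal" && cond_out$sol$status == "optimal") {
    cmp$reference <- ref_out$sol$fluxes[products]
    cmp$condition <- cond_out$sol$fluxes[products]
    cmp$ratio <- ifelse(abs(cmp$reference) < 1e-12,
                        ifelse(abs(cmp$condition) < 1e-12, 1, Inf),
                        cmp$condition / cmp$reference)
  }
  rownames(cmp) <- NULL
  structure(list(
    direction_map = dmap,
    reference_bounds = ref_bounds, condition_bounds = cond_bounds,
    product_floors = floors,
    reference_solution = ref_out$sol, condition_solution = cond_out$sol,
    product_comparison = cmp, alpha = config$alpha,
    reference_model = ref, condition_model = cond,
    diagnostics = Filter(Negate(is.null),
                         list(reference = ref_out$diag,
                              condition = cond_out$diag))),
    class = "rmetd_result")
}

#' Sensitivity of RMetD product predictions to the scaling fraction
#'
#' Re-runs [run_rmetd()] for each `alpha` and reports the per-product
#' secretion comparison; the `stable` attribute is `TRUE` when the sign of
#' (condition - reference) agrees across all alphas for every product.
#'
#' @inheritParams run_rmetd
#' @param alphas Numeric vector of scaling fractions, each in (0, 1).
#' @return Data frame `alpha`, `product`, `reference`, `condition`,
#'   `ratio`, `status`; attribute `stable`.
#' @export
sensitivity_scan <- function(reference_model, de, diet_bounds = numeric(),
                             config = rmetd_config(),
                             alphas = c(0.1, 0.2, 0.3)) {
  stopifnot(all(alphas > 0), all(alphas < 1))
  rows <- lapply(alphas, function(a) {
    cfg <- config; cfg$alpha <- a
    res <- tryCatch(run_rmetd(reference_model, de, diet_bounds, cfg),
                    error = function(e) NULL)
    if (is.null(res) || res$reference_solution$status != "optimal" ||
        res$condition_solution$status != "optimal") {
      return(data.frame(alpha = a, product = config$objective_products,
                        reference = NA_real_, condition = NA_real_,
                        ratio = NA_real_, status = "infeasible",
                        stringsAsFactors = FALSE))
    }
    cbind(alpha = a, res$product_comparison, status = "optimal")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$status == "optimal"
  stable <- all(vapply(unique(out$product), function(p) {
    d <- out$condition[ok & out$product == p] - out$reference[ok & out$product == p]
    if (!length(d)) return(FALSE)
    all(sign(round(d, 9)) == sign(round(d[1], 9)))
  }, logical(1)))
  attr(out, "stable") <- stable
  out
}
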