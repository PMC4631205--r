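# Linear-programming primitives: FBA, parsimonious FBA and FVA.
#
# All problems are bounded (every variable has finite bounds, defaulting to
# +-1000), so the two-phase simplex in boot::simplex is sufficient and exact.
# Tolerances: feasibility 1e-6, optimality comparisons 1e-9 relative.

FEAS_TOL <- 1e-6

# Solve  max/min c'v  s.t.  Aeq v = beq, Age v >= bge, lb <= v <= ub.
# Inequality rows get a surplus variable each (Age v - s = bge, s >= 0);
# the resulting equality-form bounded LP goes to the simplex core.
lp_solve <- function(obj, Aeq = NULL, beq = NULL, Age = NULL, bge = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(lb)
  stopifnot(length(ub) == n, length(obj) == n, all(lb <= ub + 1e-12))
  k <- if (is.null(Age)) 0L else nrow(Age)
  meq <- if (is.null(Aeq)) 0L else nrow(Aeq)
  A <- matrix(0, meq + k, n + k)
  rhs <- numeric(meq + k)
  if (meq) { A[seq_len(meq), seq_len(n)] <- Aeq; rhs[seq_len(meq)] <- beq }
  if (k) {
    A[meq + seq_len(k), seq_len(n)] <- Age
    A[cbind(meq + seq_len(k), n + seq_len(k))] <- -1
    rhs[meq + seq_len(k)] <- bge
  }
  res <- solve_bounded_lp(c(obj, numeric(k)), A, rhs,
                          l = c(lb, numeric(k)), u = c(ub, rep(Inf, k)),
                          maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = res$status, v = NULL, obj = NA_real_))
  }
  v <- res$x[seq_len(n)]
  list(status = "optimal", v = v, obj = sum(obj * v))
}

objective_vector <- function(model, objective = NULL) {
  obj_rxn <- if (is.null(objective)) model$objective$reaction else objective
  if (is.na(obj_rxn)) stop("no objective set on model '", model$id, "'")
  if (!obj_rxn %in% model$reactions$id) {
    stop("objective reaction ", obj_rxn, " not in model")
  }
  cc <- numeric(nrow(model$reactions))
  cc[match(obj_rxn, model$reactions$id)] <- 1
  cc
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the model objective over the steady-state
#' polytope \{v : Sv = 0, lb <= v <= ub\}.
#'
#' @param model A `metabolic_model` with an objective set (or `objective`).
#' @param objective Optional reaction id overriding the model objective.
#' @param sense `"max"` or `"min"`; defaults to the model's sense.
#' @return List of class `fba_result`: `status` (`"optimal"`,
#'   `"infeasible"`, `"iteration_limit"`), `objective_value`, and `fluxes`
#'   (named vector).
#' @export
fba <- function(model, objective = NULL, sense = NULL) {
  cc <- objective_vector(model, objective)
  sense <- if (is.null(sense)) model$objective$sense else sense
  S <- stoichiometric_matrix(model)
  sol <- lp_solve(cc, Aeq = S, beq = numeric(nrow(S)),
                  lb = model$reactions$lb, ub = model$reactions$ub,
                  maximize = sense == "max")
  fluxes <- if (is.null(sol$v)) NULL else
    stats::setNames(sol$v, model$reactions$id)
  structure(list(status = sol$status, objective_value = sol$obj,
                 fluxes = fluxes), class = "fba_result")
}

#' Parsimonious FBA
#'
#' Lexicographic solve: the objective flux is first constrained to
#' `fixed_objective_fraction` times its FBA optimum, then the total absolute
#' flux `sum(|v|)` is minimised by splitting every reaction into
#' non-negative forward and backward parts (exact for LPs, no integer
#' variables needed).
#'
#' @inheritParams fba
#' @param fixed_objective_fraction Fraction of the optimum to retain, in
#'   (0, 1]; default 1.
#' @return An `fba_result` whose `objective_value` is the retained objective
#'   flux and with an extra `total_flux` element (the minimised sum of
#'   absolute fluxes).
#' @export
pfba <- function(model, fixed_objective_fraction = 1, objective = NULL,
                 sense = NULL) {
  stopifnot(fixed_objective_fraction > 0, fixed_objective_fraction <= 1)
  first <- fba(model, objective, sense)
  if (first$status != "optimal") return(first)
  sense <- if (is.null(sense)) model$objective$sense else sense
  cc <- objective_vector(model, objective)
  target <- fixed_objective_fraction * first$objective_value
  n <- nrow(model$reactions)
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  # v = f - b with f, b >= 0; bounds carve the original box
  lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  split <- function(M) cbind(M, -M)
  Aeq <- if (nrow(S)) split(S) else matrix(0, 0, 2 * n)
  beq <- numeric(nrow(Aeq))
  obj_row <- matrix(c(cc, -cc), nrow = 1)
  if (sense == "max") {
    Age <- obj_row; bge <- target
  } else {
    Age <- -obj_row; bge <- -target
  }
  sol <- lp_solve(rep(1, 2 * n), Aeq = Aeq, beq = beq, Age = Age, bge = bge,
                  lb = lb2, ub = ub2, maximize = FALSE)
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, objective_value = target,
                          fluxes = NULL, total_flux = NA_real_,
                          note = sprintf("infeasible with objective fixed at %g", target)),
                     class = "fba_result"))
  }
  v <- sol$v[seq_len(n)] - sol$v[n + seq_len(n)]
  structure(list(status = "optimal", objective_value = sum(cc * v),
                 fluxes = stats::setNames(v, model$reactions$id),
                 total_flux = sum(abs(v))), class = "fba_result")
}

#' Flux variability analysis
#'
#' Minimum and maximum attainable flux per reaction over the feasible
#' region, optionally with the model objective constrained to at least
#' `objective_floor` (for a maximising model; at most, for a minimising
#' one). Two LPs are solved per reaction.
#'
#' @inheritParams fba
#' @param reaction_ids Reactions to scan; defaults to all.
#' @param objective_floor Optional objective bound kept active during the
#'   scan.
#' @return List of class `flux_range`: `ranges` (data frame `reaction`,
#'   `min`, `max`) and `witnesses` (per reaction, the two optimising flux
#'   vectors).
#' @export
fva <- function(model, reaction_ids = NULL, objective_floor = NULL) {
  if (is.null(reaction_ids)) reaction_ids <- model$reactions$id
  idx <- match(reaction_ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reactions: ", paste(reaction_ids[is.na(idx)], collapse = ", "))
  }
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  Age <- NULL; bge <- NULL
  if (!is.null(objective_floor)) {
    cc <- objective_vector(model)
    if (model$objective$sense == "max") {
      Age <- matrix(cc, nrow = 1); bge <- objective_floor
    } else {
      Age <- matrix(-cc, nrow = 1); bge <- -objective_floor
    }
  }
  n <- nrow(model$reactions)
  mins <- maxs <- numeric(length(idx))
  wit <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    cc <- numeric(n); cc[idx[k]] <- 1
    lo <- lp_solve(cc, Aeq = S, beq = numeric(nrow(S)), Age = Age, bge = bge,
                   lb = lb, ub = ub, maximize = FALSE)
    hi <- lp_solve(cc, Aeq = S, beq = numeric(nrow(S)), Age = Age, bge = bge,
                   lb = lb, ub = ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA infeasible for reaction ", reaction_ids[k],
           if (!is.null(objective_floor))
             sprintf(" (objective floor %g active)", objective_floor) else "")
    }
    mins[k] <- lo$obj; maxs[k] <- hi$obj
    wit[[k]] <- list(min = stats::setNames(lo$v, model$reactions$id),
                     max = stats::setNames(hi$v, model$reactions$id))
  }
  names(wit) <- reaction_ids
  structure(list(
    ranges = data.frame(reaction = reaction_ids, min = mins, max = maxs,
                        stringsAsFactors = FALSE),
    witnesses = wit), class = "flux_range")
}

#' Steady-state residual of a flux vector
#'
#' Largest absolute metabolite imbalance `max |Sv|`; optimal solutions keep
#' this below 1e-6.
#'
#' @param model A `metabolic_model`.
#' @param fluxes Named flux vector covering all reactions.
#' @return Numeric scalar.
#' @export
steady_state_residual <- function(model, fluxes) {
  S <- stoichiometric_matrix(model)
  if (!nrow(S)) return(0)
  max(abs(S %*% fluxes[colnames(S)]))
}
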