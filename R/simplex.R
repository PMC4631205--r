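# Bounded-variable primal simplex, the numeric core under FBA/pFBA/FVA.
#
# Solves  min c'x  s.t.  A x = b,  l <= x <= u  by the revised simplex
# method with explicit variable bounds, a phase-1 of artificial variables,
# and Bland's smallest-index pivoting rule (no cycling). Problems here are
# small and dense (tens of rows), so the basis is refactorised by solve()
# at every iteration; robustness matters more than speed.

SIMPLEX_TOL <- 1e-9

# One phase of the bounded simplex. `at_upper` flags nonbasic variables
# sitting at their upper bound. Returns the updated state and a status.
simplex_phase <- function(A, b, l, u, cost, basis, at_upper,
                          max_iter = 10000L) {
  m <- nrow(A); n <- ncol(A)
  for (iter in seq_len(max_iter)) {
    nonbasic <- setdiff(seq_len(n), basis)
    xN <- ifelse(at_upper[nonbasic], u[nonbasic], l[nonbasic])
    B <- A[, basis, drop = FALSE]
    rhs <- b - if (length(nonbasic))
      as.vector(A[, nonbasic, drop = FALSE] %*% xN) else 0
    xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(xB)) return(list(status = "singular"))
    y <- solve(t(B), cost[basis])
    d <- cost[nonbasic] - as.vector(y %*% A[, nonbasic, drop = FALSE])
    enter_lb <- nonbasic[!at_upper[nonbasic] & d < -SIMPLEX_TOL]
    enter_ub <- nonbasic[at_upper[nonbasic] & d > SIMPLEX_TOL]
    candidates <- sort(c(enter_lb, enter_ub))
    if (!length(candidates)) {
      x <- numeric(n)
      x[nonbasic] <- xN; x[basis] <- xB
      return(list(status = "optimal", x = x, basis = basis,
                  at_upper = at_upper))
    }
    j <- candidates[1]                        # Bland: smallest index
    t_dir <- if (at_upper[j]) -1 else 1       # direction of change of x_j
    w <- solve(B, A[, j])
    # x_B moves by -t_dir * w * delta as x_j moves by t_dir * delta
    flip <- u[j] - l[j]                       # bound-flip limit
    caps <- rep(Inf, m); to_upper <- logical(m)
    for (i in seq_len(m)) {
      wi <- -t_dir * w[i]
      if (wi > SIMPLEX_TOL) {                 # basic var increases -> hits ub
        caps[i] <- max((u[basis[i]] - xB[i]) / wi, 0)
        to_upper[i] <- TRUE
      } else if (wi < -SIMPLEX_TOL) {         # decreases -> hits lb
        caps[i] <- max((l[basis[i]] - xB[i]) / wi, 0)
      }
    }
    step <- min(flip, caps)
    if (!is.finite(step)) return(list(status = "unbounded"))
    if (min(caps) <= step + SIMPLEX_TOL && any(is.finite(caps))) {
      # a basic variable blocks first: Bland tie-break on variable index
      blockers <- which(caps <= step + SIMPLEX_TOL)
      leave <- blockers[which.min(basis[blockers])]
      at_upper[basis[leave]] <- to_upper[leave]
      basis[leave] <- j
      at_upper[j] <- FALSE                    # entering becomes basic
    } else {
      at_upper[j] <- !at_upper[j]             # bound flip, basis unchanged
    }
  }
  list(status = "iteration_limit")
}

#' Solve a bounded linear program
#'
#' Minimises (or maximises) `c'x` subject to `Aeq x = beq` and
#' `l <= x <= u`, via a two-phase bounded-variable simplex with Bland's
#' rule. Used internally by [fba()], [pfba()] and [fva()]; exported because
#' the elastic infeasibility diagnosis and tests construct LPs directly.
#'
#' @param cost Objective coefficients.
#' @param Aeq,beq Equality constraints (may have zero rows).
#' @param l,u Variable bounds (`u` may contain `Inf`).
#' @param maximize Maximise instead of minimise.
#' @return List `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `x`, `value`.
#' @export
solve_bounded_lp <- function(cost, Aeq, beq, l, u, maximize = FALSE) {
  n <- length(cost)
  stopifnot(length(l) == n, length(u) == n, all(l <= u + 1e-12))
  if (is.null(Aeq) || nrow(Aeq) == 0) {
    # pure box problem: each variable at its best bound
    sgn <- if (maximize) -1 else 1
    x <- ifelse(sgn * cost >= 0, l, ifelse(is.finite(u), u, NA))
    if (anyNA(x)) return(list(status = "unbounded", x = NULL, value = NA_real_))
    return(list(status = "optimal", x = x, value = sum(cost * x)))
  }
  m <- nrow(Aeq)
  c_min <- if (maximize) -cost else cost
  # phase 1: artificials matching the residual at the all-at-lb point
  r <- beq - as.vector(Aeq %*% l)
  D <- diag(ifelse(r >= 0, 1, -1), m)
  A <- cbind(Aeq, D)
  l_full <- c(l, rep(0, m)); u_full <- c(u, rep(Inf, m))
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)
  ph1 <- simplex_phase(A, beq, l_full, u_full,
                       c(rep(0, n), rep(1, m)), basis, at_upper)
  if (ph1$status != "optimal") {
    return(list(status = if (ph1$status == "unbounded") "infeasible"
                else ph1$status, x = NULL, value = NA_real_))
  }
  if (sum(ph1$x[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  # phase 2: pin artificials to zero and optimise the true objective
  u_full[n + seq_len(m)] <- 0
  l_full[n + seq_len(m)] <- 0
  ph2 <- simplex_phase(A, beq, l_full, u_full,
                       c(c_min, rep(0, m)), ph1$basis, ph1$at_upper)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, x = NULL, value = NA_real_))
  }
  x <- ph2$x[seq_len(n)]
  list(status = "optimal", x = x, value = sum(cost * x))
}
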