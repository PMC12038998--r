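## Bounded-variable LP solver (dense two-phase simplex, Bland's rule) and a
## small branch-and-bound MILP on top. All flux-analysis solves go through
## solve_lp().

.LP_BIG <- 1e6

## Standard-form core: min c'x  s.t.  A x = b (b >= 0), x >= 0.
## Full-tableau two-phase simplex with Bland's anti-cycling rule.
## Returns list(status, x, objective).
.simplex_core <- function(A, b, cc, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 50L * (n + m + 10L)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  ## tableau with artificial variables: [A | I | b]
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  art <- n + seq_len(m)

  price_out <- function(cost) {
    ## reduced-cost row for the current tableau
    z <- cost[basis] %*% Tb[, 1:(n + m), drop = FALSE]
    cost[1:(n + m)] - as.numeric(z)
  }
  pivot <- function(r, col) {
    Tb[r, ] <<- Tb[r, ] / Tb[r, col]
    other <- setdiff(seq_len(m), r)
    if (length(other))
      Tb[other, ] <<- Tb[other, , drop = FALSE] -
        outer(Tb[other, col], Tb[r, ])
    basis[r] <<- col
  }
  run_phase <- function(cost, allowed) {
    bland_after <- 5L * (n + m)            # Dantzig pricing, then Bland
    for (it in seq_len(max_iter)) {
      red <- price_out(cost)
      cand <- allowed[red[allowed] < -tol]
      if (!length(cand)) return("optimal")
      col <- if (it < bland_after) cand[which.min(red[cand])] else min(cand)
      colv <- Tb[, col]
      pos <- which(colv > tol)
      if (!length(pos)) return("unbounded")
      ratios <- Tb[pos, n + m + 1] / colv[pos]
      rmin <- min(ratios)
      sel <- pos[ratios <= rmin + tol]
      r <- sel[which.min(basis[sel])]      # smallest basis index leaves
      pivot(r, col)
    }
    "maxiter"
  }

  ## phase 1: minimize sum of artificials
  cost1 <- c(rep(0, n), rep(1, m))
  st <- run_phase(cost1, seq_len(n + m))
  if (st != "optimal") return(list(status = st, x = NULL, objective = NA_real_))
  if (sum(cost1[basis] * Tb[, n + m + 1]) > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  ## drive remaining artificials out of the basis where possible
  for (r in which(basis > n)) {
    col <- which(abs(Tb[r, 1:n]) > tol)[1]
    if (!is.na(col)) pivot(r, col)
  }
  ## phase 2 over structural columns only
  cost2 <- c(cc, rep(0, m))
  st <- run_phase(cost2, seq_len(n))
  if (st != "optimal") return(list(status = st, x = NULL, objective = NA_real_))
  x <- numeric(n)
  keep <- basis <= n
  x[basis[keep]] <- Tb[keep, n + m + 1]
  list(status = "optimal", x = x, objective = sum(cc * x))
}

#' Solve a bounded linear program
#'
#' Solves `min/max obj' x` subject to `Aeq x = beq`, `Ain x <= bin` and
#' `lb <= x <= ub` with a dense two-phase simplex (Bland's rule, so it
#' cannot cycle on the degenerate steady-state systems typical of flux
#' analysis). Infinite bounds are capped internally; an optimum at the cap
#' is reported as unbounded.
#'
#' @param obj Objective coefficient vector.
#' @param Aeq,beq Equality constraints (may be `NULL`).
#' @param Ain,bin Inequality (`<=`) constraints (may be `NULL`).
#' @param lb,ub Variable bounds.
#' @param maximize Logical.
#' @return List with `status` ("optimal", "infeasible", "unbounded",
#'   "maxiter"), `objective` and solution `x`.
#' @export
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Ain = NULL, bin = NULL,
                     lb, ub, maximize = FALSE) {
  n <- length(obj)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  capped <- !is.finite(lb) | !is.finite(ub)
  lb[!is.finite(lb)] <- -.LP_BIG
  ub[!is.finite(ub)] <- .LP_BIG
  if (any(lb > ub)) return(list(status = "infeasible", objective = NA_real_, x = NULL))

  ## shift y = x - lb >= 0; add slack for y <= ub - lb and for Ain rows
  width <- ub - lb
  n_in <- NROW(Ain)
  n_eq <- NROW(Aeq)
  ## columns: y (n) | bound slacks (n) | ineq slacks (n_in)
  ntot <- 2L * n + n_in
  rows <- list(); rhs <- numeric(0)
  ## y + s = width
  rows$bounds <- cbind(diag(n), diag(n),
                       matrix(0, n, n_in))
  rhs <- c(rhs, width)
  if (n_in) {
    Ain <- matrix(Ain, ncol = n)
    rows$ineq <- cbind(Ain, matrix(0, n_in, n), diag(n_in))
    rhs <- c(rhs, bin - as.numeric(Ain %*% lb))
  }
  if (n_eq) {
    Aeq <- matrix(Aeq, ncol = n)
    rows$eq <- cbind(Aeq, matrix(0, n_eq, n), matrix(0, n_eq, n_in))
    rhs <- c(rhs, beq - as.numeric(Aeq %*% lb))
  }
  A <- do.call(rbind, rows)
  cc <- c(if (maximize) -obj else obj, rep(0, n + n_in))
  res <- .simplex_core(A, rhs, cc)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, x = NULL))
  x <- res$x[seq_len(n)] + lb
  objective <- sum(obj * x)
  at_cap <- capped & (abs(x) > 0.99 * .LP_BIG)
  status <- if (any(at_cap & abs(obj) > 0)) "unbounded" else "optimal"
  list(status = status, objective = objective, x = x)
}

## Branch-and-bound mixed-integer LP for the thermodynamic constraints.
## int_idx: indices of 0/1 variables. Depth-first search, pruning on the LP
## relaxation bound against the incumbent.
solve_milp <- function(obj, Aeq = NULL, beq = NULL, Ain = NULL, bin = NULL,
                       lb, ub, int_idx = integer(0), maximize = FALSE,
                       int_tol = 1e-6, max_nodes = 2000L) {
  best <- list(status = "infeasible", objective = if (maximize) -Inf else Inf,
               x = NULL)
  nodes <- 0L
  recurse <- function(lbn, ubn) {
    if (nodes >= max_nodes) return(invisible(NULL))
    nodes <<- nodes + 1L
    rel <- solve_lp(obj, Aeq, beq, Ain, bin, lbn, ubn, maximize)
    if (rel$status != "optimal") return(invisible(NULL))
    if (best$status == "optimal") {
      if (maximize && rel$objective <= best$objective + 1e-9) return(invisible(NULL))
      if (!maximize && rel$objective >= best$objective - 1e-9) return(invisible(NULL))
    }
    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (!length(int_idx) || all(frac <= int_tol)) {
      better <- best$status != "optimal" ||
        (maximize && rel$objective > best$objective) ||
        (!maximize && rel$objective < best$objective)
      if (better) best <<- list(status = "optimal", objective = rel$objective,
                                x = rel$x)
      return(invisible(NULL))
    }
    k <- int_idx[which.max(frac)]
    lo <- lbn; hi <- ubn
    hi[k] <- 0; recurse(lo, hi)          # z_k = 0 branch
    lo <- lbn; hi <- ubn
    lo[k] <- 1; recurse(lo, hi)          # z_k = 1 branch
    invisible(NULL)
  }
  recurse(lb, ub)
  if (best$status != "optimal")
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  best
}
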