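# Dense two-phase tableau simplex with Bland's anti-cycling rule.
#
# Written for the densest-subgraph LP/ILP family: problems are small and
# dense-tableau pivoting vectorises well in R (each pivot is a rank-1
# update). Bland's rule makes every run deterministic and terminating, which
# the package relies on for byte-identical reports. All variables are
# implicitly >= 0, which matches every formulation used here.

#' Solve a linear program (maximisation, variables >= 0)
#'
#' Maximise `obj %*% v` subject to `A v (dir) b` with `dir` one of
#' `"<="`, `">="`, `"=="` per row, and `v >= 0`.
#'
#' @param obj objective coefficient vector (length n)
#' @param A constraint matrix (m x n)
#' @param dir character vector of row senses
#' @param b right-hand side vector
#' @param tol pivot/feasibility tolerance
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `objective`, and `solution` (length n)
#' @keywords internal
#' @export
lp_solve <- function(obj, A, dir, b, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(dir) == m)

  # normalise to b >= 0
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[neg]]
  }

  n_slack <- sum(dir != "==")
  n_art <- sum(dir != "<=")
  ncols <- n + n_slack + n_art
  T <- matrix(0, m, ncols)
  T[, seq_len(n)] <- A
  basis <- integer(m)
  art_cols <- integer(0)
  si <- 0L; ai <- 0L
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      si <- si + 1L
      T[i, n + si] <- 1
      basis[i] <- n + si
    } else if (dir[i] == ">=") {
      si <- si + 1L; ai <- ai + 1L
      T[i, n + si] <- -1
      T[i, n + n_slack + ai] <- 1
      basis[i] <- n + n_slack + ai
      art_cols <- c(art_cols, n + n_slack + ai)
    } else {
      ai <- ai + 1L
      T[i, n + n_slack + ai] <- 1
      basis[i] <- n + n_slack + ai
      art_cols <- c(art_cols, n + n_slack + ai)
    }
  }
  rhs <- b
  allowed <- rep(TRUE, ncols)

  pivot <- function(p, q) {
    piv <- T[p, q]
    T[p, ] <<- T[p, ] / piv
    rhs[p] <<- rhs[p] / piv
    col <- T[, q]
    col[p] <- 0
    T <<- T - outer(col, T[p, ])
    rhs <<- rhs - col * rhs[p]
    basis[p] <<- q
  }

  run_phase <- function(cost) {
    # reduced-cost row: z - c, with z from current basis
    repeat {
      cb <- cost[basis]
      red <- drop(crossprod(T, cb)) - cost
      red[!allowed] <- Inf
      enter_candidates <- which(red < -tol)
      if (length(enter_candidates) == 0L) return("optimal")
      q <- enter_candidates[1L]  # Bland: smallest index
      colq <- T[, q]
      rows <- which(colq > tol)
      if (length(rows) == 0L) return("unbounded")
      ratio <- rhs[rows] / colq[rows]
      best <- rows[ratio <= min(ratio) + tol]
      p <- best[which.min(basis[best])]  # Bland: smallest basis index leaves
      pivot(p, q)
    }
  }

  # phase 1: drive artificials to zero
  if (n_art > 0L) {
    c1 <- numeric(ncols)
    c1[art_cols] <- -1
    st <- run_phase(c1)
    w <- sum(rhs[basis %in% art_cols])
    if (st == "unbounded" || w > 1e-7) {
      return(list(status = "infeasible", objective = NA_real_, solution = rep(NA_real_, n)))
    }
    allowed[art_cols] <- FALSE
    # pivot artificials still in the basis (at value 0) out where possible
    for (i in which(basis %in% art_cols)) {
      j <- which(allowed & abs(T[i, ]) > tol)
      if (length(j) > 0L) pivot(i, j[1L])
    }
  }

  c2 <- numeric(ncols)
  c2[seq_len(n)] <- obj
  st <- run_phase(c2)
  if (st == "unbounded") {
    return(list(status = "unbounded", objective = Inf, solution = rep(NA_real_, n)))
  }
  x <- numeric(ncols)
  x[basis] <- rhs
  list(status = "optimal", objective = sum(obj * x[seq_len(n)]), solution = x[seq_len(n)])
}

#' Solve a mixed binary-integer linear program by branch and bound
#'
#' Maximise `obj %*% v` subject to `A v (dir) b`, `v >= 0`, with the
#' variables in `bin_idx` restricted to {0, 1}. Depth-first branch and
#' bound over LP relaxations; deterministic branching (most fractional,
#' lowest index on ties). Assumes the objective takes integer values at
#' integer-feasible points when `integral_obj = TRUE`, which sharpens the
#' pruning bound.
#'
#' @param obj,A,dir,b as in [lp_solve]
#' @param bin_idx indices of binary variables
#' @param maximize logical; minimisation is handled by negation
#' @param integral_obj objective is integral at feasible points
#' @param branch_up explore the z = 1 branch first
#' @return list with `status` ("optimal" or "infeasible"), `objective`,
#'   `solution`
#' @keywords internal
#' @export
milp_solve <- function(obj, A, dir, b, bin_idx, maximize = TRUE,
                       integral_obj = TRUE, branch_up = maximize) {
  sgn <- if (maximize) 1 else -1
  obj2 <- sgn * obj
  n <- length(obj)
  # binary upper bounds as rows so every node shares one matrix shape
  ub_rows <- matrix(0, length(bin_idx), n)
  ub_rows[cbind(seq_along(bin_idx), bin_idx)] <- 1
  A0 <- rbind(A, ub_rows)
  dir0 <- c(dir, rep("<=", length(bin_idx)))
  b0 <- c(b, rep(1, length(bin_idx)))

  best_val <- -Inf
  best_sol <- NULL
  itol <- 1e-6

  solve_node <- function(fix) {
    # fix: named numeric of binary fixes (0 or 1), by variable index
    Af <- A0; df <- dir0; bf <- b0
    if (length(fix) > 0L) {
      idx <- as.integer(names(fix))
      rows <- matrix(0, length(idx), n)
      rows[cbind(seq_along(idx), idx)] <- 1
      Af <- rbind(Af, rows)
      df <- c(df, rep("==", length(idx)))
      bf <- c(bf, unname(fix))
    }
    lp_solve(obj2, Af, df, bf)
  }

  stack <- list(stats::setNames(numeric(0), character(0)))
  while (length(stack) > 0L) {
    fix <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- solve_node(fix)
    if (rel$status != "optimal") next
    bound <- rel$objective
    cut <- if (integral_obj) best_val + 1 - itol else best_val + 1e-9
    if (bound < cut) next
    zv <- rel$solution[bin_idx]
    frac <- abs(zv - round(zv))
    if (all(frac < itol)) {
      if (bound > best_val + if (integral_obj) 0.5 else 1e-9) {
        sol <- rel$solution
        sol[bin_idx] <- round(zv)
        best_val <- if (integral_obj) round(bound) else bound
        best_sol <- sol
      }
      next
    }
    j <- which(frac >= itol)
    j <- j[order(-frac[j], j)][1L]
    var <- bin_idx[j]
    first <- fix; second <- fix
    first[[as.character(var)]] <- if (branch_up) 0 else 1
    second[[as.character(var)]] <- if (branch_up) 1 else 0
    # DFS pops the last element, so push the preferred branch last
    stack <- c(stack, list(first), list(second))
  }
  if (is.null(best_sol)) {
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  }
  list(status = "optimal", objective = sgn * best_val, solution = best_sol)
}
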