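# Bounded-variable two-phase primal simplex.
#
# This is the LP engine behind every optimization in the package: flux
# balance analysis, the explicit dual program, the expression-integration
# (GIMME/TEAM) LP, and all brute-force re-solves used for ranging and
# degeneracy checking.  It is written for the dense, small-to-medium
# problems this package works with and deliberately exposes everything a
# sensitivity analysis needs: the optimal basis, dual values for the
# equality constraints, and reduced costs for the variable bounds.
#
# Conventions:
#   maximize  c'x   s.t.  A x = rhs,  lb <= x <= ub
# Dual values are reported as d(objective)/d(rhs_i) for the *stated* sense,
# so for a maximization they are the classical shadow prices.

#' Solve a bounded-variable linear program
#'
#' A self-contained two-phase primal simplex for problems of the form
#' maximize (or minimize) \eqn{c'x} subject to \eqn{Ax = b} and
#' \eqn{l \le x \le u}. Bounds may be infinite; variables with
#' \code{-Inf} lower and \code{+Inf} upper bound are handled as free
#' variables. Bland's rule is used throughout, so the method cannot cycle.
#'
#' @param obj numeric objective coefficients, length \code{ncol(A)}.
#' @param A constraint matrix (dense or sparse; coerced to dense).
#' @param rhs right-hand side of the equality constraints.
#' @param lb,ub variable bounds (may be \code{-Inf}/\code{Inf}).
#' @param maximize if \code{TRUE} (default) maximize, else minimize.
#' @param tol pivot tolerance.
#' @param feas_tol feasibility tolerance used to declare phase-1 success.
#' @param max_iter iteration cap per phase.
#'
#' @return A list with elements \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}, \code{"maxiter"},
#'   \code{"numerical"}), and for optimal solves: \code{x} (solution),
#'   \code{z} (objective value), \code{y} (duals of the equality rows,
#'   sign convention \eqn{y_i = \partial z / \partial b_i} for the stated
#'   sense), \code{dj} (reduced costs of the structural variables), plus
#'   the final basis bookkeeping used by \code{\link{simplex_rhs_range}}.
#' @export
simplex_lp <- function(obj, A, rhs, lb, ub, maximize = TRUE,
                       tol = 1e-9, feas_tol = 1e-7, max_iter = 10000L) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A); n <- ncol(A)
  obj <- as.numeric(obj); rhs <- as.numeric(rhs)
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(structure(list(status = "infeasible", z = NA_real_,
                          reason = "inconsistent variable bounds"),
                     class = "simplex_solution"))
  }
  sense <- if (maximize) 1 else -1
  cvec <- sense * obj

  N <- n + m
  lbx <- c(lb, rep(0, m)); ubx <- c(ub, rep(Inf, m))
  x <- numeric(N)
  stat <- integer(N)                     # 0 basic, 1 at lb, 2 at ub, 3 free at 0
  for (j in seq_len(n)) {
    if (is.finite(lb[j]))      { x[j] <- lb[j]; stat[j] <- 1L }
    else if (is.finite(ub[j])) { x[j] <- ub[j]; stat[j] <- 2L }
    else                       { x[j] <- 0;     stat[j] <- 3L }
  }
  r <- as.numeric(rhs - A %*% x[seq_len(n)])
  s <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(s, nrow = m))
  basis <- n + seq_len(m)
  stat[basis] <- 0L
  x[basis] <- abs(r)

  run_phase <- function(cost, basis, stat, x, lock_artificials) {
    for (it in seq_len(max_iter)) {
      B <- Aext[, basis, drop = FALSE]
      Bi <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Bi)) return(list(status = "numerical"))
      nonbasic <- which(stat != 0L)
      x[basis] <- as.numeric(
        Bi %*% (rhs - Aext[, nonbasic, drop = FALSE] %*% x[nonbasic]))
      y <- as.numeric(crossprod(Bi, cost[basis]))
      enter <- 0L; dir <- 0
      for (j in nonbasic) {                    # Bland: lowest eligible index
        if (lock_artificials && j > n) next
        dj <- cost[j] - sum(y * Aext[, j])
        if (stat[j] == 1L && dj >  tol) { enter <- j; dir <-  1; break }
        if (stat[j] == 2L && dj < -tol) { enter <- j; dir <- -1; break }
        if (stat[j] == 3L && abs(dj) > tol) { enter <- j; dir <- sign(dj); break }
      }
      if (enter == 0L) {
        return(list(status = "optimal", basis = basis, stat = stat,
                    x = x, y = y, Bi = Bi))
      }
      w <- as.numeric(Bi %*% Aext[, enter])
      t_best <- if (is.finite(ubx[enter]) && is.finite(lbx[enter]))
        ubx[enter] - lbx[enter] else Inf
      leave_pos <- 0L; leave_to <- NA_integer_
      for (k in seq_len(m)) {                  # ratio test on basic variables
        delta <- -dir * w[k]; bk <- basis[k]
        tk <- NA_real_; to <- NA_integer_
        if (delta > tol && is.finite(ubx[bk])) {
          tk <- (ubx[bk] - x[bk]) / delta; to <- 2L
        } else if (delta < -tol && is.finite(lbx[bk])) {
          tk <- (lbx[bk] - x[bk]) / delta; to <- 1L
        }
        if (!is.na(tk)) {
          tk <- max(tk, 0)
          if (tk < t_best - tol) {
            t_best <- tk; leave_pos <- k; leave_to <- to
          } else if (tk <= t_best + tol &&
                     (leave_pos == 0L || bk < basis[leave_pos])) {
            # tie: Bland's rule, leave the lowest-index variable
            t_best <- min(t_best, tk); leave_pos <- k; leave_to <- to
          }
        }
      }
      if (!is.finite(t_best)) return(list(status = "unbounded"))
      if (leave_pos == 0L) {                   # entering variable bound flip
        x[enter] <- x[enter] + dir * t_best
        stat[enter] <- if (dir > 0) 2L else 1L
        x[basis] <- x[basis] - dir * t_best * w
      } else {
        bk <- basis[leave_pos]
        x[enter] <- x[enter] + dir * t_best
        x[basis] <- x[basis] - dir * t_best * w
        x[bk] <- if (leave_to == 2L) ubx[bk] else lbx[bk]
        stat[bk] <- leave_to
        basis[leave_pos] <- enter
        stat[enter] <- 0L
      }
    }
    list(status = "maxiter")
  }

  ph1 <- run_phase(c(rep(0, n), rep(-1, m)), basis, stat, x,
                   lock_artificials = FALSE)
  if (ph1$status != "optimal") {
    return(structure(list(status = ph1$status, z = NA_real_),
                     class = "simplex_solution"))
  }
  basis <- ph1$basis; stat <- ph1$stat; x <- ph1$x
  if (sum(x[n + seq_len(m)]) > feas_tol) {
    return(structure(list(status = "infeasible", z = NA_real_,
                          reason = "equality constraints inconsistent with bounds"),
                     class = "simplex_solution"))
  }
  ubx[n + seq_len(m)] <- 0                       # lock artificials at zero
  idx <- n + seq_len(m)
  x[idx][stat[idx] != 0L] <- 0

  ph2 <- run_phase(c(cvec, rep(0, m)), basis, stat, x,
                   lock_artificials = TRUE)
  if (ph2$status != "optimal") {
    st <- ph2$status
    return(structure(list(status = st, z = NA_real_),
                     class = "simplex_solution"))
  }
  basis <- ph2$basis; stat <- ph2$stat; x <- ph2$x
  xs <- x[seq_len(n)]
  dj <- cvec - as.numeric(crossprod(A, ph2$y))
  structure(list(
    status = "optimal",
    x = xs,
    z = sum(obj * xs),
    y = sense * ph2$y,
    dj = sense * dj,
    basis = basis, stat = stat, x_ext = x,
    lb_ext = lbx, ub_ext = ubx, Bi = ph2$Bi,
    m = m, n = n, maximize = maximize),
    class = "simplex_solution")
}

#' Basis range of a right-hand-side coefficient
#'
#' For an optimal simplex solution, computes the interval \eqn{[g^-, g^+]}
#' of perturbations \eqn{t} of \code{rhs[i]} over which the optimal basis
#' (and therefore the dual value of constraint \code{i}) remains valid.
#' This is classical LP ranging: as \eqn{b_i} moves by \eqn{t}, the basic
#' variables move along \eqn{B^{-1} e_i} until one of them hits a bound.
#'
#' At a primal-degenerate optimum the basis range can collapse to zero on
#' one side even though the optimal-value function is still linear there;
#' \code{\link{check_degeneracy}} therefore supplements this with
#' brute-force re-solves.
#'
#' @param sol an optimal \code{simplex_lp} solution.
#' @param i constraint (row) index.
#' @param tol zero tolerance on the direction vector.
#' @return numeric vector \code{c(lower, upper)} with
#'   \code{lower <= 0 <= upper}; entries may be infinite.
#' @export
simplex_rhs_range <- function(sol, i, tol = 1e-9) {
  stopifnot(inherits(sol, "simplex_solution"), sol$status == "optimal")
  w <- sol$Bi[, i]
  xB <- sol$x_ext[sol$basis]
  lbB <- sol$lb_ext[sol$basis]; ubB <- sol$ub_ext[sol$basis]
  g_up <- Inf; g_dn <- -Inf
  for (k in seq_along(w)) {
    if (w[k] > tol) {
      if (is.finite(ubB[k])) g_up <- min(g_up, (ubB[k] - xB[k]) / w[k])
      if (is.finite(lbB[k])) g_dn <- max(g_dn, (lbB[k] - xB[k]) / w[k])
    } else if (w[k] < -tol) {
      if (is.finite(lbB[k])) g_up <- min(g_up, (lbB[k] - xB[k]) / w[k])
      if (is.finite(ubB[k])) g_dn <- max(g_dn, (ubB[k] - xB[k]) / w[k])
    }
  }
  c(min(g_dn, 0), max(g_up, 0))
}
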