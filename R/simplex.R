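#' Solve a linear program with bounded variables
#'
#' Dense two-phase primal simplex with explicit variable bounds, the
#' workhorse behind [fba()] and [fva()]. Solves
#' \deqn{\min / \max \; c^\top x \quad \text{s.t.} \quad A x \;
#'   \{=, \le, \ge\} \; b, \qquad l \le x \le u.}
#' Nonbasic variables rest at either bound; upper bounds may be infinite
#' (detected as unboundedness when the objective can improve without
#' limit). Degenerate problems are handled by switching to Bland's rule
#' after a burn-in of Dantzig pivots, which guarantees termination.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A constraint matrix (`m` x `n`), dense or a [Matrix::Matrix].
#' @param rhs right-hand sides, length `m`.
#' @param sense character vector of `"="`, `"<="`, `">="` per row
#'   (recycled if length 1).
#' @param lb,ub variable bounds, length `n`. Lower bounds must be finite;
#'   upper bounds may be `Inf`.
#' @param maximize maximize instead of minimize.
#' @param tol optimality tolerance on reduced costs.
#' @param feas_tol feasibility tolerance for the phase-1 residual.
#' @param max_iter pivot limit; defaults to `2000 + 200 * (n + m)`.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective` and the primal solution `x`
#'   (both `NA`/`NULL` unless optimal).
#' @keywords internal
lp_solve <- function(obj, A, rhs, sense = "=", lb, ub,
                     maximize = FALSE, tol = 1e-9, feas_tol = 1e-7,
                     max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  sense <- rep_len(sense, m)
  if (!all(sense %in% c("=", "<=", ">=")))
    stop("constraint sense must be one of '=', '<=', '>='")
  if (any(!is.finite(lb)))
    stop("lp_solve requires finite lower bounds")
  if (any(lb > ub + 1e-12))
    stop("lower bound exceeds upper bound for variable(s) ",
         paste(which(lb > ub + 1e-12), collapse = ", "))

  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # slacks turn inequalities into equalities
  n_slack <- sum(sense != "=")
  if (n_slack > 0) {
    Slk <- matrix(0, m, n_slack)
    k <- 0L
    for (i in seq_len(m)) {
      if (sense[i] == "=") next
      k <- k + 1L
      Slk[i, k] <- if (sense[i] == "<=") 1 else -1
    }
    A <- cbind(A, Slk)
    cc <- c(cc, rep(0, n_slack))
    lb <- c(lb, rep(0, n_slack))
    ub <- c(ub, rep(Inf, n_slack))
  }
  nt <- n + n_slack

  # shift to 0 <= y <= ubar
  ubar <- ub - lb
  b <- as.numeric(rhs) - as.numeric(A %*% lb)
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
  }

  # artificial start basis
  Aall <- cbind(A, diag(1, m))
  ubar_all <- c(ubar, rep(Inf, m))
  art <- nt + seq_len(m)
  if (is.null(max_iter)) max_iter <- 2000L + 200L * (nt + m)

  run_phase <- function(cost, basis, at_upper, pinned) {
    # at_upper: logical over all columns (meaningful for nonbasic only)
    # pinned: columns barred from entering (artificials in phase 2)
    iter <- 0L
    bland_after <- 200L + 10L * (nt + m)
    eps <- 1e-10
    repeat {
      iter <- iter + 1L
      if (iter > max_iter)
        stop("simplex iteration limit reached (", max_iter, ")")
      B <- Aall[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(ncol(Aall)), basis)
      xN <- ifelse(at_upper[nonbasic], ubar_all[nonbasic], 0)
      rhs_eff <- b - as.numeric(Aall[, nonbasic, drop = FALSE] %*% xN)
      xB <- tryCatch(solve(B, rhs_eff), error = function(e)
        qr.solve(B, rhs_eff, tol = 1e-12))
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e)
        qr.solve(t(B), cost[basis], tol = 1e-12))
      d <- cost[nonbasic] - as.numeric(crossprod(Aall[, nonbasic, drop = FALSE], y))
      up <- at_upper[nonbasic]
      viol <- ifelse(up, d, -d)     # positive => improving move exists
      viol[pinned[nonbasic]] <- -Inf
      ok <- viol > tol
      if (!any(ok)) {
        return(list(basis = basis, at_upper = at_upper, xB = xB,
                    obj = sum(cost[basis] * xB) + sum(cost[nonbasic] * xN)))
      }
      cand <- which(ok)
      jrel <- if (iter > bland_after) cand[which.min(nonbasic[cand])]
              else cand[which.max(viol[cand])]
      j <- nonbasic[jrel]
      tdir <- if (at_upper[j]) -1 else 1   # direction entering variable moves
      w <- tryCatch(solve(B, Aall[, j]), error = function(e)
        qr.solve(B, Aall[, j], tol = 1e-12))
      dec <- tdir * w        # rate of decrease of basic vars
      step <- ubar_all[j]    # bound-flip limit
      leave <- 0L            # 0 => bound flip
      leave_at_upper <- FALSE
      for (i in seq_len(m)) {
        if (dec[i] > eps) {
          lim <- xB[i] / dec[i]
          if (lim < step - eps ||
              (lim < step + eps && leave > 0L && basis[i] < basis[leave])) {
            step <- max(lim, 0); leave <- i; leave_at_upper <- FALSE
          }
        } else if (dec[i] < -eps && is.finite(ubar_all[basis[i]])) {
          lim <- (ubar_all[basis[i]] - xB[i]) / (-dec[i])
          if (lim < step - eps ||
              (lim < step + eps && leave > 0L && basis[i] < basis[leave])) {
            step <- max(lim, 0); leave <- i; leave_at_upper <- TRUE
          }
        }
      }
      if (!is.finite(step)) return(list(unbounded = TRUE))
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]      # variable runs to its other bound
      } else {
        at_upper[basis[leave]] <- leave_at_upper
        basis[leave] <- j
        at_upper[j] <- FALSE             # flag unused while basic
      }
    }
  }

  basis <- art
  at_upper <- rep(FALSE, ncol(Aall))
  pinned <- rep(FALSE, ncol(Aall))
  cost1 <- c(rep(0, nt), rep(1, m))
  ph1 <- run_phase(cost1, basis, at_upper, pinned)
  if (isTRUE(ph1$unbounded)) stop("phase-1 LP unbounded; malformed input")
  scale <- max(1, max(abs(b)))
  if (ph1$obj > feas_tol * scale)
    return(list(status = "infeasible", objective = NA_real_, x = NULL))

  # pin artificials so they cannot re-enter; those still basic sit at ~0
  pinned[art] <- TRUE
  ubar_all[art] <- 0
  cost2 <- c(cc, rep(0, m))
  ph2 <- run_phase(cost2, ph1$basis, ph1$at_upper, pinned)
  if (isTRUE(ph2$unbounded))
    return(list(status = "unbounded", objective = NA_real_, x = NULL))

  xfull <- numeric(ncol(Aall))
  nonbasic <- setdiff(seq_len(ncol(Aall)), ph2$basis)
  xfull[nonbasic] <- ifelse(ph2$at_upper[nonbasic], ubar_all[nonbasic], 0)
  xfull[ph2$basis] <- ph2$xB
  x <- xfull[seq_len(n)] + lb[seq_len(n)]
  objective <- sum(obj * x)
  list(status = "optimal", objective = objective, x = x)
}
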