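# Thin LP layer: optimize c'v subject to A_eq v = b_eq and lb <= v <= ub.
#
# Backend: a dense bounded-variable primal simplex (two-phase, Bland's
# anti-cycling rule), written for determinism and robustness on the highly
# degenerate equality systems that stoichiometric models produce. Problem
# sizes here are tiny (tens of variables), so dense basis solves are fine.
# Infinite bounds are capped at a large finite box (FBA convention).

LP_BIG <- 1e6

solve_lp <- function(obj, A_eq, b_eq, lb, ub, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(A_eq) == n, length(lb) == n, length(ub) == n,
            length(b_eq) == nrow(A_eq))
  capped <- !is.finite(lb) | !is.finite(ub)
  lb <- pmax(lb, -LP_BIG)
  ub <- pmin(ub, LP_BIG)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  ub <- pmax(ub, lb)

  # stoichiometric matrices carry conserved-pool row dependencies; reduce to
  # a full-row-rank system after checking right-hand-side consistency
  A <- A_eq
  b <- as.numeric(b_eq)
  if (nrow(A) >= 1L) {
    qa <- qr(t(A))
    if (qa$rank < nrow(A)) {
      qaug <- qr(t(cbind(A, b)))
      if (qaug$rank > qa$rank)
        return(list(status = "infeasible", value = NA_real_, x = NULL))
      keep <- sort(qa$pivot[seq_len(qa$rank)])
      A <- A[keep, , drop = FALSE]
      b <- b[keep]
    }
  }
  res <- simplex_bounded(if (maximize) obj else -obj, A, b, lb, ub, tol = tol)
  if (res$status != "optimal")
    return(list(status = res$status, value = NA_real_, x = NULL))
  value <- sum(obj * res$x)
  status <- if (any(capped & (abs(res$x) > 0.99 * LP_BIG))) "unbounded" else "optimal"
  list(status = status, value = value, x = res$x)
}

# maximize c'x  s.t.  A x = b, lb <= x <= ub  (finite bounds, full row rank A)
simplex_bounded <- function(cc, A, b, lb, ub, tol = 1e-9, max_iter = 100000L) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # box-only problem: each variable sits at its favourable bound
    x <- ifelse(cc > 0, ub, lb)
    return(list(status = "optimal", x = x))
  }
  # start every structural variable at the bound nearer zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_upper <- abs(lb) > abs(ub)
  r <- b - as.numeric(A %*% x)
  # artificial variables close the residual; phase 1 drives them to zero
  Dsign <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(Dsign, m))
  lbe <- c(lb, rep(0, m)); ube <- c(ub, rep(LP_BIG, m))
  xe <- c(x, abs(r))
  basis <- n + seq_len(m)
  status <- c(ifelse(at_upper, 2L, 1L), rep(0L, m)) # 0 basic, 1 at lower, 2 at upper
  status[basis] <- 0L

  run_phase <- function(cost, xe, basis, status) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(ok = FALSE))
      B <- Aext[, basis, drop = FALSE]
      Binv_t <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(Binv_t)) return(list(ok = FALSE))
      nonbasic <- which(status != 0L)
      d <- cost[nonbasic] - as.numeric(crossprod(Aext[, nonbasic, drop = FALSE], Binv_t))
      movable <- ube[nonbasic] - lbe[nonbasic] > tol
      enter_ok <- movable & ((status[nonbasic] == 1L & d > tol) |
                             (status[nonbasic] == 2L & d < -tol))
      if (!any(enter_ok))
        return(list(ok = TRUE, xe = xe, basis = basis, status = status))
      e <- nonbasic[enter_ok][which.min(nonbasic[enter_ok])] # Bland: smallest index
      dir_up <- status[e] == 1L                              # moving off lower bound
      w <- tryCatch(solve(B, Aext[, e]), error = function(e) NULL)
      if (is.null(w)) return(list(ok = FALSE))
      delta_B <- if (dir_up) -w else w   # change in basic vars per unit t
      t_flip <- ube[e] - lbe[e]
      t_best <- t_flip; leave <- 0L; leave_to <- 0L
      for (i in seq_len(m)) {
        di <- delta_B[i]
        if (di < -tol) {
          ti <- (xe[basis[i]] - lbe[basis[i]]) / (-di)
          if (ti < t_best - tol || (ti < t_best + tol &&
              (leave == 0L || basis[i] < basis[leave]))) {
            t_best <- min(ti, t_best); leave <- i; leave_to <- 1L
          }
        } else if (di > tol) {
          ti <- (ube[basis[i]] - xe[basis[i]]) / di
          if (ti < t_best - tol || (ti < t_best + tol &&
              (leave == 0L || basis[i] < basis[leave]))) {
            t_best <- min(ti, t_best); leave <- i; leave_to <- 2L
          }
        }
      }
      if (t_best >= LP_BIG * 10) return(list(ok = TRUE, unbounded = TRUE))
      t_best <- max(t_best, 0)
      xe[basis] <- xe[basis] + delta_B * t_best
      xe[e] <- xe[e] + if (dir_up) t_best else -t_best
      if (leave == 0L) {
        status[e] <- if (dir_up) 2L else 1L        # bound flip, basis unchanged
      } else {
        lv <- basis[leave]
        status[lv] <- leave_to
        xe[lv] <- if (leave_to == 1L) lbe[lv] else ube[lv]
        basis[leave] <- e
        status[e] <- 0L
      }
    }
  }

  # phase 1: minimise sum of artificials == maximise -sum
  cost1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(cost1, xe, basis, status)
  if (!p1$ok) stop("LP backend failed (phase 1)")
  if (isTRUE(p1$unbounded)) stop("LP backend: phase 1 unbounded (internal error)")
  if (sum(p1$xe[n + seq_len(m)]) > 1e-6)
    return(list(status = "infeasible", x = NULL))
  # pin artificials to zero for phase 2
  ube[n + seq_len(m)] <- 0
  p1$xe[n + seq_len(m)] <- pmax(pmin(p1$xe[n + seq_len(m)], 0), 0)
  cost2 <- c(cc, rep(0, m))
  p2 <- run_phase(cost2, p1$xe, p1$basis, p1$status)
  if (!p2$ok) stop("LP backend failed (phase 2)")
  if (isTRUE(p2$unbounded)) return(list(status = "unbounded", x = NULL))
  list(status = "optimal", x = p2$xe[seq_len(n)])
}
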