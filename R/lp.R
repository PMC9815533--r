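# Internal LP layer: two-phase revised simplex for bounded variables.
#
#   max/min  c'v   s.t.  A v = rhs,  lb <= v <= ub
#
# Stoichiometric equality systems are rank-deficient (conserved moieties
# duplicate rows) and highly degenerate, which the simplex codes in the
# installed libraries do not survive; this implementation reduces the
# equality system to a row basis first and uses Bland's rule (smallest
# index) throughout, which guarantees termination. Problem sizes here are
# tiny (tens of variables), so dense per-iteration solves are irrelevant.

LP_EPS <- 1e-9

solve_lp <- function(obj, A, rhs, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  stopifnot(length(obj) == ncol(A), length(lb) == ncol(A),
            length(ub) == ncol(A), length(rhs) == nrow(A))
  lb <- pmax(lb, -1e6)
  ub <- pmin(ub, 1e6)
  if (any(lb > ub + LP_EPS)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  keep <- row_basis(A)
  res <- simplex_bv(if (maximize) -obj else obj,
                    A[keep, , drop = FALSE], rhs[keep], lb, ub)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, value = NA_real_))
  }
  # dropped rows must be consistent linear combinations; guard anyway
  if (length(rhs) > length(keep) && max(abs(A %*% res$x - rhs)) > 1e-6) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  list(status = "optimal", x = res$x, value = sum(obj * res$x))
}

# indices of a maximal linearly independent row set
row_basis <- function(A) {
  if (nrow(A) == 0) return(integer())
  qa <- qr(t(A))
  sort(qa$pivot[seq_len(qa$rank)])
}

# Minimize c'x s.t. A x = b, l <= x <= u (A full row rank, finite bounds).
simplex_bv <- function(cc, A, b, l, u, tol = LP_EPS) {
  m <- nrow(A)
  n <- ncol(A)
  if (m == 0) {
    x <- ifelse(cc > 0, l, ifelse(cc < 0, u, l))
    return(list(status = "optimal", x = x))
  }
  x0 <- l
  resid <- b - as.vector(A %*% x0)
  Ae <- cbind(A, diag(ifelse(resid < 0, -1, 1), m))
  le <- c(l, rep(0, m))
  ue <- c(u, rep(1e30, m))
  state <- list(xe = c(x0, abs(resid)),
                basis = n + seq_len(m),
                at_upper = rep(FALSE, n + m))

  p1 <- lp_phase(c(rep(0, n), rep(1, m)), state, FALSE, Ae, le, ue, n, m, tol)
  if (!identical(p1$status, "optimal")) return(list(status = "solver_error"))
  if (sum(p1$xe[n + seq_len(m)]) > 1e-7) return(list(status = "infeasible"))
  ue[n + seq_len(m)] <- 0                    # lock artificials for phase 2
  p1$xe[n + seq_len(m)] <- 0
  p2 <- lp_phase(c(cc, rep(0, m)),
                 list(xe = p1$xe, basis = p1$basis, at_upper = p1$at_upper),
                 TRUE, Ae, le, ue, n, m, tol)
  if (identical(p2$status, "unbounded")) return(list(status = "unbounded"))
  if (!identical(p2$status, "optimal")) return(list(status = "solver_error"))
  list(status = "optimal", x = p2$xe[seq_len(n)])
}

# one simplex phase; Bland's rule on entering and leaving variables
lp_phase <- function(cost, state, lock_art, Ae, le, ue, n, m, tol) {
  xe <- state$xe
  basis <- state$basis
  at_upper <- state$at_upper
  all_idx <- seq_len(n + m)
  it_max <- 1000L * (n + m)
  for (it in seq_len(it_max)) {
    B <- Ae[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(status = "singular"))
    nonbasic <- all_idx[-basis]
    if (lock_art) nonbasic <- nonbasic[nonbasic <= n]
    d <- cost[nonbasic] - as.vector(y %*% Ae[, nonbasic, drop = FALSE])
    width <- ue[nonbasic] - le[nonbasic]
    elig <- (!at_upper[nonbasic] & d < -tol & width > tol) |
            (at_upper[nonbasic] & d > tol & width > tol)
    if (!any(elig)) {
      return(list(status = "optimal", xe = xe, basis = basis,
                  at_upper = at_upper))
    }
    j <- min(nonbasic[elig])
    w <- solve(B, Ae[, j])
    dir <- if (at_upper[j]) -1 else 1          # x_j moves by dir * t
    delta <- -dir * w                          # basics move by delta * t
    xb <- xe[basis]
    ratio <- rep(Inf, m)
    hits_upper <- rep(FALSE, m)
    dec <- delta < -tol
    inc <- delta > tol
    ratio[dec] <- (xb[dec] - le[basis[dec]]) / (-delta[dec])
    ratio[inc] <- (ue[basis[inc]] - xb[inc]) / delta[inc]
    hits_upper[inc] <- TRUE
    ratio[ratio < 0] <- 0
    t_flip <- ue[j] - le[j]
    tstep <- min(t_flip, ratio)
    if (!is.finite(tstep)) return(list(status = "unbounded"))
    cand <- which(ratio <= tstep + 1e-12)
    xe[j] <- xe[j] + dir * tstep
    xe[basis] <- xb + delta * tstep
    if (length(cand) == 0L) {                  # bound flip, basis unchanged
      at_upper[j] <- !at_upper[j]
      next
    }
    leave <- cand[which.min(basis[cand])]
    out <- basis[leave]
    xe[out] <- if (hits_upper[leave]) ue[out] else le[out]
    at_upper[out] <- hits_upper[leave]
    basis[leave] <- j
    at_upper[j] <- FALSE
  }
  list(status = "iteration_limit")
}
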