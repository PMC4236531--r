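# Strictly convex bound-constrained quadratic program:
#   minimize 0.5 x' H x + d' x   subject to  lower <= x <= upper
# solved by a primal active-set method.  H must be symmetric positive
# definite.  Problems here are tiny (one variable per muscle), so dense
# solves are used throughout; optimality is certified externally via
# kkt_residual().
solve_box_qp <- function(H, d, lower, upper, tol = 1e-11, max_iter = 500L) {
  n <- length(d)
  at_lo <- rep(FALSE, n); at_hi <- rep(FALSE, n)
  x <- numeric(n)
  status <- "max_iter"
  for (iter in seq_len(max_iter)) {
    free <- !(at_lo | at_hi)
    x[at_lo] <- lower[at_lo]; x[at_hi] <- upper[at_hi]
    if (any(free)) {
      rhs <- -d[free]
      if (any(!free)) {
        rhs <- rhs - H[free, !free, drop = FALSE] %*% x[!free]
      }
      x[free] <- solve(H[free, free, drop = FALSE], rhs)
    }
    viol_lo <- free & (x < lower - tol)
    viol_hi <- free & (x > upper + tol)
    if (any(viol_lo | viol_hi)) {
      at_lo[viol_lo] <- TRUE
      at_hi[viol_hi] <- TRUE
      next
    }
    g <- drop(H %*% x) + d
    rel_lo <- at_lo & (g < -tol)   # lower-bound multiplier must be >= 0
    rel_hi <- at_hi & (g > tol)    # upper-bound multiplier must be <= 0
    if (!any(rel_lo | rel_hi)) {
      status <- "optimal"
      break
    }
    score <- rep(-Inf, n)
    score[rel_lo] <- -g[rel_lo]
    score[rel_hi] <- g[rel_hi]
    i <- which.max(score)          # release the worst bound, one at a time
    at_lo[i] <- FALSE; at_hi[i] <- FALSE
  }
  list(x = pmin(pmax(x, lower), upper), status = status, iterations = iter)
}
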