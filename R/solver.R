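# Dense bounded-variable two-phase primal simplex.
#
# Solves   min / max  c'x   s.t.  A x = b,  lb <= x <= ub.
#
# Written for the problem sizes of constraint-based mini-models (tens to a
# few hundred variables): the basis system is re-solved from scratch each
# iteration, which is numerically robust and fast at this scale. Bland's
# rule is used for both the entering and the leaving variable, so the
# method cannot cycle and is fully deterministic. Infinite bounds are
# capped internally; a solution pressed against the cap is reported as
# unbounded.

LP_BIG <- 1e9

#' Solve a linear program with equality constraints and box bounds
#'
#' @param obj Objective coefficients (length n).
#' @param A Constraint matrix (m x n), dense or sparse.
#' @param b Right-hand side (length m).
#' @param lb,ub Variable bounds (length n; infinities allowed).
#' @param maximize Maximize instead of minimize.
#' @param tol Feasibility/optimality tolerance.
#' @param max_iter Iteration cap per phase.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (length-n solution, `NA` unless optimal) and `objective`.
#' @export
solve_lp <- function(obj, A, b, lb, ub, maximize = FALSE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  capped <- !is.finite(lb) | !is.finite(ub)
  lbf <- pmax(lb, -LP_BIG); ubf <- pmin(ub, LP_BIG)
  if (any(lbf > ubf)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  sense <- if (maximize) -1 else 1
  cost <- sense * obj

  ntot <- n + m
  Afull <- cbind(A, diag(m))
  lball <- c(lbf, rep(0, m))
  uball <- c(ubf, rep(LP_BIG, m))

  # start: structural variables nonbasic at the bound nearest zero
  x <- numeric(ntot)
  pick <- ifelse(abs(lbf) <= abs(ubf), lbf, ubf)
  x[seq_len(n)] <- pick
  r <- as.numeric(b - A %*% x[seq_len(n)])
  sgn <- ifelse(r >= 0, 1, -1)
  Afull[, n + seq_len(m)] <- diag(sgn, m)
  x[n + seq_len(m)] <- abs(r)
  basis <- n + seq_len(m)
  in_basis <- logical(ntot); in_basis[basis] <- TRUE

  run_phase <- function(cvec, phase) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached")
      B <- Afull[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
      if (is.null(y)) stop("singular basis encountered in simplex")
      nb <- which(!in_basis)
      d <- cvec[nb] - as.numeric(crossprod(y, Afull[, nb, drop = FALSE]))
      at_lo <- abs(x[nb] - lball[nb]) < 1e-12 * (1 + abs(lball[nb]))
      fixed <- (uball[nb] - lball[nb]) < 1e-15
      improve <- !fixed & ((at_lo & d < -tol) | (!at_lo & d > tol))
      if (!any(improve)) return("optimal")
      j <- nb[improve][which.min(nb[improve])]       # Bland: smallest index
      dj <- d[match(j, nb)]
      sigma <- if (abs(x[j] - lball[j]) < 1e-12 * (1 + abs(lball[j]))) 1 else -1
      w <- solve(B, Afull[, j])
      # ratio test
      tmax <- uball[j] - lball[j]
      leave <- 0L
      for (i in seq_len(m)) {
        wi <- sigma * w[i]
        bi <- basis[i]
        if (wi > tol) {
          lim <- (x[bi] - lball[bi]) / wi
        } else if (wi < -tol) {
          lim <- (x[bi] - uball[bi]) / wi
        } else next
        lim <- max(lim, 0)
        if (lim < tmax - 1e-12) {
          tmax <- lim
          leave <- i
        } else if (lim <= tmax + 1e-12 && leave != 0L && bi < basis[leave]) {
          leave <- i                       # Bland tie-break on variable index
        }
      }
      if (phase == 2L && tmax >= LP_BIG / 2) return("unbounded")
      x[j] <<- x[j] + sigma * tmax
      if (m > 0) x[basis] <<- x[basis] - sigma * tmax * w
      if (leave == 0L) {
        # bound flip: variable moved across to its other bound, stays nonbasic
        x[j] <<- if (sigma > 0) uball[j] else lball[j]
      } else {
        bi <- basis[leave]
        # leaving variable lands exactly on the bound it hit
        hit_lo <- sigma * w[leave] > 0
        x[bi] <<- if (hit_lo) lball[bi] else uball[bi]
        in_basis[bi] <<- FALSE
        in_basis[j] <<- TRUE
        basis[leave] <<- j
      }
    }
  }

  # phase 1: minimize sum of artificials
  c1 <- c(rep(0, n), rep(1, m))
  st <- run_phase(c1, 1L)
  infeas <- sum(x[n + seq_len(m)])
  if (infeas > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  # pin artificials to zero and optimize the true objective
  uball[n + seq_len(m)] <- 0
  x[n + seq_len(m)] <- pmax(pmin(x[n + seq_len(m)], 0), 0)
  c2 <- c(cost, rep(0, m))
  st <- run_phase(c2, 2L)
  xs <- x[seq_len(n)]
  if (st == "unbounded" || (any(capped) && any(abs(xs) > LP_BIG / 2 - 1))) {
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  }
  # clean residual drift on basic variables
  res <- max(abs(as.numeric(A %*% xs - b)))
  if (res > 1e-6) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  list(status = "optimal", x = xs, objective = sum(obj * xs))
}
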