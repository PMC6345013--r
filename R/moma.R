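# Minimization of metabolic adjustment (MOMA).
#
# Given a wild-type reference flux distribution v_ref, MOMA predicts the
# flux state of a perturbed network as the solution of the strictly convex
# quadratic program
#
#   min  sum_j (v_j - v_ref,j)^2   s.t.  S v = 0,  lb' <= v <= ub'
#
# over ALL reactions (exchanges included). The QP is solved with the
# active-set method of quadprog; because the Hessian is the identity the
# minimizer is unique. The equality block is rank-reduced by QR before
# being handed to quadprog, which requires linearly independent equality
# constraints; a phase-1 LP feasibility check precedes the QP so that an
# infeasible perturbation is reported as such rather than mis-solved.

#' Solve a MOMA problem
#'
#' @param model A `metabolic_model` whose bounds already reflect the
#'   perturbation (e.g. via [knockout_genes()] or [set_bounds()]).
#' @param reference A `flux_state` (wild-type FBA solution) or a numeric
#'   flux vector aligned with `model$reactions$id`.
#' @param knockout Optional character vector of gene ids; applied to
#'   `model` via [knockout_genes()] before solving.
#' @return A `flux_state` with `kind = "moma"`; `objective_value` is the
#'   squared Euclidean distance to the reference, and the element
#'   `distance` carries the same value.
#' @examples
#' m <- set_medium(mini_model(), mini_minimal_medium())
#' wt <- solve_fba(m)
#' ko <- solve_moma(m, wt, knockout = "CHS")
#' @export
solve_moma <- function(model, reference, knockout = NULL) {
  if (!is.null(knockout)) model <- knockout_genes(model, knockout)
  vref <- if (inherits(reference, "flux_state")) {
    ref <- reference$raw_fluxes
    if (length(ref) != nrow(model$reactions)) {
      stop("reference flux state does not match the model's reactions")
    }
    ref
  } else {
    as.numeric(reference)
  }
  n <- nrow(model$reactions)
  if (length(vref) != n) stop("reference flux vector has wrong length")
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- model$reactions$lb
  ub <- model$reactions$ub

  feas <- solve_lp(numeric(n), S, rep(0, nrow(S)), lb, ub)
  if (feas$status != "optimal") {
    return(new_flux_state(model, rep(NA_real_, n), NA_real_, "infeasible",
                          c(moma_distance = 1), kind = "moma",
                          extra = list(distance = NA_real_)))
  }

  # equality block: S v = 0 plus pinned variables (lb == ub). The QP is
  # solved in the null space of this block: v = v0 + N z with N an
  # orthonormal null-space basis from the SVD, turning the problem into a
  # small box-constrained QP with identity Hessian — far better
  # conditioned than handing quadprog ~#metabolites equality rows.
  fixed <- which(ub - lb < 1e-15)
  Eq <- S
  beq <- rep(0, nrow(S))
  if (length(fixed) > 0) {
    P <- matrix(0, length(fixed), n)
    P[cbind(seq_along(fixed), fixed)] <- 1
    Eq <- rbind(Eq, P)
    beq <- c(beq, lb[fixed])
  }
  sv <- svd(Eq, nv = n)
  rk <- sum(sv$d > max(dim(Eq)) * .Machine$double.eps * sv$d[1])
  v0 <- sv$v[, seq_len(rk), drop = FALSE] %*%
    ((crossprod(sv$u[, seq_len(rk), drop = FALSE], beq)) / sv$d[seq_len(rk)])
  v0 <- as.numeric(v0)
  N <- if (rk >= n) matrix(0, n, 0) else sv$v[, seq.int(rk + 1, n), drop = FALSE]
  if (ncol(N) == 0) {
    v <- v0
  } else {
    active <- which(apply(abs(N), 1, max) > 1e-12)   # rows N touches
    Amat <- t(rbind(N[active, , drop = FALSE], -N[active, , drop = FALSE]))
    bvec <- c(lb[active] - v0[active], -(ub[active] - v0[active]))
    dvec <- as.numeric(crossprod(N, vref - v0))
    viol <- max(bvec - as.numeric(crossprod(Amat, dvec)))
    if (viol <= 1e-9) {
      # the unconstrained minimizer (the projection of vref) is feasible:
      # skip the active-set solve, which is badly degenerate in this case
      z <- dvec
    } else {
      z <- NULL
      for (eps in c(0, 1e-9, 1e-7)) {   # tie-relaxation ladder for quadprog
        sol <- tryCatch(
          quadprog::solve.QP(Dmat = diag(ncol(N)), dvec = dvec,
                             Amat = Amat, bvec = bvec - eps, meq = 0),
          error = function(e) NULL)
        if (!is.null(sol)) { z <- sol$solution; break }
      }
      if (is.null(z)) stop("MOMA quadratic program could not be solved")
    }
    v <- v0 + as.numeric(N %*% z)
  }
  # clip round-off outside the box
  v <- pmin(pmax(v, lb), ub)
  dist <- sum((v - vref)^2)
  new_flux_state(model, v, dist, "optimal", c(moma_distance = 1),
                 kind = "moma", extra = list(distance = dist))
}
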