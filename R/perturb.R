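# Gene essentiality screening and the overexpression-target scan.

#' Single-gene deletion screen
#'
#' For each gene, bounds to zero every reaction whose GPR becomes
#' unsatisfiable under the deletion, re-solves FBA, and calls the gene
#' essential when the knockout growth falls below `threshold` times the
#' wild-type growth. The screen is order-independent: genes are evaluated
#' in isolation against the same wild-type reference.
#'
#' @param model A `metabolic_model` with the medium already applied.
#' @param genes Genes to screen (default: all model genes).
#' @param objective As in [solve_fba()] (default: model objective, i.e.
#'   biomass).
#' @param threshold Essentiality threshold as a fraction of wild-type
#'   growth (default 0.01, i.e. growth below 1% of wild type).
#' @return A tibble of class `stilflux_deletions`: `gene`, `growth`,
#'   `wt_growth`, `ratio`, `essential`, `n_disabled`, `disabled` (list
#'   column of disabled reaction ids). Infeasible knockouts have
#'   `growth = 0`.
#' @examples
#' m <- set_medium(mini_model(), mini_minimal_medium())
#' del <- single_gene_deletion(m, genes = c("PFK", "HXK1", "CHS"))
#' @export
single_gene_deletion <- function(model, genes = NULL, objective = NULL,
                                 threshold = 0.01) {
  genes <- genes %||na% model$genes
  wt <- solve_fba(model, objective)
  if (wt$status != "optimal") {
    stop("wild-type FBA is ", wt$status, "; set a growth-supporting medium ",
         "before screening deletions")
  }
  wt_growth <- wt$objective_value
  one <- function(g) {
    off <- disabled_reactions(model, g)
    if (length(off) == 0L) {
      growth <- wt_growth
    } else {
      sol <- solve_fba(set_bounds(model, off, 0, 0), objective)
      growth <- if (sol$status == "optimal") sol$objective_value else 0
    }
    growth <- min(growth, wt_growth + 1e-6)
    tibble::tibble(gene = g, growth = growth, wt_growth = wt_growth,
                   ratio = if (wt_growth > 0) growth / wt_growth else NA_real_,
                   essential = growth < threshold * wt_growth,
                   n_disabled = length(off), disabled = list(off))
  }
  out <- dplyr::bind_rows(lapply(genes, one))
  class(out) <- c("stilflux_deletions", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Scan for flux-forcing overexpression targets
#'
#' Reproduces the in-silico target identification strategy for enhanced
#' product formation: the wild type is solved by FBA with the product
#' exchange lower-bounded at `min_product`; every reaction carrying
#' non-zero flux is then, one at a time, forced to `fold` times its
#' wild-type flux (raising the lower bound for forward flux, lowering the
#' upper bound for reverse flux), and the resulting product rate is
#' evaluated by MOMA against the wild-type reference (or by FBA on the
#' growth objective, per `method`). The product exchange itself is
#' excluded from the candidate set. Candidates are ranked by the
#' fold-change of the product rate; only improving candidates are
#' returned.
#'
#' @param model A `metabolic_model` with medium applied.
#' @param product Product exchange reaction id (e.g. `"EX_resv_e"`).
#' @param min_product Lower bound imposed on the product exchange in the
#'   wild-type simulation (mmol/gDW/h).
#' @param fold Overexpression factor applied to each wild-type flux.
#' @param objective Growth objective, as in [solve_fba()].
#' @param method `"moma"` (default): the perturbed state is the minimal
#'   metabolic adjustment from the wild-type reference, and the product
#'   rate is the product-exchange flux of that state — the immediate
#'   metabolic response. `"fba"`: lexicographic re-optimization — growth
#'   is re-maximized under the forced bound, then the product exchange is
#'   maximized at that growth — the attainable product rate of the forced
#'   strain.
#' @param tol Flux threshold defining "non-zero flux".
#' @return A tibble of class `stilflux_targets`: `reaction`, `genes`
#'   (collapsed from the GPR), `wt_flux`, `forced_flux`, `product_rate`,
#'   `fold_change`, `status`, ranked by decreasing `fold_change`. Zero rows
#'   when no forcing improves the product.
#' @export
scan_overexpression_targets <- function(model, product, min_product = 0.001,
                                        fold = 2, objective = NULL,
                                        method = c("moma", "fba"),
                                        tol = 1e-6) {
  method <- match.arg(method)
  rxn_index(model, product)
  base <- set_bounds(model, product, lb = min_product)
  wt <- solve_fba(base, objective)
  if (wt$status != "optimal") {
    stop("wild-type FBA with the product bound is ", wt$status)
  }
  wt_product <- flux_of(wt, product)
  fl <- stats::setNames(wt$raw_fluxes, model$reactions$id)
  cand <- model$reactions$id[abs(fl) > tol]
  cand <- setdiff(cand, product)

  one <- function(rid) {
    v <- fl[[rid]]
    target <- fold * v
    if (v > 0) {
      m2 <- set_bounds(base, rid, lb = min(target, base$reactions$ub[rxn_index(base, rid)]))
    } else {
      m2 <- set_bounds(base, rid, ub = max(target, base$reactions$lb[rxn_index(base, rid)]))
    }
    if (method == "moma") {
      sol <- solve_moma(m2, wt)
      rate <- if (sol$status == "optimal") flux_of(sol, product) else NA_real_
    } else {
      gsol <- solve_fba(m2, objective)
      if (gsol$status != "optimal") {
        sol <- gsol
        rate <- NA_real_
      } else {
        sol <- lexicographic_max(m2, objective, gsol$objective_value, product)
        rate <- if (sol$status == "optimal") sol$objective_value else NA_real_
      }
    }
    tibble::tibble(reaction = rid, wt_flux = v, forced_flux = target,
                   product_rate = rate,
                   fold_change = rate / wt_product, status = sol$status)
  }
  lexicographic_max <- function(model, objective, growth_opt, product) {
    ob <- fba_objective_vector(model, objective)
    S <- as.matrix(stoichiometric_matrix(model))
    n <- ncol(S)
    A <- rbind(cbind(S, 0), c(ob$vec, -1))        # growth - slack = optimum
    b <- c(rep(0, nrow(S)), growth_opt * (1 - 1e-9))
    pvec <- numeric(n + 1); pvec[rxn_index(model, product)] <- 1
    r <- solve_lp(pvec, A, b, c(model$reactions$lb, 0),
                  c(model$reactions$ub, Inf), maximize = TRUE)
    list(status = r$status, objective_value = r$objective)
  }

  out <- dplyr::bind_rows(lapply(cand, one))
  out$genes <- vapply(out$reaction, function(rid) {
    paste(gpr_genes(model$reactions$gpr[[rxn_index(model, rid)]]),
          collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  out <- out |>
    dplyr::filter(.data$status == "optimal",
                  .data$fold_change > 1 + 1e-6) |>
    dplyr::arrange(dplyr::desc(.data$fold_change)) |>
    dplyr::select("reaction", "genes", "wt_flux", "forced_flux",
                  "product_rate", "fold_change", "status")
  class(out) <- c("stilflux_targets", class(out))
  attr(out, "product") <- product
  attr(out, "wt_product") <- wt_product
  out
}
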