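# Flux balance analysis: LP assembly, media, FVA, robustness scans,
# connectivity statistics.

#' Construct a flux state
#' @noRd
new_flux_state <- function(model, x, objective_value, status, objective,
                           kind = "fba", extra = list()) {
  fluxes <- tibble::tibble(
    reaction = model$reactions$id,
    flux = if (all(is.na(x))) rep(NA_real_, nrow(model$reactions)) else {
      xf <- x
      xf[abs(xf) < 1e-6] <- 0    # zero-clamp below reported precision
      xf
    }
  )
  structure(
    c(list(fluxes = fluxes, objective_value = objective_value,
           status = status, objective = objective, kind = kind,
           raw_fluxes = x), extra),
    class = "flux_state"
  )
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> status: ", x$status, "\n", sep = "")
  if (!is.na(x$objective_value)) {
    cat("  objective (", paste(names(x$objective), collapse = ", "), "): ",
        format(x$objective_value, digits = 6), "\n", sep = "")
  }
  invisible(x)
}

#' Flux vector of a solved state
#'
#' @param x A `flux_state`.
#' @param ... Unused.
#' @return Tibble with columns `reaction`, `flux` (mmol/gDW/h; values below
#'   1e-6 in magnitude are clamped to zero).
#' @export
tidy.flux_state <- function(x, ...) x$fluxes

#' One-row summary of a solved state
#'
#' @param x A `flux_state`.
#' @param ... Unused.
#' @return One-row tibble with `status`, `objective_value`, `n_active`
#'   (reactions with non-zero reported flux).
#' @export
glance.flux_state <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    objective_value = x$objective_value,
    n_active = sum(x$fluxes$flux != 0, na.rm = TRUE)
  )
}

#' Look up one flux in a state
#'
#' @param state A `flux_state`.
#' @param reaction Reaction id(s).
#' @return Numeric flux value(s).
#' @export
flux_of <- function(state, reaction) {
  i <- match(reaction, state$fluxes$reaction)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(reaction[is.na(i)], collapse = ", "))
  state$fluxes$flux[i]
}

fba_objective_vector <- function(model, objective) {
  obj <- numeric(nrow(model$reactions))
  if (is.null(objective)) {
    if (length(model$objective) == 0) {
      stop("model has no objective and none was given")
    }
    ids <- names(model$objective)
    obj[rxn_index(model, ids)] <- model$objective
  } else if (is.character(objective)) {
    ids <- objective
    obj[rxn_index(model, ids)] <- 1
  } else {
    ids <- names(objective)
    obj[rxn_index(model, ids)] <- as.numeric(objective)
  }
  list(vec = obj, ids = ids)
}

#' Solve a flux balance analysis problem
#'
#' Maximizes (or minimizes) the objective flux subject to the steady-state
#' constraint `S v = 0` and the model's flux bounds. The optimal objective
#' value is deterministic; the flux vector is one optimal vertex and is only
#' asserted through FVA ranges.
#'
#' @param model A `metabolic_model` with bounds/medium already applied.
#' @param objective Reaction id(s), or a named numeric weight vector;
#'   `NULL` uses the model objective.
#' @param direction `"max"` or `"min"`.
#' @return A `flux_state` with `status` one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`.
#' @examples
#' m <- mini_model()
#' m <- set_medium(m, mini_minimal_medium())
#' sol <- solve_fba(m)
#' glance(sol)
#' @export
solve_fba <- function(model, objective = NULL, direction = c("max", "min")) {
  direction <- match.arg(direction)
  ob <- fba_objective_vector(model, objective)
  S <- as.matrix(stoichiometric_matrix(model))
  r <- solve_lp(ob$vec, S, rep(0, nrow(S)), model$reactions$lb,
                model$reactions$ub, maximize = direction == "max")
  if (r$status == "optimal") {
    resid <- max(abs(S %*% r$x))
    if (resid > 1e-6) r$status <- "infeasible"
  }
  new_flux_state(model, r$x, r$objective, r$status,
                 stats::setNames(rep(1, length(ob$ids)), ob$ids))
}

#' Apply a growth medium to a model
#'
#' Exchange uptake follows the convention of a negative lower bound in
#' mmol/gDW/h. All exchange reactions are first closed for uptake
#' (`lb = 0`); exchanges named in `medium` get `lb = -rate`; exchanges in
#' `unlimited` (e.g. water, protons, minerals) get `lb = -1000`. Secretion
#' bounds are untouched.
#'
#' @param model A `metabolic_model`.
#' @param medium Named numeric vector (exchange id -> maximum uptake rate,
#'   `>= 0`) or a tibble with columns `exchange`, `uptake`. May carry an
#'   `unlimited` attribute.
#' @param unlimited Character vector of exchange ids left effectively
#'   unconstrained for uptake.
#' @return The constrained model.
#' @examples
#' m <- set_medium(mini_model(), c(EX_glc__D_e = 2.0),
#'                 unlimited = c("EX_o2_e", "EX_h2o_e", "EX_h_e", "EX_nh4_e",
#'                               "EX_pi_e", "EX_so3_e"))
#' @export
set_medium <- function(model, medium, unlimited = NULL) {
  if (is.data.frame(medium)) {
    unl_attr <- attr(medium, "unlimited")
    med <- stats::setNames(medium$uptake, medium$exchange)
    if (is.null(unlimited)) unlimited <- unl_attr
  } else {
    if (is.null(unlimited)) unlimited <- attr(medium, "unlimited")
    med <- medium
  }
  unlimited <- unlimited %||na% character()
  if (any(med < 0)) stop("uptake rates must be >= 0 (applied as -lb)")
  ex_ids <- model$reactions$id[model$reactions$kind == "exchange"]
  unknown <- setdiff(c(names(med), unlimited), ex_ids)
  if (length(unknown) > 0) {
    stop("unknown exchange reaction(s): ", paste(unknown, collapse = ", "))
  }
  model <- set_bounds(model, ex_ids, lb = 0)
  if (length(med) > 0) model <- set_bounds(model, names(med), lb = -unname(med))
  if (length(unlimited) > 0) model <- set_bounds(model, unlimited, lb = -1000)
  model
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Fix the growth rate of a model
#'
#' Pins the biomass (or any) reaction to an exact flux by setting
#' `lb = ub = rate`, the constraint used when scanning product formation at
#' a fixed specific growth rate.
#'
#' @param model A `metabolic_model`.
#' @param rate Growth rate in 1/h.
#' @param reaction Reaction id; defaults to the model's biomass reaction.
#' @return The constrained model.
#' @export
fix_growth <- function(model, rate, reaction = NULL) {
  if (is.null(reaction)) {
    reaction <- model$reactions$id[model$reactions$kind == "biomass"]
    if (length(reaction) != 1) stop("model must have exactly one biomass reaction")
  }
  set_bounds(model, reaction, lb = rate, ub = rate)
}

#' Flux variability analysis
#'
#' For each reaction, computes the minimum and maximum flux attainable
#' while the objective stays at or above `fraction` of its optimum.
#'
#' @param model A `metabolic_model`.
#' @param objective As in [solve_fba()].
#' @param fraction Required fraction of the optimal objective (0-1).
#' @param reactions Reaction ids to scan (default: all).
#' @return A tibble with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, objective = NULL, fraction = 1.0,
                             reactions = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  base <- solve_fba(model, objective)
  if (base$status != "optimal") {
    stop("base FBA problem is ", base$status, "; cannot run FVA")
  }
  ob <- fba_objective_vector(model, objective)
  S <- as.matrix(stoichiometric_matrix(model))
  n <- ncol(S)
  # objective >= fraction * optimum, as an equality row with a slack column
  A <- rbind(cbind(S, 0), c(ob$vec, -1))
  b <- c(rep(0, nrow(S)), fraction * base$objective_value)
  lb <- c(model$reactions$lb, 0)
  ub <- c(model$reactions$ub, Inf)
  ids <- reactions %||na% model$reactions$id
  idx <- rxn_index(model, ids)
  one <- function(j, maximize) {
    obj <- numeric(n + 1); obj[j] <- 1
    r <- solve_lp(obj, A, b, lb, ub, maximize = maximize)
    if (r$status != "optimal") NA_real_ else r$objective
  }
  tibble::tibble(
    reaction = ids,
    min = vapply(idx, one, numeric(1), maximize = FALSE),
    max = vapply(idx, one, numeric(1), maximize = TRUE)
  )
}

#' Robustness scan of an objective against one controlled flux
#'
#' Re-optimizes the objective while the control reaction is pinned to each
#' value in turn (`lb = ub = value`), e.g. resveratrol export maximized
#' while the ethanol uptake rate is stepped from 0 to 0.05 mmol/gDW/h at a
#' fixed glucose uptake and growth rate.
#'
#' @param model A `metabolic_model` (other constraints already applied).
#' @param reaction Control reaction id.
#' @param values Flux values for the control reaction (sorted). With
#'   `uptake = TRUE` values are uptake magnitudes and the reaction is
#'   pinned to `-value`.
#' @param objective As in [solve_fba()].
#' @param uptake Interpret `values` as uptake rates of an exchange.
#' @param direction `"max"` or `"min"`.
#' @return A tibble of class `stilflux_scan` with columns `value`, `status`,
#'   `objective_value` (NA at infeasible points).
#' @export
robustness_scan <- function(model, reaction, values, objective = NULL,
                            uptake = FALSE, direction = "max") {
  stopifnot(!is.unsorted(values))
  rows <- lapply(values, function(v) {
    pin <- if (uptake) -v else v
    m2 <- set_bounds(model, reaction, lb = pin, ub = pin)
    sol <- solve_fba(m2, objective, direction)
    tibble::tibble(value = v, status = sol$status,
                   objective_value = sol$objective_value)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stilflux_scan", class(out))
  attr(out, "reaction") <- reaction
  attr(out, "uptake") <- uptake
  out
}

#' Metabolite connectivity ranking
#'
#' Counts, for every metabolite, the number of reactions it participates in
#' — structurally (all reactions) or restricted to reactions carrying flux
#' above `tol` in a given solution. Sorted by decreasing count, ties broken
#' by metabolite id.
#'
#' @param model A `metabolic_model`.
#' @param flux_state Optional `flux_state`; when given, only reactions with
#'   `|flux| > tol` are counted.
#' @param tol Flux threshold for the flux-weighted mode.
#' @return A tibble of class `stilflux_connectivity` with columns
#'   `metabolite`, `count`.
#' @export
metabolite_connectivity <- function(model, flux_state = NULL, tol = 1e-6) {
  rxns <- model$reactions
  keep <- rep(TRUE, nrow(rxns))
  if (!is.null(flux_state)) {
    fl <- flux_of(flux_state, rxns$id)
    keep <- !is.na(fl) & abs(fl) > tol
  }
  counts <- table(unlist(lapply(rxns$stoichiometry[keep], names)))
  out <- tibble::tibble(metabolite = model$metabolites$id,
                        count = as.integer(counts[model$metabolites$id]))
  out$count[is.na(out$count)] <- 0L
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$metabolite)
  class(out) <- c("stilflux_connectivity", class(out))
  out
}
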