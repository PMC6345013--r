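# Draft reconstruction from reference models via ortholog thresholds,
# exchange addition, and growth-restoring greedy gap filling.

#' Filter ortholog hits by identity and e-value thresholds
#'
#' Keeps BLAST-like hits with `identity >= min_identity` and
#' `evalue <= max_evalue` (both inclusive, matching the conventional
#' ">= 40% identity, <= 1e-30 e-value" draft-reconstruction rule). The
#' result is invariant to row order.
#'
#' @param hits A data frame with columns `query`, `subject`, `identity`
#'   (percent, 0-100), `evalue`, and optionally `reference` (reference
#'   model label).
#' @param min_identity Minimum percent identity (inclusive).
#' @param max_evalue Maximum e-value (inclusive).
#' @return A tibble of passing hits (query -> subject mapping, multi-hits
#'   preserved), sorted by query then subject.
#' @examples
#' hits <- generate_ortholog_hits(seed = 1, n_pass = 5, n_fail = 5)
#' filter_orthologs(hits)
#' @export
filter_orthologs <- function(hits, min_identity = 40, max_evalue = 1e-30) {
  stopifnot(is.finite(min_identity), is.finite(max_evalue))
  hits <- tibble::as_tibble(hits)
  req <- c("query", "subject", "identity", "evalue")
  miss <- setdiff(req, names(hits))
  if (length(miss) > 0) stop("hits table lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (any(hits$identity < 0 | hits$identity > 100)) {
    stop("percent identity must lie in [0, 100]")
  }
  if (any(hits$evalue < 0)) stop("e-values must be >= 0")
  if (!("reference" %in% names(hits))) hits$reference <- NA_character_
  hits |>
    dplyr::filter(.data$identity >= min_identity,
                  .data$evalue <= max_evalue) |>
    dplyr::distinct(.data$query, .data$subject, .data$reference) |>
    dplyr::arrange(.data$query, .data$subject)
}

#' Assemble a draft model from reference models through an ortholog mapping
#'
#' A reference reaction is imported iff its GPR is satisfiable when exactly
#' the mapped subject genes are present (absent subject genes evaluate
#' FALSE; empty GPRs import unconditionally). Imported GPRs are rewritten
#' in query gene ids (a subject hit by several queries becomes an OR).
#' Reactions appearing in several references are merged by canonical
#' duplicate detection, keeping the first occurrence in reference order;
#' groups whose members disagree on reversibility are flagged in the draft
#' report rather than auto-resolved.
#'
#' @param mapping A tibble from [filter_orthologs()] (columns `query`,
#'   `subject`, optionally `reference`).
#' @param references A named list of `metabolic_model` reference models
#'   whose GPRs use subject gene ids. When `mapping$reference` is filled,
#'   subjects only count toward the matching reference label.
#' @return A `metabolic_model` draft with a `draft_report` attribute (one
#'   row per reference reaction: imported flag, reason, merged-into id,
#'   reversibility conflict flag).
#' @export
draft_from_references <- function(mapping, references) {
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    names(references) <- paste0("ref", seq_along(references))
  }
  mapping <- tibble::as_tibble(mapping)
  if (!("reference" %in% names(mapping))) mapping$reference <- NA_character_

  mets <- list(); rxns <- list(); report <- list()
  kept_stoich <- list(); kept_ids <- character(0); kept_rev <- logical(0)
  genes_used <- character(0)

  for (lab in names(references)) {
    ref <- references[[lab]]
    map_lab <- mapping[is.na(mapping$reference) | mapping$reference == lab, ]
    present <- unique(map_lab$subject)
    # subject -> query ids (for GPR rewriting)
    s2q <- split(map_lab$query, map_lab$subject)
    for (j in seq_len(nrow(ref$reactions))) {
      r <- ref$reactions[j, ]
      expr <- parse_gpr(r$gpr)
      absent <- setdiff(gpr_genes(expr), present)
      ok <- evaluate_gpr(expr, knocked_out = absent)
      row <- tibble::tibble(reference = lab, reaction = r$id,
                            imported = ok, merged_into = NA_character_,
                            reversibility_conflict = FALSE,
                            reason = if (ok) "gpr satisfiable" else
                              "gpr unsatisfiable under mapping")
      if (ok) {
        key <- canonical_stoich_key(r$stoichiometry[[1]])$key
        hit <- match(key, names(kept_stoich))
        rev_j <- r$lb < 0 && r$ub > 0
        if (!is.na(hit)) {
          row$imported <- FALSE
          row$merged_into <- kept_ids[hit]
          row$reason <- "duplicate of imported reaction"
          row$reversibility_conflict <- xor(rev_j, kept_rev[hit])
        } else {
          new_gpr <- deparse_gpr(gpr_translate(expr, s2q))
          rid <- if (r$id %in% vapply(rxns, function(x) x$id, character(1)))
            paste0(r$id, "_", lab) else r$id
          r2 <- r
          r2$id <- rid
          r2$gpr <- new_gpr
          rxns <- c(rxns, list(r2))
          kept_stoich[[key]] <- r$stoichiometry[[1]]
          kept_ids <- c(kept_ids, rid)
          kept_rev <- c(kept_rev, rev_j)
          genes_used <- union(genes_used, gpr_genes(new_gpr))
          need <- names(r$stoichiometry[[1]])
          mets <- c(mets, list(ref$metabolites[ref$metabolites$id %in% need, ]))
        }
      }
      report <- c(report, list(row))
    }
  }
  rxn_tbl <- dplyr::bind_rows(rxns)
  met_tbl <- dplyr::distinct(dplyr::bind_rows(mets), .data$id, .keep_all = TRUE)
  draft <- metabolic_model(
    metabolites = met_tbl, reactions = rxn_tbl, genes = genes_used,
    notes = paste("draft reconstructed from references:",
                  paste(names(references), collapse = ", "))
  )
  attr(draft, "draft_report") <- dplyr::bind_rows(report)
  draft
}

#' Add exchange reactions for extracellular metabolites
#'
#' Creates one boundary reaction `EX_<base>_e` per metabolite, with
#' single-metabolite stoichiometry (coefficient -1) and closed-uptake
#' default bounds `(0, 1000)`; uptake is opened later by [set_medium()].
#'
#' @param model A `metabolic_model`.
#' @param metabolites Ids of metabolites in compartment `e`.
#' @return The extended model.
#' @export
add_exchange_reactions <- function(model, metabolites) {
  i <- match(metabolites, model$metabolites$id)
  if (anyNA(i)) stop("unknown metabolite(s): ",
                     paste(metabolites[is.na(i)], collapse = ", "))
  comp <- model$metabolites$compartment[i]
  if (any(comp != "e")) {
    stop("exchange reactions require extracellular metabolites; not in e: ",
         paste(metabolites[comp != "e"], collapse = ", "))
  }
  ids <- paste0("EX_", met_base(metabolites), "_e")
  if (any(ids %in% model$reactions$id)) {
    stop("exchange reaction already exists: ",
         paste(intersect(ids, model$reactions$id), collapse = ", "))
  }
  new <- reaction_tbl(
    id = ids,
    stoichiometry = lapply(metabolites, function(m) stats::setNames(-1, m)),
    name = paste(met_base(metabolites), "exchange"),
    lb = 0, ub = 1000, kind = "exchange", subsystem = "exchange"
  )
  add_reactions(model, new)
}

#' Greedy growth-restoring gap filling
#'
#' When the objective cannot reach `min_objective`, all candidate reactions
#' from the universal set are added, feasibility is verified, and the added
#' set is greedily pruned in the candidates' given order: a candidate is
#' removed whenever the objective still reaches `min_objective` without it.
#' The returned set is therefore minimal under this deterministic
#' procedure: removing any member breaks the target. When even the full
#' universal set cannot restore the objective, an "unfillable" result is
#' returned listing the blocked biomass precursors (objective substrates
#' that cannot be produced).
#'
#' @param model A `metabolic_model` (medium applied).
#' @param universal A `metabolic_model` or reaction tibble of candidate
#'   reactions (with any new metabolites carried in `universal$metabolites`).
#' @param objective Objective reaction id (default: model objective).
#' @param min_objective Required objective flux (mmol/gDW/h or 1/h).
#' @return A list with `status` (`"already_feasible"`, `"filled"`,
#'   `"unfillable"`), `added` (reaction ids from the universal set),
#'   `objective_value`, and `blocked` (precursor metabolite ids; only for
#'   unfillable problems).
#' @export
gap_fill <- function(model, universal, objective = NULL,
                     min_objective = 1e-3) {
  obj_ids <- if (is.null(objective)) names(model$objective) else objective
  if (length(obj_ids) == 0) stop("no objective reaction given")
  opt <- function(m) {
    sol <- solve_fba(m, obj_ids)
    if (sol$status == "optimal") sol$objective_value else -Inf
  }
  if (opt(model) >= min_objective) {
    return(list(status = "already_feasible", added = character(0),
                objective_value = opt(model), blocked = character(0)))
  }
  uni_rxns <- if (inherits(universal, "metabolic_model")) universal$reactions
    else tibble::as_tibble(universal)
  uni_mets <- if (inherits(universal, "metabolic_model")) universal$metabolites
    else NULL
  clash <- intersect(uni_rxns$id, model$reactions$id)
  if (length(clash) > 0) {
    uni_rxns$id[uni_rxns$id %in% clash] <-
      paste0(uni_rxns$id[uni_rxns$id %in% clash], "_gf")
  }
  full <- add_reactions(model, uni_rxns, metabolites = uni_mets)
  if (opt(full) < min_objective) {
    blocked <- blocked_precursors(full, obj_ids[1])
    return(list(status = "unfillable", added = character(0),
                objective_value = opt(full), blocked = blocked))
  }
  added <- uni_rxns$id
  for (rid in uni_rxns$id) {           # prune in candidate order
    trial <- setdiff(added, rid)
    m2 <- remove_reactions(full, setdiff(uni_rxns$id, trial))
    if (opt(m2) >= min_objective) added <- trial
  }
  final <- remove_reactions(full, setdiff(uni_rxns$id, added))
  list(status = "filled", added = added, objective_value = opt(final),
       blocked = character(0))
}

# Which substrates of the objective reaction cannot carry any production
# flux: for each consumed metabolite, maximize a temporary demand; blocked
# iff the optimum is (numerically) zero.
blocked_precursors <- function(model, objective_rxn) {
  s <- model$reactions$stoichiometry[[rxn_index(model, objective_rxn)]]
  subs <- names(s)[s < 0]
  blocked <- character(0)
  for (m in subs) {
    dm <- reaction_tbl(id = "DM_probe__", stoichiometry = stats::setNames(-1, m),
                       lb = 0, ub = 1000, kind = "demand")
    m2 <- suppressWarnings(add_reactions(model, dm))
    sol <- solve_fba(m2, "DM_probe__")
    if (sol$status != "optimal" || sol$objective_value < 1e-9) {
      blocked <- c(blocked, m)
    }
  }
  blocked
}
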