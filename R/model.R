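# The metabolic model container and structural operations.
#
# A model is an S3 list (class "metabolic_model") holding two tibbles plus
# scalar components:
#   metabolites: id, name, formula, charge, compartment
#   reactions:   id, name, stoichiometry (list of named numeric; negative =
#                consumed), lb, ub, gpr (canonical string), subsystem, kind
#   genes:       character vector
#   compartments: named character (id -> description)
#   objective:   named numeric (reaction id -> weight)
#   notes:       character (provenance)
#
# Metabolite ids follow the `<base>[<compartment>]` convention, e.g.
# "accoa[c]"; exchange reactions touch exactly one metabolite in "e".

COMPARTMENT_SET <- c(
  c = "cytoplasm", e = "extracellular", m = "mitochondrion", n = "nucleus",
  pm = "plasma membrane", x = "peroxisome", r = "endoplasmic reticulum",
  v = "vacuole"
)

REACTION_KINDS <- c("metabolic", "transport", "exchange", "sink", "demand",
                    "biomass", "spontaneous")

#' Build a metabolite table
#'
#' @param id,name,formula,charge,compartment Vectors recycled to a common
#'   length. `formula` uses Hill notation ("" = unknown), `charge` is an
#'   integer (`NA` = unknown) and `compartment` one of
#'   `names(stilflux_compartments())`.
#' @return A tibble with one row per metabolite.
#' @export
metabolite_tbl <- function(id, name = id, formula = "", charge = NA_integer_,
                           compartment = NULL) {
  if (is.null(compartment)) compartment <- metabolite_compartment(id)
  tibble::tibble(
    id = as.character(id), name = as.character(name),
    formula = as.character(formula), charge = as.integer(charge),
    compartment = as.character(compartment)
  )
}

#' The recognized compartment set
#'
#' Eight compartments: cytoplasm, extracellular space, mitochondrion,
#' nucleus, plasma membrane, peroxisome, endoplasmic reticulum and vacuole.
#'
#' @return A named character vector (tag -> description).
#' @export
stilflux_compartments <- function() COMPARTMENT_SET

#' Compartment tag of a metabolite id
#'
#' @param id Metabolite ids in `<base>[<compartment>]` form.
#' @return Character vector of compartment tags (`NA` when the id carries no
#'   bracketed suffix).
#' @export
metabolite_compartment <- function(id) {
  m <- regmatches(id, regexpr("\\[[^][]+\\]$", id))
  out <- rep(NA_character_, length(id))
  has <- grepl("\\[[^][]+\\]$", id)
  out[has] <- sub("^\\[", "", sub("\\]$", "", regmatches(id, regexpr("\\[[^][]+\\]$", id))))
  out
}

met_base <- function(id) sub("\\[[^][]+\\]$", "", id)

#' Build a reaction table
#'
#' @param id,name,lb,ub,gpr,subsystem,kind Vectors recycled to one row per
#'   reaction. Bounds are fluxes in mmol/gDW/h.
#' @param stoichiometry A list of named numeric vectors (metabolite id ->
#'   signed coefficient, negative = consumed), or a single named vector for
#'   a one-reaction table.
#' @return A tibble with one row per reaction.
#' @export
reaction_tbl <- function(id, stoichiometry, name = id, lb = 0, ub = 1000,
                         gpr = "", subsystem = "", kind = "metabolic") {
  if (!is.list(stoichiometry)) stoichiometry <- list(stoichiometry)
  tibble::tibble(
    id = as.character(id), name = as.character(name),
    stoichiometry = stoichiometry,
    lb = as.numeric(lb), ub = as.numeric(ub), gpr = as.character(gpr),
    subsystem = as.character(subsystem), kind = as.character(kind)
  )
}

#' Construct a metabolic model
#'
#' Assembles and validates a compartmentalized metabolic model. Validation
#' enforces: unique metabolite/reaction ids, declared compartments,
#' `lb <= ub`, non-empty stoichiometries over known metabolites, exchange
#' reactions touching exactly one extracellular metabolite, and objective
#' weights referencing existing reactions. Genes appearing in a GPR but
#' missing from `genes` are added with a warning.
#'
#' @param metabolites A tibble from [metabolite_tbl()].
#' @param reactions A tibble from [reaction_tbl()].
#' @param genes Character vector of gene ids (auto-extended from GPRs).
#' @param compartments Named character vector; defaults to the tags used.
#' @param objective Named numeric vector of reaction weights.
#' @param notes Character provenance notes.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = character(),
                            compartments = NULL, objective = numeric(),
                            notes = character()) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (is.null(compartments)) {
    used <- unique(metabolites$compartment)
    compartments <- COMPARTMENT_SET[intersect(names(COMPARTMENT_SET), used)]
  }
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         genes = unique(as.character(genes)), compartments = compartments,
         objective = objective, notes = notes),
    class = "metabolic_model"
  )
  validate_model(model)
}

#' Validate a metabolic model
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly amended (GPR genes added to the gene set
#'   with a warning when missing).
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  bad_comp <- setdiff(unique(mets$compartment), names(model$compartments))
  if (length(bad_comp) > 0L) {
    stop("undeclared compartment(s): ", paste(bad_comp, collapse = ", "))
  }
  if (any(rxns$lb > rxns$ub)) {
    stop("lower bound exceeds upper bound for: ",
         paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "))
  }
  if (!all(rxns$kind %in% REACTION_KINDS)) {
    stop("unknown reaction kind(s): ",
         paste(setdiff(rxns$kind, REACTION_KINDS), collapse = ", "))
  }
  empty <- lengths(rxns$stoichiometry) == 0L
  if (any(empty)) {
    stop("empty stoichiometry for: ", paste(rxns$id[empty], collapse = ", "))
  }
  all_refs <- unique(unlist(lapply(rxns$stoichiometry, names)))
  missing_mets <- setdiff(all_refs, mets$id)
  if (length(missing_mets) > 0L) {
    stop("reactions reference unknown metabolite(s): ",
         paste(missing_mets, collapse = ", "))
  }
  ex <- rxns$kind == "exchange"
  if (any(ex)) {
    one_met <- lengths(rxns$stoichiometry[ex]) == 1L
    if (!all(one_met)) {
      stop("exchange reactions must touch exactly one metabolite: ",
           paste(rxns$id[ex][!one_met], collapse = ", "))
    }
    ex_mets <- vapply(rxns$stoichiometry[ex], function(s) names(s)[1], character(1))
    comp <- mets$compartment[match(ex_mets, mets$id)]
    if (any(comp != "e")) {
      stop("exchange reactions must act on extracellular metabolites: ",
           paste(rxns$id[ex][comp != "e"], collapse = ", "))
    }
  }
  bad_obj <- setdiff(names(model$objective), rxns$id)
  if (length(bad_obj) > 0L) {
    stop("objective references unknown reaction(s): ",
         paste(bad_obj, collapse = ", "))
  }
  gpr_gene_set <- unique(unlist(lapply(rxns$gpr, gpr_genes)))
  extra <- setdiff(gpr_gene_set, model$genes)
  if (length(extra) > 0L) {
    warning("adding ", length(extra), " GPR gene(s) missing from the gene set: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ...")
    model$genes <- c(model$genes, extra)
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ", length(x$genes), " genes\n",
      sep = "")
  cat("  compartments: ", paste(names(x$compartments), collapse = ", "), "\n",
      sep = "")
  kinds <- table(x$reactions$kind)
  cat("  kinds: ", paste(names(kinds), kinds, sep = ":", collapse = ", "),
      "\n", sep = "")
  if (length(x$objective) > 0) {
    cat("  objective: ",
        paste(names(x$objective), x$objective, sep = " * ", collapse = " + "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row model summary
#'
#' @param x A `metabolic_model`.
#' @param ... Unused.
#' @return A one-row tibble of component counts.
#' @export
glance.metabolic_model <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x$reactions),
    n_metabolites = nrow(x$metabolites),
    n_genes = length(x$genes),
    n_exchange = sum(x$reactions$kind == "exchange"),
    n_transport = sum(x$reactions$kind == "transport"),
    n_compartments = length(x$compartments)
  )
}

#' Stoichiometric matrix
#'
#' Assembles the sparse stoichiometric matrix S (metabolites x reactions)
#' realizing the steady-state constraint S v = 0 of flux balance analysis.
#' `S[i, j]` is the signed coefficient of metabolite i in reaction j.
#'
#' @param model A `metabolic_model`.
#' @return A `Matrix::sparseMatrix` with metabolite ids as row names and
#'   reaction ids as column names.
#' @export
stoichiometric_matrix <- function(model) {
  rxns <- model$reactions
  mets <- model$metabolites$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nrow(rxns))) {
    s <- rxns$stoichiometry[[j]]
    ii <- c(ii, match(names(s), mets))
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, as.numeric(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), nrow(rxns)),
                       dimnames = list(mets, rxns$id))
}

#' Check mass and charge balance of every reaction
#'
#' Computes per-element and charge residuals for each reaction. Exchange,
#' sink, demand and biomass reactions are skipped by convention (they are
#' deliberately unbalanced boundary drains), as is any reaction touching a
#' metabolite with an unknown formula. A reaction is balanced iff all
#' element residuals and the charge residual (when all charges are known)
#' are zero within `tol`.
#'
#' @param model A `metabolic_model`.
#' @param tol Absolute residual tolerance.
#' @return A tibble with one row per reaction: `reaction`, `skipped`,
#'   `balanced`, `charge_residual`, and `residuals` (list column of named
#'   numeric element residuals).
#' @export
check_balance <- function(model, tol = 1e-6) {
  mets <- model$metabolites
  counts <- lapply(mets$formula, parse_formula)
  names(counts) <- mets$id
  charges <- stats::setNames(mets$charge, mets$id)
  skip_kinds <- c("exchange", "sink", "demand", "biomass")

  one <- function(j) {
    r <- model$reactions[j, ]
    s <- r$stoichiometry[[1]]
    if (r$kind %in% skip_kinds ||
        any(vapply(counts[names(s)], length, integer(1)) == 0L)) {
      return(tibble::tibble(reaction = r$id, skipped = TRUE, balanced = NA,
                            charge_residual = NA_real_,
                            residuals = list(numeric(0))))
    }
    elems <- unique(unlist(lapply(counts[names(s)], names)))
    resid <- stats::setNames(numeric(length(elems)), elems)
    for (m in names(s)) {
      cm <- counts[[m]]
      resid[names(cm)] <- resid[names(cm)] + s[[m]] * cm
    }
    ch <- charges[names(s)]
    charge_resid <- if (anyNA(ch)) NA_real_ else sum(s * ch)
    balanced <- all(abs(resid) <= tol) &&
      (is.na(charge_resid) || abs(charge_resid) <= tol)
    tibble::tibble(reaction = r$id, skipped = FALSE, balanced = balanced,
                   charge_residual = charge_resid, residuals = list(resid))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(model$reactions)), one))
}

# Canonical normalization key for duplicate detection: metabolites sorted by
# id, coefficients scaled so the first equals 1, rounded to 10 significant
# digits; the reversed (negated) direction maps to the same group key.
canonical_stoich_key <- function(s) {
  s <- s[order(names(s))]
  fwd <- signif(as.numeric(s) / s[[1]], 10)
  rev <- signif(as.numeric(-s) / (-s[[1]]), 10) # identical scaling; direction
  key_of <- function(coefs, dir) {
    paste0(paste(names(s), coefs, sep = ":", collapse = ";"), "|", dir)
  }
  # scaling by the first coefficient makes the forward and reversed variants
  # identical up to overall sign of the original vector; record the sign of
  # the first coefficient as the direction marker and canonicalize on it.
  dir <- if (s[[1]] > 0) "+" else "-"
  list(key = paste(names(s), fwd, sep = ":", collapse = ";"), dir = dir)
}

#' Find duplicate reactions
#'
#' Groups reactions whose stoichiometries are identical after canonical
#' normalization: metabolite ids sorted, coefficients scaled so the first
#' equals 1 (rounded to 10 significant digits). A reaction written in the
#' reversed direction matches the same group and the group is flagged as a
#' direction conflict, as are groups mixing reversible and irreversible
#' members. Grouping is an equivalence relation.
#'
#' @param model A `metabolic_model`.
#' @return A tibble with one row per duplicate group: `group`, `reactions`
#'   (list column of ids), `n`, `direction_conflict`. Zero rows when no
#'   duplicates exist.
#' @export
find_duplicate_reactions <- function(model) {
  rxns <- model$reactions
  keys <- lapply(rxns$stoichiometry, canonical_stoich_key)
  key <- vapply(keys, `[[`, character(1), "key")
  dir <- vapply(keys, `[[`, character(1), "dir")
  rev <- rxns$lb < 0 & rxns$ub > 0
  tibble::tibble(id = rxns$id, key = key, dir = dir, rev = rev) |>
    dplyr::group_by(.data$key) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(
      reactions = list(.data$id),
      n = dplyr::n(),
      direction_conflict = dplyr::n_distinct(.data$dir) > 1 ||
        dplyr::n_distinct(.data$rev) > 1,
      .groups = "drop"
    ) |>
    dplyr::mutate(group = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"key")
}

# ---- small model-editing helpers used across modules ----

rxn_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) {
    stop("unknown reaction id(s): ", paste(id[is.na(i)], collapse = ", "))
  }
  i
}

#' Set flux bounds on reactions
#'
#' @param model A `metabolic_model`.
#' @param id Reaction ids.
#' @param lb,ub New bounds (recycled); `NA` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lb = NA, ub = NA) {
  i <- rxn_index(model, id)
  lb <- rep_len(as.numeric(lb), length(i))
  ub <- rep_len(as.numeric(ub), length(i))
  keep <- is.na(lb); lb[keep] <- model$reactions$lb[i][keep]
  keep <- is.na(ub); ub[keep] <- model$reactions$ub[i][keep]
  if (any(lb > ub)) stop("lower bound exceeds upper bound")
  model$reactions$lb[i] <- lb
  model$reactions$ub[i] <- ub
  model
}

#' Reactions disabled by a gene knockout
#'
#' Evaluates every GPR with the given genes knocked out and returns the ids
#' of reactions whose rule becomes unsatisfiable. Reactions with empty GPRs
#' are never disabled.
#'
#' @param model A `metabolic_model`.
#' @param genes Character vector of knocked-out gene ids.
#' @return Character vector of disabled reaction ids.
#' @export
disabled_reactions <- function(model, genes) {
  has <- vapply(model$reactions$gpr, function(g) {
    length(intersect(gpr_genes(g), genes)) > 0
  }, logical(1))
  cand <- which(has)
  off <- cand[!vapply(model$reactions$gpr[cand], evaluate_gpr, logical(1),
                      knocked_out = genes)]
  model$reactions$id[off]
}

#' Apply a gene knockout to a model
#'
#' Bounds every reaction whose GPR becomes unsatisfiable to zero flux.
#'
#' @inheritParams disabled_reactions
#' @return The constrained model.
#' @export
knockout_genes <- function(model, genes) {
  off <- disabled_reactions(model, genes)
  if (length(off) > 0) model <- set_bounds(model, off, 0, 0)
  model
}

#' Remove reactions (and orphaned metabolites) from a model
#'
#' @param model A `metabolic_model`.
#' @param id Reaction ids to drop.
#' @param drop_orphans Drop metabolites no longer referenced by any reaction.
#' @return The reduced model.
#' @export
remove_reactions <- function(model, id, drop_orphans = FALSE) {
  i <- rxn_index(model, id)
  model$reactions <- model$reactions[-i, ]
  model$objective <- model$objective[setdiff(names(model$objective), id)]
  if (drop_orphans) {
    used <- unique(unlist(lapply(model$reactions$stoichiometry, names)))
    model$metabolites <- model$metabolites[model$metabolites$id %in% used, ]
  }
  model
}

#' Add reactions to a model
#'
#' @param model A `metabolic_model`.
#' @param reactions A tibble from [reaction_tbl()]; referenced metabolites
#'   must already exist or be supplied via `metabolites`.
#' @param metabolites Optional tibble of new metabolites.
#' @return The extended (re-validated) model.
#' @export
add_reactions <- function(model, reactions, metabolites = NULL) {
  if (!is.null(metabolites)) {
    new <- !(metabolites$id %in% model$metabolites$id)
    model$metabolites <- dplyr::bind_rows(model$metabolites, metabolites[new, ])
  }
  model$reactions <- dplyr::bind_rows(model$reactions, reactions)
  validate_model(model)
}

#' Parse a reaction equation string
#'
#' Accepts equations such as `"ac[c] + coa[c] + atp[c] -> h[c] + accoa[c] +
#' ppi[c] + amp[c]"` or `"g6p[c] <=> f6p[c]"`, with optional numeric
#' coefficients before metabolite ids. The arrow (`->` or `<=>`) is
#' informational only; direction is carried by the bounds.
#'
#' @param equation A single equation string.
#' @return A named numeric stoichiometry vector (negative = consumed).
#' @export
parse_reaction_equation <- function(equation) {
  arrow <- if (grepl("<=>", equation, fixed = TRUE)) "<=>" else
    if (grepl("->", equation, fixed = TRUE)) "->" else
      stop("equation must contain '->' or '<=>': ", equation)
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      m <- regexec("^([0-9.]+[eE]?[+-]?[0-9]*)?\\s*(\\S+)$", tm)[[1]]
      parts <- regmatches(tm, regexec("^([0-9.]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S+)$", tm))[[1]]
      coef <- if (nzchar(trimws(parts[2]))) as.numeric(trimws(parts[2])) else 1
      met <- parts[3]
      out[met] <- (out[met] %||% 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  s <- lhs
  for (m in names(rhs)) s[m] <- (s[m] %||% 0) + rhs[m]
  s <- s[s != 0]
  if (length(s) == 0L) stop("equation has empty stoichiometry: ", equation)
  s
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Format a stoichiometry as an equation string
#'
#' @param stoich Named numeric stoichiometry vector.
#' @param reversible Use `<=>` instead of `->`.
#' @return A single equation string.
#' @export
format_reaction_equation <- function(stoich, reversible = FALSE) {
  fmt <- function(v) {
    coefs <- abs(v)
    paste(ifelse(abs(coefs - 1) < 1e-12, names(v),
                 paste(format(coefs, digits = 15, trim = TRUE), names(v))),
          collapse = " + ")
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmt(lhs), if (reversible) "<=>" else "->", fmt(rhs))
}
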