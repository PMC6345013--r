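# Biomass pseudo-reaction assembly from macromolecular composition, genome
# GC content and ATP maintenance terms.
#
# The biomass reaction drains monomers in dry-weight proportion: the
# coefficient of monomer m belonging to macromolecule M is
#   (mass fraction of M, g/gDW) * (mass fraction of m within M) / (molar
#   mass of m, g/mmol)
# in mmol/gDW, so that the consumed monomer mass totals exactly 1 g per
# gram dry weight. Growth-associated maintenance (GAM) adds
# ATP + H2O -> ADP + Pi + H with the GAM coefficient; non-growth
# maintenance (NGAM) is a lower bound on a standing ATP hydrolysis
# reaction.

#' Construct a biomass composition
#'
#' @param macro Named numeric vector of macromolecular mass fractions
#'   (g/gDW) summing to 1 (tolerance 1e-9), e.g. cell_wall, protein,
#'   mannitol, ash, lipid, nucleic_acid.
#' @param monomers Named list (one entry per macromolecule) of named
#'   numeric vectors: monomer metabolite id -> mass fraction within that
#'   macromolecule (each summing to 1).
#' @param gam Growth-associated maintenance (mmol ATP/gDW).
#' @param ngam Non-growth-associated maintenance (mmol ATP/gDW/h).
#' @return An object of class `biomass_composition`.
#' @export
biomass_composition <- function(macro, monomers, gam = 60, ngam = 1.0) {
  if (abs(sum(macro) - 1) > 1e-9) {
    stop("macromolecular fractions must sum to 1 (got ", sum(macro), ")")
  }
  if (gam < 0 || ngam < 0) stop("GAM and NGAM must be >= 0")
  miss <- setdiff(names(macro), names(monomers))
  if (length(miss) > 0) {
    stop("no monomer table for macromolecule(s): ", paste(miss, collapse = ", "))
  }
  for (m in names(monomers)) {
    if (abs(sum(monomers[[m]]) - 1) > 1e-9) {
      stop("monomer mass fractions for '", m, "' must sum to 1")
    }
  }
  structure(list(macro = macro, monomers = monomers, gam = gam, ngam = ngam),
            class = "biomass_composition")
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("<biomass_composition>\n")
  for (m in names(x$macro)) {
    cat(sprintf("  %-12s %5.1f%%  (%d monomer%s)\n", m, 100 * x$macro[[m]],
                length(x$monomers[[m]]),
                if (length(x$monomers[[m]]) == 1) "" else "s"))
  }
  cat("  GAM", x$gam, "mmol ATP/gDW; NGAM", x$ngam, "mmol ATP/gDW/h\n")
  invisible(x)
}

#' Deoxynucleotide mole fractions from genome GC content
#'
#' Under the double-stranded base-pairing constraint, dGMP and dCMP each
#' take half the GC content and dAMP and dTMP half the remainder.
#'
#' @param gc GC content as a fraction in (0, 1), e.g. 0.5096.
#' @return A named numeric vector of mole fractions (dAMP, dTMP, dGMP,
#'   dCMP) summing to 1.
#' @examples
#' nucleotide_fractions_from_gc(0.5096)
#' @export
nucleotide_fractions_from_gc <- function(gc) {
  if (!is.numeric(gc) || length(gc) != 1 || is.na(gc) || gc <= 0 || gc >= 1) {
    stop("`gc` must be a fraction strictly between 0 and 1")
  }
  c(dAMP = (1 - gc) / 2, dTMP = (1 - gc) / 2, dGMP = gc / 2, dCMP = gc / 2)
}

#' Convert mole fractions to mass fractions
#'
#' @param moles Named numeric mole fractions.
#' @param molar_masses Named numeric molar masses (g/mmol) covering
#'   `names(moles)`.
#' @return Named numeric mass fractions summing to 1.
#' @export
mole_to_mass_fractions <- function(moles, molar_masses) {
  mm <- molar_masses[names(moles)]
  if (anyNA(mm)) stop("missing molar mass for: ",
                      paste(names(moles)[is.na(mm)], collapse = ", "))
  w <- moles * mm
  w / sum(w)
}

#' Build the biomass pseudo-reaction
#'
#' @param composition A [biomass_composition()].
#' @param molar_masses Named numeric vector, g/mmol, covering every monomer
#'   (e.g. from [molar_mass()] on the model formulas, with explicit values
#'   for non-elemental pseudo-species such as ash).
#' @param id Reaction id.
#' @param atp,h2o,adp,pi,h Metabolite ids of the GAM hydrolysis species.
#' @return A one-row reaction tibble (kind `"biomass"`) whose consumed
#'   monomer mass, GAM species excluded, is 1 g/gDW within 1e-6.
#' @export
build_biomass_reaction <- function(composition, molar_masses, id = "BIOMASS",
                                   atp = "atp[c]", h2o = "h2o[c]",
                                   adp = "adp[c]", pi = "pi[c]", h = "h[c]") {
  stopifnot(inherits(composition, "biomass_composition"))
  stoich <- numeric(0)
  for (macro in names(composition$macro)) {
    fr <- composition$macro[[macro]]
    if (fr == 0) next
    tab <- composition$monomers[[macro]]
    for (mon in names(tab)) {
      mm <- unname(molar_masses[mon])
      if (length(mm) == 0 || is.na(mm)) {
        stop("missing molar mass for monomer '", mon, "'")
      }
      coef <- fr * tab[[mon]] / mm
      stoich[mon] <- (stoich[mon] %||% 0) - coef
    }
  }
  mass <- -sum(stoich * unlist(molar_masses[names(stoich)]))
  if (abs(mass - 1) > 1e-6) {
    stop("biomass monomer mass does not close to 1 g/gDW (got ", mass, ")")
  }
  gam <- composition$gam
  if (gam > 0) {
    for (sp in c(atp, h2o)) stoich[sp] <- (stoich[sp] %||% 0) - gam
    for (sp in c(adp, pi, h)) stoich[sp] <- (stoich[sp] %||% 0) + gam
  }
  reaction_tbl(id = id, stoichiometry = list(stoich), name = "biomass",
               lb = 0, ub = 1000, kind = "biomass", subsystem = "biomass")
}

#' Mass drained by a biomass reaction
#'
#' Helper for the 1 g/gDW closure invariant: sums coefficient times molar
#' mass over consumed monomers, excluding the GAM/maintenance species.
#'
#' @param reaction One-row biomass reaction tibble.
#' @param molar_masses Named molar masses (g/mmol).
#' @param exclude Metabolite ids excluded from the sum.
#' @return Total consumed mass in g/gDW.
#' @export
biomass_drained_mass <- function(reaction, molar_masses,
                                 exclude = c("atp[c]", "h2o[c]", "adp[c]",
                                             "pi[c]", "h[c]")) {
  s <- reaction$stoichiometry[[1]]
  s <- s[setdiff(names(s), exclude)]
  s <- s[s < 0]
  -sum(s * unlist(molar_masses[names(s)]))
}

#' Add (or pin) the non-growth ATP maintenance requirement
#'
#' Ensures an ATP hydrolysis maintenance reaction exists (created as
#' `ATPM`: `atp + h2o -> adp + pi + h` when absent) and sets its lower
#' bound to `ngam`, so every feasible flux state spends at least that much
#' ATP regardless of growth.
#'
#' @param model A `metabolic_model`.
#' @param ngam Non-growth-associated maintenance (mmol ATP/gDW/h, >= 0).
#' @param reaction Maintenance reaction id.
#' @return The modified model.
#' @export
add_ngam <- function(model, ngam, reaction = "ATPM") {
  if (ngam < 0) stop("NGAM must be >= 0")
  if (!(reaction %in% model$reactions$id)) {
    new <- reaction_tbl(
      id = reaction,
      stoichiometry = list(c("atp[c]" = -1, "h2o[c]" = -1, "adp[c]" = 1,
                             "pi[c]" = 1, "h[c]" = 1)),
      name = "ATP maintenance", lb = 0, ub = 1000, kind = "metabolic",
      subsystem = "maintenance"
    )
    model <- add_reactions(model, new)
  }
  set_bounds(model, reaction, lb = ngam)
}
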