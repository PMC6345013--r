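# Model input/output: SBML Level 3 + fbc, a JSON dialect mirroring the
# container fields, and a two/three-file TSV dialect.
#
# SBML ids must match the SId grammar, so metabolite/reaction/gene ids are
# encoded on write (prefixes M_/R_/G_, compartment suffix, non-SId
# characters escaped as __<codepoint>__) and decoded on read; gene products
# additionally carry the original id in fbc:label.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
STILFLUX_NS <- "https://stilflux.invalid/annotation"

sid_encode <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    ok <- grepl("[A-Za-z0-9_]", chars)
    chars[!ok] <- sprintf("__%d__", vapply(chars[!ok], utf8ToInt, integer(1)))
    s <- paste(chars, collapse = "")
    if (grepl("^[0-9]", s)) s <- paste0("_", s)
    s
  }, character(1), USE.NAMES = FALSE)
}

sid_decode <- function(x) {
  vapply(x, function(s) {
    if (grepl("^_[0-9]", s)) s <- sub("^_", "", s)  # digit-guard underscore
    while (grepl("__([0-9]+)__", s)) {
      code <- regmatches(s, regexpr("__([0-9]+)__", s))
      num <- as.integer(gsub("_", "", code))
      s <- sub("__([0-9]+)__", intToUtf8(num), s)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

met_sid <- function(id, comp) paste0("M_", sid_encode(met_base(id)), "_", comp)

num_chr <- function(x) sprintf("%.17g", x)

#' Write a metabolic model to disk
#'
#' @param model A `metabolic_model`.
#' @param path Output file (`sbml`, `json`) or directory (`tsv`).
#' @param format One of `"sbml"`, `"json"`, `"tsv"` (guessed from the path
#'   extension when omitted: `.xml`/`.sbml`, `.json`, otherwise tsv).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  format <- format %||na% guess_format(path)
  switch(format,
    json = write_model_json(model, path),
    tsv = write_model_tsv(model, path),
    sbml = write_model_sbml(model, path),
    stop("unknown model format: ", format)
  )
  invisible(path)
}

#' Read a metabolic model from disk
#'
#' @param path Model file (or directory for the TSV dialect).
#' @param format As in [write_model()].
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, format = NULL) {
  format <- format %||na% guess_format(path)
  switch(format,
    json = read_model_json(path),
    tsv = read_model_tsv(path),
    sbml = read_model_sbml(path),
    stop("unknown model format: ", format)
  )
}

guess_format <- function(path) {
  if (dir.exists(path) || !grepl("\\.[A-Za-z]+$", path)) return("tsv")
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext, xml = "sbml", sbml = "sbml", json = "json", tsv = "tsv",
         stop("cannot guess model format from path: ", path))
}

# ---- JSON dialect ----

write_model_json <- function(model, path) {
  obj <- list(
    metabolites = model$metabolites,
    reactions = lapply(seq_len(nrow(model$reactions)), function(j) {
      r <- model$reactions[j, ]
      list(id = r$id, name = r$name,
           stoichiometry = as.list(r$stoichiometry[[1]]),
           lb = r$lb, ub = r$ub, gpr = r$gpr, subsystem = r$subsystem,
           kind = r$kind)
    }),
    genes = model$genes,
    compartments = as.list(model$compartments),
    objective = as.list(model$objective),
    notes = model$notes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  mets <- dplyr::bind_rows(lapply(obj$metabolites, function(m) {
    metabolite_tbl(id = m$id, name = m$name, formula = m$formula %||na% "",
                   charge = m$charge %||na% NA_integer_,
                   compartment = m$compartment)
  }))
  rxns <- dplyr::bind_rows(lapply(obj$reactions, function(r) {
    reaction_tbl(id = r$id, stoichiometry = list(unlist(r$stoichiometry)),
                 name = r$name, lb = r$lb, ub = r$ub, gpr = r$gpr %||na% "",
                 subsystem = r$subsystem %||na% "", kind = r$kind)
  }))
  metabolic_model(
    metabolites = mets, reactions = rxns,
    genes = unlist(obj$genes) %||na% character(),
    compartments = unlist(obj$compartments),
    objective = unlist(obj$objective) %||na% numeric(),
    notes = unlist(obj$notes) %||na% character()
  )
}

# ---- TSV dialect ----
# reactions.tsv: id, name, equation, lb, ub, gpr, subsystem, kind,
#                objective_coefficient
# metabolites.tsv: id, name, formula, charge, compartment
# compartments.tsv: compartment, description

write_model_tsv <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  mets <- model$metabolites
  readr::write_tsv(mets, file.path(path, "metabolites.tsv"))
  obj <- model$objective
  rx <- model$reactions
  rxns <- tibble::tibble(
    id = rx$id, name = rx$name,
    equation = vapply(seq_len(nrow(rx)), function(j) {
      format_reaction_equation(rx$stoichiometry[[j]],
                               reversible = rx$lb[j] < 0 && rx$ub[j] > 0)
    }, character(1)),
    lb = num_chr(rx$lb), ub = num_chr(rx$ub), gpr = rx$gpr,
    subsystem = rx$subsystem, kind = rx$kind,
    objective_coefficient = num_chr(
      ifelse(rx$id %in% names(obj), obj[rx$id], 0))
  )
  readr::write_tsv(rxns, file.path(path, "reactions.tsv"))
  readr::write_tsv(
    tibble::tibble(compartment = names(model$compartments),
                   description = unname(model$compartments)),
    file.path(path, "compartments.tsv"))
}

read_model_tsv <- function(path) {
  rfile <- file.path(path, "reactions.tsv")
  mfile <- file.path(path, "metabolites.tsv")
  if (!file.exists(rfile) || !file.exists(mfile)) {
    stop("TSV model directory must contain reactions.tsv and metabolites.tsv")
  }
  mets <- readr::read_tsv(mfile, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  need <- c("id", "name", "formula", "charge", "compartment")
  if (length(setdiff(need, names(mets))) > 0) {
    stop("metabolites.tsv lacks column(s): ",
         paste(setdiff(need, names(mets)), collapse = ", "))
  }
  mets <- metabolite_tbl(id = mets$id, name = mets$name,
                         formula = ifelse(is.na(mets$formula), "", mets$formula),
                         charge = suppressWarnings(as.integer(mets$charge)),
                         compartment = mets$compartment)
  rx <- readr::read_tsv(rfile, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("id", "equation", "lb", "ub", "gpr", "subsystem", "kind")
  if (length(setdiff(need, names(rx))) > 0) {
    stop("reactions.tsv lacks column(s): ",
         paste(setdiff(need, names(rx)), collapse = ", "))
  }
  rxns <- reaction_tbl(
    id = rx$id,
    stoichiometry = lapply(rx$equation, parse_reaction_equation),
    name = if ("name" %in% names(rx)) rx$name else rx$id,
    lb = as.numeric(rx$lb), ub = as.numeric(rx$ub),
    gpr = ifelse(is.na(rx$gpr), "", rx$gpr),
    subsystem = ifelse(is.na(rx$subsystem), "", rx$subsystem),
    kind = rx$kind
  )
  objective <- numeric()
  if ("objective_coefficient" %in% names(rx)) {
    oc <- as.numeric(rx$objective_coefficient)
    objective <- stats::setNames(oc[oc != 0], rx$id[oc != 0])
  }
  cfile <- file.path(path, "compartments.tsv")
  compartments <- NULL
  if (file.exists(cfile)) {
    cc <- readr::read_tsv(cfile, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
    compartments <- stats::setNames(cc$description, cc$compartment)
  }
  # the TSV dialect carries no gene list; reconstitute it from the GPRs
  genes <- unique(unlist(lapply(rxns$gpr, gpr_genes)))
  metabolic_model(metabolites = mets, reactions = rxns, genes = genes,
                  compartments = compartments, objective = objective)
}

# ---- SBML Level 3 + fbc version 2 ----

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mnode <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "false")
  loc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (i in seq_along(model$compartments)) {
    xml2::xml_add_child(loc, "compartment",
                        id = names(model$compartments)[i],
                        name = unname(model$compartments[i]),
                        constant = "true")
  }
  los <- xml2::xml_add_child(mnode, "listOfSpecies")
  mets <- model$metabolites
  sids <- met_sid(mets$id, mets$compartment)
  for (i in seq_len(nrow(mets))) {
    attrs <- list(id = sids[i], name = mets$name[i],
                  compartment = mets$compartment[i],
                  hasOnlySubstanceUnits = "false",
                  boundaryCondition = "false", constant = "false")
    if (nzchar(mets$formula[i])) {
      attrs[["fbc:chemicalFormula"]] <- mets$formula[i]
    }
    if (!is.na(mets$charge[i])) {
      attrs[["fbc:charge"]] <- as.character(mets$charge[i])
    }
    do.call(xml2::xml_add_child, c(list(los, "species"), attrs))
  }
  lop <- xml2::xml_add_child(mnode, "listOfParameters")
  rx <- model$reactions
  rids <- paste0("R_", sid_encode(rx$id))
  for (j in seq_len(nrow(rx))) {
    xml2::xml_add_child(lop, "parameter", id = paste0(rids[j], "_lb"),
                        value = num_chr(rx$lb[j]), constant = "true")
    xml2::xml_add_child(lop, "parameter", id = paste0(rids[j], "_ub"),
                        value = num_chr(rx$ub[j]), constant = "true")
  }
  lor <- xml2::xml_add_child(mnode, "listOfReactions")
  sid_of_met <- stats::setNames(sids, mets$id)
  for (j in seq_len(nrow(rx))) {
    rnode <- xml2::xml_add_child(
      lor, "reaction", id = rids[j], name = rx$name[j],
      reversible = if (rx$lb[j] < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = paste0(rids[j], "_lb"),
      "fbc:upperFluxBound" = paste0(rids[j], "_ub")
    )
    ann <- xml2::xml_add_child(rnode, "annotation")
    xml2::xml_add_child(ann, "stilflux", xmlns = STILFLUX_NS,
                        kind = rx$kind[j], subsystem = rx$subsystem[j])
    s <- rx$stoichiometry[[j]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac) > 0) {
      lre <- xml2::xml_add_child(rnode, "listOfReactants")
      for (m in names(reac)) {
        xml2::xml_add_child(lre, "speciesReference", species = sid_of_met[[m]],
                            stoichiometry = num_chr(-reac[[m]]),
                            constant = "true")
      }
    }
    if (length(prod) > 0) {
      lpr <- xml2::xml_add_child(rnode, "listOfProducts")
      for (m in names(prod)) {
        xml2::xml_add_child(lpr, "speciesReference", species = sid_of_met[[m]],
                            stoichiometry = num_chr(prod[[m]]),
                            constant = "true")
      }
    }
    if (nzchar(rx$gpr[j])) {
      gpa <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      add_gpr_xml(gpa, parse_gpr(rx$gpr[j]))
    }
  }
  if (length(model$objective) > 0) {
    loo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    onode <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                                 "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(onode, "fbc:listOfFluxObjectives")
    for (rid in names(model$objective)) {
      xml2::xml_add_child(lfo, "fbc:fluxObjective",
                          "fbc:reaction" = paste0("R_", sid_encode(rid)),
                          "fbc:coefficient" = num_chr(model$objective[[rid]]))
    }
  }
  if (length(model$genes) > 0) {
    log_ <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      xml2::xml_add_child(log_, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sid_encode(g)),
                          "fbc:label" = g)
    }
  }
  xml2::write_xml(doc, path)
}

add_gpr_xml <- function(parent, expr) {
  switch(expr$kind,
    gene = xml2::xml_add_child(parent, "fbc:geneProductRef",
                               "fbc:geneProduct" = paste0("G_", sid_encode(expr$gene))),
    op = {
      node <- xml2::xml_add_child(parent, paste0("fbc:", expr$op))
      for (a in expr$args) add_gpr_xml(node, a)
    },
    empty = invisible(NULL)
  )
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  q <- function(node, what) {
    xml2::xml_find_all(node, paste0(".//*[local-name()='", what, "']"))
  }
  attrf <- function(nodes, a) xml2::xml_attr(nodes, a)

  comp_nodes <- q(doc, "compartment")
  compartments <- stats::setNames(attrf(comp_nodes, "name"),
                                  attrf(comp_nodes, "id"))
  # gene products: map encoded id -> original label
  gp_nodes <- q(doc, "geneProduct")
  gene_map <- stats::setNames(attrf(gp_nodes, "label"), attrf(gp_nodes, "id"))

  sp_nodes <- q(doc, "species")
  sp_ids <- attrf(sp_nodes, "id")
  sp_comp <- attrf(sp_nodes, "compartment")
  orig_met <- vapply(seq_along(sp_ids), function(i) {
    base <- sub(paste0("_", sp_comp[i], "$"), "", sub("^M_", "", sp_ids[i]))
    paste0(sid_decode(base), "[", sp_comp[i], "]")
  }, character(1))
  mets <- metabolite_tbl(
    id = orig_met, name = attrf(sp_nodes, "name"),
    formula = dplyr::coalesce(attrf(sp_nodes, "chemicalFormula"), ""),
    charge = suppressWarnings(as.integer(attrf(sp_nodes, "charge"))),
    compartment = sp_comp
  )
  met_of_sid <- stats::setNames(orig_met, sp_ids)

  par_nodes <- q(doc, "parameter")
  par_val <- stats::setNames(as.numeric(attrf(par_nodes, "value")),
                             attrf(par_nodes, "id"))

  rx_nodes <- q(doc, "reaction")
  rxns <- dplyr::bind_rows(lapply(rx_nodes, function(rn) {
    rid_enc <- xml2::xml_attr(rn, "id")
    rid <- sid_decode(sub("^R_", "", rid_enc))
    reac <- xml2::xml_find_all(rn, "./*[local-name()='listOfReactants']/*")
    prod <- xml2::xml_find_all(rn, "./*[local-name()='listOfProducts']/*")
    s <- numeric(0)
    for (nd in reac) {
      m <- met_of_sid[[xml2::xml_attr(nd, "species")]]
      s[m] <- (s[m] %||% 0) - as.numeric(xml2::xml_attr(nd, "stoichiometry"))
    }
    for (nd in prod) {
      m <- met_of_sid[[xml2::xml_attr(nd, "species")]]
      s[m] <- (s[m] %||% 0) + as.numeric(xml2::xml_attr(nd, "stoichiometry"))
    }
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids) == 0) "" else deparse_gpr(sbml_gpr_tree(kids[[1]], gene_map))
    }
    ann <- xml2::xml_find_first(rn, "./*[local-name()='annotation']/*[local-name()='stilflux']")
    kind <- if (inherits(ann, "xml_missing")) "metabolic" else
      xml2::xml_attr(ann, "kind")
    subsystem <- if (inherits(ann, "xml_missing")) "" else
      xml2::xml_attr(ann, "subsystem")
    reaction_tbl(
      id = rid, stoichiometry = list(s), name = xml2::xml_attr(rn, "name"),
      lb = par_val[[paste0(rid_enc, "_lb")]],
      ub = par_val[[paste0(rid_enc, "_ub")]],
      gpr = gpr, subsystem = subsystem %||na% "", kind = kind
    )
  }))

  fo_nodes <- q(doc, "fluxObjective")
  objective <- stats::setNames(
    as.numeric(attrf(fo_nodes, "coefficient")),
    sid_decode(sub("^R_", "", attrf(fo_nodes, "reaction")))
  )
  metabolic_model(metabolites = mets, reactions = rxns,
                  genes = unname(gene_map), compartments = compartments,
                  objective = objective)
}

sbml_gpr_tree <- function(node, gene_map) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    enc <- xml2::xml_attr(node, "geneProduct")
    g <- unname(gene_map[enc])
    if (length(g) == 0 || is.na(g)) g <- sid_decode(sub("^G_", "", enc))
    structure(list(kind = "gene", gene = g), class = "gpr")
  } else {
    op <- if (nm == "and") "and" else "or"
    args <- lapply(xml2::xml_children(node), sbml_gpr_tree, gene_map = gene_map)
    structure(list(kind = "op", op = op, args = args), class = "gpr")
  }
}
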