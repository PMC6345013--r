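test_that("formula parsing follows Hill notation with integer counts", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_equal(parse_formula("HO4P"), c(H = 1L, O = 4L, P = 1L))
  expect_equal(parse_formula("C23H38N7O17P3S"),
               c(C = 23L, H = 38L, N = 7L, O = 17L, P = 3L, S = 1L))
  expect_length(parse_formula(""), 0)
  expect_error(parse_formula("C6H12O6+"), "unparseable")
  # molar mass in g/mmol
  expect_equal(molar_mass("C6H14O6"), 0.182171, tolerance = 1e-4)
  expect_true(is.na(molar_mass("")))
})

test_that("model validation enforces the container invariants", {
  mets <- metabolite_tbl(c("A[c]", "B[c]"), formula = "C", charge = 0,
                         compartment = "c")
  rxn <- reaction_tbl("R1", list(c("A[c]" = -1, "B[c]" = 1)))
  expect_s3_class(metabolic_model(mets, rxn), "metabolic_model")
  # unknown metabolite in a reaction
  bad <- reaction_tbl("R2", list(c("A[c]" = -1, "Z[c]" = 1)))
  expect_error(metabolic_model(mets, dplyr::bind_rows(rxn, bad)),
               "unknown metabolite")
  # lb > ub
  expect_error(metabolic_model(mets, reaction_tbl("R1",
    list(c("A[c]" = -1, "B[c]" = 1)), lb = 5, ub = 1)), "lower bound")
  # exchange must be a single extracellular metabolite
  expect_error(metabolic_model(mets,
    reaction_tbl("EX_A", list(c("A[c]" = -1)), kind = "exchange")),
    "extracellular")
  # objective must reference existing reactions
  expect_error(metabolic_model(mets, rxn, objective = c(NOPE = 1)),
               "unknown reaction")
  # GPR genes absent from the gene set are added with a warning
  expect_warning(metabolic_model(mets,
    reaction_tbl("R1", list(c("A[c]" = -1, "B[c]" = 1)), gpr = "gX")),
    "missing from the gene set")
})

test_that("stoichiometric matrix places signed coefficients correctly", {
  m <- toy_chain_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(4, 5))
  expect_equal(S["A[c]", "AB"], -1)
  expect_equal(S["B[c]", "AB"], 1)
  expect_equal(sum(S[, "AB"] != 0), 2)

  # the acetate-activation column of the mini-network
  mini <- mini_cached()
  Sm <- stoichiometric_matrix(mini)
  g <- Sm[, "g0770"]
  expect_equal(g[c("ac[c]", "coa[c]", "atp[c]")],
               c("ac[c]" = -1, "coa[c]" = -1, "atp[c]" = -1))
  expect_equal(g[c("h[c]", "accoa[c]", "ppi[c]", "amp[c]")],
               c("h[c]" = 1, "accoa[c]" = 1, "ppi[c]" = 1, "amp[c]" = 1))
  expect_equal(sum(g != 0), 7)
})

test_that("mass-weighted column sums vanish for balanced internal reactions", {
  mini <- mini_cached()
  S <- as.matrix(stoichiometric_matrix(mini))
  mm <- vapply(mini$metabolites$formula, function(f) {
    v <- molar_mass(f); if (is.na(v)) 0 else v
  }, numeric(1))
  bal <- check_balance(mini)
  internal <- bal$reaction[!bal$skipped]
  wsums <- as.numeric(mm %*% S[, internal])
  expect_lt(max(abs(wsums)), 1e-9)
})

test_that("balance checker flags residuals and skips boundary reactions", {
  mets <- metabolite_tbl(
    c("atp[c]", "h2o[c]", "adp[c]", "pi[c]", "h[c]", "x[e]", "u[c]"),
    formula = c("C10H12N5O13P3", "H2O", "C10H12N5O10P2", "HO4P", "H", "C", ""),
    charge = c(-4L, 0L, -3L, -2L, 1L, 0L, NA),
    compartment = c(rep("c", 5), "e", "c")
  )
  rxns <- dplyr::bind_rows(
    reaction_tbl("HYD_OK", list(c("atp[c]" = -1, "h2o[c]" = -1,
                                  "adp[c]" = 1, "pi[c]" = 1, "h[c]" = 1))),
    # ATP hydrolysis written without the proton: products minus substrates
    # leave one H and one positive charge missing (residual -1 each,
    # hand-counted from the formal charges -4 + 0 -> -3 + -2)
    reaction_tbl("HYD_NOH", list(c("atp[c]" = -1, "h2o[c]" = -1,
                                   "adp[c]" = 1, "pi[c]" = 1))),
    reaction_tbl("EX_x_e", list(c("x[e]" = -1)), kind = "exchange"),
    reaction_tbl("UNK", list(c("u[c]" = -1, "h[c]" = 1)))
  )
  m <- metabolic_model(mets, rxns)
  rep <- check_balance(m)
  expect_true(rep$balanced[rep$reaction == "HYD_OK"])
  row <- rep[rep$reaction == "HYD_NOH", ]
  expect_false(row$balanced)
  expect_equal(row$charge_residual, -1)
  expect_equal(row$residuals[[1]][["H"]], -1)
  expect_true(rep$skipped[rep$reaction == "EX_x_e"])     # convention
  expect_true(rep$skipped[rep$reaction == "UNK"])        # unknown formula
})

test_that("duplicate detection groups scaled and reversed reactions", {
  mets <- metabolite_tbl(c("A[c]", "B[c]", "C[c]"), formula = "C",
                         charge = 0, compartment = "c")
  rxns <- dplyr::bind_rows(
    reaction_tbl("F1", list(c("A[c]" = -1, "B[c]" = 1))),
    reaction_tbl("F2", list(c("A[c]" = -1, "B[c]" = 1))),
    reaction_tbl("F3", list(c("A[c]" = -2, "B[c]" = 2))),   # scaled copy
    reaction_tbl("R1", list(c("B[c]" = -1, "A[c]" = 1)), lb = -1000),
    reaction_tbl("X1", list(c("A[c]" = -1, "C[c]" = 1)))
  )
  m <- metabolic_model(mets, rxns)
  groups <- find_duplicate_reactions(m)
  expect_equal(nrow(groups), 1)
  expect_setequal(groups$reactions[[1]], c("F1", "F2", "F3", "R1"))
  expect_true(groups$direction_conflict[1])
  # equivalence-relation sanity: every reaction appears in at most one group
  ids <- unlist(groups$reactions)
  expect_equal(anyDuplicated(ids), 0)
  # the curated mini network contains no duplicates
  expect_equal(nrow(find_duplicate_reactions(mini_cached())), 0)
})

test_that("reaction equation strings parse and format consistently", {
  s <- parse_reaction_equation(
    "ac[c] + coa[c] + atp[c] -> h[c] + accoa[c] + ppi[c] + amp[c]")
  expect_equal(s[["ac[c]"]], -1)
  expect_equal(s[["amp[c]"]], 1)
  s2 <- parse_reaction_equation("2 A[c] + 0.5 B[c] <=> C[c]")
  expect_equal(s2[["A[c]"]], -2)
  expect_equal(s2[["B[c]"]], -0.5)
  # format -> parse round trip
  rt <- parse_reaction_equation(format_reaction_equation(s))
  expect_equal(rt[order(names(rt))], s[order(names(s))])
  expect_error(parse_reaction_equation("A[c] B[c]"), "->")
})
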