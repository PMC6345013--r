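test_that("ortholog filtering applies inclusive thresholds", {
  hits <- tibble::tibble(
    query = c("q1", "q2", "q3", "q4"),
    subject = c("s1", "s2", "s3", "s4"),
    identity = c(39.9, 40.0, 85, 95),
    evalue = c(1e-40, 1e-30, 1e-29, 0),
    reference = "ref"
  )
  kept <- filter_orthologs(hits)
  # 39.9% fails despite a strong e-value; 40.0 / 1e-30 are inclusive;
  # 1e-29 fails; e-value 0 passes
  expect_setequal(kept$query, c("q2", "q4"))
  expect_error(filter_orthologs(dplyr::mutate(hits, identity = identity + 10)),
               "\\[0, 100\\]")
  expect_error(filter_orthologs(hits[, 1:3]), "lacks column")
})

test_that("ortholog filtering is invariant to row order", {
  hits <- generate_ortholog_hits(seed = 11, n_pass = 25, n_fail = 40)
  a <- filter_orthologs(hits)
  b <- filter_orthologs(hits[rev(seq_len(nrow(hits))), ])
  expect_equal(a, b)
})

test_that("generated hit tables pass/fail by construction and are seed-stable", {
  hits <- generate_ortholog_hits(seed = 1, n_pass = 37, n_fail = 63)
  expect_equal(nrow(hits), 100)
  expect_equal(nrow(filter_orthologs(hits)), 37)
  expect_equal(sum(hits$passes), 37)
  # flag agrees with the thresholds row by row
  expect_equal(hits$passes, hits$identity >= 40 & hits$evalue <= 1e-30)
  expect_identical(hits, generate_ortholog_hits(seed = 1, n_pass = 37,
                                                n_fail = 63))
  expect_false(identical(hits$query,
                         generate_ortholog_hits(2, 37, 63)$query) &&
               identical(hits$identity,
                         generate_ortholog_hits(2, 37, 63)$identity))
  expect_equal(nrow(filter_orthologs(generate_ortholog_hits(1, 0, 10))), 0)
})

ref_fixture <- function() {
  mets <- metabolite_tbl(c("A[c]", "B[c]", "C[c]", "D[c]"), formula = "C",
                         charge = 0, compartment = "c")
  ref1 <- metabolic_model(mets, dplyr::bind_rows(
    reaction_tbl("R_AND", list(c("A[c]" = -1, "B[c]" = 1)), gpr = "sA and sB"),
    reaction_tbl("R_SINGLE", list(c("B[c]" = -1, "C[c]" = 1)), gpr = "sC"),
    reaction_tbl("R_OR", list(c("A[c]" = -2, "C[c]" = 2)), gpr = "sD or sE"),
    reaction_tbl("R_EMPTY", list(c("C[c]" = -1, "D[c]" = 1)), gpr = "")),
    genes = c("sA", "sB", "sC", "sD", "sE"))
  ref2 <- metabolic_model(mets, dplyr::bind_rows(
    reaction_tbl("X_DUP", list(c("A[c]" = -1, "C[c]" = 1)), gpr = "tZ"),
    reaction_tbl("X_NEW", list(c("C[c]" = -1, "A[c]" = 1)), lb = -1000,
                 gpr = "tW")),
    genes = c("tZ", "tW"))
  list(m1 = ref1, m2 = ref2)
}

test_that("draft assembly imports exactly the GPR-satisfiable reactions", {
  refs <- ref_fixture()
  mapping <- tibble::tibble(
    query = c("q1", "q2", "q3", "q4", "q5"),
    subject = c("sA", "sC", "sD", "tZ", "tW"),
    reference = c("m1", "m1", "m1", "m2", "m2"))
  draft <- draft_from_references(mapping, refs)
  # brute-force expectation: evaluate each reference GPR under the mapping
  present <- list(m1 = c("sA", "sC", "sD"), m2 = c("tZ", "tW"))
  expected <- character(0)
  seen_keys <- character(0)
  for (lab in names(refs)) {
    rx <- refs[[lab]]$reactions
    for (j in seq_len(nrow(rx))) {
      absent <- setdiff(gpr_genes(rx$gpr[j]), present[[lab]])
      if (evaluate_gpr(rx$gpr[j], absent)) {
        key <- stilflux:::canonical_stoich_key(rx$stoichiometry[[j]])$key
        if (!(key %in% seen_keys)) {
          seen_keys <- c(seen_keys, key)
          expected <- c(expected, rx$id[j])
        }
      }
    }
  }
  expect_setequal(draft$reactions$id, expected)
  # R_AND blocked (sB unmapped); duplicates merged once; empty GPR imported
  expect_false("R_AND" %in% draft$reactions$id)
  expect_true("R_EMPTY" %in% draft$reactions$id)
  expect_false("X_DUP" %in% draft$reactions$id)
  # GPRs rewritten into query ids
  expect_equal(draft$reactions$gpr[draft$reactions$id == "R_SINGLE"], "q2")
  rep <- attr(draft, "draft_report")
  expect_true(rep$reversibility_conflict[rep$reaction == "X_NEW"])
  # no imported reaction has an unsatisfiable GPR under the mapping
  for (j in seq_len(nrow(draft$reactions))) {
    expect_true(evaluate_gpr(draft$reactions$gpr[j], character(0)))
  }
})

test_that("multi-mapped subjects become OR alternatives in rewritten GPRs", {
  refs <- ref_fixture()
  mapping <- tibble::tibble(query = c("q1", "q9"), subject = c("sC", "sC"),
                            reference = "m1")
  draft <- draft_from_references(mapping, refs["m1"])
  expect_equal(draft$reactions$gpr[draft$reactions$id == "R_SINGLE"],
               "q1 or q9")
})

test_that("exchange addition enforces the single-extracellular convention", {
  mets <- metabolite_tbl(c("g[e]", "x[e]", "y[c]"), formula = "C", charge = 0,
                         compartment = c("e", "e", "c"))
  m <- metabolic_model(mets,
    reaction_tbl("T", list(c("g[e]" = -1, "y[c]" = 1)), kind = "transport"))
  m2 <- add_exchange_reactions(m, c("g[e]", "x[e]"))
  ex <- m2$reactions[m2$reactions$kind == "exchange", ]
  expect_equal(nrow(ex), 2)
  expect_equal(ex$lb, c(0, 0))           # closed uptake by default
  expect_equal(lengths(ex$stoichiometry), c(1L, 1L))
  expect_error(add_exchange_reactions(m2, "g[e]"), "already exists")
  expect_error(add_exchange_reactions(m, "y[c]"), "not in e")
})

test_that("gap filling restores rhamnose growth with exactly the missing pair", {
  m0 <- mini_model(include_rhamnose = FALSE)
  med <- c(mini_minimal_medium()[-1], EX_rmn_e = 2)
  m0 <- set_medium(m0, med)
  before <- solve_fba(m0)
  expect_true(before$status != "optimal" || before$objective_value < 1e-3)
  gf <- suppressWarnings(
    gap_fill(m0, mini_universal_set(), objective = "BIOMASS",
             min_objective = 0.01))
  expect_equal(gf$status, "filled")
  expect_setequal(gf$added, c("RMNt", "RMND"))
  expect_gte(gf$objective_value, 0.01)
})

test_that("gap filling returns nothing for an already growing model", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  gf <- gap_fill(m, mini_universal_set(), objective = "BIOMASS",
                 min_objective = 0.01)
  expect_equal(gf$status, "already_feasible")
  expect_length(gf$added, 0)
})

test_that("an unfillable gap reports blocked precursors", {
  m0 <- mini_model(include_rhamnose = FALSE)
  med <- c(mini_minimal_medium()[-1], EX_rmn_e = 2)
  m0 <- set_medium(m0, med)
  decoys <- mini_universal_set()
  decoys <- decoys[decoys$id %in% c("U_PPA2", "U_THD2"), ]
  gf <- suppressWarnings(
    gap_fill(m0, decoys, objective = "BIOMASS", min_objective = 0.01))
  expect_equal(gf$status, "unfillable")
  expect_gt(length(gf$blocked), 0)
})
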