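# Small toy models reused across tests, built in code.

toy_chain_model <- function() {
  mets <- metabolite_tbl(
    id = c("A[e]", "A[c]", "B[c]", "B[e]"),
    formula = "C2H4O2", charge = 0,
    compartment = c("e", "c", "c", "e")
  )
  rxns <- dplyr::bind_rows(
    reaction_tbl("EX_A_e", list(c("A[e]" = -1)), lb = -5, kind = "exchange"),
    reaction_tbl("At", list(c("A[e]" = -1, "A[c]" = 1)), kind = "transport",
                 gpr = "tA"),
    reaction_tbl("AB", list(c("A[c]" = -1, "B[c]" = 1)), gpr = "gAB"),
    reaction_tbl("Bt", list(c("B[c]" = -1, "B[e]" = 1)), kind = "transport"),
    reaction_tbl("EX_B_e", list(c("B[e]" = -1)), kind = "exchange")
  )
  metabolic_model(mets, rxns, genes = c("tA", "gAB"),
                  objective = c(EX_B_e = 1))
}

# chain with two parallel, identical internal paths A -> B
toy_parallel_model <- function() {
  m <- toy_chain_model()
  m$genes <- c(m$genes, "gAB2")
  add_reactions(m, reaction_tbl("AB2", list(c("A[c]" = -1, "B[c]" = 1)),
                                gpr = "gAB2"))
}

mini_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- mini_model()
    cache
  }
})
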