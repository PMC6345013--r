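test_that("FBA on a linear chain is limited by the uptake bound", {
  m <- toy_chain_model()          # EX_A lb = -5
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5, tolerance = 1e-9)
  expect_equal(flux_of(sol, "AB"), 5, tolerance = 1e-9)
  # steady state holds on the solution
  S <- as.matrix(stoichiometric_matrix(m))
  expect_lt(max(abs(S %*% sol$raw_fluxes)), 1e-6)
  # tidiers
  expect_named(tidy(sol), c("reaction", "flux"))
  expect_equal(glance(sol)$status, "optimal")
})

test_that("infeasible and unbounded problems are reported via status", {
  m <- toy_chain_model()
  m2 <- set_bounds(m, "EX_B_e", lb = 10, ub = 20)  # forced export, no supply
  m2 <- set_bounds(m2, "EX_A_e", lb = 0)
  expect_equal(solve_fba(m2)$status, "infeasible")
  m3 <- set_bounds(m, c("EX_A_e", "At", "AB", "Bt", "EX_B_e"),
                   lb = c(-Inf, 0, 0, 0, 0), ub = Inf)
  expect_equal(solve_fba(m3)$status, "unbounded")
})

test_that("set_medium closes all uptake then opens listed exchanges", {
  mini <- mini_cached()
  m <- set_medium(mini, c(EX_glc__D_e = 2.0), unlimited = c("EX_o2_e"))
  rx <- m$reactions
  expect_equal(rx$lb[rx$id == "EX_glc__D_e"], -2.0)
  expect_equal(rx$lb[rx$id == "EX_o2_e"], -1000)
  closed <- rx$lb[rx$kind == "exchange" &
                  !(rx$id %in% c("EX_glc__D_e", "EX_o2_e"))]
  expect_true(all(closed == 0))
  expect_error(set_medium(mini, c(EX_nope_e = 1)), "unknown exchange")
  expect_error(set_medium(mini, c(EX_glc__D_e = -1)), ">= 0")
  # an empty medium supports no growth
  s0 <- solve_fba(set_medium(mini, numeric(0)))
  expect_true(s0$status != "optimal" || s0$objective_value < 1e-9)
})

test_that("the minimal medium supports growth of the mini network", {
  sol <- solve_fba(set_medium(mini_cached(), mini_minimal_medium()))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0.01)
})

test_that("FVA collapses on a chain and splits over parallel paths", {
  m <- toy_chain_model()
  fva <- flux_variability(m)
  expect_equal(fva$min, fva$max, tolerance = 1e-8)   # all ranges are points
  p <- toy_parallel_model()
  fvap <- flux_variability(p, reactions = c("AB", "AB2", "EX_B_e"))
  expect_equal(fvap$min[fvap$reaction == "AB"], 0, tolerance = 1e-8)
  expect_equal(fvap$max[fvap$reaction == "AB"], 5, tolerance = 1e-8)
  expect_equal(fvap$min[fvap$reaction == "AB2"], 0, tolerance = 1e-8)
  expect_equal(fvap$max[fvap$reaction == "AB2"], 5, tolerance = 1e-8)
  expect_equal(fvap$min[fvap$reaction == "EX_B_e"], 5, tolerance = 1e-8)
})

test_that("FVA ranges bracket the FBA flux vector at fraction 1", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  sol <- solve_fba(m)
  ids <- m$reactions$id[seq(1, nrow(m$reactions), by = 7)]  # spot sample
  fva <- flux_variability(m, reactions = ids)
  v <- flux_of(sol, ids)
  expect_true(all(v >= fva$min - 1e-6 & v <= fva$max + 1e-6))
  expect_true(all(fva$min <= fva$max + 1e-9))
})

test_that("scaling all bounds by k scales the FBA optimum by k", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  base <- solve_fba(m)$objective_value
  k <- 3.5
  m2 <- m
  m2$reactions$lb <- m$reactions$lb * k
  m2$reactions$ub <- m$reactions$ub * k
  expect_equal(solve_fba(m2)$objective_value, k * base, tolerance = 1e-6)
})

test_that("adding a duplicate reaction leaves the optimum unchanged", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  base <- solve_fba(m)$objective_value
  dup <- m$reactions[m$reactions$id == "PFK", ]
  dup$id <- "PFK_copy"
  m2 <- add_reactions(m, dup) |> suppressWarnings()
  expect_equal(solve_fba(m2)$objective_value, base, tolerance = 1e-6)
})

test_that("each robustness-scan point equals a standalone pinned solve", {
  ps <- mini_production_state(mini_cached())
  vals <- c(0, 0.02, 0.05)
  rs <- robustness_scan(ps, "EX_etoh_e", vals, objective = "EX_resv_e",
                        uptake = TRUE)
  expect_equal(nrow(rs), 3)
  for (i in seq_along(vals)) {
    m2 <- set_bounds(ps, "EX_etoh_e", lb = -vals[i], ub = -vals[i])
    direct <- solve_fba(m2, "EX_resv_e")$objective_value
    expect_equal(rs$objective_value[i], direct, tolerance = 1e-9)
  }
  expect_error(robustness_scan(ps, "EX_etoh_e", c(0.05, 0)), "sorted")
})

test_that("connectivity ranks ubiquitous metabolites first, both modes", {
  mets <- metabolite_tbl(c("h2o[c]", "a[c]", "b[c]", "c[c]", "d[c]", "e[c]"),
                         formula = "H2O", charge = 0, compartment = "c")
  rxns <- dplyr::bind_rows(
    reaction_tbl("R1", list(c("a[c]" = -1, "h2o[c]" = -1, "b[c]" = 1))),
    reaction_tbl("R2", list(c("b[c]" = -1, "h2o[c]" = -1, "c[c]" = 1))),
    reaction_tbl("R3", list(c("c[c]" = -1, "h2o[c]" = 1, "a[c]" = 1))),
    reaction_tbl("R4", list(c("d[c]" = -1, "e[c]" = 1)))
  )
  m <- metabolic_model(mets, rxns)
  conn <- metabolite_connectivity(m)
  expect_equal(conn$metabolite[1], "h2o[c]")
  expect_equal(conn$count[1], 3)
  # flux mode with an all-zero vector counts nothing
  zero <- stilflux:::new_flux_state(m, rep(0, 4), 0, "optimal", c(R1 = 1))
  connz <- metabolite_connectivity(m, zero)
  expect_true(all(connz$count == 0))
})

test_that("protons and water outrank pathway intermediates in the production state", {
  ps <- mini_production_state(mini_cached())
  sol <- solve_fba(ps, "EX_resv_e")
  conn <- metabolite_connectivity(ps, sol)
  rank_of <- function(id) which(conn$metabolite == id)
  expect_lt(rank_of("h[c]"), rank_of("couma[c]"))
  expect_lt(rank_of("h2o[c]"), rank_of("4cmcoa[c]"))
  expect_lt(rank_of("h[c]"), rank_of("sme[c]"))
})
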