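test_that("the generated network satisfies the structural contracts", {
  m <- mini_cached()
  expect_s3_class(m, "metabolic_model")
  g <- glance(m)
  expect_gt(g$n_reactions, 40)
  expect_equal(sort(names(m$compartments)), c("c", "e"))
  # every internal reaction is element- and charge-balanced
  bal <- check_balance(m)
  expect_true(all(bal$balanced[!bal$skipped]))
  expect_equal(nrow(find_duplicate_reactions(m)), 0)
  # default generation is bit-reproducible
  expect_identical(mini_model(), mini_model())
  # bound jitter is deterministic under a seed and requires one
  expect_identical(mini_model(seed = 4, jitter = 0.05),
                   mini_model(seed = 4, jitter = 0.05))
  expect_error(mini_model(jitter = 0.05), "seed")
  expect_error(mini_model(knockout = "NOT_A_REACTION"), "absent reaction")
})

test_that("the network grows on glucose and exports resveratrol at fixed growth", {
  m <- mini_cached()
  growth <- solve_fba(set_medium(m, mini_minimal_medium(glucose = 2)))
  expect_equal(growth$status, "optimal")
  expect_gt(growth$objective_value, 0)
  resv <- solve_fba(mini_production_state(m), "EX_resv_e")
  expect_equal(resv$status, "optimal")
  expect_gt(resv$objective_value, 0)
})

test_that("maximum resveratrol export is pinned by sharp pathway bottlenecks", {
  ps <- mini_production_state(mini_cached())
  free <- solve_fba(ps, "EX_resv_e")$objective_value
  # p-coumaroyl-CoA bottleneck: capping the CoA-ligase at a value below the
  # free optimum caps export at exactly that value (1 per resveratrol)
  cap4cl <- 0.005
  expect_gt(free, cap4cl)
  r1 <- solve_fba(set_bounds(ps, "4CL", ub = cap4cl), "EX_resv_e")
  expect_equal(r1$objective_value, cap4cl, tolerance = 1e-8)
  # malonyl-CoA bottleneck: 3 malonyl-CoA per resveratrol. Fatty-acid
  # synthesis for the fixed growth rate claims a baseline carboxylase
  # flux; granting 0.03 above that baseline buys exactly 0.01 resveratrol.
  acc_base <- solve_fba(set_bounds(ps, "EX_resv_e", lb = 0, ub = 0),
                        objective = "ACC", direction = "min")$objective_value
  r2 <- solve_fba(set_bounds(ps, "ACC", ub = acc_base + 0.03), "EX_resv_e")
  expect_equal(r2$objective_value, 0.03 / 3, tolerance = 1e-6)
  # and the free optimum respects min(available precursors)
  max4cl <- flux_variability(ps, objective = "EX_resv_e", fraction = 0,
                             reactions = c("4CL", "ACC"))
  expect_lte(free, min(max4cl$max[max4cl$reaction == "4CL"],
                       max4cl$max[max4cl$reaction == "ACC"] / 3) + 1e-6)
})

test_that("removing the stilbene synthase drives resveratrol export to zero", {
  m <- mini_model(knockout = "CHS_STS")
  ps <- mini_production_state(m)
  sol <- solve_fba(ps, "EX_resv_e")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("resveratrol production is non-decreasing in ethanol uptake", {
  ps <- mini_production_state(mini_cached())
  rs <- robustness_scan(ps, "EX_etoh_e", seq(0, 0.05, length.out = 11),
                        objective = "EX_resv_e", uptake = TRUE)
  expect_true(all(rs$status == "optimal"))
  expect_true(all(diff(rs$objective_value) >= -1e-9))
  expect_gt(rs$objective_value[11], rs$objective_value[1])
})

test_that("ethanol assimilation turns on the acetate-activating reaction g0770", {
  ps <- mini_production_state(mini_cached())
  at0 <- solve_fba(set_bounds(ps, "EX_etoh_e", lb = 0, ub = 0), "EX_resv_e")
  at5 <- solve_fba(set_bounds(ps, "EX_etoh_e", lb = -0.05, ub = -0.05),
                   "EX_resv_e")
  # without ethanol the reaction only recycles the acetate released by
  # cysteine synthesis; every mmol of ethanol taken up adds one mmol of
  # acetate activation on top of that baseline
  expect_gt(flux_of(at5, "g0770"), flux_of(at0, "g0770"))
  expect_equal(flux_of(at5, "g0770") - flux_of(at0, "g0770"), 0.05,
               tolerance = 1e-6)
  # the route can be generated without ethanol assimilation at all
  m_no <- mini_model(include_ethanol = FALSE)
  expect_false(any(c("g0770", "ADH", "EX_etoh_e") %in% m_no$reactions$id))
})

test_that("the transcribed phenotype table has the published shape", {
  tab <- growth_phenotype_fixture()
  expect_equal(sum(tab$role == "carbon"), 20)
  expect_equal(sum(tab$role == "nitrogen"), 12)
  expect_true(all(tab$observed %in% c("+", "-")))
  expect_true(all(tab$predicted %in% c("+", "-")))
  expect_setequal(tab$substrate[tab$gapfilled],
                  c("Starch", "Sucrose", "Rhamnose", "Dextrin"))
})

test_that("the composition fixture carries the published macromolecular split", {
  comp <- composition_fixture()
  expect_equal(comp$macro[["cell_wall"]], 0.32)
  expect_equal(comp$macro[["protein"]], 0.20)
  expect_equal(comp$macro[["mannitol"]], 0.15)
  expect_equal(comp$macro[["ash"]], 0.15)
  expect_equal(comp$macro[["lipid"]], 0.14)
  expect_equal(comp$macro[["nucleic_acid"]], 0.04)
  expect_equal(sum(comp$macro), 1)
  for (tab in comp$monomers) expect_equal(sum(tab), 1, tolerance = 1e-12)
})

test_that("scan and screen results plot without error", {
  ps <- mini_production_state(mini_cached())
  rs <- robustness_scan(ps, "EX_etoh_e", c(0, 0.05), objective = "EX_resv_e",
                        uptake = TRUE)
  p1 <- autoplot(rs)
  expect_s3_class(p1, "ggplot")
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  del <- single_gene_deletion(m, genes = c("PFK", "HXT1"))
  expect_s3_class(autoplot(del), "ggplot")
  conn <- metabolite_connectivity(mini_cached())
  expect_s3_class(autoplot(conn), "ggplot")
})
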