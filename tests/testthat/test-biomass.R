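test_that("GC content fixes the deoxynucleotide mole fractions", {
  fr <- nucleotide_fractions_from_gc(0.5096)
  expect_equal(fr[["dGMP"]], 0.2548)
  expect_equal(fr[["dCMP"]], 0.2548)
  expect_equal(fr[["dAMP"]], 0.2452)
  expect_equal(fr[["dTMP"]], 0.2452)
  expect_equal(sum(fr), 1)
  expect_equal(unname(nucleotide_fractions_from_gc(0.5)), rep(0.25, 4))
  expect_error(nucleotide_fractions_from_gc(0), "between 0 and 1")
  expect_error(nucleotide_fractions_from_gc(1), "between 0 and 1")
})

test_that("composition validation enforces unit sums and non-negative maintenance", {
  expect_error(biomass_composition(c(a = 0.6, b = 0.3),
                                   list(a = c(x = 1), b = c(y = 1))),
               "sum to 1")
  expect_error(biomass_composition(c(a = 1), list(a = c(x = 0.5))),
               "sum to 1")
  expect_error(biomass_composition(c(a = 1), list(a = c(x = 1)), gam = -1),
               ">= 0")
  expect_error(biomass_composition(c(a = 1), list()), "no monomer table")
})

test_that("a pure-mannitol composition yields the hand-computed coefficient", {
  comp <- biomass_composition(c(mannitol = 1),
                              list(mannitol = c("mnl[c]" = 1)),
                              gam = 0, ngam = 0)
  r <- build_biomass_reaction(comp, c("mnl[c]" = 0.18216))
  expect_equal(r$stoichiometry[[1]][["mnl[c]"]], -5.4896, tolerance = 1e-4)
  # GAM = 0 leaves no ATP term
  expect_false("atp[c]" %in% names(r$stoichiometry[[1]]))
})

test_that("biomass monomer mass closes to 1 g/gDW for the study fractions", {
  comp <- composition_fixture()
  expect_equal(sum(comp$macro), 1)
  r <- build_biomass_reaction(comp, mini_monomer_masses())
  mass <- biomass_drained_mass(r, mini_monomer_masses())
  expect_equal(mass, 1, tolerance = 1e-6)
  # GAM hydrolysis species carry the GAM coefficient
  expect_equal(r$stoichiometry[[1]][["atp[c]"]], -comp$gam)
  expect_equal(r$stoichiometry[[1]][["adp[c]"]], comp$gam)
  expect_equal(r$stoichiometry[[1]][["h[c]"]], comp$gam)
  expect_error(build_biomass_reaction(comp, c("mnl[c]" = 0.18)),
               "missing molar mass")
})

test_that("mass closure holds across random valid compositions", {
  mm <- mini_monomer_masses()
  withr::with_seed(7, {
    for (i in 1:20) {
      w <- stats::runif(4)
      macro <- stats::setNames(w / sum(w),
                               c("cell_wall", "protein", "lipid", "mannitol"))
      pw <- stats::runif(3)
      comp <- biomass_composition(
        macro,
        list(cell_wall = c("glucan[c]" = 1),
             protein = stats::setNames(pw / sum(pw),
                                       c("glu__L[c]", "ala__L[c]", "phe__L[c]")),
             lipid = c("hdca[c]" = 1),
             mannitol = c("mnl[c]" = 1)),
        gam = stats::runif(1, 0, 100), ngam = 0)
      r <- build_biomass_reaction(comp, mm)
      expect_equal(biomass_drained_mass(r, mm), 1, tolerance = 1e-6)
    }
  })
})

test_that("raising GAM never increases the growth rate", {
  med <- mini_minimal_medium(glucose = 2)
  gams <- c(20, 60, 120)
  mu <- vapply(gams, function(g) {
    m <- mini_model(composition = composition_fixture(gam = g))
    solve_fba(set_medium(m, med))$objective_value
  }, numeric(1))
  expect_true(all(diff(mu) < 1e-9))
})

test_that("NGAM pins a maintenance floor and detects impossible demands", {
  mini <- mini_cached()
  m <- set_medium(mini, mini_minimal_medium(glucose = 2))
  sol <- solve_fba(m)
  expect_gte(flux_of(sol, "ATPM"), 1.0 - 1e-9)   # default NGAM floor
  m0 <- add_ngam(m, 0)
  expect_equal(m0$reactions$lb[m0$reactions$id == "ATPM"], 0)
  expect_error(add_ngam(m, -1), ">= 0")
  # maintenance beyond the achievable ATP turnover is infeasible
  cap <- flux_variability(m, fraction = 0, reactions = "ATPM")$max
  m_hi <- add_ngam(m, cap + 10)
  expect_equal(solve_fba(m_hi)$status, "infeasible")
  # add_ngam creates the reaction when absent
  toy <- toy_chain_model()
  mets <- metabolite_tbl(c("atp[c]", "h2o[c]", "adp[c]", "pi[c]", "h[c]"),
                         formula = "", charge = NA_integer_, compartment = "c")
  toy$metabolites <- dplyr::bind_rows(toy$metabolites, mets)
  toy2 <- add_ngam(toy, 0.5)
  expect_true("ATPM" %in% toy2$reactions$id)
})
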