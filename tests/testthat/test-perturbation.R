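test_that("deletion of the only transporter gene is lethal, isozymes are not", {
  mini <- mini_cached()
  m <- set_medium(mini, mini_minimal_medium(glucose = 2))
  del <- single_gene_deletion(m, genes = c("HXT1", "HXK1", "HXK2", "CHS"))
  res <- function(g) del[del$gene == g, ]
  expect_true(res("HXT1")$essential)          # glucose-only cut vertex
  expect_false(res("HXK1")$essential)         # OR-ed isozyme
  expect_false(res("HXK2")$essential)
  expect_false(res("CHS")$essential)          # secondary metabolism
  expect_equal(res("HXK1")$n_disabled, 0)
  expect_true(all(del$growth <= del$wt_growth + 1e-6))
})

test_that("the deletion screen is order-independent", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  genes <- c("PFK", "ARO1", "HXT1", "FAS1", "ALT1")
  a <- single_gene_deletion(m, genes = genes)
  b <- single_gene_deletion(m, genes = rev(genes))
  b <- b[match(a$gene, b$gene), ]
  expect_equal(a$growth, b$growth, tolerance = 1e-9)
  expect_equal(a$essential, b$essential)
})

test_that("essential genes stay essential when the medium shrinks", {
  mini <- mini_cached()
  rich <- set_medium(mini, mini_rich_medium())
  poor <- set_medium(mini, mini_minimal_medium(glucose = 2))
  del_rich <- single_gene_deletion(rich)
  del_poor <- single_gene_deletion(poor)
  ess_rich <- del_rich$gene[del_rich$essential]
  ess_poor <- del_poor$gene[del_poor$essential]
  # the poor medium's uptake set is a strict subset of the rich one's
  expect_true(all(ess_rich %in% ess_poor))
  # and the rich medium rescues some biosynthetic genes (aromatic uptake)
  expect_gt(length(ess_poor), length(ess_rich))
})

test_that("wild-type infeasibility aborts the screen with a diagnostic", {
  m <- set_medium(mini_cached(), numeric(0))
  expect_error(single_gene_deletion(m, genes = "PFK"), "wild-type")
})

test_that("MOMA returns the reference exactly when nothing is perturbed", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  wt <- solve_fba(m)
  sol <- solve_moma(m, wt)
  expect_equal(sol$status, "optimal")
  expect_lt(sol$distance, 1e-10)
  expect_equal(sol$raw_fluxes, wt$raw_fluxes, tolerance = 1e-5)
})

test_that("knocking out a zero-flux reaction leaves MOMA at distance zero", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  wt <- solve_fba(m)
  expect_equal(flux_of(wt, "ROMT"), 0)        # idle side branch
  sol <- solve_moma(m, wt, knockout = "ROMT")
  expect_lt(sol$distance, 1e-10)
})

test_that("MOMA growth after a knockout does not exceed the knockout FBA optimum", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  wt <- solve_fba(m)
  ko_model <- knockout_genes(m, "PFK")
  moma <- solve_moma(ko_model, wt)
  fba <- solve_fba(ko_model)
  expect_equal(moma$status, "optimal")
  expect_gt(moma$distance, 0)
  expect_lte(flux_of(moma, "BIOMASS"), fba$objective_value + 1e-6)
})

test_that("an infeasible perturbation is reported as such", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  wt <- solve_fba(m)
  dead <- set_bounds(m, "ATPM", lb = 1e5, ub = 1e5)
  expect_equal(solve_moma(dead, wt)$status, "infeasible")
})

test_that("the overexpression scan excludes the product exchange and honors fold 1", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  sc <- scan_overexpression_targets(m, "EX_resv_e", fold = 2,
                                    method = "moma")
  expect_false("EX_resv_e" %in% sc$reaction)
  expect_true(all(sc$fold_change > 1))
  expect_true(all(abs(sc$forced_flux) >= abs(sc$wt_flux) - 1e-12))
  sc1 <- scan_overexpression_targets(m, "EX_resv_e", fold = 1,
                                     method = "moma")
  expect_equal(nrow(sc1), 0)
})

test_that("forcing the stilbene pathway doubles attainable resveratrol export", {
  m <- set_medium(mini_cached(), mini_minimal_medium(glucose = 2))
  sc <- scan_overexpression_targets(m, "EX_resv_e", min_product = 0.001,
                                    fold = 2, method = "fba")
  fold_of <- function(id) sc$fold_change[sc$reaction == id]
  expect_gte(fold_of("4CL"), 2 - 1e-6)
  expect_gte(fold_of("CHS_STS"), 2 - 1e-6)
  expect_equal(sc$genes[sc$reaction == "CHS_STS"], "CHS")
})
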