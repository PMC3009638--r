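# Knockout strain design: single evaluations, exhaustive enumeration,
# evolutionary search.

design_fixture <- function() {
  list(m = toy_model(),
       cs = toy_conditions()$mixotrophy$constraints)
}

test_that("an empty deletion set reproduces the wild type", {
  fx <- design_fixture()
  wt <- fba(fx$m, fx$cs)
  res <- evaluate_design(fx$m, fx$cs, character(), "EX_succ",
                         inner = "MOMA", wild_type = wt)
  expect_equal(res$growth, wt$objective_value, tolerance = 1e-6)
  expect_equal(res$production, unname(wt$fluxes["EX_succ"]),
               tolerance = 1e-6)
  # self-consistency: reported production is the design flux of the state
  expect_equal(res$production, unname(res$fluxes["EX_succ"]),
               tolerance = 1e-12)
})

test_that("candidate set excludes boundary and orphan reactions", {
  m <- toy_model()
  cands <- design_candidates(m, "EX_succ")
  expect_false(any(grepl("^EX_", cands)))
  expect_false("BIOMASS" %in% cands)
  expect_false("ATPM" %in% cands)  # no cognate genes
  expect_true(all(c("SDH", "PYKA", "NDH") %in% cands))
})

test_that("exhaustive k=0 returns only the wild type", {
  fx <- design_fixture()
  tab <- exhaustive_knockout_search(fx$m, fx$cs, k = 0,
                                    design_reaction = "EX_succ",
                                    inner = "MOMA")
  expect_equal(nrow(tab), 1)
  expect_identical(tab$deletions, "")
})

test_that("exhaustive k=1 equals the per-reaction sweep", {
  fx <- design_fixture()
  wt <- fba(fx$m, fx$cs)
  tab <- exhaustive_knockout_search(fx$m, fx$cs, k = 1,
                                    design_reaction = "EX_succ",
                                    inner = "MOMA", wild_type = wt)
  # sweep oracle
  cands <- design_candidates(fx$m, "EX_succ")
  best_prod <- -Inf; best_id <- NULL
  for (rid in cands) {
    res <- evaluate_design(fx$m, fx$cs, rid, "EX_succ", inner = "MOMA",
                           wild_type = wt)
    if (res$feasible && res$growth >= 0.1 * wt$objective_value &&
        res$production > best_prod) {
      best_prod <- res$production; best_id <- rid
    }
  }
  top <- tab[tab$deletions != "", ][1, ]
  expect_equal(top$production, best_prod, tolerance = 1e-8)
})

test_that("production of the best design is non-decreasing in k", {
  fx <- design_fixture()
  wt <- fba(fx$m, fx$cs)
  prods <- vapply(0:2, function(k) {
    tab <- exhaustive_knockout_search(fx$m, fx$cs, k = k,
                                      design_reaction = "EX_succ",
                                      inner = "MOMA", wild_type = wt)
    max(tab$production)
  }, numeric(1))
  expect_true(all(diff(prods) >= -1e-9))
})

test_that("combinatorial guard suggests the evolutionary search", {
  fx <- design_fixture()
  expect_error(
    exhaustive_knockout_search(fx$m, fx$cs, k = 3,
                               design_reaction = "EX_succ", guard = 10),
    "evolutionary")
})

test_that("a degenerate GA (one wild-type individual, no mutation) stays wild type", {
  fx <- design_fixture()
  wt <- fba(fx$m, fx$cs)
  res <- evolutionary_knockout_search(fx$m, fx$cs, k = 0,
                                      design_reaction = "EX_succ",
                                      inner = "MOMA", wild_type = wt,
                                      population = 1, generations = 2,
                                      mutation_rate = 0, seed = 5)
  expect_length(res$deletions, 0)
  expect_equal(res$growth, wt$objective_value, tolerance = 1e-6)
})

test_that("the GA finds the exhaustive k=1 optimum and is seed-reproducible", {
  fx <- design_fixture()
  wt <- fba(fx$m, fx$cs)
  ex <- exhaustive_knockout_search(fx$m, fx$cs, k = 1,
                                   design_reaction = "EX_succ",
                                   inner = "MOMA", wild_type = wt)
  ga1 <- evolutionary_knockout_search(fx$m, fx$cs, k = 1,
                                      design_reaction = "EX_succ",
                                      inner = "MOMA", wild_type = wt,
                                      population = 20, generations = 25,
                                      seed = 42)
  ga2 <- evolutionary_knockout_search(fx$m, fx$cs, k = 1,
                                      design_reaction = "EX_succ",
                                      inner = "MOMA", wild_type = wt,
                                      population = 20, generations = 25,
                                      seed = 42)
  expect_identical(ga1$deletions, ga2$deletions)
  expect_equal(ga1$production, max(ex$production), tolerance = 1e-6)
  expect_error(
    evolutionary_knockout_search(fx$m, fx$cs, k = 1,
                                 design_reaction = "EX_succ"),
    "seed")
})

test_that("minimal gene knockouts disable their reactions", {
  m <- toy_model()
  for (rid in c("SDH", "PYKG", "HK")) {
    genes <- synflux:::min_gene_knockout(m$reactions[[rid]]$gpr)
    expect_false(evaluate_gpr(m$reactions[[rid]]$gpr, genes))
    # minimality: removing any gene from the set re-enables the reaction
    if (length(genes) > 1) {
      for (g in genes)
        expect_true(evaluate_gpr(m$reactions[[rid]]$gpr, setdiff(genes, g)))
    }
  }
  # a complex needs one subunit, an isozyme pair needs both genes
  expect_length(synflux:::min_gene_knockout(m$reactions$SDH$gpr), 1)
  expect_length(synflux:::min_gene_knockout(m$reactions$PYKG$gpr), 2)
})
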