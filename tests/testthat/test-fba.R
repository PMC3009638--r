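# FBA engine: LP correctness, two-phase photon minimization, FVA, blocked
# reactions.

test_that("FBA solves capped linear chains exactly", {
  expect_equal(fba(chain_model(cap = 1))$objective_value, 1, tolerance = 1e-9)
  expect_equal(fba(chain_model(cap = 1, gain = 2))$objective_value, 2,
               tolerance = 1e-9)
  sol <- fba(chain_model(cap = 1))
  expect_lt(mass_balance_residual(chain_model(cap = 1), sol$fluxes), 1e-9)
})

test_that("FBA optimum equals the vertex-enumeration maximum", {
  m <- branched_model()
  sol <- fba(m)
  verts <- enumerate_vertices(m)
  expect_gt(length(verts), 0)
  obj_idx <- which(reaction_ids(m) == "BIO")
  best <- max(vapply(verts, `[`, numeric(1), obj_idx))
  expect_equal(sol$objective_value, best, tolerance = 1e-7)
})

test_that("infeasibility is reported distinctly from zero growth", {
  m <- chain_model(cap = 1)
  # contradictory demands: forced export with no route
  inf <- fba(m, constraint_set(BIO = c(2, 3)))
  expect_false(is_feasible(inf))
  expect_identical(inf$status, "infeasible")
  zero <- fba(m, constraint_set(EX_A = c(0, 0)))
  expect_true(is_feasible(zero))
  expect_equal(zero$objective_value, 0, tolerance = 1e-9)
})

test_that("an objective open to the solver's infinity raises an error", {
  mets <- data.frame(id = c("A", "X"), external = c(FALSE, TRUE))
  m <- metabolic_model(mets,
                       list(reaction("IN", c(X = -1, A = 1)),
                            reaction("OUT", c(A = -1))),
                       objective = "OUT")
  expect_error(fba(m), "unbounded")
})

test_that("optimum is invariant to reaction order and reversible splitting", {
  m <- branched_model()
  ref <- fba(m)$objective_value
  # shuffled reaction order
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  m_perm <- metabolic_model(m$metabolites, unname(m$reactions[perm]),
                            objective = "BIO")
  expect_equal(fba(m_perm)$objective_value, ref, tolerance = 1e-8)
  # split the reversible BC into two irreversible halves
  rxs <- m$reactions
  rxs$BC <- NULL
  rxs$BC_f <- reaction("BC_f", c(B = -1, C = 1), upper_bound = 1)
  rxs$BC_b <- reaction("BC_b", c(C = -1, B = 1), upper_bound = 1)
  m_split <- metabolic_model(m$metabolites, unname(rxs), objective = "BIO")
  expect_equal(fba(m_split)$objective_value, ref, tolerance = 1e-8)
})

test_that("tightening a bound never increases the optimum", {
  m <- toy_model()
  cs <- toy_conditions()$mixotrophy$constraints
  ref <- fba(m, cs)$objective_value
  set.seed(3)
  for (i in 1:10) {
    rid <- sample(setdiff(reaction_ids(m), "BIOMASS"), 1)
    eb <- synflux:::effective_bounds(m, cs)
    tight <- merge_constraints(cs, constraint_set(
      stats::setNames(list(c(max(eb$lb[rid], -1), min(eb$ub[rid], 1))), rid)))
    sol <- fba(m, tight)
    if (is_feasible(sol))
      expect_lte(sol$objective_value, ref + 1e-7)
  }
})

test_that("two-phase photon minimization matches a direct LP", {
  m <- toy_model()
  cs <- toy_conditions()$autotrophy$constraints
  photons <- c("EX_lightI", "EX_lightII")
  target <- 0.9 * fba(m, cs)$objective_value
  tp <- two_phase_light_minimization(m, cs, target, photons)
  expect_equal(unname(tp$fluxes["BIOMASS"]), target, tolerance = 1e-5)
  # oracle: same LP assembled by hand
  rids <- reaction_ids(m)
  band <- merge_constraints(cs, constraint_set(
    BIOMASS = c(target * (1 - 1e-6), target * (1 + 1e-6))))
  direct <- synflux:::solve_flux_lp(m, band, as.numeric(rids %in% photons),
                                    "min")
  expect_equal(attr(tp, "photon_total"), direct$objective, tolerance = 1e-6)
  # photon demand cannot exceed the phase-1 usage at the full optimum
  expect_lte(attr(tp, "photon_total"), 1.6 + 1e-9)
})

test_that("two-phase minimization without light demand reports zero photons", {
  m <- toy_model()
  cs <- toy_conditions()$dark_heterotrophy$constraints
  tp <- two_phase_light_minimization(m, cs, 0,
                                     c("EX_lightI", "EX_lightII"))
  expect_equal(attr(tp, "photon_total"), 0, tolerance = 1e-8)
})

test_that("an unreachable growth target carries the achievable maximum", {
  m <- toy_model()
  cs <- toy_conditions()$autotrophy$constraints
  maxg <- fba(m, cs)$objective_value
  err <- tryCatch(
    two_phase_light_minimization(m, cs, maxg * 2,
                                 c("EX_lightI", "EX_lightII")),
    error = identity)
  expect_s3_class(err, "error")
  expect_equal(err$max_growth, maxg, tolerance = 1e-8)
})

test_that("FVA collapses to points on a chain and splits parallel routes", {
  ch <- fva(chain_model(cap = 1), fraction_of_optimum = 1)
  # single points up to the width of the objective-fixing band (1e-6 rel.)
  expect_true(all(abs(ch$max_flux - ch$min_flux) < 1e-5))
  pr <- fva(parallel_model(), fraction_of_optimum = 1)
  for (rid in c("ROUTE1", "ROUTE2")) {
    row <- pr[pr$reaction_id == rid, ]
    expect_equal(row$min_flux, 0, tolerance = 1e-7)
    expect_equal(row$max_flux, 1, tolerance = 1e-7)
  }
})

test_that("every FBA flux lies inside its FVA interval", {
  m <- toy_model()
  set.seed(19)
  for (i in 1:5) {
    caps <- runif(2, 0.2, 1)
    cs <- merge_constraints(
      toy_conditions()$mixotrophy$constraints,
      constraint_set(EX_lightI = c(0, caps[1]), EX_lightII = c(0, caps[2])))
    sol <- fba(m, cs)
    rng <- fva(m, cs)
    idx <- match(names(sol$fluxes), rng$reaction_id)
    expect_true(all(sol$fluxes >= rng$min_flux[idx] - 1e-6))
    expect_true(all(sol$fluxes <= rng$max_flux[idx] + 1e-6))
  }
})

test_that("blocked reactions are exactly the dead-end branch", {
  m <- deadend_model()
  rng <- fva(m, fraction_of_optimum = 0)
  blocked <- blocked_reactions(list(rng))
  # reachability oracle: E/F have no boundary exit, so AE and EF can carry
  # no steady-state flux; everything on the A->B->out path can
  expect_setequal(blocked, c("AE", "EF"))
  # blocked in one condition but open in another is not blocked overall
  open_rng <- rng
  open_rng$max_flux[open_rng$reaction_id == "AE"] <- 1
  expect_setequal(blocked_reactions(list(rng, open_rng)), "EF")
  expect_error(blocked_reactions(list(rng, rng[-1, ])), "different reaction")
})

test_that("flux report TSV mirrors the per-condition layout", {
  m <- chain_model()
  sol <- fba(m)
  rng <- fva(m)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_flux_tsv(sol, rng, tf)
  tab <- read.delim(tf)
  expect_named(tab, c("reaction_id", "flux", "min_flux", "max_flux"))
  expect_equal(nrow(tab), length(m$reactions))
})
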