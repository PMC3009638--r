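# Domain types, GPR logic, stoichiometric matrix assembly, connectivity.

test_that("stoichiometric matrix reproduces reaction stoichiometry", {
  mets <- data.frame(id = c("A", "B"), external = c(FALSE, FALSE))
  m <- metabolic_model(mets, list(reaction("R1", c(A = -1, B = 1))),
                       objective = "R1")
  S <- build_stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 1L))
  expect_equal(as.numeric(S[, "R1"]), c(-1, 1))

  mets$external <- c(TRUE, FALSE)  # A becomes a boundary species
  m2 <- metabolic_model(mets, list(reaction("R1", c(A = -1, B = 1))),
                        objective = "R1")
  S2 <- build_stoichiometric_matrix(m2)
  expect_equal(rownames(S2), "B")
  expect_equal(as.numeric(S2["B", "R1"]), 1)
})

test_that("matrix assembly matches a brute-force triple loop", {
  m <- random_structure_model(10, 15, seed = 42)
  S <- as.matrix(build_stoichiometric_matrix(m))
  ref <- matrix(0, length(internal_metabolites(m)), length(m$reactions),
                dimnames = list(internal_metabolites(m), reaction_ids(m)))
  for (rx in m$reactions) {
    for (met in names(rx$stoich)) {
      if (met %in% rownames(ref))
        ref[met, rx$id] <- ref[met, rx$id] + rx$stoich[[met]]
    }
  }
  expect_equal(S, ref)
  expect_equal(ncol(S), length(m$reactions))
  expect_equal(nrow(S), length(internal_metabolites(m)))
})

test_that("unknown metabolite in a reaction raises a structural error", {
  mets <- data.frame(id = "A", external = FALSE)
  expect_error(
    metabolic_model(mets, list(reaction("RX", c(A = -1, ZZZ = 1))),
                    objective = "RX"),
    "RX")
})

test_that("GPR evaluation: complexes, isozymes, nested truth table", {
  complex <- gpr_and("g1", "g2")
  iso <- gpr_or("g1", "g2")
  expect_false(evaluate_gpr(complex, "g1"))
  expect_true(evaluate_gpr(iso, "g1"))
  expect_false(evaluate_gpr(iso, c("g1", "g2")))

  nested <- gpr_or(gpr_and("g1", "g2"), "g3")
  genes <- c("g1", "g2", "g3")
  for (k in 0:7) {
    deleted <- genes[as.logical(bitwAnd(k, c(1L, 2L, 4L)))]
    expected <- (!("g1" %in% deleted) && !("g2" %in% deleted)) ||
      !("g3" %in% deleted)
    expect_identical(evaluate_gpr(nested, deleted), expected)
  }
})

test_that("GPR text parsing round-trips and respects precedence", {
  g <- parse_gpr("(g1 and g2) or g3")
  expect_identical(g$kind, "or")
  # AND binds tighter than OR even without parentheses
  g2 <- parse_gpr("g1 and g2 or g3")
  expect_identical(g2$kind, "or")
  expect_identical(g2$children[[1]]$kind, "and")
  expect_identical(parse_gpr(deparse_gpr(g)), g)
  expect_null(parse_gpr(""))
  expect_error(parse_gpr("g1 and (g2"), "parenthes")
  expect_error(parse_gpr("and g1"), "malformed")
})

test_that("reactions_disabled_by matches a per-reaction GPR sweep", {
  m <- toy_model()
  expect_identical(reactions_disabled_by(m, character()), character())
  expect_error(reactions_disabled_by(m, "not_a_gene"), "unknown gene")
  # single-gene reaction
  expect_true("HK" %in% reactions_disabled_by(m, "glk"))
  # isozyme partner keeps the reaction alive
  expect_false("PYKG" %in% reactions_disabled_by(m, "pyk2a"))
  expect_true("PYKG" %in% reactions_disabled_by(m, c("pyk2a", "pyk2b")))

  set.seed(7)
  for (i in 1:20) {
    del <- sample(m$genes, 2)
    got <- reactions_disabled_by(m, del)
    ref <- names(Filter(function(rx) !is.null(rx$gpr) &&
                          !evaluate_gpr(rx$gpr, del), m$reactions))
    expect_setequal(got, ref)
  }
})

test_that("gene deletion is monotone: more deletions, more disabled", {
  m <- toy_model()
  set.seed(11)
  for (i in 1:10) {
    small <- sample(m$genes, 2)
    large <- c(small, sample(setdiff(m$genes, small), 2))
    expect_true(all(reactions_disabled_by(m, small) %in%
                      reactions_disabled_by(m, large)))
  }
})

test_that("connectivity counts distinct reactions per metabolite", {
  m <- toy_model()
  conn <- metabolite_connectivity(m)
  # independent tally
  tally <- integer(0)
  for (rx in m$reactions) {
    for (met in unique(names(rx$stoich)))
      tally[met] <- (if (is.na(tally[met])) 0L else tally[met]) + 1L
  }
  for (i in seq_len(nrow(conn)))
    expect_identical(conn$neighbor_count[i],
                     unname(tally[conn$metabolite_id[i]]))
  # descending with lexicographic tie-break
  ord <- order(-conn$neighbor_count, conn$metabolite_id)
  expect_identical(ord, seq_len(nrow(conn)))
  # unfiltered total equals sum over reactions of distinct metabolites
  expect_identical(sum(conn$neighbor_count),
                   sum(vapply(m$reactions,
                              function(rx) length(unique(names(rx$stoich))),
                              integer(1))))
  # cofactor filtering removes flagged metabolites
  connf <- metabolite_connectivity(m, filter_cofactors = TRUE)
  expect_false(any(connf$metabolite_id %in%
                     m$metabolites$id[m$metabolites$cofactor]))
})

test_that("connectivity report writes the expected TSV columns", {
  m <- toy_model()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity_tsv(metabolite_connectivity(m), tf)
  tab <- read.delim(tf)
  expect_named(tab, c("metabolite_id", "name", "neighbor_count"))
  expect_gt(nrow(tab), 0)
})
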