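# Reporter-metabolite scoring, background correction, subnetwork search,
# category summaries.

test_that("gene z-scores invert the normal CDF with clamping", {
  d <- expression_dataset(c("g1", "g2", "g3", "g4"),
                          matrix(c(0.5, 1, 0.0228, 0.9), ncol = 1,
                                 dimnames = list(NULL, "c1")))
  z <- gene_zscores(d, "c1")
  expect_equal(unname(z["g1"]), 0, tolerance = 1e-12)
  expect_equal(unname(z["g2"]), qnorm(1e-10), tolerance = 1e-6)
  expect_true(is.finite(z["g2"]))
  expect_equal(unname(z["g3"]), 1.999, tolerance = 1e-3)
  expect_error(gene_zscores(d, "nope"), "absent")
  expect_error(expression_dataset("g1", matrix(1.5)), "g1")
})

test_that("z-scores are antitone in the p-value", {
  p <- sort(runif(50))
  d <- expression_dataset(sprintf("g%02d", 1:50),
                          matrix(p, ncol = 1, dimnames = list(NULL, "c1")))
  z <- gene_zscores(d, "c1")
  expect_true(all(diff(z) <= 0))
})

test_that("raw metabolite scores are neighborhood means", {
  z <- c(a = 2, b = 0, c = 1.3)
  expect_equal(metabolite_raw_score(z, c("a", "b")),
               list(score = 1, n = 2L))
  expect_equal(metabolite_raw_score(z, "c"), list(score = 1.3, n = 1L))
  expect_null(metabolite_raw_score(z, "unmeasured"))
  set.seed(2)
  z5 <- rnorm(5); names(z5) <- letters[1:5]
  expect_equal(metabolite_raw_score(z5, letters[1:5])$score, mean(z5))
})

test_that("background correction standardizes against random aggregates", {
  set.seed(99)
  z <- rnorm(4000)  # standard-normal gene scores
  names(z) <- sprintf("g%04d", seq_along(z))
  bg <- background_distribution(z, sizes = 4, n_samples = 1e5, seed = 7)
  m4 <- bg$by_size[["4"]]$m
  expect_equal(background_correct(m4, 4, bg), 0, tolerance = 1e-12)
  expect_equal(background_correct(m4 + bg$by_size[["4"]]$s, 4, bg), 1,
               tolerance = 1e-12)
  # s_4 ~ 1/sqrt(4), so a raw score of 1 corrects to about 2
  expect_equal(background_correct(1, 4, bg), 2, tolerance = 0.05 * 2 + 0.2)
  expect_error(background_correct(0, 9, bg), "lacks size")
})

test_that("constant gene scores raise a degenerate-input error", {
  m <- toy_model()
  d <- expression_dataset(m$genes,
                          matrix(0.5, length(m$genes), 1,
                                 dimnames = list(NULL, "c1")))
  expect_error(reporter_metabolites(m, d, "c1", seed = 1), "degenerate")
})

test_that("a planted reporter metabolite ranks first", {
  m <- toy_model()
  hits <- 0
  for (seed in 1:8) {
    d <- generate_expression_dataset(m, "pyr", effect_alpha = 0.1,
                                     seed = seed)
    rt <- reporter_metabolites(m, d, "contrast1", bg_samples = 2000,
                               seed = seed + 100)
    expect_identical(rt$rank, seq_len(nrow(rt)))
    if (rt$metabolite_id[1] == "pyr") hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("reporter output is seed-reproducible and order-invariant", {
  m <- toy_model()
  d <- generate_expression_dataset(m, "pyr", effect_alpha = 0.1, seed = 3)
  a <- reporter_metabolites(m, d, "contrast1", bg_samples = 2000, seed = 9)
  b <- reporter_metabolites(m, d, "contrast1", bg_samples = 2000, seed = 9)
  expect_identical(a, b)
  # permute the gene rows of the dataset
  perm <- sample(nrow(d))
  d2 <- expression_dataset(d$gene[perm],
                           matrix(d$contrast1[perm], ncol = 1,
                                  dimnames = list(NULL, "contrast1")))
  c_ <- reporter_metabolites(m, d2, "contrast1", bg_samples = 2000, seed = 9)
  expect_equal(a$corrected_score, c_$corrected_score, tolerance = 1e-9)
})

test_that("greedy subnetwork search recovers a planted co-regulated chain", {
  m <- toy_model()
  chain <- c("gltA", "icd", "aceA", "aceB", "mdh")
  recovered <- 0
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(length(m$genes))
    p[m$genes %in% chain] <- 1e-4
    d <- expression_dataset(m$genes, matrix(p, ncol = 1,
                                            dimnames = list(NULL, "c1")))
    s <- coregulated_subnetwork_search(m, d, "c1", size_limit = 8,
                                      seed = seed + 300, bg_samples = 2000)
    if (length(intersect(s, chain)) >= 4) recovered <- recovered + 1
  }
  expect_gte(recovered, 9)
})

test_that("null subnetwork scores stay well below planted ones", {
  m <- toy_model()
  null_scores <- vapply(1:10, function(seed) {
    d <- generate_expression_dataset(m, character(), effect_alpha = 1,
                                     seed = seed + 40)
    attr(coregulated_subnetwork_search(m, d, "contrast1", size_limit = 8,
                                       seed = seed + 900,
                                       bg_samples = 2000), "score")
  }, numeric(1))
  # greedy maximization inflates the naive N(0,1) scale, but the null
  # never approaches the planted-chain scores (> 5, previous test)
  expect_lt(max(null_scores), 4.5)
})

test_that("a single high-scoring isolated gene is its own subnetwork", {
  mets <- data.frame(id = c("A", "B", "X"),
                     external = c(FALSE, FALSE, TRUE))
  rxs <- list(
    reaction("EX_A", c(X = -1, A = 1), upper_bound = 1),
    reaction("R1", c(A = -1, B = 1), gpr = gpr_gene("lonely")),
    reaction("BIO", c(B = -1)))
  m <- metabolic_model(mets, rxs, objective = "BIO",
                       genes = c("lonely", paste0("bg", 1:30)))
  set.seed(1)
  p <- c(1e-6, runif(30))
  d <- expression_dataset(c("lonely", paste0("bg", 1:30)),
                          matrix(p, ncol = 1, dimnames = list(NULL, "c1")))
  s <- coregulated_subnetwork_search(m, d, "c1", size_limit = 5, seed = 4,
                                     bg_samples = 2000)
  expect_identical(as.character(s), "lonely")
})

test_that("category summaries compute rounded percentages", {
  genes <- sprintf("g%03d", 1:212)
  cmap <- stats::setNames(rep("Other", 212), genes)
  cmap[1:128] <- "Energy Metabolism"
  tab <- category_summary(genes, cmap)
  expect_equal(tab$percent[tab$category == "Energy Metabolism"], 60.38)
  genes2 <- sprintf("h%03d", 1:206)
  cmap2 <- stats::setNames(rep("Other", 206), genes2)
  cmap2[1:127] <- "Energy Metabolism"
  tab2 <- category_summary(genes2, cmap2)
  expect_equal(tab2$percent[tab2$category == "Energy Metabolism"], 61.65)
  # zero-count categories contribute 0.00 and sorting is by count
  tab3 <- category_summary(character(), cmap)
  expect_equal(nrow(tab3), 0)
  expect_true(all(diff(tab$count) <= 0))
})
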