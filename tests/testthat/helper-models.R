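# Fixture builders shared across the test files. Everything is generated in
# code; the toy phototroph and its growth conditions are cached once per
# test run.

toy_cache <- new.env(parent = emptyenv())

toy_model <- function() {
  if (is.null(toy_cache$model))
    toy_cache$model <- generate_toy_phototroph(toy_spec(seed = 1L))
  toy_cache$model
}

toy_conditions <- function() {
  if (is.null(toy_cache$conds))
    toy_cache$conds <- standard_conditions(attr(toy_model(), "uptakes"))
  toy_cache$conds
}

# linear chain: EX_A (capped) -> A -> B -> biomass drain
chain_model <- function(cap = 1, gain = 1) {
  mets <- data.frame(id = c("A", "B", "X"),
                     external = c(FALSE, FALSE, TRUE))
  rxs <- list(
    reaction("EX_A", c(X = -1, A = 1), upper_bound = cap),
    reaction("R1", c(A = -1, B = gain)),
    reaction("BIO", c(B = -1)))
  metabolic_model(mets, rxs, objective = "BIO")
}

# two identical parallel unit-capacity routes from A to B
parallel_model <- function() {
  mets <- data.frame(id = c("A", "B", "X"),
                     external = c(FALSE, FALSE, TRUE))
  rxs <- list(
    reaction("EX_A", c(X = -1, A = 1), upper_bound = 1),
    reaction("ROUTE1", c(A = -1, B = 1), upper_bound = 1),
    reaction("ROUTE2", c(A = -1, B = 1), upper_bound = 1),
    reaction("BIO", c(B = -1)))
  metabolic_model(mets, rxs, objective = "BIO")
}

# small branched network with a capped side branch; all bounds finite so
# the optimum can be cross-checked by vertex enumeration
branched_model <- function() {
  mets <- data.frame(id = c("A", "B", "C", "D", "X"),
                     external = c(rep(FALSE, 4), TRUE))
  rxs <- list(
    reaction("EX_A", c(X = -1, A = 1), upper_bound = 4),
    reaction("AB", c(A = -1, B = 1), upper_bound = 3),
    reaction("AC", c(A = -1, C = 1), upper_bound = 2),
    reaction("BC", c(B = -1, C = 1), reversible = TRUE,
             lower_bound = -1, upper_bound = 1),
    reaction("BD", c(B = -1, D = 1), upper_bound = 2),
    reaction("CD", c(C = -1, D = 2), upper_bound = 2),
    reaction("LEAK", c(C = -1), upper_bound = 1),
    reaction("BIO", c(D = -1), upper_bound = 10))
  metabolic_model(mets, rxs, objective = "BIO")
}

# model with a dangling dead-end branch (E has no exit), used for
# blocked-reaction detection
deadend_model <- function() {
  mets <- data.frame(id = c("A", "B", "E", "F", "X"),
                     external = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  rxs <- list(
    reaction("EX_A", c(X = -1, A = 1), upper_bound = 1),
    reaction("AB", c(A = -1, B = 1)),
    reaction("AE", c(A = -1, E = 1)),
    reaction("EF", c(E = -1, F = 1)),   # F is a dead end
    reaction("BIO", c(B = -1)))
  metabolic_model(mets, rxs, objective = "BIO")
}

# brute-force LP oracle: enumerate candidate vertices of
# {S v = 0, lb <= v <= ub} by activating every choice of n - rank(S)
# bounds, solving the square system, and keeping feasible points
enumerate_vertices <- function(model, constraints = NULL) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  qrS <- qr(t(S))
  S <- S[sort(qrS$pivot[seq_len(qrS$rank)]), , drop = FALSE]
  eb <- synflux:::effective_bounds(model, constraints)
  n <- ncol(S)
  need <- n - nrow(S)
  stopifnot(need >= 0)
  verts <- list()
  combos <- utils::combn(n, need, simplify = FALSE)
  for (act in combos) {
    # each activated variable sits at its lower or upper bound
    grids <- expand.grid(rep(list(c(1, 2)), length(act)))
    for (g in seq_len(nrow(grids))) {
      fixed_vals <- ifelse(unlist(grids[g, ]) == 1,
                           eb$lb[act], eb$ub[act])
      if (any(!is.finite(fixed_vals))) next
      free <- setdiff(seq_len(n), act)
      rhs <- -S[, act, drop = FALSE] %*% fixed_vals
      Sf <- S[, free, drop = FALSE]
      if (nrow(Sf) != length(free)) next
      sol <- tryCatch(solve(Sf, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n)
      v[act] <- fixed_vals
      v[free] <- sol
      if (all(v >= eb$lb - 1e-8) && all(v <= eb$ub + 1e-8))
        verts[[length(verts) + 1L]] <- v
    }
  }
  verts
}

# random well-formed model for structural tests (not necessarily growable)
random_structure_model <- function(n_mets = 10, n_rxns = 15, seed = 1) {
  set.seed(seed)
  ids <- sprintf("M%02d", seq_len(n_mets))
  mets <- data.frame(id = ids,
                     external = c(rep(FALSE, n_mets - 2), TRUE, TRUE))
  rxs <- lapply(seq_len(n_rxns), function(k) {
    nm <- sample(ids, sample(2:4, 1))
    coefs <- sample(c(-2, -1, 1, 2), length(nm), replace = TRUE)
    if (all(coefs > 0)) coefs[1] <- -coefs[1]
    if (all(coefs < 0)) coefs[length(coefs)] <- -coefs[length(coefs)]
    reaction(sprintf("R%02d", k), stats::setNames(coefs, nm),
             reversible = runif(1) < 0.4)
  })
  metabolic_model(mets, rxs, objective = "R01")
}
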