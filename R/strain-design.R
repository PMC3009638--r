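# Knockout strain design: evaluate reaction-deletion sets against a design
# objective (e.g. succinate or H2 export) with FBA or MOMA setting the inner
# flux state; exhaustive enumeration and an evolutionary (genetic-algorithm)
# search over binary deletion vectors.

#' Candidate reactions for knockout design
#'
#' Exchange/transport reactions (those touching an external metabolite),
#' spontaneous reactions (no cognate genes) and the biomass/design reactions
#' are excluded: knocking out an uptake trivially dominates otherwise.
#'
#' @param model A `metabolic_model`.
#' @param design_reaction Design objective reaction id (excluded).
#' @return Character vector of reaction ids.
#' @export
design_candidates <- function(model, design_reaction) {
  ext <- model$metabolites$id[model$metabolites$external]
  ok <- vapply(model$reactions, function(rx) {
    !is.null(rx$gpr) && !any(names(rx$stoich) %in% ext)
  }, logical(1))
  setdiff(names(model$reactions)[ok], c(model$objective, design_reaction))
}

# Smallest gene sets whose deletion disables a reaction's GPR rule
# (lexicographically-first minimal hitting set; rules are small).
min_gene_knockout <- function(gpr) {
  genes <- sort(gpr_genes(gpr))
  if (length(genes) == 0L) return(character())
  for (size in seq_along(genes)) {
    combs <- utils::combn(genes, size, simplify = FALSE)
    for (cand in combs) {
      if (!evaluate_gpr(gpr, cand)) return(cand)
    }
  }
  character()
}

#' Evaluate one knockout design
#'
#' @param model A `metabolic_model`.
#' @param constraints Optional [constraint_set()] (growth condition).
#' @param deletions Character vector of knocked-out reaction ids.
#' @param design_reaction Reaction whose flux is the design objective
#'   (an exchange/drain for the target metabolite).
#' @param inner `"MOMA"` (biological objective: minimal adjustment from the
#'   wild type) or `"FBA"` (mutant grows optimally).
#' @param wild_type Wild-type reference `flux_distribution` (required for
#'   MOMA; computed by FBA if missing).
#' @return A list of class `design_result`: `deletions`, `genes` (minimal
#'   gene knockouts implying each reaction deletion), `production`,
#'   `growth`, `inner`, `feasible`.
#' @export
evaluate_design <- function(model, constraints = NULL, deletions = character(),
                            design_reaction, inner = c("MOMA", "FBA"),
                            wild_type = NULL) {
  inner <- match.arg(inner)
  stopifnot(design_reaction %in% reaction_ids(model))
  stopifnot(all(deletions %in% reaction_ids(model)))
  if (is.null(wild_type)) wild_type <- fba(model, constraints)
  if (inner == "MOMA") {
    st <- moma(model, constraints, disabled = deletions, wild_type = wild_type)
    fluxes <- st$fluxes; growth <- st$growth
  } else {
    st <- fba(model, constraints, disabled = deletions)
    fluxes <- st$fluxes; growth <- st$objective_value
  }
  feasible <- is_feasible(st)
  production <- if (feasible) unname(fluxes[design_reaction]) else 0
  growth <- if (feasible) unname(growth) else 0
  genes <- lapply(deletions, function(rid) {
    min_gene_knockout(model$reactions[[rid]]$gpr)
  })
  names(genes) <- deletions
  structure(list(deletions = sort(deletions), genes = genes,
                 production = production, growth = growth,
                 inner = inner, feasible = feasible,
                 fluxes = fluxes),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("Knockout design (", x$inner, ")\n", sep = "")
  cat("  deletions:  ", if (length(x$deletions)) paste(x$deletions, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat(sprintf("  production: %.6g\n  growth:     %.6g\n", x$production, x$growth))
  invisible(x)
}

#' Exhaustive knockout search
#'
#' Evaluates all deletion sets of size at most `k` over the candidate
#' reactions, ranks by production (ties broken by deletion ids), and filters
#' by a minimum growth fraction of the wild type.
#'
#' @inheritParams evaluate_design
#' @param k Maximum number of simultaneous deletions.
#' @param min_growth_fraction Designs growing below this fraction of the
#'   wild-type growth are dropped (default 0.1).
#' @param candidates Candidate reactions (default [design_candidates()]).
#' @param guard Maximum number of deletion sets to enumerate.
#' @return Data frame ranked by production: `rank`, `deletions`, `genes`,
#'   `production`, `growth`; full `design_result`s in attribute `"results"`.
#' @export
exhaustive_knockout_search <- function(model, constraints = NULL, k,
                                       design_reaction,
                                       min_growth_fraction = 0.1,
                                       inner = c("MOMA", "FBA"),
                                       wild_type = NULL,
                                       candidates = NULL, guard = 20000L) {
  inner <- match.arg(inner)
  if (is.null(candidates)) candidates <- design_candidates(model, design_reaction)
  candidates <- sort(candidates)
  n_sets <- sum(vapply(0:k, function(s) choose(length(candidates), s), numeric(1)))
  if (n_sets > guard)
    stop("exhaustive search over ", n_sets, " deletion sets exceeds the guard (",
         guard, "); use evolutionary_knockout_search()")
  if (is.null(wild_type)) wild_type <- fba(model, constraints)
  if (!is_feasible(wild_type)) stop("wild type infeasible")
  wt_growth <- wild_type$objective_value

  sets <- list(character())
  if (k >= 1) {
    for (s in seq_len(k)) {
      if (s > length(candidates)) break
      sets <- c(sets, utils::combn(candidates, s, simplify = FALSE))
    }
  }
  results <- lapply(sets, function(del) {
    evaluate_design(model, constraints, del, design_reaction, inner, wild_type)
  })
  keep <- vapply(results, function(r) {
    r$feasible && r$growth >= min_growth_fraction * wt_growth
  }, logical(1))
  results <- results[keep]
  if (length(results) == 0L)
    return(data.frame(rank = integer(), deletions = character(),
                      genes = character(), production = numeric(),
                      growth = numeric(), stringsAsFactors = FALSE))
  del_str <- vapply(results, function(r)
    paste(r$deletions, collapse = ","), character(1))
  prod <- vapply(results, `[[`, numeric(1), "production")
  growth <- vapply(results, `[[`, numeric(1), "growth")
  ord <- order(-prod, del_str)
  out <- data.frame(
    rank = seq_along(ord),
    deletions = del_str[ord],
    genes = vapply(results[ord], function(r)
      paste(unlist(lapply(r$genes, paste, collapse = "+")), collapse = ";"),
      character(1)),
    production = prod[ord],
    growth = growth[ord],
    stringsAsFactors = FALSE)
  attr(out, "results") <- results[ord]
  attr(out, "wt_growth") <- wt_growth
  out
}

#' Evolutionary (OptGene-style) knockout search
#'
#' Genetic algorithm over binary reaction-deletion vectors with at most `k`
#' set bits. Fitness is the design-reaction production of
#' [evaluate_design()], zero when the growth filter fails. Tournament
#' selection, uniform crossover, bit-flip mutation, elitism of one; a seed
#' is mandatory so runs are reproducible.
#'
#' @inheritParams exhaustive_knockout_search
#' @param population Population size.
#' @param generations Number of generations.
#' @param mutation_rate Per-bit flip probability.
#' @param seed Integer RNG seed (required).
#' @return The best `design_result` found; the fitness trajectory is in
#'   attribute `"history"`.
#' @export
evolutionary_knockout_search <- function(model, constraints = NULL, k,
                                         design_reaction,
                                         min_growth_fraction = 0.1,
                                         inner = c("MOMA", "FBA"),
                                         wild_type = NULL,
                                         candidates = NULL,
                                         population = 40L, generations = 200L,
                                         mutation_rate = 0.02, seed) {
  inner <- match.arg(inner)
  if (missing(seed)) stop("a seed is required for the evolutionary search")
  if (is.null(candidates)) candidates <- design_candidates(model, design_reaction)
  candidates <- sort(candidates)
  nb <- length(candidates)
  if (is.null(wild_type)) wild_type <- fba(model, constraints)
  if (!is_feasible(wild_type)) stop("wild type infeasible")
  wt_growth <- wild_type$objective_value

  cap_bits <- function(bits) {
    on <- which(bits)
    if (length(on) > k) bits[sample(on, length(on) - k)] <- FALSE
    bits
  }
  cache <- new.env(parent = emptyenv())
  fitness <- function(bits) {
    key <- paste0("k", paste(which(bits), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- evaluate_design(model, constraints, candidates[bits],
                           design_reaction, inner, wild_type)
    fit <- if (res$feasible && res$growth >= min_growth_fraction * wt_growth)
      res$production else 0
    cache[[key]] <- fit
    fit
  }

  set.seed(seed)
  pop <- lapply(seq_len(population), function(i) {
    bits <- rep(FALSE, nb)
    n_on <- sample(0:k, 1)
    if (n_on > 0) bits[sample(nb, n_on)] <- TRUE
    bits
  })
  fits <- vapply(pop, fitness, numeric(1))
  history <- numeric(generations)

  for (gen in seq_len(generations)) {
    elite <- pop[[which.max(fits)]]
    next_pop <- list(elite)
    while (length(next_pop) < population) {
      pick <- function() {
        ij <- sample(population, 2L)
        if (fits[ij[1]] >= fits[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
      }
      p1 <- pick(); p2 <- pick()
      mask <- stats::runif(nb) < 0.5
      child <- ifelse(mask, p1, p2)
      flips <- stats::runif(nb) < mutation_rate
      child <- xor(child, flips)
      next_pop[[length(next_pop) + 1L]] <- cap_bits(child)
    }
    pop <- next_pop
    fits <- vapply(pop, fitness, numeric(1))
    history[gen] <- max(fits)
  }
  best <- pop[[which.max(fits)]]
  out <- evaluate_design(model, constraints, candidates[best],
                         design_reaction, inner, wild_type)
  attr(out, "history") <- history
  out
}

#' Write a ranked design report as TSV
#' @param designs Output of [exhaustive_knockout_search()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_design_tsv <- function(designs, path) {
  tab <- designs
  tab$production <- signif(tab$production, 6)
  tab$growth <- signif(tab$growth, 6)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
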