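# Flux balance analysis, two-phase photon minimization, flux variability
# analysis, blocked-reaction detection.

#' Construct a constraint set
#'
#' A constraint set overlays per-reaction flux bounds on a model's defaults
#' and may carry coupling rows, i.e. linear constraints over several fluxes
#' (used e.g. for a joint carbon-uptake cap over CO2 and bicarbonate).
#'
#' @param ... Named arguments, each a numeric length-2 `c(lower, upper)`
#'   bound for the reaction of that name, or a single list of such bounds.
#' @param couplings Optional list of `list(coef = <named numeric>, lower,
#'   upper)` coupling rows; `coef` names are reaction ids.
#' @return A list with class `constraint_set`.
#' @export
constraint_set <- function(..., couplings = NULL) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && is.list(args[[1]]))
    args <- args[[1]]
  for (nm in names(args)) {
    b <- args[[nm]]
    if (!is.numeric(b) || length(b) != 2L)
      stop("bound for '", nm, "' must be c(lower, upper)")
    if (b[1] > b[2]) stop("bound for '", nm, "' has lower > upper")
  }
  structure(list(bounds = args, couplings = couplings), class = "constraint_set")
}

#' Merge two constraint sets (later entries override)
#' @param a,b `constraint_set` objects (or `NULL`).
#' @return A `constraint_set`.
#' @export
merge_constraints <- function(a, b) {
  if (is.null(a)) return(b %||% constraint_set())
  if (is.null(b)) return(a)
  bounds <- a$bounds
  bounds[names(b$bounds)] <- b$bounds
  constraint_set(bounds, couplings = c(a$couplings, b$couplings))
}

# Effective lb/ub vectors for a model under a constraint set and a list of
# disabled reactions (forced to zero flux).
effective_bounds <- function(model, constraints = NULL, disabled = character()) {
  rids <- reaction_ids(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "constraint_set"))
    unknown <- setdiff(names(constraints$bounds), rids)
    if (length(unknown))
      stop("constraints for unknown reaction(s): ", paste(unknown, collapse = ", "))
    for (nm in names(constraints$bounds)) {
      lb[nm] <- constraints$bounds[[nm]][1]
      ub[nm] <- constraints$bounds[[nm]][2]
    }
  }
  if (length(disabled)) {
    unknown <- setdiff(disabled, rids)
    if (length(unknown))
      stop("disabled reaction(s) not in model: ", paste(unknown, collapse = ", "))
    lb[disabled] <- 0
    ub[disabled] <- 0
  }
  list(lb = lb, ub = ub)
}

# Expand coupling coefficient maps to dense vectors over the reaction order.
expand_couplings <- function(model, constraints) {
  if (is.null(constraints) || is.null(constraints$couplings)) return(NULL)
  rids <- reaction_ids(model)
  lapply(constraints$couplings, function(cp) {
    coef <- numeric(length(rids)); names(coef) <- rids
    unknown <- setdiff(names(cp$coef), rids)
    if (length(unknown))
      stop("coupling over unknown reaction(s): ", paste(unknown, collapse = ", "))
    coef[names(cp$coef)] <- cp$coef
    list(coef = unname(coef), lower = cp$lower %||% -Inf, upper = cp$upper %||% Inf)
  })
}

.flux_distribution <- function(fluxes, objective_value, status,
                               objective = NA_character_) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, objective = objective),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Flux distribution (", x$status, ")\n", sep = "")
  if (is_feasible(x))
    cat(sprintf("  objective %s = %.6g\n", x$objective, x$objective_value))
  invisible(x)
}

#' Is a solver result feasible?
#' @param x A `flux_distribution` or `moma_solution`.
#' @return Logical.
#' @export
is_feasible <- function(x) identical(x$status, "optimal")

#' Maximum mass-balance residual of a flux vector
#' @param model A `metabolic_model`.
#' @param fluxes Named flux vector over all reactions.
#' @return `max |S v|` over internal metabolites.
#' @export
mass_balance_residual <- function(model, fluxes) {
  S <- build_stoichiometric_matrix(model)
  max(abs(as.numeric(S %*% fluxes[colnames(S)])))
}

#' Flux balance analysis
#'
#' Solves the steady-state linear program: optimize the objective reaction's
#' flux subject to `S v = 0` and the effective flux bounds.
#'
#' @param model A `metabolic_model`.
#' @param constraints Optional [constraint_set()] overlay.
#' @param objective Objective reaction id (default: the model's biomass).
#' @param sense `"max"` or `"min"`.
#' @param disabled Reaction ids forced to zero flux (knockouts).
#' @return A `flux_distribution`; check [is_feasible()] — an infeasible
#'   constraint system is reported as status `"infeasible"`, distinct from a
#'   feasible model with zero growth.
#' @export
fba <- function(model, constraints = NULL, objective = model$objective,
                sense = c("max", "min"), disabled = character()) {
  sense <- match.arg(sense)
  rids <- reaction_ids(model)
  if (!objective %in% rids) stop("objective reaction '", objective, "' not in model")
  S <- build_stoichiometric_matrix(model)
  eb <- effective_bounds(model, constraints, disabled)
  obj <- as.numeric(rids == objective)
  sol <- solve_lp(S, eb$lb, eb$ub, obj, sense = sense,
                  couplings = expand_couplings(model, constraints))
  if (sol$status != "optimal")
    return(.flux_distribution(NULL, NA_real_, sol$status, objective))
  if (abs(sol$objective) >= 0.999 * flux_inf())
    stop("objective '", objective, "' is unbounded")
  .flux_distribution(sol$v, sol$objective, "optimal", objective)
}

# Shared internal: optimize an arbitrary linear objective over the flux space.
solve_flux_lp <- function(model, constraints, obj_vec, sense,
                          disabled = character()) {
  S <- build_stoichiometric_matrix(model)
  eb <- effective_bounds(model, constraints, disabled)
  solve_lp(S, eb$lb, eb$ub, obj_vec, sense = sense,
           couplings = expand_couplings(model, constraints))
}

#' Two-phase photon-uptake minimization
#'
#' Phase 1 (implicitly done by the caller or here as a feasibility check)
#' establishes that `target_growth` is attainable; phase 2 fixes growth at
#' the target (two-sided band, relative half-width 1e-6) and minimizes the
#' summed flux through the photon uptake reactions.
#'
#' @param model A `metabolic_model`.
#' @param constraints Optional [constraint_set()].
#' @param target_growth Growth rate (1/h) to hold fixed.
#' @param photon_reactions Ids of the photon uptake reactions.
#' @return A `flux_distribution` with attributes `photon_total` (minimized
#'   summed photon flux) and `photon_fluxes` (per-reaction uptake).
#' @export
two_phase_light_minimization <- function(model, constraints = NULL,
                                         target_growth,
                                         photon_reactions) {
  rids <- reaction_ids(model)
  stopifnot(all(photon_reactions %in% rids))
  wt <- fba(model, constraints)
  if (!is_feasible(wt)) stop("model infeasible under the supplied constraints")
  if (wt$objective_value < target_growth * (1 - 1e-6)) {
    e <- simpleError(sprintf(
      "target growth %.6g exceeds maximum achievable %.6g",
      target_growth, wt$objective_value))
    e$max_growth <- wt$objective_value
    stop(e)
  }
  band <- constraint_set(
    stats::setNames(list(c(target_growth * (1 - 1e-6),
                           target_growth * (1 + 1e-6))),
                    model$objective))
  cs <- merge_constraints(constraints, band)
  obj <- as.numeric(rids %in% photon_reactions)
  sol <- solve_flux_lp(model, cs, obj, "min")
  if (sol$status != "optimal")
    stop("phase-2 photon minimization failed: ", sol$status)
  out <- .flux_distribution(sol$v, sol$v[model$objective], "optimal",
                            model$objective)
  attr(out, "photon_total") <- sum(sol$v[photon_reactions])
  attr(out, "photon_fluxes") <- sol$v[photon_reactions]
  out
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum feasible flux subject to the
#' objective being held at `fraction_of_optimum` times its FBA optimum
#' (2 x #reactions linear programs).
#'
#' @param model A `metabolic_model`.
#' @param constraints Optional [constraint_set()].
#' @param objective Objective reaction id.
#' @param fraction_of_optimum Fraction in [0, 1] of the optimum to enforce.
#' @param reactions Reactions to scan (default: all).
#' @param disabled Reaction ids forced to zero.
#' @return A data frame of class `flux_range` with columns `reaction_id`,
#'   `min_flux`, `max_flux`. Fluxes at the solver's finite infinity are
#'   reported as `-Inf`/`Inf`.
#' @export
fva <- function(model, constraints = NULL, objective = model$objective,
                fraction_of_optimum = 1, reactions = NULL,
                disabled = character()) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  rids <- reaction_ids(model)
  if (is.null(reactions)) reactions <- rids
  stopifnot(all(reactions %in% rids))
  opt <- fba(model, constraints, objective, disabled = disabled)
  if (!is_feasible(opt))
    stop("FVA: model infeasible under the supplied constraints")
  target <- fraction_of_optimum * opt$objective_value
  lo <- if (target >= 0) target * (1 - 1e-6) else target * (1 + 1e-6)
  cs <- merge_constraints(
    constraints,
    constraint_set(stats::setNames(list(c(lo, Inf)), objective)))
  big <- flux_inf()
  S <- build_stoichiometric_matrix(model)
  eb <- effective_bounds(model, cs, disabled)
  cps <- expand_couplings(model, cs)
  mn <- mx <- numeric(length(reactions))
  state <- NULL  # warm-start basis shared across the 2n subproblems
  for (k in seq_along(reactions)) {
    obj <- as.numeric(rids == reactions[k])
    lo_sol <- solve_lp(S, eb$lb, eb$ub, obj, "min", couplings = cps,
                       warm = state)
    if (lo_sol$status == "optimal") state <- lo_sol$state
    hi_sol <- solve_lp(S, eb$lb, eb$ub, obj, "max", couplings = cps,
                       warm = state)
    if (hi_sol$status == "optimal") state <- hi_sol$state
    if (lo_sol$status != "optimal" || hi_sol$status != "optimal")
      stop("FVA subproblem infeasible for reaction '", reactions[k], "'")
    mn[k] <- lo_sol$objective
    mx[k] <- hi_sol$objective
  }
  mn[mn <= -0.999 * big] <- -Inf
  mx[mx >= 0.999 * big] <- Inf
  out <- data.frame(reaction_id = reactions, min_flux = mn, max_flux = mx,
                    stringsAsFactors = FALSE)
  class(out) <- c("flux_range", "data.frame")
  attr(out, "objective_value") <- opt$objective_value
  out
}

#' Reactions blocked in every condition
#'
#' @param ranges A list of `flux_range` objects over the same reaction set
#'   (one per growth condition).
#' @param tol Absolute flux tolerance below which a bound counts as zero.
#' @return Character vector of reaction ids whose feasible interval is
#'   `{0}` (within `tol`) in every supplied condition.
#' @export
blocked_reactions <- function(ranges, tol = 1e-6) {
  stopifnot(length(ranges) >= 1L)
  ref <- sort(ranges[[1]]$reaction_id)
  for (r in ranges) {
    if (!identical(sort(r$reaction_id), ref))
      stop("flux ranges cover different reaction sets")
  }
  blocked <- ref
  for (r in ranges) {
    idx <- match(blocked, r$reaction_id)
    ok <- abs(r$min_flux[idx]) < tol & abs(r$max_flux[idx]) < tol
    blocked <- blocked[ok]
  }
  blocked
}

#' Write a per-condition flux report as TSV
#'
#' Columns: `reaction_id`, `flux`, `min_flux`, `max_flux`.
#'
#' @param flux A `flux_distribution`.
#' @param range A `flux_range` over the same reactions.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_flux_tsv <- function(flux, range, path) {
  stopifnot(is_feasible(flux))
  idx <- match(range$reaction_id, names(flux$fluxes))
  tab <- data.frame(reaction_id = range$reaction_id,
                    flux = signif(flux$fluxes[idx], 6),
                    min_flux = signif(range$min_flux, 6),
                    max_flux = signif(range$max_flux, 6),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
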