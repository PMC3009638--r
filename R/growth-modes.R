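# Growth-regime setup for photoautotrophs: carbon/photon normalization
# arithmetic, photon-capture geometry, the four growth conditions
# (autotrophy, dark/light heterotrophy, mixotrophy) and the cross-condition
# FBA/FVA comparison pipeline.

#' Carbon-normalized uptake rate
#'
#' Converts a total carbon flux (mmol C/gDW/h) into a molecular uptake rate
#' by dividing by the carbon atoms per molecule, so different carbon sources
#' are fed at matched carbon. Mono-carbon sources (CO2, bicarbonate) are
#' unaffected; a 6-carbon sugar like glucose takes one sixth of the flux.
#'
#' @param total_carbon_flux Total carbon flux in mmol C/gDW/h.
#' @param carbons_per_molecule Carbon atoms per substrate molecule (>= 1).
#' @return Uptake in mmol/gDW/h.
#' @export
carbon_normalized_uptake <- function(total_carbon_flux, carbons_per_molecule) {
  if (carbons_per_molecule < 1)
    stop("carbons_per_molecule must be at least 1")
  total_carbon_flux / carbons_per_molecule
}

#' Cell geometry for photon-capture estimates
#'
#' @param radius_m Cell radius in meters.
#' @param dry_mass_g Cell dry mass in grams.
#' @param incident_flux Incident photon flux in mE/m^2/s.
#' @return A list of class `cell_geometry`.
#' @export
cell_geometry <- function(radius_m = 1.75e-6, dry_mass_g = 0.5e-12,
                          incident_flux = 0.15) {
  stopifnot(radius_m > 0, dry_mass_g > 0, incident_flux >= 0)
  structure(list(radius_m = radius_m, dry_mass_g = dry_mass_g,
                 incident_flux = incident_flux),
            class = "cell_geometry")
}

#' Theoretical maximum photon uptake of a spherical cell
#'
#' The incident flux intercepted by the cell's spherical surface (4 pi r^2),
#' per gram dry weight, per hour:
#' `incident_flux * 4 * pi * r^2 / mass * 3600` (mE/gDW/h). With the default
#' geometry (r = 1.75 um, 0.5 pg, 0.15 mE/m^2/s) this is about 4.16e4.
#'
#' @param geom A [cell_geometry()].
#' @return Maximum photon uptake in mE/gDW/h.
#' @export
max_photon_uptake <- function(geom = cell_geometry()) {
  stopifnot(inherits(geom, "cell_geometry"))
  geom$incident_flux * 4 * pi * geom$radius_m^2 / geom$dry_mass_g * 3600
}

#' Uptake-reaction map
#'
#' Names the model reactions that the condition builder manipulates.
#'
#' @param glucose,co2,hco3 Exchange reaction ids for the carbon sources
#'   (`hco3` may be `NA` when absent).
#' @param photons Ids of the photon uptake reactions (photosystems I/II).
#' @param maintenance Id of the ATP-maintenance hydrolysis reaction.
#' @return A list of class `uptake_map`.
#' @export
uptake_map <- function(glucose, co2, hco3 = NA_character_, photons,
                       maintenance) {
  structure(list(glucose = glucose, co2 = co2, hco3 = hco3,
                 photons = photons, maintenance = maintenance),
            class = "uptake_map")
}

.growth_modes <- c("autotrophy", "dark_heterotrophy",
                   "light_heterotrophy", "mixotrophy")

#' Build a growth condition
#'
#' Encodes the four growth regimes as constraint sets over the uptake
#' reactions, with carbon sources matched by [carbon_normalized_uptake()]:
#' autotrophy feeds CO2 + bicarbonate (jointly capped at the total carbon
#' flux) plus photons; dark heterotrophy feeds glucose only with photon
#' uptake fixed to zero; light heterotrophy adds photons to the glucose
#' feed; mixotrophy splits the carbon between glucose and CO2 by
#' `glucose_carbon_fraction` with photons open. Maintenance ATP hydrolysis
#' is fixed at `maintenance_atp` x the glucose-equivalent uptake
#' (total carbon / 6) in every mode.
#'
#' @param mode One of `"autotrophy"`, `"dark_heterotrophy"`,
#'   `"light_heterotrophy"`, `"mixotrophy"`.
#' @param uptakes An [uptake_map()] naming the model's uptake reactions.
#' @param total_carbon_flux Total carbon feed in mmol C/gDW/h (default 3.4).
#' @param photon_cap Per-photosystem photon uptake cap in mE/gDW/h
#'   (default 0.8).
#' @param glucose_carbon_fraction Mixotrophy: fraction of carbon fed as
#'   glucose (default 0.5).
#' @param maintenance_atp ATP moles per mole glucose-equivalent carbon
#'   (default 1.67).
#' @param glucose_max,co2_max Literature uptake maxima (mmol/gDW/h) against
#'   which the derived caps are checked (defaults 0.85 and 3.7).
#' @param override Skip the literature-maximum check.
#' @return A list of class `growth_condition` with `mode` and `constraints`
#'   (a [constraint_set()] including the joint-carbon coupling where
#'   needed).
#' @export
make_condition <- function(mode, uptakes, total_carbon_flux = 3.4,
                           photon_cap = 0.8, glucose_carbon_fraction = 0.5,
                           maintenance_atp = 1.67,
                           glucose_max = 0.85, co2_max = 3.7,
                           override = FALSE) {
  mode <- match.arg(mode, .growth_modes)
  stopifnot(inherits(uptakes, "uptake_map"))
  glc_uptake <- carbon_normalized_uptake(total_carbon_flux, 6)
  maint <- maintenance_atp * glc_uptake

  bounds <- list()
  couplings <- NULL
  zero <- c(0, 0)
  photons_closed <- stats::setNames(rep(list(zero), length(uptakes$photons)),
                                    uptakes$photons)
  photons_open <- stats::setNames(rep(list(c(0, photon_cap)),
                                      length(uptakes$photons)),
                                  uptakes$photons)
  has_hco3 <- !is.na(uptakes$hco3)

  if (mode == "autotrophy") {
    bounds[[uptakes$glucose]] <- zero
    bounds[[uptakes$co2]] <- c(-Inf, total_carbon_flux)
    if (has_hco3) bounds[[uptakes$hco3]] <- c(0, total_carbon_flux)
    bounds <- c(bounds, photons_open)
    # net carbon capped jointly; the CO2/bicarbonate split is the solver's
    coef <- stats::setNames(1, uptakes$co2)
    if (has_hco3) coef <- c(coef, stats::setNames(1, uptakes$hco3))
    couplings <- list(list(coef = coef, lower = -Inf,
                           upper = total_carbon_flux))
    if (!override && total_carbon_flux > co2_max + if (has_hco3) co2_max else 0)
      stop("carbon cap exceeds literature CO2 uptake maximum; set override = TRUE")
  } else if (mode %in% c("dark_heterotrophy", "light_heterotrophy")) {
    if (!override && glc_uptake > glucose_max)
      stop("glucose cap ", signif(glc_uptake, 4),
           " exceeds literature maximum ", glucose_max,
           "; set override = TRUE")
    bounds[[uptakes$glucose]] <- c(0, glc_uptake)
    bounds[[uptakes$co2]] <- c(-Inf, 0)
    if (has_hco3) bounds[[uptakes$hco3]] <- zero
    bounds <- c(bounds, if (mode == "dark_heterotrophy") photons_closed
                        else photons_open)
  } else { # mixotrophy
    f <- glucose_carbon_fraction
    stopifnot(f >= 0, f <= 1)
    glc_cap <- carbon_normalized_uptake(f * total_carbon_flux, 6)
    co2_cap <- (1 - f) * total_carbon_flux
    if (!override && glc_cap > glucose_max)
      stop("glucose cap exceeds literature maximum; set override = TRUE")
    if (!override && co2_cap > co2_max)
      stop("CO2 cap exceeds literature maximum; set override = TRUE")
    bounds[[uptakes$glucose]] <- c(0, glc_cap)
    bounds[[uptakes$co2]] <- c(-Inf, co2_cap)
    if (has_hco3) bounds[[uptakes$hco3]] <- zero
    bounds <- c(bounds, photons_open)
  }
  bounds[[uptakes$maintenance]] <- c(maint, maint)
  structure(list(mode = mode,
                 constraints = constraint_set(bounds, couplings = couplings),
                 total_carbon_flux = total_carbon_flux,
                 photon_cap = photon_cap,
                 maintenance_flux = maint),
            class = "growth_condition")
}

#' Build all four growth conditions
#' @inheritParams make_condition
#' @return Named list of `growth_condition` objects.
#' @export
standard_conditions <- function(uptakes, total_carbon_flux = 3.4,
                                photon_cap = 0.8,
                                glucose_carbon_fraction = 0.5,
                                maintenance_atp = 1.67) {
  stats::setNames(lapply(.growth_modes, make_condition, uptakes = uptakes,
                         total_carbon_flux = total_carbon_flux,
                         photon_cap = photon_cap,
                         glucose_carbon_fraction = glucose_carbon_fraction,
                         maintenance_atp = maintenance_atp),
                  .growth_modes)
}

#' Run the cross-condition comparison suite
#'
#' FBA and FVA per condition, blocked reactions across all conditions, and
#' a per-reaction comparison table of point fluxes with their feasible
#' ranges (degenerate FBA optima make the point flux arbitrary within its
#' range, which is why ranges are reported alongside).
#'
#' @param model A `metabolic_model`.
#' @param conditions Named list of `growth_condition` objects.
#' @param fraction_of_optimum FVA fraction (default 1).
#' @return A list of class `growth_mode_suite`: `solutions` (per-condition
#'   `flux_distribution` or `NULL` when infeasible), `ranges`, `blocked`,
#'   `comparison` (wide data frame), `growth` (named growth-rate vector).
#' @export
run_growth_mode_suite <- function(model, conditions,
                                  fraction_of_optimum = 1) {
  stopifnot(length(conditions) >= 1L, !is.null(names(conditions)))
  solutions <- list(); ranges <- list(); growth <- numeric()
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    sol <- fba(model, cond$constraints)
    if (!is_feasible(sol)) {
      warning("condition '", nm, "' is infeasible; skipped")
      solutions[nm] <- list(NULL)
      next
    }
    solutions[[nm]] <- sol
    growth[nm] <- sol$objective_value
    ranges[[nm]] <- fva(model, cond$constraints,
                        fraction_of_optimum = fraction_of_optimum)
  }
  if (length(ranges) == 0L) stop("all conditions infeasible")
  blocked <- blocked_reactions(unname(ranges))
  rids <- reaction_ids(model)
  comparison <- data.frame(reaction_id = rids, stringsAsFactors = FALSE)
  for (nm in names(ranges)) {
    idx <- match(rids, ranges[[nm]]$reaction_id)
    comparison[[paste0(nm, "_flux")]] <- signif(solutions[[nm]]$fluxes[rids], 6)
    comparison[[paste0(nm, "_min")]] <- signif(ranges[[nm]]$min_flux[idx], 6)
    comparison[[paste0(nm, "_max")]] <- signif(ranges[[nm]]$max_flux[idx], 6)
  }
  structure(list(solutions = solutions, ranges = ranges, blocked = blocked,
                 comparison = comparison, growth = growth),
            class = "growth_mode_suite")
}

#' @export
print.growth_mode_suite <- function(x, ...) {
  cat("Growth-mode comparison suite\n")
  for (nm in names(x$growth))
    cat(sprintf("  %-20s growth %.6g /h\n", nm, x$growth[nm]))
  cat(sprintf("  blocked in all conditions: %d reaction(s)\n",
              length(x$blocked)))
  invisible(x)
}

#' Per-reaction net carbon imbalance
#'
#' Sum of stoichiometric coefficient x carbon count per reaction, using the
#' model's carbon bookkeeping; metabolites with unknown carbon count are
#' treated as zero. Exchange reactions and the biomass drain are expected
#' to be non-zero (they move carbon across the boundary).
#'
#' @param model A `metabolic_model`.
#' @return Named numeric vector of net carbon per unit flux.
#' @export
reaction_carbon_imbalance <- function(model) {
  carbon <- stats::setNames(model$metabolites$carbon, model$metabolites$id)
  carbon[is.na(carbon)] <- 0
  vapply(model$reactions, function(rx) {
    sum(rx$stoich * carbon[names(rx$stoich)])
  }, numeric(1))
}
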