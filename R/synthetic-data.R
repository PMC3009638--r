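# Synthetic data generators: a toy photoautotroph genome-scale model with
# the structural features of a cyanobacterial network (two photosystems,
# Calvin cycle, incomplete TCA cycle completed by the glyoxylate shunt,
# dual-cofactor pyruvate kinases, bidirectional hydrogenase, multi-precursor
# biomass drain, complex and isozyme GPRs), plus planted-signal expression
# datasets, so every pipeline stage is testable without external downloads.

#' Toy phototroph specification
#'
#' @param seed Integer seed recorded with the model (generation is
#'   deterministic).
#' @param include_hydrogenase Include the bidirectional NiFe hydrogenase
#'   and the H2 exchange.
#' @param include_glyoxylate_shunt Include isocitrate lyase and malate
#'   synthase (without them the TCA branch downstream of 2-oxoglutarate is
#'   dead-ended, as the cycle lacks 2-oxoglutarate dehydrogenase).
#' @param n_decoy_genes Metabolic genes with no reaction assignment, padding
#'   the gene set (expression-analysis background).
#' @param biomass_precursor_subset Precursors drained by the biomass
#'   equation; subset of `c("ala", "glu", "glycogen", "lipid")`.
#' @return A list of class `toy_spec`.
#' @export
toy_spec <- function(seed = 1L, include_hydrogenase = TRUE,
                     include_glyoxylate_shunt = TRUE, n_decoy_genes = 10L,
                     biomass_precursor_subset = c("ala", "glu", "glycogen",
                                                  "lipid")) {
  biomass_precursor_subset <- match.arg(biomass_precursor_subset,
                                        several.ok = TRUE)
  structure(list(seed = as.integer(seed),
                 include_hydrogenase = include_hydrogenase,
                 include_glyoxylate_shunt = include_glyoxylate_shunt,
                 n_decoy_genes = as.integer(n_decoy_genes),
                 biomass_precursor_subset = biomass_precursor_subset),
            class = "toy_spec")
}

# Table of biomass precursor coefficients used by the toy (mmol/gDCW),
# taken from the full composition table with proportions preserved.
.toy_biomass_coefs <- c(ala = 0.499149,      # Alanine
                        glu = 0.255712,      # Glutamate
                        glycogen = 0.01450617,
                        lipid = 0.20683718)  # 16C-lipid

#' Generate the toy photoautotroph model
#'
#' Builds a ~40-reaction network: photon uptake for photosystems I and II,
#' a plastoquinone/plastocyanin electron transport chain producing ATP and
#' NADPH with O2 evolution, respiratory NADH dehydrogenase (isozyme pair)
#' and terminal oxidase, RuBisCO plus a condensed Calvin cycle, a glucose
#' transporter with glycolysis carrying both ATP- and GTP-cofactor pyruvate
#' kinase variants, PEP carboxylase anaplerosis, a TCA cycle lacking
#' 2-oxoglutarate dehydrogenase with an optional glyoxylate shunt, succinate
#' dehydrogenase and a succinate exchange, an optional bidirectional
#' hydrogenase, fixed-flux ATP maintenance, and a biomass drain over the
#' chosen precursors. GPRs include enzyme complexes (AND) and isozyme pairs
#' (OR). Carbon counts are bookkept on every carbon species so the network
#' is carbon-balanced by construction.
#'
#' @param spec A [toy_spec()].
#' @return A `metabolic_model` with attributes `"uptakes"` (an
#'   [uptake_map()]) and `"design_objective"` (the succinate exchange).
#' @export
generate_toy_phototroph <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))

  carbon <- c(photonI = 0, photonII = 0, co2 = 1, hco3 = 1, glc = 6,
              o2 = 0, h2o = 0, nh3 = 0, h2 = 0,
              pq = 0, pqh2 = 0, pc_ox = 0, pc_red = 0,
              atp = 0, adp = 0, pi = 0, nad = 0, nadh = 0,
              nadp = 0, nadph = 0, gtp = 0, gdp = 0, coa = 0,
              rubp = 5, pg3 = 3, g3p = 3, g6p = 6, pep = 3, pyr = 3,
              accoa = 2, cit = 6, akg = 5, succ = 4, fum = 4, mal = 4,
              oaa = 4, glx = 2,
              ala = 3, glu = 5, glycogen = 6, lipid = 16)
  externals <- c("photonI_xt", "photonII_xt", "co2_xt", "hco3_xt", "glc_xt",
                 "o2_xt", "h2o_xt", "nh3_xt", "succ_xt",
                 if (spec$include_hydrogenase) "h2_xt")
  carbon_ext <- c(photonI_xt = 0, photonII_xt = 0, co2_xt = 1, hco3_xt = 1,
                  glc_xt = 6, o2_xt = 0, h2o_xt = 0, nh3_xt = 0,
                  succ_xt = 4, h2_xt = 0)
  cofactor <- c("h2o", "atp", "adp", "pi", "nad", "nadh", "nadp", "nadph",
                "gtp", "gdp", "coa", "co2", "o2", "nh3")

  rx <- list()
  add <- function(id, stoich, rev = FALSE, gpr = NULL,
                  lb = if (rev) -Inf else 0, ub = Inf, ec = NA_character_) {
    rx[[length(rx) + 1L]] <<- reaction(id, stoich, reversible = rev,
                                       lower_bound = lb, upper_bound = ub,
                                       gpr = gpr, ec = ec)
  }

  ## boundary exchanges (photon naming mirrors the _lightI/_lightII style)
  add("EX_lightI",  c(photonI_xt = -1, photonI = 1))
  add("EX_lightII", c(photonII_xt = -1, photonII = 1))
  add("EX_co2",  c(co2_xt = -1, co2 = 1), rev = TRUE)
  add("EX_hco3", c(hco3_xt = -1, hco3 = 1))
  add("EX_glc",  c(glc_xt = -1, glc = 1), gpr = gpr_gene("glcP"))
  add("EX_o2",   c(o2 = -1, o2_xt = 1), rev = TRUE)
  add("EX_h2o",  c(h2o = -1, h2o_xt = 1), rev = TRUE)
  add("EX_nh3",  c(nh3_xt = -1, nh3 = 1))
  add("EX_succ", c(succ = -1, succ_xt = 1))
  if (spec$include_hydrogenase)
    add("EX_h2", c(h2 = -1, h2_xt = 1))

  ## light reactions and electron transport; one photon unit (mE) drives
  ## ten electron pairs in the toy, standing in for the multi-reaction
  ## photosystems of a full reconstruction
  add("PSII", c(photonII = -1, h2o = -10, pq = -10, pqh2 = 10, o2 = 5),
      gpr = gpr_and("psbA", "psbD"), ec = "_lightII")
  add("CYTB6F", c(pqh2 = -1, pc_ox = -2, adp = -1, pi = -1,
                  pq = 1, pc_red = 2, atp = 1, h2o = 1),
      gpr = gpr_and("petB", "petD"))
  add("PSI", c(photonI = -1, pc_red = -20, nadp = -10,
               pc_ox = 20, nadph = 10),
      gpr = gpr_and("psaA", "psaB"), ec = "_lightI")
  add("NDH", c(nadh = -1, pq = -1, nad = 1, pqh2 = 1),
      gpr = gpr_or("ndhF", "ndbA"), ec = "_1.6.5.3")
  add("CYTOX", c(pqh2 = -1, o2 = -0.5, adp = -1, pi = -1,
                 pq = 1, atp = 1, h2o = 2),
      gpr = gpr_and("ctaC", "ctaD"))
  add("TRANSH", c(nadph = -1, nad = -1, nadp = 1, nadh = 1), rev = TRUE,
      gpr = gpr_gene("sthA"))
  if (spec$include_hydrogenase)
    add("HOX", c(nadh = -1, nad = 1, h2 = 1), rev = TRUE,
        gpr = gpr_and("hoxH", "hoxY"))

  ## Calvin cycle
  add("RBC", c(rubp = -1, co2 = -1, h2o = -1, pg3 = 2),
      gpr = gpr_and("rbcL", "rbcS"), ec = "4.1.1.39")
  add("CA", c(hco3 = -1, co2 = 1, h2o = 1), rev = TRUE,
      gpr = gpr_gene("icfA"), ec = "4.2.1.1b")
  add("PGR", c(pg3 = -1, atp = -1, nadph = -1,
               g3p = 1, adp = 1, pi = 1, nadp = 1),
      gpr = gpr_gene("gap2"))
  add("CBBR", c(g3p = -5, atp = -3, h2o = -2, rubp = 3, adp = 3, pi = 2),
      gpr = gpr_gene("prkB"))

  ## glycolysis / gluconeogenesis
  add("HK", c(glc = -1, atp = -1, g6p = 1, adp = 1),
      gpr = gpr_gene("glk"), ec = "2.7.1.2a")
  add("PFKALD", c(g6p = -1, atp = -1, g3p = 2, adp = 1),
      gpr = gpr_gene("pfkA"), ec = "4.1.2.13b")
  add("FBPASE", c(g3p = -2, h2o = -1, g6p = 1, pi = 1),
      gpr = gpr_gene("glpX"))
  add("GAPDH", c(g3p = -1, nad = -1, adp = -1, pi = -1,
                 pg3 = 1, nadh = 1, atp = 1),
      gpr = gpr_gene("gap1"))
  add("ENO", c(pg3 = -1, pep = 1), rev = TRUE, gpr = gpr_gene("eno"))
  add("PYKA", c(pep = -1, adp = -1, pyr = 1, atp = 1),
      gpr = gpr_gene("pyk1"), ec = "2.7.1.40a")
  add("PYKG", c(pep = -1, gdp = -1, pyr = 1, gtp = 1),
      gpr = gpr_or("pyk2a", "pyk2b"), ec = "2.7.1.40c")
  add("NDK", c(gtp = -1, adp = -1, gdp = 1, atp = 1), rev = TRUE,
      gpr = gpr_gene("ndk"))
  add("GLGS", c(g6p = -1, atp = -1, glycogen = 1, adp = 1, pi = 2),
      gpr = gpr_gene("glgA"))

  ## anaplerosis, pyruvate metabolism, TCA (no 2-oxoglutarate dehydrogenase)
  add("PEPC", c(pep = -1, co2 = -1, h2o = -1, oaa = 1, pi = 1),
      gpr = gpr_gene("ppc"), ec = "4.1.1.31")
  add("PDH", c(pyr = -1, coa = -1, nad = -1, accoa = 1, co2 = 1, nadh = 1),
      gpr = gpr_and("pdhA", "pdhB"))
  add("CS", c(accoa = -1, oaa = -1, h2o = -1, cit = 1, coa = 1),
      gpr = gpr_gene("gltA"))
  add("IDH", c(cit = -1, nadp = -1, akg = 1, co2 = 1, nadph = 1),
      gpr = gpr_gene("icd"))
  if (spec$include_glyoxylate_shunt) {
    add("ICL", c(cit = -1, succ = 1, glx = 1), gpr = gpr_gene("aceA"))
    add("MS", c(glx = -1, accoa = -1, h2o = -1, mal = 1, coa = 1),
        gpr = gpr_gene("aceB"))
  }
  add("SDH", c(succ = -1, pq = -1, fum = 1, pqh2 = 1),
      gpr = gpr_and("sdhA", "sdhB"), ec = "_1.3.99.1")
  add("FUM", c(fum = -1, h2o = -1, mal = 1), rev = TRUE,
      gpr = gpr_gene("fumC"), ec = "4.2.1.2")
  add("MDH", c(mal = -1, nad = -1, oaa = 1, nadh = 1), rev = TRUE,
      gpr = gpr_gene("mdh"))
  add("ME", c(mal = -1, nadp = -1, pyr = 1, co2 = 1, nadph = 1),
      gpr = gpr_gene("maeB"))

  ## nitrogen assimilation and precursor synthesis
  add("GDH", c(akg = -1, nh3 = -1, nadph = -1, glu = 1, nadp = 1, h2o = 1),
      gpr = gpr_gene("gdhA"))
  add("ALAT", c(pyr = -1, glu = -1, ala = 1, akg = 1), rev = TRUE,
      gpr = gpr_gene("alaT"), ec = "2.6.1.1a")
  add("LIPS", c(accoa = -8, atp = -7, nadph = -14,
                lipid = 1, coa = 8, adp = 7, pi = 7, nadp = 14),
      gpr = gpr_and("accA", "fabF"))

  ## maintenance and biomass
  add("ATPM", c(atp = -1, h2o = -1, adp = 1, pi = 1), lb = 0, ub = Inf)
  bio_coefs <- .toy_biomass_coefs[spec$biomass_precursor_subset]
  gam <- 20  # growth-associated ATP, mmol per gDW
  biomass_stoich <- c(-bio_coefs,
                      atp = -gam, h2o = -gam, adp = gam, pi = gam)
  names(biomass_stoich)[seq_along(bio_coefs)] <- names(bio_coefs)
  add("BIOMASS", biomass_stoich)

  met_ids <- c(names(carbon), externals)
  mets <- data.frame(
    id = met_ids, name = met_ids,
    external = met_ids %in% externals,
    carbon = as.integer(round(c(carbon, carbon_ext[externals])[met_ids])),
    cofactor = met_ids %in% cofactor,
    stringsAsFactors = FALSE)

  decoys <- if (spec$n_decoy_genes > 0)
    sprintf("dec%02d", seq_len(spec$n_decoy_genes)) else character()
  leaves <- unique(unlist(lapply(rx, function(r) gpr_genes(r$gpr))))
  model <- metabolic_model(mets, rx, genes = c(leaves, decoys),
                           objective = "BIOMASS",
                           biomass_composition = bio_coefs)
  attr(model, "uptakes") <- uptake_map(
    glucose = "EX_glc", co2 = "EX_co2", hco3 = "EX_hco3",
    photons = c("EX_lightI", "EX_lightII"), maintenance = "ATPM")
  attr(model, "design_objective") <- "EX_succ"
  attr(model, "seed") <- spec$seed
  model
}

#' Generate a planted-signal expression dataset
#'
#' Genes neighboring the planted metabolites draw p-values from
#' Beta(`effect_alpha`, 1) (stochastically small for `effect_alpha < 1`;
#' `effect_alpha = 1` gives a pure null dataset); all other model genes
#' draw from Uniform(0, 1).
#'
#' @param model A `metabolic_model` with GPRs (e.g. the toy phototroph).
#' @param planted_metabolites Metabolite ids around which differential
#'   expression is concentrated (may be empty for a null dataset).
#' @param effect_alpha Beta shape parameter in (0, 1].
#' @param n_contrasts Number of independent contrasts to simulate.
#' @param seed Integer RNG seed (required).
#' @return An [expression_dataset()] with attribute `"planted_genes"`.
#' @export
generate_expression_dataset <- function(model, planted_metabolites = character(),
                                        effect_alpha = 0.1, n_contrasts = 1L,
                                        seed) {
  if (missing(seed)) stop("generate_expression_dataset requires a seed")
  stopifnot(effect_alpha > 0, effect_alpha <= 1)
  hood <- metabolite_gene_neighborhoods(model, filter_cofactors = TRUE)
  missing_m <- setdiff(planted_metabolites, model$metabolites$id)
  if (length(missing_m))
    stop("planted metabolite(s) not in model: ", paste(missing_m, collapse = ", "))
  no_genes <- setdiff(planted_metabolites, names(hood))
  if (length(no_genes))
    stop("planted metabolite(s) with no gene neighbors: ",
         paste(no_genes, collapse = ", "))
  planted_genes <- sort(unique(unlist(hood[planted_metabolites])))
  genes <- model$genes
  set.seed(seed)
  p <- sapply(seq_len(n_contrasts), function(i) {
    pv <- stats::runif(length(genes))
    hit <- genes %in% planted_genes
    pv[hit] <- stats::rbeta(sum(hit), effect_alpha, 1)
    pv
  })
  p <- matrix(p, nrow = length(genes),
              dimnames = list(NULL, paste0("contrast", seq_len(n_contrasts))))
  out <- expression_dataset(genes, p)
  attr(out, "planted_genes") <- planted_genes
  out
}

#' Full biomass composition table
#'
#' The published dry-weight biomass composition of the organism
#' (mmol/gDCW): 20 amino acids, 4 deoxyribonucleotides, 4 ribonucleotides,
#' 8 lipids, glycogen and the antenna chromophores.
#'
#' @return Named numeric vector of precursor coefficients.
#' @export
table3_biomass <- function() {
  c(Alanine = 0.499149, Arginine = 0.28742, Aspartate = 0.234232,
    Asparagine = 0.234232, Cysteine = 0.088988, Glutamine = 0.255712,
    Glutamate = 0.255712, Glycine = 0.595297, Histidine = 0.092056,
    Isoleucine = 0.282306, Leucine = 0.437778, Lysine = 0.333448,
    Methionine = 0.149336, Phenylalanine = 0.180021, Proline = 0.214798,
    Serine = 0.209684, Threonine = 0.246506, Tryptophan = 0.055234,
    Tyrosine = 0.133993, Valine = 0.411184,
    Glycogen = 0.01450617,
    dATP = 0.0241506, dTTP = 0.0241506, dGTP = 0.02172983,
    dCTP = 0.02172983,
    AMP = 0.14038929, UMP = 0.14038929, GMP = 0.12374585,
    CMP = 0.12374585,
    `16C-lipid` = 0.20683718, `(9Z)16C-lipid` = 0.01573412,
    `18C-lipid` = 0.00351776, `(9Z)18C-lipid` = 0.03188596,
    `(9Z,12Z)18C-lipid` = 0.03568367, `(9Z,12Z,15Z)18C-lipid` = 0.01797109,
    `(6Z,9Z,12Z)18C-lipid` = 0.05031906,
    `(6Z,9Z,12Z,15Z)18C-lipid` = 0.01448179,
    `Chlorophyll a` = 0.02728183, Carotenoids = 0.00820225)
}
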