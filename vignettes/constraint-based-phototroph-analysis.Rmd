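---
title: "Constraint-based analysis of a photoautotroph metabolic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of a photoautotroph metabolic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synflux)
```

# Scope

`synflux` implements the computational stack used to analyse genome-scale
metabolic reconstructions of photosynthetic bacteria such as
*Synechocystis* sp. PCC6803: steady-state flux balance analysis (FBA) of
autotrophic, heterotrophic and mixotrophic growth, flux variability
analysis (FVA), minimization-of-metabolic-adjustment (MOMA) mutant
predictions, genome-wide gene-deletion screens, knockout strain design for
value-added compounds, and reporter-metabolite integration of
transcriptome p-values over the network. This vignette documents the
models, the numerical choices, and the design decisions behind each
module.

# The steady-state model

A metabolic network with $m$ internal (mass-balanced) metabolites and $n$
reactions is summarized by its stoichiometric matrix $S \in
\mathbb{R}^{m \times n}$. At pseudo steady state, intracellular
metabolite pools neither accumulate nor deplete:

$$S\,v = 0, \qquad l_j \le v_j \le u_j,$$

where $v$ is the flux vector (mmol gDW$^{-1}$ h$^{-1}$; photon uptakes in
mE gDW$^{-1}$ h$^{-1}$). External boundary species have no row in $S$,
which is what lets exchange reactions act as net sources and sinks.
Irreversible reactions have $l_j \ge 0$; reversibility is data carried by
the model file, not something the package infers. Biomass formation is a
pseudo-reaction draining precursors in fixed mmol gDCW$^{-1}$ proportions;
its flux is the specific growth rate.

FBA maximizes (or minimizes) one reaction's flux over that polytope.
Because the system is underdetermined, the optimal flux *distribution* is
generally non-unique even when the optimal *value* is; all cross-condition
reports therefore show FVA ranges next to point fluxes, and the MOMA
screen records the reference vector it used.

## Model I/O

Models are read and written in the OptGene/BioOpt flat-text dialect:
`-REACTIONS` (one equation per line, `->` irreversible, `<->` reversible,
coefficients defaulting to 1), `-CONSTRAINTS` (`Rid [lo, hi]`, with
`inf`/`-inf` for unbounded), `-EXTERNAL METABOLITES`, `-OBJ` and an
optional `-DESIGNOBJ`. Headers are matched case-insensitively with or
without the leading dash, `%`/`#` lines are comments, and either side of
an equation may be empty (pure uptake or drain reactions). Gene rules are
not part of the flat format; they travel in a two-column TSV
(`reaction_id`, rule text with `AND`/`OR`/parentheses) where `AND` models
an enzyme complex (any subunit loss disables) and `OR` isozymes. The
writer emits terms and external species in sorted order, so serialization
is canonical: writing, re-reading and writing again is byte-identical.

# The linear-programming layer

No LP solver is part of base R, so the package carries its own dense
bounded-variable two-phase revised simplex (`R/lp-solver.R`). Design
points that matter to users:

* **Symbolic infinities.** `+/-Inf` bounds are data; the solver receives a
  finite magnitude instead (default $10^6$, option `synflux.inf_bound`).
  FVA maps fluxes that reach that magnitude back to `+/-Inf` in reports.
* **Zero-straddling variables are split** into positive and negative
  parts. The all-zero flux vector is then one bound-flip away from
  feasible, so phase 1 only repairs the few constraints that exclude zero
  (maintenance ATP, fixed-growth bands). This is both fast and keeps
  degenerate optima from parking spurious futile-cycle fluxes at the
  solver's finite infinity — important because the MOMA reference is an
  FBA vertex.
* **Degeneracy.** Stoichiometric systems are rank-deficient (conserved
  moiety pairs such as ATP/ADP duplicate rows up to sign); dependent rows
  are dropped before solving. Pivoting uses a Dantzig rule with a Bland
  anti-cycling fallback after $5(n+m)$ iterations.
* **Tolerances.** Feasibility $10^{-9}$, reduced-cost $10^{-9}$, reported
  zero $10^{-6}$. Every returned solution satisfies
  $\|S v\|_\infty < 10^{-6}$ (asserted in the test suite).
* **Warm starts.** FVA re-optimizes $2n$ objectives over one constraint
  set; each solve reuses the previous optimal basis.
* **Coupling rows** ($lo \le c^\top v \le up$) enter as slack columns;
  they encode the joint carbon cap over CO$_2$ and bicarbonate under
  autotrophy, where the split between the two carbon species is left to
  the solver.

# Growth conditions

`make_condition()` builds the four regimes from three numbers, matching
carbon sources across regimes per carbon atom:

| parameter | default | meaning |
|---|---|---|
| `total_carbon_flux` | 3.4 mmol C gDW$^{-1}$ h$^{-1}$ | net carbon feed, matched across regimes |
| `photon_cap` | 0.8 mE gDW$^{-1}$ h$^{-1}$ | per-photosystem light input |
| `maintenance_atp` | 1.67 mol ATP / mol glucose-equivalent | non-growth ATP demand |
| `glucose_carbon_fraction` | 0.5 | mixotrophy carbon split (an even split is the neutral default; exposed) |

Uptakes are matched *per carbon atom*: a 6-carbon sugar takes
`total_carbon_flux / 6` (0.567 mmol gDW$^{-1}$ h$^{-1}$ at the default),
mono-carbon species take the flux unchanged. Dark heterotrophy fixes
photon uptake to zero; light-activated heterotrophy re-opens it at the
autotrophic cap. Maintenance is applied as a two-sided bound on a
dedicated ATP-hydrolysis reaction at `1.67 x (total_carbon_flux/6)` in
*every* regime — one absolute maintenance requirement, independent of the
energy source, which is the conservative reading when condition-specific
measurements are unavailable. Derived caps are
checked against literature maxima (glucose 0.85, CO$_2$ 3.7 mmol
gDW$^{-1}$ h$^{-1}$) unless overridden.

The photon-capture ceiling is pure geometry: a spherical cell of radius
$r$ and dry mass $M$ under incident flux $I$ intercepts
$I \cdot 4\pi r^2 / M \cdot 3600$ mE gDW$^{-1}$ h$^{-1}$; the default
geometry (1.75 µm, 0.5 pg, 0.15 mE m$^{-2}$ s$^{-1}$) gives
$4.16 \times 10^4$.

**Two-phase light minimization.** Physiologically meaningful photon
uptakes are far below the geometric ceiling. Phase 1 finds the carbon
uptake consistent with a target growth rate with light unconstrained;
phase 2 fixes growth at that target — as a two-sided band
$[\mu(1-10^{-6}),\ \mu(1+10^{-6})]$ to avoid round-off infeasibility —
and minimizes the summed photon uptake.

**FVA** holds the objective at `fraction_of_optimum` (default 1.0) times
its optimum, with the same relative band, and minimizes/maximizes each
flux in turn. Reactions whose interval is $\{0\}$ (within $10^{-6}$) in
every studied condition are reported as blocked.

# MOMA

For a deletion mutant, MOMA predicts the flux state $x$ in the mutant's
feasible space $\Phi$ minimizing the Euclidean distance to a wild-type
reference $w$:

$$D(w, x) = \sqrt{\textstyle\sum_i (w_i - x_i)^2}, \qquad x = \arg\min_{x \in \Phi} D(w,x).$$

Growth is read off $x$, never optimized — the method deliberately drops
the optimal-growth assumption for mutants. The squared distance is
minimized (same argmin, strictly convex, hence unique). The reference $w$
defaults to the FBA solution of the unperturbed model under the same
condition; since that point may be one of several optimal vertices, the
screen stores it in the result for reproducibility.

Numerically the QP is solved with `quadprog` after two reductions that
its active-set method needs on degenerate metabolic polytopes: fixed
variables (knockouts, maintenance) are substituted out, and the remaining
equalities are eliminated through an orthonormal null-space basis, leaving
a small inequality-only program. Zero-growth mutants can still present a
feasible region with empty interior; inequalities are then relaxed by at
most $10^{-8}$ (far below every reporting tolerance) to restore one.
Pseudo-infinite bounds are kept out of the QP and verified on the
solution.

# Deletion screens and strain design

`single_gene_deletion_screen()` deletes each gene, disables the reactions
whose GPR rule turns false (reactions with no cognate genes are never
disabled), and re-solves growth with FBA or MOMA. Classes follow fixed,
configurable thresholds the source study does not print: `no_growth`
below $10^{-6}$ h$^{-1}$ absolute, `wild_type_growth` at $\ge 99\%$ of
wild type, `reduced_growth` between. Infeasible mutants are `no_growth`.
The default screen condition is mixotrophy.

Strain design searches over *reaction* deletions, reporting implicated
genes afterwards via minimal GPR hitting sets; candidate reactions
exclude exchanges/transport (anything touching a boundary species),
spontaneous reactions and the biomass/design reactions, since deleting an
uptake trivially dominates otherwise. The exhaustive search enumerates
all deletion sets up to size $k$ behind a combinatorial guard; the
evolutionary variant is a plain genetic algorithm over binary deletion
vectors capped at $k$ set bits (tournament selection of size 2, uniform
crossover, bit-flip mutation 0.02, elitism 1, population 40, 200
generations by default, seed mandatory), with fitness equal to the design
flux of the inner FBA/MOMA state and zero when growth falls below
`min_growth_fraction` (default 0.1) of wild type. Designs are filtered by
that same growth floor and ranked by production with lexicographic
tie-breaks, so rankings are deterministic.

# Reporter metabolites

Expression integration follows the reporter-features scheme. Per-gene
p-values become z-scores through the inverse normal CDF,
$z_g = \Phi^{-1}(1 - p_g)$, with $p$ clamped to
$[10^{-10}, 1 - 10^{-10}]$ so scores stay finite. Each metabolite is
scored by the plain arithmetic mean of its $N_j$ neighboring gene scores
(the $1/\sqrt{N}$ weighting found elsewhere in the reporter literature is
*not* used here),
then standardized against the Monte-Carlo background of random size-$N$
gene aggregates:

$$z_j^{\mathrm{corr}} = \frac{z_j - m_N}{s_N},$$

with 10,000 aggregates per distinct neighborhood size by default, sampled
with replacement from the scored genes under a mandatory seed (the pool is
sorted by gene id first, so results are invariant to gene order). A gene
neighbors a metabolite when one of its reactions involves it; cofactor
metabolites (configurable list: water, adenylates, NAD(P)(H), CO$_2$,
O$_2$, phosphate, and similar currency species) are excluded from
neighborhoods, otherwise ATP and water would connect everything. Genes
with missing p-values are excluded from scoring and backgrounds; constant
gene scores make $s_N = 0$ and raise a degenerate-input error.

The co-regulated subnetwork search is the package's own documented
greedy heuristic (metabolic subnetwork searches in the literature leave
the algorithm largely open): from each
top-decile gene, greedily add the adjacent gene (genes are adjacent when
their reactions share a non-cofactor metabolite) that maximizes the
background-corrected aggregate score, stop when the score would drop or a
size limit is reached, and return the best-scoring set over all starts.
Because the greedy maximizes over many starts and extensions, its *null*
scores run above the naive standard-normal scale (observed null maxima
near 4 over 20 replicates on the toy network, versus planted-chain scores
above 5); the tests therefore check separation from planted signal rather
than an absolute normal-theory cutoff, and results from this module are
best read comparatively.

# The synthetic phototroph

Every analysis is exercised on a generated ~45-reaction toy
photoautotroph rather than on downloaded data. It reproduces, at reduced
scale, the structural features the analyses rely on:

* photon exchanges for photosystems I and II feeding a
  plastoquinone/plastocyanin electron chain with O$_2$ evolution,
  photophosphorylation and NADPH production (one photon unit drives ten
  electron pairs — a lumping of the multi-reaction photosystems of a full
  reconstruction);
* respiratory NADH dehydrogenase (an isozyme pair) and terminal oxidase,
  plus a reversible transhydrogenase;
* RuBisCO and a condensed Calvin cycle; glucose transport and glycolysis
  with *both* ATP- and GTP-cofactor pyruvate-kinase variants;
* PEP-carboxylase anaplerosis and a TCA cycle **lacking 2-oxoglutarate
  dehydrogenase**, completed (optionally) by the glyoxylate shunt, with
  succinate dehydrogenase and a succinate exchange — the substrate of the
  strain-design examples;
* an optional bidirectional hydrogenase with an H$_2$ exchange;
* a biomass drain over alanine, glutamate, glycogen and a 16-carbon lipid
  with the published composition coefficients (the full 39-precursor
  table ships as `table3_biomass()`; the toy uses a subset so it stays
  under 40 reactions while preserving relative proportions), plus 20 mmol
  gDW$^{-1}$ growth-associated ATP;
* GPRs containing at least one two-subunit complex and one isozyme pair,
  plus ten decoy genes with no reaction assignment that pad the
  expression background.

Carbon counts are bookkept on every species, so each internal reaction is
carbon-balanced by construction and uptake equals biomass carbon plus
CO$_2$ release in any steady state. The model grows in all four regimes
under the default conditions (autotrophy ≈ 0.27 h$^{-1}$, photon-limited;
dark heterotrophy ≈ 0.19; light heterotrophy ≈ 0.55; mixotrophy ≈ 0.41 at
the 50/50 carbon split).

The expression generator plants Beta($\alpha$, 1) p-values
($\alpha = 0.1$ by default; $\alpha = 1$ is the exact uniform null) on
genes neighboring chosen metabolites. Pyruvate is the canonical planted
metabolite in the tests: it has the largest distinctive gene neighborhood
in the toy (seven genes across both pyruvate kinases, pyruvate
dehydrogenase, malic enzyme and alanine transaminase), which makes
recovery a property of the method rather than of a lucky seed.

What the toy does **not** emulate: genome scale (hundreds of reactions,
dead ends, duplicated subsystems), proton/charge balancing,
thermodynamic directionality, kinetic regulation, and the noise structure
of real microarrays. Passing tests demonstrate that the algorithms are
implemented correctly and behave as the theory predicts on a faithful
miniature — not that any particular biological conclusion transfers.

# Problem sizes and runtime

The test-suite defaults were chosen so the whole suite runs in about a
minute on one core: the 45-reaction toy for all LP/QP work, FVA
containment over 100 random constraint draws, deletion screens over 55
genes, exhaustive design up to $k = 2$ (~330 MOMA solves), evolutionary
search with population 30 for 40 generations, and reporter analyses with
2,000–5,000 background aggregates over 20 (recovery) and 50 (null
calibration) seeded replicates. `scripts/acceptance.R` re-derives the
headline numbers with the same sizes.

# Known limitations

* The simplex is dense; it is comfortable at a few hundred reactions but
  not designed for multi-thousand-reaction pan-genome models.
* Degenerate FBA optima are returned as an arbitrary (reproducible)
  vertex; interpret single point fluxes only together with FVA ranges.
* No thermodynamic/loopless constraints and no parsimonious-FBA cleanup:
  internal cycles with zero objective cost can carry flux within their
  bounds.
* MOMA's tiny inequality relaxation ($\le 10^{-8}$) means reported
  mutant fluxes can violate a bound by that amount.
* The subnetwork search is greedy and seed-start dependent by design; its
  absolute scores are inflated by selection and should be compared
  between datasets, not against normal quantiles.
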