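# Core domain types: metabolites, reactions, gene-protein-reaction rules,
# genome-scale model container, stoichiometric matrix, connectivity.

#' Default cofactor metabolite names
#'
#' Currency metabolites (water, adenylates, redox carriers, inorganic ions)
#' that are excluded from connectivity rankings and from reporter-metabolite
#' neighborhoods when cofactor filtering is on. Matching is by metabolite id
#' or name, case-insensitively.
#'
#' @return Character vector of cofactor identifiers.
#' @export
default_cofactors <- function() {
  c("H2O", "ATP", "ADP", "AMP", "phosphate", "diphosphate", "H+",
    "NAD+", "NADH", "NADP+", "NADPH", "CO2", "O2", "NH3", "CoA",
    # common short ids used in flat-text models
    "h2o", "atp", "adp", "amp", "pi", "ppi", "h", "nad", "nadh",
    "nadp", "nadph", "co2", "o2", "nh3", "coa", "gtp", "gdp")
}

## ---- GPR boolean trees ----------------------------------------------------

#' Gene-association tree constructors
#'
#' A gene-protein-reaction (GPR) rule is a boolean tree over gene ids.
#' `gpr_gene` is a leaf; `gpr_and` encodes an enzyme complex (loss of any
#' subunit disables the reaction); `gpr_or` encodes isozymes (any one gene
#' suffices).
#'
#' @param gene A gene id.
#' @param ... Child nodes (gpr trees or bare gene id strings).
#' @return A list with class `gpr` describing the tree node.
#' @export
gpr_gene <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  structure(list(kind = "gene", gene = gene), class = "gpr")
}

#' @rdname gpr_gene
#' @export
gpr_and <- function(...) .gpr_node("and", list(...))

#' @rdname gpr_gene
#' @export
gpr_or <- function(...) .gpr_node("or", list(...))

.gpr_node <- function(kind, children) {
  if (length(children) == 0L) stop("GPR ", kind, " node needs children")
  children <- lapply(children, function(ch) {
    if (is.character(ch)) gpr_gene(ch) else ch
  })
  ok <- vapply(children, inherits, logical(1), "gpr")
  if (!all(ok)) stop("GPR children must be gpr nodes or gene id strings")
  structure(list(kind = kind, children = children), class = "gpr")
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' @param gpr A `gpr` tree.
#' @param deleted Character vector of deleted gene ids.
#' @return `TRUE` if the reaction remains enzymatically feasible.
#' @export
evaluate_gpr <- function(gpr, deleted = character()) {
  stopifnot(inherits(gpr, "gpr"))
  switch(gpr$kind,
    gene = !(gpr$gene %in% deleted),
    and  = all(vapply(gpr$children, evaluate_gpr, logical(1), deleted = deleted)),
    or   = any(vapply(gpr$children, evaluate_gpr, logical(1), deleted = deleted)),
    stop("unknown GPR node kind: ", gpr$kind)
  )
}

#' List the gene ids appearing in a GPR tree
#' @param gpr A `gpr` tree (or `NULL`).
#' @return Character vector of gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character())
  stopifnot(inherits(gpr, "gpr"))
  if (gpr$kind == "gene") return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}

#' Parse a boolean GPR rule from text
#'
#' Accepts rules in the conventional `AND`/`OR`/parentheses syntax, e.g.
#' `"(g1 and g2) or g3"`. Operator keywords are case-insensitive; `AND`
#' binds tighter than `OR`.
#'
#' @param text Rule text.
#' @return A `gpr` tree, or `NULL` for empty/blank text.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || !nzchar(trimws(text))) return(NULL)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    parts <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      parts[[length(parts) + 1L]] <- parse_and()
    }
    if (length(parts) == 1L) parts[[1]] else do.call(gpr_or, parts)
  }
  parse_and <- function() {
    left <- parse_atom()
    parts <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      parts[[length(parts) + 1L]] <- parse_atom()
    }
    if (length(parts) == 1L) parts[[1]] else do.call(gpr_and, parts)
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of GPR rule: ", text)
    if (t == "(") {
      node <- parse_or()
      if (!identical(take(), ")")) stop("unbalanced parentheses in GPR rule: ", text)
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed GPR rule near '", t, "': ", text)
    gpr_gene(t)
  }
  node <- parse_or()
  if (!is.na(peek())) stop("trailing tokens in GPR rule: ", text)
  node
}

#' Render a GPR tree as rule text
#' @param gpr A `gpr` tree (or `NULL`).
#' @return A character string (`""` for `NULL`).
#' @export
deparse_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  stopifnot(inherits(gpr, "gpr"))
  switch(gpr$kind,
    gene = gpr$gene,
    and  = paste0("(", paste(vapply(gpr$children, deparse_gpr, character(1)),
                             collapse = " and "), ")"),
    or   = paste0("(", paste(vapply(gpr$children, deparse_gpr, character(1)),
                             collapse = " or "), ")")
  )
}

## ---- Reactions and models -------------------------------------------------

#' Construct a reaction
#'
#' @param id Reaction id token.
#' @param stoich Named numeric vector of signed stoichiometric coefficients
#'   (negative = substrate, positive = product), names are metabolite ids.
#' @param reversible Logical; irreversible reactions must have
#'   `lower_bound >= 0`.
#' @param lower_bound,upper_bound Flux bounds in mmol/gDW/h; `-Inf`/`Inf`
#'   denote symbolically unbounded.
#' @param gpr A `gpr` tree or `NULL` (no cognate genes).
#' @param ec Optional EC number text.
#' @return A list with class `reaction`.
#' @export
reaction <- function(id, stoich, reversible = FALSE,
                     lower_bound = if (reversible) -Inf else 0,
                     upper_bound = Inf, gpr = NULL, ec = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoich) == 0L || is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector")
  if (anyDuplicated(names(stoich)))
    stop("reaction '", id, "': duplicate metabolite in stoichiometry")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower bound exceeds upper bound")
  if (!reversible && lower_bound < 0)
    stop("reaction '", id, "': irreversible reaction with negative lower bound")
  if (!is.null(gpr) && !inherits(gpr, "gpr")) stop("gpr must be a gpr tree or NULL")
  structure(list(id = id, stoich = stoich, reversible = reversible,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 gpr = gpr, ec = ec),
            class = "reaction")
}

#' Construct a genome-scale metabolic model
#'
#' @param metabolites Data frame with columns `id`, `name`, `external`
#'   (logical), `carbon` (integer carbon count, `NA` = unknown), `cofactor`
#'   (logical). Missing optional columns are filled with defaults.
#' @param reactions List of [reaction()] objects.
#' @param genes Character vector of gene ids; defaults to the union of all
#'   GPR leaves.
#' @param objective Id of the biomass (objective) reaction.
#' @param biomass_composition Named numeric vector of biomass precursor
#'   coefficients (mmol/gDCW), optional bookkeeping.
#' @return A list with class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL,
                            objective, biomass_composition = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!"id" %in% names(metabolites)) stop("metabolites need an 'id' column")
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"external" %in% names(metabolites)) metabolites$external <- FALSE
  if (!"carbon" %in% names(metabolites)) metabolites$carbon <- NA_integer_
  if (!"cofactor" %in% names(metabolites)) metabolites$cofactor <- FALSE
  if (any(!is.na(metabolites$carbon) & metabolites$carbon < 0))
    stop("carbon counts must be non-negative")
  rownames(metabolites) <- NULL

  stopifnot(is.list(reactions))
  ok <- vapply(reactions, inherits, logical(1), "reaction")
  if (!all(ok)) stop("all reactions must be built with reaction()")
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  names(reactions) <- rids

  for (rx in reactions) {
    unknown <- setdiff(names(rx$stoich), metabolites$id)
    if (length(unknown))
      stop("reaction '", rx$id, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!objective %in% rids)
    stop("objective reaction '", objective, "' not in model")

  gpr_leaves <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))
  if (is.null(genes)) genes <- gpr_leaves
  missing_genes <- setdiff(gpr_leaves, genes)
  if (length(missing_genes))
    stop("GPR gene(s) absent from the model gene set: ",
         paste(missing_genes, collapse = ", "))

  structure(list(metabolites = metabolites, reactions = reactions,
                 genes = sort(unique(genes)), objective = objective,
                 biomass_composition = biomass_composition),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  n_int <- sum(!x$metabolites$external)
  cat("Genome-scale metabolic model\n")
  cat(sprintf("  reactions:   %d\n", length(x$reactions)))
  cat(sprintf("  metabolites: %d internal, %d external\n",
              n_int, nrow(x$metabolites) - n_int))
  cat(sprintf("  genes:       %d\n", length(x$genes)))
  cat(sprintf("  objective:   %s\n", x$objective))
  invisible(x)
}

#' Reaction and internal-metabolite id accessors
#' @param model A `metabolic_model`.
#' @return Character vector of ids.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' @rdname reaction_ids
#' @export
internal_metabolites <- function(model)
  model$metabolites$id[!model$metabolites$external]

## ---- Stoichiometric matrix ------------------------------------------------

#' Assemble the stoichiometric matrix S
#'
#' One row per internal (mass-balanced) metabolite, one column per reaction;
#' entry (i, j) is the signed coefficient of metabolite i in reaction j.
#' External boundary metabolites have no row, which is what makes exchange
#' reactions net sources/sinks in the steady-state system S v = 0.
#'
#' @param model A `metabolic_model`.
#' @return A sparse `Matrix::dgCMatrix` with metabolite/reaction dimnames.
#' @export
build_stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- internal_metabolites(model)
  rids <- reaction_ids(model)
  row_of <- stats::setNames(seq_along(mets), mets)
  i <- integer(); j <- integer(); x <- numeric()
  for (k in seq_along(model$reactions)) {
    rx <- model$reactions[[k]]
    unknown <- setdiff(names(rx$stoich), model$metabolites$id)
    if (length(unknown))
      stop("structural integrity error in reaction '", rx$id,
           "': unknown metabolite(s) ", paste(unknown, collapse = ", "))
    keep <- names(rx$stoich) %in% mets
    if (any(keep)) {
      i <- c(i, row_of[names(rx$stoich)[keep]])
      j <- c(j, rep.int(k, sum(keep)))
      x <- c(x, unname(rx$stoich[keep]))
    }
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(mets), length(rids)),
                       dimnames = list(mets, rids))
}

## ---- Gene deletions -------------------------------------------------------

#' Reactions disabled by a set of gene deletions
#'
#' A reaction is disabled when its GPR rule evaluates to infeasible under the
#' deletions; reactions with no cognate genes are never disabled.
#'
#' @param model A `metabolic_model`.
#' @param deleted Character vector of deleted gene ids (must be model genes).
#' @return Character vector of disabled reaction ids.
#' @export
reactions_disabled_by <- function(model, deleted) {
  stopifnot(inherits(model, "metabolic_model"))
  unknown <- setdiff(deleted, model$genes)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  if (length(deleted) == 0L) return(character())
  disabled <- vapply(model$reactions, function(rx) {
    !is.null(rx$gpr) && !evaluate_gpr(rx$gpr, deleted)
  }, logical(1))
  names(model$reactions)[disabled]
}

## ---- Connectivity ---------------------------------------------------------

#' Metabolite connectivity ranking
#'
#' Connectivity of a metabolite is the number of distinct reactions it
#' participates in (as substrate or product). Rows are sorted by descending
#' neighbor count, ties broken lexicographically by metabolite id.
#'
#' @param model A `metabolic_model`.
#' @param filter_cofactors Exclude metabolites flagged as cofactors.
#' @return Data frame with columns `metabolite_id`, `name`, `neighbor_count`.
#' @export
metabolite_connectivity <- function(model, filter_cofactors = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  counts <- integer(nrow(model$metabolites))
  names(counts) <- model$metabolites$id
  for (rx in model$reactions) {
    ids <- unique(names(rx$stoich))
    counts[ids] <- counts[ids] + 1L
  }
  keep <- counts > 0L
  if (filter_cofactors) keep <- keep & !model$metabolites$cofactor
  out <- data.frame(metabolite_id = model$metabolites$id[keep],
                    name = model$metabolites$name[keep],
                    neighbor_count = unname(counts[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$neighbor_count, out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a connectivity report as TSV
#' @param connectivity Output of [metabolite_connectivity()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_connectivity_tsv <- function(connectivity, path) {
  utils::write.table(connectivity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
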