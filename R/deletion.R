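# Genome-wide single-gene deletion screens (FBA and MOMA) with three-class
# essentiality calls.

#' Classify mutant growth against wild type
#'
#' @param mutant_growth Mutant growth rate (1/h).
#' @param wt_growth Wild-type growth rate (1/h), must be positive.
#' @param zero_tol Absolute growth below which a mutant is called
#'   `no_growth`.
#' @param wt_fraction Fraction of wild-type growth at or above which a
#'   mutant is called `wild_type_growth`.
#' @return One of `"no_growth"`, `"reduced_growth"`, `"wild_type_growth"`.
#' @export
classify_growth <- function(mutant_growth, wt_growth,
                            zero_tol = 1e-6, wt_fraction = 0.99) {
  stopifnot(wt_growth > 0)
  if (is.na(mutant_growth)) return("no_growth")
  if (mutant_growth < -zero_tol)
    stop("negative mutant growth beyond tolerance: ", mutant_growth)
  if (mutant_growth < zero_tol) return("no_growth")
  if (mutant_growth >= wt_fraction * wt_growth) return("wild_type_growth")
  "reduced_growth"
}

#' Single-gene deletion screen
#'
#' Deletes each model gene in turn, disables the reactions whose GPR rules
#' become infeasible, and re-solves growth with FBA or MOMA (wild-type FBA
#' reference). Infeasible mutants are classed `no_growth`.
#'
#' @param model A `metabolic_model`.
#' @param constraints Optional [constraint_set()] (the growth condition;
#'   typically mixotrophic).
#' @param method `"FBA"` or `"MOMA"`.
#' @param genes Genes to screen (default: all model genes).
#' @param zero_tol,wt_fraction Classification thresholds, see
#'   [classify_growth()].
#' @return Data frame with one row per gene: `gene`, `n_disabled`,
#'   `disabled` (comma-separated reaction ids), `mutant_growth`,
#'   `moma_growth` (NA for FBA screens), `class`. The wild-type growth is
#'   attached as attribute `"wt_growth"`.
#' @export
single_gene_deletion_screen <- function(model, constraints = NULL,
                                        method = c("FBA", "MOMA"),
                                        genes = model$genes,
                                        zero_tol = 1e-6, wt_fraction = 0.99) {
  method <- match.arg(method)
  stopifnot(all(genes %in% model$genes))
  wt <- fba(model, constraints)
  if (!is_feasible(wt) || wt$objective_value <= 0)
    stop("wild type does not grow under the supplied constraints")
  wt_growth <- wt$objective_value

  rows <- lapply(genes, function(g) {
    disabled <- reactions_disabled_by(model, g)
    if (length(disabled) == 0L) {
      growth <- wt_growth
      moma_growth <- if (method == "MOMA") wt_growth else NA_real_
    } else if (method == "FBA") {
      mut <- fba(model, constraints, disabled = disabled)
      growth <- if (is_feasible(mut)) mut$objective_value else NA_real_
      moma_growth <- NA_real_
    } else {
      mut <- moma(model, constraints, disabled = disabled, wild_type = wt)
      growth <- if (is_feasible(mut)) mut$growth else NA_real_
      moma_growth <- growth
    }
    cls <- classify_growth(if (is.na(growth)) 0 else max(growth, 0),
                           wt_growth, zero_tol, wt_fraction)
    data.frame(gene = g, n_disabled = length(disabled),
               disabled = paste(disabled, collapse = ","),
               mutant_growth = if (is.na(growth)) 0 else growth,
               moma_growth = moma_growth, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "wt_growth") <- wt_growth
  attr(out, "method") <- method
  out
}

#' Write a deletion screen as TSV
#' @param screen Output of [single_gene_deletion_screen()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_screen_tsv <- function(screen, path) {
  tab <- data.frame(gene_id = screen$gene, class = screen$class,
                    fba_growth = signif(screen$mutant_growth, 6),
                    moma_growth = signif(screen$moma_growth, 6),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
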