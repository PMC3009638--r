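# Reporter-metabolite scoring of differential-expression p-values over the
# metabolic network: gene z-scores, neighborhood averaging, Monte-Carlo
# background correction, greedy co-regulated subnetwork search, and KEGG
# category summaries.

#' Construct an expression dataset
#'
#' @param genes Character vector of gene ids.
#' @param pvalues Numeric matrix (genes x contrasts) or named list of
#'   per-contrast numeric vectors of p-values in [0, 1]; `NA` = unmeasured.
#' @return A data frame of class `expression_dataset` with column `gene`
#'   and one column per contrast.
#' @export
expression_dataset <- function(genes, pvalues) {
  if (is.list(pvalues) && !is.data.frame(pvalues))
    pvalues <- do.call(cbind, pvalues)
  pvalues <- as.matrix(pvalues)
  stopifnot(nrow(pvalues) == length(genes))
  if (is.null(colnames(pvalues)))
    colnames(pvalues) <- paste0("contrast", seq_len(ncol(pvalues)))
  bad <- which(!is.na(pvalues) & (pvalues < 0 | pvalues > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop("p-value outside [0, 1] for gene '", genes[bad[1, 1]], "'")
  out <- data.frame(gene = genes, pvalues, stringsAsFactors = FALSE,
                    check.names = FALSE)
  class(out) <- c("expression_dataset", "data.frame")
  out
}

#' Read an expression dataset from TSV
#' @param con File path or connection; first column `gene`, remaining
#'   columns one per contrast.
#' @return An `expression_dataset`.
#' @export
read_expression_tsv <- function(con) {
  tab <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(tab)) stop("expression TSV needs a 'gene' column")
  expression_dataset(tab$gene, as.matrix(tab[setdiff(names(tab), "gene")]))
}

#' Convert per-gene p-values to z-scores
#'
#' z = qnorm(1 - p), the inverse normal CDF of the complementary p-value,
#' with p clamped to [1e-10, 1 - 1e-10] so scores stay finite.
#'
#' @param data An [expression_dataset()].
#' @param contrast Contrast (column) name.
#' @return Named numeric vector of z-scores over the measured genes.
#' @export
gene_zscores <- function(data, contrast) {
  if (!contrast %in% setdiff(names(data), "gene"))
    stop("contrast '", contrast, "' absent from the dataset")
  p <- data[[contrast]]
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad))
    stop("p-value outside [0, 1] for gene '", data$gene[bad[1]], "'")
  keep <- !is.na(p)
  p <- pmin(pmax(p[keep], 1e-10), 1 - 1e-10)
  stats::setNames(stats::qnorm(1 - p), data$gene[keep])
}

#' Metabolite-to-gene neighborhoods
#'
#' A gene neighbors a metabolite when one of the gene's reactions involves
#' that metabolite. Cofactor metabolites are excluded by default (currency
#' metabolites such as ATP or water would otherwise connect everything), as
#' are external boundary species.
#'
#' @param model A `metabolic_model` with GPRs attached.
#' @param filter_cofactors Drop metabolites flagged as cofactors.
#' @param include_external Keep external boundary metabolites.
#' @return Named list: metabolite id -> character vector of gene ids.
#' @export
metabolite_gene_neighborhoods <- function(model, filter_cofactors = TRUE,
                                          include_external = FALSE) {
  mets <- model$metabolites
  keep <- rep(TRUE, nrow(mets))
  if (filter_cofactors) keep <- keep & !mets$cofactor
  if (!include_external) keep <- keep & !mets$external
  hood <- stats::setNames(vector("list", sum(keep)), mets$id[keep])
  for (rx in model$reactions) {
    genes <- gpr_genes(rx$gpr)
    if (length(genes) == 0L) next
    for (m in intersect(names(rx$stoich), names(hood)))
      hood[[m]] <- c(hood[[m]], genes)
  }
  hood <- lapply(hood, function(g) sort(unique(g)))
  hood[vapply(hood, length, integer(1)) > 0L]
}

#' Raw reporter score of one metabolite
#'
#' @param z Named gene z-score vector (see [gene_zscores()]).
#' @param neighbor_genes Gene ids neighboring the metabolite.
#' @return `list(score, n)`: the arithmetic mean z over the scored
#'   neighbors and the count used; `NULL` when no neighbor is scored.
#' @export
metabolite_raw_score <- function(z, neighbor_genes) {
  scored <- intersect(neighbor_genes, names(z))
  if (length(scored) == 0L) return(NULL)
  list(score = mean(z[scored]), n = length(scored))
}

#' Monte-Carlo background distribution of aggregate scores
#'
#' For each aggregate size N, the mean `m_N` and standard deviation `s_N`
#' of `n_samples` random size-N aggregates (means of gene z-scores sampled
#' with replacement from the scored genes).
#'
#' @param z Named gene z-score vector.
#' @param sizes Integer vector of aggregate sizes needed.
#' @param n_samples Aggregates per size (default 10000).
#' @param seed Integer RNG seed (required for reproducibility).
#' @return A list of class `background_distribution`: per size, `m` and `s`.
#' @export
background_distribution <- function(z, sizes, n_samples = 10000L, seed) {
  if (missing(seed)) stop("background sampling requires a seed")
  sizes <- sort(unique(as.integer(sizes)))
  stopifnot(all(sizes >= 1L))
  # sample from a name-sorted pool so results do not depend on gene order
  if (!is.null(names(z))) z <- z[order(names(z))]
  set.seed(seed)
  bg <- lapply(sizes, function(N) {
    agg <- rowMeans(matrix(sample(z, N * n_samples, replace = TRUE),
                           nrow = n_samples, ncol = N))
    list(m = mean(agg), s = stats::sd(agg))
  })
  names(bg) <- as.character(sizes)
  structure(list(by_size = bg, n_samples = n_samples, seed = seed),
            class = "background_distribution")
}

#' Background-correct a raw aggregate score
#'
#' corrected = (raw - m_N) / s_N for the aggregate's size N.
#'
#' @param raw Raw aggregate score.
#' @param n Aggregate size.
#' @param bg A [background_distribution()] containing size `n`.
#' @return Corrected score.
#' @export
background_correct <- function(raw, n, bg) {
  stopifnot(inherits(bg, "background_distribution"))
  e <- bg$by_size[[as.character(n)]]
  if (is.null(e)) stop("background distribution lacks size ", n)
  if (!is.finite(e$s) || e$s <= 0)
    stop("degenerate input: background standard deviation is zero ",
         "(constant gene scores)")
  (raw - e$m) / e$s
}

#' Reporter-metabolite analysis
#'
#' Full pipeline: gene z-scores, per-metabolite neighborhood means, and
#' Monte-Carlo background correction, returning metabolites ranked by the
#' corrected score (metabolites around which expression changes
#' concentrate rank first).
#'
#' @param model A `metabolic_model` with GPRs attached.
#' @param data An [expression_dataset()].
#' @param contrast Contrast name.
#' @param bg_samples Random aggregates per distinct neighborhood size.
#' @param seed Integer RNG seed (required).
#' @param filter_cofactors Exclude cofactor metabolites from neighborhoods.
#' @return Data frame of class `reporter_table`: `metabolite_id`,
#'   `n_genes`, `raw_score`, `corrected_score`, `rank`.
#' @export
reporter_metabolites <- function(model, data, contrast, bg_samples = 10000L,
                                 seed, filter_cofactors = TRUE) {
  if (missing(seed)) stop("reporter_metabolites requires a seed")
  z <- gene_zscores(data, contrast)
  hood <- metabolite_gene_neighborhoods(model, filter_cofactors)
  raw <- lapply(hood, function(genes) metabolite_raw_score(z, genes))
  skipped <- names(raw)[vapply(raw, is.null, logical(1))]
  if (length(skipped))
    message("skipping ", length(skipped),
            " metabolite(s) with no scored neighbor genes")
  raw <- raw[!vapply(raw, is.null, logical(1))]
  if (length(raw) == 0L) stop("no metabolite has scored neighbor genes")
  sizes <- vapply(raw, `[[`, numeric(1), "n")
  bg <- background_distribution(z, sizes, n_samples = bg_samples, seed = seed)
  corrected <- mapply(function(r) background_correct(r$score, r$n, bg), raw)
  out <- data.frame(metabolite_id = names(raw),
                    n_genes = as.integer(sizes),
                    raw_score = vapply(raw, `[[`, numeric(1), "score"),
                    corrected_score = as.numeric(corrected),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$corrected_score, out$metabolite_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("reporter_table", "data.frame")
  out
}

#' Gene adjacency graph of a metabolic model
#'
#' Two genes are adjacent when their reactions share a non-cofactor
#' internal metabolite.
#'
#' @param model A `metabolic_model` with GPRs attached.
#' @return Named list: gene id -> character vector of adjacent gene ids.
#' @export
gene_adjacency <- function(model) {
  hood <- metabolite_gene_neighborhoods(model, filter_cofactors = TRUE)
  genes <- sort(unique(unlist(hood)))
  adj <- stats::setNames(vector("list", length(genes)), genes)
  for (members in hood) {
    for (g in members) adj[[g]] <- c(adj[[g]], setdiff(members, g))
  }
  lapply(adj, function(g) sort(unique(g)))
}

#' Greedy co-regulated subnetwork search
#'
#' Starting from each gene in the top decile of z-scores, greedily extends
#' the set with the adjacent gene that maximizes the background-corrected
#' aggregate score (mean z of the set, corrected for its size), stopping
#' when the score would drop or `size_limit` is reached. Returns the
#' best-scoring connected gene set over all starts.
#'
#' @param model A `metabolic_model` with GPRs attached.
#' @param data An [expression_dataset()].
#' @param contrast Contrast name.
#' @param size_limit Maximum subnetwork size.
#' @param seed Integer RNG seed (background sampling).
#' @param bg_samples Random aggregates per size.
#' @return Character vector of gene ids (attribute `"score"` holds the
#'   corrected aggregate score); empty when the gene graph is empty.
#' @export
coregulated_subnetwork_search <- function(model, data, contrast,
                                          size_limit = 10L, seed,
                                          bg_samples = 10000L) {
  if (missing(seed)) stop("subnetwork search requires a seed")
  z <- gene_zscores(data, contrast)
  adj <- gene_adjacency(model)
  pool <- intersect(names(adj), names(z))
  if (length(pool) == 0L) return(character())
  bg <- background_distribution(z, seq_len(size_limit),
                                n_samples = bg_samples, seed = seed)
  score_set <- function(set) background_correct(mean(z[set]), length(set), bg)

  zp <- sort(z[pool], decreasing = TRUE)
  starts <- names(zp)[seq_len(max(1L, ceiling(length(zp) / 10)))]
  best <- NULL; best_score <- -Inf
  for (s in starts) {
    set <- s
    current <- score_set(set)
    repeat {
      if (length(set) >= size_limit) break
      frontier <- setdiff(intersect(unique(unlist(adj[set])), pool), set)
      if (length(frontier) == 0L) break
      cand_scores <- vapply(frontier, function(g) score_set(c(set, g)),
                            numeric(1))
      g_best <- frontier[order(-cand_scores, frontier)][1]
      if (cand_scores[g_best] <= current) break
      set <- c(set, g_best)
      current <- cand_scores[g_best]
    }
    if (current > best_score) { best <- set; best_score <- current }
  }
  structure(sort(best), score = best_score)
}

#' Category (KEGG orthology) summary of a gene set
#'
#' @param genes Character vector of gene ids.
#' @param category_map Named character vector (gene -> category) or a data
#'   frame with columns `gene` and `category`. Genes without a category are
#'   counted under `"Unclassified"`.
#' @return Data frame `category`, `count`, `percent` (percent of the total,
#'   rounded to 2 decimals), sorted by descending count.
#' @export
category_summary <- function(genes, category_map) {
  if (is.data.frame(category_map))
    category_map <- stats::setNames(category_map$category, category_map$gene)
  if (length(genes) == 0L)
    return(data.frame(category = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  cats <- category_map[genes]
  cats[is.na(cats)] <- "Unclassified"
  counts <- sort(table(cats), decreasing = TRUE)
  total <- length(genes)
  out <- data.frame(category = names(counts),
                    count = as.integer(counts),
                    percent = if (total > 0)
                      round(100 * as.integer(counts) / total, 2) else numeric(0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a reporter table as TSV
#' @param reporter A `reporter_table`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_reporter_tsv <- function(reporter, path) {
  tab <- reporter
  tab$raw_score <- signif(tab$raw_score, 6)
  tab$corrected_score <- signif(tab$corrected_score, 6)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
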