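# Reader/writer for the OptGene/BioOpt flat-text model dialect.
#
# Layout (headers case-insensitive, leading dash optional; '%' or '#' start
# comment lines; blank lines ignored):
#
#   -REACTIONS
#   R1 : A + 2 B -> C
#   R2 : X <-> Y
#   -CONSTRAINTS
#   R1 [0, 10]
#   -EXTERNAL METABOLITES
#   co2_xt
#   -OBJ
#   biomass max
#   -DESIGNOBJ
#   EX_succ max
#
# "->" means irreversible (default bounds [0, inf]); "<->" reversible
# (default [-inf, inf]). Coefficients default to 1 and use '.' decimals.
# Metabolite tokens may contain dashes/underscores but not spaces.
# GPR rules are not part of the flat format; see read_gpr_tsv().

.og_headers <- c(reactions = "reactions",
                 constraints = "constraints",
                 external = "external metabolites",
                 obj = "obj",
                 designobj = "designobj")

.og_match_header <- function(line) {
  h <- tolower(trimws(sub("^-+", "", trimws(line))))
  hit <- names(.og_headers)[h == .og_headers]
  if (length(hit)) hit else NA_character_
}

.og_parse_side <- function(text, rid, lineno, sign) {
  terms <- strsplit(text, "+", fixed = TRUE)[[1]]
  out <- numeric(); nm <- character()
  for (term in terms) {
    toks <- strsplit(trimws(term), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) next
    coef <- suppressWarnings(as.numeric(toks[1]))
    if (!is.na(coef) && length(toks) >= 2L) {
      met <- paste(toks[-1], collapse = "")
      if (length(toks) > 2L)
        stop("line ", lineno, ": metabolite token with spaces in reaction '",
             rid, "'")
    } else {
      coef <- 1
      if (length(toks) > 1L)
        stop("line ", lineno, ": cannot parse term '", trimws(term),
             "' in reaction '", rid, "'")
      met <- toks[1]
    }
    nm <- c(nm, met); out <- c(out, sign * coef)
  }
  stats::setNames(out, nm)
}

.og_parse_equation <- function(line, lineno) {
  colon <- regexpr(":", line, fixed = TRUE)
  if (colon < 0) stop("line ", lineno, ": missing ':' in reaction line")
  rid <- trimws(substr(line, 1L, colon - 1L))
  if (!nzchar(rid) || grepl("[[:space:]]", rid))
    stop("line ", lineno, ": bad reaction id")
  body <- substr(line, colon + 1L, nchar(line))
  rev <- grepl("<->", body, fixed = TRUE)
  arrow <- if (rev) "<->" else "->"
  pos <- gregexpr(arrow, body, fixed = TRUE)[[1]]
  if (length(pos) != 1L || pos[1] < 0)
    stop("line ", lineno, ": reaction '", rid, "' needs exactly one arrow")
  # either side may be empty (pure uptake or drain reactions)
  lhs <- .og_parse_side(substr(body, 1L, pos - 1L), rid, lineno, -1)
  rhs <- .og_parse_side(substr(body, pos + nchar(arrow), nchar(body)),
                        rid, lineno, +1)
  stoich <- c(lhs, rhs)
  # merge metabolites appearing on both sides
  stoich <- tapply(stoich, names(stoich), sum)
  stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L)
    stop("line ", lineno, ": reaction '", rid, "' has empty net stoichiometry")
  list(id = rid, stoich = stoich, reversible = rev)
}

.og_parse_bound_token <- function(tok, lineno) {
  tok <- trimws(tok)
  if (tolower(tok) %in% c("inf", "+inf")) return(Inf)
  if (tolower(tok) == "-inf") return(-Inf)
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) stop("line ", lineno, ": bad bound '", tok, "'")
  v
}

#' Read a metabolic model in OptGene/BioOpt flat-text format
#'
#' @param con A file path or text connection.
#' @param carbon Optional named integer vector of per-metabolite carbon
#'   counts to attach.
#' @param cofactors Character vector used to flag cofactor metabolites
#'   (matched case-insensitively against ids); default [default_cofactors()].
#' @return A [metabolic_model()]; the design objective (if declared) is
#'   attached as attribute `"design_objective"`.
#' @export
read_optgene <- function(con, carbon = NULL, cofactors = default_cofactors()) {
  lines <- if (is.character(con) && length(con) == 1L && !grepl("\n", con))
    readLines(con) else if (inherits(con, "connection")) readLines(con)
  else strsplit(con, "\n", fixed = TRUE)[[1]]

  section <- NA_character_
  eqs <- list(); constraints <- list(); externals <- character()
  objective <- NULL; design_obj <- NULL
  seen_headers <- character()

  for (lineno in seq_along(lines)) {
    raw <- lines[[lineno]]
    line <- trimws(raw)
    if (!nzchar(line) || grepl("^[%#]", line)) next
    hdr <- .og_match_header(line)
    if (!is.na(hdr)) {
      if (hdr %in% seen_headers)
        stop("line ", lineno, ": duplicate section header '", line, "'")
      seen_headers <- c(seen_headers, hdr)
      section <- hdr
      next
    }
    if (is.na(section)) stop("line ", lineno, ": content before first section header")
    if (section == "reactions") {
      eq <- .og_parse_equation(line, lineno)
      if (eq$id %in% names(eqs))
        stop("line ", lineno, ": duplicate reaction id '", eq$id, "'")
      eqs[[eq$id]] <- eq
    } else if (section == "constraints") {
      m <- regmatches(line, regexec("^(\\S+)\\s*\\[([^,]+),([^]]+)\\]\\s*$", line))[[1]]
      if (length(m) != 4L) stop("line ", lineno, ": bad constraint line '", line, "'")
      bounds <- c(.og_parse_bound_token(m[3], lineno),
                  .og_parse_bound_token(m[4], lineno))
      attr(bounds, "lineno") <- lineno
      constraints[[m[2]]] <- bounds
    } else if (section == "external") {
      if (grepl("[[:space:]]", line))
        stop("line ", lineno, ": external metabolite id contains spaces")
      externals <- c(externals, line)
    } else if (section == "obj") {
      toks <- strsplit(line, "[[:space:]]+")[[1]]
      objective <- list(id = toks[1],
                        sense = if (length(toks) > 1L) tolower(toks[2]) else "max",
                        lineno = lineno)
    } else if (section == "designobj") {
      toks <- strsplit(line, "[[:space:]]+")[[1]]
      design_obj <- list(id = toks[1], lineno = lineno)
    }
  }

  if (is.null(objective)) stop("model document declares no objective")
  for (rid in names(constraints)) {
    if (!rid %in% names(eqs))
      stop("line ", attr(constraints[[rid]], "lineno"),
           ": constraint for unknown reaction '", rid, "'")
  }
  if (!objective$id %in% names(eqs))
    stop("line ", objective$lineno, ": objective reaction '", objective$id,
         "' not declared")
  if (!is.null(design_obj) && !design_obj$id %in% names(eqs))
    stop("line ", design_obj$lineno, ": design objective reaction '",
         design_obj$id, "' not declared")

  met_ids <- unique(unlist(lapply(eqs, function(e) names(e$stoich))))
  unknown_ext <- setdiff(externals, met_ids)
  met_ids <- unique(c(met_ids, externals))
  metabolites <- data.frame(
    id = met_ids, name = met_ids,
    external = met_ids %in% externals,
    carbon = if (is.null(carbon)) NA_integer_ else
      unname(carbon[met_ids]),
    cofactor = tolower(met_ids) %in% tolower(cofactors),
    stringsAsFactors = FALSE)

  reactions <- lapply(eqs, function(e) {
    b <- constraints[[e$id]]
    lb <- if (!is.null(b)) b[1] else if (e$reversible) -Inf else 0
    ub <- if (!is.null(b)) b[2] else Inf
    reaction(e$id, e$stoich, reversible = e$reversible,
             lower_bound = lb, upper_bound = ub)
  })

  model <- metabolic_model(metabolites, unname(reactions),
                           objective = objective$id)
  attr(model, "objective_sense") <- objective$sense
  if (!is.null(design_obj)) attr(model, "design_objective") <- design_obj$id
  model
}

.og_fmt_num <- function(x) {
  if (is.infinite(x)) return(if (x > 0) "inf" else "-inf")
  format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

.og_fmt_side <- function(stoich) {
  paste(vapply(seq_along(stoich), function(i) {
    coef <- abs(stoich[i])
    if (coef == 1) names(stoich)[i]
    else paste(.og_fmt_num(coef), names(stoich)[i])
  }, character(1)), collapse = " + ")
}

#' Write a metabolic model in OptGene/BioOpt flat-text format
#'
#' Output is deterministic: sections in fixed order, reactions in model
#' order, so two writes of the same model are byte-identical and
#' `read_optgene(write_optgene(m))` reproduces `m` structurally.
#'
#' @param model A `metabolic_model`.
#' @param path Optional file path; when `NULL` the document is returned as a
#'   character vector of lines.
#' @return The lines, invisibly when written to a file.
#' @export
write_optgene <- function(model, path = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  out <- c("% OptGene/BioOpt flat-text model", "-REACTIONS")
  for (rx in model$reactions) {
    st <- rx$stoich[order(names(rx$stoich))]  # canonical term order
    lhs <- st[st < 0]
    rhs <- st[st > 0]
    arrow <- if (rx$reversible) "<->" else "->"
    out <- c(out, paste0(rx$id, " : ", .og_fmt_side(lhs), " ", arrow, " ",
                         .og_fmt_side(rhs)))
  }
  out <- c(out, "-CONSTRAINTS")
  for (rx in model$reactions) {
    def_lb <- if (rx$reversible) -Inf else 0
    if (!identical(rx$lower_bound, def_lb) || !identical(rx$upper_bound, Inf))
      out <- c(out, sprintf("%s [%s, %s]", rx$id,
                            .og_fmt_num(rx$lower_bound),
                            .og_fmt_num(rx$upper_bound)))
  }
  out <- c(out, "-EXTERNAL METABOLITES",
           sort(model$metabolites$id[model$metabolites$external]),
           "-OBJ",
           paste(model$objective,
                 attr(model, "objective_sense") %||% "max"))
  if (!is.null(attr(model, "design_objective")))
    out <- c(out, "-DESIGNOBJ", attr(model, "design_objective"))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene-protein-reaction rules from a two-column TSV
#'
#' Expects columns `reaction_id` and `gpr` (boolean rule text using
#' AND/OR/parentheses). Rules are parsed and attached to the matching
#' reactions of `model`; genes are added to the model's gene set.
#'
#' @param model A `metabolic_model`.
#' @param con TSV file path or connection.
#' @param extra_genes Additional gene ids to register (e.g. metabolic genes
#'   with no reaction assignment).
#' @return The model with GPRs attached.
#' @export
read_gpr_tsv <- function(model, con, extra_genes = character()) {
  tab <- utils::read.delim(con, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "gpr") %in% names(tab)))
    stop("GPR table needs columns 'reaction_id' and 'gpr'")
  unknown <- setdiff(tab$reaction_id, reaction_ids(model))
  if (length(unknown))
    stop("GPR rules for unknown reaction(s): ", paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    model$reactions[[tab$reaction_id[i]]]$gpr <- parse_gpr(tab$gpr[i])
  }
  leaves <- unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr))))
  model$genes <- sort(unique(c(model$genes, leaves, extra_genes)))
  model
}

#' Write gene-protein-reaction rules as a two-column TSV
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_gpr_tsv <- function(model, path) {
  rows <- Filter(function(rx) !is.null(rx$gpr), model$reactions)
  tab <- data.frame(
    reaction_id = vapply(rows, `[[`, character(1), "id"),
    gpr = vapply(rows, function(rx) deparse_gpr(rx$gpr), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
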