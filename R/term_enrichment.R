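#' Materialize ancestor-closed annotations
#'
#' A gene directly annotated to a term is implicitly annotated to every
#' ancestor of that term; this returns the closure as a term -> gene-set
#' list.
#'
#' @param graph A [term_graph()].
#' @return Named list: for each term, the character vector of genes
#'   annotated to it or to any descendant.
#' @export
materialize_annotations <- function(graph) {
  stopifnot(inherits(graph, "term_graph"))
  g <- graph$igraph
  # ancestors (incl. self) of each annotated term, following child->parent
  anc_cache <- new.env(parent = emptyenv())
  ancestors_of <- function(term) {
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    a <- names(igraph::subcomponent(g, term, mode = "out"))
    anc_cache[[term]] <- a
    a
  }
  out <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(graph$annotations))) {
    gene <- graph$annotations$gene[i]
    for (t in ancestors_of(graph$annotations$term[i])) {
      out[[t]] <- c(out[[t]], gene)
    }
  }
  res <- lapply(as.list(out), unique)
  res[order(names(res))]
}

#' Hypergeometric over-representation analysis against a term graph
#'
#' One-sided (upper-tail) hypergeometric test per term using
#' ancestor-materialized annotations restricted to the background gene
#' universe.  Terms with no annotated background gene are skipped.
#'
#' @param gene_set Character vector of genes of interest (must be a
#'   subset of `background`).
#' @param background Character vector: the background gene universe
#'   (e.g. all profiled genes).
#' @param graph A [term_graph()].
#' @param method Multiple-testing correction, `"bonferroni"` (default)
#'   or `"bh"`.
#' @param alpha Significance level applied to the adjusted p-values.
#' @return Data frame with term_id, k (overlap), n_set, K_term, N,
#'   p_raw, p_adj, significant.
#' @export
hypergeom_enrichment <- function(gene_set, background, graph,
                                 method = c("bonferroni", "bh"),
                                 alpha = 0.05) {
  method <- match.arg(method)
  background <- unique(background)
  if (length(background) == 0) stop("background gene universe is empty")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background))
    stop("gene_set must be a subset of the background")
  ann <- materialize_annotations(graph)
  ann <- lapply(ann, intersect, background)
  K <- vapply(ann, length, integer(1))
  keep <- K > 0
  ann <- ann[keep]; K <- K[keep]
  N <- length(background)
  n <- length(gene_set)
  k <- vapply(ann, function(gs) length(intersect(gs, gene_set)), integer(1))
  # upper tail including k: P(X >= k)
  p_raw <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_adj <- correct_pvalues(p_raw, method)
  data.frame(
    term_id = names(ann), k = k, n_set = n, K_term = K, N = N,
    p_raw = p_raw, p_adj = p_adj, significant = p_adj < alpha,
    row.names = NULL
  )
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(m * p, 1)`) or Benjamini-Hochberg step-up adjusted
#' p-values.  Stands in for graph-aware corrections such as g:SCS, which
#' are deliberately out of scope.
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same order as the input.
#' @export
correct_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

# Depth of every term = length of the shortest root-to-term path
# (roots, i.e. terms with no parent, have depth 0).
term_depths <- function(graph) {
  g <- graph$igraph
  roots <- names(which(igraph::degree(g, mode = "out") == 0))
  d <- igraph::distances(g, v = roots, mode = "in")
  depths <- apply(d, 2, min)
  depths[!is.finite(depths)] <- NA_real_
  depths
}

#' Roll significant terms up to ancestor terms at a given depth
#'
#' Maps each term to its ancestor(s) at `ancestor_level` steps from the
#' roots (depth = shortest path from a root; roots have depth 0).  Terms
#' at or above the requested level map to themselves; a term whose
#' ancestor set has no member at exactly the level maps to its deepest
#' ancestors not exceeding it.  A term may appear under several
#' ancestors (one row per ancestor-term pair).
#'
#' @param significant_terms Character vector of term ids present in the
#'   graph.
#' @param graph A [term_graph()].
#' @param ancestor_level Target depth of the grouping ancestors
#'   (default 1).
#' @return Data frame with columns `ancestor`, `term`.
#' @export
rollup_ancestors <- function(significant_terms, graph, ancestor_level = 1) {
  stopifnot(ancestor_level >= 0)
  missing <- setdiff(significant_terms, graph$terms)
  if (length(missing))
    stop("term(s) absent from graph: ", paste(missing, collapse = ", "))
  depths <- term_depths(graph)
  g <- graph$igraph
  rows <- lapply(significant_terms, function(t) {
    if (!is.na(depths[t]) && depths[t] <= ancestor_level)
      return(data.frame(ancestor = t, term = t))
    anc <- setdiff(names(igraph::subcomponent(g, t, mode = "out")), t)
    da <- depths[anc]
    at_level <- anc[!is.na(da) & da == ancestor_level]
    if (length(at_level) == 0) {
      below <- anc[!is.na(da) & da < ancestor_level]
      if (length(below) == 0) return(data.frame(ancestor = t, term = t))
      at_level <- below[depths[below] == max(depths[below])]
    }
    data.frame(ancestor = sort(at_level), term = t)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
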