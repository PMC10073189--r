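#' Rank a reference signature by descending z-score
#'
#' Produces the ordered gene list a query is scored against.  Ordering
#' is strict: z descending, ties broken by gene id.
#'
#' @param sig An `expression_signature`.
#' @return Object of class `ranked_reference` (ordered `gene_ids`,
#'   aligned `z`, metadata).
#' @export
rank_reference <- function(sig) {
  ord <- order(-sig$z, sig$gene_ids)
  structure(list(
    gene_ids = sig$gene_ids[ord],
    z = sig$z[ord],
    meta = sig$meta,
    id = sig$id
  ), class = "ranked_reference")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum enrichment of a gene set in a ranked reference: walking
#' down the ranked list, hitting a set member increments the sum by
#' `|z|^w / sum_set |z|^w` and a miss decrements by `1 / (N - n)`; the
#' score is the running deviation of maximum absolute value (signed),
#' bounded in \[-1, 1\].  When the positive and negative extremes tie in
#' magnitude (within 1e-12) the positive deviation is returned: a
#' deterministic rule robust to floating-point accumulation order.
#'
#' @param reference A `ranked_reference`.
#' @param gene_set Character vector of gene ids; must be a proper
#'   non-empty subset of the reference genes.
#' @param weight_exponent Weight on `|z|` (default 1; 0 recovers the
#'   classic unweighted statistic).
#' @return Enrichment score in \[-1, 1\].
#' @export
weighted_ks_enrichment <- function(reference, gene_set, weight_exponent = 1) {
  stopifnot(inherits(reference, "ranked_reference"))
  N <- length(reference$gene_ids)
  gene_set <- unique(gene_set)
  n <- length(gene_set)
  if (n == 0) stop("gene set is empty")
  if (n >= N) stop("gene set must be a proper subset of the reference genes")
  hit <- reference$gene_ids %in% gene_set
  if (sum(hit) != n) stop("gene set contains genes absent from the reference")
  w <- abs(reference$z)^weight_exponent
  wsum <- sum(w[hit])
  inc <- numeric(N)
  if (wsum > 0) {
    inc[hit] <- w[hit] / wsum
  } else {
    inc[hit] <- 1 / n   # degenerate all-zero weights: fall back to uniform
  }
  inc[!hit] <- -1 / (N - n)
  run <- cumsum(inc)
  hi <- max(run); lo <- min(run)
  if (hi >= -lo - 1e-12) hi else lo
}

#' Weighted two-sided connectivity score (WTCS)
#'
#' Combines the enrichment of the query's up and down gene sets in a
#' ranked reference: `wtcs = (ES_up - ES_down) / 2` when the two scores
#' have opposite signs, and 0 otherwise (the opposite-sign rule).  Query
#' genes absent from the reference are dropped with a warning; at least
#' half of each side must survive.
#'
#' @param query A `query_signature`.
#' @param reference A `ranked_reference`.
#' @param weight_exponent Passed to [weighted_ks_enrichment()].
#' @return Score in \[-1, 1\].
#' @export
wtcs <- function(query, reference, weight_exponent = 1) {
  stopifnot(inherits(query, "query_signature"))
  up <- intersect(query$up, reference$gene_ids)
  down <- intersect(query$down, reference$gene_ids)
  n_dropped <- (length(query$up) - length(up)) +
    (length(query$down) - length(down))
  if (n_dropped > 0)
    warning(n_dropped, " query gene(s) absent from reference dropped")
  if (length(up) == 0 && length(down) == 0)
    stop("both query sides empty after intersecting with the reference")
  if (length(up) < length(query$up) / 2 || length(down) < length(query$down) / 2)
    stop("fewer than half of a query side remains after intersection")
  es_up <- weighted_ks_enrichment(reference, up, weight_exponent)
  es_down <- weighted_ks_enrichment(reference, down, weight_exponent)
  if (es_up * es_down < 0) (es_up - es_down) / 2 else 0
}

#' Sign-stratified normalization of raw connectivity scores
#'
#' Normalizes a query x reference WTCS matrix to NCS by dividing each
#' score by the mean |WTCS| of the same-sign scores within the
#' reference's group (cell line x perturbation type); zeros stay zero.
#'
#' @param raw Numeric matrix, queries x references.
#' @param groups Character/factor vector assigning every reference
#'   column to a group.
#' @return NCS matrix of the same shape.
#' @export
normalize_scores <- function(raw, groups) {
  if (length(groups) != ncol(raw))
    stop("every reference must be assigned to a group")
  ncs <- raw
  for (g in unique(groups)) {
    block <- raw[, groups == g, drop = FALSE]
    pos <- block[block > 0]; neg <- block[block < 0]
    mu_pos <- if (length(pos)) mean(pos) else NA_real_
    mu_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    if ((length(pos) && mu_pos == 0) || (length(neg) && mu_neg == 0))
      stop("group '", g, "' has zero same-sign mean with nonzero members")
    block[block > 0] <- block[block > 0] / mu_pos
    block[block < 0] <- block[block < 0] / mu_neg
    ncs[, groups == g] <- block
  }
  ncs
}

#' Tau percentile of a normalized connectivity score
#'
#' `tau = sign(ncs) * 100 * (fraction of touchstone |NCS| values strictly
#' below |ncs|)`, in \[-100, 100\].
#'
#' @param ncs_value Normalized connectivity score.
#' @param touchstone_ncs NCS values of the touchstone references in the
#'   same (cell line, perturbation type) group.
#' @return Tau in \[-100, 100\].
#' @export
tau_percentile <- function(ncs_value, touchstone_ncs) {
  if (length(touchstone_ncs) == 0) stop("touchstone group is empty")
  sign(ncs_value) * 100 * mean(abs(touchstone_ncs) < abs(ncs_value))
}

#' Summarize per-cell-line Tau scores into one value
#'
#' The maximal-magnitude quantile rule: take the 33rd and 67th
#' percentiles (nearest-rank) of the per-cell-line values and return
#' whichever has the larger absolute value (ties favour the upper
#' quantile).
#'
#' @param per_cell_taus Numeric vector, one Tau per cell line (>= 1).
#' @return Summary Tau.
#' @export
summarize_across_cells <- function(per_cell_taus) {
  x <- per_cell_taus[!is.na(per_cell_taus)]
  if (length(x) == 0) stop("need at least one cell-line value")
  s <- sort(x)
  n <- length(s)
  q_lo <- s[ceiling(0.33 * n)]
  q_hi <- s[ceiling(0.67 * n)]
  if (abs(q_hi) >= abs(q_lo)) q_hi else q_lo
}

#' Average Tau over query compounds
#'
#' Arithmetic mean of each reference's Tau over all query compounds
#' (e.g. the average connectivity of a reference with the six statin
#' queries).
#'
#' @param taus Numeric matrix, queries x references; no missing entries
#'   allowed.
#' @return Named vector of mean Tau per reference.
#' @export
average_connectivity <- function(taus) {
  if (anyNA(taus)) {
    bad <- colnames(taus)[colSums(is.na(taus)) > 0]
    stop("missing Tau for reference(s): ", paste(bad, collapse = ", "))
  }
  colMeans(taus)
}

#' Drop duplicate compound profiles, preferring touchstone ids
#'
#' When the same compound name was profiled under more than one
#' compound id, only the touchstone-flagged id is retained (first id
#' lexicographically if the flag does not disambiguate).
#'
#' @param x A [signature_matrix()].
#' @param compounds A [compound_table()] keyed by `compound_id`.
#' @return A reduced `signature_matrix`.
#' @export
dedupe_references <- function(x, compounds) {
  cm <- x$column_meta
  ts <- setNames(compounds$in_touchstone, compounds$compound_id)
  keep <- rep(TRUE, ncol(x$values))
  for (nm in unique(cm$compound)) {
    idx <- which(cm$compound == nm)
    if (length(idx) < 2) next
    by_cell <- split(idx, cm$cell_line[idx])
    for (idx_c in by_cell) {
      if (length(idx_c) < 2) next
      flag <- ts[cm$compound_id[idx_c]]
      flag[is.na(flag)] <- FALSE
      pick <- if (any(flag)) idx_c[flag][order(cm$compound_id[idx_c][flag])][1]
              else idx_c[order(cm$compound_id[idx_c])][1]
      keep[setdiff(idx_c, pick)] <- FALSE
    }
  }
  subset_columns(x, colnames(x$values)[keep])
}

#' Subset a signature matrix by column ids
#' @param x A [signature_matrix()].
#' @param ids Column ids to keep.
#' @return A `signature_matrix`.
#' @export
subset_columns <- function(x, ids) {
  stopifnot(all(ids %in% colnames(x$values)))
  signature_matrix(x$values[, ids, drop = FALSE],
                   is_landmark = x$gene_is_landmark,
                   column_meta = x$column_meta[ids, , drop = FALSE])
}

#' Full connectivity profile of a set of queries against a reference set
#'
#' Drives the scoring chain within each cell line: WTCS for every
#' query x reference pair, sign-stratified normalization to NCS within
#' (cell line, perturbation type) groups, Tau percentiles against the
#' touchstone members of each group (the scored reference itself is
#' excluded from its percentile background), then cross-cell-line
#' summarization and averaging over the query compounds.
#'
#' @param x A [signature_matrix()] holding the reference signatures.
#' @param queries List of `query_signature` objects.
#' @param compounds A [compound_table()]; `in_touchstone` defines the
#'   percentile background.  Groups with no touchstone member fall back
#'   to the full group.
#' @param weight_exponent KS weight exponent (default 1).
#' @return List with `long` (data frame: query_id, reference_id,
#'   compound, cell_line, wtcs, ncs, tau), `summary_tau` (query x
#'   compound matrix, Tau summarized across cell lines) and `avg_tau`
#'   (named vector: mean summarized Tau per reference compound).
#' @export
connectivity_scores <- function(x, queries, compounds = NULL,
                                weight_exponent = 1) {
  validate_signature_matrix(x)
  cm <- x$column_meta
  if (is.null(compounds)) {
    compounds <- compound_table(data.frame(
      compound_id = unique(cm$compound_id),
      name = unique(cm$compound_id)))
  }
  ts <- setNames(compounds$in_touchstone, compounds$compound_id)
  is_ts <- ts[cm$compound_id]
  is_ts[is.na(is_ts)] <- FALSE
  groups <- paste(cm$cell_line, cm$pert_type, sep = "|")
  qids <- vapply(queries, function(q) q$query_id, character(1))
  refs <- colnames(x$values)

  ranked <- lapply(refs, function(id) rank_reference(get_signature(x, id)))
  names(ranked) <- refs
  W <- matrix(0, length(queries), length(refs), dimnames = list(qids, refs))
  for (i in seq_along(queries)) for (j in seq_along(refs)) {
    W[i, j] <- wtcs(queries[[i]], ranked[[j]], weight_exponent)
  }
  NCS <- normalize_scores(W, groups)
  TAU <- NCS * NA_real_
  for (g in unique(groups)) {
    in_g <- which(groups == g)
    bg <- in_g[is_ts[in_g]]
    if (length(bg) == 0) bg <- in_g       # no touchstone member: full group
    for (i in seq_len(nrow(NCS))) for (j in in_g) {
      TAU[i, j] <- tau_percentile(NCS[i, j], NCS[i, setdiff(bg, j)])
    }
  }
  long <- data.frame(
    query_id = rep(qids, times = length(refs)),
    reference_id = rep(refs, each = length(qids)),
    compound = rep(cm$compound, each = length(qids)),
    cell_line = rep(cm$cell_line, each = length(qids)),
    wtcs = as.vector(W), ncs = as.vector(NCS), tau = as.vector(TAU),
    row.names = NULL
  )
  # summarize per (query, compound) across cell lines
  comps <- unique(cm$compound)
  S <- matrix(NA_real_, length(qids), length(comps),
              dimnames = list(qids, comps))
  for (i in seq_along(qids)) for (cp in comps) {
    S[i, cp] <- summarize_across_cells(TAU[i, cm$compound == cp])
  }
  list(long = long, summary_tau = S, avg_tau = average_connectivity(S))
}
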