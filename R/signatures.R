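#' Extract one perturbation signature from a signature matrix
#'
#' @param x A [signature_matrix()].
#' @param column_id Column (perturbation) id.
#' @return Object of class `expression_signature`: gene ids, z-scores,
#'   landmark flags and the column metadata.
#' @export
get_signature <- function(x, column_id) {
  validate_signature_matrix(x)
  j <- match(column_id, colnames(x$values))
  if (is.na(j)) stop("no such column id: ", column_id)
  structure(list(
    gene_ids = rownames(x$values),
    z = unname(x$values[, j]),
    is_landmark = x$gene_is_landmark,
    meta = as.list(x$column_meta[j, , drop = FALSE]),
    id = column_id
  ), class = "expression_signature")
}

#' Build a query signature from the extreme landmark genes
#'
#' Selects the `k` landmark genes with the largest z-scores (the "up"
#' set) and the `k` with the smallest (the "down" set), the standard
#' construction for connectivity queries (default `k = 50`).  Ties in z
#' are broken by lexicographic gene id so the result is deterministic
#' and independent of the input gene order.
#'
#' @param sig An `expression_signature` (see [get_signature()]).
#' @param k Genes per side; the signature must contain at least `2 * k`
#'   landmark genes (no silent truncation).
#' @return Object of class `query_signature` with ordered `up` and
#'   `down` gene vectors.
#' @export
build_query <- function(sig, k = 50) {
  stopifnot(inherits(sig, "expression_signature"), k >= 1)
  lm_idx <- which(sig$is_landmark)
  if (length(lm_idx) < 2 * k)
    stop(sprintf("need >= %d landmark genes to build a k=%d query, have %d",
                 2 * k, k, length(lm_idx)))
  ids <- sig$gene_ids[lm_idx]
  z <- sig$z[lm_idx]
  ord_up <- order(-z, ids)     # z desc, ties by gene id
  ord_dn <- order(z, ids)      # z asc, ties by gene id
  structure(list(
    up = ids[ord_up[seq_len(k)]],
    down = ids[ord_dn[seq_len(k)]],
    k = k,
    query_id = sig$id
  ), class = "query_signature")
}

#' Write a query signature as two-column TSV (gene, direction)
#' @param q A `query_signature`.
#' @param path Output path.
#' @export
write_query <- function(q, path) {
  df <- data.frame(gene = c(q$up, q$down),
                   direction = rep(c("up", "down"), each = q$k))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson correlation between two signatures
#'
#' Computed over the intersection of gene ids, either across all genes
#' (the default, mirroring correlation over the full profiled gene
#' space) or landmark genes only.
#'
#' @param a,b `expression_signature` objects.
#' @param gene_scope `"all"` or `"landmark"`.
#' @return Pearson r.
#' @export
signature_correlation <- function(a, b, gene_scope = c("all", "landmark")) {
  gene_scope <- match.arg(gene_scope)
  ga <- a$gene_ids; gb <- b$gene_ids
  if (gene_scope == "landmark") {
    ga <- ga[a$is_landmark]; gb <- gb[b$is_landmark]
  }
  shared <- intersect(ga, gb)
  if (length(shared) < 3) stop("need >= 3 shared genes for correlation")
  za <- a$z[match(shared, a$gene_ids)]
  zb <- b$z[match(shared, b$gene_ids)]
  if (sd(za) == 0 || sd(zb) == 0)
    stop("correlation undefined for a constant signature")
  cor(za, zb)
}

#' Drop discordant compounds from a signature collection
#'
#' For each compound, computes its mean pairwise Pearson correlation
#' with all other compounds in the collection and drops compounds whose
#' mean falls below `min_mean_r`.  This reproduces the pre-filtering of
#' a query drug class where one member shows poor agreement with the
#' rest (e.g. a statin whose signature does not correlate with the other
#' statins).
#'
#' @param sigs List of `expression_signature` objects (>= 3).
#' @param min_mean_r Threshold on the mean pairwise correlation
#'   (default 0.2).
#' @param gene_scope Passed to [signature_correlation()].
#' @return List with `kept`, `dropped` (character ids) and `report`
#'   (data frame of per-compound mean correlations).
#' @export
concordance_filter <- function(sigs, min_mean_r = 0.2,
                               gene_scope = c("all", "landmark")) {
  gene_scope <- match.arg(gene_scope)
  if (length(sigs) < 3) stop("need >= 3 compounds for a concordance filter")
  ids <- vapply(sigs, function(s) s$id, character(1))
  n <- length(sigs)
  rmat <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rmat[i, j] <- rmat[j, i] <-
      signature_correlation(sigs[[i]], sigs[[j]], gene_scope)
  }
  mean_r <- (rowSums(rmat) - 1) / (n - 1)
  keep <- mean_r >= min_mean_r
  list(
    kept = ids[keep],
    dropped = ids[!keep],
    report = data.frame(compound = ids, mean_r = mean_r,
                        kept = keep, row.names = NULL)
  )
}
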