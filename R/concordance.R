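#' Genes perturbed by a compound
#'
#' Splits a signature into up- and down-regulated gene sets by a strict
#' z-score threshold: `up = {z > threshold}`, `down = {z < -threshold}`
#' (a gene at exactly +/- threshold is excluded).
#'
#' @param sig An `expression_signature`.
#' @param threshold Positive z-score cutoff (default 1; 1.5 and 2 are
#'   the usual sensitivity settings).
#' @return List with `up`, `down` (character gene sets) and `threshold`.
#' @export
perturbed_genes <- function(sig, threshold = 1) {
  stopifnot(threshold > 0)
  list(up = sig$gene_ids[sig$z > threshold],
       down = sig$gene_ids[sig$z < -threshold],
       threshold = threshold)
}

#' Directional overlap of genes perturbed by two compounds
#'
#' Genes differentially expressed (|z| > threshold) by both compounds,
#' split by whether the two compounds move them in the same or opposite
#' direction.
#'
#' @param sig_a,sig_b `expression_signature` objects over a shared gene
#'   universe.
#' @param threshold Passed to [perturbed_genes()].
#' @return List with `same_direction`, `opposite_direction`, per-class
#'   subsets (`same_up`, `same_down`) and the compound `pair`.
#' @export
shared_perturbation <- function(sig_a, sig_b, threshold = 1) {
  pa <- perturbed_genes(sig_a, threshold)
  pb <- perturbed_genes(sig_b, threshold)
  same_up <- intersect(pa$up, pb$up)
  same_down <- intersect(pa$down, pb$down)
  opposite <- union(intersect(pa$up, pb$down), intersect(pa$down, pb$up))
  list(
    same_direction = union(same_up, same_down),
    opposite_direction = opposite,
    same_up = same_up, same_down = same_down,
    pair = c(sig_a$id, sig_b$id),
    threshold = threshold
  )
}

#' Per-pair directional table for reporting
#'
#' @param sig_a,sig_b `expression_signature` objects.
#' @param threshold z-score cutoff.
#' @return Data frame: gene, z_a, z_b, direction_class in
#'   \{same_up, same_down, opposite\}.
#' @export
shared_perturbation_table <- function(sig_a, sig_b, threshold = 1) {
  sp <- shared_perturbation(sig_a, sig_b, threshold)
  genes <- c(sp$same_up, sp$same_down, sp$opposite_direction)
  cls <- c(rep("same_up", length(sp$same_up)),
           rep("same_down", length(sp$same_down)),
           rep("opposite", length(sp$opposite_direction)))
  data.frame(
    gene = genes,
    z_a = sig_a$z[match(genes, sig_a$gene_ids)],
    z_b = sig_b$z[match(genes, sig_b$gene_ids)],
    direction_class = cls,
    row.names = NULL
  )
}
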