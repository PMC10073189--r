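#' Parameters for the signature simulator
#'
#' The generator emulates the statistical structure of a perturbation
#' signature collection: compounds of the same class share a latent
#' per-gene perturbation direction, scaled by `strength` and buried in
#' i.i.d. Gaussian noise, then column-standardized to a z-like scale.
#' Two classes can be made pharmacologically concordant by pointing them
#' at the same latent id.  The default world mirrors the analysis scale
#' of a single-cell-line compound screen: 978 landmark genes, 6 statins
#' and 12 of 38 antidepressants sharing one latent direction, 2 inert
#' controls, and 100 background compounds each with its own latent.
#'
#' @param n_genes Number of genes (default 978).
#' @param n_landmark Number of landmark genes (first `n_landmark` gene
#'   ids; default `n_genes`).
#' @param classes Data frame with columns `label` (class vocabulary
#'   entry), `n_compounds`, `strength` (latent scale, >= 0) and `latent`
#'   (latent id; `NA` gives every compound its own latent).
#' @param noise_sd Gene-level noise standard deviation (> 0, default 1).
#' @param cell_lines Character vector of cell lines (default `"HA1E"`).
#' @param latent_cell_cor Correlation of class latents across cell lines
#'   (0 = independently drawn per cell line, the default).
#' @param seed Integer seed.
#' @return List of class `sig_sim_params`.
#' @export
sig_sim_params <- function(n_genes = 978, n_landmark = n_genes,
                           classes = NULL, noise_sd = 1,
                           cell_lines = "HA1E", latent_cell_cor = 0,
                           seed = 1) {
  if (is.null(classes)) {
    classes <- data.frame(
      label = c("statin", "antidepressant", "antidepressant",
                "control", "background"),
      n_compounds = c(6L, 12L, 26L, 2L, 100L),
      strength = c(2, 2, 2, 2, 2),
      latent = c("L_lipid", "L_lipid", "L_ad", "L_ctl", NA),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(n_landmark <= n_genes, n_landmark >= 1, noise_sd > 0,
            all(classes$strength >= 0), all(classes$n_compounds >= 1),
            latent_cell_cor >= 0, latent_cell_cor <= 1)
  structure(list(n_genes = n_genes, n_landmark = n_landmark,
                 classes = classes, noise_sd = noise_sd,
                 cell_lines = cell_lines,
                 latent_cell_cor = latent_cell_cor, seed = seed),
            class = "sig_sim_params")
}

#' Simulate a signature collection with planted compound classes
#'
#' @param params A [sig_sim_params()].
#' @return List with `signatures` (a [signature_matrix()]), `compounds`
#'   (a [compound_table()]) and `truth` (latent assignment per compound
#'   and the latent vectors per cell line).
#' @export
simulate_signatures <- function(params = sig_sim_params()) {
  stopifnot(inherits(params, "sig_sim_params"))
  withr::local_seed(params$seed)
  cl <- params$classes
  n_cpd <- sum(cl$n_compounds)
  gene_ids <- sprintf("G%05d", seq_len(params$n_genes))
  is_lm <- seq_len(params$n_genes) <= params$n_landmark

  class_label <- rep(cl$label, cl$n_compounds)
  strength <- rep(cl$strength, cl$n_compounds)
  latent_id <- rep(ifelse(is.na(cl$latent),
                          paste0("L_own_", seq_len(nrow(cl))), cl$latent),
                   cl$n_compounds)
  own <- is.na(rep(cl$latent, cl$n_compounds))
  latent_id[own] <- paste0(latent_id[own], "_", which(own))
  compound_id <- sprintf("CPD-%03d", seq_len(n_cpd))
  # names numbered within label so that class rows sharing a label (e.g.
  # two antidepressant subsets on different latents) never collide
  name <- character(n_cpd)
  for (lbl in unique(class_label)) {
    idx <- which(class_label == lbl)
    name[idx] <- sprintf("%s_%02d", lbl, seq_along(idx))
  }
  atc <- c(statin = "C10AA", antidepressant = "N06A")[class_label]

  lat_ids <- unique(latent_id)
  rho <- params$latent_cell_cor
  base <- matrix(rnorm(params$n_genes * length(lat_ids)),
                 params$n_genes, length(lat_ids), dimnames = list(gene_ids, lat_ids))
  latents <- list()
  cols <- list(); meta <- list()
  for (cell in params$cell_lines) {
    L <- if (rho == 1) base else
      rho * base + sqrt(1 - rho^2) *
        matrix(rnorm(length(base)), nrow(base), ncol(base),
               dimnames = dimnames(base))
    latents[[cell]] <- L
    for (j in seq_len(n_cpd)) {
      z <- strength[j] * L[, latent_id[j]] +
        rnorm(params$n_genes, 0, params$noise_sd)
      z <- z / sd(z)  # z-like scale
      cid <- sprintf("%s:%s", compound_id[j], cell)
      cols[[cid]] <- z
      meta[[cid]] <- data.frame(
        compound = name[j], compound_id = compound_id[j], cell_line = cell,
        dose = "10 uM", time = "24 h", pert_type = "trt_cp",
        stringsAsFactors = FALSE)
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- gene_ids
  cm <- do.call(rbind, meta)
  rownames(cm) <- colnames(vals)
  sig <- signature_matrix(vals, is_landmark = is_lm, column_meta = cm)
  compounds <- compound_table(data.frame(
    compound_id = compound_id, name = name, atc_code = unname(atc),
    class_label = class_label, in_touchstone = TRUE,
    stringsAsFactors = FALSE))
  truth <- list(
    latent_id = setNames(latent_id, compound_id),
    strength = setNames(strength, compound_id),
    latents = latents,
    params = params
  )
  list(signatures = sig, compounds = compounds, truth = truth)
}

#' Simulate a random ontology DAG with gene annotations
#'
#' Terms are arranged in levels 0 (roots) to `depth`; each non-root term
#' draws 1-2 parents from strictly shallower levels, guaranteeing
#' acyclicity.  Each gene is directly annotated to 1-3 random terms;
#' ancestor closure is left to [materialize_annotations()].
#'
#' @param n_terms Number of terms (>= depth + 1).
#' @param n_genes Number of genes, or a character vector of gene ids.
#' @param depth Maximum depth (>= 1).
#' @param seed Integer seed.
#' @param n_roots Number of root terms (default `max(1, n_terms %/% 10)`).
#' @return A [term_graph()].
#' @export
simulate_term_graph <- function(n_terms = 50, n_genes = 200, depth = 3,
                                seed = 1, n_roots = max(1L, n_terms %/% 10L)) {
  stopifnot(depth >= 1, n_terms >= depth + 1, n_roots >= 1,
            n_terms - n_roots >= depth)
  withr::local_seed(seed)
  genes <- if (is.character(n_genes)) n_genes
           else sprintf("G%05d", seq_len(n_genes))
  term_ids <- sprintf("T%04d", seq_len(n_terms))
  level <- integer(n_terms)
  level[seq_len(n_roots)] <- 0L
  rest <- setdiff(seq_len(n_terms), seq_len(n_roots))
  # make sure every level 1..depth is populated, then fill randomly
  lv <- c(seq_len(depth), sample(seq_len(depth), length(rest) - depth,
                                 replace = TRUE))
  level[rest] <- sort(lv)
  edges <- list()
  for (i in rest) {
    shallower <- which(level < level[i])
    np <- sample(1:2, 1)
    parents <- sample(shallower, min(np, length(shallower)))
    edges[[length(edges) + 1L]] <-
      data.frame(child = term_ids[i], parent = term_ids[parents])
  }
  edges <- do.call(rbind, edges)
  ann <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g,
               term = sample(term_ids, sample(1:3, 1)))
  }))
  term_graph(edges, ann,
             term_names = setNames(paste("term", term_ids), term_ids))
}

#' Parameters for the two-cohort genotype/phenotype simulator
#'
#' Genotypes are drawn from an AR(1)-correlated latent Gaussian
#' thresholded to Hardy-Weinberg dosages, so adjacent variants are in
#' tunable LD.  Expression and trait are standardized to unit variance
#' before effect injection, so `b_zx` is in SD-of-expression per allele
#' and `b_xy` in SD-per-SD units.  Three scenarios: `causal` (the
#' eQTL variant drives the trait through expression), `null`
#' (`b_xy = 0`), and `linkage` (the trait is driven directly by a second
#' variant in LD with the eQTL variant, target `r^2` = `linkage_r2`).
#' The eQTL and GWAS cohorts are drawn independently (two-sample
#' setting, no overlap), and LD is estimated from a third reference
#' sample.
#'
#' @param n_individuals Per-cohort sample size (default 10000).
#' @param n_variants Number of cis-region variants (default 15).
#' @param maf Minor/effect allele frequency in (0, 0.5\], scalar or
#'   per-variant (default 0.3).
#' @param ld_decay_rho AR(1) latent correlation in \[0, 1) (default 0.8).
#' @param b_zx Variant -> expression effect, SD per allele (default 0.3).
#' @param b_xy Expression -> trait effect, SD per SD (default 0.2); in
#'   the linkage scenario this is the direct per-SD-of-genotype effect
#'   of the second variant on the trait.
#' @param scenario `"causal"`, `"null"` or `"linkage"`.
#' @param linkage_r2 Target genotype `r^2` between the two causal
#'   variants in the linkage scenario (default 0.6).
#' @param n_ld_ref LD reference sample size (default 2000).
#' @param seed Integer seed.
#' @return List of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_individuals = 10000, n_variants = 15,
                              maf = 0.3, ld_decay_rho = 0.8,
                              b_zx = 0.3, b_xy = 0.2,
                              scenario = c("causal", "null", "linkage"),
                              linkage_r2 = 0.6, n_ld_ref = 2000, seed = 1) {
  scenario <- match.arg(scenario)
  maf <- rep(maf, length.out = n_variants)
  stopifnot(all(maf > 0), all(maf <= 0.5),
            ld_decay_rho >= 0, ld_decay_rho < 1,
            n_individuals >= 10, n_variants >= 1)
  if (scenario == "linkage" && n_variants < 2)
    stop("linkage scenario requires at least 2 variants")
  structure(list(n_individuals = n_individuals, n_variants = n_variants,
                 maf = maf, ld_decay_rho = ld_decay_rho, b_zx = b_zx,
                 b_xy = b_xy, scenario = scenario, linkage_r2 = linkage_r2,
                 n_ld_ref = n_ld_ref, seed = seed),
            class = "cohort_sim_params")
}

# latent-Gaussian AR(1) genotypes under Hardy-Weinberg; n x m dosages
.sim_genotypes <- function(n, maf, rho) {
  m <- length(maf)
  Z <- matrix(rnorm(n * m), n, m)
  if (m > 1 && rho > 0) {
    R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
    Z <- Z %*% chol(R)
  }
  thr0 <- qnorm((1 - maf)^2)   # below: 0 copies
  thr1 <- qnorm(1 - maf^2)     # above: 2 copies
  G <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    G[, j] <- (Z[, j] > thr0[j]) + (Z[, j] > thr1[j])
  }
  G
}

# per-variant marginal OLS of y on each dosage column
.marginal_stats <- function(G, y, ids, alleles) {
  n <- length(y)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  sxy <- as.vector(crossprod(Gc, yc))
  b <- sxy / sxx
  syy <- sum(yc^2)
  sigma2 <- pmax((syy - b * sxy) / (n - 2), 1e-12)
  se <- sqrt(sigma2 / sxx)
  p <- pmax(2 * pnorm(-abs(b / se)), 1e-300)
  sumstats(data.frame(
    SNP = ids, A1 = alleles$a1, A2 = alleles$a2,
    freq = colMeans(G) / 2, b = b, se = se, p = p, N = n,
    stringsAsFactors = FALSE))
}

#' Simulate two-cohort eQTL + GWAS summary statistics with known truth
#'
#' @param params A [cohort_sim_params()].
#' @param flip_gwas_coding Randomly code half of the GWAS records on the
#'   other allele (exercises harmonization; default `TRUE`).
#' @return List with `eqtl` and `gwas` (`sumstats` tables), `ld`
#'   (list: `ld` signed correlation matrix, `variant_ids`, `n_ref`) and
#'   `truth` (scenario, `true_b_xy`, causal variant ids, realized
#'   linkage `r^2`).
#' @export
simulate_cohort <- function(params = cohort_sim_params(),
                            flip_gwas_coding = TRUE) {
  stopifnot(inherits(params, "cohort_sim_params"))
  withr::local_seed(params$seed)
  m <- params$n_variants
  n <- params$n_individuals
  ids <- sprintf("rs%04d", seq_len(m))
  pair_pool <- rbind(c("A", "G"), c("T", "C"), c("C", "A"), c("G", "T"))
  pick <- sample(nrow(pair_pool), m, replace = TRUE)
  alleles <- list(a1 = pair_pool[pick, 1], a2 = pair_pool[pick, 2])

  vc <- (m + 1L) %/% 2L  # causal eQTL variant: middle of the region
  var_g <- 2 * params$maf[vc] * (1 - params$maf[vc])
  if (params$b_zx^2 * var_g >= 1)
    stop("b_zx too large: explained expression variance >= 1")

  # LD reference first, so the linkage partner can be chosen from it
  G_ref <- .sim_genotypes(params$n_ld_ref, params$maf, params$ld_decay_rho)
  rownames_ld <- ids
  ldm <- ld_from_dosages(t(G_ref))
  dimnames(ldm) <- list(ids, ids)

  v2 <- NA_integer_; realized_r2 <- NA_real_
  if (params$scenario == "linkage") {
    r2 <- ldm[vc, ]^2
    r2[vc] <- NA
    v2 <- which.min(abs(r2 - params$linkage_r2))
    realized_r2 <- ldm[vc, v2]^2
  }

  # eQTL cohort: expression x driven by the causal variant
  G1 <- .sim_genotypes(n, params$maf, params$ld_decay_rho)
  x1 <- params$b_zx * G1[, vc] +
    rnorm(n, 0, sqrt(1 - params$b_zx^2 * var_g))
  eqtl <- .marginal_stats(G1, x1, ids, alleles)

  # GWAS cohort: independent sample
  G2 <- .sim_genotypes(n, params$maf, params$ld_decay_rho)
  y <- switch(params$scenario,
    causal = {
      x2 <- params$b_zx * G2[, vc] +
        rnorm(n, 0, sqrt(1 - params$b_zx^2 * var_g))
      params$b_xy * x2 + rnorm(n, 0, sqrt(max(1 - params$b_xy^2, 1e-8)))
    },
    null = rnorm(n),
    linkage = {
      g2s <- (G2[, v2] - mean(G2[, v2])) / sd(G2[, v2])
      params$b_xy * g2s + rnorm(n, 0, sqrt(max(1 - params$b_xy^2, 1e-8)))
    })
  gwas <- .marginal_stats(G2, y, ids, alleles)

  if (flip_gwas_coding) {
    fl <- runif(m) < 0.5
    gwas$b[fl] <- -gwas$b[fl]
    gwas$freq[fl] <- 1 - gwas$freq[fl]
    tmp <- gwas$A1[fl]; gwas$A1[fl] <- gwas$A2[fl]; gwas$A2[fl] <- tmp
  }

  truth <- list(
    scenario = params$scenario,
    true_b_xy = if (params$scenario == "causal") params$b_xy else 0,
    causal_variant_eqtl = ids[vc],
    causal_variant_gwas = if (params$scenario == "linkage") ids[v2]
                          else if (params$scenario == "causal") ids[vc]
                          else NA_character_,
    linkage_realized_r2 = realized_r2,
    params = params
  )
  list(eqtl = eqtl, gwas = gwas,
       ld = list(ld = ldm, variant_ids = ids, n_ref = params$n_ld_ref),
       truth = truth)
}

#' Harmonize a whole GWAS region to the eQTL allele coding
#'
#' Applies [harmonize()] row-by-row (matching on `SNP`) and returns the
#' GWAS table re-expressed on the eQTL effect alleles, ready for
#' [heidi_test()].
#'
#' @param eqtl,gwas `sumstats` tables sharing variant ids.
#' @return A `sumstats` table (the harmonized GWAS records, rows in
#'   eQTL order, restricted to shared variants).
#' @export
harmonize_region <- function(eqtl, gwas) {
  shared <- intersect(eqtl$SNP, gwas$SNP)
  eq <- eqtl[match(shared, eqtl$SNP), ]
  gw <- gwas[match(shared, gwas$SNP), ]
  out <- gw
  for (i in seq_len(nrow(eq))) {
    h <- harmonize(eq[i, ], gw[i, ])
    out$A1[i] <- h$effect_allele; out$A2[i] <- h$other_allele
    out$b[i] <- h$b_zy; out$freq[i] <- h$eaf_zy
  }
  out
}
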