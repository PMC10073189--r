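#' Select the strongest eQTL instrument for a gene
#'
#' Instrument strength is approximated by `F = (b/se)^2` (the squared
#' z-score, the usual single-SNP approximation).  Among records passing
#' `f_stat > f_min` the record with the smallest eQTL p-value is
#' returned; ties are broken by variant id.
#'
#' @param eqtl A `sumstats` table of cis-eQTL records for one gene.
#' @param f_min Weak-instrument cutoff (default 10).
#' @return List of class `instrument`: `variant_id`, `b_zx`, `se_zx`,
#'   `p_zx`, `f_stat`, plus the alleles and frequency.
#' @export
select_instrument <- function(eqtl, f_min = 10) {
  if (nrow(eqtl) < 1) stop("no eQTL records")
  f <- (eqtl$b / eqtl$se)^2
  ok <- f > f_min
  if (!any(ok)) stop("no valid instrument: all F-statistics <= ", f_min)
  cand <- eqtl[ok, , drop = FALSE]
  cand_f <- f[ok]
  ord <- order(cand$p, cand$SNP)
  top <- cand[ord[1], ]
  structure(list(
    variant_id = top$SNP, b_zx = top$b, se_zx = top$se, p_zx = top$p,
    f_stat = cand_f[ord[1]], effect_allele = top$A1, other_allele = top$A2,
    eaf = top$freq
  ), class = "instrument")
}

#' Harmonize an eQTL record with a GWAS record
#'
#' Aligns the GWAS effect to the eQTL's effect allele: if the GWAS
#' record is coded on the other allele, its beta sign is flipped (and
#' its allele frequency complemented).  A strand-ambiguous palindromic
#' pair (A/T or C/G) with allele frequency near 0.5 cannot be aligned
#' reliably and is warned about (and dropped when
#' `palindromic_action = "drop"`).  Setting `frame_inhibition` marks the
#' pair so that downstream SMR effects are reported per one standard
#' deviation *decrease* in expression (genetically proxied target
#' inhibition); stored summary statistics are never modified.
#'
#' @param eqtl_rec,gwas_rec Single-row `sumstats` records (or one-row
#'   data frames) for the same variant.
#' @param frame_inhibition Logical; report downstream effects on the
#'   inhibition scale.
#' @param palindromic_action `"warn"` (default) or `"drop"` (returns
#'   `NULL`).
#' @param eaf_window Half-width around 0.5 within which a palindromic
#'   variant counts as ambiguous (default 0.08).
#' @return List of class `harmonized_pair` (or `NULL` when dropped).
#' @export
harmonize <- function(eqtl_rec, gwas_rec, frame_inhibition = FALSE,
                      palindromic_action = c("warn", "drop"),
                      eaf_window = 0.08) {
  palindromic_action <- match.arg(palindromic_action)
  if (eqtl_rec$SNP != gwas_rec$SNP)
    stop("variant ids differ: ", eqtl_rec$SNP, " vs ", gwas_rec$SNP)
  ea <- c(eqtl_rec$A1, eqtl_rec$A2)
  ga <- c(gwas_rec$A1, gwas_rec$A2)
  if (!setequal(ea, ga))
    stop(sprintf("allele mismatch for %s: {%s,%s} vs {%s,%s}",
                 eqtl_rec$SNP, ea[1], ea[2], ga[1], ga[2]))
  pal <- setequal(ea, c("A", "T")) || setequal(ea, c("C", "G"))
  if (pal && abs(eqtl_rec$freq - 0.5) < eaf_window) {
    warning("strand-ambiguous palindromic variant ", eqtl_rec$SNP,
            " with allele frequency near 0.5")
    if (palindromic_action == "drop") return(NULL)
  }
  b_zy <- gwas_rec$b
  eaf_y <- gwas_rec$freq
  if (gwas_rec$A1 != eqtl_rec$A1) {
    b_zy <- -b_zy
    eaf_y <- 1 - eaf_y
  }
  structure(list(
    variant_id = eqtl_rec$SNP,
    effect_allele = eqtl_rec$A1, other_allele = eqtl_rec$A2,
    b_zx = eqtl_rec$b, se_zx = eqtl_rec$se, p_zx = eqtl_rec$p,
    b_zy = b_zy, se_zy = gwas_rec$se, p_zy = gwas_rec$p,
    eaf_zx = eqtl_rec$freq, eaf_zy = eaf_y,
    inhibition_framed = isTRUE(frame_inhibition)
  ), class = "harmonized_pair")
}

#' Summary-data Mendelian randomization test
#'
#' The SMR ratio estimate of the causal effect of exposure (gene
#' expression) on outcome: `b_xy = b_zy / b_zx`, with the chi-square
#' statistic `T = (z_zx^2 * z_zy^2) / (z_zx^2 + z_zy^2)` (1 df),
#' `se_xy = |b_xy| / sqrt(T)` and a Wald 95% CI.  If the pair was
#' harmonized with `frame_inhibition = TRUE` the reported effect (and
#' CI) is negated, i.e. expressed per SD decrease of expression.
#'
#' @param pair A `harmonized_pair`.
#' @return List of class `smr_result`: `b_xy`, `se_xy`, `ci95`,
#'   `t_smr`, `p_smr`.
#' @export
smr_test <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  if (pair$se_zx <= 0 || pair$se_zy <= 0) stop("standard errors must be > 0")
  if (pair$b_zx == 0) stop("b_zx = 0: SMR ratio undefined")
  z_zx2 <- (pair$b_zx / pair$se_zx)^2
  z_zy2 <- (pair$b_zy / pair$se_zy)^2
  b_xy <- pair$b_zy / pair$b_zx
  t_smr <- if (z_zy2 == 0) 0 else (z_zx2 * z_zy2) / (z_zx2 + z_zy2)
  p_smr <- pchisq(t_smr, df = 1, lower.tail = FALSE)
  se_xy <- if (t_smr > 0) abs(b_xy) / sqrt(t_smr) else NA_real_
  if (pair$inhibition_framed) b_xy <- -b_xy
  ci <- if (is.na(se_xy)) c(NA_real_, NA_real_)
        else c(b_xy - 1.96 * se_xy, b_xy + 1.96 * se_xy)
  structure(list(
    variant_id = pair$variant_id,
    b_xy = b_xy, se_xy = se_xy, ci95 = ci,
    t_smr = t_smr, p_smr = p_smr,
    inhibition_framed = pair$inhibition_framed
  ), class = "smr_result")
}

#' Bonferroni threshold for a gene x trait testing grid
#'
#' @param n_genes Number of target genes tested.
#' @param n_traits Number of outcome traits tested.
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / (n_genes * n_traits)` (e.g. 0.05 / (3 x 29) =
#'   0.00057 at two significant figures).
#' @export
multiple_testing_threshold <- function(n_genes, n_traits, alpha = 0.05) {
  stopifnot(n_genes >= 1, n_traits >= 1)
  alpha / (n_genes * n_traits)
}

# Tail probability of Q = sum(lambda_k * chisq_1) at q.
# Imhof's exact inversion formula by numerical quadrature, with a
# Satterthwaite moment-matching fallback and a Monte-Carlo option.
pquadform <- function(q, lambda, method = c("imhof", "satterthwaite", "mc"),
                      nsim = 1e5) {
  method <- match.arg(method)
  lambda <- lambda[abs(lambda) > 1e-12]
  if (length(lambda) == 0) return(1)
  if (q <= 0) return(1)
  if (max(lambda) - min(lambda) < 1e-12 * max(abs(lambda)))  # exact case
    return(pchisq(q / lambda[1], df = length(lambda), lower.tail = FALSE))
  if (method == "mc") {
    draws <- vapply(seq_len(nsim), function(i)
      sum(lambda * rchisq(length(lambda), 1)), numeric(1))
    return(mean(draws >= q))
  }
  if (method == "imhof") {
    theta <- function(u) 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- function(u) exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    integrand <- function(u) sin(theta(u)) / (u * rho(u))
    p <- tryCatch({
      int <- integrate(integrand, lower = 0, upper = Inf,
                       subdivisions = 1000L, rel.tol = 1e-9,
                       stop.on.error = FALSE)
      0.5 + int$value / pi
    }, error = function(e) NA_real_)
    if (!is.na(p)) return(min(max(p, 0), 1))
    # fall through to Satterthwaite on quadrature failure
  }
  sc <- sum(lambda^2) / sum(lambda)
  df <- sum(lambda)^2 / sum(lambda^2)
  pchisq(q / sc, df = df, lower.tail = FALSE)
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Tests whether the SMR ratio estimates from SNPs in LD with the top
#' instrument are mutually consistent, distinguishing a single shared
#' causal variant (consistent ratios, high p) from distinct variants in
#' linkage (heterogeneous ratios, low p).  Candidate SNPs are those with
#' eQTL chi-square above `eqtl_chisq_min` and `r^2` with the top SNP
#' inside `r2_window`, capped at `max_snps` by eQTL significance.  For
#' each candidate the deviation `d_i = b_xy(i) - b_xy(top)` is
#' standardized with a delta-method covariance that uses the signed LD
#' `r`; the statistic `T = sum z_d^2` follows a weighted sum of 1-df
#' chi-squares whose tail probability is computed from the eigenvalues
#' of the `z_d` correlation matrix (Imhof quadrature by default).
#'
#' @param region_eqtl,region_gwas `sumstats` tables over the cis region,
#'   harmonized to the same effect alleles per variant (rows matched by
#'   `SNP`).
#' @param ld Signed LD correlation matrix with variant ids as dimnames
#'   (covering all candidates), or an object with `$ld`.
#' @param top An `instrument` (see [select_instrument()]).
#' @param r2_window Numeric length-2: admissible `r^2` range with the
#'   top SNP (default `c(0.05, 0.9)`).
#' @param max_snps Cap on candidate SNPs (default 20).
#' @param min_snps Minimum candidates required (default 3); below this
#'   the result is flagged not-computed rather than given a p-value.
#' @param eqtl_chisq_min eQTL chi-square cutoff for candidates
#'   (default 10).
#' @param p_method Tail method for the quadratic form (see details).
#' @return List of class `heidi_result`: `p_heidi`, `n_snps_used`
#'   (candidates plus the top SNP), `passed` (`p_heidi > 0.01`),
#'   `computed`.
#' @export
heidi_test <- function(region_eqtl, region_gwas, ld, top,
                       r2_window = c(0.05, 0.9), max_snps = 20,
                       min_snps = 3, eqtl_chisq_min = 10,
                       p_method = c("imhof", "satterthwaite", "mc")) {
  p_method <- match.arg(p_method)
  if (is.list(ld) && !is.matrix(ld)) ld <- ld$ld
  stopifnot(inherits(top, "instrument"))
  if (!(top$variant_id %in% region_eqtl$SNP))
    stop("top instrument absent from the eQTL region")
  shared <- intersect(region_eqtl$SNP, region_gwas$SNP)
  shared <- intersect(shared, rownames(ld))
  eq <- region_eqtl[match(shared, region_eqtl$SNP), ]
  gw <- region_gwas[match(shared, region_gwas$SNP), ]
  if (!all(eq$A1 == gw$A1 & eq$A2 == gw$A2))
    stop("region summary statistics are not allele-aligned; harmonize first")
  t_id <- top$variant_id
  if (!(t_id %in% shared)) stop("top instrument lacks GWAS or LD coverage")
  r_top <- ld[t_id, shared]
  chi_eq <- (eq$b / eq$se)^2
  is_cand <- shared != t_id &
    chi_eq > eqtl_chisq_min &
    r_top^2 >= r2_window[1] & r_top^2 <= r2_window[2]
  cand <- shared[is_cand]
  if (length(cand) > max_snps) {
    ord <- order(eq$p[match(cand, shared)], cand)
    cand <- cand[ord[seq_len(max_snps)]]
  }
  if (length(cand) < min_snps) {
    return(structure(list(p_heidi = NA_real_, n_snps_used = length(cand) + 1L,
                          passed = NA, computed = FALSE),
                     class = "heidi_result"))
  }
  snps <- c(t_id, cand)
  i_eq <- match(snps, shared)
  bzx <- eq$b[i_eq]; szx <- eq$se[i_eq]
  bzy <- gw$b[i_eq]; szy <- gw$se[i_eq]
  R <- ld[snps, snps]
  bxy <- bzy / bzx
  m <- length(snps)
  # delta-method covariance of the ratio estimates, eQTL and GWAS cohorts
  # independent: cov(bxy_i, bxy_j) =
  #   r_ij*szy_i*szy_j/(bzx_i*bzx_j) + bzy_i*bzy_j*r_ij*szx_i*szx_j/(bzx_i^2*bzx_j^2)
  Vxy <- R * outer(szy, szy) / outer(bzx, bzx) +
    outer(bzy, bzy) * R * outer(szx, szx) / outer(bzx^2, bzx^2)
  # d_i = bxy_i - bxy_top for i = 2..m
  idx <- 2:m
  Vd <- Vxy[idx, idx, drop = FALSE] -
    matrix(Vxy[idx, 1], m - 1, m - 1) -
    t(matrix(Vxy[idx, 1], m - 1, m - 1)) +
    Vxy[1, 1]
  d <- bxy[idx] - bxy[1]
  sd_d <- sqrt(diag(Vd))
  z_d <- d / sd_d
  Cd <- Vd / outer(sd_d, sd_d)
  Tstat <- sum(z_d^2)
  lam <- eigen(Cd, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  p <- pquadform(Tstat, lam, method = p_method)
  structure(list(p_heidi = p, n_snps_used = m, passed = p > 0.01,
                 computed = TRUE, t_heidi = Tstat),
            class = "heidi_result")
}
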