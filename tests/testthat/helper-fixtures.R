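# fixtures are built in code; nothing is read from disk

# a bare expression_signature without going through a matrix
as_sig <- function(z, ids = sprintf("g%d", seq_along(z)),
                   landmark = rep(TRUE, length(z)), id = "sig1",
                   cell_line = "HA1E") {
  structure(list(gene_ids = ids, z = z, is_landmark = landmark,
                 meta = list(compound = id, compound_id = id,
                             cell_line = cell_line, dose = "", time = "",
                             pert_type = "trt_cp"),
                 id = id),
            class = "expression_signature")
}

random_signature_matrix <- function(n_genes = 20, n_cols = 5, seed = 42) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n_genes * n_cols), n_genes, n_cols,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("c%02d", seq_len(n_cols))))
    signature_matrix(vals)
  })
}

# independent running-sum oracle for the weighted KS enrichment score:
# explicit loop, written against the definition, not the implementation.
# Ties between the positive and negative extreme favour the positive one
# (the declared tie rule).
brute_force_es <- function(z_desc, hit, w = 1) {
  N <- length(z_desc)
  n <- sum(hit)
  denom <- sum(abs(z_desc[hit])^w)
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(N)) {
    run <- if (hit[i]) {
      run + (if (denom > 0) abs(z_desc[i])^w / denom else 1 / n)
    } else {
      run - 1 / (N - n)
    }
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (hi >= -lo - 1e-12) hi else lo
}

# exact combinatorial upper-tail hypergeometric P(X >= k)
hyper_tail_oracle <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# one-row sumstats record
ss_rec <- function(SNP = "rs1", A1 = "A", A2 = "G", freq = 0.3,
                   b = 0.1, se = 0.02, p = NULL, N = 10000) {
  if (is.null(p)) p <- 2 * pnorm(-abs(b / se))
  sumstats(data.frame(SNP = SNP, A1 = A1, A2 = A2, freq = freq,
                      b = b, se = se, p = p, N = N))
}

# tiny simulated MR dataset -> (instrument, smr pair, heidi inputs)
sim_mr_once <- function(scenario, seed, n_variants = 15, n = 10000,
                        n_ld_ref = 2000) {
  cs <- simulate_cohort(cohort_sim_params(
    scenario = scenario, seed = seed, n_variants = n_variants,
    n_individuals = n, n_ld_ref = n_ld_ref), flip_gwas_coding = FALSE)
  inst <- select_instrument(cs$eqtl)
  pair <- harmonize(cs$eqtl[match(inst$variant_id, cs$eqtl$SNP), ],
                    cs$gwas[match(inst$variant_id, cs$gwas$SNP), ])
  list(cohort = cs, inst = inst, pair = pair)
}
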