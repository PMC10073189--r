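test_that("class structure is planted: within-class r exceeds between-class r", {
  sim <- simulate_signatures(sig_sim_params(
    n_genes = 978,
    classes = data.frame(label = c("statin", "antidepressant"),
                         n_compounds = c(10L, 10L),
                         strength = c(2, 2), latent = c("LA", "LB")),
    noise_sd = 1, seed = 123))
  v <- sim$signatures$values
  cl <- sim$compounds$class_label[match(sim$signatures$column_meta$compound_id,
                                        sim$compounds$compound_id)]
  cc <- cor(v)
  same <- outer(cl, cl, "==") & upper.tri(cc)
  diff <- outer(cl, cl, "!=") & upper.tri(cc)
  gap <- mean(cc[same]) - mean(cc[diff])
  expect_gt(gap, 0.2)
  # latent strength 2, noise 1: expected within-class r = 4/5
  expect_equal(mean(cc[same]), 0.8, tolerance = 0.05)
  expect_equal(mean(cc[diff]), 0, tolerance = 0.05)
})

test_that("degenerate strengths behave: zero gives noise, tiny noise gives r ~ 1", {
  pure_noise <- simulate_signatures(sig_sim_params(
    n_genes = 400,
    classes = data.frame(label = "background", n_compounds = 12L,
                         strength = 0, latent = "L"),
    seed = 5))
  cc <- cor(pure_noise$signatures$values)
  expect_lt(abs(mean(cc[upper.tri(cc)])), 3 / sqrt(400))

  tight <- simulate_signatures(sig_sim_params(
    n_genes = 200,
    classes = data.frame(label = "statin", n_compounds = 2L,
                         strength = 1, latent = "L"),
    noise_sd = 1e-4, seed = 5))
  expect_gt(cor(tight$signatures$values)[1, 2], 0.999)
})

test_that("simulator output passes io invariants and round-trips", {
  sim <- simulate_signatures(sig_sim_params(n_genes = 50, classes =
    data.frame(label = "background", n_compounds = 4L, strength = 1,
               latent = NA), seed = 2))
  expect_silent(validate_signature_matrix(sim$signatures))
  path <- withr::local_tempfile(fileext = ".gct")
  write_gct(sim$signatures, path)
  back <- read_gct(path)
  expect_identical(back$values, sim$signatures$values)
  expect_s3_class(sim$compounds, "compound_table")
})

test_that("fixed seeds give bit-identical simulator output", {
  p <- sig_sim_params(n_genes = 60, seed = 9, classes = data.frame(
    label = "background", n_compounds = 5L, strength = 1, latent = NA))
  expect_identical(simulate_signatures(p), simulate_signatures(p))
  cp <- cohort_sim_params(n_individuals = 500, n_variants = 5,
                          n_ld_ref = 100, seed = 9)
  expect_identical(simulate_cohort(cp), simulate_cohort(cp))
  g1 <- simulate_term_graph(20, 10, 2, seed = 4)
  g2 <- simulate_term_graph(20, 10, 2, seed = 4)
  # the embedded igraph holds environment pointers; compare the data
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$annotations, g2$annotations)
  expect_identical(g1$term_names, g2$term_names)
})

test_that("cohort simulator produces internally consistent summary stats", {
  cs <- simulate_cohort(cohort_sim_params(n_individuals = 2000,
                                          n_variants = 8, n_ld_ref = 200,
                                          seed = 3))
  for (tab in list(cs$eqtl, cs$gwas)) {
    expect_s3_class(tab, "sumstats")
    p_re <- 2 * pnorm(-abs(tab$b / tab$se))
    expect_equal(tab$p, pmax(p_re, 1e-300), tolerance = 1e-10)
    expect_true(all(tab$freq > 0 & tab$freq < 1))
  }
  expect_silent(validate_ld_matrix(cs$ld$ld))
})

test_that("ld_decay_rho = 0 gives near-zero off-diagonal LD", {
  cs <- simulate_cohort(cohort_sim_params(n_individuals = 200,
                                          n_variants = 6, ld_decay_rho = 0,
                                          n_ld_ref = 2000, seed = 8))
  off <- cs$ld$ld[upper.tri(cs$ld$ld)]
  expect_lt(max(abs(off)), 4 / sqrt(2000))
})

test_that("genotypes respect allele frequency and Hardy-Weinberg", {
  cs <- simulate_cohort(cohort_sim_params(n_individuals = 5000,
                                          n_variants = 4, maf = 0.3,
                                          n_ld_ref = 100, seed = 10))
  expect_equal(cs$eqtl$freq, rep(0.3, 4), tolerance = 0.03)
})

test_that("linkage scenario picks a partner variant near the target r2", {
  cs <- simulate_cohort(cohort_sim_params(scenario = "linkage",
                                          n_individuals = 500,
                                          seed = 11))
  expect_false(is.na(cs$truth$linkage_realized_r2))
  expect_equal(cs$truth$linkage_realized_r2, 0.6, tolerance = 0.25)
  expect_false(cs$truth$causal_variant_gwas == cs$truth$causal_variant_eqtl)
  expect_equal(cs$truth$true_b_xy, 0)
  expect_error(simulate_cohort(cohort_sim_params(scenario = "linkage",
                                                 n_variants = 1)),
               "at least 2")
})

test_that("the strongest eQTL in a causal simulation is the planted variant", {
  cs <- simulate_cohort(cohort_sim_params(seed = 14, n_individuals = 5000,
                                          n_ld_ref = 100))
  inst <- select_instrument(cs$eqtl)
  expect_identical(inst$variant_id, cs$truth$causal_variant_eqtl)
  expect_gt(inst$f_stat, 10)
})
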