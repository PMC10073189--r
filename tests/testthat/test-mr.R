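test_that("select_instrument applies the F cutoff and picks the smallest p", {
  # a record with p = 4.1e-7 has z ~ 5.06, F ~ 25.6: a valid instrument
  z <- qnorm(4.1e-7 / 2)
  rec <- ss_rec(SNP = "rs9481408", b = abs(z) * 0.02, se = 0.02, p = 4.1e-7)
  inst <- select_instrument(rec, f_min = 10)
  expect_equal(inst$f_stat, 25.6, tolerance = 0.02)
  expect_identical(inst$variant_id, "rs9481408")

  # all records with |z| < 3.16 have F <= 10: no valid instrument
  weak <- ss_rec(SNP = c("rs1", "rs2"), b = c(0.03, -0.02), se = c(0.01, 0.01),
                 p = NULL)
  weak$b <- c(0.031, -0.030); weak$p <- 2 * pnorm(-abs(weak$b / weak$se))
  expect_error(select_instrument(weak, f_min = 10), "no valid instrument")

  # smallest p wins among eligible records
  two <- ss_rec(SNP = c("rsA", "rsB"), b = c(0.1, 0.1), se = c(0.0155, 0.0175),
                p = c(1e-10, 1e-8))
  expect_identical(select_instrument(two)$variant_id, "rsA")
})

test_that("harmonize aligns alleles, flips signs, and is an involution", {
  eq <- ss_rec(SNP = "rs1", A1 = "A", A2 = "G", freq = 0.3, b = 0.5, se = 0.05)
  gw_same <- ss_rec(SNP = "rs1", A1 = "A", A2 = "G", freq = 0.31, b = 0.1,
                    se = 0.02)
  h <- harmonize(eq, gw_same)
  expect_equal(h$b_zy, 0.1)
  gw_flip <- ss_rec(SNP = "rs1", A1 = "G", A2 = "A", freq = 0.69, b = -0.1,
                    se = 0.02)
  h2 <- harmonize(eq, gw_flip)
  expect_equal(h2$b_zy, 0.1)          # flipped back to the eQTL coding
  expect_equal(h2$eaf_zy, 0.31)
  # flipping the GWAS coding twice is the identity
  gw_twice <- gw_flip
  gw_twice$A1 <- "A"; gw_twice$A2 <- "G"
  gw_twice$b <- -gw_twice$b; gw_twice$freq <- 1 - gw_twice$freq
  expect_equal(harmonize(eq, gw_twice)$b_zy, h$b_zy)

  gw_bad <- ss_rec(SNP = "rs1", A1 = "A", A2 = "C")
  expect_error(harmonize(eq, gw_bad), "allele mismatch")
  gw_other <- ss_rec(SNP = "rs2")
  expect_error(harmonize(eq, gw_other), "variant ids differ")
})

test_that("palindromic variants near 0.5 frequency are flagged", {
  eq <- ss_rec(SNP = "rs1", A1 = "A", A2 = "T", freq = 0.49)
  gw <- ss_rec(SNP = "rs1", A1 = "A", A2 = "T", freq = 0.51)
  expect_warning(harmonize(eq, gw), "palindromic")
  expect_warning(dropped <- harmonize(eq, gw, palindromic_action = "drop"),
                 "palindromic")
  expect_null(dropped)
  # palindromic but far from 0.5: fine
  eq2 <- ss_rec(SNP = "rs1", A1 = "C", A2 = "G", freq = 0.1)
  gw2 <- ss_rec(SNP = "rs1", A1 = "C", A2 = "G", freq = 0.1)
  expect_silent(harmonize(eq2, gw2))
})

test_that("smr_test reproduces the worked ratio example", {
  eq <- ss_rec(SNP = "rs1", b = 0.5, se = 0.05)
  gw <- ss_rec(SNP = "rs1", b = 0.1, se = 0.02)
  res <- smr_test(harmonize(eq, gw))
  expect_equal(res$b_xy, 0.2)
  expect_equal(res$t_smr, 20)
  expect_equal(res$se_xy, 0.2 / sqrt(20), tolerance = 1e-12)
  expect_equal(res$p_smr, pchisq(20, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$ci95, 0.2 + c(-1.96, 1.96) * res$se_xy)

  # b_zy = 0: estimate 0, p = 1
  gw0 <- ss_rec(SNP = "rs1", b = 0, se = 0.02, p = 1)
  res0 <- smr_test(harmonize(eq, gw0))
  expect_equal(res0$b_xy, 0)
  expect_equal(res0$p_smr, 1)
  eq0 <- ss_rec(SNP = "rs1", b = 0, se = 0.02, p = 1)
  expect_error(smr_test(harmonize(eq0, gw)), "undefined")
})

test_that("smr_test is scale-equivariant and chi2(1) matches squared normal", {
  withr::local_seed(19)
  for (rep in 1:20) {
    eq <- ss_rec(SNP = "rs1", b = rnorm(1, 0.4, 0.1), se = runif(1, 0.02, 0.1))
    gw <- ss_rec(SNP = "rs1", b = rnorm(1, 0, 0.05), se = runif(1, 0.01, 0.05))
    base <- smr_test(harmonize(eq, gw))
    cs <- 3.7
    gw2 <- gw; gw2$b <- gw$b * cs; gw2$se <- gw$se * cs
    scaled <- smr_test(harmonize(eq, gw2))
    expect_equal(scaled$b_xy, cs * base$b_xy, tolerance = 1e-12)
    expect_equal(scaled$se_xy, cs * base$se_xy, tolerance = 1e-12)
    expect_equal(scaled$p_smr, base$p_smr, tolerance = 1e-12)
    # p from the 1-df chi-square equals the two-sided normal p of b/se
    p_norm <- 2 * pnorm(-abs(base$b_xy / base$se_xy))
    expect_equal(base$p_smr, p_norm, tolerance = 1e-10)
  }
})

test_that("inhibition framing negates the reported effect only", {
  cs <- sim_mr_once("causal", seed = 42, n_variants = 3, n = 5000,
                    n_ld_ref = 100)
  plain <- smr_test(cs$pair)
  framed_pair <- harmonize(
    cs$cohort$eqtl[match(cs$inst$variant_id, cs$cohort$eqtl$SNP), ],
    cs$cohort$gwas[match(cs$inst$variant_id, cs$cohort$gwas$SNP), ],
    frame_inhibition = TRUE)
  framed <- smr_test(framed_pair)
  expect_equal(framed$b_xy, -plain$b_xy)
  expect_equal(framed$p_smr, plain$p_smr)
  expect_equal(sort(framed$ci95), sort(-plain$ci95))
  # the underlying truth is +0.2, so the framed estimate is near -0.2
  expect_lt(framed$b_xy, 0)
})

test_that("multiple_testing_threshold is alpha over the testing grid", {
  expect_equal(signif(multiple_testing_threshold(3, 29), 2), 0.00057)
  expect_equal(multiple_testing_threshold(1, 1), 0.05)
  expect_equal(multiple_testing_threshold(2, 10), 0.0025)
  expect_error(multiple_testing_threshold(0, 5), "n_genes")
})

test_that("pquadform agrees with Monte Carlo across methods", {
  withr::local_seed(27)
  for (rep in 1:5) {
    lam <- sort(runif(sample(3:8, 1), 0.1, 2), decreasing = TRUE)
    q <- sum(lam) * runif(1, 0.5, 2.5)
    p_im <- pquadform(q, lam, "imhof")
    p_sat <- pquadform(q, lam, "satterthwaite")
    p_mc <- pquadform(q, lam, "mc", nsim = 2e5)
    mc_err <- 4 * sqrt(max(p_mc * (1 - p_mc), 1e-6) / 2e5)
    expect_lt(abs(p_im - p_mc), mc_err + 1e-3)
    expect_lt(abs(p_sat - p_mc), 0.05)  # moment matching is approximate
  }
  expect_equal(pquadform(0, c(1, 1)), 1)
  # single unit weight: plain chi-square tail
  expect_equal(pquadform(3.84, 1), pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("heidi_test: consistent region gives p ~ 1; few SNPs not computed", {
  # construct a region where every SNP implies exactly the same ratio
  m <- 6
  ids <- sprintf("rs%d", 1:m)
  r <- 0.9^abs(outer(1:m, 1:m, "-")); dimnames(r) <- list(ids, ids)
  bzx <- c(0.5, 0.45, 0.4, 0.35, 0.3, 0.25)
  eq <- sumstats(data.frame(SNP = ids, A1 = "A", A2 = "G", freq = 0.3,
                            b = bzx, se = 0.02, p = 2 * pnorm(-bzx / 0.02),
                            N = 3e4))
  gw <- sumstats(data.frame(SNP = ids, A1 = "A", A2 = "G", freq = 0.3,
                            b = 0.2 * bzx, se = 0.01,
                            p = 2 * pnorm(-0.2 * bzx / 0.01), N = 3e4))
  inst <- select_instrument(eq)
  h <- heidi_test(eq, gw, r, inst)
  expect_true(h$computed)
  expect_gt(h$p_heidi, 0.99)
  expect_true(h$passed)
  expect_equal(h$n_snps_used, 6)  # five candidates + the top SNP

  # shrink the r2 window so fewer than min_snps candidates survive
  h2 <- heidi_test(eq, gw, r, inst, r2_window = c(0.35, 0.37))
  expect_false(h2$computed)
  expect_true(is.na(h2$p_heidi))
  expect_true(is.na(h2$passed))
})

test_that("heidi_test enforces allele alignment and candidate rules", {
  cs <- simulate_cohort(cohort_sim_params(seed = 55, n_individuals = 4000,
                                          n_ld_ref = 500))
  inst <- select_instrument(cs$eqtl)
  # unharmonized GWAS: about half the alleles are recoded -> error
  expect_error(heidi_test(cs$eqtl, cs$gwas, cs$ld, inst), "allele-aligned")
  gw <- harmonize_region(cs$eqtl, cs$gwas)
  h <- heidi_test(cs$eqtl, gw, cs$ld, inst)
  expect_true(h$computed)
  expect_lte(h$n_snps_used, 21)
})

test_that("HEIDI separates single-variant from linkage architectures", {
  # small-replicate behavioural check (full calibration in acceptance)
  null_p <- vapply(1:20, function(i) {
    d <- sim_mr_once("causal", seed = 300 + i)
    gw <- harmonize_region(d$cohort$eqtl, d$cohort$gwas)
    heidi_test(d$cohort$eqtl, gw, d$cohort$ld, d$inst)$p_heidi
  }, numeric(1))
  link_p <- vapply(1:20, function(i) {
    d <- sim_mr_once("linkage", seed = 600 + i)
    gw <- harmonize_region(d$cohort$eqtl, d$cohort$gwas)
    heidi_test(d$cohort$eqtl, gw, d$cohort$ld, d$inst)$p_heidi
  }, numeric(1))
  expect_gt(mean(null_p > 0.01, na.rm = TRUE), 0.8)
  expect_lt(median(link_p, na.rm = TRUE), median(null_p, na.rm = TRUE))
})
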