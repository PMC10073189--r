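test_that("weighted KS enrichment reproduces the hand-enumerated example", {
  ref <- rank_reference(as_sig(c(3, 2, 1, 0.5)))
  # set at ranks 1 and 3: running deviations 0.75, 0.25, 0.50, 0.00
  expect_equal(weighted_ks_enrichment(ref, c("g1", "g3")), 0.75)
  # set occupying the top ranks gives ES = 1, the bottom ranks ES = -1
  expect_equal(weighted_ks_enrichment(ref, c("g1", "g2")), 1)
  expect_equal(weighted_ks_enrichment(ref, c("g3", "g4")), -1)
  expect_error(weighted_ks_enrichment(ref, character(0)), "empty")
  expect_error(weighted_ks_enrichment(ref, paste0("g", 1:4)), "proper subset")
  expect_error(weighted_ks_enrichment(ref, "nope"), "absent")
})

test_that("ES matches the brute-force running-sum oracle on random instances", {
  withr::local_seed(101)
  for (rep in 1:300) {
    N <- sample(4:12, 1)
    z <- round(rnorm(N), 3)
    ref <- rank_reference(as_sig(z, ids = sprintf("r%02d", 1:N)))
    n_set <- sample(seq_len(N - 1), 1)
    set <- sample(ref$gene_ids, n_set)
    w <- sample(c(0, 1, 2), 1)
    expect_equal(weighted_ks_enrichment(ref, set, w),
                 brute_force_es(ref$z, ref$gene_ids %in% set, w),
                 tolerance = 1e-13)
  }
})

test_that("ES and WTCS are bounded in [-1, 1] on random inputs", {
  withr::local_seed(202)
  for (rep in 1:200) {
    N <- sample(10:40, 1)
    ref <- rank_reference(as_sig(rnorm(N), ids = sprintf("r%02d", 1:N)))
    set <- sample(ref$gene_ids, sample(2:(N - 2), 1))
    es <- weighted_ks_enrichment(ref, set)
    expect_gte(es, -1); expect_lte(es, 1)
  }
  for (rep in 1:100) {
    z <- rnorm(40)
    ref <- rank_reference(as_sig(z, ids = sprintf("r%02d", 1:40)))
    q <- build_query(as_sig(rnorm(40), ids = sprintf("r%02d", 1:40)), k = 5)
    s <- wtcs(q, ref)
    expect_gte(s, -1); expect_lte(s, 1)
  }
})

test_that("wtcs applies the opposite-sign rule and self-connectivity is 1", {
  # query from a reference's own extremes: ES_up = 1, ES_down = -1, wtcs = 1
  withr::local_seed(5)
  z <- rnorm(60)
  sig <- as_sig(z, ids = sprintf("r%02d", 1:60))
  q <- build_query(sig, k = 10)
  expect_equal(wtcs(q, rank_reference(sig)), 1)
  # inverted reference: perfect anti-connectivity
  expect_equal(wtcs(q, rank_reference(as_sig(-z, ids = sig$gene_ids))), -1)
  # same-sign enrichment scores give 0: query up and down both drawn from
  # the top of the reference's ranking
  ranked <- rank_reference(sig)
  qq <- structure(list(up = ranked$gene_ids[1:5],
                       down = ranked$gene_ids[6:10],
                       k = 5, query_id = "q"), class = "query_signature")
  expect_equal(wtcs(qq, ranked), 0)
})

test_that("query genes absent from the reference are dropped with a warning", {
  ref <- rank_reference(as_sig(rnorm(20), ids = sprintf("r%02d", 1:20)))
  q <- structure(list(up = c("r01", "r02", "r03", "missing1"),
                      down = c("r18", "r19", "r20", "missing2"),
                      k = 4, query_id = "q"), class = "query_signature")
  expect_warning(s <- wtcs(q, ref), "absent")
  expect_gte(s, -1); expect_lte(s, 1)
  # losing more than half a side is an error
  q2 <- structure(list(up = c("r01", "m1", "m2", "m3"),
                       down = c("r19", "r20", "m4", "m5"),
                       k = 4, query_id = "q"), class = "query_signature")
  expect_error(suppressWarnings(wtcs(q2, ref)), "half")
})

test_that("normalize_scores divides by the same-sign group mean", {
  W <- matrix(c(0.2, 0.4), 1, 2, dimnames = list("q", c("r1", "r2")))
  ncs <- normalize_scores(W, groups = c("g", "g"))
  expect_equal(unname(ncs[1, ]), c(0.2 / 0.3, 0.4 / 0.3), tolerance = 1e-12)
  # equal positive scores normalize to 1; zero stays zero; sign preserved
  W2 <- matrix(c(0.3, 0.3, 0, -0.1), 1, 4,
               dimnames = list("q", paste0("r", 1:4)))
  ncs2 <- normalize_scores(W2, rep("g", 4))
  expect_equal(unname(ncs2[1, ]), c(1, 1, 0, -1))
  expect_error(normalize_scores(W, groups = "g"), "group")
})

test_that("tau percentile counts strictly smaller touchstone magnitudes", {
  ts <- seq(0.1, 1.0, by = 0.1)
  expect_equal(tau_percentile(0.55, ts), 50)
  expect_equal(tau_percentile(-0.55, ts), -50)
  expect_equal(tau_percentile(2, ts), 100)
  expect_equal(tau_percentile(0, ts), 0)
  expect_equal(tau_percentile(0.05, ts), 0)
  # antisymmetry with fixed touchstone magnitudes
  withr::local_seed(33)
  for (v in rnorm(20)) {
    expect_equal(tau_percentile(-v, ts), -tau_percentile(v, ts))
  }
  expect_error(tau_percentile(0.5, numeric(0)), "empty")
})

test_that("cross-cell summarization picks the maximal-magnitude tercile", {
  expect_equal(summarize_across_cells(c(-95, 0, 20)), -95)
  expect_equal(summarize_across_cells(rep(42, 9)), 42)
  expect_equal(summarize_across_cells(7), 7)
  # tie in magnitude favours the upper quantile
  expect_equal(summarize_across_cells(c(-50, 0, 50)), 50)
})

test_that("average_connectivity is the column mean and rejects missing refs", {
  withr::local_seed(8)
  taus <- matrix(runif(6 * 100, -100, 100), 6, 100,
                 dimnames = list(paste0("q", 1:6), paste0("r", 1:100)))
  expect_equal(average_connectivity(taus), colMeans(taus))
  expect_equal(unname(average_connectivity(
    matrix(c(99, 81), 2, 1, dimnames = list(NULL, "r")))), 90)
  taus[2, 5] <- NA
  expect_error(average_connectivity(taus), "r5")
})

test_that("dedupe_references keeps the touchstone-flagged duplicate", {
  m <- random_signature_matrix(n_genes = 10, n_cols = 3)
  m$column_meta$compound <- c("drugA", "drugA", "drugB")
  m$column_meta$compound_id <- c("c01", "c02", "c03")
  cpds <- compound_table(data.frame(
    compound_id = c("c01", "c02", "c03"),
    name = c("drugA", "drugA2", "drugB"),
    in_touchstone = c(FALSE, TRUE, TRUE)))
  out <- dedupe_references(m, cpds)
  expect_setequal(out$column_meta$compound_id, c("c02", "c03"))
})

test_that("planted shared-class compounds score highest in self-queries", {
  # two compounds sharing a latent connect strongly; an unrelated one does not
  sim <- simulate_signatures(sig_sim_params(
    n_genes = 300, classes = data.frame(
      label = c("statin", "antidepressant", "background"),
      n_compounds = c(2L, 2L, 10L), strength = c(3, 3, 3),
      latent = c("L1", "L1", NA)), seed = 77))
  sig <- sim$signatures
  q <- build_query(get_signature(sig, colnames(sig$values)[1]), k = 25)
  ranked <- lapply(colnames(sig$values),
                   function(id) rank_reference(get_signature(sig, id)))
  scores <- vapply(ranked, function(r) wtcs(q, r), numeric(1))
  names(scores) <- colnames(sig$values)
  shared <- sim$compounds$compound_id[sim$compounds$class_label %in%
                                        c("statin", "antidepressant")]
  shared_cols <- rownames(sig$column_meta)[sig$column_meta$compound_id %in% shared]
  expect_true(min(scores[shared_cols]) > max(scores[setdiff(names(scores),
                                                            shared_cols)]))
})
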