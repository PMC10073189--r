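#' Default pipeline configuration
#'
#' Returns the primary-analysis settings: queries from the top 50 up-
#' and down-regulated landmark genes (sensitivity alternates 100/150),
#' perturbed genes at |z| > 1 (alternates 1.5/2), a Tau cutoff of 90,
#' chi-square class enrichment at alpha 0.05, and SMR settings
#' (F > 10, HEIDI pass at p > 0.01, Bonferroni threshold over the
#' gene x trait grid).  Every sensitivity alternate is reachable by
#' overriding a single field.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # transcriptomic arm
    query_class = "statin", target_class = "antidepressant",
    k_query = 50L, min_mean_r = 0.2, tau_cutoff = 90,
    z_threshold = 1, weight_exponent = 1,
    enrichment_alpha = 0.05, chisq_correction = "none",
    term_method = "bonferroni", term_alpha = 0.05,
    top_n_refs = 5L, ancestor_level = 1L,
    # MR arm
    f_min = 10, mr_alpha = 0.05, n_genes_tested = 3L, n_traits_tested = 29L,
    frame_inhibition = TRUE, heidi_r2_window = c(0.05, 0.9),
    heidi_max_snps = 20L, heidi_min_snps = 3L, heidi_eqtl_chisq_min = 10
  )
  structure(modifyList(cfg, list(...)), class = "run_config")
}

.write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the transcriptomic (connectivity) arm end to end
#'
#' Chains: concordance filter of the query class -> query construction
#' -> connectivity scoring (WTCS/NCS/Tau, cross-cell summary, average
#' over queries) -> Tau-threshold classification with the query class
#' excluded -> chi-square class enrichment -> directional concordance of
#' the query class with the top target-class compounds -> hypergeometric
#' term enrichment (union-of-evidence over pairs).
#'
#' @param sig A [signature_matrix()] (or a GCT path).
#' @param compounds A [compound_table()] (or a TSV path).
#' @param graph A [term_graph()], or `NULL` to skip term enrichment.
#' @param config A [run_config()].
#' @param out_dir Optional directory for stage TSVs and the JSON
#'   summary; existing files are only overwritten with `force = TRUE`.
#' @param force Overwrite existing outputs.
#' @return List with `stages` (per-stage results) and `summary`
#'   (JSON-ready counts, statistics and config echo).
#' @export
run_transcriptomic_arm <- function(sig, compounds, graph = NULL,
                                   config = run_config(), out_dir = NULL,
                                   force = FALSE) {
  if (is.character(sig)) sig <- read_gct(sig)
  if (is.character(compounds)) compounds <- read_compound_table(compounds)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    existing <- list.files(out_dir, pattern = "^transcriptomic_")
    if (length(existing) && !force)
      stop("outputs exist in ", out_dir, "; use force = TRUE to overwrite")
  }
  cm_all <- sig$column_meta
  sig <- dedupe_references(sig, compounds)
  cm <- sig$column_meta
  cls <- setNames(compounds$class_label, compounds$name)

  # 1. concordance filter of the query-class signatures (first cell line)
  qcell <- cm$cell_line[1]
  q_cols <- colnames(sig$values)[cm$cell_line == qcell &
                                 cls[cm$compound] == config$query_class]
  if (length(q_cols) < 3)
    stop("stage filter: need >= 3 query-class signatures in cell line ", qcell)
  q_sigs <- lapply(q_cols, function(id) get_signature(sig, id))
  filt <- concordance_filter(q_sigs, min_mean_r = config$min_mean_r)

  # 2. query construction
  kept_sigs <- q_sigs[match(filt$kept, vapply(q_sigs, `[[`, "", "id"))]
  queries <- lapply(kept_sigs, build_query, k = config$k_query)

  # 3. connectivity scoring
  conn <- connectivity_scores(sig, queries, compounds,
                              weight_exponent = config$weight_exponent)
  avg_tau <- conn$avg_tau

  # 4. class enrichment among high-connectivity references
  query_members <- compounds$name[compounds$class_label == config$query_class]
  target_members <- compounds$name[compounds$class_label == config$target_class]
  parts <- threshold_classify(avg_tau, cutoff = config$tau_cutoff,
                              exclude = query_members)
  universe <- c(parts$high, parts$low)
  tab <- enrichment_table(parts$high, universe, target_members)
  enr <- class_enrichment_test(tab, correction = config$chisq_correction)

  # 5. directional concordance with the top target-class compounds
  tgt_tau <- sort(avg_tau[intersect(names(avg_tau), target_members)],
                  decreasing = TRUE)
  top_refs <- names(head(tgt_tau, config$top_n_refs))
  pair_tables <- list()
  same_union <- character(0); opp_union <- character(0)
  for (qs in kept_sigs) for (tn in top_refs) {
    t_col <- colnames(sig$values)[cm$compound == tn & cm$cell_line == qcell][1]
    if (is.na(t_col)) next
    ts <- get_signature(sig, t_col)
    sp <- shared_perturbation(qs, ts, threshold = config$z_threshold)
    pair_tables[[paste(qs$id, t_col, sep = "|")]] <- sp
    same_union <- union(same_union, sp$same_direction)
    opp_union <- union(opp_union, sp$opposite_direction)
  }

  # 6. term enrichment, union-of-evidence over pairs
  term_res <- NULL
  if (!is.null(graph)) {
    background <- rownames(sig$values)
    enrich_dir <- function(genes_by_pair) {
      hits <- lapply(genes_by_pair, function(gs) {
        if (length(gs) == 0) return(NULL)
        res <- hypergeom_enrichment(gs, background, graph,
                                    method = config$term_method,
                                    alpha = config$term_alpha)
        res[res$significant, , drop = FALSE]
      })
      do.call(rbind, hits)
    }
    same_by_pair <- lapply(pair_tables, `[[`, "same_direction")
    opp_by_pair <- lapply(pair_tables, `[[`, "opposite_direction")
    sig_same <- enrich_dir(same_by_pair)
    sig_opp <- enrich_dir(opp_by_pair)
    term_res <- list(
      same = unique(sig_same$term_id),
      opposite = unique(sig_opp$term_id)
    )
    term_res$rollup_same <- if (length(term_res$same))
      rollup_ancestors(term_res$same, graph, config$ancestor_level) else NULL
  }

  stages <- list(filter = filt, query = queries, connectivity = conn,
                 class_enrichment = list(table = tab, test = enr),
                 concordance = pair_tables, term_enrichment = term_res)
  summary <- list(
    stages = list(
      filter = list(kept = filt$kept, dropped = filt$dropped),
      query = list(k = config$k_query, n_queries = length(queries)),
      connectivity = list(
        n_references = length(avg_tau),
        n_high = length(parts$high),
        median_query_pairwise_tau = {
          q_ids <- vapply(kept_sigs, `[[`, "", "id")
          q_comp <- unique(cm$compound[match(q_ids, colnames(sig$values))])
          unname(median(conn$summary_tau[, q_comp]))
        }
      ),
      class_enrichment = list(table = tab, chi2 = enr$chi2, p = enr$p,
                              odds_ratio = enr$odds_ratio),
      concordance = list(n_pairs = length(pair_tables),
                         n_same_union = length(same_union),
                         n_opposite_union = length(opp_union)),
      term_enrichment = if (is.null(term_res)) list(skipped = TRUE) else
        list(n_same_terms = length(term_res$same),
             n_opposite_terms = length(term_res$opposite))
    ),
    config = unclass(config),
    seed = config$seed
  )
  if (!is.null(out_dir)) {
    .write_tsv(conn$long, out_dir, "transcriptomic_connectivity_long.tsv")
    .write_tsv(data.frame(compound = names(avg_tau), avg_tau = avg_tau),
               out_dir, "transcriptomic_avg_tau.tsv")
    .write_tsv(filt$report, out_dir, "transcriptomic_filter.tsv")
    jsonlite::write_json(summary,
                         file.path(out_dir, "transcriptomic_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(stages = stages, summary = summary)
}

#' Run the Mendelian-randomization arm
#'
#' For each (gene, trait) dataset: select the strongest eQTL instrument
#' passing the F cutoff, harmonize it with the GWAS record, run the SMR
#' test, the HEIDI heterogeneity test on the surrounding region, and
#' flag significance at the Bonferroni threshold for the gene x trait
#' grid.
#'
#' @param datasets Named list; each element a list with `eqtl`, `gwas`
#'   (`sumstats`) and `ld` (matrix or list with `$ld`), e.g. the output
#'   of [simulate_cohort()].
#' @param config A [run_config()].
#' @param out_dir Optional output directory (TSV + JSON summary).
#' @param force Overwrite existing outputs.
#' @return List with `results` (one row per dataset) and `summary`.
#' @export
run_mr_arm <- function(datasets, config = run_config(), out_dir = NULL,
                       force = FALSE) {
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    existing <- list.files(out_dir, pattern = "^mr_")
    if (length(existing) && !force)
      stop("outputs exist in ", out_dir, "; use force = TRUE to overwrite")
  }
  thr <- multiple_testing_threshold(config$n_genes_tested,
                                    config$n_traits_tested, config$mr_alpha)
  rows <- lapply(names(datasets), function(nm) {
    ds <- datasets[[nm]]
    inst <- select_instrument(ds$eqtl, f_min = config$f_min)
    i_eq <- match(inst$variant_id, ds$eqtl$SNP)
    i_gw <- match(inst$variant_id, ds$gwas$SNP)
    if (is.na(i_gw)) stop("instrument ", inst$variant_id,
                          " absent from GWAS for dataset ", nm)
    pair <- harmonize(ds$eqtl[i_eq, ], ds$gwas[i_gw, ],
                      frame_inhibition = config$frame_inhibition)
    smr <- smr_test(pair)
    gwas_h <- harmonize_region(ds$eqtl, ds$gwas)
    heidi <- heidi_test(ds$eqtl, gwas_h, ds$ld, inst,
                        r2_window = config$heidi_r2_window,
                        max_snps = config$heidi_max_snps,
                        min_snps = config$heidi_min_snps,
                        eqtl_chisq_min = config$heidi_eqtl_chisq_min)
    data.frame(
      dataset = nm, instrument = inst$variant_id, f_stat = inst$f_stat,
      b_xy = smr$b_xy, se_xy = smr$se_xy,
      ci_lo = smr$ci95[1], ci_hi = smr$ci95[2],
      p_smr = smr$p_smr, p_heidi = heidi$p_heidi,
      n_snps_heidi = heidi$n_snps_used, heidi_passed = heidi$passed,
      significant_at_corrected = smr$p_smr < thr,
      row.names = NULL)
  })
  results <- do.call(rbind, rows)
  summary <- list(
    threshold = thr,
    n_datasets = nrow(results),
    n_significant = sum(results$significant_at_corrected),
    config = unclass(config), seed = config$seed
  )
  if (!is.null(out_dir)) {
    .write_tsv(results, out_dir, "mr_results.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "mr_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, summary = summary)
}

#' Run the full synthetic analysis end to end
#'
#' Simulates a signature collection, a term graph and three genotype
#' cohorts (causal, null, linkage), then runs both analysis arms.  All
#' randomness flows from `config$seed` through named per-stage
#' sub-seeds, so a fixed seed gives byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param force Overwrite existing outputs.
#' @return List with `transcriptomic`, `mr` and the simulated `inputs`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL, force = FALSE) {
  seed <- config$seed
  sim <- simulate_signatures(sig_sim_params(seed = stage_seed(seed, "signatures")))
  graph <- simulate_term_graph(n_terms = 60,
                               n_genes = rownames(sim$signatures$values),
                               depth = 3,
                               seed = stage_seed(seed, "terms"))
  cohorts <- list(
    GENE1_causal = simulate_cohort(cohort_sim_params(
      scenario = "causal", seed = stage_seed(seed, "cohort_causal"))),
    GENE2_null = simulate_cohort(cohort_sim_params(
      scenario = "null", seed = stage_seed(seed, "cohort_null"))),
    GENE3_linkage = simulate_cohort(cohort_sim_params(
      scenario = "linkage", seed = stage_seed(seed, "cohort_linkage")))
  )
  tx <- run_transcriptomic_arm(sim$signatures, sim$compounds, graph,
                               config = config, out_dir = out_dir,
                               force = force)
  mr <- run_mr_arm(cohorts, config = config, out_dir = out_dir, force = force)
  list(transcriptomic = tx, mr = mr,
       inputs = list(signatures = sim, term_graph = graph, cohorts = cohorts))
}
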