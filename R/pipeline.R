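#' Percentage and odds-ratio arithmetic for headline summaries
#'
#' `headline_pct()` computes 100 * numerator / denominator rounded half-up
#' at the requested precision (so printed percentages are reproducible
#' deterministically); `odds_ratio_from_props()` converts two proportions
#' into an odds ratio. A zero denominator yields NaN.
#'
#' @param numerator,denominator counts.
#' @param digits decimal digits for the printed percentage.
#' @return Numeric scalar.
#' @export
headline_pct <- function(numerator, denominator, digits = 0) {
  if (denominator == 0) return(NaN)
  round_half_up(100 * numerator / denominator, digits)
}

#' @rdname headline_pct
#' @param p1,p2 proportions in (0, 1).
#' @export
odds_ratio_from_props <- function(p1, p2) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1)) return(NaN)
  (p1 / (1 - p1)) / (p2 / (1 - p2))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration: generate the toy genome, guide library and
#' cohort; align guides and filter multi-targeting ones; gate genes on
#' guide count and aggregate guide LFCs into gene scores; fit the score
#' mixture, derive the binarization threshold (unless overridden) and
#' classify genes into never / sometimes / broadly essential; annotate
#' paralog pairs (identity filter, WGD/SSD, complexes); call putative
#' synthetic lethal pairs in the requested modes with copy-number and
#' nonsense follow-ups; and assemble the headline report.
#'
#' @param config a [cohort_config()].
#' @param tau_override optional fixed binarization threshold (e.g. for
#'   sensitivity reruns at -0.4 / -0.6); default derives the threshold
#'   from the fitted mixture.
#' @param fdr_level FDR level for SL calling (default 0.10).
#' @param sl_modes SL pair-selection modes to run (subset of
#'   c("closest", "all")).
#' @param skip_alignment if `TRUE`, guide alignment and multi-target
#'   filtering are skipped and all guides are taken at face value (useful
#'   for large simulation studies where the genome stage is not under
#'   test).
#' @param n_restarts EM restarts per component count.
#' @param output_dir optional directory; when given, all stage artifacts
#'   are written there (cohort tables, guide map, score and binary
#'   matrices, SL tables, report JSON).
#' @return List of class `paralethal_run` with all stage artifacts and a
#'   `report` element (see [headline_report()]).
#' @export
run_pipeline <- function(config = cohort_config(), tau_override = NULL,
                         fdr_level = 0.10, sl_modes = c("closest", "all"),
                         skip_alignment = FALSE, n_restarts = 10,
                         output_dir = NULL) {
  sl_modes <- match.arg(sl_modes, c("closest", "all"), several.ok = TRUE)
  if (skip_alignment) {
    genome <- NULL
    guides <- NULL
    cohort <- generate_cohort(config)
    map <- data.frame(sgRNA = cohort$guides$guide_id,
                      gene = cohort$guides$intended_gene,
                      retained = TRUE, reason = "retained",
                      stringsAsFactors = FALSE)
    hits <- NULL
  } else {
    genome <- generate_toy_genome(config)
    guides <- generate_guide_library(genome, config$guides_per_gene,
                                     seed = config$seed + 1L)
    cohort <- generate_cohort(config, genome, guides)
    hits <- align_guides(guides, genome)
    map <- build_guide_gene_map(guides, hits, genome$genes)
  }
  gate <- gate_genes_by_guide_count(map,
                                    gene_universe = cohort$genes,
                                    min_guides = 3)
  scores <- score_genes(cohort$lfc, map, gate$retained$gene)

  gt <- cohort$ground_truth
  ess_ref <- names(gt$category)[gt$category == "broadly"]
  non_ref <- names(gt$category)[gt$category == "never"]
  qc <- tryCatch(precision_recall_qc(scores, ess_ref, non_ref),
                 error = function(e) list(per_line = NULL, mean_auc = NA_real_))

  fit <- fit_score_mixture(as.vector(scores), seed = config$seed,
                           n_restarts = n_restarts)
  tau <- if (!is.null(tau_override)) tau_override else
    essentiality_threshold(fit)
  bin <- binarize_scores(scores, tau)
  summ <- summarize_essentiality(bin)

  pairs <- filter_paralog_pairs(cohort$pairs, coding_genes = cohort$genes)
  dup <- classify_duplication(pairs, cohort$wgd_list_a, cohort$wgd_list_b)
  pairs <- annotate_complexes(dup$pairs, cohort$complexes)
  paralogy <- summarize_paralogy(pairs, cohort$genes)

  expressed <- rownames(cohort$expression)
  sl <- list()
  for (mode in sl_modes) {
    testable <- select_testable_pairs(summ$genes, pairs, expressed, mode)
    if (nrow(testable) == 0) { sl[[mode]] <- NULL; next }
    tested <- sl_test_pairs(testable, bin, cohort$expression)
    called <- call_sl(tested, fdr_level)
    called <- cn_followup(called, cohort$copy_number, bin)
    called <- nonsense_followup(called, cohort$mutations, bin)
    sl[[mode]] <- list(table = called,
                       summary = attr(called, "summary") %||%
                         attr(call_sl(tested, fdr_level), "summary"),
                       enrichment = sl_enrichment(called))
  }

  report <- headline_report(summ, paralogy, dup, sl, fit, tau, qc,
                            gene_universe = cohort$genes)
  run <- structure(list(config = config, genome = genome, cohort = cohort,
                        guide_map = map, gate = gate, scores = scores,
                        qc = qc, fit = fit, threshold = tau, bin = bin,
                        essentiality = summ, pairs = pairs,
                        paralogy = paralogy, sl = sl, report = report),
                   class = "paralethal_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' Assemble the headline report
#'
#' Aggregates the category counts and percentages, the paralog/singleton
#' split per category with Fisher odds ratios, the paralog-count by
#' category chi-squared, closest-paralog identity comparisons
#' (Mann-Whitney), the WGD/SSD/singleton category table, the multi-feature
#' multinomial-logit likelihood-ratio comparison, and per-mode SL counts
#' and enrichments. Percentages are always recomputed from the stored
#' counts.
#'
#' @param summ [summarize_essentiality()] result.
#' @param paralogy [summarize_paralogy()] result.
#' @param dup [classify_duplication()] result.
#' @param sl named list of SL results per mode.
#' @param fit,tau,qc mixture fit, threshold, and PR-QC results.
#' @param gene_universe all scored-universe genes.
#' @return List of report sections.
#' @export
headline_report <- function(summ, paralogy, dup, sl, fit, tau, qc,
                            gene_universe) {
  g <- merge(summ$genes, paralogy, by = "gene")
  g$is_paralog <- !g$is_singleton
  n <- nrow(g)
  cat_counts <- table(factor(g$category,
                             levels = c("never", "sometimes", "broadly")))
  categories <- data.frame(
    category = names(cat_counts),
    n = as.integer(cat_counts),
    pct = vapply(as.integer(cat_counts), headline_pct, numeric(1),
                 denominator = n, digits = 1))

  or_never <- fisher_exact_or(
    sum(g$is_paralog & g$category == "never"),
    sum(g$is_paralog & g$category != "never"),
    sum(!g$is_paralog & g$category == "never"),
    sum(!g$is_paralog & g$category != "never"))
  or_broadly_singleton <- fisher_exact_or(
    sum(!g$is_paralog & g$category == "broadly"),
    sum(!g$is_paralog & g$category != "broadly"),
    sum(g$is_paralog & g$category == "broadly"),
    sum(g$is_paralog & g$category != "broadly"))

  cnt_tab <- table(g$n_paralogs_bin[g$is_paralog], g$category[g$is_paralog])
  chisq_paralog_count <- tryCatch(chi_squared_test(cnt_tab),
                                  error = function(e) NULL)

  par <- g[g$is_paralog & !is.na(g$max_identity), ]
  mw_broadly <- if (sum(par$category == "broadly") >= 1 &&
                    sum(par$category != "broadly") >= 1)
    mann_whitney_u(par$max_identity[par$category == "broadly"],
                   par$max_identity[par$category != "broadly"]) else NULL

  g$duplication_mode <- dup$genes$duplication_mode[match(g$gene,
                                                         dup$genes$gene)]
  g$duplication_mode[is.na(g$duplication_mode)] <- "singleton"
  wgd_tab <- table(g$duplication_mode, g$category)

  lrt <- NULL
  pg <- par
  pg$duplication_mode <- g$duplication_mode[match(pg$gene, g$gene)]
  if (nrow(pg) > 30 && length(unique(pg$category)) == 3) {
    pg$wgd <- as.integer(pg$duplication_mode == "WGD")
    full <- c("n_paralogs", "max_identity", "wgd")
    lrt <- lapply(setNames(full, full), function(f)
      tryCatch(multinomial_logit_lrt(pg, "category", full, f),
               error = function(e) NULL))
  }

  sl_summary <- lapply(sl, function(m) {
    s <- m$summary
    s$pct_A1_flagged <- headline_pct(s$n_unique_A1_flagged,
                                     s$n_unique_A1_tested, 1)
    s$n_cn_driven <- sum(m$table$cn_driven, na.rm = TRUE)
    s$n_nonsense_driven <- sum(m$table$nonsense_driven, na.rm = TRUE)
    s$n_cn_or_nonsense <- sum(m$table$cn_driven | m$table$nonsense_driven,
                              na.rm = TRUE)
    s
  })

  list(n_genes = n,
       categories = categories,
       paralog_split = local({
         tab <- table(factor(g$category,
                             levels = c("never", "sometimes", "broadly")),
                      factor(g$is_paralog, levels = c(FALSE, TRUE)))
         data.frame(category = rownames(tab),
                    n_paralog = as.integer(tab[, "TRUE"]),
                    n_singleton = as.integer(tab[, "FALSE"]))
       }),
       pct_paralog = headline_pct(sum(g$is_paralog), n, 1),
       or_never_paralog = or_never,
       or_broadly_singleton = or_broadly_singleton,
       paralog_count_by_category = list(table = cnt_tab,
                                        chisq = chisq_paralog_count),
       identity_broadly_vs_rest = mw_broadly,
       wgd_category_table = wgd_tab,
       logit_lrt = lrt,
       sl = sl_summary,
       sl_enrichment = lapply(sl, `[[`, "enrichment"),
       threshold = as.numeric(tau),
       mixture = list(k = fit$k, weights = fit$weights, means = fit$means,
                      sds = fit$sds, aic = fit$aic),
       mean_pr_auc = qc$mean_auc)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(run$cohort, file.path(dir, "cohort"))
  if (!is.null(run$genome)) write_toy_genome(run$genome, file.path(dir, "cohort"))
  write.csv(run$guide_map, file.path(dir, "guide_gene_map.csv"),
            row.names = FALSE)
  write_matrix_csv(run$scores, file.path(dir, "gene_scores.csv"))
  write_matrix_csv(run$bin, file.path(dir, "binary_essentiality.csv"))
  write.csv(run$essentiality$genes, file.path(dir, "gene_summaries.csv"),
            row.names = FALSE)
  for (mode in names(run$sl))
    write.csv(run$sl[[mode]]$table,
              file.path(dir, sprintf("sl_pairs_%s.csv", mode)),
              row.names = FALSE)
  report <- run$report
  report$wgd_category_table <- as.data.frame.matrix(report$wgd_category_table)
  report$paralog_count_by_category$table <-
    as.data.frame.matrix(report$paralog_count_by_category$table)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Run the downstream pipeline on user-supplied tables
#'
#' For cohorts where gene-level fitness scores were produced elsewhere
#' (e.g. copy-number-corrected scores): skips genome/guide processing and
#' runs mixture binarization, paralog annotation and SL calling on the
#' supplied matrices.
#'
#' @param scores gene-by-line fitness score matrix (more negative = larger
#'   fitness defect).
#' @param expression,cn gene-by-line matrices; `cn` may be NULL.
#' @param mutations long mutation table or NULL.
#' @param pairs raw directional paralog-pair table.
#' @param wgd_list_a,wgd_list_b WGD pair lists (may be empty data.frames).
#' @param complexes complex membership table (complex_id, gene).
#' @param coding_genes protein-coding universe (default: scored genes).
#' @param tau_override,fdr_level,sl_modes,n_restarts,seed as in
#'   [run_pipeline()].
#' @return List with the same downstream components as [run_pipeline()].
#' @export
run_pipeline_tables <- function(scores, expression, cn = NULL,
                                mutations = NULL, pairs,
                                wgd_list_a, wgd_list_b, complexes,
                                coding_genes = rownames(scores),
                                tau_override = NULL, fdr_level = 0.10,
                                sl_modes = c("closest", "all"),
                                n_restarts = 10, seed = 1L) {
  sl_modes <- match.arg(sl_modes, c("closest", "all"), several.ok = TRUE)
  fit <- fit_score_mixture(as.vector(scores), seed = seed,
                           n_restarts = n_restarts)
  tau <- if (!is.null(tau_override)) tau_override else
    essentiality_threshold(fit)
  bin <- binarize_scores(scores, tau)
  summ <- summarize_essentiality(bin)
  pairs <- filter_paralog_pairs(pairs, coding_genes = coding_genes)
  dup <- classify_duplication(pairs, wgd_list_a, wgd_list_b)
  pairs <- annotate_complexes(dup$pairs, complexes)
  paralogy <- summarize_paralogy(pairs, coding_genes)
  sl <- list()
  for (mode in sl_modes) {
    testable <- select_testable_pairs(summ$genes, pairs, rownames(expression),
                                      mode)
    if (nrow(testable) == 0) next
    tested <- sl_test_pairs(testable, bin, expression)
    called <- call_sl(tested, fdr_level)
    if (!is.null(cn)) called <- cn_followup(called, cn, bin)
    if (!is.null(mutations)) called <- nonsense_followup(called, mutations, bin)
    sl[[mode]] <- list(table = called, summary = attr(called, "summary"),
                       enrichment = sl_enrichment(called))
  }
  qc <- list(mean_auc = NA_real_)
  report <- headline_report(summ, paralogy, dup, sl, fit, tau, qc,
                            gene_universe = coding_genes)
  list(fit = fit, threshold = tau, bin = bin, essentiality = summ,
       pairs = pairs, paralogy = paralogy, sl = sl, report = report)
}
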