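#' Select testable (A1, A2) paralog pairs
#'
#' A focal gene A1 qualifies iff it is sometimes (but not broadly)
#' essential and essential in at least `min_fraction` (default 1%) of its
#' scored cell lines. In mode "closest" each qualifying A1 contributes its
#' most sequence-similar paralog among the partners with expression data;
#' in mode "all" it contributes every partner with expression data. A1
#' genes with no expressed partner are excluded and counted.
#'
#' @param gene_summary per-gene essentiality summary (data.frame from
#'   [summarize_essentiality()]`$genes`).
#' @param pairs annotated directional pair table.
#' @param expressed_genes genes with expression data.
#' @param mode "closest" or "all".
#' @param min_fraction inclusive essentiality floor (default 0.01).
#' @return data.frame of testable pairs (A1, A2, pair annotations,
#'   is_closest_pair); excluded-A1 count in `attr(, "n_excluded_no_expr")`.
#' @export
select_testable_pairs <- function(gene_summary, pairs, expressed_genes,
                                  mode = c("closest", "all"),
                                  min_fraction = 0.01) {
  mode <- match.arg(mode)
  a1_ok <- gene_summary$gene[gene_summary$category == "sometimes" &
                               gene_summary$fraction_essential >= min_fraction]
  p <- pairs[pairs$A1 %in% a1_ok & pairs$A2 %in% expressed_genes, ,
             drop = FALSE]
  n_excluded <- length(setdiff(intersect(a1_ok, pairs$A1), p$A1))
  if (nrow(p) > 0) {
    # closest expressed partner per A1: max identity, ties alphabetical
    p <- p[order(p$A1, -p$identity_A1_in_A2, p$A2), , drop = FALSE]
    p$is_closest_pair <- !duplicated(p$A1)
    if (mode == "closest") p <- p[p$is_closest_pair, , drop = FALSE]
  } else {
    p$is_closest_pair <- logical(0)
  }
  rownames(p) <- NULL
  attr(p, "n_excluded_no_expr") <- n_excluded
  attr(p, "mode") <- mode
  p
}

#' Expression-stratified differential test for one pair
#'
#' Two-sample t-test of A2 expression between the cell lines where A1 is
#' essential and those where it is not, over the lines with both an
#' essentiality call for A1 and expression for A2. Pairs with fewer than 2
#' usable lines in either stratum are skipped (NA statistics).
#'
#' @param a1_calls named 0/1/NA vector: A1's binarized essentiality per
#'   line.
#' @param a2_expr named numeric vector: A2 expression per line.
#' @return List: n_lines_A1_essential, n_lines_A1_nonessential,
#'   mean_expr_A2_essential, mean_expr_A2_nonessential, t, p.
#' @export
sl_expression_test <- function(a1_calls, a2_expr) {
  common <- intersect(names(a1_calls)[!is.na(a1_calls)],
                      names(a2_expr)[!is.na(a2_expr)])
  ess <- a2_expr[common[a1_calls[common] == 1]]
  non <- a2_expr[common[a1_calls[common] == 0]]
  if (length(ess) < 2 || length(non) < 2)
    return(list(n_lines_A1_essential = length(ess),
                n_lines_A1_nonessential = length(non),
                mean_expr_A2_essential = NA_real_,
                mean_expr_A2_nonessential = NA_real_,
                t = NA_real_, p = NA_real_))
  tt <- two_sample_t(ess, non)
  list(n_lines_A1_essential = length(ess),
       n_lines_A1_nonessential = length(non),
       mean_expr_A2_essential = mean(ess),
       mean_expr_A2_nonessential = mean(non),
       t = unname(tt$statistic), p = tt$p_value)
}

#' Test all selected pairs against expression
#'
#' Runs [sl_expression_test()] for every testable pair; pairs skipped for
#' lack of lines are kept with NA statistics and counted.
#'
#' @param testable pair table from [select_testable_pairs()].
#' @param bin binarized essentiality matrix (genes x lines).
#' @param expression expression matrix (genes x lines).
#' @return The pair table with test columns appended.
#' @export
sl_test_pairs <- function(testable, bin, expression) {
  res <- lapply(seq_len(nrow(testable)), function(i) {
    a1 <- testable$A1[i]; a2 <- testable$A2[i]
    if (!a1 %in% rownames(bin) || !a2 %in% rownames(expression))
      return(list(n_lines_A1_essential = 0L, n_lines_A1_nonessential = 0L,
                  mean_expr_A2_essential = NA_real_,
                  mean_expr_A2_nonessential = NA_real_,
                  t = NA_real_, p = NA_real_))
    sl_expression_test(bin[a1, ], expression[a2, ])
  })
  cbind(testable, do.call(rbind, lapply(res, as.data.frame)))
}

#' Call putative synthetic lethal pairs at an FDR level
#'
#' Benjamini-Hochberg FDR over the tested pairs' p-values (one family per
#' mode); a pair is flagged putative SL iff q < `fdr_level` and the mean A2
#' expression is strictly lower in the A1-essential stratum.
#'
#' @param results tested pair table from [sl_test_pairs()].
#' @param fdr_level FDR level (default 0.10).
#' @return The table with `q` and `is_putative_SL`; counts in
#'   `attr(, "summary")` (n_tested, n_flagged, n_unique_A1_tested,
#'   n_unique_A1_flagged, frac_A1_flagged).
#' @export
call_sl <- function(results, fdr_level = 0.10) {
  if (nrow(results) == 0) stop("no tested pairs", call. = FALSE)
  results$q <- bh_fdr(results$p)
  lower <- results$mean_expr_A2_essential < results$mean_expr_A2_nonessential
  results$is_putative_SL <- !is.na(results$q) & results$q < fdr_level &
    !is.na(lower) & lower
  n_a1 <- length(unique(results$A1))
  n_a1_fl <- length(unique(results$A1[results$is_putative_SL]))
  attr(results, "summary") <- list(
    n_tested = nrow(results), n_flagged = sum(results$is_putative_SL),
    n_unique_A1_tested = n_a1, n_unique_A1_flagged = n_a1_fl,
    frac_A1_flagged = if (n_a1 > 0) n_a1_fl / n_a1 else NaN,
    fdr_level = fdr_level)
  results
}

#' Copy-number follow-up for flagged SL pairs
#'
#' For each putative SL pair with copy-number data for A2, the same
#' stratified t-test is applied to A2 copy number; the BH family is the set
#' of evaluable flagged pairs. A pair is CN-driven iff p < 0.05, q < 0.10
#' and copy number is lower in the A1-essential stratum.
#'
#' @param called table from [call_sl()].
#' @param cn copy-number matrix (genes x lines).
#' @param bin binarized essentiality matrix.
#' @return `called` with cn_p, cn_q, cn_driven columns (NA where not
#'   evaluable).
#' @export
cn_followup <- function(called, cn, bin) {
  called$cn_p <- NA_real_; called$cn_q <- NA_real_
  called$cn_lower_in_essential <- NA
  idx <- which(called$is_putative_SL)
  for (i in idx) {
    a1 <- called$A1[i]; a2 <- called$A2[i]
    if (!a2 %in% rownames(cn) || !a1 %in% rownames(bin)) next
    r <- sl_expression_test(bin[a1, ], cn[a2, ])
    called$cn_p[i] <- r$p
    called$cn_lower_in_essential[i] <-
      if (is.na(r$t)) NA else r$mean_expr_A2_essential < r$mean_expr_A2_nonessential
  }
  eval_idx <- idx[!is.na(called$cn_p[idx])]
  called$cn_q[eval_idx] <- bh_fdr(called$cn_p[eval_idx])
  called$cn_driven <- !is.na(called$cn_p) & called$cn_p < 0.05 &
    !is.na(called$cn_q) & called$cn_q < 0.10 &
    !is.na(called$cn_lower_in_essential) & called$cn_lower_in_essential
  called
}

#' Nonsense-mutation follow-up for flagged SL pairs
#'
#' Restricted to flagged pairs whose A2 carries a nonsense mutation in at
#' least one cell line with essentiality data for A1. Builds the 2x2 table
#' of A1-essential vs not by A2 nonsense-mutated vs not and applies a
#' one-sided (enrichment) Fisher exact test; BH across the evaluated pairs.
#' A pair is nonsense-driven iff p < 0.05 and q < 0.10.
#'
#' @param called table from [call_sl()].
#' @param mutations long mutation table (gene, cell_line,
#'   Variant_Classification).
#' @param bin binarized essentiality matrix.
#' @return `called` with nonsense_p, nonsense_q, nonsense_driven columns;
#'   the number of flagged pairs with no A2 nonsense mutation in
#'   `attr(, "n_no_nonsense")`.
#' @export
nonsense_followup <- function(called, mutations, bin) {
  nons <- mutations[mutations$Variant_Classification == "Nonsense_Mutation", ]
  mut_lines <- split(nons$cell_line, nons$gene)
  called$nonsense_p <- NA_real_; called$nonsense_q <- NA_real_
  n_skipped <- 0L
  idx <- which(called$is_putative_SL)
  for (i in idx) {
    a1 <- called$A1[i]; a2 <- called$A2[i]
    if (!a1 %in% rownames(bin)) next
    calls <- bin[a1, ]
    lines_ok <- names(calls)[!is.na(calls)]
    mut <- intersect(unique(mut_lines[[a2]]), lines_ok)
    if (length(mut) == 0) { n_skipped <- n_skipped + 1L; next }
    ess <- lines_ok[calls[lines_ok] == 1]
    a <- length(intersect(ess, mut))
    b <- length(ess) - a
    cc <- length(mut) - a
    d <- length(lines_ok) - a - b - cc
    called$nonsense_p[i] <- fisher_exact_or(a, b, cc, d,
                                            alternative = "greater")$p_value
  }
  eval_idx <- idx[!is.na(called$nonsense_p[idx])]
  called$nonsense_q[eval_idx] <- bh_fdr(called$nonsense_p[eval_idx])
  called$nonsense_driven <- !is.na(called$nonsense_p) &
    called$nonsense_p < 0.05 &
    !is.na(called$nonsense_q) & called$nonsense_q < 0.10
  attr(called, "n_no_nonsense") <- n_skipped
  called
}

#' Enrichment battery over tested SL pairs
#'
#' Fisher exact tests of the putative-SL flag against duplication mode and
#' protein complex membership (overall and within subsets), plus
#' two-sample t-tests of pair sequence identity (SL vs non-SL) overall and
#' within the WGD, SSD and complex-member subsets. Pair identity is the
#' percent of A1's sequence matched in A2.
#'
#' @param called annotated tested pair table from [call_sl()] (needs
#'   duplication_mode, either_in_complex, same_complex,
#'   identity_A1_in_A2).
#' @return data.frame: analysis, subset, n, statistic name, estimate,
#'   rate_group1, rate_group2, p, note.
#' @export
sl_enrichment <- function(called) {
  fisher_row <- function(analysis, subset_name, d, grp) {
    a <- sum(d$is_putative_SL & grp); b <- sum(!d$is_putative_SL & grp)
    cc <- sum(d$is_putative_SL & !grp); dd <- sum(!d$is_putative_SL & !grp)
    note <- if (a + cc == 0 || min(a, cc) == 0)
      "a stratum has zero SL calls; OR degenerate" else ""
    res <- fisher_exact_or(a, b, cc, dd)
    data.frame(analysis = analysis, subset = subset_name,
               n = nrow(d), statistic = "OR",
               estimate = unname(res$statistic),
               rate_group1 = if (a + b > 0) a / (a + b) else NaN,
               rate_group2 = if (cc + dd > 0) cc / (cc + dd) else NaN,
               p = res$p_value, note = note, stringsAsFactors = FALSE)
  }
  t_row <- function(analysis, subset_name, d) {
    x <- d$identity_A1_in_A2[d$is_putative_SL]
    y <- d$identity_A1_in_A2[!d$is_putative_SL]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(analysis = analysis, subset = subset_name,
                        n = nrow(d), statistic = "t", estimate = NA_real_,
                        rate_group1 = mean(x), rate_group2 = mean(y),
                        p = NA_real_, note = "a group has < 2 pairs",
                        stringsAsFactors = FALSE))
    tt <- two_sample_t(x, y)
    data.frame(analysis = analysis, subset = subset_name, n = nrow(d),
               statistic = "t", estimate = unname(tt$statistic),
               rate_group1 = mean(x), rate_group2 = mean(y),
               p = tt$p_value, note = "", stringsAsFactors = FALSE)
  }
  d <- called
  wgd <- d$duplication_mode == "WGD"
  out <- rbind(
    fisher_row("SL vs WGD (vs SSD)", "all tested", d, wgd),
    fisher_row("SL vs either gene in complex", "all tested", d,
               d$either_in_complex),
    fisher_row("SL vs both genes in same complex", "all tested", d,
               d$same_complex),
    fisher_row("SL vs WGD (vs SSD)", "either in complex",
               d[d$either_in_complex, , drop = FALSE],
               wgd[d$either_in_complex]),
    fisher_row("SL vs either gene in complex", "WGD pairs",
               d[wgd, , drop = FALSE], d$either_in_complex[wgd]),
    t_row("identity: SL vs non-SL", "all tested", d),
    t_row("identity: SL vs non-SL", "WGD pairs", d[wgd, , drop = FALSE]),
    t_row("identity: SL vs non-SL", "SSD pairs", d[!wgd, , drop = FALSE]),
    t_row("identity: SL vs non-SL", "either in complex",
          d[d$either_in_complex, , drop = FALSE]))
  rownames(out) <- NULL
  out
}
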