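summary_row <- function(gene, n_ess, n_scored, category = "sometimes") {
  data.frame(gene = gene, n_lines_scored = n_scored, n_lines_essential = n_ess,
             fraction_essential = n_ess / n_scored, category = category,
             bin = NA, stringsAsFactors = FALSE)
}

test_that("the 1% essentiality floor is inclusive and excludes broadly genes", {
  gs <- rbind(summary_row("low", 5, 554),        # 0.90% -> excluded
              summary_row("in", 6, 554),         # 1.08% -> included
              summary_row("broad", 520, 554, "broadly"),
              summary_row("never0", 0, 554, "never"))
  pairs <- data.frame(A1 = c("low", "in", "broad", "never0"),
                      A2 = paste0("p", 1:4),
                      identity_A1_in_A2 = 50, identity_A2_in_A1 = 50,
                      stringsAsFactors = FALSE)
  sel <- select_testable_pairs(gs, pairs, expressed_genes = paste0("p", 1:4),
                               mode = "all")
  expect_setequal(sel$A1, "in")
})

test_that("closest mode keeps the most similar expressed partner only", {
  gs <- summary_row("a1", 10, 60)
  pairs <- data.frame(A1 = "a1", A2 = c("p_close", "p_far", "p_unexpr"),
                      identity_A1_in_A2 = c(80, 40, 95),
                      identity_A2_in_A1 = c(75, 35, 90),
                      stringsAsFactors = FALSE)
  sel <- select_testable_pairs(gs, pairs, c("p_close", "p_far"), "closest")
  expect_equal(sel$A2, "p_close")   # 95% partner has no expression data
  sel_all <- select_testable_pairs(gs, pairs, c("p_close", "p_far"), "all")
  expect_setequal(sel_all$A2, c("p_close", "p_far"))
  expect_equal(sel_all$is_closest_pair, c(TRUE, FALSE))
})

test_that("the stratified expression test reproduces hand computations", {
  calls <- setNames(c(1, 1, 1, 0, 0, 0), paste0("L", 1:6))
  expr <- setNames(c(1, 1, 2, 5, 6, 7), paste0("L", 1:6))
  r <- sl_expression_test(calls, expr)
  expect_equal(r$t, -7, tolerance = 1e-12)
  expect_equal(r$mean_expr_A2_essential, 4 / 3)
  expect_equal(r$n_lines_A1_essential, 3)

  r0 <- sl_expression_test(calls, setNames(rep(2, 6), paste0("L", 1:6)))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)

  # a stratum with < 2 usable lines is skipped
  r_skip <- sl_expression_test(setNames(c(1, 0, 0, 0), paste0("L", 1:4)),
                               expr[1:4])
  expect_true(is.na(r_skip$p))
})

test_that("SL calling enforces FDR and the direction filter", {
  res <- data.frame(A1 = paste0("a", 1:4), A2 = paste0("b", 1:4),
                    p = c(1, 1, 1e-8, 1e-8),
                    mean_expr_A2_essential = c(1, 1, 1, 9),
                    mean_expr_A2_nonessential = c(1, 1, 5, 5),
                    stringsAsFactors = FALSE)
  called <- call_sl(res)
  expect_equal(called$is_putative_SL, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(attr(called, "summary")$n_flagged, 1)

  all_null <- call_sl(transform(res, p = 1))
  expect_equal(sum(all_null$is_putative_SL), 0)
  expect_error(call_sl(res[0, ]), "no tested pairs")
})

test_that("nonsense follow-up applies the one-sided hypergeometric", {
  lines <- sprintf("L%02d", 1:60)
  bin <- matrix(0L, 1, 60, dimnames = list("A1", lines))
  bin["A1", 1:10] <- 1L
  called <- data.frame(A1 = "A1", A2 = "A2", is_putative_SL = TRUE,
                       stringsAsFactors = FALSE)
  muts <- data.frame(gene = "A2", cell_line = lines[1:10],
                     Variant_Classification = "Nonsense_Mutation",
                     stringsAsFactors = FALSE)
  r <- nonsense_followup(called, muts, bin)
  expect_equal(r$nonsense_p, 1 / choose(60, 10), tolerance = 1e-12)
  expect_true(r$nonsense_driven)

  # single mutation in a non-essential line: upper tail is everything
  muts1 <- data.frame(gene = "A2", cell_line = lines[60],
                      Variant_Classification = "Nonsense_Mutation",
                      stringsAsFactors = FALSE)
  r1 <- nonsense_followup(called, muts1, bin)
  expect_equal(r1$nonsense_p, 1)
  expect_false(r1$nonsense_driven)

  # no nonsense-mutated A2 at all: evaluable set empty, run succeeds
  r2 <- nonsense_followup(called, muts1[0, ], bin)
  expect_true(is.na(r2$nonsense_p))
  expect_equal(attr(r2, "n_no_nonsense"), 1)
})

test_that("CN follow-up flags planted CN-driven pairs and not expression-only ones", {
  cfg <- quick_cfg(n_genes = 200, n_cell_lines = 40, n_planted_sl_pairs = 12,
                   frac_sl_cn_driven = 0.5, seed = 71)
  co <- generate_cohort(cfg)
  bin <- binarize_scores(quick_scores(co), implied_threshold(cfg))
  summ <- summarize_essentiality(bin)
  sel <- select_testable_pairs(summ$genes, co$pairs,
                               rownames(co$expression), "all")
  called <- call_sl(sl_test_pairs(sel, bin, co$expression))
  called <- cn_followup(called, co$copy_number, bin)
  gt <- co$ground_truth$planted_sl
  key <- paste(called$A1, called$A2)
  cn_truth <- setNames(gt$cn_driven, paste(gt$A1, gt$A2))
  found <- key %in% names(cn_truth) & called$is_putative_SL
  agree <- called$cn_driven[found] == cn_truth[key[found]]
  expect_gte(mean(agree), 0.8)
})

test_that("closest-mode calls are a subset of all-pairs tests", {
  cfg <- quick_cfg(n_genes = 300, n_cell_lines = 40, seed = 72)
  co <- generate_cohort(cfg)
  bin <- binarize_scores(quick_scores(co), implied_threshold(cfg))
  summ <- summarize_essentiality(bin)
  run_mode <- function(mode) {
    sel <- select_testable_pairs(summ$genes, co$pairs,
                                 rownames(co$expression), mode)
    call_sl(sl_test_pairs(sel, bin, co$expression))
  }
  closest <- run_mode("closest"); all_m <- run_mode("all")
  expect_true(all(paste(closest$A1, closest$A2) %in%
                    paste(all_m$A1, all_m$A2)))
  s_c <- attr(closest, "summary"); s_a <- attr(all_m, "summary")
  expect_gte(s_a$n_unique_A1_flagged, s_c$n_unique_A1_flagged)
  # no flagged pair ever has higher mean expression in the essential stratum
  flagged <- all_m[all_m$is_putative_SL, ]
  expect_true(all(flagged$mean_expr_A2_essential <
                    flagged$mean_expr_A2_nonessential))
})

test_that("planted pairs are detected with very small p-values", {
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    cfg <- quick_cfg(seed = 700 + s)
    co <- generate_cohort(cfg)
    bin <- binarize_scores(quick_scores(co), implied_threshold(cfg))
    summ <- summarize_essentiality(bin)
    sel <- select_testable_pairs(summ$genes, co$pairs,
                                 rownames(co$expression), "all")
    tested <- sl_test_pairs(sel, bin, co$expression)
    gt <- co$ground_truth$planted_sl
    m <- match(paste(gt$A1, gt$A2), paste(tested$A1, tested$A2))
    p <- tested$p[m[!is.na(m)]]
    hits <- hits + sum(p < 0.001, na.rm = TRUE)
    total <- total + length(p)
  }
  expect_gte(hits / total, 0.95)
})

test_that("enrichment battery reports degenerate strata with a note", {
  d <- data.frame(is_putative_SL = rep(c(TRUE, FALSE), c(0, 40)),
                  duplication_mode = rep(c("WGD", "SSD"), 20),
                  either_in_complex = rep(c(TRUE, FALSE), each = 20),
                  same_complex = FALSE,
                  identity_A1_in_A2 = runif(40, 20, 100))
  e <- sl_enrichment(d)
  expect_true(any(grepl("zero SL calls", e$note)))
  expect_true(all(e$p[e$statistic == "OR"] == 1, na.rm = TRUE))
})
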