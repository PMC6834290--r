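test_that("guide-to-gene mapping drops multi-gene loci and intergenic hits", {
  # handcrafted genome: one guide locus inside gene A, one in the A/B overlap,
  # one in open intergenic sequence
  proto1 <- "ACGTACGTACGTACGTACGT"
  proto2 <- "TTGACCATGGTTGACCATGG"
  proto3 <- "GATTACAGATTACAGATTAC"
  base <- paste(rep("A", 3000), collapse = "")
  chr <- base
  chr <- paste0(substr(chr, 1, 100), proto1, "AGG",
                substr(chr, 124, nchar(chr)))
  chr <- paste0(substr(chr, 1, 600), proto2, "CGG",
                substr(chr, 624, nchar(chr)))
  chr <- paste0(substr(chr, 1, 1500), proto3, "TGG",
                substr(chr, 1524, nchar(chr)))
  genome <- list(sequences = c(chr1 = chr))
  genes <- data.frame(gene = c("A", "B"),
                      chrom = "chr1",
                      start = c(50, 610), end = c(700, 1100),
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  guides <- data.frame(guide_id = c("g1", "g2", "g3"),
                       protospacer = c(proto1, proto2, proto3),
                       intended_gene = c("A", "A", ""),
                       stringsAsFactors = FALSE)
  hits <- align_guides(guides, genome)
  map <- build_guide_gene_map(guides, hits, genes)
  expect_true(map$retained[map$sgRNA == "g1"])
  expect_equal(map$gene[map$sgRNA == "g1"], "A")
  expect_equal(map$reason[map$sgRNA == "g2"], "multi-gene locus")
  expect_equal(map$reason[map$sgRNA == "g3"], "intergenic")
})

test_that("retained/dropped verdicts equal an oracle rescan on a toy cohort", {
  cfg <- tiny_genome_cfg(seed = 21, duplication_mutation_rate = 0.03)
  genome <- generate_toy_genome(cfg)
  guides <- generate_guide_library(genome, 3, seed = 22)
  map <- build_guide_gene_map(guides, align_guides(guides, genome),
                              genome$genes)
  for (i in seq_len(nrow(guides))) {
    o <- oracle_align(guides$protospacer[i], genome$sequences)
    multi <- oracle_is_multi(o)
    perfect <- o[o$n_mismatches == 0, , drop = FALSE]
    retained_oracle <- FALSE
    if (!multi && nrow(perfect) == 1) {
      in_gene <- genome$genes$chrom == perfect$chromosome &
        genome$genes$start < perfect$end & genome$genes$end > perfect$start
      retained_oracle <- sum(in_gene) == 1
    }
    expect_equal(map$retained[i], retained_oracle,
                 label = guides$guide_id[i])
  }
})

test_that("gene gating enforces the minimum guide count", {
  map <- data.frame(
    sgRNA = paste0("g", 1:9),
    gene = c(rep("A", 4), rep("B", 2), rep("C", 3)),
    retained = c(rep(TRUE, 4), TRUE, TRUE, TRUE, TRUE, FALSE),
    reason = "retained", stringsAsFactors = FALSE)
  gate <- gate_genes_by_guide_count(map, gene_universe = c("A", "B", "C", "D"))
  expect_setequal(gate$retained$gene, "A")
  expect_setequal(gate$dropped$gene, c("B", "C", "D"))
  expect_equal(gate$dropped$reason[gate$dropped$gene == "D"], "no guides")
  expect_equal(gate$dropped$reason[gate$dropped$gene == "B"],
               "too few guides")
})

test_that("gene scores are guide means with per-line missing handling", {
  lfc <- rbind(g1 = c(-1, 0), g2 = c(-2, 0), g3 = c(-3, NA),
               g4 = c(5, 5))
  colnames(lfc) <- c("L1", "L2")
  map <- data.frame(sgRNA = c("g1", "g2", "g3", "g4"),
                    gene = c("A", "A", "A", "B"),
                    retained = c(TRUE, TRUE, TRUE, FALSE),
                    reason = "x", stringsAsFactors = FALSE)
  s <- score_genes(lfc, map, "A")
  expect_equal(s["A", "L1"], -2)
  expect_true(is.na(s["A", "L2"]))      # only 2 informative guides
  zero <- lfc[1:3, ]; zero[] <- 0
  s0 <- score_genes(zero, map, "A")
  expect_equal(unname(s0["A", ]), c(0, 0))
})

test_that("precision-recall AUC is average precision over ranked references", {
  scores <- matrix(c(-3, -2, -1, 0), dimnames = list(c("e1", "e2", "n1", "n2"),
                                                     "L1"))
  qc <- precision_recall_qc(scores, c("e1", "e2"), c("n1", "n2"))
  expect_equal(qc$mean_auc, 1)

  # positives at ranks 1 and 3 of 4 labeled genes
  scores <- matrix(c(-3, -2, -1, 0), dimnames = list(c("e1", "n1", "e2", "n2"),
                                                     "L1"))
  qc <- precision_recall_qc(scores, c("e1", "e2"), c("n1", "n2"))
  expect_equal(qc$mean_auc, (1 / 1 + 2 / 3) / 2)

  # reversed perfect ranking equals the oracle on the same ordering
  scores <- matrix(c(-3, -2, -1, 0), dimnames = list(c("n1", "n2", "e1", "e2"),
                                                     "L1"))
  qc <- precision_recall_qc(scores, c("e1", "e2"), c("n1", "n2"))
  expect_equal(qc$mean_auc, oracle_ap(c(FALSE, FALSE, TRUE, TRUE)))

  expect_error(precision_recall_qc(scores, c("zz"), c("n1")), "intersect")
  expect_error(precision_recall_qc(scores, c("e1", "n1"), c("n1")), "disjoint")
})

test_that("high-identity paralogs are dropped at a higher rate than genes overall", {
  cfg <- tiny_genome_cfg(seed = 31, n_genes = 24,
                         n_duplicate_gene_pairs = 4)
  genome <- generate_toy_genome(cfg)
  guides <- generate_guide_library(genome, 4, seed = 32)
  map <- build_guide_gene_map(guides, align_guides(guides, genome),
                              genome$genes)
  gate <- gate_genes_by_guide_count(map, gene_universe = genome$genes$gene)
  high_id <- unique(unlist(genome$duplications[
    genome$duplications$identity_pct >= 90, c("source_gene", "target_gene")]))
  drop_rate_high <- mean(high_id %in% gate$dropped$gene)
  drop_rate_all <- nrow(gate$dropped) / nrow(genome$genes)
  expect_gt(drop_rate_high, drop_rate_all)
})
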