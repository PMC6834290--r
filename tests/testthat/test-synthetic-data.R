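test_that("generation is deterministic: same config and seed, identical bundles", {
  cfg <- tiny_genome_cfg(seed = 51)
  g1 <- generate_toy_genome(cfg); g2 <- generate_toy_genome(cfg)
  expect_identical(g1, g2)
  co1 <- generate_cohort(cfg, g1, generate_guide_library(g1, 4, seed = 1))
  co2 <- generate_cohort(cfg, g2, generate_guide_library(g2, 4, seed = 1))
  expect_identical(co1, co2)

  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  write_toy_genome(g1, d1); write_toy_genome(g2, d2)
  for (f in c("genome.fa", "genes.bed"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("FASTA/BED round-trip preserves gene layout (2 x 50 kb, 40 genes)", {
  cfg <- cohort_config(n_genes = 40, n_cell_lines = 10,
                       n_chromosomes = 2, chromosome_length = 50000,
                       n_planted_sl_pairs = 2, n_duplicate_gene_pairs = 0,
                       seed = 52)
  g <- generate_toy_genome(cfg)
  d <- file.path(tempdir(), "roundtrip")
  write_toy_genome(g, d)
  back <- read_toy_genome(file.path(d, "genome.fa"), file.path(d, "genes.bed"))
  expect_identical(back$sequences, g$sequences)
  expect_equal(nrow(back$genes), 40)
  expect_true(all(back$genes$start >= 0))
  expect_true(all(back$genes$end <= 50000))
  expect_true(all(back$genes$end - back$genes$start == 1000))
  # both strands present, split compatible with a fair coin
  n_plus <- sum(back$genes$strand == "+")
  expect_true(abs(n_plus - 20) <= 3 * sqrt(40 * 0.25))
  # non-overlapping intervals per chromosome
  for (chr in unique(back$genes$chrom)) {
    gg <- back$genes[back$genes$chrom == chr, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(diff(gg$start) >= 1000))
  }
})

test_that("zero-rate duplication makes every NGG window of the source occur twice", {
  cfg <- tiny_genome_cfg(seed = 53, n_duplicate_gene_pairs = 1)
  g <- generate_toy_genome(cfg)
  dup <- g$duplications
  src <- g$genes[g$genes$gene == dup$source_gene[1], ]
  s <- substr(g$sequences[[src$chrom]], src$start + 1, src$end)
  both_strands <- c(g$sequences, vapply(g$sequences, oracle_revcomp,
                                        character(1)))
  pam_sites <- gregexpr("(?=[ACGT]GG)", s, perl = TRUE)[[1]]
  pam_sites <- pam_sites[pam_sites > 20][1:10]   # first 10 complete windows
  for (p in pam_sites) {
    window <- substr(s, p - 20, p + 2)           # 20-mer + NGG
    n_occ <- sum(vapply(both_strands, function(chr)
      length(gregexpr(window, chr, fixed = TRUE)[[1]]) *
        (regexpr(window, chr, fixed = TRUE) > 0), numeric(1)))
    expect_gte(n_occ, 2)
  }
})

test_that("genes without PAM sites yield zero guides and a warning", {
  genome <- list(
    sequences = c(chr1 = paste(rep("A", 2000), collapse = "")),
    genes = data.frame(gene = "dead", chrom = "chr1", start = 100,
                       end = 1100, strand = "+", stringsAsFactors = FALSE))
  expect_warning(gl <- generate_guide_library(genome, 4, seed = 1),
                 "no usable NGG")
  expect_equal(nrow(gl), 0)
  expect_equal(attr(gl, "short_genes"), "dead")
})

test_that("guide arithmetic: 4 guides per gene over 40 PAM-rich genes gives 160", {
  cfg <- cohort_config(n_genes = 40, n_cell_lines = 10, n_chromosomes = 2,
                       chromosome_length = 50000, n_planted_sl_pairs = 0,
                       n_duplicate_gene_pairs = 0, seed = 54)
  g <- generate_toy_genome(cfg)
  gl <- generate_guide_library(g, 4, seed = 2)
  expect_equal(nrow(gl), 160)
  expect_true(all(table(gl$intended_gene) == 4))
})

test_that("every emitted guide relocates to an NGG PAM by string search", {
  cfg <- tiny_genome_cfg(seed = 55, n_duplicate_gene_pairs = 0)
  g <- generate_toy_genome(cfg)
  gl <- generate_guide_library(g, 3, seed = 3)
  for (i in seq_len(nrow(gl))) {
    gene <- g$genes[g$genes$gene == gl$intended_gene[i], ]
    seq <- g$sequences[[gene$chrom]]
    target <- if (gene$strand == "+") gl$protospacer[i] else
      oracle_revcomp(gl$protospacer[i])
    pos <- regexpr(target, substr(seq, gene$start + 1, gene$end),
                   fixed = TRUE)
    expect_gt(pos, 0)
    abs_pos <- gene$start + as.integer(pos)      # 1-based genome position
    pam <- if (gene$strand == "+")
      substr(seq, abs_pos + 20, abs_pos + 22) else
      oracle_revcomp(substr(seq, abs_pos - 3, abs_pos - 1))
    expect_equal(substr(pam, 2, 3), "GG", label = gl$guide_id[i])
  }
})

test_that("ground-truth category counts are exact", {
  cfg <- cohort_config(n_genes = 600, n_cell_lines = 10,
                       n_planted_sl_pairs = 0, seed = 56)
  co <- generate_cohort(cfg)
  expect_equal(sum(co$ground_truth$category == "broadly"), 36)  # 0.06 * 600
  expect_equal(sum(co$ground_truth$category == "never"), 288)
  expect_equal(sum(co$ground_truth$category == "sometimes"), 276)
})

test_that("zero planted pairs yields an empty ground-truth SL list", {
  co <- generate_cohort(quick_cfg(n_planted_sl_pairs = 0, seed = 57))
  expect_equal(nrow(co$ground_truth$planted_sl), 0)
})

test_that("pooled component draws match the model-implied mixture weights", {
  cfg <- quick_cfg(n_genes = 600, n_cell_lines = 60,
                   n_planted_sl_pairs = 0, seed = 58)
  co <- generate_cohort(cfg)
  counts <- co$ground_truth$component_counts
  n <- sum(counts)
  w_hat <- counts / n
  w_imp <- implied_mixture(cfg)$weights
  # SE combines the per-draw multinomial part and the between-gene spread of
  # the sometimes-essential per-gene frequency
  n_som <- sum(co$ground_truth$category == "sometimes")
  var_f <- diff(cfg$sometimes_frac_range)^2 / 12
  se <- sqrt(w_imp * (1 - w_imp) / n +
               (cfg$frac_sometimes^2 * var_f / n_som) * c(1, cfg$moderate_line_frac^2, (1 - cfg$moderate_line_frac)^2))
  expect_true(all(abs(w_hat - w_imp) <= 3 * se))
})

test_that("planted SL pairs show lower A2 expression in A1-essential lines", {
  co <- generate_cohort(quick_cfg(seed = 59))
  gt <- co$ground_truth
  for (i in seq_len(nrow(gt$planted_sl))) {
    a1 <- gt$planted_sl$A1[i]; a2 <- gt$planted_sl$A2[i]
    lo <- co$cell_lines %in% gt$low_lines[[a1]]
    expect_lt(mean(co$expression[a2, lo]), mean(co$expression[a2, !lo]))
    # A1's score is essential-component exactly in those lines
    expect_true(all(co$true_scores[a1, lo] < -0.2))
    expect_true(all(co$true_scores[a1, !lo] > -0.7))
  }
})

test_that("emitted tables share consistent gene and line indices", {
  co <- generate_cohort(quick_cfg(seed = 60))
  expect_equal(colnames(co$true_scores), co$cell_lines)
  expect_equal(colnames(co$expression), co$cell_lines)
  expect_equal(colnames(co$copy_number), co$cell_lines)
  expect_equal(colnames(co$lfc), co$cell_lines)
  expect_true(all(rownames(co$expression) %in% co$genes))
  expect_true(all(rownames(co$copy_number) %in% co$genes))
  expect_true(all(co$mutations$gene %in% co$genes))
  expect_true(all(co$mutations$cell_line %in% co$cell_lines))
  expect_true(all(c(co$pairs$A1, co$pairs$A2) %in% co$genes))
  expect_false(any(is.na(co$true_scores)))
  expect_false(any(is.na(co$expression)))
})

test_that("cohort bundles round-trip through the on-disk formats", {
  co <- generate_cohort(quick_cfg(seed = 63))
  d <- file.path(tempdir(), "bundle")
  write_cohort(co, d)
  lfc <- read_matrix_csv(file.path(d, "logfold_change.csv"))
  expect_equal(lfc, co$lfc)
  expr <- read_matrix_csv(file.path(d, "expression.csv"))
  expect_equal(expr, co$expression)
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_equal(length(gt$category), length(co$genes))
  muts <- read.csv(file.path(d, "mutation_calls.csv"))
  expect_true("Nonsense_Mutation" %in% muts$Variant_Classification)
})
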