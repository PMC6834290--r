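#' Configuration for a synthetic screen cohort
#'
#' Bundles every tunable of the synthetic-data generator: cohort dimensions,
#' paralogy structure, essentiality category fractions, the three score
#' components of the generating Gaussian mixture, expression/copy-number/
#' mutation parameters, planted synthetic-lethal structure, and toy-genome
#' sizing. Defaults emulate the statistical structure of a large CRISPR
#' dependency screen compendium at desk scale: 60 cell lines, 600 genes of
#' which 61% are paralogs, 64% of paralog pairs from whole-genome
#' duplication, and category fractions 48% never / 46% sometimes / 6%
#' broadly essential.
#'
#' @param n_cell_lines number of cell lines screened.
#' @param n_genes number of genes in the cohort.
#' @param frac_paralog fraction of genes that belong to a paralog family.
#' @param family_size_weights sampling weights for paralog family sizes
#'   2,3,4,5 (chosen so roughly 30% of paralog genes have exactly one
#'   paralog).
#' @param frac_wgd_pairs fraction of paralog pairs labelled whole-genome
#'   duplicates.
#' @param frac_never,frac_sometimes,frac_broadly essentiality category
#'   fractions; must sum to 1 and `frac_sometimes` must be positive.
#' @param n_planted_sl_pairs number of paralog pairs planted with a true
#'   buffering (synthetic lethal) relationship.
#' @param essential_mean,essential_sd,moderate_mean,moderate_sd,tolerated_mean,tolerated_sd
#'   parameters of the three score components (severe fitness defect,
#'   moderate defect, no defect); means must be ordered
#'   essential < moderate < tolerated.
#' @param expr_high_mean,expr_low_mean,expr_sd log2(TPM+1)-like expression
#'   states for planted partner genes and their shared noise sd.
#' @param frac_sl_cn_driven fraction of planted SL pairs whose low-expression
#'   lines also carry reduced copy number.
#' @param nonsense_rate per-gene, per-line probability of a background
#'   nonsense mutation.
#' @param low_state_frac fraction of cell lines in which a planted partner
#'   (A2) gene sits in its low-expression state.
#' @param sometimes_frac_range range of the per-gene essential-line
#'   frequency for non-planted sometimes-essential genes.
#' @param moderate_line_frac probability that a non-essential line of a
#'   sometimes-essential gene draws from the moderate component (rather than
#'   the tolerated one).
#' @param sl_wgd_or target odds ratio by which planted SL pairs are enriched
#'   among WGD pairs.
#' @param complex_same_rate_ssd probability that an SSD pair is planted into
#'   a shared protein complex.
#' @param complex_wgd_or odds ratio of shared-complex planting for WGD vs
#'   SSD pairs.
#' @param n_complexes number of protein complexes in the synthetic complex
#'   table.
#' @param complex_extra_rate per-gene probability of joining a random
#'   complex independently of pair planting.
#' @param plant_essential_complex if `TRUE`, one complex is populated
#'   entirely with broadly essential genes (recoverable by enrichment).
#' @param plant_nonsense_pair if `TRUE`, one planted SL pair has its partner
#'   gene nonsense-mutated in the low-expression lines.
#' @param expr_missing_frac,cn_missing_frac fractions of genes absent from
#'   the expression / copy-number tables.
#' @param cn_baseline,cn_sd,cn_low_delta copy-number baseline, noise sd, and
#'   reduction applied in the low state of CN-driven planted pairs.
#' @param identity_range,sl_identity_range uniform ranges (percent) for the
#'   bidirectional sequence identity of ordinary and planted-SL paralog
#'   pairs.
#' @param guides_per_gene sgRNAs designed per gene.
#' @param guide_noise_sd i.i.d. Gaussian noise added to each guide's
#'   log-fold change around its gene's true score.
#' @param gene_length,intergenic_gap toy-genome gene interval length and the
#'   mean gap between consecutive genes (bases).
#' @param n_chromosomes number of toy chromosomes; default scales with
#'   `n_genes` (about 150 genes per chromosome).
#' @param chromosome_length length of each toy chromosome; default sized so
#'   all genes fit with room to spare.
#' @param n_duplicate_gene_pairs number of gene pairs whose sequence is
#'   duplicated in the toy genome (source of genuine multi-targeting).
#' @param duplication_mutation_rate per-base substitution rate applied when
#'   copying a duplicated gene's sequence.
#' @param seed integer seed from which all generator randomness flows.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_cell_lines = 60,
                          n_genes = 600,
                          frac_paralog = 0.61,
                          family_size_weights = c(`2` = 0.45, `3` = 0.25,
                                                  `4` = 0.17, `5` = 0.13),
                          frac_wgd_pairs = 0.64,
                          frac_never = 0.48,
                          frac_sometimes = 0.46,
                          frac_broadly = 0.06,
                          n_planted_sl_pairs = 40,
                          essential_mean = -1.0, essential_sd = 0.2,
                          moderate_mean = -0.5, moderate_sd = 0.15,
                          tolerated_mean = 0.0, tolerated_sd = 0.15,
                          expr_high_mean = 5, expr_low_mean = 1, expr_sd = 0.8,
                          frac_sl_cn_driven = 0.36,
                          nonsense_rate = 0.02,
                          low_state_frac = 0.30,
                          sometimes_frac_range = c(0.05, 0.80),
                          moderate_line_frac = 0.25,
                          sl_wgd_or = 2.3,
                          complex_same_rate_ssd = 0.15,
                          complex_wgd_or = 2.3,
                          n_complexes = 30,
                          complex_extra_rate = 0.10,
                          plant_essential_complex = TRUE,
                          plant_nonsense_pair = TRUE,
                          expr_missing_frac = 0.02,
                          cn_missing_frac = 0.01,
                          cn_baseline = 1.0, cn_sd = 0.1, cn_low_delta = 0.5,
                          identity_range = c(20, 100),
                          sl_identity_range = c(60, 100),
                          guides_per_gene = 4,
                          guide_noise_sd = 0.1,
                          gene_length = 1000,
                          intergenic_gap = 500,
                          n_chromosomes = NULL,
                          chromosome_length = NULL,
                          n_duplicate_gene_pairs = 8,
                          duplication_mutation_rate = 0.05,
                          seed = 1L) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot_count(cfg$n_cell_lines, "n_cell_lines", 2L)
  stopifnot_count(cfg$n_genes, "n_genes", 4L)
  stopifnot_count(cfg$n_planted_sl_pairs, "n_planted_sl_pairs", 0L)
  for (f in c("frac_paralog", "frac_wgd_pairs", "frac_never", "frac_sometimes",
              "frac_broadly", "frac_sl_cn_driven", "nonsense_rate",
              "low_state_frac", "moderate_line_frac", "expr_missing_frac",
              "cn_missing_frac"))
    stopifnot_fraction(cfg[[f]], f)
  if (abs(cfg$frac_never + cfg$frac_sometimes + cfg$frac_broadly - 1) > 1e-9)
    stop("category fractions must sum to 1", call. = FALSE)
  if (cfg$frac_sometimes <= 0)
    stop("frac_sometimes must be positive", call. = FALSE)
  if (!(cfg$essential_mean < cfg$moderate_mean &&
        cfg$moderate_mean < cfg$tolerated_mean))
    stop("score component means must satisfy essential < moderate < tolerated",
         call. = FALSE)
  if (any(c(cfg$essential_sd, cfg$moderate_sd, cfg$tolerated_sd) <= 0))
    stop("score component sds must be positive", call. = FALSE)
  # generous upper bound on how many pairs the family structure can host
  n_paralog <- round(cfg$frac_paralog * cfg$n_genes)
  if (cfg$n_planted_sl_pairs > n_paralog %/% 2)
    stop("n_planted_sl_pairs exceeds the number of paralog pairs the cohort can host",
         call. = FALSE)
  invisible(cfg)
}

#' Model-implied pooled score mixture of a synthetic cohort
#'
#' Given a cohort configuration, returns the weights, means and sds of the
#' three-component Gaussian mixture that the generator's gene-by-line scores
#' follow when pooled. Never-essential genes draw every line from the
#' tolerated component and broadly essential genes from the essential
#' component; sometimes-essential genes are per-line mixtures (essential at
#' a per-gene frequency, otherwise moderate or tolerated), and planted SL
#' genes switch between the essential and tolerated components with the
#' partner's expression state. The implied weights are the reference for
#' Monte-Carlo checks of the generator and for the analytic binarization
#' boundary.
#'
#' @param config a [cohort_config()].
#' @return List with `weights`, `means`, `sds` (components sorted by
#'   ascending mean: essential, moderate, tolerated).
#' @export
implied_mixture <- function(config) {
  cfg <- config
  n <- cfg$n_genes
  n_sl <- cfg$n_planted_sl_pairs
  frac_sl <- n_sl / n                       # A1 genes, one per planted pair
  frac_som_free <- max(cfg$frac_sometimes - frac_sl, 0)
  f_bar <- mean(cfg$sometimes_frac_range)   # mean essential-line frequency
  m <- cfg$moderate_line_frac
  w_ess <- cfg$frac_broadly + frac_som_free * f_bar + frac_sl * cfg$low_state_frac
  w_mod <- frac_som_free * (1 - f_bar) * m
  w_tol <- 1 - w_ess - w_mod
  list(weights = c(w_ess, w_mod, w_tol),
       means = c(cfg$essential_mean, cfg$moderate_mean, cfg$tolerated_mean),
       sds = c(cfg$essential_sd, cfg$moderate_sd, cfg$tolerated_sd))
}

#' Analytic essentiality boundary of the generating mixture
#'
#' Equal-weighted-density crossing between the essential and moderate
#' components of the model-implied pooled mixture (see [implied_mixture()]),
#' computed by the same bisection used on fitted mixtures.
#'
#' @param config a [cohort_config()].
#' @return Threshold (scalar).
#' @export
implied_threshold <- function(config) {
  mix <- implied_mixture(config)
  mixture_boundary(mix$weights[1:2], mix$means[1:2], mix$sds[1:2])
}
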