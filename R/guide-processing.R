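#' Exhaustively align protospacers against a genome
#'
#' Scans every offset of every chromosome on both strands for occurrences of
#' each 20-nt protospacer with at most `max_mismatch` mismatches, keeping
#' only hits with a canonical NGG PAM immediately 3' of the protospacer on
#' the hit strand ("N" matches any base). Coordinates are reported on the
#' forward strand, 0-based half-open. Mismatch positions are indexed 1..20
#' from the PAM-distal (5') end of the protospacer, so the "two most
#' PAM-distal nucleotides" are positions 1 and 2.
#'
#' @param guides data.frame with columns `guide_id` and `protospacer`
#'   (20-nt, ACGT only).
#' @param genome a `toy_genome` list (or any list with a named character
#'   vector `sequences`).
#' @param max_mismatch maximum mismatches over the protospacer (default 2).
#' @return data.frame of hits: guide_id, chromosome, strand, start, end,
#'   n_mismatches, mismatch_positions (comma-separated), pam. Counts of
#'   discarded hits (non-NGG PAM; PAM clipped by a contig end) are attached
#'   as attributes `n_noncanonical` and `n_end_clipped`.
#' @export
align_guides <- function(guides, genome, max_mismatch = 2) {
  protos <- toupper(guides$protospacer)
  bad <- grepl("[^ACGT]", protos) | nchar(protos) != 20L | is.na(protos)
  if (any(bad))
    stop("protospacers must be 20-nt ACGT strings; offending guides: ",
         paste(utils::head(guides$guide_id[bad], 5), collapse = ", "),
         call. = FALSE)
  res <- scan_guides_cpp(unname(genome$sequences), protos,
                         as.integer(max_mismatch))
  mmp <- ifelse(res$n_mismatches == 0, "",
                ifelse(is.na(res$mm2), as.character(res$mm1),
                       paste(res$mm1, res$mm2, sep = ",")))
  hits <- data.frame(
    guide_id = guides$guide_id[res$guide],
    chromosome = names(genome$sequences)[res$chrom],
    strand = ifelse(res$strand > 0, "+", "-"),
    start = res$start, end = res$start + 20L,
    n_mismatches = res$n_mismatches,
    mismatch_positions = mmp,
    pam = res$pam,
    stringsAsFactors = FALSE)
  attr(hits, "n_end_clipped") <- res$n_end_clipped
  attr(hits, "n_noncanonical") <- res$n_noncanonical
  hits
}

#' Align a single protospacer
#'
#' Convenience wrapper around [align_guides()] for one guide.
#'
#' @param protospacer 20-nt ACGT string.
#' @param genome genome list as in [align_guides()].
#' @param max_mismatch maximum mismatches (default 2).
#' @return Hit data.frame (see [align_guides()]).
#' @export
align_guide <- function(protospacer, genome, max_mismatch = 2) {
  align_guides(data.frame(guide_id = "guide", protospacer = protospacer,
                          stringsAsFactors = FALSE),
               genome, max_mismatch)
}

parse_mm_positions <- function(s) {
  if (is.na(s) || s == "") return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Classify a guide's hit list as multi-targeting
#'
#' A guide is multi-targeting iff it has (a) two or more perfect hits, or
#' (b) at least one perfect hit plus at least one single-mismatch hit, or
#' (c) at least one perfect hit plus at least one double-mismatch hit whose
#' mismatches both fall in the two most PAM-distal positions (1 and 2).
#' Double-mismatch hits with any mismatch outside positions 1-2 never
#' trigger rule (c). Guides with no hits at all are flagged "unalignable";
#' guides with hits but no perfect hit get reason "no perfect hit".
#'
#' @param hits hit data.frame for one guide (canonical-PAM hits from
#'   [align_guides()]).
#' @return List with `is_multi` (logical) and `reason` (character).
#' @export
classify_multi_targeting <- function(hits) {
  if (NROW(hits) == 0)
    return(list(is_multi = FALSE, reason = "unalignable"))
  n_perfect <- sum(hits$n_mismatches == 0)
  n_one <- sum(hits$n_mismatches == 1)
  distal_double <- vapply(
    hits$mismatch_positions[hits$n_mismatches == 2],
    function(s) all(parse_mm_positions(s) %in% c(1L, 2L)), logical(1))
  if (n_perfect >= 2)
    return(list(is_multi = TRUE, reason = "multiple perfect"))
  if (n_perfect >= 1 && n_one >= 1)
    return(list(is_multi = TRUE, reason = "perfect plus single mismatch"))
  if (n_perfect >= 1 && any(distal_double))
    return(list(is_multi = TRUE, reason = "perfect plus PAM-distal double mismatch"))
  if (n_perfect == 0)
    return(list(is_multi = FALSE, reason = "no perfect hit"))
  list(is_multi = FALSE, reason = "single target")
}

#' Build the guide-to-gene map
#'
#' Applies the multi-targeting filter and locus-to-gene assignment: a guide
#' is retained iff it has exactly one perfect hit, is not multi-targeting,
#' and its perfect hit overlaps exactly one gene interval. Dropped guides
#' carry a reason: "multi-target", "no perfect hit", "unalignable",
#' "multi-gene locus" or "intergenic".
#'
#' @param guides guide table (guide_id, protospacer, intended_gene).
#' @param hits hit table from [align_guides()].
#' @param genes gene intervals (gene, chrom, start, end, strand; 0-based
#'   half-open).
#' @return data.frame (sgRNA, gene, retained, reason); `gene` is the mapped
#'   gene for retained guides, `NA` otherwise.
#' @export
build_guide_gene_map <- function(guides, hits, genes) {
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  # overlap every hit with the gene annotation in one pass
  gr_hits <- GenomicRanges::GRanges(
    hits$chromosome, IRanges::IRanges(hits$start + 1L, hits$end))
  ov <- GenomicRanges::findOverlaps(gr_hits, gr_genes, ignore.strand = TRUE)
  hit_genes <- split(genes$gene[S4Vectors::subjectHits(ov)],
                     factor(S4Vectors::queryHits(ov),
                            levels = seq_len(nrow(hits))))
  hits$n_genes_hit <- lengths(hit_genes)
  hits$gene_hit <- vapply(hit_genes, function(g)
    if (length(g) == 1) g else NA_character_, character(1), USE.NAMES = FALSE)
  hit_split <- split(seq_len(nrow(hits)), hits$guide_id)
  out <- data.frame(sgRNA = guides$guide_id, gene = NA_character_,
                    retained = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(guides))) {
    gid <- guides$guide_id[i]
    h <- hits[hit_split[[gid]], , drop = FALSE]
    cls <- classify_multi_targeting(h)
    if (cls$reason == "unalignable") { out$reason[i] <- "unalignable"; next }
    if (cls$is_multi) { out$reason[i] <- "multi-target"; next }
    if (cls$reason == "no perfect hit") { out$reason[i] <- "no perfect hit"; next }
    p <- h[h$n_mismatches == 0, , drop = FALSE]
    if (p$n_genes_hit[1] == 0) { out$reason[i] <- "intergenic"; next }
    if (p$n_genes_hit[1] > 1) { out$reason[i] <- "multi-gene locus"; next }
    out$gene[i] <- p$gene_hit[1]
    out$retained[i] <- TRUE
    out$reason[i] <- "retained"
  }
  out
}

#' Gate genes on retained guide count
#'
#' Genes targeted by fewer than `min_guides` retained guides are excluded
#' from scoring: one or two guides are considered insufficient for a
#' reliable gene score.
#'
#' @param map guide-gene map from [build_guide_gene_map()] (or a data.frame
#'   with columns gene and retained).
#' @param gene_universe all genes the library was designed against; genes
#'   with zero retained guides are reported from this set.
#' @param min_guides minimum retained guides per gene (default 3).
#' @return List with `retained` and `dropped` data.frames (gene, n_guides,
#'   and for dropped a reason: "too few guides" or "no guides").
#' @export
gate_genes_by_guide_count <- function(map, gene_universe = NULL,
                                      min_guides = 3) {
  counts <- table(map$gene[map$retained])
  gene_universe <- gene_universe %||% sort(unique(stats::na.omit(
    c(map$gene, if ("intended_gene" %in% names(map)) map$intended_gene))))
  n_guides <- setNames(rep(0L, length(gene_universe)), gene_universe)
  n_guides[names(counts)] <- as.integer(counts)
  keep <- n_guides >= min_guides
  list(
    retained = data.frame(gene = gene_universe[keep],
                          n_guides = unname(n_guides[keep]),
                          stringsAsFactors = FALSE),
    dropped = data.frame(gene = gene_universe[!keep],
                         n_guides = unname(n_guides[!keep]),
                         reason = ifelse(n_guides[!keep] == 0,
                                         "no guides", "too few guides"),
                         stringsAsFactors = FALSE))
}

#' Aggregate guide log-fold changes into gene scores
#'
#' Gene score in a cell line is the arithmetic mean of the retained guides'
#' log-fold changes in that line. This is a deliberately simple aggregation
#' scorer: it performs no copy-number artefact correction, and pre-computed
#' corrected gene scores can be supplied to the downstream stages instead.
#' A guide with a missing LFC is omitted from that line's mean; if fewer
#' than `min_guides` informative guides remain in a line, the gene's score
#' in that line is missing.
#'
#' @param lfc sgRNA-by-line numeric matrix.
#' @param map guide-gene map from [build_guide_gene_map()].
#' @param retained_genes genes to score (e.g. from
#'   [gate_genes_by_guide_count()]).
#' @param min_guides minimum informative guides per line (default 3).
#' @return Gene-by-line score matrix.
#' @export
score_genes <- function(lfc, map, retained_genes, min_guides = 3) {
  scores <- matrix(NA_real_, length(retained_genes), ncol(lfc),
                   dimnames = list(retained_genes, colnames(lfc)))
  m <- map[map$retained & map$gene %in% retained_genes, ]
  for (g in retained_genes) {
    rows <- m$sgRNA[m$gene == g]
    sub <- lfc[rows, , drop = FALSE]
    n_inf <- colSums(!is.na(sub))
    v <- colMeans(sub, na.rm = TRUE)
    v[n_inf < min_guides] <- NA_real_
    scores[g, ] <- v
  }
  scores
}

#' Precision-recall QC against reference gene sets
#'
#' Per cell line, genes in the union of the reference essential and
#' nonessential sets are ranked by ascending score (most negative first)
#' and the area under the precision-recall curve is computed as the average
#' precision over the ranked reference-essential genes.
#'
#' @param scores gene-by-line score matrix.
#' @param essential_ref,nonessential_ref disjoint reference gene sets; both
#'   must intersect the scored genes.
#' @return List with `per_line` (named AUC vector) and `mean_auc`.
#' @export
precision_recall_qc <- function(scores, essential_ref, nonessential_ref) {
  if (length(intersect(essential_ref, nonessential_ref)) > 0)
    stop("reference sets must be disjoint", call. = FALSE)
  ess <- intersect(essential_ref, rownames(scores))
  non <- intersect(nonessential_ref, rownames(scores))
  if (length(ess) == 0 || length(non) == 0)
    stop("reference sets do not intersect the scored genes", call. = FALSE)
  labeled <- c(ess, non)
  auc <- vapply(colnames(scores), function(cl) {
    s <- scores[labeled, cl]
    ok <- !is.na(s)
    g <- labeled[ok]
    ord <- order(s[ok], g[ok])      # ascending score; names break ties
    pos <- g[ord] %in% ess
    average_precision(pos)
  }, numeric(1))
  list(per_line = auc, mean_auc = mean(auc, na.rm = TRUE))
}

average_precision <- function(pos) {
  if (!any(pos)) return(NA_real_)
  ranks <- which(pos)
  mean(seq_along(ranks) / ranks)
}
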