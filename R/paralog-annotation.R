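pair_key <- function(g1, g2) paste(pmin(g1, g2), pmax(g1, g2), sep = "|")

#' Filter a raw paralog-pair table
#'
#' Keeps directional pairs whose bidirectional protein sequence identities
#' are both at or above `min_identity` percent and whose genes are both in
#' the protein-coding set. Pairs with a missing identity are dropped and
#' counted.
#'
#' @param pairs data.frame with columns A1, A2, identity_A1_in_A2,
#'   identity_A2_in_A1 (percent of the first/second gene's protein sequence
#'   matched in the other).
#' @param coding_genes character vector of protein-coding gene symbols.
#' @param min_identity inclusive identity floor in percent (default 20).
#' @return Filtered pair table; per-rule removal counts in
#'   `attr(, "removed")`.
#' @export
filter_paralog_pairs <- function(pairs, coding_genes, min_identity = 20) {
  n0 <- nrow(pairs)
  miss <- is.na(pairs$identity_A1_in_A2) | is.na(pairs$identity_A2_in_A1)
  p <- pairs[!miss, , drop = FALSE]
  low <- p$identity_A1_in_A2 < min_identity | p$identity_A2_in_A1 < min_identity
  p <- p[!low, , drop = FALSE]
  noncoding <- !(p$A1 %in% coding_genes) | !(p$A2 %in% coding_genes)
  p <- p[!noncoding, , drop = FALSE]
  rownames(p) <- NULL
  attr(p, "removed") <- c(missing_identity = sum(miss),
                          below_min_identity = sum(low),
                          non_coding = sum(noncoding),
                          kept = nrow(p), input = n0)
  p
}

#' Per-gene paralogy summary
#'
#' For every gene in the universe: the number of distinct paralog partners,
#' the closest paralog (the partner in which the largest percent of the
#' gene's own protein sequence is matched, i.e. maximal identity_A1_in_A2
#' with the gene as A1; ties broken by lexicographically smallest partner
#' symbol) and that maximal identity. Genes absent from the pair table are
#' singletons. Paralog counts are also binned as 0, 1, 2, 3, 4+.
#'
#' @param pairs filtered directional pair table.
#' @param gene_universe all genes to summarize (singletons included).
#' @return data.frame: gene, n_paralogs, closest_paralog, max_identity,
#'   is_singleton, n_paralogs_bin.
#' @export
summarize_paralogy <- function(pairs, gene_universe) {
  out <- data.frame(gene = gene_universe, n_paralogs = 0L,
                    closest_paralog = NA_character_,
                    max_identity = NA_real_, is_singleton = TRUE,
                    stringsAsFactors = FALSE)
  if (nrow(pairs) > 0) {
    sp <- split(pairs[, c("A2", "identity_A1_in_A2")], pairs$A1)
    idx <- match(names(sp), gene_universe)
    for (j in seq_along(sp)) {
      i <- idx[j]
      if (is.na(i)) next
      d <- sp[[j]]
      d <- d[!duplicated(d$A2), , drop = FALSE]
      best <- which(d$identity_A1_in_A2 == max(d$identity_A1_in_A2))
      best <- best[order(d$A2[best])][1]
      out$n_paralogs[i] <- nrow(d)
      out$closest_paralog[i] <- d$A2[best]
      out$max_identity[i] <- d$identity_A1_in_A2[best]
      out$is_singleton[i] <- FALSE
    }
  }
  out$n_paralogs_bin <- ifelse(out$n_paralogs >= 4, "4+",
                               as.character(out$n_paralogs))
  out
}

#' Classify duplication mode of paralog pairs and genes
#'
#' A pair is a whole-genome duplicate (WGD) iff the unordered pair appears
#' on either of the two supplied WGD lists; all other pairs are small-scale
#' duplicates (SSD). A gene is marked WGD if it is part of at least one WGD
#' pair, regardless of any SSD pairs it is also part of.
#'
#' @param pairs directional pair table.
#' @param wgd_list_a,wgd_list_b data.frames of unordered gene-symbol pairs
#'   (columns gene1, gene2).
#' @return List with `pairs` (input plus `duplication_mode`) and `genes`
#'   (data.frame: gene, duplication_mode in WGD/SSD).
#' @export
classify_duplication <- function(pairs, wgd_list_a, wgd_list_b) {
  wgd_keys <- unique(c(
    if (NROW(wgd_list_a)) pair_key(wgd_list_a[[1]], wgd_list_a[[2]]),
    if (NROW(wgd_list_b)) pair_key(wgd_list_b[[1]], wgd_list_b[[2]])))
  pairs$duplication_mode <- ifelse(pair_key(pairs$A1, pairs$A2) %in% wgd_keys,
                                   "WGD", "SSD")
  genes <- sort(unique(c(pairs$A1, pairs$A2)))
  wgd_genes <- unique(c(pairs$A1[pairs$duplication_mode == "WGD"],
                        pairs$A2[pairs$duplication_mode == "WGD"]))
  list(pairs = pairs,
       genes = data.frame(gene = genes,
                          duplication_mode = ifelse(genes %in% wgd_genes,
                                                    "WGD", "SSD"),
                          stringsAsFactors = FALSE))
}

#' Annotate paralog pairs with protein complex membership
#'
#' @param pairs directional pair table.
#' @param complexes data.frame (complex_id, gene).
#' @return Pair table with logical columns `either_in_complex` (A1 or A2 is
#'   a member of any complex) and `same_complex` (some single complex
#'   contains both).
#' @export
annotate_complexes <- function(pairs, complexes) {
  members <- unique(complexes$gene)
  by_gene <- split(complexes$complex_id, complexes$gene)
  pairs$either_in_complex <- pairs$A1 %in% members | pairs$A2 %in% members
  pairs$same_complex <- mapply(function(a, b) {
    ca <- by_gene[[a]]; cb <- by_gene[[b]]
    !is.null(ca) && !is.null(cb) && length(intersect(ca, cb)) > 0
  }, pairs$A1, pairs$A2, USE.NAMES = FALSE)
  pairs
}
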