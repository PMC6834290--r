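BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Generate a toy genome with planted gene duplications
#'
#' Builds random-base chromosomes carrying non-overlapping gene intervals on
#' both strands. For a configured number of gene pairs, the second gene's
#' sequence is overwritten with a copy of the first gene's sequence, mutated
#' at a configured per-base rate; exact copies (rate 0) guarantee genuine
#' multi-mapping sgRNA sites. All coordinates are 0-based half-open on the
#' forward strand.
#'
#' @param config a [cohort_config()]; genome sizing fields are used
#'   (`n_genes`, `gene_length`, `intergenic_gap`, `n_chromosomes`,
#'   `chromosome_length`, `n_duplicate_gene_pairs`,
#'   `duplication_mutation_rate`).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return List of class `toy_genome` with `sequences` (named character
#'   vector of chromosomes), `genes` (data.frame: gene, chrom, start, end,
#'   strand) and `duplications` (data.frame: source_gene, target_gene,
#'   n_mutated, identity_pct).
#' @export
generate_toy_genome <- function(config, seed = config$seed) {
  cfg <- config
  n_genes <- cfg$n_genes
  glen <- cfg$gene_length
  n_chrom <- cfg$n_chromosomes %||% max(2L, ceiling(n_genes / 150))
  per_chrom <- ceiling(n_genes / n_chrom)
  # sized so even maximal random gaps leave room for every gene
  clen <- cfg$chromosome_length %||%
    max(20000L, per_chrom * (glen + ceiling(1.6 * cfg$intergenic_gap)) + 2000L)
  if (n_chrom < 2 || clen < 20000)
    stop("toy genome needs at least 2 chromosomes of at least 20 kb", call. = FALSE)
  if (per_chrom * (glen + 50) + 100 > clen)
    stop("requested gene count cannot be placed without overlap; ",
         "increase chromosome_length or n_chromosomes", call. = FALSE)

  with_local_seed(seed, {
    seqs <- vapply(seq_len(n_chrom), function(i)
      paste(sample(BASES, clen, replace = TRUE), collapse = ""), character(1))
    names(seqs) <- sprintf("chr%d", seq_len(n_chrom))

    # lay genes left-to-right with random gaps, round-robin over chromosomes
    chrom_of <- rep(seq_len(n_chrom), length.out = n_genes)
    chrom_of <- sort(chrom_of)
    genes <- vector("list", n_chrom)
    gap_lo <- max(20L, round(cfg$intergenic_gap * 0.4))
    gap_hi <- max(gap_lo + 1L, round(cfg$intergenic_gap * 1.6))
    idx <- 0L
    for (ci in seq_len(n_chrom)) {
      k <- sum(chrom_of == ci)
      if (k == 0) next
      gaps <- sample(gap_lo:gap_hi, k, replace = TRUE)
      starts <- 100L + cumsum(gaps) + (seq_len(k) - 1L) * glen
      ends <- starts + glen
      if (ends[k] + 100 > clen)
        stop("requested gene count cannot be placed without overlap on ",
             names(seqs)[ci], call. = FALSE)
      genes[[ci]] <- data.frame(
        gene = sprintf("G%04d", idx + seq_len(k)),
        chrom = names(seqs)[ci],
        start = starts, end = ends,
        strand = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE)
      idx <- idx + k
    }
    genes <- do.call(rbind, genes)
    rownames(genes) <- NULL

    # plant duplications: copy source gene sequence over the target interval
    n_dup <- min(cfg$n_duplicate_gene_pairs, n_genes %/% 2)
    dup <- data.frame(source_gene = character(0), target_gene = character(0),
                      n_mutated = integer(0), identity_pct = numeric(0),
                      stringsAsFactors = FALSE)
    if (n_dup > 0) {
      picked <- sample(genes$gene, 2L * n_dup)
      src <- picked[seq_len(n_dup)]
      dst <- picked[n_dup + seq_len(n_dup)]
      n_mut <- integer(n_dup)
      for (i in seq_len(n_dup)) {
        gs <- genes[genes$gene == src[i], ]
        gd <- genes[genes$gene == dst[i], ]
        s <- substr(seqs[[gs$chrom]], gs$start + 1L, gs$end)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        mut <- which(runif(glen) < cfg$duplication_mutation_rate)
        for (j in mut) ch[j] <- sample(setdiff(BASES, ch[j]), 1L)
        n_mut[i] <- length(mut)
        seqs[[gd$chrom]] <- paste0(
          substr(seqs[[gd$chrom]], 1L, gd$start),
          paste(ch, collapse = ""),
          substr(seqs[[gd$chrom]], gd$end + 1L, nchar(seqs[[gd$chrom]])))
      }
      dup <- data.frame(source_gene = src, target_gene = dst,
                        n_mutated = n_mut,
                        identity_pct = 100 * (glen - n_mut) / glen,
                        stringsAsFactors = FALSE)
    }
    structure(list(sequences = seqs, genes = genes, duplications = dup),
              class = "toy_genome")
  })
}

#' Write a toy genome to FASTA and BED
#'
#' @param genome a [generate_toy_genome()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (`fasta`, `bed`).
#' @export
write_toy_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  bed <- file.path(dir, "genes.bed")
  dna <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dna, fasta, width = 80L)
  g <- genome$genes
  bed_df <- data.frame(g$chrom, g$start, g$end, g$gene, 0L, g$strand)
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fasta, bed = bed))
}

#' Read a genome FASTA and gene BED back into a `toy_genome`-shaped list
#'
#' @param fasta FASTA path.
#' @param bed BED path (0-based half-open, 6 columns).
#' @return List with `sequences` and `genes` as in [generate_toy_genome()].
#' @export
read_toy_genome <- function(fasta, bed) {
  dna <- Biostrings::readDNAStringSet(fasta)
  seqs <- setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
  b <- utils::read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  genes <- data.frame(gene = b[[4]], chrom = b[[1]], start = b[[2]],
                      end = b[[3]], strand = b[[6]], stringsAsFactors = FALSE)
  structure(list(sequences = seqs, genes = genes,
                 duplications = NULL), class = "toy_genome")
}

#' Design an sgRNA library against a toy genome
#'
#' For each annotated gene, emits up to `guides_per_gene` 20-nt protospacers
#' whose genomic occurrence lies immediately 5' of an NGG PAM on the gene's
#' annotated strand, with both protospacer and PAM inside the gene interval.
#' Genes with too few PAM sites yield fewer guides and a recorded warning.
#'
#' @param genome a [generate_toy_genome()] result.
#' @param guides_per_gene guides to design per gene (default 4).
#' @param seed RNG seed for site selection.
#' @return data.frame (guide_id, protospacer, intended_gene); genes with a
#'   guide shortfall are listed in `attr(, "short_genes")`.
#' @export
generate_guide_library <- function(genome, guides_per_gene = 4, seed = 1L) {
  genes <- genome$genes
  with_local_seed(seed, {
    rows <- vector("list", nrow(genes))
    short <- character(0)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      s <- substr(genome$sequences[[g$chrom]], g$start + 1L, g$end)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      L <- length(ch)
      if (g$strand == "+") {
        # protospacer [p, p+20), PAM [p+20, p+23) needs GG at p+21, p+22 (1-based)
        cand <- which(ch == "G")
        cand <- cand[cand >= 22 & cand + 1 <= L]
        cand <- cand[ch[cand + 1] == "G"] - 21L   # protospacer start, 1-based in gene
        protos <- if (length(cand)) substring(s, cand, cand + 19L)
          else character(0)
      } else {
        # reverse-strand PAM: forward CC at positions q, q+1 with protospacer
        # at forward [q+3, q+23); protospacer sequence is the revcomp
        cand <- which(ch == "C")
        cand <- cand[cand + 22 <= L]
        cand <- cand[ch[cand + 1] == "C"]
        windows <- if (length(cand)) substring(s, cand + 3L, cand + 22L)
          else character(0)
        protos <- vapply(windows, revcomp_chr, character(1), USE.NAMES = FALSE)
      }
      keep <- which(!grepl("[^ACGT]", protos))
      if (length(keep) == 0) {
        short <- c(short, g$gene)
        warning("gene ", g$gene, " has no usable NGG PAM site; 0 guides emitted",
                call. = FALSE)
        next
      }
      take <- keep[sample.int(length(keep), min(guides_per_gene, length(keep)))]
      if (length(take) < guides_per_gene) {
        short <- c(short, g$gene)
        warning("gene ", g$gene, " has only ", length(take),
                " usable PAM sites (requested ", guides_per_gene, ")",
                call. = FALSE)
      }
      rows[[i]] <- data.frame(
        guide_id = sprintf("sg_%s_%02d", g$gene, seq_along(take)),
        protospacer = protos[take],
        intended_gene = g$gene,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(guide_id = character(0), protospacer = character(0),
                        intended_gene = character(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "short_genes") <- short
    out
  })
}
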