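# Independent pure-R oracles, deliberately written differently from the
# package implementations (vectorized sliding windows, literal enumeration).

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# all canonical-PAM hits of one protospacer, every offset, both strands
oracle_align <- function(proto, sequences, max_mm = 2) {
  p_fw <- strsplit(proto, "", fixed = TRUE)[[1]]
  p_rc <- strsplit(oracle_revcomp(proto), "", fixed = TRUE)[[1]]
  hits <- list()
  for (chrom in names(sequences)) {
    ch <- strsplit(sequences[[chrom]], "", fixed = TRUE)[[1]]
    L <- length(ch)
    n_win <- L - 20L + 1L
    if (n_win < 1) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") p_fw else p_rc
      mm <- integer(n_win)
      for (j in 1:20) mm <- mm + (ch[j:(L - 20 + j)] != pat[j])
      for (s1 in which(mm <= max_mm)) {          # 1-based window start
        if (strand == "+") {
          if (s1 + 22 > L) next
          if (ch[s1 + 21] != "G" || ch[s1 + 22] != "G") next
          pam <- paste(ch[(s1 + 20):(s1 + 22)], collapse = "")
        } else {
          if (s1 - 3 < 1) next
          if (ch[s1 - 3] != "C" || ch[s1 - 2] != "C") next
          pam <- oracle_revcomp(paste(ch[(s1 - 3):(s1 - 1)], collapse = ""))
        }
        win <- ch[s1:(s1 + 19)]
        mm_idx <- which(win != pat)
        mm_pos <- if (strand == "+") mm_idx else sort(21L - mm_idx)
        hits[[length(hits) + 1L]] <- data.frame(
          chromosome = chrom, strand = strand, start = s1 - 1L,
          end = s1 + 19L, n_mismatches = length(mm_pos),
          mismatch_positions = paste(mm_pos, collapse = ","),
          pam = pam, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(chromosome = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      n_mismatches = integer(0),
                      mismatch_positions = character(0),
                      pam = character(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# literal application of the three multi-targeting rules
oracle_is_multi <- function(hits) {
  perfect <- hits$n_mismatches == 0
  one <- hits$n_mismatches == 1
  two_distal <- hits$n_mismatches == 2 &
    vapply(strsplit(hits$mismatch_positions, ","), function(v)
      all(as.integer(v) %in% c(1L, 2L)), logical(1))
  sum(perfect) >= 2 ||
    (sum(perfect) >= 1 && sum(one) >= 1) ||
    (sum(perfect) >= 1 && sum(two_distal) >= 1)
}

# brute-force BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    cands <- vapply(i:n, function(j) p[o[j]] * n / j, numeric(1))
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# exhaustive two-sided Fisher p by hypergeometric enumeration (fixed margins)
oracle_fisher_two_sided <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(a_range, function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1), numeric(1))
  p_obs <- probs[a_range == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive one-sided hypergeometric upper tail
oracle_hyper_upper <- function(k, K, N, n_draw) {
  a_range <- k:min(K, n_draw)
  sum(vapply(a_range, function(a)
    choose(K, a) * choose(N - K, n_draw - a) / choose(N, n_draw), numeric(1)))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  combs <- utils::combn(n1 + n2, n1)
  u_stat <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_stat(seq_len(n1))
  u_all <- apply(combs, 2, function(idx) {
    r <- rank(pool)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * n2 / 2
  min(1, sum(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9) / ncol(combs))
}

# average precision of a ranked 0/1 vector, literal definition
oracle_ap <- function(pos) {
  ranks <- which(pos)
  mean(cumsum(pos)[ranks] / ranks)
}

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

# small, fast cohort configurations for tests (defaults overridable)
cfg_with_defaults <- function(defaults, overrides) {
  defaults[names(overrides)] <- overrides
  do.call(cohort_config, defaults)
}

quick_cfg <- function(...) {
  cfg_with_defaults(list(n_genes = 150, n_cell_lines = 30,
                         n_planted_sl_pairs = 10,
                         n_duplicate_gene_pairs = 0), list(...))
}

tiny_genome_cfg <- function(...) {
  cfg_with_defaults(list(n_genes = 16, n_cell_lines = 10,
                         n_planted_sl_pairs = 0, n_chromosomes = 2,
                         chromosome_length = 22000,
                         n_duplicate_gene_pairs = 2,
                         duplication_mutation_rate = 0), list(...))
}

# score a cohort quickly: per-gene mean of its guides' LFCs
quick_scores <- function(cohort) {
  g <- cohort$guides$intended_gene
  m <- rowsum(cohort$lfc, g) / as.vector(table(g)[sort(unique(g))])
  m[cohort$genes, , drop = FALSE]
}
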