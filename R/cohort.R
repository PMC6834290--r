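exact_counts <- function(n, fracs) {
  # largest-remainder allocation so category counts are exact, not Bernoulli
  raw <- n * fracs
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1L
  }
  as.integer(counts)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# integer split of n_planted over WGD/SSD candidate pools hitting a target OR
solve_planting_split <- function(n_planted, n_w, n_s, target_or) {
  if (n_planted == 0) return(c(w = 0L, s = 0L))
  if (n_s == 0) return(c(w = n_planted, s = 0L))
  if (n_w == 0) return(c(w = 0L, s = n_planted))
  best <- NULL; best_d <- Inf
  for (m_w in max(0, n_planted - n_s):min(n_w, n_planted)) {
    m_s <- n_planted - m_w
    if (m_w %in% c(0, n_w) || m_s %in% c(0, n_s)) next
    or <- (m_w / (n_w - m_w)) / (m_s / (n_s - m_s))
    d <- abs(log(or) - log(target_or))
    if (d < best_d) { best_d <- d; best <- c(w = m_w, s = m_s) }
  }
  if (is.null(best)) {
    m_w <- min(n_w, max(n_planted - n_s, round(n_planted * n_w / (n_w + n_s))))
    best <- c(w = m_w, s = n_planted - m_w)
  }
  best
}

#' Generate a synthetic screen cohort with planted ground truth
#'
#' Produces an internally consistent bundle of tables mirroring a CRISPR
#' dependency screen release: guide-level log-fold changes, expression,
#' copy-number and mutation tables, a bidirectional paralog-pair table with
#' WGD labels and protein-complex membership, plus the ground truth that was
#' planted (per-gene essentiality category, synthetic-lethal pairs and their
#' copy-number / nonsense drivers, multi-targeting genes).
#'
#' Scores follow a three-component Gaussian mixture: never-essential genes
#' draw every cell line from the tolerated component and broadly essential
#' genes from the essential component; sometimes-essential genes draw the
#' essential component at a per-gene frequency and otherwise the moderate or
#' tolerated component; planted SL genes (A1) draw the essential component
#' exactly in the cell lines where their partner (A2) is in its
#' low-expression state and the tolerated component elsewhere. The pooled
#' score distribution therefore matches [implied_mixture()].
#'
#' @param config a [cohort_config()].
#' @param genome optional [generate_toy_genome()] result; when supplied, the
#'   cohort gene universe is the genome's gene set and duplicated gene pairs
#'   become high-identity paralog pairs.
#' @param guides optional [generate_guide_library()] table; when absent an
#'   abstract guide table (`guides_per_gene` per gene, no protospacers) is
#'   synthesized.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return List of class `cohort`; see Details for components.
#' @export
generate_cohort <- function(config, genome = NULL, guides = NULL,
                            seed = config$seed) {
  cfg <- config
  validate_cohort_config(cfg)
  genes <- if (!is.null(genome)) genome$genes$gene else
    sprintf("G%04d", seq_len(cfg$n_genes))
  n <- length(genes)
  lines <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
  L <- length(lines)

  with_local_seed(seed, {
    ## --- paralog families -------------------------------------------------
    dup <- if (!is.null(genome) && NROW(genome$duplications) > 0)
      genome$duplications else NULL
    forced <- if (!is.null(dup)) unique(c(dup$source_gene, dup$target_gene))
      else character(0)
    n_par_target <- round(cfg$frac_paralog * n)
    pool <- setdiff(genes, forced)
    n_free <- max(n_par_target - length(forced), 0)
    free_genes <- pool[sample.int(length(pool), min(n_free, length(pool)))]
    sizes <- integer(0)
    remaining <- length(free_genes)
    szs <- as.integer(names(cfg$family_size_weights))
    while (remaining >= 2) {
      s <- sample(szs, 1L, prob = cfg$family_size_weights)
      s <- min(s, remaining)
      if (s < 2) break
      sizes <- c(sizes, s)
      remaining <- remaining - s
    }
    fam_assign <- split(free_genes[seq_len(sum(sizes))],
                        rep(seq_along(sizes), sizes))
    if (!is.null(dup))
      fam_assign <- c(fam_assign,
                      lapply(seq_len(nrow(dup)), function(i)
                        c(dup$source_gene[i], dup$target_gene[i])))

    pair_list <- lapply(fam_assign, function(fam) {
      if (length(fam) < 2) return(NULL)
      cmb <- utils::combn(sort(fam), 2)
      data.frame(g1 = cmb[1, ], g2 = cmb[2, ], stringsAsFactors = FALSE)
    })
    upairs <- do.call(rbind, pair_list)
    rownames(upairs) <- NULL
    upairs$is_dup <- FALSE
    if (!is.null(dup)) {
      key <- paste(pmin(dup$source_gene, dup$target_gene),
                   pmax(dup$source_gene, dup$target_gene))
      upairs$is_dup <- paste(upairs$g1, upairs$g2) %in% key
      upairs$dup_identity <- dup$identity_pct[
        match(paste(upairs$g1, upairs$g2), key)]
    }
    upairs$wgd <- runif(nrow(upairs)) < cfg$frac_wgd_pairs
    paralog_genes <- unique(c(upairs$g1, upairs$g2))

    ## --- essentiality categories ------------------------------------------
    counts <- exact_counts(n, c(cfg$frac_never, cfg$frac_sometimes,
                                cfg$frac_broadly))
    category <- setNames(sample(rep(c("never", "sometimes", "broadly"),
                                    counts)), genes)

    ## --- planted SL pairs --------------------------------------------------
    n_sl <- cfg$n_planted_sl_pairs
    cand <- which(!upairs$is_dup &
                    (category[upairs$g1] == "sometimes" |
                       category[upairs$g2] == "sometimes"))
    split_ws <- solve_planting_split(n_sl, sum(upairs$wgd[cand]),
                                     sum(!upairs$wgd[cand]), cfg$sl_wgd_or)
    pick_disjoint <- function(idx, m, used) {
      chosen <- integer(0)
      for (i in idx[sample.int(length(idx))]) {
        if (length(chosen) == m) break
        gs <- c(upairs$g1[i], upairs$g2[i])
        if (!any(gs %in% used)) { chosen <- c(chosen, i); used <- c(used, gs) }
      }
      list(chosen = chosen, used = used)
    }
    used <- character(0)
    pw <- pick_disjoint(cand[upairs$wgd[cand]], split_ws["w"], used)
    ps <- pick_disjoint(cand[!upairs$wgd[cand]], split_ws["s"], pw$used)
    planted_idx <- c(pw$chosen, ps$chosen)
    if (length(planted_idx) < n_sl)
      stop("could not plant ", n_sl, " vertex-disjoint SL pairs; ",
           "category fractions are inconsistent with n_genes", call. = FALSE)
    planted <- upairs[planted_idx, c("g1", "g2", "wgd")]
    a1_is_g1 <- ifelse(
      category[planted$g1] == "sometimes" & category[planted$g2] == "sometimes",
      runif(nrow(planted)) < 0.5,
      category[planted$g1] == "sometimes")
    planted$A1 <- ifelse(a1_is_g1, planted$g1, planted$g2)
    planted$A2 <- ifelse(a1_is_g1, planted$g2, planted$g1)

    ## --- pair identities ----------------------------------------------------
    npair <- nrow(upairs)
    planted_key <- paste(pmin(planted$A1, planted$A2),
                         pmax(planted$A1, planted$A2))
    is_planted <- paste(upairs$g1, upairs$g2) %in% planted_key
    id12 <- runif(npair, cfg$identity_range[1], cfg$identity_range[2])
    id12[is_planted] <- runif(sum(is_planted), cfg$sl_identity_range[1],
                              cfg$sl_identity_range[2])
    id21 <- clamp(id12 + rnorm(npair, 0, 3),
                  cfg$identity_range[1], cfg$identity_range[2])
    if (!is.null(dup)) {
      id12[upairs$is_dup] <- upairs$dup_identity[upairs$is_dup]
      id21[upairs$is_dup] <- upairs$dup_identity[upairs$is_dup]
    }
    upairs$identity_12 <- round(id12, 2)
    upairs$identity_21 <- round(id21, 2)

    ## --- expression ---------------------------------------------------------
    expr <- matrix(rnorm(n * L,
                         mean = rep(runif(n, 2, cfg$expr_high_mean + 1), L),
                         sd = cfg$expr_sd),
                   nrow = n, dimnames = list(genes, lines))
    n_low <- max(2L, round(cfg$low_state_frac * L))
    low_lines <- lapply(seq_len(nrow(planted)), function(i)
      sort(sample(lines, n_low)))
    names(low_lines) <- planted$A1
    for (i in seq_len(nrow(planted))) {
      a2 <- planted$A2[i]
      lo <- lines %in% low_lines[[i]]
      expr[a2, lo] <- rnorm(sum(lo), cfg$expr_low_mean, cfg$expr_sd)
      expr[a2, !lo] <- rnorm(sum(!lo), cfg$expr_high_mean, cfg$expr_sd)
    }

    ## --- true gene scores ---------------------------------------------------
    draw <- function(k, mean, sd) rnorm(k, mean, sd)
    scores <- matrix(NA_real_, n, L, dimnames = list(genes, lines))
    f_g <- setNames(rep(NA_real_, n), genes)
    comp_counts <- c(essential = 0L, moderate = 0L, tolerated = 0L)
    for (g in genes) {
      cat_g <- category[[g]]
      if (g %in% planted$A1) {
        lo <- lines %in% low_lines[[g]]
        scores[g, lo] <- draw(sum(lo), cfg$essential_mean, cfg$essential_sd)
        scores[g, !lo] <- draw(sum(!lo), cfg$tolerated_mean, cfg$tolerated_sd)
        comp_counts <- comp_counts + c(sum(lo), 0L, sum(!lo))
      } else if (cat_g == "never") {
        scores[g, ] <- draw(L, cfg$tolerated_mean, cfg$tolerated_sd)
        comp_counts[3] <- comp_counts[3] + L
      } else if (cat_g == "broadly") {
        scores[g, ] <- draw(L, cfg$essential_mean, cfg$essential_sd)
        comp_counts[1] <- comp_counts[1] + L
      } else {
        f <- runif(1, cfg$sometimes_frac_range[1], cfg$sometimes_frac_range[2])
        f_g[[g]] <- f
        ess <- runif(L) < f
        mod <- !ess & runif(L) < cfg$moderate_line_frac
        tol <- !ess & !mod
        scores[g, ess] <- draw(sum(ess), cfg$essential_mean, cfg$essential_sd)
        scores[g, mod] <- draw(sum(mod), cfg$moderate_mean, cfg$moderate_sd)
        scores[g, tol] <- draw(sum(tol), cfg$tolerated_mean, cfg$tolerated_sd)
        comp_counts <- comp_counts + c(sum(ess), sum(mod), sum(tol))
      }
    }

    ## --- guide library and LFCs ---------------------------------------------
    if (is.null(guides)) {
      guides <- data.frame(
        guide_id = sprintf("sg_%s_%02d", rep(genes, each = cfg$guides_per_gene),
                           rep(seq_len(cfg$guides_per_gene), n)),
        protospacer = NA_character_,
        intended_gene = rep(genes, each = cfg$guides_per_gene),
        stringsAsFactors = FALSE)
    }
    lfc <- scores[guides$intended_gene, , drop = FALSE] +
      matrix(rnorm(nrow(guides) * L, 0, cfg$guide_noise_sd), nrow(guides), L)
    rownames(lfc) <- guides$guide_id

    ## --- copy number ---------------------------------------------------------
    cn <- matrix(rnorm(n * L, cfg$cn_baseline, cfg$cn_sd),
                 nrow = n, dimnames = list(genes, lines))
    n_cn_driven <- round(cfg$frac_sl_cn_driven * nrow(planted))
    cn_driven_idx <- if (nrow(planted)) sort(sample(nrow(planted), n_cn_driven))
      else integer(0)
    planted$cn_driven <- seq_len(max(nrow(planted), 0)) %in% cn_driven_idx
    for (i in cn_driven_idx) {
      lo <- lines %in% low_lines[[i]]
      cn[planted$A2[i], lo] <- cn[planted$A2[i], lo] - cfg$cn_low_delta
    }

    ## --- mutations ------------------------------------------------------------
    mut <- matrix(runif(n * L) < cfg$nonsense_rate,
                  nrow = n, dimnames = list(genes, lines))
    planted$nonsense_planted <- rep(FALSE, nrow(planted))
    if (cfg$plant_nonsense_pair && nrow(planted) > 0) {
      i <- 1L
      planted$nonsense_planted[i] <- TRUE
      mut[planted$A2[i], ] <- lines %in% low_lines[[i]]
    }
    idx <- which(mut, arr.ind = TRUE)
    mutations <- data.frame(
      gene = genes[idx[, 1]], cell_line = lines[idx[, 2]],
      Variant_Classification = "Nonsense_Mutation", stringsAsFactors = FALSE)
    n_mis <- round(3 * nrow(mutations))
    if (n_mis > 0) {
      mutations <- rbind(mutations, data.frame(
        gene = sample(genes, n_mis, replace = TRUE),
        cell_line = sample(lines, n_mis, replace = TRUE),
        Variant_Classification = "Missense_Mutation", stringsAsFactors = FALSE))
    }
    mutations <- mutations[order(mutations$gene, mutations$cell_line), ]
    rownames(mutations) <- NULL

    ## --- complexes --------------------------------------------------------------
    cpx_ids <- sprintf("CPX%03d", seq_len(cfg$n_complexes))
    membership <- list()
    start_cpx <- 1L
    if (cfg$plant_essential_complex) {
      broad <- names(category)[category == "broadly"]
      if (length(broad) >= 4) {
        membership[[length(membership) + 1L]] <- data.frame(
          complex_id = cpx_ids[1], gene = sample(broad, min(8, length(broad))),
          stringsAsFactors = FALSE)
        start_cpx <- 2L
      }
    }
    odds_ssd <- cfg$complex_same_rate_ssd / (1 - cfg$complex_same_rate_ssd)
    p_wgd <- odds_ssd * cfg$complex_wgd_or / (1 + odds_ssd * cfg$complex_wgd_or)
    p_pair <- ifelse(upairs$wgd, p_wgd, cfg$complex_same_rate_ssd)
    joint <- which(runif(npair) < p_pair)
    for (i in joint) {
      cid <- sample(cpx_ids[start_cpx:cfg$n_complexes], 1L)
      membership[[length(membership) + 1L]] <- data.frame(
        complex_id = cid, gene = c(upairs$g1[i], upairs$g2[i]),
        stringsAsFactors = FALSE)
    }
    extra <- which(runif(n) < cfg$complex_extra_rate)
    if (length(extra)) {
      membership[[length(membership) + 1L]] <- data.frame(
        complex_id = sample(cpx_ids[start_cpx:cfg$n_complexes], length(extra),
                            replace = TRUE),
        gene = genes[extra], stringsAsFactors = FALSE)
    }
    complexes <- if (length(membership)) unique(do.call(rbind, membership))
      else data.frame(complex_id = character(0), gene = character(0),
                      stringsAsFactors = FALSE)
    complexes <- complexes[order(complexes$complex_id, complexes$gene), ]
    rownames(complexes) <- NULL

    ## --- WGD lists (two overlapping sources, union = truth) ---------------------
    wgd_pairs <- upairs[upairs$wgd, c("g1", "g2")]
    in_a <- runif(nrow(wgd_pairs)) < 0.7
    in_b <- runif(nrow(wgd_pairs)) < 0.5
    in_a[!in_a & !in_b] <- TRUE
    wgd_list_a <- wgd_pairs[in_a, , drop = FALSE]
    wgd_list_b <- wgd_pairs[in_b, , drop = FALSE]
    names(wgd_list_a) <- names(wgd_list_b) <- c("gene1", "gene2")
    rownames(wgd_list_a) <- rownames(wgd_list_b) <- NULL

    ## --- directional pair table ---------------------------------------------------
    pairs <- rbind(
      data.frame(A1 = upairs$g1, A2 = upairs$g2,
                 identity_A1_in_A2 = upairs$identity_12,
                 identity_A2_in_A1 = upairs$identity_21,
                 wgd_flag = upairs$wgd, stringsAsFactors = FALSE),
      data.frame(A1 = upairs$g2, A2 = upairs$g1,
                 identity_A1_in_A2 = upairs$identity_21,
                 identity_A2_in_A1 = upairs$identity_12,
                 wgd_flag = upairs$wgd, stringsAsFactors = FALSE))
    pairs <- pairs[order(pairs$A1, pairs$A2), ]
    rownames(pairs) <- NULL

    ## --- missingness ---------------------------------------------------------------
    protected <- unique(c(planted$A1, planted$A2))
    droppable <- setdiff(genes, protected)
    expr_drop <- sample(droppable, round(cfg$expr_missing_frac * n))
    cn_drop <- sample(droppable, round(cfg$cn_missing_frac * n))
    expression <- expr[!genes %in% expr_drop, , drop = FALSE]
    copy_number <- cn[!genes %in% cn_drop, , drop = FALSE]

    ground_truth <- list(
      category = category,
      planted_sl = planted[, c("A1", "A2", "wgd", "cn_driven",
                               "nonsense_planted")],
      low_lines = low_lines,
      sometimes_frac = f_g[!is.na(f_g)],
      multi_target_genes = forced,
      paralog_genes = paralog_genes,
      component_counts = comp_counts,
      mixture = implied_mixture(cfg),
      threshold = implied_threshold(cfg))

    structure(list(
      genes = genes, cell_lines = lines,
      true_scores = scores, lfc = lfc, guides = guides,
      expression = expression, copy_number = copy_number,
      mutations = mutations, pairs = pairs,
      wgd_list_a = wgd_list_a, wgd_list_b = wgd_list_b,
      complexes = complexes, ground_truth = ground_truth,
      config = cfg), class = "cohort")
  })
}

#' Write a cohort bundle to disk
#'
#' Emits CSV tables mirroring the column roles of a DepMap-style release
#' (log-fold changes, guide library, expression, copy number, long-format
#' mutation calls, paralog pairs, WGD lists, complex membership) plus the
#' ground truth as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(cohort$lfc, file.path(dir, "logfold_change.csv"), "sgRNA")
  write.csv(cohort$guides, file.path(dir, "guide_library.csv"),
            row.names = FALSE)
  write_matrix_csv(cohort$expression, file.path(dir, "expression.csv"))
  write_matrix_csv(cohort$copy_number, file.path(dir, "copy_number.csv"))
  write.csv(cohort$mutations, file.path(dir, "mutation_calls.csv"),
            row.names = FALSE)
  write.csv(cohort$pairs, file.path(dir, "paralog_pairs.csv"),
            row.names = FALSE)
  write.csv(cohort$wgd_list_a, file.path(dir, "wgd_list_a.csv"),
            row.names = FALSE)
  write.csv(cohort$wgd_list_b, file.path(dir, "wgd_list_b.csv"),
            row.names = FALSE)
  write.csv(cohort$complexes, file.path(dir, "complexes.csv"),
            row.names = FALSE)
  gt <- cohort$ground_truth
  gt$category <- as.list(gt$category)
  gt$sometimes_frac <- as.list(gt$sometimes_frac)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
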