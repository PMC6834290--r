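as_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), 2, 2)
  }
  if (any(m < 0) || any(m != round(m)) || any(is.na(m)))
    stop("2x2 table requires non-negative integer counts", call. = FALSE)
  if (sum(m) == 0) stop("2x2 table is empty", call. = FALSE)
  m
}

#' Fisher's exact test with the sample odds ratio
#'
#' The reported odds ratio is the cross-product (sample) estimate
#' ad/(bc) — Inf if bc = 0 with ad > 0, NaN if both products are 0 — and
#' the p-value is the exact Fisher p: two-sided by the point-probability
#' method (sum of hypergeometric probabilities no larger than that of the
#' observed table), or a one-sided tail when `alternative` is "greater" or
#' "less" (used for enrichment questions).
#'
#' @param a,b,c,d cell counts (rows = group, cols = outcome); alternatively
#'   `a` may be a 2x2 matrix.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return List: statistic (named OR), p_value, table, alternative.
#' @export
fisher_exact_or <- function(a, b = NULL, c = NULL, d = NULL,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- as_2x2(a, b, c, d)
  ad <- m[1, 1] * m[2, 2]
  bc <- m[1, 2] * m[2, 1]
  or <- if (bc == 0 && ad == 0) NaN else if (bc == 0) Inf else ad / bc
  p <- fisher.test(m, alternative = alternative)$p.value
  list(statistic = c(OR = or), p_value = p, table = m,
       alternative = alternative)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: q_(i) = min over j >= i of p_(j) * n / j, capped at 1
#' and mapped back to the input order.
#'
#' @param p vector of p-values in \[0, 1\] (NAs propagate).
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Two-sample t-test (pooled-variance Student's form)
#'
#' Two-sided Student's t with pooled variance and df = n1 + n2 - 2 by
#' default; Welch's form behind `var_equal = FALSE`. Degenerate inputs with
#' zero pooled variance give t = 0, p = 1 when the means are equal, and a
#' flagged p = 0 otherwise.
#'
#' @param x,y numeric vectors with at least 2 finite values each.
#' @param var_equal pooled-variance Student's t (default) vs Welch.
#' @return List: statistic (named t), p_value, df, mean_diff (mean(x) -
#'   mean(y)), degenerate flag.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need at least 2 finite values", call. = FALSE)
  md <- mean(x) - mean(y)
  pooled <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  if (pooled == 0 && var(x) == 0 && var(y) == 0) {
    if (md == 0)
      return(list(statistic = c(t = 0), p_value = 1,
                  df = length(x) + length(y) - 2, mean_diff = 0,
                  degenerate = TRUE))
    return(list(statistic = c(t = sign(md) * Inf), p_value = 0,
                df = length(x) + length(y) - 2, mean_diff = md,
                degenerate = TRUE))
  }
  res <- t.test(x, y, var.equal = var_equal)
  list(statistic = c(t = unname(res$statistic)), p_value = res$p.value,
       df = unname(res$parameter), mean_diff = md, degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Reports the U statistic for the first sample (midranks under ties). The
#' two-sided p-value is exact by enumeration when n1 + n2 <= 12 and there
#' are no ties, and a tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return List: statistic (named U), p_value, method.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (n1 + n2 <= 12 && !ties) {
    p <- wilcox.test(x, y, exact = TRUE)$p.value
    method <- "exact"
  } else {
    n <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = c(U = u), p_value = min(p, 1), method = method)
}

#' Pearson chi-squared test on an r x c table
#'
#' Without continuity correction; df = (r-1)(c-1). A zero row or column
#' margin is an input error.
#'
#' @param tab contingency matrix of counts.
#' @return List: statistic (named chisq), p_value, df.
#' @export
chi_squared_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero row or column margin", call. = FALSE)
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = c(chisq = unname(res$statistic)), p_value = res$p.value,
       df = unname(res$parameter))
}

#' Likelihood-ratio comparison of nested multinomial logit models
#'
#' Fits 3-class (or generally multi-class) multinomial logistic regressions
#' of the essentiality category on the full and the reduced feature sets by
#' maximum likelihood and compares them with a likelihood ratio test:
#' LRT = 2 (logL_full - logL_reduced), with df equal to the difference in
#' free parameter count ((k-1) per added feature for a k-level outcome).
#'
#' @param data data.frame holding outcome and features.
#' @param outcome name of the (factor) outcome column.
#' @param features_full,features_reduced character vectors of feature column
#'   names; the reduced set must be a subset of the full set (empty =
#'   intercept-only).
#' @return List: logL_full, logL_reduced, statistic (named LRT), df,
#'   p_value.
#' @export
multinomial_logit_lrt <- function(data, outcome, features_full,
                                  features_reduced = character(0)) {
  if (!all(features_reduced %in% features_full))
    stop("models are not nested: reduced features must be a subset of the full set",
         call. = FALSE)
  data[[outcome]] <- factor(data[[outcome]])
  form <- function(fs) as.formula(paste(
    outcome, "~", if (length(fs)) paste(fs, collapse = " + ") else "1"))
  fit <- function(fs) nnet::multinom(form(fs), data = data, trace = FALSE,
                                     maxit = 1000, reltol = 1e-12)
  mf <- fit(features_full)
  mr <- fit(features_reduced)
  llf <- logLik(mf); llr <- logLik(mr)
  df <- attr(llf, "df") - attr(llr, "df")
  lrt <- 2 * (as.numeric(llf) - as.numeric(llr))
  p <- if (df == 0) 1 else pchisq(max(lrt, 0), df, lower.tail = FALSE)
  list(logL_full = as.numeric(llf), logL_reduced = as.numeric(llr),
       statistic = c(LRT = lrt), df = df, p_value = p)
}

#' Protein complex enrichment with a custom background
#'
#' Per complex, a one-sided hypergeometric test for over-representation of
#' the query gene set among the complex's members within the supplied
#' background universe, followed by Benjamini-Hochberg FDR across the
#' tested complexes. Complexes with no background members are skipped.
#'
#' @param query character vector of query genes (must be a subset of the
#'   background).
#' @param background character vector: the gene universe.
#' @param complexes data.frame (complex_id, gene).
#' @return data.frame sorted by p: complex_id, n_complex (background
#'   members), n_overlap, expected, p, q.
#' @export
complex_enrichment <- function(query, background, complexes) {
  query <- unique(query); background <- unique(background)
  if (!all(query %in% background))
    stop("query genes must be a subset of the background", call. = FALSE)
  N <- length(background); n_q <- length(query)
  by_cpx <- split(complexes$gene, complexes$complex_id)
  rows <- lapply(names(by_cpx), function(id) {
    members <- intersect(unique(by_cpx[[id]]), background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, query))
    p <- phyper(k - 1, K, N - K, n_q, lower.tail = FALSE)
    data.frame(complex_id = id, n_complex = K, n_overlap = k,
               expected = n_q * K / N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(complex_id = character(0), n_complex = integer(0),
                      n_overlap = integer(0), expected = numeric(0),
                      p = numeric(0), q = numeric(0)))
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$complex_id), ]
  rownames(out) <- NULL
  out
}
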