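em_gmm_1d <- function(x, k, means0, sds0, w0, max_iter = 500, tol = 1e-8) {
  res <- em_gmm_1d_cpp(as.numeric(x), as.numeric(means0), as.numeric(sds0),
                       as.numeric(w0), as.integer(max_iter), as.numeric(tol))
  if (is.null(res)) return(NULL)
  res$weights <- res$weights / sum(res$weights)
  res
}

mixture_density <- function(grid, weights, means, sds) {
  rowSums(vapply(seq_along(weights), function(j)
    weights[j] * dnorm(grid, means[j], sds[j]), numeric(length(grid))))
}

# incremental init: previous best fit plus a narrow component at the peak
# of the positive residual (empirical kde minus model density); this is
# what reliably discovers low-weight shoulder components that random
# restarts miss.
residual_peak_init <- function(x, fprev) {
  d <- stats::density(x, n = 512)
  resid <- d$y - mixture_density(d$x, fprev$weights, fprev$means, fprev$sds)
  new_mu <- d$x[which.max(resid)]
  m0 <- c(fprev$means, new_mu)
  s0 <- c(fprev$sds, sd(x) / 10)
  w0 <- c(fprev$weights * 0.95, 0.05)
  o <- order(m0)
  list(means = m0[o], sds = s0[o], weights = w0[o])
}

#' Fit a Gaussian mixture to pooled fitness scores
#'
#' Fits 1-D Gaussian mixture models with `k_range` components by EM and
#' selects the model minimizing AIC = 2(3k - 1) - 2 logL, counting k means,
#' k variances and k - 1 free weights. For each k the EM is run from an
#' incremental initialization (the best (k-1)-component fit plus a narrow
#' component at the peak of the positive density residual, which reliably
#' finds low-weight shoulder components) and from `n_restarts - 1` random
#' initializations (restart r uses seed `seed + r - 1`; initial means are
#' random data quantiles, so fitting is invariant to the order of the
#' scores); the best log-likelihood is kept. Components are reported sorted
#' by ascending mean.
#'
#' Unequal-variance 1-D mixtures have an unbounded likelihood: a component
#' can collapse onto a handful of near-identical points, gaining just
#' enough log-likelihood to fool AIC. Converged solutions containing such
#' spikes — any component narrower than `min_sd_frac` of the pooled
#' standard deviation or lighter than `min_weight` — are therefore treated
#' as degenerate and the restart is rejected.
#'
#' @param x numeric vector of pooled scores; non-finite values are dropped.
#' @param k_range component counts to try (default 1:5).
#' @param seed base RNG seed for the restarts.
#' @param n_restarts initializations per k (default 10).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param min_sd_frac,min_weight degeneracy guards: minimum component sd as
#'   a fraction of the pooled sd, and minimum component weight.
#' @return Object of class `mixture_fit`: k, weights, means, sds, loglik,
#'   aic, the per-k AIC table, and the seed/restart metadata.
#' @export
fit_score_mixture <- function(x, k_range = 1:5, seed = 1L, n_restarts = 10,
                              max_iter = 500, tol = 1e-8,
                              min_sd_frac = 0.1, min_weight = 0.02) {
  x <- x[is.finite(x)]
  if (length(x) < 10 * max(k_range))
    stop("need at least 10 * max(k_range) finite scores", call. = FALSE)
  k_range <- sort(k_range)
  sd_x <- sd(x)
  admissible <- function(fit) {
    !is.null(fit) && min(fit$sds) >= min_sd_frac * sd_x &&
      min(fit$weights) >= min_weight
  }
  fits <- list()
  aic_tab <- data.frame(k = integer(0), loglik = numeric(0), aic = numeric(0))
  prev <- NULL
  for (k in k_range) {
    best <- NULL
    if (k == 1) {
      mu <- mean(x); sdv <- sqrt(mean((x - mu)^2))
      best <- list(weights = 1, means = mu, sds = sdv,
                   loglik = sum(dnorm(x, mu, sdv, log = TRUE)))
    } else {
      if (!is.null(prev) && prev$k == k - 1) {
        init <- residual_peak_init(x, prev)
        fit <- em_gmm_1d(x, k, init$means, init$sds, init$weights,
                         max_iter = max_iter, tol = tol)
        if (admissible(fit)) best <- fit
      }
      for (r in seq_len(max(n_restarts - 1L, 1L))) {
        fit <- with_local_seed(seed + r - 1L, {
          probs <- sort(runif(k, 0.02, 0.98))
          means0 <- unname(quantile(x, probs))
          em_gmm_1d(x, k, means0, rep(sd_x / sqrt(k), k), rep(1 / k, k),
                    max_iter = max_iter, tol = tol)
        })
        if (admissible(fit) && (is.null(best) || fit$loglik > best$loglik))
          best <- fit
      }
    }
    if (is.null(best)) {
      warning("EM did not converge for k = ", k, "; skipping", call. = FALSE)
      next
    }
    aic <- 2 * (3 * k - 1) - 2 * best$loglik
    aic_tab <- rbind(aic_tab,
                     data.frame(k = k, loglik = best$loglik, aic = aic))
    fits[[as.character(k)]] <- c(best, list(k = k, aic = aic))
    prev <- c(best, list(k = k))
  }
  if (nrow(aic_tab) == 0) stop("mixture fitting failed for every k", call. = FALSE)
  sel <- fits[[as.character(aic_tab$k[which.min(aic_tab$aic)])]]
  ord <- order(sel$means)
  structure(list(k = sel$k,
                 weights = sel$weights[ord],
                 means = sel$means[ord],
                 sds = sel$sds[ord],
                 loglik = sel$loglik, aic = sel$aic,
                 aic_by_k = aic_tab,
                 seed = seed, n_restarts = n_restarts,
                 n = length(x),
                 boundary_rule = "equal weighted density"),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Gaussian mixture fit: k =", x$k, " (AIC-selected), n =", x$n, "\n")
  print(data.frame(weight = round(x$weights, 4), mean = round(x$means, 4),
                   sd = round(x$sds, 4)))
  invisible(x)
}

#' Equal-weighted-density boundary between two mixture components
#'
#' Finds the point between the two component means where the weighted
#' component densities are equal (equivalently, where posterior
#' responsibility switches between the components), by bisection on a sign
#' change to an interval narrower than 1e-8. If several crossings exist in
#' the open interval, the one closest to the second (higher) mean is
#' returned.
#'
#' @param weights,means,sds length-2 numeric vectors (first component must
#'   have the lower mean).
#' @return The boundary point.
#' @export
mixture_boundary <- function(weights, means, sds) {
  stopifnot(length(weights) == 2, means[1] < means[2])
  g <- function(x) weights[1] * dnorm(x, means[1], sds[1]) -
    weights[2] * dnorm(x, means[2], sds[2])
  grid <- seq(means[1], means[2], length.out = 2001)
  gv <- g(grid)
  sgn <- sign(gv)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(cross) == 0) {
    flat <- which(gv == 0)
    if (length(flat)) return(grid[max(flat)])
    stop("no weighted-density crossing between the component means; ",
         "component 1 (w=", signif(weights[1], 3), ", m=", signif(means[1], 3),
         ") vs component 2 (w=", signif(weights[2], 3), ", m=",
         signif(means[2], 3), ")", call. = FALSE)
  }
  i <- max(cross)                       # crossing closest to the upper mean
  lo <- grid[i]; hi <- grid[i + 1]
  flo <- g(lo)
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    fm <- g(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Essentiality threshold from a mixture fit
#'
#' The binarization threshold is the boundary point between the lowest-mean
#' ("essential", severe fitness defect) component and the second
#' ("moderate fitness defect") component of the fitted mixture: the point
#' where their weighted densities are equal.
#'
#' @param fit a [fit_score_mixture()] result with at least 2 components.
#' @return Threshold (scalar) with the boundary rule attached as an
#'   attribute.
#' @export
essentiality_threshold <- function(fit) {
  if (fit$k < 2)
    stop("threshold requires a mixture with at least 2 components",
         call. = FALSE)
  tau <- mixture_boundary(fit$weights[1:2], fit$means[1:2], fit$sds[1:2])
  attr(tau, "rule") <- "equal weighted density (= equal posterior) between components 1 and 2"
  tau
}

#' Binarize a score matrix at a threshold
#'
#' A gene is called essential in a cell line iff its score is at or below
#' the threshold (inclusive). Missing scores stay missing.
#'
#' @param scores gene-by-line numeric matrix.
#' @param tau finite threshold.
#' @return Integer matrix (1 = essential, 0 = not, NA = missing) with the
#'   threshold attached as attribute `threshold`.
#' @export
binarize_scores <- function(scores, tau) {
  if (!is.finite(tau)) stop("threshold must be finite", call. = FALSE)
  b <- (scores <= tau) * 1L
  storage.mode(b) <- "integer"
  attr(b, "threshold") <- as.numeric(tau)
  b
}

#' Summarize per-gene essentiality across cell lines
#'
#' Computes, per gene, the number and fraction of scored lines in which it
#' is essential and assigns the essentiality category: "never" (essential
#' in 0 lines), "broadly" (essential in at least 90% of scored lines),
#' otherwise "sometimes". Genes with a positive fraction are also assigned
#' to decile bins (0-10], (10-20], ..., (90-100]. Per-line essential-gene
#' counts and their median are reported alongside.
#'
#' @param bin binary essentiality matrix from [binarize_scores()].
#' @param broadly_cutoff fraction at or above which a gene is broadly
#'   essential (default 0.9).
#' @return List with `genes` (data.frame: gene, n_lines_scored,
#'   n_lines_essential, fraction_essential, category, bin), `per_line`
#'   (named essential counts) and `median_essential_per_line`.
#' @export
summarize_essentiality <- function(bin, broadly_cutoff = 0.9) {
  scored <- rowSums(!is.na(bin))
  if (any(scored == 0)) {
    warning(sum(scored == 0), " gene(s) scored in zero lines excluded",
            call. = FALSE)
    bin <- bin[scored > 0, , drop = FALSE]
    scored <- scored[scored > 0]
  }
  ess <- rowSums(bin == 1L, na.rm = TRUE)
  frac <- ess / scored
  category <- ifelse(ess == 0, "never",
                     ifelse(frac >= broadly_cutoff, "broadly", "sometimes"))
  bin_lab <- rep(NA_character_, length(frac))
  pos <- frac > 0
  bin_lab[pos] <- as.character(cut(100 * frac[pos], breaks = seq(0, 100, 10),
                                   include.lowest = FALSE))
  genes_df <- data.frame(gene = rownames(bin), n_lines_scored = scored,
                         n_lines_essential = ess, fraction_essential = frac,
                         category = category, bin = bin_lab,
                         stringsAsFactors = FALSE, row.names = NULL)
  per_line <- colSums(bin == 1L, na.rm = TRUE)
  list(genes = genes_df, per_line = per_line,
       median_essential_per_line = median(per_line))
}
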