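#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided test on paired differences (zero differences are dropped,
#' midranks for ties). For n <= 15 the null distribution of the positive
#' rank sum is enumerated exactly over all 2^n sign assignments of the
#' observed ranks (so ties are handled exactly); above that, the normal
#' approximation with tie-corrected variance is used (no continuity
#' correction).
#'
#' @param x paired differences, or first sample if `y` is given.
#' @param y optional second sample (differences become `x - y`).
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("wilcoxon_signed_rank: all differences are zero")
  if (n < 5) stop("wilcoxon_signed_rank: need >= 5 non-zero differences")
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= 15) {
    # exact: distribution of W+ over all sign assignments of the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.numeric(signs %*% r)
    p_le <- mean(w_all <= w_obs)
    p_ge <- mean(w_all >= w_obs)
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_obs - mu) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Holm-Bonferroni step-down adjustment
#'
#' Adjusts p-values from smallest to largest:
#' `adj_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))` in ascending order,
#' returned in the original order. `m` may exceed the number of p-values
#' supplied (a fixed family size).
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @param m family size (>= `length(p)`).
#' @return Adjusted p-values (same order as input).
#' @export
holm_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("holm_adjust: p-values must lie in [0, 1]")
  if (m < length(p)) stop("holm_adjust: m must be >= length(p)")
  ord <- order(p)
  ps <- p[ord]
  adj <- pmin(1, (m - seq_along(ps) + 1) * ps)
  adj <- cummax(adj)
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Pairwise method comparison with Holm correction
#'
#' For every metric in the report collection, runs the Wilcoxon signed-rank
#' test on the paired percent changes of every pair of methods (matching on
#' `pair_id`), adjusts within each metric family with Holm-Bonferroni at
#' family size `m` (5 methods give C(5,2) = 10 comparisons, the default
#' family size), and flags adjusted p-values below `alpha`.
#'
#' @param reports tibble with columns `pair_id`, `method`, `metric`,
#'   `pct_change` (as produced by [evaluate_pair]).
#' @param alpha significance level (default 0.05).
#' @param m Holm family size (default 10).
#' @return A tibble: metric, method pair, raw and adjusted p, significance.
#' @export
compare_methods <- function(reports, alpha = 0.05, m = 10L) {
  out <- list()
  for (metric in unique(reports$metric)) {
    sub <- reports[reports$metric == metric, ]
    methods <- sort(unique(sub$method))
    if (length(methods) < 2) next
    prs <- combn(methods, 2)
    pvals <- numeric(ncol(prs)); amed <- numeric(ncol(prs)); bmed <- numeric(ncol(prs))
    for (i in seq_len(ncol(prs))) {
      a <- sub[sub$method == prs[1, i], ]
      b <- sub[sub$method == prs[2, i], ]
      shared <- intersect(a$pair_id, b$pair_id)
      if (length(shared) < 5)
        stop("compare_methods: need >= 5 shared pairs per method pair")
      av <- a$pct_change[match(shared, a$pair_id)]
      bv <- b$pct_change[match(shared, b$pair_id)]
      keep <- !is.na(av) & !is.na(bv)
      av <- av[keep]; bv <- bv[keep]
      nz <- sum(av != bv)
      pvals[i] <- if (length(av) >= 5 && nz == 0) 1
                  else if (nz < 5) NA_real_   # too few informative pairs
                  else wilcoxon_signed_rank(av, bv)
      amed[i] <- if (length(av)) median(av) else NA_real_
      bmed[i] <- if (length(bv)) median(bv) else NA_real_
    }
    fam <- max(m, ncol(prs))
    adj <- rep(NA_real_, length(pvals))
    ok <- !is.na(pvals)
    if (any(ok)) adj[ok] <- holm_adjust(pvals[ok], m = fam)
    out[[length(out) + 1]] <- tibble::tibble(
      metric = metric, method_a = prs[1, ], method_b = prs[2, ],
      median_pct_a = amed, median_pct_b = bmed,
      p_value = pvals, p_adjusted = adj,
      significant = !is.na(adj) & adj < alpha)
  }
  do.call(rbind, out)
}
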