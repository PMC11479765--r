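# Thin wrappers over the standard statistical comparisons used throughout
# the pipeline: Wilcoxon signed-rank for paired data, Kruskal-Wallis with
# Dunn-Sidak post hoc pairs, chi-square goodness of fit, and z-tests for
# permutation and decoder distributions.

#' Grouped or paired statistical comparison
#'
#' @param x Numeric vector (first sample, counts, or a distribution of
#'   permuted/accuracy values depending on `test`).
#' @param y Second paired sample (for `wilcoxon_signed_rank`) or the
#'   reference value (for the z-tests; default 0).
#' @param groups Group labels (for `kruskal_wallis_dunn_sidak`).
#' @param test One of "wilcoxon_signed_rank", "kruskal_wallis_dunn_sidak",
#'   "chi_square", "one_sided_z", "two_sided_z".
#' @return list with `statistic`, `p`, and test-specific extras (post hoc
#'   table for Kruskal-Wallis). Identical paired samples return W = 0 and
#'   p = 1 rather than erroring.
#' @export
group_stats <- function(x, y = NULL, groups = NULL,
                        test = c("wilcoxon_signed_rank",
                                 "kruskal_wallis_dunn_sidak",
                                 "chi_square", "one_sided_z", "two_sided_z")) {
  test <- match.arg(test)
  switch(test,
    wilcoxon_signed_rank = {
      if (length(x) != length(y)) stop("paired samples must have equal length")
      d <- x - y
      if (all(d == 0)) return(list(statistic = 0, p = 1))
      w <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                               exact = FALSE))
      list(statistic = unname(w$statistic), p = w$p.value)
    },
    kruskal_wallis_dunn_sidak = {
      k <- stats::kruskal.test(x, g = factor(groups))
      list(statistic = unname(k$statistic), p = k$p.value,
           post_hoc = dunn_sidak(x, factor(groups)))
    },
    chi_square = {
      cs <- suppressWarnings(stats::chisq.test(x, p = rep(1 / length(x),
                                                          length(x))))
      list(statistic = unname(cs$statistic), p = cs$p.value)
    },
    one_sided_z = {
      ref <- if (is.null(y)) 0 else y
      s <- stats::sd(x)
      z <- if (s > 0) (mean(x) - ref) / s else sign(mean(x) - ref) * Inf
      list(statistic = z, p = stats::pnorm(z, lower.tail = FALSE))
    },
    two_sided_z = {
      ref <- if (is.null(y)) 0 else y
      s <- stats::sd(x)
      z <- if (s > 0) (mean(x) - ref) / s else sign(mean(x) - ref) * Inf
      list(statistic = z, p = 2 * stats::pnorm(-abs(z)))
    })
}

# Dunn's rank-based post hoc z-tests with Sidak family-wise correction.
dunn_sidak <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  m <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(p) {
    i <- g == p[1]; j <- g == p[2]
    ni <- sum(i); nj <- sum(j)
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    z <- (mean(r[i]) - mean(r[j])) / se
    praw <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = p[1], group2 = p[2], z = z, p_raw = praw,
               p_adj = 1 - (1 - praw)^m, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bonferroni-adjusted significance level
#' @param alpha Nominal family-wise level.
#' @param m Number of comparisons.
#' @return Per-comparison alpha.
#' @export
bonferroni_alpha <- function(alpha, m) alpha / m
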