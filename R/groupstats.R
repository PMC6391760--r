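#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Classical single-factor between/within variance decomposition over two or
#' more groups, followed by Tukey HSD pairwise comparisons at `alpha`.
#'
#' @param samples named list of numeric vectors, one per group.
#' @param alpha significance level for the post-hoc flags (default 0.05).
#' @return object of class `anova_groups`: list with `F`, `df_between`,
#'   `df_within`, `p`, and `posthoc` (data.frame of pairs with adjusted p and
#'   significance flag).
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(samples, alpha = 0.05) {
  if (length(samples) < 2L) stop_volecall("need at least two groups")
  if (any(vapply(samples, length, 1L) < 2L))
    stop_volecall("each group needs at least 2 values")
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("g", seq_along(samples))
  d <- data.frame(value = unlist(samples, use.names = FALSE),
                  group = factor(rep(names(samples),
                                     vapply(samples, length, 1L))))
  if (stats::var(d$value) == 0)
    stop_volecall("degenerate input: zero total variance")
  fit <- stats::aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"],
                        significant = tk[, "p adj"] < alpha,
                        row.names = NULL)
  structure(list(F = tab["group", "F value"],
                 df_between = tab["group", "Df"],
                 df_within = tab["Residuals", "Df"],
                 p = tab["group", "Pr(>F)"],
                 posthoc = posthoc),
            class = "anova_groups")
}

#' @export
print.anova_groups <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.2f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$posthoc)
  invisible(x)
}

#' Kruskal-Wallis rank test and median test
#'
#' Nonparametric group comparison for parameters that are not normally
#' distributed (peak frequency here): the Kruskal-Wallis H statistic, plus the
#' median test — a chi-squared test on the counts of values above vs at-or-
#' below the grand median per group — and pairwise mean-rank z comparisons
#' with Bonferroni adjustment.
#'
#' @param samples named list of numeric vectors, one per group.
#' @return list with `H`, `p_kw`, `chi2_median`, `df_median`, `p_median`,
#'   `median_counts` (2 x k table) and `pairwise` (data.frame with z and
#'   Bonferroni-adjusted p per pair).
#' @export
kruskal_wallis_median <- function(samples) {
  if (length(samples) < 2L) stop_volecall("need at least two groups")
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("g", seq_along(samples))
  values <- unlist(samples, use.names = FALSE)
  if (length(unique(values)) == 1L) stop_volecall("all values tied")
  g <- factor(rep(names(samples), vapply(samples, length, 1L)),
              levels = names(samples))
  kw <- stats::kruskal.test(values, g)
  grand <- stats::median(values)
  counts <- rbind(above = tapply(values > grand, g, sum),
                  at_or_below = tapply(values <= grand, g, sum))
  med <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  # pairwise Dunn-type z on mean ranks, Bonferroni-adjusted
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  pw <- apply(pairs, 2, function(pr) {
    i <- g == pr[1]; j <- g == pr[2]
    se <- sqrt(tie_corr * n * (n + 1) / 12 * (1 / sum(i) + 1 / sum(j)))
    z <- abs(mean(r[i]) - mean(r[j])) / se
    c(z = z, p = 2 * stats::pnorm(-z))
  })
  pairwise <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
                         z = pw["z", ],
                         p_adj = pmin(1, pw["p", ] * ncol(pairs)))
  list(H = unname(kw$statistic), p_kw = kw$p.value,
       chi2_median = unname(med$statistic),
       df_median = unname(med$parameter), p_median = med$p.value,
       median_counts = counts, pairwise = pairwise)
}

#' Compare two attribution percentages by chi-squared
#'
#' Rebuilds the 2 x 2 (correct, incorrect) contingency table from two
#' percentages and their sample sizes and applies the chi-squared test,
#' with Yates continuity correction by default.
#'
#' @param p1,p2 percent correct, in \[0, 100\].
#' @param n1,n2 number of classified observations behind each percentage.
#' @param yates apply the continuity correction (default TRUE).
#' @return list with `chi2`, `df`, `p` and the reconstructed `table`.
#' @export
compare_proportions_chi2 <- function(p1, n1, p2, n2, yates = TRUE) {
  if (p1 < 0 || p1 > 100 || p2 < 0 || p2 > 100)
    stop_volecall("percentages must lie in [0, 100]")
  if (n1 < 1 || n2 < 1) stop_volecall("sample sizes must be at least 1")
  c1 <- round(p1 / 100 * n1); c2 <- round(p2 / 100 * n2)
  tab <- rbind(c(c1, n1 - c1), c(c2, n2 - c2))
  dimnames(tab) <- list(sample = c("1", "2"), c("correct", "incorrect"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}
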