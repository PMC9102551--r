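# Normality-gated differential expression. Per cohort, each group's values
# are taken as normally distributed about the group mean when the group
# either has more than 30 observations or produces a non-significant
# two-sided Kolmogorov-Smirnov p-value against a normal reference. When all
# groups pass, the cohort is analysed parametrically (ANOVA + Tukey HSD);
# otherwise nonparametrically (Kruskal-Wallis + Dunn's all-pairs rank
# comparison with Bonferroni correction). Homoscedasticity (Levene) is
# reported but informational: it does not alter the plan.

#' Normality gate and test plan for a cohort
#'
#' A group passes when `n > n_large` (default 30) or when the two-sided KS
#' test against a normal reference gives `p > alpha`. By default the
#' reference uses the group's own estimated mean and standard deviation;
#' this is known to make the KS test conservative (estimated-parameter
#' effect), so a fixed reference can be supplied via `ks_mean`/`ks_sd`
#' when the null distribution is known. Groups too small for the KS test
#' (`n < 2`) fail with reason `"insufficient n for KS"`.
#'
#' @param groups named list of numeric vectors (>= 1 group, each `n >= 1`).
#' @param alpha KS significance level.
#' @param n_large group size above which normality is assumed outright.
#' @param ks_mean,ks_sd optional fixed reference parameters for the KS test;
#'   `NULL` (default) estimates them per group.
#' @return a `TestPlan`: list with `plan` (`"parametric"` or
#'   `"nonparametric"`), `groups` (per-group verdict data frame with
#'   reasons), and `levene_p` (informational; `NA` when not computable).
#' @export
normality_gate <- function(groups, alpha = 0.05, n_large = 30,
                           ks_mean = NULL, ks_sd = NULL) {
  if (!is.list(groups) || length(groups) < 1)
    stop("`groups` must be a non-empty list of numeric vectors", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(lengths(groups) < 1)) stop("each group needs n >= 1", call. = FALSE)
  verdict <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    n <- length(x)
    if (n > n_large)
      return(data.frame(group = g, n = n, ks_p = NA_real_, passes = TRUE,
                        reason = sprintf("n > %d", n_large),
                        stringsAsFactors = FALSE))
    if (n < 2 || stats::sd(x) == 0)
      return(data.frame(group = g, n = n, ks_p = NA_real_, passes = FALSE,
                        reason = "insufficient n for KS",
                        stringsAsFactors = FALSE))
    mu <- if (is.null(ks_mean)) mean(x) else ks_mean
    sg <- if (is.null(ks_sd)) stats::sd(x) else ks_sd
    p <- suppressWarnings(stats::ks.test(x, "pnorm", mu, sg,
                                         alternative = "two.sided")$p.value)
    data.frame(group = g, n = n, ks_p = p, passes = p > alpha,
               reason = if (p > alpha) "KS non-significant" else "KS significant",
               stringsAsFactors = FALSE)
  }))
  levene_p <- NA_real_
  if (length(groups) >= 2 && all(lengths(groups) >= 2)) {
    vals <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), lengths(groups)))
    levene_p <- tryCatch(
      car::leveneTest(vals ~ fac)[1, "Pr(>F)"],
      error = function(e) NA_real_)
  }
  structure(list(plan = if (all(verdict$passes)) "parametric" else "nonparametric",
                 groups = verdict, alpha = alpha, levene_p = levene_p),
            class = "TestPlan")
}

#' @export
print.TestPlan <- function(x, ...) {
  cat(sprintf("Test plan: %s (alpha = %g, Levene p = %s)\n", x$plan,
              x$alpha, format(x$levene_p, digits = 3)))
  print(x$groups, ...)
  invisible(x)
}

#' Dunn's all-pairs rank comparison
#'
#' Post-hoc test after Kruskal-Wallis: all observations are ranked jointly,
#' and for each pair of groups
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` where
#' `T = sum(t^3 - t) / (12 (N - 1))` corrects for ties. Two-sided normal
#' p-values with Bonferroni adjustment by default.
#'
#' @param values numeric vector.
#' @param groups factor/character vector parallel to `values`.
#' @param p_adjust_method passed to [stats::p.adjust()]; default
#'   `"bonferroni"`.
#' @return data frame `comparison`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust_method = "bonferroni") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tabulate(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(seq_along(lev), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    (rbar[i] - rbar[j]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    comparison = apply(pairs, 2, function(ij) paste(lev[ij], collapse = " - ")),
    z = unname(z), p = unname(p),
    p_adj = stats::p.adjust(p, p_adjust_method),
    stringsAsFactors = FALSE)
}

#' Differential expression of one gene across labelled groups
#'
#' Runs the plan chosen by [normality_gate()]: ANOVA followed by Tukey's HSD
#' when all groups meet the normality conditions, otherwise Kruskal-Wallis
#' followed by Dunn's all-pairs comparison with Bonferroni correction. With
#' only two groups the omnibus test is replaced by the matching two-group
#' test (Welch t / Wilcoxon rank-sum), flagged in the output.
#'
#' @param values numeric expression values.
#' @param groups group label per value (>= 2 groups).
#' @param alpha significance level for the gate.
#' @param gene optional gene name carried into the report.
#' @param ... passed to [normality_gate()] (e.g. `ks_mean`, `ks_sd`).
#' @return a `de_result`: list with `gene`, `plan` (the `TestPlan`), `np`
#'   (nonparametric flag), `omnibus` (method, statistic, p), `pairwise`
#'   (comparison, `dif` = difference of means or of medians, adjusted p),
#'   `group_stats`, and `two_group_fallback`.
#' @export
run_de <- function(values, groups, alpha = 0.05, gene = NULL, ...) {
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop("need at least 2 groups for a comparison", call. = FALSE)
  split_vals <- split(values, groups)
  plan <- normality_gate(split_vals, alpha = alpha, ...)
  np <- plan$plan == "nonparametric"
  k <- nlevels(groups)
  lev <- levels(groups)
  group_stats <- data.frame(
    group = lev, n = as.integer(lengths(split_vals)),
    mean = vapply(split_vals, mean, 0),
    median = vapply(split_vals, stats::median, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  center <- if (np) group_stats$median else group_stats$mean
  names(center) <- lev
  pair_dif <- function(cmp) {
    ab <- strsplit(cmp, " - ", fixed = TRUE)[[1]]
    center[[ab[1]]] - center[[ab[2]]]
  }
  fallback <- k == 2
  if (fallback) {
    ht <- if (np) stats::wilcox.test(values ~ groups, exact = FALSE)
          else stats::t.test(values ~ groups)
    cmp <- paste(lev, collapse = " - ")
    omnibus <- list(method = ht$method, statistic = unname(ht$statistic),
                    p = ht$p.value)
    pairwise <- data.frame(comparison = cmp, dif = pair_dif(cmp),
                           p_adj = ht$p.value, stringsAsFactors = FALSE)
  } else if (np) {
    kw <- stats::kruskal.test(values, groups)
    dt <- dunn_test(values, groups)
    omnibus <- list(method = kw$method, statistic = unname(kw$statistic),
                    p = kw$p.value)
    pairwise <- data.frame(comparison = dt$comparison,
                           dif = vapply(dt$comparison, pair_dif, 0),
                           p_adj = dt$p_adj, stringsAsFactors = FALSE)
  } else {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    cmps <- gsub("-", " - ", rownames(tk), fixed = TRUE)
    omnibus <- list(method = "One-way ANOVA", statistic = an[1, "F value"],
                    p = an[1, "Pr(>F)"])
    pairwise <- data.frame(comparison = cmps, dif = unname(tk[, "diff"]),
                           p_adj = unname(tk[, "p adj"]),
                           stringsAsFactors = FALSE)
  }
  rownames(pairwise) <- NULL
  structure(list(gene = gene, plan = plan, np = np, omnibus = omnibus,
                 pairwise = pairwise, group_stats = group_stats,
                 two_group_fallback = fallback),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Differential expression%s: %s%s\n",
              if (is.null(x$gene)) "" else paste0(" of ", x$gene),
              x$omnibus$method,
              if (x$np) " [np]" else ""))
  cat(sprintf("  omnibus p = %.4g%s\n", x$omnibus$p,
              if (x$two_group_fallback) " (two-group fallback)" else ""))
  print(cbind(x$pairwise, np = x$np), ...)
  invisible(x)
}
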