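#' @rdname two_sample_t
#' @export
print.stat_result <- function(x, ...) {
  df <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n",
              x$test_name, x$statistic, df, x$p_value))
  invisible(x)
}

group_summaries <- function(groups) {
  do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(group = if (!is.null(names(groups))) names(groups)[i] else
                 as.character(i),
               n = length(g), mean = mean(g),
               sem = stats::sd(g) / sqrt(length(g)))
  }))
}

#' One-way ANOVA with Tukey's HSD post hoc test
#'
#' F statistic with (k - 1, N - k) degrees of freedom; pairwise p-values
#' adjusted with the studentized-range distribution at the given family
#' level.
#'
#' @param groups named (or unnamed) list of numeric samples, each n >= 2.
#' @param alpha family-wise significance level for the Tukey intervals.
#' @return object of class `stat_result` with `pairwise` Tukey rows and
#'   per-group mean +/- SEM summaries.
#' @export
one_way_anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, integer(1))),
                                  levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  f_stat <- tab["group", "F value"]
  p <- tab["group", "Pr(>F)"]
  if (is.na(f_stat)) { f_stat <- 0; p <- 1 }  # zero within-group variance only
  structure(list(test_name = "one_way_anova_tukey", statistic = f_stat,
                 df = c(tab["group", "Df"], tab["Residuals", "Df"]),
                 p_value = p, group_summaries = group_summaries(groups),
                 pairwise = pairwise),
            class = "stat_result")
}

#' Student's two-sample t-test (pooled variance)
#'
#' Equal-variance t with `n_a + n_b - 2` degrees of freedom; two-tailed by
#' default. The statistic's sign follows `mean(a) - mean(b)`. Samples with
#' zero pooled variance give t = 0, p = 1 when the means agree and an error
#' otherwise.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param equal_var pool variances (TRUE, default) or Welch (FALSE).
#' @param two_tailed two-sided p-value (default); FALSE halves it towards
#'   the observed direction.
#' @return object of class `stat_result`.
#' @export
two_sample_t <- function(a, b, equal_var = TRUE, two_tailed = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  pooled_var <- ((length(a) - 1) * stats::var(a) +
                   (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) != mean(b))
      stop("zero pooled variance with different means: t undefined")
    res <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                p.value = 1)
  } else {
    res <- stats::t.test(a, b, var.equal = equal_var,
                         alternative = "two.sided")
  }
  p <- res$p.value
  if (!two_tailed) p <- p / 2
  structure(list(test_name = "two_sample_t",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter), p_value = p,
                 group_summaries = group_summaries(list(a = a, b = b))),
            class = "stat_result")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sided p-value (an
#' exact small-sample p is available on request).
#'
#' @param a,b non-empty numeric samples.
#' @param exact use the exact p-value computation instead of the asymptotic
#'   formula.
#' @return object of class `stat_result`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  structure(list(test_name = "ks_two_sample",
                 statistic = unname(res$statistic), df = NA_real_,
                 p_value = res$p.value,
                 group_summaries = group_summaries(list(a = a, b = b))),
            class = "stat_result")
}

#' Critical value of Grubbs' test
#'
#' `G_crit = (n - 1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)` for the two-sided test (alpha/n when
#' one-sided).
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @param two_sided two-sided test (default).
#' @return critical G value.
#' @export
grubbs_critical <- function(n, alpha = 0.05, two_sided = TRUE) {
  stopifnot(n >= 3)
  denom <- if (two_sided) 2 * n else n
  tq <- stats::qt(1 - alpha / denom, df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Iterative Grubbs outlier test
#'
#' Repeatedly computes `G = max |x - mean| / sd`, removes the most extreme
#' value while G exceeds the critical value, and stops when no remaining
#' value is significant (or fewer than 3 values remain, or the sd is zero).
#' Indices refer to the original input order, listed in removal order, so
#' the output is stable under permutation of distinct values.
#'
#' @param values numeric vector.
#' @param alpha significance level.
#' @param two_sided two-sided test (default).
#' @return list with `outlier_indices`, the `G` statistic and critical
#'   value of each removal iteration, and `kept_indices`.
#' @export
grubbs_test <- function(values, alpha = 0.05, two_sided = TRUE) {
  idx <- seq_along(values)
  removed <- integer(0)
  G_seq <- numeric(0); crit_seq <- numeric(0)
  repeat {
    n <- length(idx)
    if (n < 3) break
    x <- values[idx]
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    crit <- grubbs_critical(n, alpha, two_sided)
    if (G <= crit) break
    worst <- idx[which.max(dev)]  # ties: first occurrence
    removed <- c(removed, worst)
    G_seq <- c(G_seq, G); crit_seq <- c(crit_seq, crit)
    idx <- setdiff(idx, worst)
  }
  list(outlier_indices = removed, G = G_seq, critical = crit_seq,
       kept_indices = idx)
}
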