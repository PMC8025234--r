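#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis into the omnibus
#' statistic `K2 = Z(sqrt(b1))^2 + Z(b2)^2`, chi-squared with 2 df under
#' normality. Requires `n >= 8`.
#'
#' @param x numeric sample.
#' @return list with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness transform (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

star_label <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Normality-gated test routing for group comparisons
#'
#' Implements the common decision tree: each group is tested for normality
#' with the D'Agostino-Pearson omnibus test at alpha 0.05; groups too small
#' for the test (`n < normal_min_n`, default 8) are assumed Gaussian. If
#' all groups pass and there are two groups, an unpaired two-tailed t test
#' is used; two groups with any non-normal group route to Mann-Whitney U;
#' more than two all-normal groups route to one-way ANOVA with Tukey's post
#' hoc; otherwise Kruskal-Wallis with Dunn's post hoc. One non-normal group
#' makes the whole comparison nonparametric.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha normality-test alpha (default 0.05).
#' @param normal_min_n smallest n at which the normality test is applied;
#'   below it, normality is assumed (default 8).
#' @param var_equal use the classical equal-variance t test (default TRUE).
#' @return a `group_comparison`: list with `test_used` (one of `"t"`,
#'   `"mann_whitney"`, `"anova_tukey"`, `"kruskal_dunn"`), `normality`
#'   (logical per group), `comparisons` (data.frame of pairwise `group1`,
#'   `group2`, `p`, `stars`), and `omnibus_p` for >2 groups.
#' @export
route_and_test <- function(groups, alpha = 0.05, normal_min_n = 8,
                           var_equal = TRUE) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("every group needs n >= 2")
  normality <- vapply(groups, function(g) {
    if (length(g) < normal_min_n) TRUE
    else dagostino_pearson(g)$p.value >= alpha
  }, logical(1))
  all_normal <- all(normality)
  two <- length(groups) == 2
  nm <- names(groups)
  omnibus_p <- NA_real_
  if (two && all_normal) {
    test_used <- "t"
    p <- stats::t.test(groups[[1]], groups[[2]], var.equal = var_equal)$p.value
    comparisons <- data.frame(group1 = nm[1], group2 = nm[2], p = p)
  } else if (two) {
    test_used <- "mann_whitney"
    p <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE)$p.value
    comparisons <- data.frame(group1 = nm[1], group2 = nm[2], p = p)
  } else if (all_normal) {
    test_used <- "anova_tukey"
    df <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(nm, ns), levels = nm))
    fit <- stats::aov(value ~ group, data = df)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    pairs_ <- strsplit(rownames(tk), "-", fixed = TRUE)
    comparisons <- data.frame(group1 = vapply(pairs_, `[`, "", 2),
                              group2 = vapply(pairs_, `[`, "", 1),
                              p = tk[, "p adj"])
  } else {
    test_used <- "kruskal_dunn"
    df <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(nm, ns), levels = nm))
    omnibus_p <- stats::kruskal.test(value ~ group, data = df)$p.value
    comparisons <- dunn_posthoc(df$value, df$group)
  }
  comparisons$stars <- star_label(comparisons$p)
  rownames(comparisons) <- NULL
  structure(list(test_used = test_used, normality = normality,
                 comparisons = comparisons, omnibus_p = omnibus_p,
                 n = ns, normal_min_n = normal_min_n),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> test:", x$test_used, "\n")
  print(x$comparisons)
  invisible(x)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie correction, p values
#' Bonferroni-adjusted for the number of comparisons (the convention of
#' common statistics packages).
#'
#' @param values numeric vector.
#' @param groups factor of the same length.
#' @return data.frame with `group1`, `group2`, `z`, `p` (adjusted).
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  out <- list()
  for (i in 1:(length(lv) - 1)) {
    for (j in (i + 1):length(lv)) {
      se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[i] + 1 / ni[j]))
      z <- (rbar[i] - rbar[j]) / se
      out[[length(out) + 1]] <- data.frame(group1 = lv[i], group2 = lv[j],
                                           z = unname(z),
                                           p = 2 * stats::pnorm(-abs(z)))
    }
  }
  res <- do.call(rbind, out)
  res$p <- pmin(res$p * nrow(res), 1)
  res
}

#' Percent-of-control normalization
#'
#' Expresses every value as a percent of the control group mean, so the
#' control group averages exactly 100%.
#'
#' @param values numeric vector to normalize.
#' @param control_values numeric vector of the control group.
#' @return `100 * values / mean(control_values)`.
#' @export
percent_of_control <- function(values, control_values) {
  cm <- mean(control_values)
  if (cm == 0) stop("control mean is zero")
  100 * values / cm
}
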