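# The gated statistical decision tree:
#   Shapiro-Wilk on residuals ->
#     normal:     2 groups t-test; >= 3 groups one-way ANOVA + Holm-Sidak
#     non-normal: 2 groups Mann-Whitney U; >= 3 groups Kruskal-Wallis + Dunn
# Significance flagged at p < 0.05.

#' Normality gate on group residuals
#'
#' Shapiro-Wilk test on residuals (values minus their group means). The gate
#' passes — the parametric branch is taken — when p > `alpha`. Degenerate
#' inputs (any group with fewer than 3 values, or zero residual variance)
#' force the nonparametric branch with a warning.
#'
#' @param groups list of numeric vectors.
#' @param alpha gate level (default 0.05).
#' @return list: `normal` (logical), `p_value`, `forced` (TRUE when the gate
#'   could not be tested and was forced nonparametric).
#' @export
residual_normality <- function(groups, alpha = 0.05) {
  abort_if(!is.list(groups) || length(groups) < 2,
           "`groups` must be a list of >= 2 numeric vectors")
  sizes <- lengths(groups)
  if (any(sizes < 3)) {
    warning("group with n < 3: normality gate forced nonparametric",
            call. = FALSE)
    return(list(normal = FALSE, p_value = NA_real_, forced = TRUE))
  }
  resid <- unlist(lapply(groups, function(g) g - mean(g)))
  if (sd(resid) == 0) {
    warning("zero residual variance: normality gate forced nonparametric",
            call. = FALSE)
    return(list(normal = FALSE, p_value = NA_real_, forced = TRUE))
  }
  p <- shapiro.test(resid)$p.value
  list(normal = p > alpha, p_value = p, forced = FALSE)
}

# step-down Sidak adjustment (Holm-Sidak): sorted ascending, the k-th raw p
# among m is adjusted to 1 - (1 - p)^(m - k + 1), with monotonicity enforced
sidak_stepdown <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Dunn's rank-based multiple contrasts after Kruskal-Wallis (tie-corrected),
# adjusted with the Sidak family correction to parallel the parametric
# branch.
dunn_posthoc <- function(groups, labels) {
  values <- unlist(groups)
  n <- lengths(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, rep(seq_along(groups), n), mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(length(groups), 2)
  res <- lapply(seq_len(ncol(combs)), function(ci) {
    i <- combs[1, ci]; j <- combs[2, ci]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z <- (rbar[i] - rbar[j]) / se
    data.frame(contrast = paste(labels[i], labels[j], sep = " vs "),
               statistic = unname(z),
               p_raw = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- sidak_stepdown(out$p_raw)
  out
}

# pairwise pooled-variance t contrasts after one-way ANOVA, Holm-Sidak
# adjusted; the pooled variance is the ANOVA within-group mean square
holm_sidak_posthoc <- function(groups, labels) {
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  df_w <- sum(n) - length(groups)
  ms_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    df_w
  combs <- utils::combn(length(groups), 2)
  res <- lapply(seq_len(ncol(combs)), function(ci) {
    i <- combs[1, ci]; j <- combs[2, ci]
    se <- sqrt(ms_w * (1 / n[i] + 1 / n[j]))
    tt <- (means[i] - means[j]) / se
    data.frame(contrast = paste(labels[i], labels[j], sep = " vs "),
               statistic = unname(tt),
               p_raw = 2 * pt(-abs(tt), df_w), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- sidak_stepdown(out$p_raw)
  out
}

#' Compare groups with the gated parametric/nonparametric decision tree
#'
#' Routes exactly per the study's decision tree using the
#' [residual_normality()] gate: with a normal gate, a (pooled-variance)
#' t-test for two groups or a one-way ANOVA with Holm-Sidak post hoc
#' contrasts for three or more; with a non-normal gate, a Mann-Whitney U
#' test for two groups or a Kruskal-Wallis test with Dunn's multiple
#' contrasts (Sidak-adjusted) for three or more.
#'
#' @param groups list of >= 2 numeric vectors.
#' @param labels group labels (default `names(groups)` or G1, G2, ...).
#' @param alpha significance level (default 0.05).
#' @param gate_alpha normality-gate level (default 0.05).
#' @return list of class `"stat_result"`: `test_name`, `statistic`, `df`,
#'   `p_value`, `significant`, `group_sizes`, `normality`
#'   (gate decision), `posthoc` (data.frame or NULL).
#' @export
compare_groups <- function(groups, labels = NULL, alpha = 0.05,
                           gate_alpha = 0.05) {
  abort_if(!is.list(groups) || length(groups) < 2,
           "need >= 2 groups")
  abort_if(any(lengths(groups) == 0), "groups must be non-empty")
  labels <- labels %||% names(groups) %||%
    paste0("G", seq_along(groups))
  gate <- residual_normality(groups, alpha = gate_alpha)
  k <- length(groups)

  if (gate$normal) {
    if (k == 2) {
      ht <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      res <- list(test_name = "t-test", statistic = unname(ht$statistic),
                  df = unname(ht$parameter), p_value = ht$p.value,
                  posthoc = NULL)
    } else {
      values <- unlist(groups)
      fac <- factor(rep(seq_len(k), lengths(groups)))
      fit <- aov(values ~ fac)
      tab <- anova(fit)
      res <- list(test_name = "one-way ANOVA",
                  statistic = tab$`F value`[1],
                  df = unname(tab$Df), p_value = tab$`Pr(>F)`[1],
                  posthoc = holm_sidak_posthoc(groups, labels))
    }
  } else {
    if (k == 2) {
      ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]]))
      res <- list(test_name = "Mann-Whitney U",
                  statistic = unname(ht$statistic), df = NA_real_,
                  p_value = ht$p.value, posthoc = NULL)
    } else {
      ht <- kruskal.test(groups)
      res <- list(test_name = "Kruskal-Wallis",
                  statistic = unname(ht$statistic),
                  df = unname(ht$parameter), p_value = ht$p.value,
                  posthoc = dunn_posthoc(groups, labels))
    }
  }
  structure(c(res, list(significant = res$p_value < alpha, alpha = alpha,
                        group_sizes = unname(lengths(groups)),
                        labels = labels, normality = gate)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s (groups n = %s; gate %s)\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) " *" else "",
              paste(x$group_sizes, collapse = "/"),
              if (x$normality$normal) "normal" else "non-normal"))
  if (!is.null(x$posthoc)) {
    cat("post hoc contrasts:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Percent change of a treated group relative to a reference
#'
#' `100 * (mean(reference) - mean(treated)) / mean(reference)`; positive
#' values are reductions relative to the reference.
#'
#' @param reference,treated numeric vectors.
#' @return percent change (scalar).
#' @examples
#' percent_change(rep(16, 5), rep(10.4, 5))  # 35
#' @export
percent_change <- function(reference, treated) {
  m <- mean(reference)
  abort_if(m == 0, "reference mean is zero")
  100 * (m - mean(treated)) / m
}
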