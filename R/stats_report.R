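# Cohort-level reporting: planned comparisons + descriptive summaries.

#' Summarize a cohort table with planned comparisons
#'
#' Runs one gated group comparison ([compare_groups()]) per entry of `plan`
#' and produces a descriptive table (n, mean, SEM, median, IQR per group).
#' Censored values (e.g. thresholds with no response at the 80 dB SPL
#' ceiling) are excluded from comparisons, with the excluded count reported
#' per comparison.
#'
#' @param table a `"cohort_table"` (see [simulate_cohort()]) or data.frame
#'   with columns `metric`, `value`, grouping columns, and optionally
#'   `censored`.
#' @param plan list of comparisons; each a list with `metric`, `factor`
#'   (grouping column, e.g. `"genotype"`), and optional `filter` (named list
#'   of column = value restrictions) and `name`.
#' @param alpha significance level (default 0.05).
#' @return list of class `"cohort_report"`: `results` (tibble, one row per
#'   comparison with the routed test, p-value, significance and censored
#'   count; post hoc tables in the `posthoc` list-column), `descriptives`
#'   (tibble per comparison x group).
#' @export
summarize_cohort <- function(table, plan = list(), alpha = 0.05) {
  abort_if(!is.data.frame(table), "`table` must be a data.frame")
  abort_if(!all(c("metric", "value") %in% names(table)),
           "`table` needs `metric` and `value` columns")
  if (!"censored" %in% names(table)) table$censored <- FALSE

  res_rows <- list(); desc_rows <- list()
  for (ci in seq_along(plan)) {
    cmp <- plan[[ci]]
    abort_if(is.null(cmp$metric) || is.null(cmp$factor),
             "each plan entry needs `metric` and `factor`")
    abort_if(!cmp$metric %in% table$metric,
             sprintf("plan references absent metric '%s'", cmp$metric))
    abort_if(!cmp$factor %in% names(table),
             sprintf("plan references absent factor column '%s'", cmp$factor))
    sub <- table[table$metric == cmp$metric, , drop = FALSE]
    for (f in names(cmp$filter %||% list()))
      sub <- sub[sub[[f]] == cmp$filter[[f]], , drop = FALSE]
    n_cens <- sum(sub$censored)
    sub_ok <- sub[!sub$censored, , drop = FALSE]
    groups <- split(sub_ok$value, sub_ok[[cmp$factor]])
    groups <- groups[lengths(groups) > 0]
    abort_if(length(groups) < 2,
             sprintf("comparison %d has fewer than 2 non-empty groups", ci))
    sr <- suppressWarnings(
      compare_groups(groups, labels = names(groups), alpha = alpha))
    cmp_name <- cmp$name %||%
      sprintf("%s by %s%s", cmp$metric, cmp$factor,
              if (length(cmp$filter %||% list()))
                paste0(" [", paste(names(cmp$filter), unlist(cmp$filter),
                                   sep = "=", collapse = ", "), "]")
              else "")
    res_rows[[ci]] <- tibble::tibble(
      comparison = cmp_name, metric = cmp$metric, factor = cmp$factor,
      test_name = sr$test_name, statistic = sr$statistic,
      p_value = sr$p_value, significant = sr$significant,
      gate_normal = sr$normality$normal,
      n_censored_excluded = n_cens,
      posthoc = list(sr$posthoc))
    desc_rows[[ci]] <- do.call(rbind, lapply(names(groups), function(g) {
      v <- groups[[g]]
      data.frame(comparison = cmp_name, group = g, n = length(v),
                 mean = mean(v), sem = sd(v) / sqrt(length(v)),
                 median = median(v),
                 iqr_lo = unname(quantile(v, 0.25)),
                 iqr_hi = unname(quantile(v, 0.75)),
                 stringsAsFactors = FALSE)
    }))
  }

  # descriptives for every metric when no plan is given
  if (length(plan) == 0) {
    sub_ok <- table[!table$censored, , drop = FALSE]
    key <- interaction(sub_ok$metric, drop = TRUE)
    desc_rows <- lapply(split(sub_ok, key), function(s) {
      data.frame(comparison = NA_character_, group = s$metric[1],
                 n = nrow(s), mean = mean(s$value),
                 sem = sd(s$value) / sqrt(nrow(s)),
                 median = median(s$value),
                 iqr_lo = unname(quantile(s$value, 0.25)),
                 iqr_hi = unname(quantile(s$value, 0.75)),
                 stringsAsFactors = FALSE)
    })
  }

  structure(list(
    results = if (length(res_rows)) do.call(rbind, res_rows) else
      tibble::tibble(),
    descriptives = tibble::as_tibble(do.call(rbind, desc_rows))),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  if (nrow(x$results)) {
    cat("Planned comparisons:\n")
    print(x$results[, c("comparison", "test_name", "p_value", "significant")])
  }
  cat("\nDescriptives:\n")
  print(x$descriptives)
  invisible(x)
}
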