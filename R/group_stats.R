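#' Descriptive summary of one group of values
#'
#' Mean, standard error and the five-number summary used for
#' box-and-whisker displays: the box spans the 25th-75th percentiles
#' (linear-interpolation quantiles, type 7), the median is marked and the
#' whiskers span the sample range.
#'
#' @param values Numeric vector (length >= 1).
#' @param label Group label to attach.
#' @return One-row tibble: `label`, `n`, `mean`, `sem` (`NA` when n = 1),
#'   `min`, `q1`, `median`, `q3`, `max`.
#' @export
group_summary <- function(values, label = "group") {
  if (length(values) == 0 || all(is.na(values))) abort("empty value list")
  values <- values[!is.na(values)]
  q <- unname(quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  tibble(
    label = label,
    n = length(values),
    mean = mean(values),
    sem = if (length(values) >= 2) sd(values) / sqrt(length(values)) else NA_real_,
    min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5]
  )
}

#' Map a p-value to a significance annotation
#'
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001, otherwise
#' `ns`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Two-tailed unpaired t-test
#'
#' Student's two-sample t-test with pooled variance (the classic
#' "unpaired t-test"; `df = na + nb - 2`), two-tailed. A Welch
#' (unequal-variance) version is available behind `welch = TRUE`. When the
#' pooled variance is zero the statistic degenerates: equal means give
#' `t = 0, p = 1`; unequal means are flagged (`degenerate = TRUE`) with an
#' infinite statistic.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch approximation instead of pooled variance?
#' @return One-row tibble: `t`, `df`, `p`, `stars`, `degenerate`.
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
unpaired_t_test <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("each group needs at least 2 values")
  if (welch) {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    return(tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                  p = ht$p.value, stars = p_stars(ht$p.value),
                  degenerate = FALSE))
  }
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (diff == 0) {
      return(tibble(t = 0, df = df, p = 1, stars = "ns", degenerate = FALSE))
    }
    return(tibble(t = sign(diff) * Inf, df = df, p = 0, stars = "***",
                  degenerate = TRUE))
  }
  tstat <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), df)
  tibble(t = tstat, df = df, p = p, stars = p_stars(p), degenerate = FALSE)
}

#' Compare a feature across organelle groups
#'
#' Reproduces the box-plot-and-t-test comparison of a physicochemical
#' feature across localisation groups: a [group_summary()] per group and a
#' two-tailed unpaired t-test (pooled variance by default) for every
#' unordered pair of groups, with significance stars. No multiple-testing
#' correction is applied, mirroring per-pair reporting. Groups are ordered
#' PO, PO_MITO, MITO, ER (then any others alphabetically).
#'
#' @param data Data frame with a grouping column and the feature column.
#' @param feature Name of the feature column (string), e.g.
#'   `"tail_charge"`.
#' @param group_col Name of the grouping column (default `"label"`, with
#'   `"location"` used automatically when present instead).
#' @param welch Use Welch's test instead of pooled variance?
#' @return Object of class `ta_group_comparison`: list with `summaries`
#'   (one row per group), `tests` (one row per pair: `group_a`, `group_b`,
#'   `t`, `df`, `p`, `stars`, `degenerate`), `feature`, and `data` (group,
#'   value pairs). Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
compare_groups <- function(data, feature, group_col = NULL, welch = FALSE) {
  data <- as_tibble(data)
  group_col <- group_col %||%
    intersect(c("label", "location"), names(data))[1]
  if (is.na(group_col) || !group_col %in% names(data)) {
    abort("no grouping column found (expected 'label' or 'location')")
  }
  if (!feature %in% names(data)) {
    abort(paste0("unknown feature column: ", feature))
  }
  vals <- tibble(group = as.character(data[[group_col]]),
                 value = data[[feature]])
  vals <- vals[!is.na(vals$value), ]
  groups <- unique(vals$group)
  canonical <- c("PO", "PO_MITO", "MITO", "ER")
  groups <- c(intersect(canonical, groups),
              sort(setdiff(groups, canonical)))
  if (length(groups) < 2) {
    abort("at least 2 groups are required for a comparison")
  }
  summaries <- purrr::map_dfr(groups, function(g) {
    group_summary(vals$value[vals$group == g], label = g)
  })
  pairs <- utils::combn(groups, 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    res <- unpaired_t_test(vals$value[vals$group == ga],
                           vals$value[vals$group == gb], welch = welch)
    dplyr::bind_cols(tibble(group_a = ga, group_b = gb), res)
  })
  structure(
    list(summaries = summaries, tests = tests, feature = feature,
         data = vals),
    class = "ta_group_comparison"
  )
}

#' @export
print.ta_group_comparison <- function(x, ...) {
  cat("Group comparison of", x$feature, "\n\nSummaries:\n")
  print(x$summaries)
  cat("\nPairwise unpaired t-tests:\n")
  print(x$tests)
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `ta_group_comparison` object.
#' @param ... Unused.
#' @export
tidy.ta_group_comparison <- function(x, ...) {
  x$tests
}

#' @rdname compare_groups
#' @export
glance.ta_group_comparison <- function(x, ...) {
  tibble(feature = x$feature, n_groups = nrow(x$summaries),
         n_total = sum(x$summaries$n),
         n_significant = sum(x$tests$p < 0.05))
}
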