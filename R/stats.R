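# Rank-based group comparison as applied to per-fish severities: the
# Kruskal-Wallis omnibus test, Dunn's pairwise post hoc on pooled
# mid-ranks with Bonferroni adjustment, and the Mann-Whitney U test for
# two-group comparisons. The omnibus and two-sample tests are delegated to
# the standard stats implementations; Dunn's test is implemented here
# (1964 form, pooled tie correction with the 12(N-1) denominator). A
# parametric one-way ANOVA, when wanted, is stats::oneway.test /
# stats::aov applied to the same long-format data; it is not re-wrapped.

validate_groups <- function(values, groups, min_groups = 2) {
  stopifnot(length(values) == length(groups))
  if (any(!is.finite(values))) nq_error("nq_value_error", "non-finite values")
  g <- factor(groups)
  if (nlevels(g) < min_groups)
    nq_error("nq_value_error", sprintf("need at least %d groups", min_groups))
  if (any(table(g) == 0)) nq_error("nq_value_error", "empty group")
  g
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square upper-tail p-value on
#' `groups - 1` degrees of freedom (mid-ranks for ties). The degenerate
#' all-values-identical case returns H = 0, p = 1.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @return list (class `nq_stat`) with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- validate_groups(values, groups)
  if (length(values) < 3) nq_error("nq_value_error", "need at least 3 observations")
  if (length(unique(values)) == 1) {
    return(structure(list(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                          method = "Kruskal-Wallis H"), class = "nq_stat"))
  }
  kt <- kruskal.test(values, g)
  structure(list(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value,
                 method = "Kruskal-Wallis H"),
            class = "nq_stat")
}

#' Dunn's pairwise post hoc test with Bonferroni adjustment
#'
#' For each pair (i, j), `z = (Ri - Rj) / sqrt((N(N+1)/12 -
#' sum(t^3 - t) / (12(N-1))) * (1/ni + 1/nj))` on pooled mid-ranks, where
#' the tie sum runs over tie groups; two-sided normal p-values, adjusted
#' by Bonferroni over the number of pairs (capped at 1).
#'
#' @inheritParams kruskal_wallis
#' @param adjust p-value adjustment method (default `"bonferroni"`; any
#'   [stats::p.adjust()] method).
#' @return data.frame (group_a, group_b, z, p_raw, p_adjusted).
#' @export
dunn_posthoc <- function(values, groups, adjust = "bonferroni") {
  g <- validate_groups(values, groups)
  N <- length(values)
  r <- rank(values)  # mid-ranks
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  var_core <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  labs <- levels(g)
  pairs <- utils::combn(seq_along(labs), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_core * (1 / n[i] + 1 / n[j]))
    z[k] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p_raw[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group_a = labs[pairs[1, ]], group_b = labs[pairs[2, ]],
             z = z, p_raw = p_raw,
             p_adjusted = p.adjust(p_raw, method = adjust))
}

#' Mann-Whitney U test for two samples
#'
#' U statistic on mid-ranks. The p-value is exact (full enumeration of
#' rank arrangements) when `length(a) * length(b) <= 400` and the pooled
#' data have no ties; otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param a,b numeric samples (non-empty).
#' @return list (class `nq_stat`) with `statistic` (U for sample `a`),
#'   `p_value`, `exact` flag.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) nq_error("nq_value_error", "empty input sample")
  if (any(!is.finite(c(a, b)))) nq_error("nq_value_error", "non-finite values")
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !has_ties && length(a) * length(b) <= 400
  wt <- suppressWarnings(wilcox.test(a, b, exact = use_exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 exact = use_exact,
                 method = "Mann-Whitney U"),
            class = "nq_stat")
}

#' @export
print.nq_stat <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      if (!is.null(x$df)) paste0(", df = ", x$df),
      ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}
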