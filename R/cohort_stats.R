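test_result <- function(test_name, statistic, p_value, n, method_detail,
                        extra = list()) {
  structure(c(list(test_name = test_name, statistic = unname(statistic),
                   p_value = unname(p_value), n = n,
                   method_detail = method_detail), extra),
            class = "drg_test_result")
}

#' @export
print.drg_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s)\n", x$test_name,
              x$statistic, x$p_value, x$method_detail))
  invisible(x)
}

#' Normality screen (Kolmogorov-Smirnov with Lilliefors correction)
#'
#' One-sample Kolmogorov-Smirnov statistic against a normal law with
#' mean and SD estimated from the sample; because the parameters are
#' estimated, the p-value uses the Lilliefors correction (a plain KS
#' p-value would be anticonservative).
#'
#' @param values Numeric vector, n >= 5.
#' @return A test result with the KS D statistic and Lilliefors p-value.
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) stop("need n >= 5")
  if (stats::var(values) == 0) stop("zero variance: normality undefined")
  lt <- nortest::lillie.test(values)
  test_result("Kolmogorov-Smirnov (Lilliefors)", lt$statistic, lt$p.value,
              length(values), "parameters estimated from sample")
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test with midrank ties. The p-value is exact (full
#' enumeration of the U distribution) when the combined sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' tie and continuity corrections is used. A comparison with zero total
#' rank-variance (all observations identical) is reported as p = 1.
#'
#' @param group_a,group_b Numeric vectors.
#' @param alternative \code{"two.sided"}, \code{"less"} or
#'   \code{"greater"}.
#' @param exact Force the exact (\code{TRUE}) or asymptotic (\code{FALSE})
#'   path; \code{NULL} (default) applies the automatic rule. The exact path
#'   requires tie-free data.
#' @return A test result; the statistic is U for \code{group_a}.
#' @export
mann_whitney_u <- function(group_a, group_b, alternative = "two.sided",
                           exact = NULL) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- if (is.null(exact)) (na + nb) <= 12L && !ties else exact
  if (use_exact && ties) stop("exact path requires tie-free data")
  if (stats::var(r) == 0) {
    return(test_result("Mann-Whitney U", u, 1, c(na, nb),
                       "degenerate: all observations tied",
                       list(exact = FALSE)))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    group_a, group_b, alternative = alternative,
    exact = use_exact, correct = TRUE))
  test_result("Mann-Whitney U", u, wt$p.value, c(na, nb),
              if (use_exact) "exact (enumeration)"
              else "normal approximation, tie + continuity corrections",
              list(exact = use_exact))
}

# exact signed-rank distribution over 2*midranks (integers), by convolution
wsr_exact_pvalue <- function(ranks, v_obs, alternative) {
  r2 <- as.integer(round(2 * ranks))
  dist <- c(1)                       # distribution of 2V, offset 0
  for (r in r2) dist <- c(dist, numeric(r)) + c(numeric(r), dist)
  dist <- dist / sum(dist)
  v2 <- round(2 * v_obs)
  support <- seq_along(dist) - 1L
  p_le <- sum(dist[support <= v2 + 1e-9])
  p_ge <- sum(dist[support >= v2 - 1e-9])
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le,
         greater = p_ge)
}

#' Wilcoxon signed-rank test
#'
#' Paired-sample signed-rank test. Zero differences are dropped (the
#' original Wilcoxon convention) and reported; the p-value is exact
#' (convolution of the signed-rank distribution, valid with tied absolute
#' differences through midranks) when at most 12 non-zero differences
#' remain, otherwise a normal approximation with tie and continuity
#' corrections is used. If all differences are zero the result is the
#' degenerate p = 1 with a flag.
#'
#' @param paired_a,paired_b Paired numeric vectors.
#' @param alternative Alternative hypothesis.
#' @param exact Force the exact (\code{TRUE}) or asymptotic (\code{FALSE})
#'   path; \code{NULL} applies the automatic rule.
#' @return A test result; the statistic is V, the positive-rank sum.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 alternative = "two.sided", exact = NULL) {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must have equal length")
  d <- paired_a - paired_b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n_dropped <- length(d) - length(nz)
  if (length(nz) == 0L)
    return(test_result("Wilcoxon signed-rank", 0, 1, 0,
                       "degenerate: all differences zero",
                       list(degenerate = TRUE, n_zero_dropped = n_dropped)))
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  use_exact <- if (is.null(exact)) length(nz) <= 12L else exact
  p <- if (use_exact) {
    wsr_exact_pvalue(r, v, alternative)
  } else {
    suppressWarnings(stats::wilcox.test(
      nz, alternative = alternative, exact = FALSE, correct = TRUE))$p.value
  }
  test_result("Wilcoxon signed-rank", v, p, length(nz),
              paste0(if (use_exact) "exact (enumeration)"
                     else "normal approximation, tie + continuity corrections",
                     "; ", n_dropped, " zero differences dropped"),
              list(exact = use_exact, degenerate = FALSE,
                   n_zero_dropped = n_dropped))
}

#' Categorical association test with automatic method choice
#'
#' Pearson chi-squared test without continuity correction, switching to
#' Fisher's exact test (two-sided, hypergeometric tail summation) when the
#' table is 2x2 and any expected cell count is below 5. The chosen method
#' is recorded in the result.
#'
#' @param counts Matrix of non-negative integer counts.
#' @return A test result.
#' @export
categorical_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  use_fisher <- all(dim(counts) == c(2L, 2L)) && any(expected < 5)
  if (use_fisher) {
    ft <- stats::fisher.test(counts)
    test_result("Fisher exact", NA_real_, ft$p.value, sum(counts),
                "2x2 with expected count < 5",
                list(method = "fisher"))
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    test_result("Pearson chi-squared", ct$statistic, ct$p.value, sum(counts),
                "no continuity correction",
                list(method = "chisq", df = unname(ct$parameter)))
  }
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; p-value from the t approximation with
#' n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @return A test result with statistic rho.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need n >= 4 pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("zero rank variance")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  test_result("Spearman rho", ct$estimate, ct$p.value, length(x),
              "t approximation, n - 2 df")
}

#' Signed percent difference
#'
#' \code{100 * (a - b) / b}, the convention used to report group contrasts
#' such as "+9.4\%" for medians 102.4 vs 93.6 ms.
#'
#' @param value_a,value_b Numeric; \code{value_b} must be positive.
#' @param digits Decimal places for rounding (default 1, as reported).
#' @return Signed percent difference, rounded.
#' @export
percent_difference <- function(value_a, value_b, digits = 1) {
  if (any(value_b <= 0)) stop("value_b must be > 0")
  round(100 * (value_a - value_b) / value_b, digits)
}

iqr_string <- function(x, digits = 1) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  sprintf("%.*f (%.*f-%.*f)", digits, q[2], digits, q[1], digits, q[3])
}

#' Stratified descriptive table with per-row tests
#'
#' Builds a two-group descriptive table in the median (IQR) / n (percent)
#' style: numeric variables are summarised as type-7 median and
#' interquartile range and compared by the Mann-Whitney U test; logical or
#' two-level variables as count (percent) and compared by the automatic
#' chi-squared / Fisher rule. For \code{grouping = "mutation_class"} the
#' VUS subjects are excluded so the contrast is classical vs nonclassical.
#'
#' @param subjects Subject-level data frame (as from
#'   \code{\link{generate_cohort}} merged with \code{\link{summarise_cohort}}
#'   output).
#' @param grouping \code{"sex"} or \code{"mutation_class"}.
#' @param variables Variables to tabulate; defaults to all numeric and
#'   logical columns except identifiers.
#' @return Data frame: one row per variable with per-group summaries, the
#'   p-value and the test used.
#' @export
build_cohort_tables <- function(subjects,
                                grouping = c("mutation_class", "sex"),
                                variables = NULL) {
  grouping <- match.arg(grouping)
  if (grouping == "mutation_class") {
    subjects <- subjects[subjects$mutation_class != "VUS", , drop = FALSE]
    glab <- c("classical", "nonclassical")
  } else {
    glab <- c("male", "female")
  }
  g <- subjects[[grouping]]
  if (any(table(factor(g, levels = glab)) == 0))
    stop("a group has no subjects")
  if (is.null(variables)) {
    variables <- names(subjects)[vapply(subjects, function(col)
      is.numeric(col) || is.logical(col), logical(1))]
    variables <- setdiff(variables, c("subject_id"))
  }
  rows <- lapply(variables, function(v) {
    x <- subjects[[v]]
    a <- x[g == glab[1]]; b <- x[g == glab[2]]
    if (is.logical(x)) {
      tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
      tr <- categorical_test(tab)
      data.frame(variable = v,
                 group1 = sprintf("%d (%.1f%%)", sum(a),
                                  100 * mean(a)),
                 group2 = sprintf("%d (%.1f%%)", sum(b),
                                  100 * mean(b)),
                 p_value = tr$p_value, test = tr$test_name,
                 stringsAsFactors = FALSE)
    } else {
      tr <- if (stats::var(c(a, b)) == 0)
        test_result("Mann-Whitney U", NA_real_, 1, c(length(a), length(b)),
                    "constant variable")
      else mann_whitney_u(a, b)
      data.frame(variable = v, group1 = iqr_string(a),
                 group2 = iqr_string(b),
                 p_value = tr$p_value, test = tr$test_name,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0(glab, "_n", table(factor(g, levels = glab)))
  attr(out, "grouping") <- grouping
  attr(out, "group_n") <- as.integer(table(factor(g, levels = glab)))
  out
}
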