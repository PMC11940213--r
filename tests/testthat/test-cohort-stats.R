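test_that("normality screen calibrates on normal and rejects lognormal data", {
  set.seed(201)
  p_norm <- vapply(1:100, function(i)
    ks_normality(rnorm(1000))$p_value, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_ln <- vapply(1:50, function(i)
    ks_normality(rlnorm(1000))$p_value, numeric(1))
  expect_true(all(p_ln < 0.05))
  expect_error(ks_normality(rep(3, 20)), "variance")
  expect_error(ks_normality(1:4), "n >= 5")
})

test_that("Mann-Whitney U exact path matches enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)

  set.seed(202)
  for (i in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.5)
    expect_equal(mann_whitney_u(a, b)$p_value, mwu_enum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney degenerate and asymptotic paths behave", {
  r <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$p_value, 1)
  set.seed(203)
  gaps <- vapply(1:100, function(i) {
    a <- rnorm(6); b <- rnorm(6)
    abs(mann_whitney_u(a, b, exact = FALSE)$p_value -
          mann_whitney_u(a, b, exact = TRUE)$p_value)
  }, numeric(1))
  expect_lt(max(gaps), 0.02)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Wilcoxon signed-rank exact path matches sign-pattern enumeration", {
  a <- c(3.1, 4.2, 1.7, 8.8, 2.2, 6.1, 0.4, 5.5)
  r <- wilcoxon_signed_rank(a + 1, a)
  expect_equal(r$p_value, 2 / 2^8)
  expect_true(r$exact)

  set.seed(204)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    x <- rnorm(n); y <- rnorm(n, 0.3)
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, wsr_enum_p(x - y),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon zero-difference and asymptotic conventions", {
  a <- c(1, 2, 3, 4, 5)
  r <- wilcoxon_signed_rank(a, a)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  r2 <- wilcoxon_signed_rank(c(1, 2, 3, 4.5), c(1, 2, 2, 4))
  expect_equal(r2$n_zero_dropped, 2L)

  set.seed(205)
  gaps <- vapply(1:100, function(i) {
    x <- rnorm(12); y <- rnorm(12, 0.2)
    abs(wilcoxon_signed_rank(x, y, exact = FALSE)$p_value -
          wilcoxon_signed_rank(x, y, exact = TRUE)$p_value)
  }, numeric(1))
  expect_lt(max(gaps), 0.02)
})

test_that("categorical test picks chi-squared or Fisher appropriately", {
  r <- categorical_test(matrix(10, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$method, "chisq")

  r2 <- categorical_test(rbind(c(5, 0), c(0, 5)))
  expect_equal(r2$method, "fisher")
  expect_equal(r2$p_value, 2 / choose(10, 5), tolerance = 1e-9)

  set.seed(206)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 2), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (!any(exp_cells < 5)) next
    expect_equal(categorical_test(tab)$p_value, fisher_enum_p(tab),
                 tolerance = 1e-9)
  }
  expect_error(categorical_test(rbind(c(1, -2), c(3, 4))), "non-negative")
  expect_error(categorical_test(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("Spearman rho matches the rank-then-Pearson oracle", {
  x <- 1:10
  expect_equal(spearman_rho(x, x + 0.5)$statistic, 1)
  expect_equal(spearman_rho(x, rev(x))$statistic, -1)

  set.seed(207)
  for (i in 1:10) {
    x <- sample(1:8, 20, replace = TRUE)   # ties on both sides
    y <- x + sample(1:4, 20, replace = TRUE)
    r <- spearman_rho(x, y)
    o <- spearman_oracle(x, y)
    expect_equal(r$statistic, o$rho, tolerance = 1e-12)
    expect_equal(r$p_value, o$p, tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 10), rnorm(10)), "rank variance")
})

test_that("percent differences reproduce the reported contrasts", {
  expect_equal(percent_difference(102.4, 93.6), 9.4)
  expect_equal(percent_difference(96.8, 92.9), 4.2)
  expect_equal(percent_difference(1323.9, 905.4), 46.2)
  expect_equal(percent_difference(1342.1, 987.8), 35.9)
  expect_equal(percent_difference(7, 7), 0)
  expect_error(percent_difference(5, 0), "value_b")
})

test_that("cohort tables stratify, test and summarise per row", {
  co <- generate_cohort(cohort_spec(seed = 2))
  cons <- average_readers(co$samples)
  subjects <- merge(co$subjects, summarise_cohort(cons), by = "subject_id")

  tab <- build_cohort_tables(subjects, "mutation_class")
  expect_equal(attr(tab, "group_n"), c(18L, 54L))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))

  # constant variable: p = 1 row
  subjects$const <- 5
  tabc <- build_cohort_tables(subjects, "sex", variables = "const")
  expect_equal(tabc$p_value, 1)

  # medians in the table equal a sort-based percentile oracle
  med_oracle <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
  }
  cl <- subjects$drg_t2_ms[subjects$mutation_class == "classical"]
  row <- build_cohort_tables(subjects, "mutation_class",
                             variables = "drg_t2_ms")
  printed <- as.numeric(sub(" .*", "", row[[2]]))
  expect_equal(printed, round(med_oracle(cl), 1))
})
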