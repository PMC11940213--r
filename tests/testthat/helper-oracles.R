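# Independent brute-force oracles used to validate the statistical engine
# and simulators. These deliberately avoid the code paths they check.

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mwu_enum_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  lo <- mean(u_all <= u_obs + 1e-9)
  hi <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# exact two-sided Wilcoxon signed-rank p by enumeration of sign patterns
wsr_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  lo <- mean(v_all <= v_obs + 1e-9)
  hi <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# two-sided Fisher exact p for a 2x2 table by enumeration over fixed margins
fisher_enum_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  p_of <- function(a) {
    stats::dhyper(a, rs[1], rs[2], cs[1])
  }
  p_obs <- p_of(tab[1, 1])
  a_range <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- vapply(a_range, p_of, numeric(1))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ICC(2,1) and its mean squares from explicit sums of squares
icc_ms_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Spearman rho as Pearson on midranks, p via the t approximation
spearman_oracle <- function(x, y) {
  r <- stats::cor(rank(x), rank(y))
  n <- length(x)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * stats::pt(-abs(tval), n - 2))
}

# small DRG geometry that fits a 16x16x8 grid, for fast pipeline tests
tiny_drg_defs <- function(t2_l5_ms = 93, t2_s1_ms = 97) {
  d <- drgt2map::default_drg_defs(t2_l5_ms, t2_s1_ms)
  d$cx_mm <- c(6, 18, 6, 18)
  d$cy_mm <- c(6, 6, 18, 18)
  d$cz_mm <- 7.2
  d[, c("ax_mm", "ay_mm")] <- 3.4
  d$az_mm <- 3.4
  d
}

tiny_phantom_spec <- function(..., drg_defs = tiny_drg_defs()) {
  drgt2map::phantom_spec(grid_shape = c(16L, 16L, 8L),
                         drg_defs = drg_defs, ...)
}
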