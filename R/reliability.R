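koo_li_bin <- function(icc) {
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good"
  else "excellent"
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1): single-measurement absolute agreement under a two-way random
#' effects model, computed from the two-way ANOVA mean squares
#' (between-targets, between-raters, error) with the F-based 95% confidence
#' interval of McGraw and Wong (Satterthwaite denominator degrees of
#' freedom). The point estimate is interpreted on the conventional
#' poor / moderate / good / excellent bins with cut points 0.5, 0.75 and
#' 0.9.
#'
#' @param ratings Numeric matrix, targets in rows and raters in columns.
#'   Rows containing missing values are dropped (listwise deletion) and
#'   counted in the result.
#' @param conf_level Confidence level for the interval.
#' @return An object of class \code{icc_result}: \code{icc}, \code{ci_low},
#'   \code{ci_high}, \code{model_descriptor}, \code{n_targets},
#'   \code{n_raters}, \code{n_dropped}, \code{interpretation},
#'   \code{small_sample} (flagged when fewer than 5 targets remain).
#' @export
icc_two_way_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2L) stop("need at least 2 raters")
  complete <- stats::complete.cases(ratings)
  n_dropped <- sum(!complete)
  ratings <- ratings[complete, , drop = FALSE]
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L) stop("need at least 2 complete targets")
  small <- n < 5L
  if (stats::var(as.vector(ratings)) == 0)
    stop("ratings are constant: ICC is undefined")

  ms <- icc_mean_squares(ratings)
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # perfect agreement: aov returns float-noise mean squares (~1e-27), so
  # test the error terms relative to the between-target scale
  if (mse <= 1e-12 * msr && msc <= 1e-12 * msr) {
    return(structure(list(icc = 1, ci_low = 1, ci_high = 1,
                          model_descriptor =
                            "two-way random, absolute agreement, single measurement",
                          n_targets = n, n_raters = k, n_dropped = n_dropped,
                          interpretation = koo_li_bin(1),
                          small_sample = small, conf_level = conf_level),
                     class = "icc_result"))
  }

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)

  structure(list(icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
                 model_descriptor =
                   "two-way random, absolute agreement, single measurement",
                 n_targets = n, n_raters = k, n_dropped = n_dropped,
                 interpretation = koo_li_bin(icc),
                 small_sample = small, conf_level = conf_level),
            class = "icc_result")
}

# two-way ANOVA mean squares via stats::aov (targets and raters as factors)
icc_mean_squares <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  d <- data.frame(value = as.vector(ratings),
                  target = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ target + rater, data = d))[[1]]
  list(msr = tab["target", "Mean Sq"], msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

#' Consistency ICC (two-way mixed, single measurement)
#'
#' ICC(3,1) point estimate, provided for contrast with the
#' absolute-agreement form: systematic rater offsets do not lower
#' consistency but do lower agreement.
#'
#' @inheritParams icc_two_way_agreement
#' @return The ICC(3,1) point estimate.
#' @export
icc_consistency <- function(ratings) {
  ratings <- as.matrix(ratings)
  ratings <- ratings[stats::complete.cases(ratings), , drop = FALSE]
  k <- ncol(ratings)
  ms <- icc_mean_squares(ratings)
  (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
}

#' Test-retest reliability ICC
#'
#' Treats the two visits as the two "raters" of an absolute-agreement
#' ICC(2,1) on paired per-subject summaries.
#'
#' @param visit1,visit2 Paired numeric vectors of per-subject summaries.
#' @return An \code{icc_result}.
#' @export
test_retest_icc <- function(visit1, visit2) {
  if (length(visit1) != length(visit2))
    stop("visit1 and visit2 must be paired (equal length)")
  if (length(visit1) < 2L) stop("need at least 2 paired subjects")
  icc_two_way_agreement(cbind(visit1 = visit1, visit2 = visit2))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f (%d%% CI %.3f-%.3f), %s agreement\n",
              x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$interpretation))
  cat(sprintf("  %s; %d targets x %d raters\n", x$model_descriptor,
              x$n_targets, x$n_raters))
  invisible(x)
}
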