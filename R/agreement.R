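#' Paired measurements from two methods
#'
#' @param method_a,method_b numeric vectors of equal length (`n >= 2`), one
#'   value per scan from each measurement method.
#' @return An object of class `paired_measurements`.
#' @export
paired_measurements <- function(method_a, method_b) {
  if (length(method_a) != length(method_b))
    stop("paired measurements must have equal lengths")
  if (length(method_a) < 2L)
    stop("at least 2 pairs are required")
  if (anyNA(method_a) || anyNA(method_b))
    stop("paired measurements contain missing values")
  structure(list(method_a = as.numeric(method_a),
                 method_b = as.numeric(method_b),
                 n = length(method_a)),
            class = "paired_measurements")
}

#' Bland-Altman agreement analysis
#'
#' Method-agreement assessment from the paired differences `a - b`: their
#' mean (bias), sample standard deviation (reported as the measurement
#' error), and limits of agreement at mean difference +/- 2 SD.  The report
#' also carries the Pearson correlation and the single-measurement,
#' absolute-agreement intraclass correlation ICC(2,1) for the same pairs
#' (both `NA` when `n < 3`), plus the (mean, difference) points for
#' plotting.
#'
#' @param pairs a [paired_measurements] object.
#' @return An object of class `agreement_report` with fields
#'   `mean_difference`, `sd_difference`, `lower_limit`, `upper_limit`,
#'   `measurement_error`, `pearson_r`, `icc`, `n`, and a data frame
#'   `points` with columns `mean` and `difference`.
#' @seealso [pearson_r()], [icc_agreement()]
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  diffs <- pairs$method_a - pairs$method_b
  means <- (pairs$method_a + pairs$method_b) / 2
  bias <- mean(diffs)
  s <- sd(diffs)                      # sample SD, n - 1 denominator
  r <- if (pairs$n >= 3 && sd(pairs$method_a) > 0 && sd(pairs$method_b) > 0)
    pearson_r(pairs) else NA_real_
  ic <- if (pairs$n >= 3) icc_agreement(pairs) else NA_real_
  structure(list(mean_difference = bias, sd_difference = s,
                 lower_limit = bias - 2 * s, upper_limit = bias + 2 * s,
                 measurement_error = s, pearson_r = r, icc = ic,
                 n = pairs$n,
                 points = data.frame(mean = means, difference = diffs)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  mean difference    %8.3f\n", x$mean_difference))
  cat(sprintf("  SD of differences  %8.3f  (reported as measurement error)\n",
              x$sd_difference))
  cat(sprintf("  limits (+/- 2 SD)  [%.3f, %.3f]\n", x$lower_limit, x$upper_limit))
  cat(sprintf("  Pearson r          %8.3f\n", x$pearson_r))
  cat(sprintf("  ICC(2,1)           %8.3f\n", x$icc))
  invisible(x)
}

#' Pearson product-moment correlation of paired methods
#'
#' @param pairs a [paired_measurements] object with `n >= 3` and nonzero
#'   variance in both methods.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  if (pairs$n < 3) stop("Pearson correlation requires n >= 3 pairs")
  if (sd(pairs$method_a) == 0 || sd(pairs$method_b) == 0)
    stop("correlation undefined: one method has zero variance")
  cor(pairs$method_a, pairs$method_b)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC,
#' assembled from the two-way ANOVA mean squares (subjects crossed with
#' methods).  Unlike Pearson's r it penalizes a systematic offset between
#' methods.  When every value is identical the ICC is returned as 1 by
#' convention (with a message).
#'
#' @param pairs a [paired_measurements] object with `n >= 3`.
#' @return ICC estimate (`<= 1`; can be negative for discordant pairs).
#' @export
icc_agreement <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  n <- pairs$n
  if (n < 3) stop("ICC requires n >= 3 pairs")
  vals <- c(pairs$method_a, pairs$method_b)
  if (all(vals == vals[1])) {
    message("all measurements identical; ICC = 1 by convention")
    return(1)
  }
  k <- 2
  df <- data.frame(value = vals,
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(c("a", "b"), each = n)))
  ms <- summary(aov(value ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]  # between subjects
  msc <- ms[2]  # between raters
  mse <- ms[3]  # residual
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with the p-value from the large-sample
#' t approximation (two-sided).
#'
#' @param x,y numeric vectors of equal length, `n >= 4`, neither constant.
#' @return List with elements `rho` and `p_value`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal lengths")
  if (length(x) < 4) stop("Spearman correlation requires n >= 4")
  if (anyNA(x) || anyNA(y)) stop("inputs contain missing values")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined: constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, p_value = ct$p.value)
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided comparison of two independent groups.  The U statistic is
#' computed from midranks; the p-value is exact (enumeration over rank
#' assignments) when `n_a * n_b <= 400` and there are no ties, otherwise the
#' normal approximation with tie and continuity corrections is used.
#'
#' @param group_a,group_b nonempty numeric vectors.
#' @return List with elements `u_statistic` (U for `group_a`), `p_value`,
#'   and `exact` (logical, whether the exact distribution was used).
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty")
  if (anyNA(group_a) || anyNA(group_b)) stop("inputs contain missing values")
  na <- length(group_a); nb <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  use_exact <- (na * nb <= 400) && !ties
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = use_exact,
                                     correct = TRUE))
  list(u_statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact)
}
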