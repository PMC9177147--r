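#' Group-level one-sample t-test with effect size
#'
#' Two-tailed one-sample Student t-test against `mu`, reported with Cohen's
#' d_z (`t / sqrt(n)`), the 95% confidence interval of the mean, and degrees
#' of freedom `n - 1`. This is the group test used for every scalar summary
#' statistic in the package (mean pattern correlations, contrasts, ...).
#'
#' @param values numeric vector, one value per subject (n >= 2).
#' @param mu null value (default 0).
#' @return list of class `"group_test"` with fields `t_stat`, `df`,
#'   `p_two_tailed`, `d_z`, `ci95`, `mean`, `n`.
#' @export
one_sample_t <- function(values, mu = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a one-sample t-test")
  if (stats::sd(values) == 0) stop("zero sample SD; t statistic undefined")
  tt <- stats::t.test(values, mu = mu, alternative = "two.sided", conf.level = 0.95)
  structure(
    list(t_stat = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
         p_two_tailed = tt$p.value, d_z = cohens_dz(unname(tt$statistic), n),
         ci95 = as.numeric(tt$conf.int), mean = mean(values), n = n),
    class = "group_test"
  )
}

#' Group-level paired-samples t-test
#'
#' Equivalent to [one_sample_t] on the paired differences `a - b`.
#'
#' @param a,b numeric vectors of equal length (n >= 2), paired by subject.
#' @return a `"group_test"` (see [one_sample_t]).
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  one_sample_t(as.numeric(a) - as.numeric(b))
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, d_z = %.3f, mean = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$df, x$t_stat, x$p_two_tailed, x$d_z, x$mean, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Cohen's d_z for one-sample and paired designs
#'
#' @param t_stat t statistic.
#' @param n sample size (>= 2).
#' @return `t_stat / sqrt(n)`.
#' @export
cohens_dz <- function(t_stat, n) {
  if (n < 2) stop("n must be >= 2")
  t_stat / sqrt(n)
}

#' Bonferroni significance mask
#'
#' Rejects hypothesis i iff `p[i] < alpha / m`, with `m = length(p)`
#' (strict inequality).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param alpha family-wise error level (default 0.05).
#' @return logical vector.
#' @export
bonferroni_mask <- function(p_values, alpha = 0.05) {
  check_pvalues(p_values)
  p_values < alpha / length(p_values)
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Standard step-up procedure: sort p-values ascending, find the largest k
#' with `p_(k) <= k * q / m`, and reject the k smallest.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param q false discovery rate (default 0.05).
#' @return logical vector in the original order.
#' @export
bh_mask <- function(p_values, q = 0.05) {
  check_pvalues(p_values)
  m <- length(p_values)
  o <- order(p_values)
  ok <- p_values[o] <= q * seq_len(m) / m
  k <- if (any(ok)) max(which(ok)) else 0L
  mask <- logical(m)
  if (k > 0L) mask[o[seq_len(k)]] <- TRUE
  mask
}

check_pvalues <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  invisible(p)
}

# vectorised per-row one-sample t against 0 for a vertices x subjects matrix;
# returns list(t, p, effect). Rows with zero SD get t = NA.
rowwise_t <- function(mat) {
  n <- ncol(mat)
  mu <- rowMeans(mat)
  sdv <- sqrt(rowSums((mat - mu)^2) / (n - 1))
  t_stat <- mu / (sdv / sqrt(n))
  t_stat[sdv == 0] <- NA_real_
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  list(t = t_stat, p = p, effect = mu, df = n - 1L)
}
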