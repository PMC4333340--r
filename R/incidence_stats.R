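# Exact categorical statistics: incidence with Clopper-Pearson intervals,
# Fisher's exact 2x2 test with the minimum-likelihood two-sided rule (the
# convention of R's fisher.test, which these analyses historically used),
# and an exact binomial test for laterality bias against 0.5.

#' Incidence estimate with exact binomial confidence interval
#'
#' @param affected_count affected animals, `0 <= affected_count <= n`.
#' @param n animals evaluated, `> 0`.
#' @param conf_level confidence level for the Clopper-Pearson interval.
#' @return an `incidence_estimate`: `count`, `n`, `proportion`, `percent`
#'   (rounded to one decimal for display), `ci_low`, `ci_high`.
#' @examples
#' incidence(351, 4994)   # 7.0% of the F2 population affected
#' @export
incidence <- function(affected_count, n, conf_level = 0.95) {
  if (length(n) != 1L || n <= 0) stop("n must be a positive count")
  k <- affected_count
  if (length(k) != 1L || k < 0 || k > n)
    stop("affected_count must be between 0 and n")
  alpha <- 1 - conf_level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(count = as.integer(k), n = as.integer(n),
                 proportion = k / n, percent = round(100 * k / n, 1L),
                 ci_low = lo, ci_high = hi, conf_level = conf_level),
            class = "incidence_estimate")
}

#' @export
print.incidence_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.0f%% CI %.1f-%.1f%%)\n", x$count, x$n,
              x$percent, 100 * x$conf_level, 100 * x$ci_low,
              100 * x$ci_high))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value by the minimum-likelihood rule: with margins
#' fixed, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (within relative
#' tolerance 1e-7), i.e. the convention of `stats::fisher.test` rather
#' than tail doubling.
#'
#' @param table 2x2 matrix (or coercible) of non-negative counts.
#' @return two-sided p-value in (0, 1].
#' @examples
#' # congenic strain 1 (49/238 affected) vs congenic strain 2 (35/298)
#' fisher_exact_2x2(rbind(c(49, 189), c(35, 263)))   # 0.0059
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0)) stop("cells must be non-negative")
  if (any(tab != round(tab))) stop("cells must be integer counts")
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ]); c1 <- sum(tab[, 1L])
  if (r1 + r2 == 0) stop("table has no observations")
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1L, 1L], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Exact test for laterality bias
#'
#' Two-sided exact test of k right-sided cases among n unilateral cases
#' against the symmetric null probability 0.5. Bilateral cases must be
#' excluded upstream. The default is the exact binomial construction
#' (minimum-likelihood two-sided rule); `method = "fisher"` instead
#' compares the observed split to an equal-sized balanced pseudo-group
#' with [fisher_exact_2x2()], for workflows that route every categorical
#' comparison through Fisher's test.
#'
#' @param k_right right-sided cases, `0 <= k_right <= n_unilateral`.
#' @param n_unilateral unilateral cases, `> 0`.
#' @param method `"binomial"` (default) or `"fisher"`.
#' @return two-sided p-value.
#' @examples
#' side_bias_test(200, 238)   # < 2.2e-16: strong right-side bias
#' @export
side_bias_test <- function(k_right, n_unilateral,
                           method = c("binomial", "fisher")) {
  method <- match.arg(method)
  n <- n_unilateral; k <- k_right
  if (length(n) != 1L || n <= 0) stop("n_unilateral must be positive")
  if (k < 0 || k > n) stop("k_right must be between 0 and n_unilateral")
  if (method == "binomial") {
    probs <- stats::dbinom(0:n, n, 0.5)
    min(1, sum(probs[probs <= probs[k + 1L] * (1 + 1e-7)]))
  } else {
    ref <- c(floor(n / 2), ceiling(n / 2))
    fisher_exact_2x2(rbind(c(k, n - k), ref))
  }
}
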