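## Shared inferential machinery used by every pipeline stage.

#' Hodges-Lehmann effect size with signed-rank confidence interval
#'
#' Point estimate is the median of Walsh averages; the 95% CI is obtained
#' by inverting the Wilcoxon signed-rank test (exact for n <= 25 without
#' ties, normal approximation otherwise), the standard way paired effect
#' sizes are reported throughout this pipeline.
#'
#' @param paired_diffs numeric vector of paired differences
#' @param conf.level confidence level (default 0.95)
#' @return object of class \code{paired_effect}: list with
#'   \code{median}, \code{ci} (length 2), \code{n}, \code{p},
#'   \code{degenerate} (all differences zero)
#' @export
signed_rank_effect <- function(paired_diffs, conf.level = 0.95) {
  d <- paired_diffs[is.finite(paired_diffs)]
  n <- length(d)
  if (n < 6) stop("need at least 6 paired differences for CI inversion")
  if (all(d == d[1])) {
    ## no spread: the estimate is the common value, the interval collapses
    out <- list(median = d[1], ci = c(d[1], d[1]), n = n,
                p = if (d[1] == 0) 1 else NA_real_, degenerate = TRUE)
    class(out) <- "paired_effect"
    return(out)
  }
  exact <- n <= 25 && !any(duplicated(abs(d))) && !any(d == 0)
  wt <- suppressWarnings(stats::wilcox.test(d, conf.int = TRUE,
                                            conf.level = conf.level,
                                            exact = exact, correct = TRUE))
  out <- list(median = unname(wt$estimate),
              ci = unname(as.numeric(wt$conf.int)),
              n = n, p = wt$p.value, degenerate = FALSE)
  class(out) <- "paired_effect"
  out
}

#' @export
print.paired_effect <- function(x, ...) {
  cat(sprintf("paired effect (Hodges-Lehmann): %.4g, 95%% CI [%.4g %.4g], n = %d, p = %.3g\n",
              x$median, x$ci[1], x$ci[2], x$n, x$p))
  invisible(x)
}

#' Monte-Carlo posterior difference of two binomial proportions
#'
#' Uniform Beta(1,1) priors give Beta(k+1, n-k+1) posteriors; the
#' difference p1 - p2 is summarised by the median and the 2.5th/97.5th
#' percentiles of \code{n_samples} paired posterior draws.
#'
#' @param k1,n1 successes / trials in condition 1
#' @param k2,n2 successes / trials in condition 2
#' @param n_samples number of posterior draws (default 1000)
#' @param seed integer seed
#' @param prior "uniform" (Beta(1,1)) or "jeffreys" (Beta(1/2,1/2))
#' @return list with \code{median}, \code{ci}, counts and \code{n_samples}
#' @export
binomial_posterior_diff <- function(k1, n1, k2, n2, n_samples = 1000,
                                    seed = 1L, prior = c("uniform", "jeffreys")) {
  prior <- match.arg(prior)
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n_samples >= 1)
  a <- if (prior == "uniform") 1 else 0.5
  b <- if (prior == "uniform") 1 else 0.5
  set.seed(seed)
  p1 <- stats::rbeta(n_samples, k1 + a, n1 - k1 + b)
  p2 <- stats::rbeta(n_samples, k2 + a, n2 - k2 + b)
  d <- p1 - p2
  list(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
       median = stats::median(d),
       ci = unname(stats::quantile(d, c(0.025, 0.975))),
       n_samples = n_samples)
}

#' Binomial proportion with exact (Clopper-Pearson) confidence interval
#'
#' @param k successes
#' @param n trials
#' @param conf.level confidence level (default 0.95)
#' @return list with \code{proportion} and \code{ci}
#' @export
binomial_proportion_ci <- function(k, n, conf.level = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  bt <- stats::binom.test(k, n, conf.level = conf.level)
  list(proportion = k / n, ci = unname(as.numeric(bt$conf.int)), k = k, n = n)
}

#' Pearson chi-square test against the uniform distribution
#'
#' @param bin_counts integer counts per bin
#' @return list with \code{statistic}, \code{dof}, \code{p}
#' @export
chi_square_uniformity <- function(bin_counts) {
  if (length(bin_counts) < 2) stop("need at least 2 bins")
  ntot <- sum(bin_counts)
  if (ntot <= 0) stop("total count must be positive")
  e <- ntot / length(bin_counts)
  stat <- sum((bin_counts - e)^2 / e)
  dof <- length(bin_counts) - 1L
  list(statistic = stat, dof = dof,
       p = stats::pchisq(stat, dof, lower.tail = FALSE))
}
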