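#' Hartigans' dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and any unimodal distribution function (convex left of
#' the mode, concave right of it, an atom at the mode allowed). It is
#' computed exactly on the empirical CDF by minimizing, over modal
#' positions, the maximal band violation of the greatest-convex-minorant /
#' least-concave-majorant geometry. The statistic lies in (0, 0.25]; two
#' equal point masses attain the maximum 0.25; a sample of identical
#' values is degenerate unimodal with dip 0.
#'
#' @param x numeric sample, n >= 4.
#' @return the dip statistic (numeric scalar).
#' @examples
#' dipStatistic(c(0, 0, 1, 1)) # 0.25, maximally bimodal
#' @export
dipStatistic <- function(x) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) < 4)
    prStop("undefinedStatisticError",
           "dip statistic requires at least 4 observations, got %d",
           length(x))
  .dip_stat_cpp(x)
}

#' Monte-Carlo dip test of unimodality
#'
#' Tests the sample against a uniform(0, 1) null of matched size: the
#' p-value is the fraction of `nBoot` uniform samples whose dip is at
#' least the observed dip. The uniform null is the classical calibration
#' for the dip test (the uniform is the asymptotically least favorable
#' unimodal distribution).
#'
#' @param x numeric sample, n >= 4.
#' @param nBoot number of Monte-Carlo null samples (default 10000).
#' @param seed integer seed for the null draws.
#' @return list with `dip`, `p`, `n_boot`, `seed`.
#' @examples
#' dipTest(c(rnorm(50, 0), rnorm(50, 8)), nBoot = 200, seed = 1)$p
#' @export
dipTest <- function(x, nBoot = 10000, seed = 1) {
  if (nBoot < 1)
    prStop("undefinedStatisticError", "nBoot must be >= 1")
  d <- dipStatistic(x)
  n <- sum(is.finite(x))
  nulls <- withSeed(seed, .dip_null_cpp(n, as.integer(nBoot)))
  list(dip = d, p = mean(nulls >= d), n_boot = as.integer(nBoot),
       seed = as.integer(seed))
}
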